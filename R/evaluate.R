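#' Pearson correlation with a defined degenerate case
#'
#' Standard Pearson coefficient; a constant vector has no defined
#' correlation and is flagged as 0 with a warning.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return correlation coefficient.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("pearson: length mismatch")
  if (length(x) < 2) stop("pearson: need at least 2 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Pearson correlation undefined, returning 0")
    return(0)
  }
  stats::cor(x, y)
}

#' Mean squared error
#' @param x,y numeric vectors of equal length >= 1.
#' @return mean of squared differences.
#' @export
mse <- function(x, y) {
  if (length(x) != length(y)) stop("mse: length mismatch")
  if (length(x) < 1) stop("mse: empty input")
  mean((x - y)^2)
}

#' Classification accuracy
#' @param predicted,truth label vectors of equal length >= 1.
#' @return fraction of exact matches.
#' @export
accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("accuracy: length mismatch")
  if (length(predicted) == 0) stop("accuracy: empty input")
  mean(predicted == truth)
}

#' Cohen's kappa for multi-class agreement
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with expected agreement `p_e`
#' computed from the marginal label frequencies. When every observation
#' carries one single shared label (`p_e = 1`), kappa is defined as 1 for
#' perfect agreement and 0 otherwise, with a warning.
#'
#' @param predicted,truth label vectors of equal length.
#' @return kappa coefficient.
#' @export
cohens_kappa <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("cohens_kappa: length mismatch")
  n <- length(predicted)
  if (n == 0) stop("cohens_kappa: empty input")
  labels <- union(predicted, truth)
  p_o <- mean(predicted == truth)
  pp <- table(factor(predicted, levels = labels)) / n
  pt <- table(factor(truth, levels = labels)) / n
  p_e <- sum(pp * pt)
  if (p_e >= 1 - 1e-12) {
    warning("single shared label: kappa degenerate")
    return(if (p_o == 1) 1 else 0)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Normalize cancer contributions by healthy controls
#'
#' Each cancer entity's estimated proportion in a case is divided by the
#' maximum estimate of that entity across the control samples, putting
#' entities with different control baselines on a comparable scale. When
#' the control maximum is zero, a positive case value maps to `Inf`
#' (detected above any finite competitor) and zero stays zero.
#'
#' @param A_cases cases x entities proportion matrix.
#' @param A_controls controls x entities proportion matrix (same
#'   columns).
#' @param cancer_entities columns to normalize (default
#'   [cancer_entities()] intersected with the columns).
#' @return cases x cancer-entities matrix of normalized contributions.
#' @export
normalize_by_controls <- function(A_cases, A_controls,
                                  cancer_entities = NULL) {
  if (is.null(cancer_entities))
    cancer_entities <- intersect(cancer_entities(), colnames(A_cases))
  if (!all(cancer_entities %in% colnames(A_cases)) ||
      !all(cancer_entities %in% colnames(A_controls)))
    stop("cancer entities missing from cases or controls")
  if (nrow(A_controls) < 1) stop("need at least one control")
  ctrl_max <- apply(A_controls[, cancer_entities, drop = FALSE], 2, max)
  raw <- A_cases[, cancer_entities, drop = FALSE]
  norm <- sweep(raw, 2, ctrl_max, "/")
  norm[raw == 0] <- 0            # 0 / 0 convention
  norm[raw > 0 & rep(ctrl_max == 0, each = nrow(raw))] <- Inf
  norm
}

#' Assign a tissue of origin from normalized cancer contributions
#'
#' The predicted label is the cancer entity with the highest normalized
#' contribution (ties broken by raw contribution, then lexicographically);
#' when every raw cancer contribution is zero the call is `"normal"`.
#' Subtype grouping (CEAD/CESC to CERCA, COAD/READ to COLCA) is applied
#' after the argmax.
#'
#' @param normalized cases x cancer-entities matrix from
#'   [normalize_by_controls()].
#' @param raw matching matrix of raw (un-normalized) contributions.
#' @param group_subtypes apply [group_cancer_subtypes()] to the calls
#'   (default TRUE).
#' @return data.frame with `sample`, `label` and the normalized values.
#' @export
assign_too <- function(normalized, raw, group_subtypes = TRUE) {
  normalized <- as.matrix(normalized); raw <- as.matrix(raw)
  stopifnot(all(dim(normalized) == dim(raw)))
  ents <- colnames(normalized)
  label <- vapply(seq_len(nrow(normalized)), function(i) {
    if (all(raw[i, ] == 0)) return("normal")
    nv <- normalized[i, ]
    cand <- which(nv == max(nv))
    if (length(cand) > 1) {
      rv <- raw[i, cand]
      cand <- cand[rv == max(rv)]
    }
    ents[cand[order(ents[cand])[1]]]
  }, character(1))
  if (group_subtypes) {
    g <- label != "normal"
    label[g] <- group_cancer_subtypes(label[g])
  }
  data.frame(sample = rownames(normalized) %||% seq_len(nrow(normalized)),
             label = label, normalized, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Aggregate blood proportions to complete-blood-count classes
#'
#' Lymphocytes = B + CD4+ T + CD8+ T + NK cells; neutrophils and
#' monocytes pass through. The three classes are renormalized to sum to
#' one; erythroblasts (not reported by a CBC differential) are excluded
#' from the renormalization.
#'
#' @param A proportion matrix (samples x entities) containing the seven
#'   blood entity columns.
#' @return samples x 3 matrix with columns `neutrophils`, `lymphocytes`,
#'   `monocytes`.
#' @export
aggregate_to_cbc_classes <- function(A) {
  A <- as.matrix(A)
  need <- blood_entities()
  if (!all(need %in% colnames(A)))
    stop("missing blood entity column(s): ",
         paste(setdiff(need, colnames(A)), collapse = ", "))
  lymph <- rowSums(A[, c("B", "CD4T", "CD8T", "NK"), drop = FALSE])
  out <- cbind(neutrophils = A[, "neutrophils"],
               lymphocytes = lymph,
               monocytes = A[, "monocytes"])
  s <- rowSums(out)
  s[s == 0] <- 1
  out / s
}

#' Limit of detection from a dilution series
#'
#' Scans tumor fractions in descending order, per replicate: detection
#' holds at a fraction when the estimated contribution of the true tumor
#' entity is positive AND the top cancer contributor is the true entity.
#' The replicate's LOD is the smallest fraction down to which detection
#' holds uninterruptedly from the top; if detection already fails at the
#' highest fraction, the LOD is recorded as that highest fraction and
#' flagged. The summary LOD is the mean over replicates.
#'
#' @param estimates data.frame with columns `fraction`, `replicate`, and
#'   one column per cancer entity holding estimated contributions.
#' @param true_entity name of the spiked-in tumor entity (must be one of
#'   the cancer columns).
#' @param cancer_cols names of the cancer-entity columns; default: all
#'   columns except `fraction` and `replicate`.
#' @return list of class `lod_result`: `per_replicate` (data.frame with
#'   `replicate`, `lod`, `failed_at_top`), `lod` (mean over replicates).
#' @export
limit_of_detection <- function(estimates, true_entity, cancer_cols = NULL) {
  if (is.null(cancer_cols))
    cancer_cols <- setdiff(colnames(estimates), c("fraction", "replicate", "sample"))
  stopifnot(true_entity %in% cancer_cols)
  reps <- sort(unique(estimates$replicate))
  per <- lapply(reps, function(r) {
    e <- estimates[estimates$replicate == r, , drop = FALSE]
    e <- e[order(-e$fraction), , drop = FALSE]
    vals <- as.matrix(e[, cancer_cols, drop = FALSE])
    top <- cancer_cols[max.col(vals, ties.method = "first")]
    ok <- vals[, true_entity] > 0 & top == true_entity
    if (!ok[1])
      return(data.frame(replicate = r, lod = e$fraction[1],
                        failed_at_top = TRUE))
    n_ok <- if (all(ok)) length(ok) else which(!ok)[1] - 1
    data.frame(replicate = r, lod = e$fraction[n_ok], failed_at_top = FALSE)
  })
  per <- do.call(rbind, per)
  structure(list(per_replicate = per, lod = mean(per$lod)),
            class = "lod_result")
}

#' @export
print.lod_result <- function(x, ...) {
  cat(sprintf("<lod_result> mean LOD %.3g%% over %d replicate(s)%s\n",
              x$lod, nrow(x$per_replicate),
              if (any(x$per_replicate$failed_at_top))
                " [detection failed at the top fraction in some replicates]"
              else ""))
  invisible(x)
}
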