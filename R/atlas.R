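#' Configuration for marker-atlas construction
#'
#' Defaults follow the marker-selection procedure used throughout the
#' package: a CpG is a differentially methylated site (DMS) when its
#' methylation ratio differs by at least `margin` from every other entity;
#' sites are chained downstream into regions of at least `min_cpgs` CpGs
#' with consecutive gaps of at most `max_gap` bp and a minimum genomic
#' length of `min_region_len` bp; regions are then scored with a Fisher
#' exact test and can be filtered at `alpha` after multiple-testing
#' correction, or shortlisted to the `top_k` most significant per entity.
#'
#' @param margin minimum one-versus-all methylation-ratio difference
#'   (fraction, default 0.30).
#' @param min_cpgs minimum number of DMS per region (default 4).
#' @param max_gap maximum gap between consecutive chained sites, bp
#'   (default 500).
#' @param min_region_len minimum region length in bp; 50, 100 and 250 are
#'   the conventional choices (default 100).
#' @param alpha significance cutoff for the Fisher test (default 0.001).
#' @param correction `"bonferroni"` or `"none"`.
#' @param top_k regions kept per entity in `"balanced"` marker mode
#'   (default 23).
#' @param replicate_variance_cutoff maximum per-replicate ratio range
#'   tolerated when aggregating replicates (default 0.25).
#' @param min_replicate_depth replicates with total below this do not
#'   enter the variance screen (default 5).
#' @param compare `"each"` enforces the margin against every other entity
#'   individually; `"pooled"` against the count-pooled rest.
#' @param alternative sidedness of the Fisher test (default two-sided).
#' @return A list of class `atlas_config`.
#' @export
atlas_config <- function(margin = 0.30, min_cpgs = 4L, max_gap = 500L,
                         min_region_len = 100L, alpha = 0.001,
                         correction = c("bonferroni", "none"),
                         top_k = 23L,
                         replicate_variance_cutoff = 0.25,
                         min_replicate_depth = 5,
                         compare = c("each", "pooled"),
                         alternative = c("two.sided", "greater", "less")) {
  stopifnot(margin > 0, margin < 1, min_cpgs >= 2, min_region_len > 0,
            alpha > 0, alpha <= 1, max_gap > 0)
  structure(list(margin = margin, min_cpgs = as.integer(min_cpgs),
                 max_gap = as.integer(max_gap),
                 min_region_len = as.integer(min_region_len),
                 alpha = alpha, correction = match.arg(correction),
                 top_k = as.integer(top_k),
                 replicate_variance_cutoff = replicate_variance_cutoff,
                 min_replicate_depth = min_replicate_depth,
                 compare = match.arg(compare),
                 alternative = match.arg(alternative)),
            class = "atlas_config")
}

#' Aggregate replicate CpG tables into one entity
#'
#' CpGs whose methylation-ratio range across replicates exceeds `cutoff`
#' (computed among replicates with total >= `min_depth`) are dropped as
#' highly variant; the remaining counts are summed per CpG. CpGs absent
#' from a replicate simply contribute nothing for that replicate.
#'
#' @param tables list of [cpg_table()] replicates of one entity.
#' @param cutoff maximum tolerated ratio range (default 0.25).
#' @param min_depth minimum replicate total for the variance screen.
#' @param entity label for the aggregated table; defaults to the first
#'   replicate's entity.
#' @return A [cpg_table()] with summed counts.
#' @export
aggregate_replicates <- function(tables, cutoff = 0.25, min_depth = 5,
                                 entity = NULL) {
  if (length(tables) == 0) stop("aggregate_replicates: no replicates given")
  stopifnot(all(vapply(tables, inherits, logical(1), "cpg_table")))
  if (is.null(entity)) entity <- attr(tables[[1]], "entity")
  if (length(tables) == 1) {
    out <- tables[[1]]
    attr(out, "entity") <- entity
    return(out)
  }
  all_df <- do.call(rbind, lapply(seq_along(tables), function(i) {
    t_i <- tables[[i]]
    data.frame(chrom = t_i$chrom, pos = t_i$pos, meth = t_i$meth,
               total = t_i$total, stringsAsFactors = FALSE)
  }))
  key <- paste(all_df$chrom, all_df$pos, sep = "\r")
  meth <- rowsum(all_df$meth, key)
  total <- rowsum(all_df$total, key)
  # ratio range among sufficiently covered replicates
  deep <- all_df$total >= min_depth
  ratio <- all_df$meth[deep] / all_df$total[deep]
  dkey <- key[deep]
  rmin <- tapply(ratio, dkey, min)
  rmax <- tapply(ratio, dkey, max)
  variant <- names(rmin)[(rmax - rmin) > cutoff]
  keep <- !(rownames(meth) %in% variant)
  kk <- rownames(meth)[keep]
  parts <- do.call(rbind, strsplit(kk, "\r", fixed = TRUE))
  if (is.null(parts)) parts <- matrix(character(0), 0, 2)
  cpg_table(chrom = parts[, 1], pos = as.integer(parts[, 2]),
            meth = meth[keep, 1], total = total[keep, 1], entity = entity)
}

# ratio matrix over the CpGs covered (total > 0) in every entity
.common_ratio_matrix <- function(entity_tables) {
  keys <- lapply(entity_tables, function(t)
    paste(t$chrom, t$pos, sep = "\r")[t$total > 0])
  common <- Reduce(intersect, keys)
  if (length(common) == 0)
    return(list(chrom = character(0), pos = integer(0),
                R = matrix(0, 0, length(entity_tables))))
  common <- sort(common)
  R <- vapply(entity_tables, function(t) {
    k <- paste(t$chrom, t$pos, sep = "\r")
    i <- match(common, k)
    t$meth[i] / t$total[i]
  }, numeric(length(common)))
  R <- matrix(R, nrow = length(common))
  parts <- do.call(rbind, strsplit(common, "\r", fixed = TRUE))
  ord <- order(parts[, 1], as.integer(parts[, 2]))
  list(chrom = parts[ord, 1], pos = as.integer(parts[ord, 2]),
       R = R[ord, , drop = FALSE])
}

#' Detect differentially methylated sites (one-versus-all)
#'
#' A CpG is emitted for entity `t` when its methylation ratio differs by at
#' least `margin` from each of the other entities (`compare = "each"`), or
#' from the count-pooled rest (`compare = "pooled"`). Direction is `hyper`
#' when the target ratio exceeds all others, `hypo` when it is below all.
#' Only CpGs covered (total > 0) in every entity are tested; uncovered
#' sites are skipped with a message.
#'
#' @param entity_tables named list of aggregated [cpg_table()]s, one per
#'   entity.
#' @param margin minimum ratio difference (default 0.30).
#' @param compare `"each"` or `"pooled"`; see [atlas_config()].
#' @return data.frame with columns `entity`, `chrom`, `pos`, `direction`,
#'   sorted by (entity, chrom, pos).
#' @export
detect_dms <- function(entity_tables, margin = 0.30,
                       compare = c("each", "pooled")) {
  compare <- match.arg(compare)
  stopifnot(length(entity_tables) >= 2)
  if (is.null(names(entity_tables)))
    names(entity_tables) <- vapply(entity_tables, attr, character(1), "entity")
  n_sites_total <- length(unique(unlist(lapply(entity_tables, function(t)
    paste(t$chrom, t$pos, sep = "\r")))))
  cm <- .common_ratio_matrix(entity_tables)
  skipped <- n_sites_total - length(cm$pos)
  if (skipped > 0)
    message(skipped, " CpG site(s) not covered in all entities; skipped")
  R <- cm$R
  out <- list()
  for (t_idx in seq_along(entity_tables)) {
    rt <- R[, t_idx]
    others <- R[, -t_idx, drop = FALSE]
    if (compare == "each") {
      omax <- do.call(pmax, as.data.frame(others))
      omin <- do.call(pmin, as.data.frame(others))
    } else {
      pm <- Reduce(`+`, lapply(entity_tables[-t_idx], function(t) {
        k <- paste(t$chrom, t$pos, sep = "\r")
        i <- match(paste(cm$chrom, cm$pos, sep = "\r"), k)
        t$meth[i]
      }))
      pd <- Reduce(`+`, lapply(entity_tables[-t_idx], function(t) {
        k <- paste(t$chrom, t$pos, sep = "\r")
        i <- match(paste(cm$chrom, cm$pos, sep = "\r"), k)
        t$total[i]
      }))
      omax <- omin <- pm / pd
    }
    hyper <- (rt - omax) >= margin
    hypo <- (omin - rt) >= margin
    hit <- hyper | hypo
    if (any(hit))
      out[[length(out) + 1]] <- data.frame(
        entity = names(entity_tables)[t_idx],
        chrom = cm$chrom[hit], pos = cm$pos[hit],
        direction = ifelse(hyper[hit], "hyper", "hypo"),
        stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(entity = character(0), chrom = character(0),
                      pos = integer(0), direction = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$entity, res$chrom, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Extend differentially methylated sites to regions
#'
#' Greedy downstream chaining: within one (entity, direction, chromosome)
#' track, consecutive sites at most `max_gap` bp apart form one maximal
#' region `[first_pos, last_pos + 1)`. A region is kept when it contains at
#' least `min_cpgs` sites and spans at least `min_region_len` bp.
#'
#' @param dms data.frame from [detect_dms()].
#' @param min_cpgs minimum number of chained sites (default 4).
#' @param max_gap maximum gap between consecutive sites, bp (default 500).
#' @param min_region_len minimum region length, bp (default 100).
#' @return Region data.frame (`chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `target_entity`, `direction`, `n_cpgs`), coordinate-sorted.
#' @export
extend_to_regions <- function(dms, min_cpgs = 4L, max_gap = 500L,
                              min_region_len = 100L) {
  if (nrow(dms) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = numeric(0), strand = character(0),
                      target_entity = character(0), direction = character(0),
                      n_cpgs = integer(0), stringsAsFactors = FALSE))
  grp <- interaction(dms$entity, dms$direction, dms$chrom, drop = TRUE)
  pieces <- lapply(split(dms, grp), function(g) {
    g <- g[order(g$pos), , drop = FALSE]
    brk <- cumsum(c(0, diff(g$pos) > max_gap))
    do.call(rbind, lapply(split(g$pos, brk), function(p) {
      data.frame(chrom = g$chrom[1], start = min(p), end = max(p) + 1L,
                 target_entity = g$entity[1], direction = g$direction[1],
                 n_cpgs = length(p), stringsAsFactors = FALSE)
    }))
  })
  reg <- do.call(rbind, pieces)
  reg <- reg[reg$n_cpgs >= min_cpgs &
               (reg$end - reg$start) >= min_region_len, , drop = FALSE]
  reg <- reg[order(reg$chrom, reg$start, reg$end, reg$target_entity), ,
             drop = FALSE]
  rownames(reg) <- NULL
  if (nrow(reg) == 0) return(extend_to_regions(dms[0, , drop = FALSE]))
  reg$name <- sprintf("%s_%s_%d_%s", reg$target_entity, reg$chrom,
                      reg$start, reg$direction)
  reg$score <- 0
  reg$strand <- "."
  reg[, c("chrom", "start", "end", "name", "score", "strand",
          "target_entity", "direction", "n_cpgs")]
}

# two-sided conditional exact p for a 2x2 table, via the hypergeometric
# distribution over all tables with the observed margins (same definition
# and 1+1e-7 relative tolerance as stats::fisher.test)
.fisher_p_2x2 <- function(a, b, c, d,
                          alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  m <- a + b; n <- c + d; k <- a + c
  if (m + n == 0) return(1)
  lo <- max(0, k - n); hi <- min(k, m)
  x <- lo:hi
  dens <- stats::dhyper(x, m, n, k)
  obs <- dens[a - lo + 1]
  p <- switch(alternative,
              two.sided = sum(dens[dens <= obs * (1 + 1e-7)]),
              greater = sum(dens[x >= a]),
              less = sum(dens[x <= a]))
  min(1, p)
}

#' Fisher exact test on region-summed CpG counts
#'
#' Tests whether the target entity's region-level methylation differs from
#' the pooled remaining entities, on the 2x2 table
#' `[[meth_t, unmeth_t], [sum_j meth_j, sum_j unmeth_j]]` (j != t).
#' All-zero tables return p = 1 by convention.
#'
#' @param meth,total numeric vectors of region-summed methylated and total
#'   CpG counts, one element per entity.
#' @param target index or name of the target entity.
#' @param alternative sidedness; default two-sided.
#' @return The exact p-value.
#' @export
fisher_test_region <- function(meth, total, target,
                               alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (is.character(target)) target <- match(target, names(meth))
  stopifnot(length(meth) == length(total), !is.na(target))
  if (any(meth > total)) stop("meth exceeds total")
  a <- meth[target]; b <- total[target] - meth[target]
  c_ <- sum(meth[-target]); d <- sum(total[-target]) - c_
  .fisher_p_2x2(a, b, c_, d, alternative)
}

#' Score candidate marker regions
#'
#' Sums per-CpG counts of every entity over each region and attaches the
#' one-versus-rest Fisher exact p-value for the region's target entity.
#'
#' @param entity_tables named list of [cpg_table()]s.
#' @param regions region data.frame from [extend_to_regions()].
#' @param alternative Fisher-test sidedness.
#' @return `regions` with added columns `fisher_p` and per-entity summed
#'   counts kept in attributes `meth_counts` / `total_counts` (entities x
#'   regions matrices).
#' @export
score_regions <- function(entity_tables, regions,
                          alternative = "two.sided") {
  counts <- .sum_counts_over_regions(entity_tables, regions)
  p <- vapply(seq_len(nrow(regions)), function(k) {
    fisher_test_region(counts$M[, k], counts$D[, k],
                       target = regions$target_entity[k],
                       alternative = alternative)
  }, numeric(1))
  regions$fisher_p <- p
  attr(regions, "meth_counts") <- counts$M
  attr(regions, "total_counts") <- counts$D
  regions
}

#' Select marker regions
#'
#' Three modes: `"all"` keeps every candidate; `"significant"` keeps
#' regions whose corrected p-value is at most `alpha` (Bonferroni divisor =
#' number of candidates entering the test); `"balanced"` keeps the `top_k`
#' smallest-p regions per entity (ties broken by longer region, then by
#' genomic coordinate). Output is coordinate-sorted.
#'
#' @param stats scored regions from [score_regions()].
#' @param mode `"all"`, `"significant"` or `"balanced"`.
#' @param alpha significance cutoff (default 0.001).
#' @param correction `"bonferroni"` or `"none"`.
#' @param top_k per-entity shortlist size (default 23).
#' @return The selected subset of `stats`, with a `corrected_p` column.
#' @export
select_markers <- function(stats, mode = c("all", "significant", "balanced"),
                           alpha = 0.001,
                           correction = c("bonferroni", "none"),
                           top_k = 23L) {
  mode <- match.arg(mode)
  correction <- match.arg(correction)
  n_cand <- nrow(stats)
  stats$corrected_p <- if (correction == "bonferroni")
    pmin(1, stats$fisher_p * n_cand) else stats$fisher_p
  keep <- switch(mode,
    all = rep(TRUE, n_cand),
    significant = stats$corrected_p <= alpha,
    balanced = {
      sel <- logical(n_cand)
      for (ent in unique(stats$target_entity)) {
        idx <- which(stats$target_entity == ent)
        if (length(idx) < top_k)
          message("entity '", ent, "' has only ", length(idx),
                  " candidate(s) for top_k = ", top_k, "; keeping all")
        len <- stats$end[idx] - stats$start[idx]
        ord <- idx[order(stats$fisher_p[idx], -len,
                         stats$chrom[idx], stats$start[idx])]
        sel[utils::head(ord, top_k)] <- TRUE
      }
      sel
    })
  out <- stats[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# region-summed count matrices (entities x regions) with a cumsum lookup
.sum_counts_over_regions <- function(entity_tables, regions) {
  J <- length(entity_tables)
  K <- nrow(regions)
  labels <- names(entity_tables) %||%
    vapply(entity_tables, attr, character(1), "entity")
  D <- matrix(0, J, K, dimnames = list(labels, regions$name))
  M <- matrix(0, J, K, dimnames = list(labels, regions$name))
  for (j in seq_len(J)) {
    t_j <- entity_tables[[j]]
    for (ch in unique(regions$chrom)) {
      rk <- which(regions$chrom == ch)
      sites <- t_j[t_j$chrom == ch, , drop = FALSE]
      if (nrow(sites) == 0) next
      cm <- cumsum(sites$meth); cd <- cumsum(sites$total)
      # count sites with start <= pos < end
      up <- findInterval(regions$end[rk] - 1L, sites$pos)
      lo <- findInterval(regions$start[rk] - 1L, sites$pos)
      M[j, rk] <- c(0, cm)[up + 1] - c(0, cm)[lo + 1]
      D[j, rk] <- c(0, cd)[up + 1] - c(0, cd)[lo + 1]
    }
  }
  list(D = D, M = M)
}

#' Build region-level count matrices from per-CpG tables
#'
#' For every region and entity, sums the methylated and total CpG counts of
#' all CpGs falling inside the region interval (0-based half-open); CpGs
#' between chained seed sites are included. In condensed mode the given
#' tables are one-per-tissue aggregates; in full mode pass one table per
#' replicate together with `tissue_map`.
#'
#' @param entity_tables named list of [cpg_table()]s (one per entity, or
#'   one per replicate when `condensed = FALSE`).
#' @param regions region data.frame.
#' @param condensed logical; see above.
#' @param tissue_map character vector mapping replicate rows to tissues
#'   (required when `condensed = FALSE`).
#' @return A [count_atlas()]; regions with zero covered CpGs in some
#'   entity yield (0, 0) cells and are flagged in attribute
#'   `zero_coverage_cells`.
#' @export
build_count_atlas <- function(entity_tables, regions, condensed = TRUE,
                              tissue_map = NULL) {
  if (!condensed && is.null(tissue_map))
    stop("full-atlas mode requires tissue_map")
  counts <- .sum_counts_over_regions(entity_tables, regions)
  atl <- count_atlas(counts$D, counts$M,
                     regions[, c("chrom", "start", "end", "name")],
                     entities = rownames(counts$D),
                     tissue_map = if (!condensed) tissue_map)
  zero <- which(counts$D == 0, arr.ind = TRUE)
  attr(atl, "zero_coverage_cells") <- zero
  atl
}

#' Build a marker atlas end-to-end
#'
#' Runs DMS detection, region extension, region scoring, marker selection
#' and count-matrix construction in one call.
#'
#' @param entity_tables named list of aggregated [cpg_table()]s.
#' @param config an [atlas_config()].
#' @param mode marker-selection mode, see [select_markers()].
#' @param condensed,tissue_map see [build_count_atlas()].
#' @return list with `regions` (scored, selected), `atlas`
#'   (a [count_atlas()]), and `dms` (the detected sites).
#' @export
build_atlas <- function(entity_tables, config = atlas_config(),
                        mode = "all", condensed = TRUE, tissue_map = NULL) {
  dms <- detect_dms(entity_tables, margin = config$margin,
                    compare = config$compare)
  regions <- extend_to_regions(dms, min_cpgs = config$min_cpgs,
                               max_gap = config$max_gap,
                               min_region_len = config$min_region_len)
  stats <- score_regions(entity_tables, regions,
                         alternative = config$alternative)
  sel <- select_markers(stats, mode = mode, alpha = config$alpha,
                        correction = config$correction,
                        top_k = config$top_k)
  atl <- build_count_atlas(entity_tables, sel, condensed = condensed,
                           tissue_map = tissue_map)
  list(regions = sel, atlas = atl, dms = dms)
}
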