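#' Deconvolution configuration
#'
#' Settings for the coverage-weighted matrix-factorization fit. The
#' objective is the coverage-weighted mean absolute error between observed
#' cfDNA methylation ratios and the product `A G` of proportions and atlas
#' ratios, plus an L1 tether pulling the refined atlas `G` toward the
#' observed atlas ratios (known entities only, weighted by atlas
#' coverage). Optimization uses Adam on unconstrained parameters: rows of
#' `A` through a normalized-exponential (softmax) map, entries of `G`
#' through a logistic map, so the simplex and [0,1] constraints hold at
#' every iterate.
#'
#' @param n_unknowns number of unknown contributors `h` to learn from the
#'   samples (default 0).
#' @param max_iters maximum Adam iterations (default 5000).
#' @param learning_rate Adam step size (default 0.01).
#' @param tolerance early-stopping threshold: stop when the objective
#'   improves by less than this over `patience` iterations (default 1e-6).
#' @param patience length of the early-stopping window (default 100).
#' @param lambda weight of the atlas tether (default 1.0).
#' @param beta1,beta2,epsilon Adam moment decay constants and stabilizer.
#' @param seed integer seed controlling the initialization jitter of
#'   unknown profiles; the optimizer itself is deterministic.
#' @return list of class `deconv_config`.
#' @export
deconv_config <- function(n_unknowns = 0L, max_iters = 5000L,
                          learning_rate = 0.01, tolerance = 1e-6,
                          patience = 100L, lambda = 1.0,
                          beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                          seed = 0L) {
  stopifnot(n_unknowns >= 0, max_iters >= 1, learning_rate > 0,
            tolerance > 0, lambda >= 0)
  structure(list(n_unknowns = as.integer(n_unknowns),
                 max_iters = as.integer(max_iters),
                 learning_rate = learning_rate, tolerance = tolerance,
                 patience = as.integer(patience), lambda = lambda,
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 seed = as.integer(seed)),
            class = "deconv_config")
}

#' Methylation ratio matrix
#'
#' `R = M / D` where `D > 0`; cells with zero total count are missing
#' (`NA`) and carry no information downstream.
#'
#' @param D,M count matrices, `M <= D` cell-wise.
#' @return numeric matrix with `NA` at masked (zero-coverage) cells.
#' @export
compute_ratios <- function(D, M) {
  if (any(M > D + 1e-9)) stop("compute_ratios: M exceeds D")
  R <- M / D
  R[D == 0] <- NA_real_
  R
}

#' Per-sample coverage weights
#'
#' Each marker region is weighted by its total CpG count so that regions
#' with better-estimated methylation ratios dominate the objective;
#' weights are normalized to sum to one per sample and zero-coverage
#' regions get weight zero.
#'
#' @param D cfDNA total-count matrix (samples x regions).
#' @return weight matrix with rows summing to 1.
#' @export
compute_weights <- function(D) {
  rs <- rowSums(D)
  if (any(rs == 0)) {
    nm <- rownames(D) %||% as.character(seq_len(nrow(D)))
    stop("sample '", nm[which(rs == 0)[1]], "' has zero coverage everywhere")
  }
  D / rs
}

# impute masked atlas ratio cells with the cross-entity region mean
# (0.5 when a region is masked in every entity)
.impute_ratios <- function(R) {
  if (!anyNA(R)) return(R)
  colmean <- colMeans(R, na.rm = TRUE)
  colmean[is.nan(colmean)] <- 0.5
  idx <- which(is.na(R), arr.ind = TRUE)
  R[idx] <- colmean[idx[, 2]]
  R
}

#' Nonnegative least-squares deconvolution
#'
#' The classical reference-based baseline: each sample's ratio profile is
#' regressed on the atlas rows under nonnegativity, and the solution is
#' renormalized to the simplex (uniform when the NNLS solution is
#' identically zero). Masked cfDNA cells are excluded from the fit;
#' `R_atlas` must contain no masked cells (impute first).
#'
#' @param R_cfdna samples x regions ratio matrix (may contain `NA`).
#' @param R_atlas entities x regions ratio matrix (no `NA`).
#' @return proportion matrix (samples x entities), rows on the simplex.
#' @export
nnls_deconvolve <- function(R_cfdna, R_atlas) {
  if (anyNA(R_atlas))
    stop("R_atlas contains masked cells; impute before NNLS")
  R_cfdna <- matrix(R_cfdna, ncol = ncol(R_atlas),
                    dimnames = if (is.matrix(R_cfdna)) dimnames(R_cfdna))
  J <- nrow(R_atlas)
  if (ncol(R_atlas) < J)
    warning("fewer regions than entities: system is under-determined")
  X <- t(R_atlas)
  A <- matrix(0, nrow(R_cfdna), J,
              dimnames = list(rownames(R_cfdna), rownames(R_atlas)))
  for (i in seq_len(nrow(R_cfdna))) {
    r <- R_cfdna[i, ]
    use <- !is.na(r)
    if (!any(use)) stop("sample ", i, " has no covered regions")
    a <- if (J == 1) {
      max(0, sum(X[use, 1] * r[use]) / max(sum(X[use, 1]^2), 1e-12))
    } else {
      pracma::lsqnonneg(X[use, , drop = FALSE], r[use])$x
    }
    s <- sum(a)
    A[i, ] <- if (s > 0) a / s else rep(1 / J, J)
  }
  A
}

#' Learn unknown contributors from deconvolution residuals
#'
#' Repeats `h` times: deconvolve the samples against the current atlas by
#' NNLS, form per-cell residuals `R - A0 R_atlas`, and define the unknown
#' profile per region as the clipped sum of the reconstruction's
#' coverage-weighted mean and the coverage-weighted mean residual across
#' samples (weights column-normalized from `W`). The profile is appended
#' as a new atlas row with pseudo-counts: per-region total = median across
#' atlas rows, methylated = round(profile x total). A small seeded jitter
#' makes the seed the single source of randomness.
#'
#' @param R_cfdna samples x regions ratio matrix (may contain `NA`).
#' @param W per-sample coverage weights from [compute_weights()].
#' @param D_atlas,M_atlas,R_atlas current atlas counts and ratios
#'   (`R_atlas` without masked cells).
#' @param h number of unknown rows to append.
#' @param seed integer seed for the initialization jitter.
#' @return list with extended `D`, `M`, `R` and `labels`
#'   (`unknown_1` ... appended).
#' @export
estimate_unknowns <- function(R_cfdna, W, D_atlas, M_atlas, R_atlas, h,
                              seed = 0L) {
  labels <- rownames(R_atlas) %||% paste0("entity_", seq_len(nrow(R_atlas)))
  if (h == 0)
    return(list(D = D_atlas, M = M_atlas, R = R_atlas, labels = labels))
  set.seed(seed)
  Ruse <- R_cfdna
  for (u in seq_len(h)) {
    A0 <- nnls_deconvolve(Ruse, R_atlas)
    recon <- A0 %*% R_atlas
    resid <- Ruse - recon
    # column-normalized coverage weights over samples
    wc <- sweep(W, 2, pmax(colSums(W), 1e-12), "/")
    wc[is.na(Ruse)] <- 0
    recon0 <- recon; recon0[is.na(Ruse)] <- 0
    resid0 <- resid; resid0[is.na(resid)] <- 0
    u_prof <- colSums(wc * recon0) + colSums(wc * resid0)
    covered <- colSums(wc) > 0
    u_prof[!covered] <- colMeans(R_atlas)[!covered]
    u_prof <- pmin(1, pmax(0, u_prof + stats::runif(length(u_prof), -0.01, 0.01)))
    d_new <- apply(D_atlas, 2, stats::median)
    m_new <- round(u_prof * d_new)
    lab <- paste0("unknown_", u)
    D_atlas <- rbind(D_atlas, d_new)
    M_atlas <- rbind(M_atlas, m_new)
    R_atlas <- rbind(R_atlas, u_prof)
    labels <- c(labels, lab)
    rownames(D_atlas) <- rownames(M_atlas) <- rownames(R_atlas) <- labels
  }
  list(D = D_atlas, M = M_atlas, R = R_atlas, labels = labels)
}

.softmax_rows <- function(P) {
  E <- exp(P - apply(P, 1, max))
  E / rowSums(E)
}

#' Fit proportions and refined atlas by weighted-MAE matrix factorization
#'
#' Jointly minimizes
#' `sum_ik w_ik |R_ik - (AG)_ik| + lambda sum_jk v_jk |G_jk - Ratlas_jk|`
#' with `A` on the row simplex (softmax parameterization) and `G` in
#' [0,1] (logistic parameterization), by Adam. `v` are atlas-coverage
#' weights normalized per atlas row; unknown rows and zero-coverage atlas
#' cells carry no tether. `A` is initialized from NNLS and `G` from the
#' atlas ratios. The returned parameters are the best (lowest-objective)
#' iterate, so the final objective never exceeds the initial one.
#'
#' @param R_cfdna samples x regions ratio matrix (`NA` at masked cells).
#' @param W per-sample coverage weights ([compute_weights()]).
#' @param R_atlas (entities + h) x regions ratio matrix, no `NA`.
#' @param D_atlas matching total-count matrix (pseudo-counts for unknown
#'   rows).
#' @param config a [deconv_config()].
#' @param n_known number of leading atlas rows that are known entities
#'   (tethered); remaining rows are unknowns. Default: all rows.
#' @param mask_tether optional logical matrix (same shape as `R_atlas`)
#'   marking cells whose tether weight is forced to zero (e.g. imputed
#'   zero-coverage atlas cells).
#' @return list with `A`, `G`, `loss_trace`, `iterations`.
#' @export
fit_deconvolution <- function(R_cfdna, W, R_atlas, D_atlas,
                              config = deconv_config(),
                              n_known = nrow(R_atlas),
                              mask_tether = NULL) {
  J <- nrow(R_atlas); K <- ncol(R_atlas); N <- nrow(R_cfdna)
  stopifnot(ncol(R_cfdna) == K, nrow(D_atlas) == J, ncol(D_atlas) == K)
  masked <- is.na(R_cfdna)
  Ruse <- R_cfdna; Ruse[masked] <- 0
  Wuse <- W; Wuse[masked] <- 0

  # atlas tether weights: per-row-normalized coverage, known rows only
  v <- D_atlas / pmax(rowSums(D_atlas), 1e-12)
  if (n_known < J) v[(n_known + 1):J, ] <- 0
  if (!is.null(mask_tether)) v[mask_tether] <- 0
  lambda <- config$lambda

  A0 <- nnls_deconvolve(R_cfdna, R_atlas)
  P <- log(A0 + 1e-8)
  eps <- 1e-6
  # qlogis/plogis drop dim attributes; keep J x K shape explicitly
  Q <- matrix(stats::qlogis(pmin(1 - eps, pmax(eps, R_atlas))), J, K)
  sigm <- function(Q) matrix(stats::plogis(Q), J, K)

  mP <- vP <- matrix(0, N, J); mQ <- vQ <- matrix(0, J, K)
  b1 <- config$beta1; b2 <- config$beta2; ae <- config$epsilon
  lr <- config$learning_rate
  loss_fun <- function(A, G) {
    sum(Wuse * abs(A %*% G - Ruse)) + lambda * sum(v * abs(G - R_atlas))
  }
  A <- .softmax_rows(P); G <- sigm(Q)
  best_loss <- loss_fun(A, G)
  best <- list(A = A, G = G)
  trace <- numeric(config$max_iters + 1)
  trace[1] <- best_loss
  it <- 0
  while (it < config$max_iters) {
    it <- it + 1
    E <- A %*% G - Ruse
    S <- Wuse * sign(E)
    gA <- S %*% t(G)
    gG <- crossprod(A, S) + lambda * v * sign(G - R_atlas)
    gP <- A * (gA - rowSums(A * gA))
    gQ <- gG * G * (1 - G)
    mP <- b1 * mP + (1 - b1) * gP; vP <- b2 * vP + (1 - b2) * gP^2
    mQ <- b1 * mQ + (1 - b1) * gQ; vQ <- b2 * vQ + (1 - b2) * gQ^2
    c1 <- 1 - b1^it; c2 <- 1 - b2^it
    P <- P - lr * (mP / c1) / (sqrt(vP / c2) + ae)
    Q <- Q - lr * (mQ / c1) / (sqrt(vQ / c2) + ae)
    A <- .softmax_rows(P); G <- sigm(Q)
    l <- loss_fun(A, G)
    if (!is.finite(l))
      stop("non-finite objective at iteration ", it)
    trace[it + 1] <- l
    if (l < best_loss) { best_loss <- l; best <- list(A = A, G = G) }
    if (it > config$patience &&
        trace[it + 1 - config$patience] - l < config$tolerance) break
  }
  dimnames(best$A) <- list(rownames(R_cfdna), rownames(R_atlas))
  dimnames(best$G) <- dimnames(R_atlas)
  list(A = best$A, G = best$G, loss = best_loss,
       loss_trace = trace[seq_len(it + 1)], iterations = it)
}

# Pearson similarity between rows of G and rows of R_atlas;
# zero-variance rows get similarity 0
.row_similarity <- function(G, R_atlas) {
  sim <- matrix(0, nrow(R_atlas), nrow(G))
  for (j in seq_len(nrow(R_atlas))) {
    for (g in seq_len(nrow(G))) {
      x <- R_atlas[j, ]; y <- G[g, ]
      sim[j, g] <- if (stats::sd(x) == 0 || stats::sd(y) == 0) 0
                   else stats::cor(x, y)
    }
  }
  sim
}

# Hungarian algorithm (shortest augmenting path), minimizes total cost;
# cost is n x m with n <= m; returns the assigned column for each row
.hungarian <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1); way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(Inf, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- Inf; j1 <- 0
      for (j in seq_len(m)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          if (p[j + 1] > 0) u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else minv[j + 1] <- minv[j + 1] - delta
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0) ans[p[j + 1]] <- j
  ans
}

#' Re-identify atlas entities after refinement
#'
#' Matches each atlas entity to the most similar row of the refined ratio
#' matrix `G` (Pearson correlation between rows), as an optimal one-to-one
#' bipartite assignment; G rows left unmatched are labeled
#' `unknown_1`, `unknown_2`, ... in row order.
#'
#' @param G refined ratio matrix ((entities + h) x regions).
#' @param R_atlas observed atlas ratio matrix (entities x regions).
#' @param labels atlas entity labels; default `rownames(R_atlas)`.
#' @return character vector: one label per row of `G`.
#' @export
reidentify_entities <- function(G, R_atlas, labels = rownames(R_atlas)) {
  if (nrow(G) < nrow(R_atlas))
    stop("G must have at least as many rows as R_atlas")
  if (is.null(labels)) labels <- paste0("entity_", seq_len(nrow(R_atlas)))
  sim <- .row_similarity(G, R_atlas)
  assign <- .hungarian(-sim)
  out <- rep(NA_character_, nrow(G))
  out[assign] <- labels
  if (anyNA(out))
    out[is.na(out)] <- paste0("unknown_", seq_len(sum(is.na(out))))
  out
}

#' Deconvolve cfDNA mixtures against a reference atlas
#'
#' Full pipeline: methylation ratios for atlas and mixtures, per-sample
#' coverage weights, residual-based estimation of `h` unknown contributor
#' profiles, the coverage-weighted matrix-factorization fit, and
#' re-identification of the refined atlas rows. Deterministic given
#' `config$seed`.
#'
#' @param mixture a [mixture_counts()].
#' @param atlas a [count_atlas()] over the same regions in the same order.
#' @param config a [deconv_config()].
#' @return Object of class `deconv_result`: `proportions` (samples x
#'   (entities + h), columns named by the identity map, rows on the
#'   simplex), `G` (refined atlas ratios), `identity_map`, `loss_trace`,
#'   `nnls` (the NNLS baseline proportions over known entities), and
#'   `config`.
#' @export
deconvolve <- function(mixture, atlas, config = deconv_config()) {
  stopifnot(inherits(mixture, "methyl_counts"), inherits(atlas, "methyl_counts"))
  ra <- atlas$regions; rm_ <- mixture$regions
  if (nrow(ra) != nrow(rm_) ||
      !all(ra$chrom == rm_$chrom & ra$start == rm_$start & ra$end == rm_$end)) {
    bad <- if (nrow(ra) != nrow(rm_)) 1 else
      which(!(ra$chrom == rm_$chrom & ra$start == rm_$start &
                ra$end == rm_$end))[1]
    stop(sprintf("region mismatch between mixture and atlas (first at row %d: %s:%d-%d vs %s:%d-%d)",
                 bad, rm_$chrom[min(bad, nrow(rm_))], rm_$start[min(bad, nrow(rm_))],
                 rm_$end[min(bad, nrow(rm_))], ra$chrom[min(bad, nrow(ra))],
                 ra$start[min(bad, nrow(ra))], ra$end[min(bad, nrow(ra))]))
  }
  R_cfdna <- compute_ratios(mixture$D, mixture$M)
  R_atlas_raw <- compute_ratios(atlas$D, atlas$M)
  imputed <- is.na(R_atlas_raw)
  R_atlas <- .impute_ratios(R_atlas_raw)
  W <- compute_weights(mixture$D)
  n_known <- nrow(R_atlas)
  ext <- estimate_unknowns(R_cfdna, W, atlas$D, atlas$M, R_atlas,
                           h = config$n_unknowns, seed = config$seed)
  mask_tether <- rbind(imputed,
                       matrix(FALSE, nrow(ext$R) - n_known, ncol(ext$R)))
  fit <- fit_deconvolution(R_cfdna, W, ext$R, ext$D, config,
                           n_known = n_known, mask_tether = mask_tether)
  idmap <- reidentify_entities(fit$G, R_atlas, labels = atlas$labels)
  A <- fit$A
  colnames(A) <- idmap
  rownames(A) <- mixture$labels
  structure(list(proportions = A, G = fit$G, identity_map = idmap,
                 loss = fit$loss, loss_trace = fit$loss_trace,
                 nnls = nnls_deconvolve(R_cfdna, R_atlas),
                 config = config),
            class = "deconv_result")
}

#' @export
print.deconv_result <- function(x, ...) {
  cat(sprintf("<deconv_result> %d sample(s) x %d contributor(s); best objective %.6g after %d iterations\n",
              nrow(x$proportions), ncol(x$proportions),
              x$loss, length(x$loss_trace) - 1))
  invisible(x)
}
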