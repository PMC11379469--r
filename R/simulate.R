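#' Generate a synthetic reference atlas
#'
#' Builds a count atlas with a planted block structure: a share of the
#' regions is split evenly among entities as discriminative markers
#' (methylation ratio near `owner_high` for the owning entity, near
#' `other_low` for the rest), the remainder are shared background regions
#' with a common ratio. Counts are drawn binomially at a Poisson depth
#' around `depth`. The noise-free ratio matrix is returned alongside.
#'
#' @param n_entities number of atlas entities (default 13).
#' @param n_regions number of marker regions (must be >= `n_entities`).
#' @param depth mean per-region total CpG count (default 100).
#' @param seed integer seed.
#' @param owner_high,other_low center of the discriminative ratios.
#' @param specific_frac fraction of regions that are entity-specific
#'   (default 0.8).
#' @param entities entity labels; defaults to the canonical 13-entity set
#'   when `n_entities` is 13, else `entity_1`, ...
#' @return list with `atlas` (a [count_atlas()]) and `ratios` (the true
#'   entities x regions ratio matrix).
#' @export
make_synthetic_atlas <- function(n_entities = 13L, n_regions = 10L * n_entities,
                                 depth = 100, seed = 1L,
                                 owner_high = 0.9, other_low = 0.1,
                                 specific_frac = 0.8, entities = NULL) {
  stopifnot(n_regions >= n_entities)
  set.seed(seed)
  if (is.null(entities)) {
    entities <- if (n_entities == 13)
      c(blood_entities(), cancer_entities())
    else paste0("entity_", seq_len(n_entities))
  }
  n_spec <- max(n_entities, floor(specific_frac * n_regions))
  ratios <- matrix(0, n_entities, n_regions)
  owner <- rep(seq_len(n_entities), length.out = n_spec)
  for (k in seq_len(n_spec)) {
    ratios[, k] <- pmin(1, pmax(0, stats::rnorm(n_entities, other_low, 0.03)))
    ratios[owner[k], k] <- pmin(1, pmax(0, stats::rnorm(1, owner_high, 0.03)))
  }
  if (n_spec < n_regions)
    for (k in (n_spec + 1):n_regions)
      ratios[, k] <- stats::runif(1, 0.2, 0.8)
  D <- matrix(stats::rpois(n_entities * n_regions, depth),
              n_entities, n_regions)
  M <- matrix(stats::rbinom(n_entities * n_regions, D, ratios),
              n_entities, n_regions)
  regions <- data.frame(chrom = "chrS",
                        start = seq_len(n_regions) * 1000L,
                        end = seq_len(n_regions) * 1000L + 500L,
                        stringsAsFactors = FALSE)
  regions$name <- paste0("region_", seq_len(n_regions))
  rownames(ratios) <- entities
  colnames(ratios) <- regions$name
  list(atlas = count_atlas(D, M, regions, entities = entities),
       ratios = ratios)
}

#' Draw mixture proportions from a Dirichlet distribution
#'
#' @param n_samples number of samples.
#' @param alpha Dirichlet concentration: a scalar (symmetric) or a vector
#'   of one positive value per entity (default symmetric 1.0).
#' @param n_entities number of entities, required when `alpha` is scalar.
#' @param seed integer seed.
#' @return samples x entities matrix with rows on the simplex.
#' @export
sample_proportions <- function(n_samples, alpha = 1, n_entities = NULL,
                               seed = 1L) {
  if (length(alpha) == 1) {
    stopifnot(!is.null(n_entities))
    alpha <- rep(alpha, n_entities)
  }
  stopifnot(all(alpha > 0))
  set.seed(seed)
  J <- length(alpha)
  g <- matrix(stats::rgamma(n_samples * J, shape = rep(alpha, each = n_samples)),
              n_samples, J)
  g / rowSums(g)
}

#' Synthesize cfDNA mixture counts
#'
#' The expected region ratio of each sample is `(A ratios)_ik`; total
#' counts are Poisson around the per-region mean depth (optionally
#' heteroscedastic via log-normal per-region multipliers) and methylated
#' counts binomial given totals. `noise = "none"` returns the exact
#' expected counts `M = r D` at constant depth (real-valued), for
#' noise-free oracle constructions.
#'
#' @param A samples x entities proportion matrix (rows on the simplex).
#' @param ratios entities x regions true ratio matrix.
#' @param mean_depth mean total CpG count per region.
#' @param seed integer seed.
#' @param noise `"binomial"` (default) or `"none"`.
#' @param heteroscedastic if `TRUE`, per-region depth multipliers are
#'   drawn log-normal(0, `depth_sdlog`), giving order-of-magnitude
#'   coverage differences between regions.
#' @param depth_sdlog sdlog of the multipliers (default 1.2, roughly a
#'   10-fold interdecile depth range).
#' @param region_template optional region data.frame to stamp on the
#'   output (defaults to synthetic coordinates).
#' @return a [mixture_counts()]; the per-region mean depths used are kept
#'   in attribute `region_depth`.
#' @export
synthesize_mixture_counts <- function(A, ratios, mean_depth = 100,
                                      seed = 1L, noise = c("binomial", "none"),
                                      heteroscedastic = FALSE,
                                      depth_sdlog = 1.2,
                                      region_template = NULL) {
  noise <- match.arg(noise)
  stopifnot(ncol(A) == nrow(ratios))
  set.seed(seed)
  N <- nrow(A); K <- ncol(ratios)
  Rexp <- A %*% ratios
  if (any(Rexp < -1e-9 | Rexp > 1 + 1e-9))
    warning("expected ratios outside [0,1]; clipping")
  Rexp <- pmin(1, pmax(0, Rexp))
  depth_k <- rep(mean_depth, K)
  if (heteroscedastic)
    depth_k <- mean_depth * stats::rlnorm(K, 0, depth_sdlog)
  if (noise == "none") {
    D <- matrix(rep(depth_k, each = N), N, K)
    M <- Rexp * D
  } else {
    D <- matrix(stats::rpois(N * K, rep(depth_k, each = N)), N, K)
    M <- matrix(stats::rbinom(N * K, D, Rexp), N, K)
  }
  regions <- region_template %||% data.frame(
    chrom = "chrS", start = seq_len(K) * 1000L,
    end = seq_len(K) * 1000L + 500L,
    name = colnames(ratios) %||% paste0("region_", seq_len(K)),
    stringsAsFactors = FALSE)
  out <- mixture_counts(D, M, regions,
                        samples = rownames(A) %||% paste0("sample_", seq_len(N)))
  attr(out, "region_depth") <- depth_k
  out
}

#' Add an unknown contributor to a mixture design
#'
#' Draws one extra entity with a random uniform methylation profile and
#' mixes it in at a per-sample proportion drawn from `proportion_range`;
#' existing proportions are rescaled so rows remain on the simplex.
#'
#' @param A samples x entities proportion matrix.
#' @param ratios entities x regions true ratio matrix.
#' @param proportion_range range of the unknown's proportion, inside
#'   (0, 1) (default c(0.05, 0.3)).
#' @param seed integer seed.
#' @return list with `A` (extra `unknown` column), `ratios` (extra row)
#'   and `profile` (the unknown's ratio vector).
#' @export
inject_unknown <- function(A, ratios, proportion_range = c(0.05, 0.3),
                           seed = 1L) {
  stopifnot(proportion_range[1] >= 0, proportion_range[2] < 1,
            proportion_range[1] <= proportion_range[2])
  set.seed(seed)
  profile <- stats::runif(ncol(ratios))
  p <- stats::runif(nrow(A), proportion_range[1], proportion_range[2])
  A2 <- cbind(A * (1 - p), unknown = p)
  colnames(A2) <- c(colnames(A), "unknown")
  ratios2 <- rbind(ratios, unknown = profile)
  list(A = A2, ratios = ratios2, profile = profile)
}

#' Default tumor-fraction grid for dilution series
#' @return the 12-value percentage grid from 50 down to 0.1.
#' @export
dilution_fractions <- function() c(50, 25, 12.5, 10, 7.5, 5, 4, 3, 2, 1, 0.5, 0.1)

#' Build an in-silico tumor dilution series
#'
#' For each tumor fraction `f` (percent) and replicate, the expected
#' region ratio is `(f/100) * tumor profile + (1 - f/100) * background`,
#' and counts are drawn at `mean_depth` (default 6, the shallow
#' whole-genome regime in which detection limits are measured).
#'
#' @param tumor_entity name or index of the tumor row in `ratios`.
#' @param ratios entities x regions true ratio matrix.
#' @param background ratio vector of the healthy cfDNA background;
#'   default: proportion-weighted blood-entity mixture if the canonical
#'   blood labels are present, else the column mean of the non-tumor rows.
#' @param fractions percentage grid, descending (default
#'   [dilution_fractions()]).
#' @param replicates replicates per fraction (default 10).
#' @param mean_depth mean per-region total count (default 6).
#' @param seed integer seed.
#' @return list with `mixtures` (a [mixture_counts()], rows ordered by
#'   fraction then replicate), `design` (data.frame: sample, fraction,
#'   replicate) and `truth` (true tumor fraction per sample, 0-1 scale).
#' @export
make_dilution_series <- function(tumor_entity, ratios, background = NULL,
                                 fractions = dilution_fractions(),
                                 replicates = 10L, mean_depth = 6,
                                 seed = 1L) {
  stopifnot(all(fractions > 0), all(fractions <= 100), replicates >= 1)
  if (is.character(tumor_entity))
    tumor_entity <- match(tumor_entity, rownames(ratios))
  stopifnot(!is.na(tumor_entity))
  tumor <- ratios[tumor_entity, ]
  if (is.null(background)) {
    bl <- intersect(blood_entities(), rownames(ratios))
    background <- if (length(bl) > 0)
      colMeans(ratios[bl, , drop = FALSE])
    else colMeans(ratios[-tumor_entity, , drop = FALSE])
  }
  design <- expand.grid(replicate = seq_len(replicates),
                        fraction = fractions)[, c("fraction", "replicate")]
  design <- design[order(-design$fraction, design$replicate), ]
  rownames(design) <- NULL
  f <- design$fraction / 100
  Rexp <- outer(f, tumor) + outer(1 - f, background)
  set.seed(seed)
  N <- nrow(design); K <- ncol(ratios)
  D <- matrix(stats::rpois(N * K, mean_depth), N, K)
  M <- matrix(stats::rbinom(N * K, D, pmin(1, pmax(0, Rexp))), N, K)
  regions <- data.frame(chrom = "chrS", start = seq_len(K) * 1000L,
                        end = seq_len(K) * 1000L + 500L,
                        name = colnames(ratios) %||% paste0("region_", seq_len(K)),
                        stringsAsFactors = FALSE)
  design$sample <- sprintf("f%g_rep%d", design$fraction, design$replicate)
  mx <- mixture_counts(D, M, regions, samples = design$sample)
  list(mixtures = mx, design = design[, c("sample", "fraction", "replicate")],
       truth = f)
}
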