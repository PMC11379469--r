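# Shared fixtures and independent oracles.

# Two-sided Fisher exact p by full hypergeometric enumeration over the
# fixed margins, from log-binomial coefficients only (independent of the
# dhyper-based implementation path).
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m + n == 0) return(1)
  x <- max(0, k - n):min(k, m)
  p <- exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  pobs <- exp(lchoose(m, a) + lchoose(n, k - a) - lchoose(m + n, k))
  min(1, sum(p[p <= pobs * (1 + 1e-7)]))
}

# small per-CpG tables with a planted marker block: entity 1 fully
# methylated over `block_pos`, all entities otherwise at `base_ratio`
planted_block_tables <- function(n_entities = 4, block_pos = c(100, 180, 300, 450),
                                 base_ratio = 0.5, depth = 50,
                                 n_background = 30, seed = 1) {
  set.seed(seed)
  bg_pos <- sort(sample(setdiff(seq(1000, 50000, by = 10), block_pos),
                        n_background))
  pos <- c(block_pos, bg_pos)
  lapply(seq_len(n_entities), function(j) {
    r <- rep(base_ratio, length(pos))
    if (j == 1) r[seq_along(block_pos)] <- 1
    else r[seq_along(block_pos)] <- 0
    cpg_table(chrom = rep("chr1", length(pos)), pos = pos,
              meth = round(r * depth), total = rep(depth, length(pos)),
              entity = paste0("ent", j))
  })
}

# named list wrapper
named_tables <- function(tables) {
  names(tables) <- vapply(tables, attr, character(1), "entity")
  tables
}

# noiseless exactly-representable mixture setup shared by several tests
noiseless_setup <- function(n_entities = 4, n_regions = 50, n_samples = 10,
                            seed = 5) {
  syn <- make_synthetic_atlas(n_entities, n_regions, depth = 1e6, seed = seed)
  A <- sample_proportions(n_samples, 1, n_entities, seed = seed + 1)
  colnames(A) <- syn$atlas$labels
  R_atlas <- compute_ratios(syn$atlas$D, syn$atlas$M)
  mx <- synthesize_mixture_counts(A, R_atlas, mean_depth = 1000,
                                  seed = seed + 2, noise = "none",
                                  region_template = syn$atlas$regions)
  list(syn = syn, A = A, R_atlas = R_atlas, mx = mx)
}
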