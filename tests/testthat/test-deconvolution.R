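test_that("ratios and weights follow their definitions", {
  D <- rbind(c(10, 0, 7), c(10, 30, 60))
  M <- rbind(c(5, 0, 7), c(1, 3, 6))
  R <- compute_ratios(D, M)
  expect_equal(R[1, ], c(0.5, NA, 1.0))
  expect_error(compute_ratios(D, D + 1), "exceeds")

  W <- compute_weights(rbind(c(10, 30, 60), c(5, 0, 5)))
  expect_equal(W[1, ], c(0.1, 0.3, 0.6))
  expect_equal(W[2, ], c(0.5, 0, 0.5))
  expect_equal(unname(compute_weights(matrix(7, 2, 4))[1, ]), rep(0.25, 4))
  expect_error(compute_weights(rbind(c(1, 1), c(0, 0))), "zero coverage")
})

test_that("NNLS recovers proportions on identity and noiseless designs", {
  R_atlas <- rbind(c(1, 0), c(0, 1))
  expect_equal(unname(nnls_deconvolve(matrix(c(0.3, 0.7), 1), R_atlas)[1, ]),
               c(0.3, 0.7), tolerance = 1e-10)
  # a sample equal to an atlas row maps to the indicator
  s <- noiseless_setup()
  A1 <- nnls_deconvolve(s$R_atlas[2, , drop = FALSE], s$R_atlas)
  expect_equal(unname(A1[1, ]), c(0, 1, 0, 0), tolerance = 1e-8)
  # random noiseless 4-entity mixtures on 50 regions
  R_mix <- compute_ratios(s$mx$D, s$mx$M)
  A_hat <- nnls_deconvolve(R_mix, s$R_atlas)
  expect_lt(max(abs(A_hat - s$A)), 1e-6)
})

test_that("degenerate NNLS inputs have defined behavior", {
  # all-zero solution -> uniform proportions
  R_atlas <- rbind(c(1, 1), c(1, 1))
  A <- nnls_deconvolve(matrix(c(0, 0), 1), R_atlas)
  expect_equal(unname(A[1, ]), c(0.5, 0.5))
  expect_warning(nnls_deconvolve(matrix(0.5, 1, 1), matrix(0.5, 2, 1)),
                 "under-determined")
  expect_error(nnls_deconvolve(matrix(0.5, 1, 2), rbind(c(NA, 1), c(0, 1))),
               "masked")
})

test_that("estimate_unknowns appends exactly h rows with valid pseudo-counts", {
  s <- noiseless_setup()
  R_mix <- compute_ratios(s$mx$D, s$mx$M)
  W <- compute_weights(s$mx$D)
  ext0 <- estimate_unknowns(R_mix, W, s$syn$atlas$D, s$syn$atlas$M,
                            s$R_atlas, h = 0)
  expect_identical(ext0$R, s$R_atlas)
  ext2 <- estimate_unknowns(R_mix, W, s$syn$atlas$D, s$syn$atlas$M,
                            s$R_atlas, h = 2, seed = 4)
  expect_equal(nrow(ext2$R), nrow(s$R_atlas) + 2)
  expect_equal(utils::tail(ext2$labels, 2), c("unknown_1", "unknown_2"))
  expect_true(all(ext2$R >= 0 & ext2$R <= 1))
  expect_true(all(ext2$M <= ext2$D + 1e-9))
  # zero-residual limit: the appended profile is the coverage-weighted
  # mean reconstruction, i.e. close to the weighted mean cfDNA profile
  wc <- sweep(W, 2, colSums(W), "/")
  expect_lt(max(abs(ext2$R[5, ] - colSums(wc * R_mix))), 0.0101)  # jitter bound
})

test_that("the factorization fit respects constraints and descends", {
  s <- noiseless_setup(n_samples = 4)
  R_mix <- compute_ratios(s$mx$D, s$mx$M)
  W <- compute_weights(s$mx$D)
  fit <- fit_deconvolution(R_mix, W, s$R_atlas, s$syn$atlas$D,
                           deconv_config(max_iters = 300))
  expect_true(all(abs(rowSums(fit$A) - 1) < 1e-6))
  expect_true(all(fit$A >= 0))
  expect_true(all(fit$G >= 0 & fit$G <= 1))
  # returned parameters are the best iterate, never worse than the start
  expect_lte(fit$loss, fit$loss_trace[1])

  # single sample equal to atlas row j -> indicator on j
  fit1 <- fit_deconvolution(s$R_atlas[3, , drop = FALSE],
                            matrix(1 / ncol(s$R_atlas), 1, ncol(s$R_atlas)),
                            s$R_atlas, s$syn$atlas$D, deconv_config())
  expect_equal(unname(fit1$A[1, ]), c(0, 0, 1, 0), tolerance = 1e-3)
})

test_that("non-finite objectives are reported with the iteration", {
  R <- matrix(c(0.5, NaN), 1, 2)
  R[is.nan(R)] <- NA  # masked cell
  W <- matrix(c(1, 0), 1, 2)
  expect_silent(fit_deconvolution(R, W, matrix(0.5, 1, 2), matrix(10, 1, 2),
                                  deconv_config(max_iters = 5)))
})

test_that("entity re-identification solves the assignment exactly", {
  s <- noiseless_setup()
  perm <- c(3, 1, 4, 2)
  G <- s$R_atlas[perm, ]
  map <- reidentify_entities(G, s$R_atlas)
  expect_equal(map, rownames(s$R_atlas)[perm])

  # extra noise row becomes unknown_1
  set.seed(9)
  G2 <- rbind(s$R_atlas, runif(ncol(s$R_atlas)))
  map2 <- reidentify_entities(G2, s$R_atlas)
  expect_equal(map2, c(rownames(s$R_atlas), "unknown_1"))

  # duplicate rows still yield a one-to-one assignment
  G3 <- s$R_atlas; G3[2, ] <- G3[1, ]
  map3 <- reidentify_entities(G3, s$R_atlas)
  expect_equal(sort(map3), sort(rownames(s$R_atlas)))

  # constant row has similarity 0 but the map stays injective
  G4 <- rbind(s$R_atlas, 0.5)
  expect_equal(reidentify_entities(G4, s$R_atlas)[5], "unknown_1")
})

test_that("deconvolve handles edge cases and degenerate atlases", {
  s <- noiseless_setup()
  # 1-entity atlas: all proportions are 1
  atl1 <- count_atlas(s$syn$atlas$D[1, , drop = FALSE],
                      s$syn$atlas$M[1, , drop = FALSE],
                      s$syn$atlas$regions, entities = "only")
  suppressWarnings(res1 <- deconvolve(s$mx, atl1, deconv_config(max_iters = 10)))
  expect_true(all(res1$proportions == 1))

  # region mismatch names the discordant region
  atl_bad <- s$syn$atlas
  atl_bad$regions$start[3] <- atl_bad$regions$start[3] + 1L
  expect_error(deconvolve(s$mx, atl_bad), "region mismatch.*row 3")
})

test_that("deconvolution is bitwise deterministic under a fixed seed", {
  s <- noiseless_setup(n_samples = 6)
  cfg <- deconv_config(n_unknowns = 1, max_iters = 200, seed = 77)
  r1 <- deconvolve(s$mx, s$syn$atlas, cfg)
  r2 <- deconvolve(s$mx, s$syn$atlas, cfg)
  expect_identical(r1$proportions, r2$proportions)
  expect_identical(r1$G, r2$G)
  expect_identical(r1$loss_trace, r2$loss_trace)
})

test_that("masked cfDNA cells never influence the result", {
  syn <- make_synthetic_atlas(4, 40, depth = 200, seed = 15)
  A <- sample_proportions(6, 1, 4, seed = 16)
  mx <- synthesize_mixture_counts(A, syn$ratios, mean_depth = 50, seed = 17,
                                  region_template = syn$atlas$regions)
  # zero out coverage of some cells
  mx$D[1, 1:5] <- 0; mx$M[1, 1:5] <- 0
  mx2 <- mx
  mx2$M[1, 1:5] <- 0  # stays zero: counts must satisfy M <= D = 0
  cfg <- deconv_config(max_iters = 200, seed = 5)
  r1 <- deconvolve(mx, syn$atlas, cfg)
  # perturbing the (masked) ratio upstream cannot happen through counts;
  # verify instead at the fit level with an explicit ratio perturbation
  R <- compute_ratios(mx$D, mx$M); W <- compute_weights(mx$D)
  R_atlas <- compute_ratios(syn$atlas$D, syn$atlas$M)
  Rp <- R; Rp[1, 1:5] <- NA  # identical mask
  f1 <- fit_deconvolution(R, W, R_atlas, syn$atlas$D, cfg)
  f2 <- fit_deconvolution(Rp, W, R_atlas, syn$atlas$D, cfg)
  expect_identical(f1$A, f2$A)
  expect_true(all(abs(rowSums(r1$proportions) - 1) < 1e-6))
})

test_that("simplex conservation holds across h and noisy inputs", {
  syn <- make_synthetic_atlas(5, 60, depth = 100, seed = 25)
  A <- sample_proportions(8, 0.5, 5, seed = 26)
  mx <- synthesize_mixture_counts(A, syn$ratios, mean_depth = 20, seed = 27,
                                  region_template = syn$atlas$regions)
  for (h in 0:2) {
    res <- deconvolve(mx, syn$atlas,
                      deconv_config(n_unknowns = h, max_iters = 150, seed = h))
    expect_equal(ncol(res$proportions), 5 + h)
    expect_true(all(abs(rowSums(res$proportions) - 1) < 1e-6))
    expect_true(all(res$proportions >= 0))
    expect_true(all(res$G >= 0 & res$G <= 1))
    expect_equal(sum(grepl("^unknown_", res$identity_map)), h)
  }
})
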