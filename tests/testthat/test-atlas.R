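test_that("replicate aggregation sums counts and drops variant CpGs", {
  r1 <- cpg_table("chr1", c(10, 20), meth = c(3, 9), total = c(10, 10), entity = "e")
  r2 <- cpg_table("chr1", c(10, 20), meth = c(2, 1), total = c(10, 10), entity = "e")
  agg <- aggregate_replicates(list(r1, r2), cutoff = 0.25)
  # pos 10: range 0.1 <= 0.25 -> summed; pos 20: range 0.8 -> dropped
  expect_equal(agg$pos, 10L)
  expect_equal(agg$meth, 5)
  expect_equal(agg$total, 20)

  # shallow replicates do not enter the variance screen
  r3 <- cpg_table("chr1", 20, meth = 1, total = 2, entity = "e")
  agg2 <- aggregate_replicates(list(r1, r3), cutoff = 0.25, min_depth = 5)
  expect_true(20 %in% agg2$pos)

  expect_equal(as.data.frame(aggregate_replicates(list(r1))),
               as.data.frame(r1))
  expect_error(aggregate_replicates(list()), "no replicates")
})

test_that("one-vs-all DMS detection enforces the margin against each entity", {
  mk <- function(r, ent) cpg_table("chr1", c(100, 200, 300), meth = round(r * 100),
                                   total = rep(100, 3), entity = ent)
  # site 100: target 0.9 vs others <= 0.60 -> hyper
  # site 200: target 0.9 but one other at 0.65 -> margin 0.25 < 0.30, no DMS
  # site 300: target 0.0 vs others >= 0.30 -> hypo
  tabs <- named_tables(list(mk(c(0.90, 0.90, 0.00), "t"),
                            mk(c(0.55, 0.65, 0.35), "o1"),
                            mk(c(0.60, 0.30, 0.30), "o2")))
  dms <- detect_dms(tabs, margin = 0.30)
  t_hits <- dms[dms$entity == "t", ]
  expect_setequal(t_hits$pos, c(100L, 300L))
  expect_equal(t_hits$direction[t_hits$pos == 100], "hyper")
  expect_equal(t_hits$direction[t_hits$pos == 300], "hypo")
})

test_that("sites not covered in every entity are skipped, not an error", {
  t1 <- cpg_table("chr1", c(10, 20), meth = c(10, 0), total = c(10, 10), entity = "a")
  t2 <- cpg_table("chr1", 10, meth = 0, total = 10, entity = "b")
  expect_message(dms <- detect_dms(named_tables(list(t1, t2)), margin = 0.3),
                 "skipped")
  expect_true(all(dms$pos == 10))
})

test_that("region extension follows the chaining, gap and length rules", {
  mk_dms <- function(pos) data.frame(entity = "e", chrom = "chr1",
                                     pos = pos, direction = "hyper")
  # 4 sites within gaps <= 500 spanning 351 bp -> one region [100, 451)
  r <- extend_to_regions(mk_dms(c(100, 180, 300, 450)),
                         min_cpgs = 4, max_gap = 500, min_region_len = 100)
  expect_equal(nrow(r), 1)
  expect_equal(r$start, 100)
  expect_equal(r$end, 451)
  expect_equal(r$n_cpgs, 4L)

  # gap 300 -> 900 breaks the chain; 3-CpG fragment rejected
  r2 <- extend_to_regions(mk_dms(c(100, 200, 300, 900)),
                          min_cpgs = 4, max_gap = 500, min_region_len = 50)
  expect_equal(nrow(r2), 0)

  # 4 sites spanning 40 bp rejected on length
  r3 <- extend_to_regions(mk_dms(c(100, 110, 120, 139)),
                          min_cpgs = 4, max_gap = 500, min_region_len = 50)
  expect_equal(nrow(r3), 0)

  empty <- data.frame(entity = character(0), chrom = character(0),
                      pos = integer(0), direction = character(0))
  expect_equal(nrow(extend_to_regions(empty)), 0)
})

test_that("emitted regions always satisfy the configured rules (randomized)", {
  set.seed(99)
  for (rep in 1:5) {
    dms <- data.frame(entity = sample(c("a", "b"), 200, TRUE),
                      chrom = sample(c("chr1", "chr2"), 200, TRUE),
                      pos = sample(1:20000, 200),
                      direction = sample(c("hyper", "hypo"), 200, TRUE))
    cfgs <- list(c(4, 500, 100), c(3, 200, 50), c(5, 1000, 250))
    for (cf in cfgs) {
      reg <- extend_to_regions(dms, min_cpgs = cf[1], max_gap = cf[2],
                               min_region_len = cf[3])
      if (nrow(reg) == 0) next
      expect_true(all(reg$n_cpgs >= cf[1]))
      expect_true(all(reg$end - reg$start >= cf[3]))
      for (i in seq_len(nrow(reg))) {
        inside <- dms[dms$entity == reg$target_entity[i] &
                        dms$direction == reg$direction[i] &
                        dms$chrom == reg$chrom[i] &
                        dms$pos >= reg$start[i] & dms$pos < reg$end[i], ]
        expect_true(all(diff(sort(inside$pos)) <= cf[2]))
        expect_gte(nrow(inside), cf[1])
      }
    }
  }
})

test_that("region Fisher p agrees with closed forms and conventions", {
  expect_equal(fisher_test_region(c(5, 5), c(10, 10), 1), 1.0)
  expect_equal(fisher_test_region(c(0, 0), c(0, 0), 1), 1.0)
  expect_equal(fisher_test_region(c(10, 0), c(10, 10), 1),
               oracle_fisher(10, 0, 0, 10), tolerance = 1e-12)
})

test_that("region Fisher p matches both the enumeration oracle and fisher.test", {
  set.seed(3)
  for (i in 1:200) {
    cts <- rpois(4, 10)
    a <- cts[1]; b <- cts[2]; c_ <- cts[3]; d <- cts[4]
    p <- fisher_test_region(c(a, c_), c(a + b, c_ + d), 1)
    expect_equal(p, oracle_fisher(a, b, c_, d), tolerance = 1e-12)
    if (i <= 50)
      expect_equal(p, stats::fisher.test(matrix(c(a, c_, b, d), 2))$p.value,
                   tolerance = 1e-12)
  }
})

test_that("marker selection modes behave and nest correctly", {
  set.seed(8)
  n <- 200
  stats <- data.frame(chrom = "chr1", start = seq_len(n) * 1000,
                      end = seq_len(n) * 1000 + sample(100:500, n, TRUE),
                      name = paste0("r", seq_len(n)),
                      target_entity = rep(c("a", "b", "c", "d"), each = 50),
                      direction = "hyper",
                      fisher_p = 10^runif(n, -12, 0))
  all_m <- select_markers(stats, mode = "all")
  sig <- select_markers(stats, mode = "significant", alpha = 0.001)
  bal <- select_markers(stats, mode = "balanced", top_k = 23)
  expect_equal(nrow(all_m), n)
  expect_true(all(sig$name %in% all_m$name))
  expect_true(all(bal$name %in% all_m$name))
  expect_equal(nrow(bal), 4 * 23)
  expect_true(all(table(bal$target_entity) == 23))
  # Bonferroni arithmetic: p = 1e-7 among 200 candidates -> corrected 2e-5 kept;
  # among 1e5 candidates the same p would be dropped at alpha = 0.001
  expect_true(all(sig$corrected_p <= 0.001))
  expect_equal(sig$corrected_p, pmin(1, sig$fisher_p * n))
  big <- stats; big$fisher_p <- 1e-7
  expect_equal(nrow(select_markers(big, mode = "significant", alpha = 0.001)), n)
  # with "none" no multiplication happens
  none <- select_markers(stats, mode = "significant", alpha = 0.001,
                         correction = "none")
  expect_true(all(none$corrected_p == none$fisher_p))
})

test_that("top_k larger than a candidate pool keeps the whole pool", {
  stats <- data.frame(chrom = "chr1", start = 1:3 * 1000, end = 1:3 * 1000 + 200,
                      name = paste0("r", 1:3), target_entity = "a",
                      direction = "hyper", fisher_p = c(0.1, 0.2, 0.3))
  expect_message(out <- select_markers(stats, mode = "balanced", top_k = 23),
                 "keeping all")
  expect_equal(nrow(out), 3)
})

test_that("count atlas sums per-CpG counts over region intervals", {
  t1 <- cpg_table("chr1", c(100, 180), meth = c(3, 2), total = c(10, 10),
                  entity = "a")
  t2 <- cpg_table("chr1", c(100, 180), meth = c(0, 0), total = c(5, 5),
                  entity = "b")
  regions <- data.frame(chrom = "chr1", start = 100L, end = 181L, name = "r1")
  atl <- build_count_atlas(named_tables(list(t1, t2)), regions)
  expect_equal(unname(atl$M[, 1]), c(5, 0))
  expect_equal(unname(atl$D[, 1]), c(20, 10))

  # full-atlas mode: one row per replicate, tissue mapping retained
  full <- build_count_atlas(named_tables(list(t1, t2)), regions,
                            condensed = FALSE, tissue_map = c("tis", "tis"))
  expect_equal(nrow(full$D), 2)
  expect_equal(full$tissue_map, c("tis", "tis"))

  # empty region list -> 0-column matrices
  empty <- build_count_atlas(named_tables(list(t1, t2)), regions[0, ])
  expect_equal(ncol(empty$D), 0)

  # region with no covered CpGs in one entity is flagged
  t3 <- cpg_table("chr2", 5, meth = 1, total = 2, entity = "c")
  atl2 <- build_count_atlas(named_tables(list(t1, t3)), regions)
  expect_equal(unname(atl2$D[2, 1]), 0)
  expect_equal(nrow(attr(atl2, "zero_coverage_cells")), 1)
})

test_that("a planted uniquely-methylated block is recovered as a hyper marker", {
  for (seed in 1:3) {
    tabs <- named_tables(planted_block_tables(seed = seed))
    res <- build_atlas(tabs, atlas_config(min_region_len = 100), mode = "all")
    hit <- res$regions[res$regions$target_entity == "ent1" &
                         res$regions$direction == "hyper", ]
    expect_gte(nrow(hit), 1)
    expect_true(any(hit$start <= 100 & hit$end >= 451))
  }
})
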