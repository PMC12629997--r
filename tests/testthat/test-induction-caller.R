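test_that("bin_depth averages per-base depth with zero-filled gaps", {
  tab <- data.frame(contig = "c", pos = 1:1000, depth = 10)
  cov <- bin_depth(tab, 100)
  expect_equal(cov$depth, rep(10, 10))

  tab2 <- data.frame(contig = "c", pos = 1:250, depth = 4)
  cov2 <- bin_depth(tab2, 100)
  expect_equal(cov2$bin_width, c(100, 100, 50))
  expect_equal(cov2$depth, c(4, 4, 4))

  tab3 <- data.frame(contig = "c", pos = 1:100, depth = 5)
  cov3 <- bin_depth(tab3, 100, contig_length = c(c = 200))
  expect_equal(cov3$depth, c(5, 0))

  expect_error(bin_depth(data.frame(contig = "c", pos = c(2, 1),
                                    depth = 1)), "unsorted")
  expect_error(bin_depth(data.frame(contig = "c", pos = c(1, 1),
                                    depth = 1)), "duplicated")
})

test_that("mask_regions labels any bin overlapping a region by >= 1 bp", {
  cov <- binned_coverage("c", rep(1, 5), 100)
  m1 <- mask_regions(cov, data.frame(start = 100, end = 300))
  expect_equal(m1$region_mask, c("host", "region_1", "region_1",
                                 "host", "host"))
  m2 <- mask_regions(cov, data.frame(start = 150, end = 250))
  expect_equal(m2$region_mask, c("host", "region_1", "region_1",
                                 "host", "host"))
  m3 <- mask_regions(cov, data.frame(start = numeric(), end = numeric()))
  expect_true(all(m3$region_mask == "host"))
})

test_that("zscore_ave matches the hand-derived value and degenerates safely", {
  cov <- binned_coverage("c", c(8, 9, 10, 10, 10, 11, 12, 20, 20),
                         region_mask = c(rep("host", 7), "p", "p"))
  expect_equal(zscore_ave(cov, "p"), 6.745)

  at_med <- binned_coverage("c", c(8, 9, 10, 11, 12, 10, 10),
                            region_mask = c(rep("host", 5), "p", "p"))
  expect_equal(zscore_ave(at_med, "p"), 0)

  flat <- binned_coverage("c", c(10, 10, 10, 50),
                          region_mask = c("host", "host", "host", "p"))
  expect_true(is.na(zscore_ave(flat, "p")))

  no_host <- binned_coverage("c", c(1, 2), region_mask = c("p", "p"))
  expect_error(zscore_ave(no_host, "p"), "host")
})

test_that("cohens_d matches the hand-derived value and degenerates safely", {
  cov <- binned_coverage("c", c(8, 10, 12, 18, 20, 22),
                         region_mask = c(rep("host", 3), rep("p", 3)))
  expect_equal(cohens_d(cov, "p"), -5)

  same <- binned_coverage("c", c(1, 2, 3, 1, 2, 3),
                          region_mask = c(rep("host", 3), rep("p", 3)))
  expect_equal(cohens_d(same, "p"), 0)

  const <- binned_coverage("c", rep(5, 4),
                           region_mask = c("host", "host", "p", "p"))
  expect_true(is.na(cohens_d(const, "p")))

  short <- binned_coverage("c", c(1, 2, 3),
                           region_mask = c("host", "host", "p"))
  expect_error(cohens_d(short, "p"), "2 bins")
})

test_that("fold_change uses the median host baseline", {
  cov <- binned_coverage("c", c(5, 10, 15, 40, 40),
                         region_mask = c(rep("host", 3), "p", "p"))
  expect_equal(fold_change(cov, "p"), 4)
  expect_equal(fold_change(cov, "p", baseline = "mean"), 4)

  eq <- binned_coverage("c", c(5, 10, 15, 10),
                        region_mask = c(rep("host", 3), "p"))
  expect_equal(fold_change(eq, "p"), 1)

  zero <- binned_coverage("c", c(0, 0, 0, 10),
                          region_mask = c(rep("host", 3), "p"))
  expect_true(is.na(fold_change(zero, "p")))
})

test_that("the retention rule ORs the z clause with the fold+effect clause", {
  expect_true(call_induction(3.5, 0, 1))
  expect_true(call_induction(2.0, 0.71, 2.0))
  expect_false(call_induction(2.0, 5, 1.9))
  expect_false(call_induction(3.49, 0.69, 10))
  # undefined components fail their own clause only
  expect_true(call_induction(NA, -0.8, 3))
  expect_true(call_induction(4, NA, NA))
  expect_false(call_induction(NA, NA, 10))
  # Cohen's d enters by magnitude (negative for induced regions)
  expect_true(call_induction(0, -2, 5))
})

test_that("boundary refinement trims flanks once against a fixed threshold", {
  cov <- binned_coverage("c", c(1, 1, 50, 60, 55, 1))
  reg <- data.frame(start = 0, end = 600)
  out <- refine_boundaries(cov, reg)
  expect_equal(c(out$start, out$end), c(200, 500))

  flat <- refine_boundaries(binned_coverage("c", rep(30, 4)),
                            data.frame(start = 0, end = 400))
  expect_equal(c(flat$start, flat$end), c(0, 400))

  interior <- refine_boundaries(binned_coverage("c", c(50, 1, 50)),
                                data.frame(start = 0, end = 300))
  expect_equal(c(interior$start, interior$end), c(0, 300))

  # idempotent, and output never extends the input span
  again <- refine_boundaries(cov, out)
  expect_equal(again, out)
  expect_gte(out$start, reg$start)
  expect_lte(out$end, reg$end)

  # at the default fraction the maximum bin always survives; an explicit
  # threshold above every bin exercises the empty-result guard
  expect_warning(
    empty <- refine_boundaries(binned_coverage("c", c(1, 1, 1)),
                               data.frame(start = 0, end = 300), frac = 2),
    "trimmed")
  expect_equal(nrow(empty), 0)
})

test_that("merging respects half-open adjacency and conserves spans", {
  m1 <- merge_overlapping(data.frame(contig = "c", start = c(10, 50),
                                     end = c(100, 150)))
  expect_equal(c(m1$start, m1$end), c(10, 150))

  abut <- merge_overlapping(data.frame(contig = "c", start = c(10, 100),
                                       end = c(100, 150)))
  expect_equal(nrow(abut), 2)

  sweep <- merge_overlapping(data.frame(contig = "c",
                                        start = c(0, 40, 200),
                                        end = c(50, 90, 300)))
  expect_equal(sweep$start, c(0, 200))
  expect_equal(sweep$end, c(90, 300))

  # order invariance and covered-bp conservation on random inputs
  set.seed(21)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    start <- sample(0:500, n)
    regs <- data.frame(contig = "c", start = start,
                       end = start + sample(10:200, n, replace = TRUE))
    merged <- merge_overlapping(regs)
    shuffled <- merge_overlapping(regs[sample(n), , drop = FALSE])
    expect_equal(merged$start, shuffled$start)
    expect_equal(merged$end, shuffled$end)
    covered <- function(tab) {
      pos <- unlist(Map(seq, tab$start, tab$end - 1))
      length(unique(pos))
    }
    expect_equal(covered(merged), covered(regs))
  }

  # completeness of a merged region is the member maximum
  comp <- merge_overlapping(data.frame(contig = "c", start = c(0, 40),
                                       end = c(50, 90),
                                       completeness = c(30, 80)))
  expect_equal(comp$completeness, 80)
  expect_equal(comp$quality, "high")
})

test_that("hallmark length cut-offs derive from the middle 80% of lengths", {
  expect_equal(derive_length_cutoff(rep(500, 10)), 250)
  expect_equal(derive_length_cutoff(1:100), 25.25)
  expect_error(derive_length_cutoff(1:3), ">= 5")

  hits <- data.frame(contig_id = c("c1", "c2", "c3", "c3"),
                     gene = c("terminase_large", "terminase_large",
                              "portal", "mystery"),
                     protein_length = c(300, 200, 250, 999))
  expect_warning(kept <- filter_hallmarks(hits), "mystery")
  expect_setequal(kept, c("c1", "c3"))
  expect_length(filter_hallmarks(hits[0, ]), 0)
})

test_that("vectorized statistics agree with naive per-bin loops", {
  set.seed(77)
  for (i in 1:50) {
    n_h <- sample(10:60, 1)
    n_p <- sample(3:20, 1)
    host <- stats::rnbinom(n_h, size = 10, mu = 30)
    ph <- stats::rnbinom(n_p, size = 10, mu = sample(30:300, 1))
    cov <- binned_coverage("c", c(host, ph),
                           region_mask = c(rep("host", n_h), rep("p", n_p)))
    if (stats::median(abs(host - stats::median(host))) > 0)
      expect_equal(zscore_ave(cov, "p"), naive_zscore_ave(host, ph),
                   tolerance = 1e-12)
    expect_equal(cohens_d(cov, "p"), naive_cohens_d(host, ph),
                 tolerance = 1e-12)
  }
})

test_that("induced-call probability is monotone in the induction fold", {
  folds <- c(1, 2, 5, 10)
  rate <- vapply(folds, function(f) {
    calls <- vapply(1:40, function(s) {
      sim <- sim_region_track(fold = f, seed = 1000 + s)
      st <- induction_stats(sim$cov)
      st$induced[1]
    }, logical(1))
    mean(calls)
  }, numeric(1))
  expect_true(all(diff(rate) >= 0))
  expect_lt(rate[1], 0.1)
  expect_equal(rate[4], 1)
})

test_that("the end-to-end caller recovers a planted region", {
  lys <- gen_lysogen(40000, data.frame(position = 15000,
                                       phage_length = 10000), seed = 5)
  cov <- simulate_coverage(nchar(lys$genome), lys$truth, base_depth = 25,
                           induction_fold = 8, seed = 5)
  # round-trip the track through the depth-table dialect
  depth_tab <- data.frame(contig = "lysogen_1",
                          pos = rep(cov$bin_start, cov$bin_width) +
                            unlist(lapply(cov$bin_width, seq_len)),
                          depth = rep(cov$depth, cov$bin_width))
  res <- call_induced_regions(depth_tab, data.frame(
    contig = "lysogen_1", start = 14900, end = 25100, completeness = 90))
  expect_true(res$calls$induced[1])
  expect_lte(abs(res$refined$start - 15000), 100)
  expect_lte(abs(res$refined$end - 25000), 100)
})
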