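test_that("frequency change is exact and guards the zero denominator", {
  expect_equal(frequency_change(0.2, 0.2), 0)
  expect_equal(frequency_change(0.10, 0.15), 50)
  expect_true(is.na(frequency_change(0, 0.5)))

  # swapping the sets maps change c to 100 * (-c) / (100 + c)
  set.seed(51)
  f1 <- stats::runif(50, 0.01, 1)
  f2 <- stats::runif(50, 0.01, 1)
  c_fwd <- frequency_change(f1, f2)
  c_rev <- frequency_change(f2, f1)
  expect_equal(c_rev, 100 * (-c_fwd) / (100 + c_fwd), tolerance = 1e-9)
})

test_that("category enrichment matches a hypergeometric oracle", {
  # the (20,80 / 5,95) table, embedded as two annotation sets
  annot_in <- data.frame(genome = "gi", gene_id = paste0("a", 1:100),
                         category = rep(c("tail", "other"), c(20, 80)))
  annot_cry <- data.frame(genome = "gc", gene_id = paste0("b", 1:100),
                          category = rep(c("tail", "other"), c(5, 95)))
  enr <- category_enrichment(annot_in, annot_cry, mode = "total")
  tail_row <- enr[enr$category == "tail", ]
  expect_equal(tail_row$p_value, fisher_oracle(20, 80, 5, 95),
               tolerance = 1e-9)
  expect_equal(tail_row$p_value,
               stats::fisher.test(matrix(c(20, 80, 5, 95), 2))$p.value)
  expect_equal(tail_row$freq_change, 100 * (0.05 - 0.20) / 0.20)

  # random small-margin tables against exhaustive enumeration
  set.seed(52)
  for (i in 1:25) {
    a <- sample(0:15, 1); b <- sample(1:15, 1)
    c_ <- sample(0:15, 1); d <- sample(1:15, 1)
    if ((a + c_) == 0) next
    expect_equal(stats::fisher.test(matrix(c(a, b, c_, d), 2))$p.value,
                 fisher_oracle(a, b, c_, d), tolerance = 1e-9)
  }
})

test_that("enrichment handles identity, single category and zero margins", {
  annot <- data.frame(genome = rep(c("g1", "g2"), each = 5),
                      gene_id = paste0("x", 1:10),
                      category = rep(c("head", "lysis"), 5))
  same <- category_enrichment(annot, annot, mode = "total")
  expect_true(all(same$p_adj == 1))
  expect_true(all(same$freq_change == 0))

  single <- data.frame(genome = "g", gene_id = paste0("y", 1:4),
                       category = "head")
  enr1 <- category_enrichment(single, annot, mode = "total")
  head_only <- enr1[enr1$category == "head", ]
  expect_equal(head_only$p_adj >= head_only$p_value, TRUE)

  # a category absent from both sets cannot arise; one with zero total
  # margin on one side is still a valid Fisher table, but a fully zero
  # column is degenerate
  zero <- data.frame(genome = "g", gene_id = "z1", category = "head")
  enr2 <- category_enrichment(zero, zero, mode = "presence")
  expect_true(all(enr2$p_value == 1))
})

test_that("presence mode counts genomes, not genes", {
  annot_in <- data.frame(genome = rep(c("g1", "g2"), c(4, 1)),
                         gene_id = paste0("a", 1:5),
                         category = c(rep("tail", 4), "head"))
  annot_cry <- data.frame(genome = c("h1", "h2"), gene_id = c("b1", "b2"),
                          category = c("tail", "tail"))
  enr <- category_enrichment(annot_in, annot_cry, mode = "presence")
  tail_row <- enr[enr$category == "tail", ]
  expect_equal(tail_row$n_in, 1L)     # one genome of two contains tail
  expect_equal(tail_row$f_in, 0.5)
  expect_equal(tail_row$f_cry, 1)
})

test_that("gap events recover planted fixtures exactly", {
  fx <- gen_alignment_fixture(
    6000,
    planted_hgt = data.frame(pos = c(1000, 4000), size = c(60, 120)),
    planted_indel = data.frame(pos = 2500, size = 80),
    seed = 9)
  ev <- call_gap_events(fx$blocks, fx$len_a, fx$len_b)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$type[order(ev$qstart)], c("HGT", "indel", "HGT"))
  hgt <- ev[ev$type == "HGT", ]
  want <- fx$truth[fx$truth$type == "HGT", ]
  expect_equal(hgt$qstart, want$qstart)
  expect_equal(hgt$qend, want$qend)
  expect_equal(hgt$sstart, want$sstart)
  expect_equal(hgt$send, want$send)
  ind <- ev[ev$type == "indel", ]
  expect_equal(ind$qstart, fx$truth$qstart[fx$truth$type == "indel"])
  expect_equal(ind$size_q, 80)
  expect_equal(ind$size_s, 0)
})

test_that("sub-threshold gaps and terminal gaps yield no events", {
  # 40-bp gaps on both sides: below the 50-bp minimum
  blocks <- data.frame(qstart = c(1, 1041), qend = c(1000, 2000),
                       sstart = c(1, 1041), send = c(1000, 2000))
  expect_equal(nrow(call_gap_events(blocks, 2000, 2000)), 0)

  # unaligned sequence at the ends of either genome is never an event
  interior <- data.frame(qstart = 201, qend = 1800,
                         sstart = 101, send = 1700)
  expect_equal(nrow(call_gap_events(interior, 2000, 1900)), 0)

  # a 49/51 asymmetric gap is a single indel on the qualifying side
  asym <- data.frame(qstart = c(1, 1052), qend = c(1000, 2000),
                     sstart = c(1, 1050), send = c(1000, 2000))
  ev <- call_gap_events(asym, 2000, 2000)
  expect_equal(ev$type, "indel")
  expect_equal(ev$size_q, 51)
  expect_equal(ev$size_s, 49)
})

test_that("non-collinear pairs are excluded and overlaps rejected", {
  rearranged <- data.frame(qstart = c(1, 1101), qend = c(1000, 2000),
                           sstart = c(1001, 1), send = c(1900, 900))
  expect_warning(ev <- call_gap_events(rearranged, 2000, 2000),
                 "not collinear")
  expect_equal(nrow(ev), 0)
  expect_true(isTRUE(attr(ev, "excluded")))

  overlapping <- data.frame(qstart = c(1, 900), qend = c(1000, 2000),
                            sstart = c(1, 901), send = c(1000, 2000))
  expect_error(call_gap_events(overlapping, 2000, 2000), "overlapping")
})

test_that("event-count summaries tabulate pairs for the rank-sum test", {
  fx <- gen_alignment_fixture(
    6000,
    planted_hgt = data.frame(pos = c(1000, 4000), size = c(60, 120)),
    planted_indel = data.frame(pos = 2500, size = 80),
    seed = 9)
  ev <- call_gap_events(fx$blocks, fx$len_a, fx$len_b)
  res <- compare_event_counts(list(p1 = ev), list(p2 = ev))
  expect_equal(res$summary$n_total, c(3, 3))
  expect_equal(res$summary$n_hgt, c(2, 2))
  expect_equal(res$summary$n_indel, c(1, 1))

  empty <- compare_event_counts(list(), list())
  expect_equal(nrow(empty$summary), 0)
  expect_true(is.na(empty$p_value))
})
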