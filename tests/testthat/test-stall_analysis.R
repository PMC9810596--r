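# two-gene toy system used by several blocks
toy_system <- local({
  g <- mito_genome(paste0("ATGAAATAA", "ATGCCCTGCTAA"))
  orfs <- orf_annotation(data.frame(gene = c("A", "B"), start = c(0, 9),
                                    end = c(9, 21), strand = "+",
                                    polya_completion = 0))
  list(genome = g, orfs = orfs)
})

test_that("relative transcript occupancy sums to 1 and is scale-invariant", {
  tab <- make_table(toy_system$genome, toy_system$orfs,
                    list(A = c(10L, 5L, 5L), B = c(20L, 20L, 20L, 20L)))
  occ <- relative_transcript_occupancy(tab)
  expect_equal(occ$fraction[occ$gene == "A"], 0.2)
  expect_equal(occ$fraction[occ$gene == "B"], 0.8)
  expect_equal(sum(occ$fraction), 1, tolerance = 1e-12)

  tab3 <- tab; tab3$count <- tab3$count * 7L
  expect_equal(relative_transcript_occupancy(tab3)$fraction, occ$fraction)

  one <- make_table(toy_system$genome, toy_system$orfs[1, ],
                    list(A = c(1L, 1L, 1L)))
  expect_equal(relative_transcript_occupancy(one)$fraction, 1)
  empty <- make_table(toy_system$genome, toy_system$orfs,
                      list(A = 0L, B = 0L))
  expect_error(relative_transcript_occupancy(empty), "empty")
})

test_that("size factors follow the stated mean-over-total formula", {
  tab <- make_table(toy_system$genome, toy_system$orfs,
                    list(A = c(50L, 25L, 25L), B = c(75L, 75L, 75L, 75L)))
  sf <- size_factors(tab)  # totals 100 and 300, mean 200
  expect_equal(unname(sf["A"]), 2.0)
  expect_equal(unname(sf["B"]), 2 / 3)

  # equal totals give unit factors; a single gene gives 1
  tab_eq <- make_table(toy_system$genome, toy_system$orfs,
                       list(A = c(2L, 2L, 2L), B = c(2L, 2L, 1L, 1L)))
  expect_equal(unname(size_factors(tab_eq)), c(1, 1))
  one <- make_table(toy_system$genome, toy_system$orfs[1, ],
                    list(A = c(3L, 3L, 3L)))
  expect_equal(unname(size_factors(one)), 1)

  # scaling equalizes every gene total to the pre-scaling mean
  gt <- gene_totals(tab)
  expect_equal(unname(gt * sf), rep(mean(gt), 2), tolerance = 1e-9)

  expect_error(size_factors(make_table(toy_system$genome, toy_system$orfs,
                                       list(A = 0L, B = 0L))), "all-zero")
  expect_warning(size_factors(make_table(toy_system$genome,
                                         toy_system$orfs,
                                         list(A = c(1L, 1L, 1L), B = 0L))),
                 "zero-count")
})

test_that("terminal-window occupancy matches proportionality and extremes", {
  cytb <- FX$orfs[FX$orfs$gene == "CYTB", ]  # 100 codons
  uniform <- make_table(FX$genome, cytb, list(CYTB = rep(1L, 100)))
  rep1 <- terminal_window_occupancy(uniform, cytb, sf = c(CYTB = 1))
  expect_equal(rep1$window_occupancy, 0.15)

  only_stop <- make_table(FX$genome, cytb,
                          list(CYTB = c(rep(0L, 99), 25L)))
  rep2 <- terminal_window_occupancy(only_stop, cytb, sf = c(CYTB = 1))
  expect_equal(rep2$window_occupancy, 1.0)

  # the window excluding the stop shifts one codon upstream
  shifted <- make_table(FX$genome, cytb,
                        list(CYTB = c(rep(0L, 84), 1L, rep(0L, 14), 9L)))
  with_stop <- terminal_window_occupancy(shifted, cytb, sf = c(CYTB = 1),
                                         include_stop = TRUE)
  no_stop <- terminal_window_occupancy(shifted, cytb, sf = c(CYTB = 1),
                                       include_stop = FALSE)
  expect_equal(with_stop$window_occupancy, 0.9)   # stop codon included
  expect_equal(no_stop$window_occupancy, 0.1)     # codon 84 included instead

  # occupancy is invariant to the size factor within one gene
  rep3 <- terminal_window_occupancy(uniform, cytb, sf = c(CYTB = 123.4))
  expect_equal(rep3$window_occupancy, rep1$window_occupancy)

  # genes shorter than the window are skipped with a warning
  short <- toy_system$orfs[1, ]
  tab_s <- make_table(toy_system$genome, short, list(A = c(1L, 1L, 1L)))
  expect_warning(res <- terminal_window_occupancy(tab_s, short,
                                                  sf = c(A = 1)),
                 "skipped")
  expect_identical(nrow(res), 0L)
})

test_that("stall fold changes are 1 for identical samples and stabilized
           at zero counts", {
  cytb <- FX$orfs[FX$orfs$gene == "CYTB", ]
  tab <- make_table(FX$genome, cytb,
                    list(CYTB = c(rep(2L, 85), rep(3L, 15))))
  rep1 <- terminal_window_occupancy(tab, cytb, sf = c(CYTB = 1))
  fc <- stall_fold_change(rep1, rep1)
  expect_equal(fc$fold_change, 1)
  expect_false(any(fc$stabilized))

  zero_win <- make_table(FX$genome, cytb,
                         list(CYTB = c(rep(2L, 85), rep(0L, 15))))
  rep0 <- terminal_window_occupancy(zero_win, cytb, sf = c(CYTB = 1))
  fc0 <- stall_fold_change(rep1, rep0)
  expect_true(fc0$stabilized)
  expect_true(is.finite(fc0$fold_change) && fc0$fold_change > 0)

  # mismatched window definitions are refused
  rep_ns <- terminal_window_occupancy(tab, cytb, sf = c(CYTB = 1),
                                      include_stop = FALSE)
  expect_error(stall_fold_change(rep1, rep_ns), "window definitions")
})

test_that("codon identity profiles aggregate and normalize as stated", {
  g <- mito_genome("ATGAAAAAATAA")
  orfs <- orf_annotation(data.frame(gene = "G", start = 0, end = 12,
                                    strand = "+", polya_completion = 0))
  tab <- make_table(g, orfs, list(G = c(1L, 2L, 3L, 4L)))
  prof <- codon_identity_profile(tab, g, orfs)
  vals <- setNames(prof$value, prof$codon)
  expect_equal(unname(vals[c("ATG", "AAA", "TAA")]), c(0.1, 0.5, 0.4))
  expect_equal(sum(prof$value), 1, tolerance = 1e-12)
  # ordered by mtDNA codon frequency (AAA occurs twice, others once)
  expect_identical(prof$codon[1], "AAA")

  # uniform occupancy is flat per codon occurrence
  tab_u <- make_table(g, orfs, list(G = rep(2L, 4)))
  per <- codon_identity_profile(tab_u, g, orfs,
                                normalization = "per_occurrence")
  expect_equal(per$value, rep(per$value[1], nrow(per)))
  expect_true(all(per$frequency > 0))

  fc <- codon_identity_fold_change(prof, prof)
  expect_equal(fc$fold_change, rep(1, nrow(fc)))

  # a zero reference cell is stabilized to a finite flagged ratio
  tab_z <- make_table(g, orfs, list(G = c(1L, 2L, 3L, 0L)))
  prof_z <- codon_identity_profile(tab_z, g, orfs)
  fcz <- codon_identity_fold_change(prof, prof_z)
  row <- fcz[fcz$codon == "TAA", ]
  expect_true(row$stabilized)
  expect_true(is.finite(row$fold_change))
})

test_that("the queue scan finds a planted upstream peak", {
  cytb <- FX$orfs[FX$orfs$gene == "CYTB", ]
  counts <- rep(2L, 100)
  counts[100 - 12] <- 30L  # codon index 87 = stop index 99 minus 12
  tab <- make_table(FX$genome, cytb, list(CYTB = counts))
  hit <- upstream_queue_scan(tab, cytb)
  expect_identical(hit$offset, 12L)
  expect_true(hit$called)
  expect_equal(hit$fold, 15)

  flat <- make_table(FX$genome, cytb, list(CYTB = rep(2L, 100)))
  none <- upstream_queue_scan(flat, cytb)
  expect_false(none$called)
  expect_equal(none$fold, 1)

  expect_error(upstream_queue_scan(tab, cytb, stop_index = 10L),
               "search window")
})

test_that("fold changes between replicate draws center at 1", {
  genes <- c("COX1", "ND6")
  fcs <- matrix(NA_real_, nrow = 20, ncol = 2,
                dimnames = list(NULL, genes))
  for (i in 1:20) {
    a <- simulate_reads(FX$genome, FX$orfs,
                        wt_like_config(FX$orfs, n_reads = 3000,
                                       seed = 1000 + i))
    b <- simulate_reads(FX$genome, FX$orfs,
                        wt_like_config(FX$orfs, n_reads = 3000,
                                       seed = 2000 + i))
    ta <- count_table_from_truth(a$truth, FX$orfs, FX$genome)
    tb <- count_table_from_truth(b$truth, FX$orfs, FX$genome)
    fc <- stall_fold_change(terminal_window_occupancy(ta, FX$orfs),
                            terminal_window_occupancy(tb, FX$orfs))
    fcs[i, ] <- fc$fold_change[match(genes, fc$gene)]
  }
  for (g in genes) {
    m <- mean(fcs[, g])
    se <- sd(fcs[, g]) / sqrt(nrow(fcs))
    expect_lt(abs(m - 1), 3 * se + 0.05)
  }
})

test_that("planted terminal multipliers are recovered in rank order", {
  stalls <- list(stall_spec("COX2", "terminal", 2),
                 stall_spec("ND4", "terminal", 5),
                 stall_spec("CYTB", "terminal", 10))
  ko <- simulate_reads(FX$genome, FX$orfs,
                       simulation_config(n_reads = 20000, seed = 61,
                                         stalls = stalls))
  wt <- simulate_reads(FX$genome, FX$orfs,
                       simulation_config(n_reads = 20000, seed = 62))
  tko <- count_table_from_truth(ko$truth, FX$orfs, FX$genome)
  twt <- count_table_from_truth(wt$truth, FX$orfs, FX$genome)
  fc <- stall_fold_change(terminal_window_occupancy(tko, FX$orfs),
                          terminal_window_occupancy(twt, FX$orfs))
  got <- fc$fold_change[match(c("COX2", "ND4", "CYTB"), fc$gene)]
  expect_identical(order(got), 1:3)
})
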