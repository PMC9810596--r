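ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

test_that("adapter trimming finds exact and mismatched adapter starts", {
  # fixed insert whose 3' end shares no qualifying prefix with the adapter
  insert <- paste0(strrep("ACGT", 7), "AC")
  read <- data.frame(read_id = "r1",
                     sequence = paste0(insert, substr(ADAPTER, 1, 20)))
  tr <- trim_adapter(read, ADAPTER)
  expect_identical(tr$sequence, insert)
  expect_identical(tr$trimmed_length, 30L)
  expect_true(tr$adapter_found)

  # no adapter content: untouched (insert chosen free of short adapter hits)
  clean <- paste0(strrep("AC", 20), "TT")
  tr2 <- trim_adapter(data.frame(read_id = "r2", sequence = clean), ADAPTER)
  expect_false(tr2$adapter_found)
  expect_identical(tr2$sequence, clean)

  # one mismatch within 20 adapter bases still trims at the same point
  mangled <- substr(ADAPTER, 1, 20)
  substr(mangled, 9, 9) <- "A"  # position off the adapter's own letters
  read3 <- data.frame(read_id = "r3", sequence = paste0(insert, mangled))
  tr3 <- trim_adapter(read3, ADAPTER, max_error_rate = 0.1)
  expect_true(tr3$adapter_found)
  expect_identical(tr3$sequence, insert)

  expect_error(trim_adapter(data.frame(read_id = "e", sequence = "")),
               "empty read")
})

test_that("trimming matches a literal per-suffix oracle and is idempotent", {
  set.seed(99)
  reads <- data.frame(
    read_id = sprintf("r%03d", 1:120),
    sequence = vapply(1:120, function(i) {
      ins <- random_dna(sample(10:45, 1))
      keep <- sample(0:21, 1)
      paste0(ins, substr(ADAPTER, 1, keep))
    }, character(1)), stringsAsFactors = FALSE)
  got <- trim_adapter(reads, ADAPTER)
  # oracle applied to the same fixpoint semantics
  for (i in seq_len(nrow(reads))) {
    s <- reads$sequence[i]
    repeat {
      p <- oracle_trim_pos(s, ADAPTER, 3L, 0.1)
      if (is.na(p)) break
      s <- substr(s, 1, p - 1L)
    }
    expect_identical(got$sequence[i], s)
  }
  again <- trim_adapter(got, ADAPTER)
  expect_identical(again$sequence, got$sequence)
})

test_that("length filtering keeps the inclusive 25-35 window", {
  reads <- data.frame(read_id = c("a", "b", "c", "d"),
                      sequence = vapply(c(24, 25, 35, 36), random_dna,
                                        character(1)),
                      adapter_found = TRUE, stringsAsFactors = FALSE)
  kept <- length_filter(reads, 25, 35)
  expect_identical(kept$read_id, c("b", "c"))
  expect_identical(attr(kept, "discarded"),
                   c(short = 1L, long = 1L, untrimmed = 0L))

  expect_identical(nrow(length_filter(reads[0, ], 25, 35)), 0L)
  all_in <- reads[2:3, ]
  expect_identical(length_filter(all_in, 25, 35)$read_id, all_in$read_id)

  # untrimmed reads are discarded by default, retained on request
  reads$adapter_found <- c(TRUE, FALSE, TRUE, TRUE)
  expect_identical(length_filter(reads, 25, 35)$read_id, "c")
  expect_identical(length_filter(reads, 25, 35,
                                 drop_untrimmed = FALSE)$read_id, c("b", "c"))
})

test_that("the mapper resolves exact, reverse-complement and origin reads", {
  set.seed(17)
  g <- mito_genome(random_dna(300))
  doubled <- paste0(g$sequence, g$sequence)

  r_fwd <- substr(g$sequence, 101, 130)
  r_rev <- rc_chr(substr(g$sequence, 201, 230))
  r_org <- substr(doubled, 296, 296 + 29)  # spans the circular origin
  aln <- map_reads(g, data.frame(
    read_id = c("f", "r", "o"), sequence = c(r_fwd, r_rev, r_org)))
  expect_identical(aln$status, rep("UNIQUE", 3))
  expect_identical(aln$five_prime_pos, c(100L, 229L, 295L))
  expect_identical(aln$strand, c("+", "-", "+"))
  expect_identical(aln$n_mismatches, c(0L, 0L, 0L))

  # a read and its reverse complement map to the same locus, strands swapped
  aln2 <- map_reads(g, data.frame(read_id = "rc", sequence = rc_chr(r_fwd)))
  expect_identical(aln2$five_prime_pos, 129L)
  expect_identical(aln2$strand, "-")

  # ties are never broken silently
  rep_seq <- substr(g$sequence, 1, 40)
  g_rep <- mito_genome(paste0(rep_seq, random_dna(60), rep_seq))
  aln3 <- map_reads(g_rep, data.frame(read_id = "m",
                                      sequence = substr(rep_seq, 1, 30)))
  expect_identical(aln3$status, "MULTI")

  expect_error(map_reads(g, data.frame(read_id = "x",
                                       sequence = random_dna(301))),
               "longer than the genome")
})

test_that("the mapper agrees with the naive doubled-genome oracle", {
  set.seed(4242)
  for (rep in 1:5) {
    L <- sample(60:120, 1)
    g <- mito_genome(random_dna(L))
    doubled <- paste0(g$sequence, g$sequence)
    reads <- character(0)
    for (k in 1:12) {
      w <- sample(20:30, 1)
      o <- sample(0:(L - 1), 1)          # includes origin-spanning starts
      fwd <- substr(doubled, o + 1, o + w)
      reads <- c(reads,
                 fwd,
                 rc_chr(fwd),
                 mutate_read(fwd, sample(1:2, 1)),
                 random_dna(w))
    }
    df <- data.frame(read_id = sprintf("r%02d", seq_along(reads)),
                     sequence = reads, stringsAsFactors = FALSE)
    got <- map_reads(g, df, max_mismatches = 1L)
    for (i in seq_along(reads)) {
      exp <- oracle_map(g$sequence, reads[i], 1L)
      expect_identical(got$status[i], exp$status)
      if (exp$status == "UNIQUE") {
        expect_identical(got$five_prime_pos[i], as.integer(exp$pos))
        expect_identical(got$strand[i], exp$strand)
        expect_identical(got$n_mismatches[i], exp$mm)
      }
    }
  }
})

test_that("unique alignments of simulated reads hit the planted loci", {
  cfg <- wt_like_config(FX$orfs, n_reads = 1500, seed = 55)
  sim <- simulate_reads(FX$genome, FX$orfs, cfg)
  res <- process_reads(FX$genome, sim$reads)
  expect_identical(attr(res$filtered, "discarded")[["untrimmed"]], 0L)
  uni <- res$alignments[res$alignments$status == "UNIQUE", ]
  truth <- sim$truth[match(uni$read_id, sim$truth$read_id), ]
  expect_true(all(uni$five_prime_pos == truth$five_prime_pos))
  expect_true(all(uni$strand == truth$strand))
  expect_true(all(uni$n_mismatches == 0L))
})

test_that("SAM output carries 1-based positions and strand flags", {
  set.seed(31)
  g <- mito_genome(random_dna(200))
  r_fwd <- substr(g$sequence, 51, 80)
  reads <- data.frame(read_id = c("f", "r"),
                      sequence = c(r_fwd, rc_chr(r_fwd)),
                      stringsAsFactors = FALSE)
  aln <- map_reads(g, reads)
  tmp <- tempfile(fileext = ".sam")
  write_sam(aln, reads, g, tmp)
  lines <- readLines(tmp)
  body <- strsplit(lines[!startsWith(lines, "@")], "\t")
  expect_identical(vapply(body, `[`, "", 4), c("51", "51"))
  expect_identical(vapply(body, `[`, "", 2), c("0", "16"))
  expect_identical(vapply(body, `[`, "", 6), c("30M", "30M"))
  # SEQ is always reported on the forward genome strand
  expect_identical(vapply(body, `[`, "", 10), c(r_fwd, r_fwd))
})
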