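# Shared fixtures and independent oracles for the test suite.

# the bundled synthetic human-layout fixture, built once per test run
FX <- synthetic_mito_genome()

rc_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_read <- function(read, n_mut) {
  b <- strsplit(read, "")[[1]]
  pos <- sample(seq_along(b), n_mut)
  for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1)
  paste(b, collapse = "")
}

# Independent mapping oracle: naive scan over the doubled genome string on
# both strands, ranking loci by mismatch count. Vectorized with utf8ToInt
# but structurally unrelated to the package's C++ scan.
oracle_map <- function(genome_seq, read, max_mm = 1L) {
  L <- nchar(genome_seq)
  g <- utf8ToInt(paste0(genome_seq, genome_seq))
  scan_mm <- function(r_int) {
    w <- length(r_int)
    idx <- outer(seq_len(L) - 1L, seq_len(w), "+")
    rowSums(matrix(g[idx], nrow = L) !=
            matrix(r_int, nrow = L, ncol = w, byrow = TRUE))
  }
  mm_p <- scan_mm(utf8ToInt(read))
  mm_m <- scan_mm(utf8ToInt(rc_chr(read)))
  best <- min(mm_p, mm_m)
  if (best > max_mm) {
    return(list(status = "UNMAPPED", pos = NA_integer_,
                strand = NA_character_, mm = NA_integer_))
  }
  n_best <- sum(mm_p == best) + sum(mm_m == best)
  if (n_best > 1L) {
    return(list(status = "MULTI", pos = NA_integer_,
                strand = NA_character_, mm = as.integer(best)))
  }
  w <- nchar(read)
  if (any(mm_p == best)) {
    list(status = "UNIQUE", pos = which(mm_p == best) - 1L,
         strand = "+", mm = as.integer(best))
  } else {
    o <- which(mm_m == best) - 1L
    list(status = "UNIQUE", pos = (o + w - 1L) %% L,
         strand = "-", mm = as.integer(best))
  }
}

# Independent adapter-trimming oracle: literal scan over every suffix
# position of one read.
oracle_trim_pos <- function(seq, adapter, min_overlap, max_error_rate) {
  w <- nchar(seq)
  a <- strsplit(adapter, "")[[1]]
  s <- strsplit(seq, "")[[1]]
  for (p in seq_len(max(0L, w - min_overlap + 1L))) {
    ov <- min(w - p + 1L, length(a))
    mm <- sum(s[p:(p + ov - 1L)] != a[seq_len(ov)])
    if (mm <= floor(ov * max_error_rate)) return(p)
  }
  NA_integer_
}

# minimal count table constructed directly from per-cell counts
make_table <- function(genome, orfs, counts_by_gene, sample_id = "s") {
  asg <- do.call(rbind, lapply(names(counts_by_gene), function(g) {
    cnt <- counts_by_gene[[g]]
    idx <- rep(seq_along(cnt) - 1L, times = cnt)
    data.frame(gene = rep(g, length(idx)), codon_index = idx,
               stringsAsFactors = FALSE)
  }))
  build_count_table(asg, orfs, genome, sample_id = sample_id)
}

# delta-method standard error of a ratio of two independent binomial
# proportions p_s / p_r estimated from (x_s, n_s) and (x_r, n_r)
ratio_se <- function(x_s, n_s, x_r, n_r) {
  p_s <- x_s / n_s
  p_r <- x_r / n_r
  (p_s / p_r) * sqrt(p_s * (1 - p_s) / (n_s * p_s^2) +
                     p_r * (1 - p_r) / (n_r * p_r^2))
}
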