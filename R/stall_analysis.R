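#' Relative mitoribosome occupancy per transcript
#'
#' Fraction of all assigned A-site counts carried by each gene, i.e. the
#' occupancy of mitoribosomes on each transcript relative to the total
#' occupancy on all transcripts.
#'
#' @param table A `codon_count_table`.
#' @return data.frame with `gene`, `count` and `fraction` (sums to 1).
#' @export
relative_transcript_occupancy <- function(table) {
  gt <- gene_totals(table)
  total <- sum(gt)
  if (total <= 0) stop("empty count table")
  data.frame(gene = names(gt), count = as.numeric(gt),
             fraction = as.numeric(gt) / total, stringsAsFactors = FALSE)
}

#' Per-gene size factors
#'
#' The size factor of a gene is the mean of all gene totals divided by the
#' gene's own total, so that after scaling every gene's total equals the
#' pre-scaling mean. It removes transcript-level differences before
#' comparing codon occupancy across samples. Genes with zero counts are
#' excluded with a warning.
#'
#' @param table A `codon_count_table`.
#' @return Named numeric vector of size factors.
#' @export
size_factors <- function(table) {
  gt <- gene_totals(table)
  if (all(gt == 0)) stop("all-zero count table")
  zero <- gt == 0
  if (any(zero)) {
    warning("excluding zero-count gene(s): ",
            paste(names(gt)[zero], collapse = ", "))
    gt <- gt[!zero]
  }
  mean(gt) / gt
}

window_indices <- function(n_codons, window_codons, include_stop) {
  if (include_stop) (n_codons - window_codons):(n_codons - 1L)
  else (n_codons - window_codons - 1L):(n_codons - 2L)
}

#' Terminal-window occupancy per gene
#'
#' Quantifies stalling near the 3' end of each transcript: the sum of
#' size-factor-scaled counts over the gene's final `window_codons` codons
#' divided by the scaled total on that gene. With `include_stop = TRUE`
#' (default) the window is the stop codon plus the preceding
#' `window_codons - 1` sense codons; with `FALSE` it is the
#' `window_codons` sense codons immediately upstream of the stop. The size
#' factor cancels within a gene but is applied so windows are comparable
#' across genes and samples. Genes shorter than the window are skipped
#' with a warning.
#'
#' @param table A `codon_count_table`.
#' @param orfs The matching [orf_annotation()].
#' @param sf Optional size factors (default computed from `table`).
#' @param window_codons Window size in codons (default 15).
#' @param include_stop Whether the stop codon is part of the window.
#' @return data.frame with `gene`, `window_count`, `gene_total` (both
#'   scaled) and `window_occupancy`, carrying the window definition as
#'   attributes `window_codons` and `include_stop`.
#' @export
terminal_window_occupancy <- function(table, orfs, sf = NULL,
                                      window_codons = 15L,
                                      include_stop = TRUE) {
  if (is.null(sf)) sf <- size_factors(table)
  n_cod <- orf_codon_counts(orfs)
  rows <- lapply(names(n_cod), function(g) {
    n <- n_cod[[g]]
    if (window_codons >= n) {
      warning("window of ", window_codons, " codons >= length of gene ", g,
              "; gene skipped")
      return(NULL)
    }
    if (!g %in% names(sf)) return(NULL)
    sub <- table[table$gene == g, ]
    win <- window_indices(n, window_codons, include_stop)
    wc <- sum(sub$count[sub$codon_index %in% win]) * sf[[g]]
    tot <- sum(sub$count) * sf[[g]]
    data.frame(gene = g, window_count = wc, gene_total = tot,
               window_occupancy = if (tot > 0) wc / tot else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(gene = character(0), window_count = numeric(0),
                      gene_total = numeric(0), window_occupancy = numeric(0),
                      stringsAsFactors = FALSE)
  }
  attr(out, "window_codons") <- as.integer(window_codons)
  attr(out, "include_stop") <- include_stop
  out
}

#' Terminal stall fold change versus a reference sample
#'
#' Per-gene ratio of terminal-window occupancies between a sample and a
#' reference (e.g. knockout versus wildtype). When either window count is
#' zero, a Haldane-style pseudocount is added to both window counts before
#' forming occupancies, and the gene is flagged. Genes absent from the
#' reference are skipped with a warning; the two reports must share the
#' same window definition.
#'
#' @param sample_report,reference_report Outputs of
#'   [terminal_window_occupancy()].
#' @param pseudocount Stabilizing count (default 0.5).
#' @return data.frame with `gene`, `occupancy_sample`,
#'   `occupancy_reference`, `fold_change`, `stabilized`.
#' @export
stall_fold_change <- function(sample_report, reference_report,
                              pseudocount = 0.5) {
  for (a in c("window_codons", "include_stop")) {
    if (!identical(attr(sample_report, a), attr(reference_report, a))) {
      stop("sample and reference use different window definitions")
    }
  }
  missing <- setdiff(sample_report$gene, reference_report$gene)
  if (length(missing)) {
    warning("gene(s) absent from reference skipped: ",
            paste(missing, collapse = ", "))
  }
  genes <- intersect(sample_report$gene, reference_report$gene)
  s <- sample_report[match(genes, sample_report$gene), ]
  r <- reference_report[match(genes, reference_report$gene), ]
  stab <- s$window_count == 0 | r$window_count == 0
  occ_s <- ifelse(stab, (s$window_count + pseudocount) / s$gene_total,
                  s$window_occupancy)
  occ_r <- ifelse(stab, (r$window_count + pseudocount) / r$gene_total,
                  r$window_occupancy)
  data.frame(gene = genes, occupancy_sample = occ_s,
             occupancy_reference = occ_r,
             fold_change = occ_s / occ_r, stabilized = stab,
             stringsAsFactors = FALSE)
}

#' Codon-identity occupancy profile
#'
#' Sums A-site counts over all genes by the identity of the decoded codon
#' and normalizes to the sample's grand total (`normalization = "total"`);
#' `"per_occurrence"` additionally divides each identity by its occurrence
#' count in the coding mtDNA, yielding occupancy per codon occurrence
#' (identities absent from the ORFs are excluded from that variant). Both
#' ordering keys used in presentations are carried: the codon frequency in
#' the mtDNA and the sample's sequencing coverage.
#'
#' @param table A `codon_count_table`.
#' @param genome A [mito_genome()].
#' @param orfs An [orf_annotation()].
#' @param normalization `"total"` or `"per_occurrence"`.
#' @return data.frame with `codon`, `count`, `frequency` (occurrences in
#'   the ORF set), `value` (normalized occupancy), ordered by decreasing
#'   frequency, with attribute `normalization`.
#' @export
codon_identity_profile <- function(table, genome, orfs,
                                   normalization = c("total",
                                                     "per_occurrence")) {
  normalization <- match.arg(normalization)
  freq <- codon_frequency(genome, orfs)
  agg <- tapply(table$count, factor(table$codon, levels = names(freq)), sum)
  agg[is.na(agg)] <- 0
  total <- sum(agg)
  if (total <= 0) stop("empty count table")
  value <- as.numeric(agg) / total
  out <- data.frame(codon = names(freq), count = as.numeric(agg),
                    frequency = as.integer(freq), value = value,
                    stringsAsFactors = FALSE)
  if (normalization == "per_occurrence") {
    out <- out[out$frequency > 0, ]
    out$value <- out$value / out$frequency
  }
  out <- out[order(-out$frequency, out$codon), ]
  rownames(out) <- NULL
  attr(out, "normalization") <- normalization
  out
}

#' Codon-identity fold change versus a reference profile
#'
#' @param sample_profile,reference_profile Outputs of
#'   [codon_identity_profile()] with the same normalization mode.
#' @param pseudocount Stabilizer used when either normalized value is zero:
#'   the pseudocount is added to both raw counts and values recomputed;
#'   such codons are flagged.
#' @return data.frame with `codon`, `value_sample`, `value_reference`,
#'   `fold_change`, `stabilized`.
#' @export
codon_identity_fold_change <- function(sample_profile, reference_profile,
                                       pseudocount = 0.5) {
  if (!identical(attr(sample_profile, "normalization"),
                 attr(reference_profile, "normalization"))) {
    stop("profiles use different normalization modes")
  }
  codons <- intersect(sample_profile$codon, reference_profile$codon)
  s <- sample_profile[match(codons, sample_profile$codon), ]
  r <- reference_profile[match(codons, reference_profile$codon), ]
  stab <- s$count == 0 | r$count == 0
  # stabilized values are recomputed from counts on each profile's own
  # count-to-value scale, so flagged cells stay finite and comparable
  scale_s <- ifelse(s$count > 0, s$value / s$count, NA)
  scale_r <- ifelse(r$count > 0, r$value / r$count, NA)
  unit_s <- stats::median(scale_s, na.rm = TRUE)
  unit_r <- stats::median(scale_r, na.rm = TRUE)
  vs <- ifelse(stab, (s$count + pseudocount) * unit_s, s$value)
  vr <- ifelse(stab, (r$count + pseudocount) * unit_r, r$value)
  data.frame(codon = codons, value_sample = vs, value_reference = vr,
             fold_change = vs / vr, stabilized = stab,
             stringsAsFactors = FALSE)
}

#' Scan for a queued-ribosome peak upstream of a stall
#'
#' Searches a window of offsets upstream of a stalled codon (default
#' 10--16 codons, bracketing the ~12 codons one 35-nt footprint spans) for
#' the maximal secondary peak, and reports its fold enrichment over the
#' gene's median codon count. A peak below `min_fold` is reported but not
#' called.
#'
#' @param table A `codon_count_table`.
#' @param orf Single-row [orf_annotation()] of the gene to scan.
#' @param stop_index 0-based codon index of the stalled codon (defaults to
#'   the gene's stop codon).
#' @param search_window Candidate offsets in codons.
#' @param sf Optional size factors (scaling cancels within one gene).
#' @param min_fold Minimal fold-over-median to call a queued peak.
#' @return One-row data.frame with `gene`, `offset`, `count`,
#'   `median_count`, `fold` and `called`.
#' @export
upstream_queue_scan <- function(table, orf, stop_index = NULL,
                                search_window = 10:16, sf = NULL,
                                min_fold = 2) {
  stopifnot(nrow(orf) == 1L)
  n <- unname(orf_codon_counts(orf))
  if (is.null(stop_index)) stop_index <- n - 1L
  if (stop_index <= max(search_window)) {
    stop("search window extends upstream of the gene start")
  }
  scale <- if (is.null(sf)) 1 else sf[[orf$gene]]
  sub <- table[table$gene == orf$gene, ]
  cnt <- setNames(sub$count, sub$codon_index)[as.character(stop_index -
                                                           search_window)]
  cnt[is.na(cnt)] <- 0
  cnt <- cnt * scale
  med <- stats::median(sub$count) * scale
  best <- which.max(cnt)
  fold <- if (med > 0) unname(cnt[best]) / med else Inf
  data.frame(gene = orf$gene, offset = search_window[best],
             count = unname(cnt[best]), median_count = med, fold = fold,
             called = fold >= min_fold, stringsAsFactors = FALSE)
}
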