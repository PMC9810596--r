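#' Trim the 3' adapter from reads
#'
#' For each read, finds the 5'-most position at which a prefix of the
#' adapter (of length at least `min_overlap`) matches the read suffix with
#' a mismatch fraction of at most `max_error_rate`, and truncates the read
#' there. The scan is applied to a fixpoint, so a trimmed read never retains
#' a qualifying adapter prefix at its 3' end (and trimming is idempotent).
#' Reads in which no qualifying position exists are returned unchanged with
#' `adapter_found = FALSE`.
#'
#' @param reads data.frame with `read_id` and `sequence` columns.
#' @param adapter Adapter sequence (default TruSeq small-RNA 3' adapter).
#' @param min_overlap Minimum adapter prefix length considered (>= 3).
#' @param max_error_rate Maximum mismatch fraction within the overlap.
#' @return data.frame with `read_id`, `sequence` (trimmed),
#'   `trimmed_length` and `adapter_found`.
#' @export
trim_adapter <- function(reads, adapter = "TGGAATTCTCGGGTGCCAAGG",
                         min_overlap = 3L, max_error_rate = 0.1) {
  stopifnot(nchar(adapter) >= min_overlap, min_overlap >= 3L)
  seqs <- toupper(reads$sequence)
  if (any(nchar(seqs) == 0L)) stop("empty read in input")
  found <- rep(FALSE, length(seqs))
  repeat {
    cut <- trim_positions(seqs, adapter, min_overlap, max_error_rate)
    hit <- !is.na(cut)
    if (!any(hit)) break
    found <- found | hit
    seqs[hit] <- substr(seqs[hit], 1L, cut[hit] - 1L)
  }
  data.frame(read_id = reads$read_id, sequence = seqs,
             trimmed_length = nchar(seqs), adapter_found = found,
             stringsAsFactors = FALSE)
}

# one scan pass: for each sequence, the 1-based position where the adapter
# match starts, or NA. Vectorized per width group via character matrices.
trim_positions <- function(seqs, adapter, min_overlap, max_error_rate) {
  a <- strsplit(adapter, "")[[1]]
  A <- length(a)
  cut <- rep(NA_integer_, length(seqs))
  widths <- nchar(seqs)
  for (w in sort(unique(widths))) {
    idx <- which(widths == w)
    if (w < min_overlap) next
    M <- matrix(unlist(strsplit(seqs[idx], ""), use.names = FALSE),
                nrow = length(idx), ncol = w, byrow = TRUE)
    pos <- rep(NA_integer_, length(idx))
    for (p in seq_len(w - min_overlap + 1L)) {
      ov <- min(w - p + 1L, A)
      allowed <- floor(ov * max_error_rate)
      mm <- rowSums(M[, p:(p + ov - 1L), drop = FALSE] !=
                    matrix(a[seq_len(ov)], nrow = length(idx), ncol = ov,
                           byrow = TRUE))
      newly <- is.na(pos) & mm <= allowed
      pos[newly] <- p
      if (!anyNA(pos)) break
    }
    cut[idx] <- pos
  }
  cut
}

#' Filter reads by footprint length
#'
#' Retains reads whose trimmed length lies in `[min_len, max_len]`;
#' optionally discards reads in which no adapter was found (the default:
#' with 50-nt raw reads and footprints under 41 nt the adapter must be
#' present, so untrimmed reads are artefacts).
#'
#' @param reads data.frame from [trim_adapter()] (columns `read_id`,
#'   `sequence`, and optionally `adapter_found`).
#' @param min_len,max_len Inclusive length bounds in nt.
#' @param drop_untrimmed Discard reads with `adapter_found == FALSE`.
#' @return The retained rows, with an attribute `discarded` giving counts
#'   `short`, `long` and `untrimmed`.
#' @export
length_filter <- function(reads, min_len = 25L, max_len = 35L,
                          drop_untrimmed = TRUE) {
  stopifnot(min_len <= max_len)
  len <- nchar(reads$sequence)
  untrimmed <- if (drop_untrimmed && "adapter_found" %in% names(reads)) {
    !reads$adapter_found
  } else {
    rep(FALSE, nrow(reads))
  }
  short <- !untrimmed & len < min_len
  long <- !untrimmed & len > max_len
  keep <- !untrimmed & !short & !long
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "discarded") <- c(short = sum(short), long = sum(long),
                              untrimmed = sum(untrimmed))
  out
}

#' Map reads exhaustively to a circular genome
#'
#' Scans every circular offset of the genome on both strands (the reference
#' is a few kb, so exhaustive scanning is exact and fast) and ranks loci by
#' mismatch count. A read is `UNIQUE` iff a single locus attains the minimal
#' count and that minimum is at most `max_mismatches`; ties are never broken
#' silently and give `MULTI`. `five_prime_pos` is the 0-based genomic
#' coordinate of the read's 5' base; on the minus strand that is the
#' highest-coordinate aligned base.
#'
#' @param genome A [mito_genome()].
#' @param reads data.frame with `read_id` and `sequence`.
#' @param max_mismatches Maximum tolerated mismatches (default 1,
#'   approximating short-read aligner tolerance at footprint lengths).
#' @return data.frame with `read_id`, `five_prime_pos`, `strand`,
#'   `n_mismatches`, `status` (`UNIQUE`/`MULTI`/`UNMAPPED`) and `width`.
#' @export
map_reads <- function(genome, reads, max_mismatches = 1L) {
  if (nrow(reads) == 0L) {
    return(data.frame(read_id = character(0), five_prime_pos = integer(0),
                      strand = character(0), n_mismatches = integer(0),
                      status = character(0), width = integer(0),
                      stringsAsFactors = FALSE))
  }
  seqs <- toupper(reads$sequence)
  if (any(nchar(seqs) > genome$length)) stop("read longer than the genome")
  if (any(nchar(seqs) == 0L)) stop("empty read in input")
  hits <- .scan_reads(genome$sequence, seqs, as.integer(max_mismatches))
  cbind(data.frame(read_id = reads$read_id, stringsAsFactors = FALSE),
        hits, data.frame(width = nchar(seqs)))
}

#' Write alignments as minimal SAM
#'
#' Emits an unsorted single-reference SAM with 1-based `POS`, FLAG 0/16 for
#' plus/minus strand, `MAPQ` 255 and an ungapped `<len>M` CIGAR. Reads
#' spanning the circular origin keep their full-length CIGAR with `POS` at
#' the 5'-side offset. Only `UNIQUE` alignments are written.
#'
#' @param alignments data.frame from [map_reads()].
#' @param reads data.frame with `read_id` and `sequence` (trimmed).
#' @param genome The [mito_genome()] mapped against.
#' @param path Output SAM path.
#' @export
write_sam <- function(alignments, reads, genome, path) {
  aln <- alignments[alignments$status == "UNIQUE", , drop = FALSE]
  seqs <- reads$sequence[match(aln$read_id, reads$read_id)]
  w <- nchar(seqs)
  minus <- aln$strand == "-"
  # POS of the leftmost aligned base (5' base on +, 3' base on -)
  left <- ifelse(minus, (aln$five_prime_pos - w + 1L) %% genome$length,
                 aln$five_prime_pos)
  out_seq <- seqs
  if (any(minus)) {
    out_seq[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[minus])))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", genome$name, genome$length)), con)
  if (nrow(aln)) {
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                       aln$read_id, ifelse(minus, 16L, 0L), genome$name,
                       left + 1L, w, out_seq), con)
  }
  invisible(path)
}

#' Run trimming, filtering and mapping in one call
#'
#' @param genome A [mito_genome()].
#' @param reads Raw reads data.frame (`read_id`, `sequence`).
#' @param adapter,min_overlap,max_error_rate Passed to [trim_adapter()].
#' @param min_len,max_len,drop_untrimmed Passed to [length_filter()].
#' @param max_mismatches Passed to [map_reads()].
#' @return List with `trimmed`, `filtered` (with `discarded` attribute) and
#'   `alignments`.
#' @export
process_reads <- function(genome, reads,
                          adapter = "TGGAATTCTCGGGTGCCAAGG",
                          min_overlap = 3L, max_error_rate = 0.1,
                          min_len = 25L, max_len = 35L,
                          drop_untrimmed = TRUE, max_mismatches = 1L) {
  trimmed <- trim_adapter(reads, adapter, min_overlap, max_error_rate)
  filtered <- length_filter(trimmed, min_len, max_len, drop_untrimmed)
  alignments <- map_reads(genome, filtered, max_mismatches)
  list(trimmed = trimmed, filtered = filtered, alignments = alignments)
}
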