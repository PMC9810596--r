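#' A-site genomic position of an alignment
#'
#' The A-site's first base sits a fixed number of nt downstream (3'-ward)
#' of the footprint's 5' end: `five_prime_pos + offset` on the plus strand,
#' `five_prime_pos - offset` on the minus strand, modulo the circular
#' genome length.
#'
#' @param five_prime_pos 0-based genomic coordinate(s) of footprint 5' ends.
#' @param strand `"+"`/`"-"` per alignment.
#' @param genome_length Circular genome length in nt.
#' @param offset A-site offset in nt (default 14).
#' @return Integer vector of 0-based A-site coordinates.
#' @export
asite_genomic_position <- function(five_prime_pos, strand, genome_length,
                                   offset = 14L) {
  L <- as.integer(genome_length)
  pos <- as.integer(five_prime_pos)
  ifelse(strand == "+", (pos + offset) %% L, (pos - offset) %% L)
}

#' Assign unique alignments to A-site codons
#'
#' Converts each `UNIQUE` alignment's A-site position into a codon index in
#' every same-strand ORF containing it. In bicistronic overlap regions a
#' position can fall into two ORFs and is counted toward both (the
#' double-count is reported); A-sites outside all same-strand ORFs are
#' tallied as off-ORF rather than silently dropped.
#'
#' @param genome A [mito_genome()].
#' @param orfs An [orf_annotation()].
#' @param alignments data.frame from [map_reads()].
#' @param offset A-site offset in nt.
#' @return data.frame with `read_id`, `gene`, `codon_index`, `codon`,
#'   `genomic_a_pos` and `strand` (possibly several rows per read), with
#'   attributes `off_orf` (count of unique alignments whose A-site lies in
#'   no same-strand ORF) and `overlap_reads` (reads assigned to more than
#'   one ORF).
#' @export
assign_alignments <- function(genome, orfs, alignments, offset = 14L) {
  aln <- alignments[alignments$status == "UNIQUE", , drop = FALSE]
  if (any(aln$width < offset + 1L)) {
    stop("footprint shorter than offset + 1 cannot carry an A-site")
  }
  apos <- asite_genomic_position(aln$five_prime_pos, aln$strand,
                                 genome$length, offset)
  pieces <- vector("list", nrow(orfs))
  for (i in seq_len(nrow(orfs))) {
    orf <- orfs[i, ]
    same <- aln$strand == orf$strand
    idx <- rep(NA_integer_, nrow(aln))
    idx[same] <- genomic_to_codon_index(orf, apos[same], genome$length)
    hit <- which(!is.na(idx))
    if (length(hit)) {
      cods <- codons_of(genome, orf)
      pieces[[i]] <- data.frame(
        read_id = aln$read_id[hit], gene = orf$gene,
        codon_index = idx[hit], codon = cods[idx[hit] + 1L],
        genomic_a_pos = apos[hit], strand = orf$strand,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, pieces[!vapply(pieces, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(read_id = character(0), gene = character(0),
                      codon_index = integer(0), codon = character(0),
                      genomic_a_pos = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
  }
  assigned <- unique(out$read_id)
  attr(out, "off_orf") <- nrow(aln) - length(assigned)
  attr(out, "overlap_reads") <- sum(table(out$read_id) > 1L)
  out
}

#' Build a per-sample codon count table
#'
#' The central object of the analysis: A-site counts indexed by
#' `(gene, codon_index)` over the complete codon grid of the annotation
#' (cells without assignments are explicit zeros).
#'
#' @param assignments data.frame from [assign_alignments()] (one sample).
#' @param orfs The [orf_annotation()] defining the codon grid.
#' @param genome The [mito_genome()] (for codon identities).
#' @param sample_id Sample label stored with the table.
#' @return A `codon_count_table`: data.frame with `sample`, `gene`,
#'   `codon_index`, `codon`, `count`.
#' @export
build_count_table <- function(assignments, orfs, genome,
                              sample_id = "sample") {
  grid <- do.call(rbind, lapply(seq_len(nrow(orfs)), function(i) {
    cods <- codons_of(genome, orfs[i, ])
    data.frame(gene = orfs$gene[i], codon_index = seq_along(cods) - 1L,
               codon = cods, stringsAsFactors = FALSE)
  }))
  key <- paste(grid$gene, grid$codon_index)
  cnt <- table(factor(paste(assignments$gene, assignments$codon_index),
                      levels = key))
  out <- data.frame(sample = sample_id, grid,
                    count = as.integer(cnt), stringsAsFactors = FALSE)
  class(out) <- c("codon_count_table", "data.frame")
  out
}

#' Per-gene total counts of a count table
#'
#' @param table A `codon_count_table`.
#' @return Named numeric vector of per-gene totals (annotation order).
#' @export
gene_totals <- function(table) {
  t <- tapply(table$count, table$gene, sum)
  setNames(as.numeric(t), names(t))[unique(table$gene)]
}

#' Grand total of a count table
#'
#' @param table A `codon_count_table`.
#' @return Total assigned A-site count.
#' @export
grand_total <- function(table) sum(table$count)

#' Write / read a codon count table as tidy TSV
#'
#' @param table A `codon_count_table`.
#' @param path TSV path.
#' @export
write_count_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("codon_count_table", "data.frame")
  out
}

#' Count table directly from a simulation truth table
#'
#' Replays the generator's planted `(gene, codon index)` assignments into a
#' count table, bypassing read processing. With error-free reads this equals
#' the table produced by the full pipeline restricted to retained footprint
#' lengths; it is used for fast closed-form comparisons.
#'
#' @param truth Truth data.frame from [simulate_reads()].
#' @param orfs,genome,sample_id As in [build_count_table()].
#' @param min_len,max_len Footprint length window retained for counting.
#' @return A `codon_count_table`.
#' @export
count_table_from_truth <- function(truth, orfs, genome,
                                   sample_id = "truth",
                                   min_len = 25L, max_len = 35L) {
  keep <- truth$footprint_length >= min_len & truth$footprint_length <= max_len
  build_count_table(
    data.frame(gene = truth$gene[keep],
               codon_index = truth$a_site_codon_index[keep],
               stringsAsFactors = FALSE),
    orfs, genome, sample_id = sample_id)
}
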