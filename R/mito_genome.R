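#' Circular mitochondrial genome
#'
#' Container for a single circular replicon. All coordinates used in this
#' package are 0-based, half-open, on the forward axis of this sequence;
#' strand only changes reading direction. Positions are interpreted modulo
#' the genome length, so annotations and reads may wrap the origin.
#'
#' @param sequence Nucleotide string over \{A,C,G,T\} (case-insensitive).
#' @param name Text identifier for the replicon.
#' @param circular Logical; mitochondrial genomes are circular and the
#'   mapper and coordinate arithmetic assume it.
#' @return An object of class `MitoGenome`: a list with elements `name`,
#'   `sequence` (upper case), `length` and `circular`.
#' @examples
#' g <- mito_genome("ATGAAATAA", name = "toy")
#' g$length
#' @export
mito_genome <- function(sequence, name = "mtDNA", circular = TRUE) {
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) == 0L) stop("genome sequence must be non-empty")
  if (grepl("[^ACGT]", sequence)) {
    stop("genome sequence must be over the alphabet {A,C,G,T}")
  }
  structure(
    list(name = as.character(name), sequence = sequence,
         length = nchar(sequence), circular = isTRUE(circular)),
    class = "MitoGenome"
  )
}

#' @export
print.MitoGenome <- function(x, ...) {
  cat(sprintf("MitoGenome '%s': %d nt, %s\n", x$name, x$length,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Read a single-record FASTA as a MitoGenome
#'
#' @param path Path to a FASTA file with exactly one record.
#' @param circular Logical, passed to [mito_genome()].
#' @return A `MitoGenome`.
#' @export
read_genome_fasta <- function(path, circular = TRUE) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1L) {
    stop("expected a single-record FASTA, found ", length(set), " records")
  }
  nm <- sub("\\s.*$", "", names(set)[1])
  mito_genome(as.character(set[[1]]), name = nm, circular = circular)
}

#' Write a MitoGenome to FASTA
#'
#' @param genome A `MitoGenome`.
#' @param path Output file path.
#' @export
write_genome_fasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(genome$sequence)
  names(set) <- genome$name
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# circular slice: len bases starting at 0-based pos, wrapping the origin
circ_slice <- function(genome, pos0, len) {
  L <- genome$length
  if (len > 2L * L) stop("slice longer than twice the genome")
  pos0 <- ((pos0 %% L) + L) %% L
  doubled <- paste0(genome$sequence, genome$sequence)
  substr(doubled, pos0 + 1L, pos0 + len)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' ORF annotation table
#'
#' Validates and normalizes a set of protein-coding ORF annotations.
#' `start`/`end` are 0-based half-open genomic coordinates of the transcribed
#' coding region on the forward axis (an ORF wrapping the origin has
#' `end > genome length` after unwrapping); `strand` is `+` or `-`;
#' `polya_completion` is the number (0--2) of A residues appended
#' post-transcriptionally to complete the terminal stop codon, an annotation
#' input rather than something inferred from sequence. Overlapping ORFs
#' (bicistronic pairs) are allowed.
#'
#' @param df A data.frame with columns `gene`, `start`, `end`, `strand`,
#'   `polya_completion`.
#' @param genome Optional `MitoGenome` used to range-check coordinates.
#' @return The validated data.frame with class `orf_annotation` prepended.
#' @export
orf_annotation <- function(df, genome = NULL) {
  req <- c("gene", "start", "end", "strand", "polya_completion")
  if (!all(req %in% names(df))) {
    stop("annotation must have columns: ", paste(req, collapse = ", "))
  }
  df <- as.data.frame(df)[, req]
  df$gene <- as.character(df$gene)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$strand <- as.character(df$strand)
  df$polya_completion <- as.integer(df$polya_completion)
  if (anyDuplicated(df$gene)) stop("gene symbols must be unique")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(df$polya_completion < 0L | df$polya_completion > 2L)) {
    stop("polya_completion must be in 0..2")
  }
  if (any(df$end <= df$start)) {
    stop("ORFs must satisfy start < end after circular unwrapping")
  }
  if (any((df$end - df$start + df$polya_completion) %% 3L != 0L)) {
    stop("ORF length plus polya_completion must be divisible by 3")
  }
  if (!is.null(genome)) {
    L <- genome$length
    if (any(df$start < 0L | df$start >= L) || any(df$end > df$start + L)) {
      stop("ORF coordinates outside the unwrapped genome range")
    }
  }
  class(df) <- c("orf_annotation", "data.frame")
  df
}

#' Read an ORF annotation table (TSV)
#'
#' Expects a tab-separated file with header
#' `gene  start  end  strand  polya_completion` using 0-based half-open
#' coordinates.
#'
#' @param path Path to the TSV file.
#' @param genome Optional `MitoGenome` for range checks.
#' @return An `orf_annotation` data.frame.
#' @export
read_orf_table <- function(path, genome = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  orf_annotation(df, genome = genome)
}

#' Write an ORF annotation table (TSV)
#'
#' @param orfs An `orf_annotation` data.frame.
#' @param path Output file path.
#' @export
write_orf_table <- function(orfs, path) {
  utils::write.table(orfs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a minimal GFF3 as an ORF annotation
#'
#' Reads CDS (or gene, if no CDS present) features from a GFF3 file,
#' converting 1-based inclusive coordinates to the package's 0-based
#' half-open convention. The gene symbol is taken from the `gene=` or `ID=`
#' attribute; `polya_completion=` may be supplied as a non-standard
#' attribute and defaults to 0.
#'
#' @param path Path to a GFF3 file.
#' @param genome Optional `MitoGenome` for range checks.
#' @return An `orf_annotation` data.frame.
#' @export
read_orf_gff3 <- function(path, genome = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  fields <- fields[vapply(fields, length, 1L) == 9L]
  if (length(fields) == 0L) stop("no GFF3 feature lines found in ", path)
  m <- do.call(rbind, fields)
  keep <- m[, 3] == "CDS"
  if (!any(keep)) keep <- m[, 3] == "gene"
  m <- m[keep, , drop = FALSE]
  attr_get <- function(attrs, key) {
    hit <- regmatches(attrs, regexpr(paste0("(^|;)", key, "=[^;]+"), attrs))
    ifelse(lengths(regmatches(attrs, gregexpr(paste0("(^|;)", key, "="), attrs))) > 0,
           sub(paste0("^.*", key, "="), "", hit), NA_character_)
  }
  gene <- attr_get(m[, 9], "gene")
  gene[is.na(gene)] <- attr_get(m[is.na(gene), 9, drop = TRUE], "ID")
  polya <- suppressWarnings(as.integer(attr_get(m[, 9], "polya_completion")))
  polya[is.na(polya)] <- 0L
  orf_annotation(data.frame(
    gene = gene,
    start = as.integer(m[, 4]) - 1L,  # 1-based inclusive -> 0-based half-open
    end = as.integer(m[, 5]),
    strand = m[, 7],
    polya_completion = polya,
    stringsAsFactors = FALSE
  ), genome = genome)
}

orf_row <- function(orfs, gene) {
  i <- match(gene, orfs$gene)
  if (is.na(i)) stop("gene not found in annotation: ", gene)
  orfs[i, , drop = FALSE]
}

#' mRNA-sense coding sequence of an ORF
#'
#' Returns the coding sequence in translation order: the forward genomic
#' slice for `+` ORFs, the reverse complement for `-` ORFs, with
#' `polya_completion` A residues appended to complete the terminal stop
#' codon. The result length is always divisible by 3.
#'
#' @param genome A `MitoGenome`.
#' @param orf A single-row `orf_annotation` (or a row subset thereof).
#' @return A nucleotide string.
#' @examples
#' g <- mito_genome("ATGAAATAA")
#' orfs <- orf_annotation(data.frame(gene = "X", start = 0, end = 9,
#'                                   strand = "+", polya_completion = 0))
#' orf_mrna_sequence(g, orfs[1, ])
#' @export
orf_mrna_sequence <- function(genome, orf) {
  stopifnot(nrow(orf) == 1L)
  L <- genome$length
  if (orf$start < 0L || orf$start >= L || orf$end > orf$start + L) {
    stop("invalid annotation: coordinates outside the unwrapped genome range")
  }
  genomic <- circ_slice(genome, orf$start, orf$end - orf$start)
  mrna <- if (orf$strand == "+") genomic else revcomp(genomic)
  paste0(mrna, strrep("A", orf$polya_completion))
}

#' Codons of an ORF in translation order
#'
#' @inheritParams orf_mrna_sequence
#' @return Character vector of 3-nt codons whose concatenation equals
#'   [orf_mrna_sequence()].
#' @export
codons_of <- function(genome, orf) {
  mrna <- orf_mrna_sequence(genome, orf)
  n <- nchar(mrna) %/% 3L
  substring(mrna, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Number of codons of each ORF
#'
#' @param orfs An `orf_annotation`.
#' @return Named integer vector of codon counts (including the stop codon).
#' @export
orf_codon_counts <- function(orfs) {
  setNames(as.integer((orfs$end - orfs$start + orfs$polya_completion) %/% 3L),
           orfs$gene)
}

#' Codon frequency across an ORF set
#'
#' Tabulates in-frame codon occurrences over all annotated ORFs (reading
#' each ORF in its own frame and strand, polyA-completed). Every one of the
#' 64 codons is present in the result, possibly with count 0. Overlapping
#' ORFs contribute independently, so shared genomic bases are counted once
#' per reading frame in which they are translated.
#'
#' @param genome A `MitoGenome`.
#' @param orfs An `orf_annotation`.
#' @return Named integer vector of length 64 (codon -> occurrence count).
#' @export
codon_frequency <- function(genome, orfs) {
  if (nrow(orfs) == 0L) stop("annotation set must be non-empty")
  all_codons <- all_codon_identities()
  counts <- setNames(integer(64L), all_codons)
  for (i in seq_len(nrow(orfs))) {
    tab <- table(codons_of(genome, orfs[i, ]))
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  counts
}

all_codon_identities <- function() {
  b <- c("A", "C", "G", "T")
  paste0(rep(b, each = 16L), rep(rep(b, each = 4L), 4L), rep(b, 16L))
}

#' Convert a genomic position to a codon index within one ORF
#'
#' For a position inside the ORF, returns the 0-based codon index along the
#' mRNA: `floor((pos - start)/3)` on `+`, `floor((end - 1 - pos)/3)` on `-`
#' (both modulo the genome for origin-wrapping ORFs). Positions falling in
#' the genomically encoded bases of a polyA-completed terminal codon map to
#' the final codon index. Positions outside the ORF give `NA`.
#'
#' @param orf A single-row `orf_annotation`.
#' @param genomic_pos Integer vector of 0-based genomic positions.
#' @param genome_length Genome length in nt (for circular unwrapping).
#' @return Integer vector of codon indices, `NA` where not in the ORF.
#' @export
genomic_to_codon_index <- function(orf, genomic_pos, genome_length) {
  stopifnot(nrow(orf) == 1L)
  L <- as.integer(genome_length)
  len <- orf$end - orf$start
  rel <- ((as.integer(genomic_pos) - orf$start) %% L + L) %% L
  inside <- rel < len
  m <- if (orf$strand == "+") rel else (len - 1L) - rel
  idx <- m %/% 3L
  idx[!inside] <- NA_integer_
  idx
}
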