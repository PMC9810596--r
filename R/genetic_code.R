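#' Vertebrate mitochondrial genetic code
#'
#' Builds the genetic-code object used throughout the package. The amino
#' acid table is NCBI translation table 2 (vertebrate mitochondrial, via
#' [Biostrings::getGeneticCode()]): UGA is reassigned to tryptophan and
#' AUA encodes methionine. On top of that table the stop codons are split
#' into two categories: the canonical stops `TAA`/`TAG` (recognized by
#' mtRF1a) and the non-canonical stops `AGA`/`AGG`, which have no cognate
#' tRNAs in human mitochondria and terminate COX1 and ND6 respectively.
#'
#' @param table Optional named character vector of 64 codon -> amino-acid
#'   (one-letter) entries overriding the built-in table for cross-species
#'   use. Stop codons must be `"*"`.
#' @param canonical_stops,noncanonical_stops Codon sets for the two stop
#'   categories; together they must equal the `"*"` entries of `table`.
#' @param start_codons Set of start codons; AUA/AUU are reassigned starts
#'   in vertebrate mitochondria.
#' @return An object of class `genetic_code`.
#' @examples
#' code <- mito_genetic_code()
#' classify_codons(code, c("TGA", "AGA", "TAA"))
#' @export
mito_genetic_code <- function(table = NULL,
                              canonical_stops = c("TAA", "TAG"),
                              noncanonical_stops = c("AGA", "AGG"),
                              start_codons = c("ATG", "ATA", "ATT")) {
  if (is.null(table)) {
    table <- Biostrings::getGeneticCode("2")  # SGC1, vertebrate mitochondrial
  }
  table <- table[order(names(table))]
  if (length(table) != 64L || !setequal(names(table), all_codon_identities())) {
    stop("genetic code table must map exactly the 64 codons")
  }
  stops <- names(table)[table == "*"]
  if (!setequal(stops, c(canonical_stops, noncanonical_stops))) {
    stop("stop categories must partition the '*' entries of the table")
  }
  structure(
    list(table = table,
         canonical_stops = canonical_stops,
         noncanonical_stops = noncanonical_stops,
         start_codons = start_codons),
    class = "genetic_code"
  )
}

#' Classify codons under a genetic code
#'
#' @param code A `genetic_code` from [mito_genetic_code()].
#' @param codons Character vector of 3-nt codons over \{A,C,G,T\}.
#' @return A data.frame with columns `codon`, `category` (one of
#'   `"AMINO_ACID"`, `"CANONICAL_STOP"`, `"NONCANONICAL_STOP"`) and
#'   `residue` (one-letter amino acid, `NA` for stops).
#' @export
classify_codons <- function(code, codons) {
  stopifnot(inherits(code, "genetic_code"))
  codons <- toupper(codons)
  bad <- nchar(codons) != 3L | grepl("[^ACGT]", codons)
  if (any(bad)) {
    stop("invalid codon(s): ", paste(unique(codons[bad]), collapse = ", "))
  }
  aa <- unname(code$table[codons])
  category <- ifelse(codons %in% code$canonical_stops, "CANONICAL_STOP",
              ifelse(codons %in% code$noncanonical_stops, "NONCANONICAL_STOP",
                     "AMINO_ACID"))
  data.frame(codon = codons, category = category,
             residue = ifelse(category == "AMINO_ACID", aa, NA_character_),
             stringsAsFactors = FALSE)
}
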