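# Synthetic circular genome emulating the human mtDNA layout.
#
# The construction mirrors the qualitative layout of the human
# mitochondrial genome without reusing its coordinates or sequence:
# 13 protein-coding ORFs in human gene order, ND6 on the minus strand,
# COX1 terminating at the non-canonical stop AGA and ND6 at AGG (with the
# genome's single in-frame CGG codon immediately upstream of ND6's stop),
# two bicistronic overlaps (ATP8/ATP6 offset by 46 nt and ND4L/ND4 by 7 nt,
# in different reading frames), and five ORFs whose terminal UAA stop is
# completed post-transcriptionally by polyadenylation (T or TA at the
# genomic 3' end). The remaining 11 of 13 ORFs terminate at UAA/UAG.

with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

FORBIDDEN_INTERNAL <- c("TAA", "TAG", "AGA", "AGG", "CGG")

internal_codon_pool <- function() {
  setdiff(all_codon_identities(), FORBIDDEN_INTERNAL)
}

sample_codons <- function(n, pool = internal_codon_pool()) {
  if (n == 0L) return(character(0))
  sample(pool, n, replace = TRUE)
}

random_spacer <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

in_frame_codons <- function(seq, from = 1L) {
  n <- (nchar(seq) - from + 1L) %/% 3L
  if (n <= 0L) return(character(0))
  starts <- from + 3L * (seq_len(n) - 1L)
  substring(seq, starts, starts + 2L)
}

#' Synthetic human-layout mitochondrial genome fixture
#'
#' Deterministically constructs a small circular genome that reproduces the
#' features of the human mitochondrial coding layout that matter for stall
#' analysis: 13 ORFs named after the human mtDNA genes, ND6 on the minus
#' strand, COX1 ending at AGA and ND6 at AGG, exactly one in-frame CGG codon
#' across all ORFs (the penultimate codon of ND6), two bicistronic overlaps
#' in shifted reading frames (ATP8/ATP6, ND4L/ND4), alternative start codons
#' (ATA for ND3, ATT for ND5), and five UAA stops completed by
#' polyadenylation. It is a synthetic stand-in, not the NC_012920 sequence;
#' ORF lengths are scaled down (about 1.1 kb of codons on a ~3.6 kb circle)
#' so exhaustive analyses stay fast.
#'
#' @param seed Integer seed for the construction's private RNG stream; the
#'   default defines the bundled fixture shipped in `inst/extdata`.
#' @return A list with elements `genome` (a [mito_genome()]), `orfs` (an
#'   [orf_annotation()]) and `code` (a [mito_genetic_code()]).
#' @examples
#' fx <- synthetic_mito_genome()
#' fx$genome
#' @export
synthetic_mito_genome <- function(seed = 20260923L) {
  with_local_seed(seed, build_synthetic_mito_genome())
}

build_synthetic_mito_genome <- function() {
  pool <- internal_codon_pool()
  pool_end_a <- pool[substr(pool, 3, 3) == "A"]
  pool_start_a <- pool[substr(pool, 1, 1) == "A"]

  # plain + strand ORF: returns list(mrna, genomic, polya)
  plain_orf <- function(n_codons, stop_codon, polya, start_codon = "ATG") {
    body <- sample_codons(n_codons - 2L, pool)
    mrna <- paste(c(start_codon, body, stop_codon), collapse = "")
    list(mrna = mrna,
         genomic = substr(mrna, 1L, nchar(mrna) - polya),
         polya = polya)
  }

  # ATP8 (40 codons, ends TAA) with ATP6 starting 46 nt before ATP8's end.
  # ATP6's first codon (ATG) is pinned inside ATP8 via codon 25 ending in A
  # and codon 26 starting TG; ATP8's tail is resampled until the overlap is
  # clean in ATP6's frame (no stop or CGG codons).
  make_atp8 <- function() {
    repeat {
      c25 <- sample(pool_end_a, 1L)
      c26 <- paste0("TG", sample(c("A", "C", "G", "T"), 1L))
      codons <- c("ATG", sample_codons(23L, pool), c25, c26,
                  sample_codons(13L, pool), "TAA")
      seq <- paste(codons, collapse = "")
      stopifnot(nchar(seq) == 120L)
      overlap_frame <- in_frame_codons(seq, from = 75L)  # ATP6 codons 1..15
      if (overlap_frame[1] == "ATG" &&
          !any(overlap_frame %in% FORBIDDEN_INTERNAL)) {
        return(seq)
      }
    }
  }

  # ND4L (35 codons, ends TAA) with ND4 starting 7 nt before ND4L's end;
  # codon 33 ends in A and codon 34 starts TG, pinning ND4's ATG. The two
  # ND4-frame codons inside the overlap are clean by construction.
  make_nd4l <- function() {
    c33 <- sample(pool_end_a, 1L)
    c34 <- paste0("TG", sample(c("A", "C", "G", "T"), 1L))
    seq <- paste(c("ATG", sample_codons(31L, pool), c33, c34, "TAA"),
                 collapse = "")
    stopifnot(nchar(seq) == 105L)
    seq
  }

  # continuation of a nested ORF whose first fixed base(s) come from the
  # upstream ORF: first fresh codon is drawn conditioned on the fixed prefix
  nested_continuation <- function(fixed_prefix, n_codons_left, stop_codon,
                                  polya) {
    cand <- pool[startsWith(pool, fixed_prefix)]
    first <- sample(cand, 1L)
    fresh_first <- substr(first, nchar(fixed_prefix) + 1L, 3L)
    body <- sample_codons(n_codons_left - 2L, pool)
    genomic_tail <- paste(c(fresh_first, body,
                            substr(stop_codon, 1L, 3L - polya)),
                          collapse = "")
    genomic_tail
  }

  segs <- character(0)
  orfs <- list()
  pos <- 0L
  add_seg <- function(s) {
    segs[[length(segs) + 1L]] <<- s
    pos <<- pos + nchar(s)
  }
  add_orf <- function(gene, start, end, strand, polya) {
    orfs[[length(orfs) + 1L]] <<- data.frame(
      gene = gene, start = start, end = end, strand = strand,
      polya_completion = polya, stringsAsFactors = FALSE)
  }

  add_seg(random_spacer(5L))

  # ND1
  o <- plain_orf(80L, "TAA", 0L)
  add_orf("ND1", pos, pos + nchar(o$genomic), "+", 0L); add_seg(o$genomic)
  add_seg(random_spacer(24L))

  # ND2 (UAA completed by one polyA base)
  o <- plain_orf(90L, "TAA", 1L)
  add_orf("ND2", pos, pos + nchar(o$genomic), "+", 1L); add_seg(o$genomic)
  add_seg(random_spacer(30L))

  # COX1 terminates at the non-canonical stop AGA
  o <- plain_orf(150L, "AGA", 0L)
  add_orf("COX1", pos, pos + nchar(o$genomic), "+", 0L); add_seg(o$genomic)
  add_seg(random_spacer(27L))

  # COX2
  o <- plain_orf(70L, "TAA", 0L)
  add_orf("COX2", pos, pos + nchar(o$genomic), "+", 0L); add_seg(o$genomic)
  add_seg(random_spacer(22L))

  # ATP8 / ATP6 bicistronic pair (46 nt overlap, frames shifted by 2)
  atp8 <- make_atp8()
  atp8_start <- pos
  add_orf("ATP8", atp8_start, atp8_start + 120L, "+", 0L)
  add_seg(atp8)
  atp6_start <- atp8_start + 120L - 46L
  atp6_tail <- nested_continuation("A", 75L - 15L, "TAA", polya = 1L)
  add_orf("ATP6", atp6_start, atp6_start + 46L + nchar(atp6_tail), "+", 1L)
  add_seg(atp6_tail)
  add_seg(random_spacer(26L))

  # COX3 (UAA completed by two polyA bases)
  o <- plain_orf(80L, "TAA", 2L)
  add_orf("COX3", pos, pos + nchar(o$genomic), "+", 2L); add_seg(o$genomic)
  add_seg(random_spacer(21L))

  # ND3 (alternative start ATA, UAA completed by two polyA bases)
  o <- plain_orf(40L, "TAA", 2L, start_codon = "ATA")
  add_orf("ND3", pos, pos + nchar(o$genomic), "+", 2L); add_seg(o$genomic)
  add_seg(random_spacer(23L))

  # ND4L / ND4 bicistronic pair (7 nt overlap)
  nd4l <- make_nd4l()
  nd4l_start <- pos
  add_orf("ND4L", nd4l_start, nd4l_start + 105L, "+", 0L)
  add_seg(nd4l)
  nd4_start <- nd4l_start + 105L - 7L
  # ND4 codons 1-2 live inside ND4L; codon 3 starts at ND4L's final base 'A'
  nd4_tail <- nested_continuation("A", 120L - 3L + 1L, "TAA", polya = 2L)
  add_orf("ND4", nd4_start, nd4_start + 7L + nchar(nd4_tail), "+", 2L)
  add_seg(nd4_tail)
  add_seg(random_spacer(25L))

  # ND5 (alternative start ATT)
  o <- plain_orf(140L, "TAA", 0L, start_codon = "ATT")
  add_orf("ND5", pos, pos + nchar(o$genomic), "+", 0L); add_seg(o$genomic)
  add_seg(random_spacer(28L))

  # ND6 on the minus strand: mRNA carries the genome's only in-frame CGG
  # as its penultimate codon, followed by the non-canonical stop AGG
  nd6_mrna <- paste(c("ATG", sample_codons(57L, pool), "CGG", "AGG"),
                    collapse = "")
  nd6_genomic <- revcomp(nd6_mrna)
  add_orf("ND6", pos, pos + nchar(nd6_genomic), "-", 0L)
  add_seg(nd6_genomic)
  add_seg(random_spacer(24L))

  # CYTB
  o <- plain_orf(100L, "TAG", 0L)
  add_orf("CYTB", pos, pos + nchar(o$genomic), "+", 0L); add_seg(o$genomic)
  add_seg(random_spacer(120L))  # control-region-like tail

  genome <- mito_genome(paste(segs, collapse = ""), name = "synthetic_mtDNA")
  ann <- orf_annotation(do.call(rbind, orfs), genome = genome)
  code <- mito_genetic_code()

  # construction self-checks: single CGG, designed stop identities
  freq <- codon_frequency(genome, ann)
  stopifnot(freq[["CGG"]] == 1L)
  stops <- vapply(seq_len(nrow(ann)), function(i) {
    cods <- codons_of(genome, ann[i, ])
    cods[length(cods)]
  }, character(1))
  stopifnot(stops[ann$gene == "COX1"] == "AGA",
            stops[ann$gene == "ND6"] == "AGG",
            sum(stops %in% c("TAA", "TAG")) == 11L)

  list(genome = genome, orfs = ann, code = code)
}
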