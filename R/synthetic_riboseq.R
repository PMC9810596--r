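#' Stall specification for the read simulator
#'
#' Describes one programmed stalling event: an occupancy multiplier at a
#' codon (typically the stop codon) and, optionally, a queued-ribosome peak
#' one footprint length upstream. A 35-nt mitoribosome footprint spans about
#' 12 codons, so trailing ribosomes queued behind a stalled one pause
#' 12--13 codons upstream; `queue_offset` defaults to 12.
#'
#' @param gene Gene symbol the stall applies to.
#' @param codon_index 0-based codon index of the stall, or the string
#'   `"terminal"` for the stop codon.
#' @param multiplier Occupancy enhancement (>= 1) at `codon_index`.
#' @param queue_multiplier Enhancement applied `queue_offset` codons
#'   upstream of `codon_index` (1 = no queued peak).
#' @param queue_offset Distance of the queued peak in codons.
#' @return An object of class `stall_spec`.
#' @export
stall_spec <- function(gene, codon_index = "terminal", multiplier,
                       queue_multiplier = 1, queue_offset = 12L) {
  stopifnot(multiplier >= 1, queue_multiplier >= 1, queue_offset >= 1)
  structure(list(gene = gene, codon_index = codon_index,
                 multiplier = multiplier,
                 queue_multiplier = queue_multiplier,
                 queue_offset = as.integer(queue_offset)),
            class = "stall_spec")
}

#' Default footprint length distribution
#'
#' Triangular distribution over 25--40 nt peaking at 33--35 nt: gel slices
#' of 30--40 nt are excised during library preparation and mitoribosome
#' footprints usually comprise 35 nt. Lengths above 35 nt are generated so
#' the `max_length` filter of the counting stage is exercised.
#'
#' @return Named numeric vector of probabilities over lengths 25..40.
#' @export
default_length_distribution <- function() {
  lens <- 25:40
  w <- c(1:9, 9, 9, 7, 5, 3, 2, 1)
  setNames(w / sum(w), lens)
}

#' Simulation configuration
#'
#' @param n_reads Number of reads to simulate.
#' @param transcript_weights Named positive weights per gene. A gene is
#'   sampled proportionally to `weight * sum(density)`, so with uniform
#'   per-codon density an equal weight gives longer genes more reads.
#'   `NULL` (default) assigns every annotated gene weight 1.
#' @param stalls List of [stall_spec()] objects.
#' @param length_distribution Named probability vector over footprint
#'   lengths (nt); default [default_length_distribution()].
#' @param adapter 3' adapter ligated to each footprint (TruSeq small-RNA
#'   adapter by default).
#' @param read_length Raw sequencer read length; the emitted read is
#'   footprint + adapter truncated to this many bases.
#' @param offset A-site offset: the A-site's first base sits exactly this
#'   many nt downstream of the footprint 5' end, for all footprint lengths.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_reads = 50000L,
                              transcript_weights = NULL,
                              stalls = list(),
                              length_distribution = default_length_distribution(),
                              adapter = "TGGAATTCTCGGGTGCCAAGG",
                              read_length = 50L,
                              offset = 14L,
                              seed = 1L) {
  stopifnot(n_reads > 0L)
  p <- as.numeric(length_distribution)
  if (abs(sum(p) - 1) > 1e-8) stop("length distribution must sum to 1")
  lens <- as.integer(names(length_distribution))
  counted <- lens[p > 0]
  if (offset + 3L > min(counted)) {
    stop("offset + 3 must not exceed the minimum footprint length")
  }
  if (inherits(stalls, "stall_spec")) stalls <- list(stalls)
  structure(list(n_reads = as.integer(n_reads),
                 transcript_weights = transcript_weights,
                 stalls = stalls,
                 length_distribution = length_distribution,
                 adapter = toupper(adapter),
                 read_length = as.integer(read_length),
                 offset = as.integer(offset),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Per-codon occupancy weights for one ORF
#'
#' Builds the sampling density the simulator uses: a constant base density
#' multiplied, at each programmed stall, by its occupancy multiplier, and by
#' the queue multiplier `queue_offset` codons upstream.
#'
#' @param orf Single-row [orf_annotation()].
#' @param stalls List of [stall_spec()]; only entries matching `orf$gene`
#'   apply.
#' @param base_density Positive baseline weight per codon.
#' @return Numeric weight vector of length equal to the ORF codon count
#'   (position `i` is codon index `i - 1`).
#' @export
build_density_profile <- function(orf, stalls = list(), base_density = 1) {
  stopifnot(nrow(orf) == 1L, base_density > 0)
  n <- unname(orf_codon_counts(orf))
  w <- rep(as.numeric(base_density), n)
  for (s in stalls) {
    if (!identical(s$gene, orf$gene)) next
    idx <- if (identical(s$codon_index, "terminal")) n - 1L
           else as.integer(s$codon_index)
    if (idx < 0L || idx >= n) {
      stop("stall codon index out of range for gene ", orf$gene)
    }
    w[idx + 1L] <- w[idx + 1L] * s$multiplier
    if (s$queue_multiplier > 1) {
      q <- idx - s$queue_offset
      if (q < 0L) stop("queue offset extends upstream of gene ", orf$gene)
      w[q + 1L] <- w[q + 1L] * s$queue_multiplier
    }
  }
  w
}

#' Simulate mitoribosome-profiling reads with ground truth
#'
#' Draws, for each read, a gene (proportional to transcript weight times
#' total density), an A-site codon (proportional to the gene's density
#' profile), and a footprint length; the footprint is the strand-aware
#' genomic sequence whose 5' end lies `offset` nt upstream of the A-site
#' first base, extended 3'-ward and wrapped across the circular origin where
#' needed. The emitted read is footprint + adapter truncated to the raw read
#' length, with constant quality. No sequencing errors are introduced unless
#' `error_rate > 0`.
#'
#' @param genome A [mito_genome()].
#' @param orfs An [orf_annotation()].
#' @param config A [simulation_config()].
#' @param error_rate Optional per-base substitution probability applied to
#'   the footprint portion (default 0, so every read maps back exactly).
#' @return List with `reads` (data.frame `read_id`, `sequence`, `quality`)
#'   and `truth` (data.frame `read_id`, `gene`, `a_site_codon_index`,
#'   `strand`, `footprint_length`, `five_prime_pos`).
#' @export
simulate_reads <- function(genome, orfs, config, error_rate = 0) {
  stopifnot(inherits(config, "simulation_config"))
  with_local_seed(config$seed, {
    genes <- orfs$gene
    weights <- config$transcript_weights
    if (is.null(weights)) weights <- setNames(rep(1, length(genes)), genes)
    if (!all(genes %in% names(weights))) {
      weights <- weights[names(weights) %in% genes]
      genes <- names(weights)
    }
    if (any(weights < 0) || sum(weights) <= 0) {
      stop("transcript weights must be positive")
    }
    dens <- lapply(genes, function(g) {
      build_density_profile(orf_row(orfs, g), config$stalls)
    })
    names(dens) <- genes
    mass <- weights[genes] * vapply(dens, sum, 1.0)
    if (sum(mass) <= 0) stop("all-zero sampling weights")

    n <- config$n_reads
    gene_of <- sample(genes, n, replace = TRUE, prob = mass)
    codon_of <- integer(n)
    for (g in genes) {
      sel <- which(gene_of == g)
      if (length(sel)) {
        codon_of[sel] <- sample.int(length(dens[[g]]), length(sel),
                                    replace = TRUE, prob = dens[[g]]) - 1L
      }
    }
    lens <- as.integer(names(config$length_distribution))
    len_of <- sample(lens, n, replace = TRUE,
                     prob = as.numeric(config$length_distribution))

    L <- genome$length
    ost <- orfs$start[match(gene_of, orfs$gene)]
    oen <- orfs$end[match(gene_of, orfs$gene)]
    strand <- orfs$strand[match(gene_of, orfs$gene)]
    plus <- strand == "+"
    apos <- integer(n)
    apos[plus] <- (ost[plus] + 3L * codon_of[plus]) %% L
    apos[!plus] <- (oen[!plus] - 1L - 3L * codon_of[!plus]) %% L

    five_prime <- integer(n)
    slice_start <- integer(n)  # leftmost genomic base of the footprint
    five_prime[plus] <- (apos[plus] - config$offset) %% L
    slice_start[plus] <- five_prime[plus]
    five_prime[!plus] <- (apos[!plus] + config$offset) %% L
    slice_start[!plus] <- (five_prime[!plus] - len_of[!plus] + 1L) %% L

    doubled <- paste0(genome$sequence, genome$sequence)
    fp <- substring(doubled, slice_start + 1L, slice_start + len_of)
    if (any(!plus)) {
      fp[!plus] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(fp[!plus])))
    }
    if (error_rate > 0) {
      fp <- vapply(fp, function(s) {
        b <- strsplit(s, "")[[1]]
        hit <- runif(length(b)) < error_rate
        if (any(hit)) {
          b[hit] <- vapply(b[hit], function(x) {
            sample(setdiff(c("A", "C", "G", "T"), x), 1L)
          }, character(1))
        }
        paste(b, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    raw <- substr(paste0(fp, config$adapter), 1L, config$read_length)
    ids <- sprintf("read%06d", seq_len(n))

    list(
      reads = data.frame(read_id = ids, sequence = raw,
                         quality = strrep("I", nchar(raw)),
                         stringsAsFactors = FALSE),
      truth = data.frame(read_id = ids, gene = gene_of,
                         a_site_codon_index = codon_of, strand = strand,
                         footprint_length = len_of,
                         five_prime_pos = five_prime,
                         stringsAsFactors = FALSE)
    )
  })
}

#' Write reads as FASTQ
#'
#' @param reads data.frame with `read_id`, `sequence` and optionally
#'   `quality` columns (constant quality is filled in if absent).
#' @param path Output FASTQ path.
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("quality" %in% names(reads)) reads$quality
          else strrep("I", nchar(reads$sequence))
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- reads$read_id
  Biostrings::writeXStringSet(seqs, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
  invisible(path)
}

#' Read a FASTQ file into a data.frame
#'
#' @param path FASTQ path (gzip allowed).
#' @return data.frame with `read_id` and `sequence`.
#' @export
read_fastq <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = sub("\\s.*$", "", names(seqs)),
             sequence = as.character(seqs), stringsAsFactors = FALSE)
}

#' Write a simulation's outputs
#'
#' Writes the FASTQ, the ground-truth table (TSV) and a YAML echo of the
#' configuration under a common prefix.
#'
#' @param sim Result of [simulate_reads()].
#' @param config The [simulation_config()] used.
#' @param out_prefix Path prefix for `<prefix>.fastq`, `<prefix>.truth.tsv`
#'   and `<prefix>.config.yml`.
#' @return Invisibly, the three paths written.
#' @export
write_simulation <- function(sim, config, out_prefix) {
  fq <- paste0(out_prefix, ".fastq")
  tr <- paste0(out_prefix, ".truth.tsv")
  cf <- paste0(out_prefix, ".config.yml")
  write_fastq(sim$reads, fq)
  utils::write.table(sim$truth, tr, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  echo <- config
  echo$stalls <- lapply(config$stalls, unclass)
  echo$length_distribution <- as.list(config$length_distribution)
  yaml::write_yaml(unclass(echo), cf)
  invisible(c(fq, tr, cf))
}
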