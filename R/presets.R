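# Study-condition presets for the synthetic fixture. The wildtype-like
# library reproduces the reported relative transcript occupancies (COX1
# carrying ~20% of mitoribosome-protected fragments); the knockout-like
# library reproduces loss of the AGA/AGG release factor: COX1 occupancy
# halved to ~10%, ND6 doubled, and terminal stalls on COX1 and ND6 whose
# magnitudes are derived analytically from the reported last-15-codon fold
# changes (4.5 for COX1, 2.5 for ND6) with a queued-ribosome peak 12 codons
# upstream of each stall.

WT_TRANSCRIPT_SHARES <- c(
  ND1 = 0.07, ND2 = 0.07, COX1 = 0.20, COX2 = 0.09, ATP8 = 0.02,
  ATP6 = 0.07, COX3 = 0.09, ND3 = 0.04, ND4L = 0.03, ND4 = 0.10,
  ND5 = 0.08, ND6 = 0.02, CYTB = 0.12
)

ko_transcript_shares <- function() {
  s <- WT_TRANSCRIPT_SHARES
  rest <- setdiff(names(s), c("COX1", "ND6"))
  s[rest] <- s[rest] * (1 - 0.10 - 0.04) / sum(s[rest])
  s["COX1"] <- 0.10
  s["ND6"] <- 0.04
  s
}

#' Terminal stall magnitude for a target fold change
#'
#' Inverts the closed-form expectation of the last-`window`-codon occupancy
#' statistic: for a gene of `n_codons` with uniform base density, a terminal
#' stall of total excess weight `S` (split between the stop codon and a
#' queued peak inside the window) changes the window occupancy from
#' `window/n` to `(window - 2 + S)/(n - 2 + S)`. Solving
#' `fold_change = occ_stalled/occ_uniform` for `S` gives the multiplier mass
#' needed to emulate an observed fold change.
#'
#' @param n_codons Gene length in codons (including the stop).
#' @param fold_change Target terminal-window fold change (> 1).
#' @param window Window size in codons (default 15, stop included).
#' @return Total excess weight `S` = terminal multiplier + queue multiplier.
#' @export
stall_mass_for_fold_change <- function(n_codons, fold_change, window = 15L) {
  n <- as.numeric(n_codons); w <- as.numeric(window); f <- fold_change
  if (f * w >= n) stop("fold change unattainable: window occupancy would exceed 1")
  (f * w * n - 2 * f * w - w * n + 2 * n) / (n - f * w)
}

#' Expected terminal-window fold change for a density profile
#'
#' Closed-form expectation of the stall statistic: the ratio of window
#' occupancies computed directly from two per-codon density vectors. Used as
#' the analytic oracle for stall-recovery checks.
#'
#' @param density_sample,density_reference Per-codon weight vectors
#'   (positions ordered by codon index).
#' @param window Window size in codons, counted from the 3' end.
#' @return The expected fold change (a single number).
#' @export
expected_terminal_fold_change <- function(density_sample, density_reference,
                                          window = 15L) {
  occ <- function(d) {
    n <- length(d)
    sum(d[(n - window + 1L):n]) / sum(d)
  }
  occ(density_sample) / occ(density_reference)
}

#' Wildtype-like simulation preset
#'
#' Uniform per-codon density on every ORF; transcript weights chosen so the
#' expected read share of each gene matches the wildtype relative
#' occupancies (COX1 ~20% of footprints).
#'
#' @param orfs The fixture's [orf_annotation()].
#' @param n_reads,seed Passed to [simulation_config()].
#' @return A [simulation_config()].
#' @export
wt_like_config <- function(orfs, n_reads = 50000L, seed = 101L) {
  n_cod <- orf_codon_counts(orfs)
  shares <- WT_TRANSCRIPT_SHARES[names(n_cod)]
  simulation_config(n_reads = n_reads,
                    transcript_weights = shares / n_cod,
                    stalls = list(), seed = seed)
}

#' Knockout-like simulation preset
#'
#' Emulates loss of the non-canonical-stop release factor: terminal stalls
#' at the AGA stop of COX1 and the AGG stop of ND6, each with a queued
#' ribosome peak 12 codons upstream, with stall magnitudes derived from the
#' reported terminal fold changes via [stall_mass_for_fold_change()], and
#' COX1's transcript share halved (ND6's doubled).
#'
#' @param orfs The fixture's [orf_annotation()].
#' @param n_reads,seed Passed to [simulation_config()].
#' @param fold_changes Named target fold changes for the stalled genes.
#' @param queue_share Fraction of each stall's excess weight placed on the
#'   queued peak.
#' @return A [simulation_config()].
#' @export
ko_like_config <- function(orfs, n_reads = 50000L, seed = 202L,
                           fold_changes = c(COX1 = 4.5, ND6 = 2.5),
                           queue_share = 1 / 6) {
  n_cod <- orf_codon_counts(orfs)
  stalls <- lapply(names(fold_changes), function(g) {
    S <- stall_mass_for_fold_change(n_cod[[g]], fold_changes[[g]])
    stall_spec(g, "terminal", multiplier = S * (1 - queue_share),
               queue_multiplier = S * queue_share, queue_offset = 12L)
  })
  shares <- ko_transcript_shares()[names(n_cod)]
  cfg <- simulation_config(n_reads = n_reads, stalls = stalls, seed = seed)
  dens_mass <- vapply(names(n_cod), function(g) {
    sum(build_density_profile(orf_row(orfs, g), stalls))
  }, 1.0)
  cfg$transcript_weights <- shares / dens_mass
  cfg
}
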