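#' Default length distribution of the synthetic benchmark
#'
#' Geometric-like distribution over lengths 2..30 with mode at 3, chosen so
#' that the majority of peptides are 2-4-mers, emulating the strongly
#' short-skewed length profile of curated antioxidant peptide collections.
#' Weights: 0.65 at length 2, then `0.65^(L-3)` from length 3, normalized.
#'
#' @return Named numeric vector of probabilities over lengths 2..30.
#' @export
default_length_probs <- function() {
  L <- 2:30
  w <- c(0.65, 0.65^(0:27))
  setNames(w / sum(w), L)
}

#' Specification of a synthetic benchmark
#'
#' The stated world of the synthetic generator: sample sizes and strata
#' fractions mirror the published benchmark (687 positives of which 81
#' chelators and 70 dual-labeled; 717 negatives of which 500
#' background-sampled), the length distribution is short-skewed with mode 3,
#' and positives carry a composition-level signal: the frequencies of
#' `signal_residues` (H/W/Y, the residues reported enriched in antioxidant
#' peptides) are multiplied by `enrichment` and renormalized.
#'
#' @param n_positives,n_negatives Stratum totals.
#' @param length_probs Probability vector over lengths 2..30.
#' @param signal_residues Residues enriched in positives.
#' @param enrichment Frequency multiplier (>= 1) applied to signal residues.
#' @param chel_fraction_of_positives Fraction of positives with chelator
#'   label (81/687).
#' @param both_fraction Fraction of positives with both labels (70/687).
#' @param random_fraction_of_negatives Fraction of negatives in the RANDOM
#'   stratum (500/717); the rest are NON_AO.
#' @param background_freqs Residue frequencies of the negative/background
#'   distribution (uniform by default, removing any external dependency).
#' @param positional_motif Optional residue set (e.g. `c("L", "V")`); when
#'   given, each positive's N-terminal residue is drawn uniformly from it,
#'   planting a position-dependent signal that exercises the convolution's
#'   positional sensitivity (composition signal alone is position-free).
#' @param seed RNG seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_positives = 687L, n_negatives = 717L,
                         length_probs = default_length_probs(),
                         signal_residues = c("H", "W", "Y"), enrichment = 3,
                         chel_fraction_of_positives = 81 / 687,
                         both_fraction = 70 / 687,
                         random_fraction_of_negatives = 500 / 717,
                         background_freqs = rep(1 / 20, 20),
                         positional_motif = NULL, seed = 1L) {
  stopifnot(enrichment >= 1, length(background_freqs) == 20L,
            abs(sum(background_freqs) - 1) < 1e-8)
  if (both_fraction > chel_fraction_of_positives) {
    stop("both_fraction cannot exceed chel_fraction_of_positives", call. = FALSE)
  }
  if (chel_fraction_of_positives < 0 || chel_fraction_of_positives > 1 ||
      both_fraction < 0) {
    stop("stratum fractions must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(positional_motif) &&
      !all(positional_motif %in% aa_alphabet())) {
    stop("positional_motif must use canonical residues", call. = FALSE)
  }
  structure(list(n_positives = as.integer(n_positives),
                 n_negatives = as.integer(n_negatives),
                 length_probs = length_probs / sum(length_probs),
                 signal_residues = signal_residues, enrichment = enrichment,
                 chel_fraction_of_positives = chel_fraction_of_positives,
                 both_fraction = both_fraction,
                 random_fraction_of_negatives = random_fraction_of_negatives,
                 background_freqs = setNames(background_freqs, aa_alphabet()),
                 positional_motif = positional_motif,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

sample_peptide_seqs <- function(n, length_probs, freqs) {
  lens <- as.integer(names(length_probs))[
    sample.int(length(length_probs), n, replace = TRUE, prob = length_probs)]
  vapply(lens, function(l) {
    paste(sample(aa_alphabet(), l, replace = TRUE, prob = freqs), collapse = "")
  }, character(1))
}

#' Generate a synthetic benchmark peptide set
#'
#' Positives are i.i.d. residue strings drawn from the enriched composition,
#' negatives from the background composition; strata (`FRS`, `CHEL`,
#' `FRS_CHEL`, `NON_AO`, `RANDOM`) are assigned by rounding the stated
#' fractions. Deterministic under `spec$seed`.
#'
#' @param spec A [fixture_spec()].
#' @return A labeled `peptide_set` ready for partitioning.
#' @export
make_benchmark <- function(spec = fixture_spec()) {
  set.seed(spec$seed)
  n_pos <- spec$n_positives
  n_both <- round(spec$both_fraction * n_pos)
  n_chel_only <- round(spec$chel_fraction_of_positives * n_pos) - n_both
  n_frs_only <- n_pos - n_chel_only - n_both
  if (n_chel_only < 0 || n_frs_only < 0) stop("infeasible stratum fractions", call. = FALSE)
  n_neg <- spec$n_negatives
  n_random <- round(spec$random_fraction_of_negatives * n_neg)
  n_nonao <- n_neg - n_random

  pos_freqs <- spec$background_freqs
  sig <- match(spec$signal_residues, aa_alphabet())
  pos_freqs[sig] <- pos_freqs[sig] * spec$enrichment
  pos_freqs <- pos_freqs / sum(pos_freqs)

  pos_seqs <- sample_peptide_seqs(n_pos, spec$length_probs, pos_freqs)
  if (!is.null(spec$positional_motif)) {
    heads <- sample(spec$positional_motif, n_pos, replace = TRUE)
    substr(pos_seqs, 1L, 1L) <- heads
  }
  neg_seqs <- sample_peptide_seqs(n_neg, spec$length_probs, spec$background_freqs)

  stratum <- c(rep("FRS", n_frs_only), rep("CHEL", n_chel_only),
               rep("FRS_CHEL", n_both), rep("NON_AO", n_nonao),
               rep("RANDOM", n_random))
  frs <- c(rep(1L, n_frs_only), rep(0L, n_chel_only), rep(1L, n_both),
           rep(0L, n_neg))
  chel <- c(rep(0L, n_frs_only), rep(1L, n_chel_only), rep(1L, n_both),
            rep(0L, n_neg))
  peptide_set(c(pos_seqs, neg_seqs), frs = frs, chel = chel, stratum = stratum,
              id = c(paste0("pos", seq_len(n_pos)), paste0("neg", seq_len(n_neg))),
              validate = FALSE)
}

#' Generate synthetic background proteins
#'
#' I.i.d. residue strings standing in for random database proteins as a
#' source of random-negative peptides; no download required.
#'
#' @param n Number of proteins.
#' @param length_range Inclusive range of protein lengths.
#' @param background_freqs 20-vector of residue frequencies.
#' @param seed RNG seed.
#' @return data.frame with `id`, `sequence`.
#' @export
make_background_proteins <- function(n, length_range = c(50L, 500L),
                                     background_freqs = rep(1 / 20, 20), seed = 1L) {
  set.seed(seed)
  if (n == 0L) return(data.frame(id = character(0), sequence = character(0)))
  lens <- sample(length_range[1]:length_range[2], n, replace = TRUE)
  seqs <- vapply(lens, function(l) {
    paste(sample(aa_alphabet(), l, replace = TRUE, prob = background_freqs),
          collapse = "")
  }, character(1))
  data.frame(id = paste0("bg", seq_len(n)), sequence = seqs,
             stringsAsFactors = FALSE)
}
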