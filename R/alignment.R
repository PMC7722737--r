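#' Alignment scoring parameters
#'
#' Global-alignment scoring used for every sequence identity in the package:
#' 1 for identical residues, 0 for dissimilar, -10 for opening and extending
#' a gap, 0 for end gaps. Because open and extend are equal the gap model is
#' linear (-10 per internal gap column, end columns free); parameters with
#' `gap_open != gap_extend` are rejected rather than silently approximated.
#'
#' @param match,mismatch,gap_open,gap_extend,end_gap Scoring terms.
#' @return An `alignment_params` list.
#' @export
alignment_params <- function(match = 1, mismatch = 0, gap_open = -10,
                             gap_extend = -10, end_gap = 0) {
  if (gap_open != gap_extend) {
    stop("linear gap model requires gap_open == gap_extend", call. = FALSE)
  }
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, end_gap = end_gap),
            class = "alignment_params")
}

check_align_seq <- function(x, arg) {
  if (length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop("`", arg, "` must be a non-empty sequence", call. = FALSE)
  }
  s <- toupper(x)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% aa_alphabet())
  if (length(bad)) {
    stop(sprintf("non-canonical residue '%s' at position %d", chars[bad[1]], bad[1]),
         call. = FALSE)
  }
  s
}

#' Global Needleman-Wunsch alignment
#'
#' Optimal global alignment under [alignment_params()], with end gaps
#' (leading/trailing gaps in either sequence) priced at `end_gap`. Among
#' co-optimal alignments the traceback prefers match/mismatch over gaps,
#' then a gap in `b` over a gap in `a`; under the default scoring all
#' co-optimal alignments carry the same identity count.
#'
#' @param a,b Sequences over the canonical alphabet, length >= 1.
#' @param params An [alignment_params()].
#' @return List with `score`, `matches` (identical aligned positions),
#'   `columns` (alignment length), and the aligned strings `a_aln`, `b_aln`.
#' @examples
#' needleman_wunsch("HWYD", "HWYD")$score  # 4
#' needleman_wunsch("AH", "H")$score       # 1 (flanking end gap is free)
#' @export
needleman_wunsch <- function(a, b, params = alignment_params()) {
  a <- check_align_seq(a, "a"); b <- check_align_seq(b, "b")
  nw_pair_cpp(a, b, params$match, params$mismatch, params$gap_extend, params$end_gap)
}

identity_denominator <- function(a_len, b_len, columns,
                                 normalize = c("longer", "shorter", "alignment_columns")) {
  normalize <- match.arg(normalize)
  switch(normalize,
         shorter = min(a_len, b_len),
         longer = max(a_len, b_len),
         alignment_columns = columns)
}

#' Pairwise percent identity
#'
#' Identically aligned positions of the optimal global alignment divided, by
#' default, by the length of the longer sequence. Longer-length
#' normalization keeps a short peptide merely contained in a 30-mer from
#' scoring as identical, so single-linkage clustering only collapses when
#' same-length peptides truly resemble each other (e.g. 3-mer pairs at 2/3
#' identity below a 0.66 threshold); `"shorter"` and `"alignment_columns"`
#' are available conventions.
#'
#' @inheritParams needleman_wunsch
#' @param normalize Denominator convention.
#' @return Identity fraction in `[0, 1]`.
#' @examples
#' percent_identity("AAAA", "AAAT")                        # 0.75
#' percent_identity("AH", "H", normalize = "shorter")      # 1
#' @export
percent_identity <- function(a, b, params = alignment_params(),
                             normalize = c("longer", "shorter", "alignment_columns")) {
  nw <- needleman_wunsch(a, b, params)
  nw$matches / identity_denominator(nchar(a), nchar(b), nw$columns, normalize)
}

#' All-pairs identity matrix
#'
#' Computes each unordered pair once in compiled code and mirrors the result;
#' the diagonal is 1. Returns the identity matrix with the raw NW score and
#' match-count matrices attached (used by the k-NN tie-break).
#'
#' @param peptides A `peptide_set` or character vector of sequences.
#' @inheritParams percent_identity
#' @return Symmetric numeric matrix with `score` and `matches` matrix
#'   attributes; dimnames are peptide ids when available.
#' @export
identity_matrix <- function(peptides, params = alignment_params(),
                            normalize = c("longer", "shorter", "alignment_columns")) {
  normalize <- match.arg(normalize)
  if (normalize == "alignment_columns") {
    stop("alignment_columns normalization is only available pairwise", call. = FALSE)
  }
  seqs <- if (is.character(peptides)) peptides else peptides$sequence
  ids <- if (is.character(peptides)) names(peptides) else peptides$id
  if (length(seqs) < 2L) stop("need at least 2 peptides", call. = FALSE)
  res <- nw_all_pairs_cpp(seqs, params$match, params$mismatch,
                          params$gap_extend, params$end_gap)
  len <- nchar(seqs)
  denom <- if (normalize == "shorter") outer(len, len, pmin) else outer(len, len, pmax)
  idm <- res$matches / denom
  if (!is.null(ids)) dimnames(idm) <- list(ids, ids)
  attr(idm, "score") <- res$score
  attr(idm, "matches") <- res$matches
  idm
}

#' Query-versus-reference identity matrix
#'
#' Rectangular counterpart of [identity_matrix()] for k-NN prediction.
#'
#' @param query,reference `peptide_set`s or character vectors.
#' @inheritParams percent_identity
#' @return `length(query) x length(reference)` identity matrix with `score`
#'   attribute.
#' @export
identity_cross <- function(query, reference, params = alignment_params(),
                           normalize = c("longer", "shorter")) {
  normalize <- match.arg(normalize)
  qs <- if (is.character(query)) query else query$sequence
  rs <- if (is.character(reference)) reference else reference$sequence
  res <- nw_cross_cpp(qs, rs, params$match, params$mismatch,
                      params$gap_extend, params$end_gap)
  denom <- if (normalize == "shorter") outer(nchar(qs), nchar(rs), pmin)
           else outer(nchar(qs), nchar(rs), pmax)
  idm <- res$matches / denom
  attr(idm, "score") <- res$score
  idm
}
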