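#' The canonical amino-acid alphabet
#'
#' Fixed alphabetical one-letter order used for one-hot column indexing
#' throughout the package. Any fixed order is equivalent for the model; this
#' one is documented so encodings are reproducible.
#'
#' @return Character vector of the 20 canonical one-letter residue codes.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

PEPTIDE_STRATA <- c("FRS", "CHEL", "FRS_CHEL", "NON_AO", "RANDOM", "UNKNOWN")

#' Validate and normalize an amino-acid sequence
#'
#' Uppercases, strips whitespace, and rejects any residue outside the 20
#' canonical amino acids (B, J, O, U, X, Z and gap characters are errors, not
#' imputed). In `"peptide"` mode the length must lie in `[min_len, max_len]`
#' (2-30 by default); `"protein"` mode checks the alphabet only.
#'
#' @param raw Character scalar, the sequence to validate.
#' @param mode `"peptide"` (length-checked) or `"protein"` (alphabet only).
#' @param min_len,max_len Allowed peptide length range.
#' @return The normalized sequence string.
#' @examples
#' validate_sequence("hwyd")     # "HWYD"
#' validate_sequence("HW YD")    # "HWYD"
#' @export
validate_sequence <- function(raw, mode = c("peptide", "protein"),
                              min_len = 2L, max_len = 30L) {
  mode <- match.arg(mode)
  if (length(raw) != 1L || is.na(raw)) {
    stop("`raw` must be a single non-missing string", call. = FALSE)
  }
  s <- toupper(gsub("[[:space:]]+", "", as.character(raw)))
  if (!nzchar(s)) stop("sequence is empty after whitespace stripping", call. = FALSE)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% aa_alphabet())
  if (length(bad)) {
    stop(sprintf("non-canonical residue '%s' at position %d in '%s'",
                 chars[bad[1]], bad[1], s), call. = FALSE)
  }
  n <- nchar(s)
  if (mode == "peptide" && (n < min_len || n > max_len)) {
    stop(sprintf("peptide length %d outside [%d, %d]: '%s'", n, min_len, max_len, s),
         call. = FALSE)
  }
  if (mode == "protein" && n < 2L) {
    stop("protein sequence must have length >= 2", call. = FALSE)
  }
  s
}

#' Construct a validated peptide set
#'
#' The package's peptide container is a plain `data.frame` with columns
#' `id`, `sequence`, `frs`, `chel`, `stratum` (class `"peptide_set"`).
#' Labels are binary (or `NA` when unknown); `stratum` records provenance:
#' `FRS`, `CHEL`, `FRS_CHEL` (both activities), `NON_AO` (experimentally
#' negative), `RANDOM` (background-sampled negative) or `UNKNOWN`.
#' Stratum/label consistency is enforced: `FRS_CHEL` implies both labels 1;
#' `NON_AO`/`RANDOM` imply both labels 0.
#'
#' @param sequence Character vector of peptide sequences.
#' @param frs,chel Binary activity labels (`NA` allowed).
#' @param stratum Provenance stratum per peptide.
#' @param id Optional ids; defaults to `pep1`, `pep2`, ...
#' @param validate Validate sequences (set `FALSE` only for trusted input).
#' @return A `peptide_set` data.frame.
#' @export
peptide_set <- function(sequence, frs = NA_integer_, chel = NA_integer_,
                        stratum = "UNKNOWN", id = NULL, validate = TRUE) {
  n <- length(sequence)
  if (validate) {
    sequence <- vapply(sequence, validate_sequence, character(1), USE.NAMES = FALSE)
  }
  frs <- as.integer(rep_len(frs, n))
  chel <- as.integer(rep_len(chel, n))
  stratum <- rep_len(as.character(stratum), n)
  if (is.null(id)) id <- paste0("pep", seq_len(n))
  if (anyDuplicated(id)) warning("duplicate peptide ids", call. = FALSE)
  bad_s <- !stratum %in% PEPTIDE_STRATA
  if (any(bad_s)) stop("unknown stratum: ", stratum[which(bad_s)[1]], call. = FALSE)
  bad_lab <- !is.na(frs) & !frs %in% c(0L, 1L) | !is.na(chel) & !chel %in% c(0L, 1L)
  if (any(bad_lab)) stop("labels must be binary or NA", call. = FALSE)
  viol <- (stratum == "FRS_CHEL" & !(frs %in% 1L & chel %in% 1L)) |
    (stratum %in% c("NON_AO", "RANDOM") & !(frs %in% 0L & chel %in% 0L)) |
    (stratum == "FRS" & !frs %in% 1L) |
    (stratum == "CHEL" & !chel %in% 1L)
  if (any(viol)) {
    stop("stratum/label inconsistency for id ", id[which(viol)[1]], call. = FALSE)
  }
  out <- data.frame(id = as.character(id), sequence = sequence, frs = frs,
                    chel = chel, stratum = stratum, stringsAsFactors = FALSE)
  class(out) <- c("peptide_set", "data.frame")
  out
}

#' @export
print.peptide_set <- function(x, ...) {
  cat(sprintf("peptide_set: %d peptides (%d FRS+, %d CHEL+)\n",
              nrow(x), sum(x$frs %in% 1L), sum(x$chel %in% 1L)))
  NextMethod()
}

#' One-hot encode a peptide
#'
#' Each residue becomes a 20-dimensional indicator row (columns ordered as
#' [aa_alphabet()]); the N-terminal residue maps to row 1 and rows beyond the
#' sequence length are zero padding, giving a `max_len x 20` matrix whose
#' total equals the peptide length.
#'
#' @param sequence A validated peptide string.
#' @param max_len Padded length (30).
#' @return A `max_len x 20` binary matrix with residue-letter column names.
#' @export
one_hot_encode <- function(sequence, max_len = 30L) {
  n <- nchar(sequence)
  if (n > max_len) {
    stop(sprintf("sequence length %d exceeds max_len %d", n, max_len), call. = FALSE)
  }
  m <- matrix(0, nrow = max_len, ncol = 20L, dimnames = list(NULL, aa_alphabet()))
  idx <- match(strsplit(sequence, "", fixed = TRUE)[[1]], aa_alphabet())
  if (anyNA(idx)) stop("non-canonical residue in sequence", call. = FALSE)
  m[cbind(seq_len(n), idx)] <- 1
  m
}

#' Decode a one-hot matrix back to its sequence
#'
#' @param mat A matrix produced by [one_hot_encode()].
#' @return The peptide string.
#' @export
decode_one_hot <- function(mat) {
  rs <- rowSums(mat)
  n <- sum(rs > 0)
  if (n && any(rs[seq_len(n)] != 1)) stop("not a valid one-hot matrix", call. = FALSE)
  paste(aa_alphabet()[max.col(mat[seq_len(n), , drop = FALSE])], collapse = "")
}

#' Encode a peptide set as a batch array
#'
#' Stacks one-hot matrices into a `B x max_len x 20` array with aligned label
#' vectors, the input format of the network.
#'
#' @param peptides A `peptide_set`, or character vector of sequences.
#' @param max_len Padded length.
#' @return An `encoded_batch`: list with `features` (array), `frs`, `chel`,
#'   `ids`, `sequences`.
#' @export
encode_batch <- function(peptides, max_len = 30L) {
  if (is.character(peptides)) peptides <- peptide_set(peptides)
  b <- nrow(peptides)
  feat <- array(0, dim = c(b, max_len, 20L))
  for (i in seq_len(b)) feat[i, , ] <- one_hot_encode(peptides$sequence[i], max_len)
  structure(list(features = feat, frs = peptides$frs, chel = peptides$chel,
                 ids = peptides$id, sequences = peptides$sequence),
            class = "encoded_batch")
}

#' Read peptides from CSV/TSV/FASTA
#'
#' CSV/TSV files use the documented schema `sequence,frs,chel,stratum[,id]`
#' (column names remappable via `column_map`, so external tables with
#' different headers load without editing). FASTA input yields unlabeled peptides.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"` or `"fasta"`.
#' @param column_map Named list mapping schema roles to file column names.
#' @param dedupe Drop exact duplicate sequences (keeping the first).
#' @return A `peptide_set`.
#' @export
read_peptide_table <- function(path, format = c("auto", "csv", "tsv", "fasta"),
                               column_map = list(sequence = "sequence", frs = "frs",
                                                 chel = "chel", stratum = "stratum",
                                                 id = "id"),
                               dedupe = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", tab = "tsv",
                     fa = "fasta", faa = "fasta", fasta = "fasta",
                     stop("cannot infer format from extension '", ext, "'", call. = FALSE))
  }
  if (format == "fasta") {
    recs <- read_fasta(path, mode = "peptide")
    out <- peptide_set(recs$sequence, id = recs$id)
  } else {
    # na.strings = "": the dipeptide "NA" (Asn-Ala) is a real sequence
    tab <- if (format == "csv") {
      read.csv(path, stringsAsFactors = FALSE, na.strings = "")
    } else {
      read.delim(path, stringsAsFactors = FALSE, na.strings = "")
    }
    need <- c(sequence = column_map$sequence, frs = column_map$frs,
              chel = column_map$chel)
    miss <- need[!need %in% names(tab)]
    if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
    seqs <- character(nrow(tab))
    for (i in seq_len(nrow(tab))) {
      seqs[i] <- tryCatch(validate_sequence(tab[[need["sequence"]]][i]),
                          error = function(e) {
        stop(sprintf("parse error at line %d of %s: %s", i + 1L, path,
                     conditionMessage(e)), call. = FALSE)
      })
    }
    strat <- if (!is.null(column_map$stratum) && column_map$stratum %in% names(tab))
      tab[[column_map$stratum]] else "UNKNOWN"
    ids <- if (!is.null(column_map$id) && column_map$id %in% names(tab))
      as.character(tab[[column_map$id]]) else NULL
    to_label <- function(x) { x[x %in% "NA"] <- NA; as.integer(x) }
    out <- peptide_set(seqs, frs = to_label(tab[[need["frs"]]]),
                       chel = to_label(tab[[need["chel"]]]),
                       stratum = strat, id = ids, validate = FALSE)
  }
  if (dedupe) {
    dup <- duplicated(out$sequence)
    if (any(dup)) {
      warning(sum(dup), " duplicate sequence(s) removed", call. = FALSE)
      out <- out[!dup, , drop = FALSE]
      class(out) <- c("peptide_set", "data.frame")
    }
  }
  out
}

#' Write a peptide set to CSV
#'
#' Inverse of [read_peptide_table()] for the labeled CSV schema; round-trips
#' sequences and labels exactly.
#'
#' @param peptides A `peptide_set`.
#' @param path Output path.
#' @export
write_peptide_table <- function(peptides, path) {
  write.csv(as.data.frame(peptides)[, c("sequence", "frs", "chel", "stratum", "id")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read protein or peptide records from FASTA
#'
#' Multi-record FASTA (wrapped or unwrapped lines), parsed with Biostrings.
#'
#' @param path FASTA file.
#' @param mode `"protein"` (alphabet check only) or `"peptide"` (2-30 length check).
#' @return data.frame with columns `id`, `sequence`.
#' @export
read_fasta <- function(path, mode = c("protein", "peptide")) {
  mode <- match.arg(mode)
  ss <- Biostrings::readBStringSet(path)
  if (!length(ss)) stop("empty FASTA: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(ss))
  if (any(!nzchar(ids))) stop("FASTA record with empty id", call. = FALSE)
  seqs <- vapply(as.character(ss), validate_sequence, character(1),
                 mode = mode, USE.NAMES = FALSE)
  data.frame(id = ids, sequence = seqs, stringsAsFactors = FALSE)
}

#' Write sequence records to FASTA
#'
#' @param records data.frame with `id` and `sequence` columns.
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  ss <- Biostrings::BStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write prediction records to CSV
#'
#' Emits `sequence,frs_score,chel_score` (plus `frs_call,chel_call` when a
#' threshold is supplied; a score equal to the threshold is called 1), scores
#' printed with 4 decimals, rows in input order.
#'
#' @param records data.frame with `sequence`, `frs_score`, `chel_score`.
#' @param path Output path.
#' @param threshold Optional operating threshold for binary calls.
#' @export
write_predictions <- function(records, path, threshold = NULL) {
  stopifnot(all(c("sequence", "frs_score", "chel_score") %in% names(records)))
  if (nrow(records) &&
      (any(records$frs_score < 0 | records$frs_score > 1) ||
       any(records$chel_score < 0 | records$chel_score > 1))) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  out <- data.frame(sequence = records$sequence,
                    frs_score = sprintf("%.4f", records$frs_score),
                    chel_score = sprintf("%.4f", records$chel_score),
                    stringsAsFactors = FALSE)
  if (nrow(records) == 0L) out <- out[0, , drop = FALSE]
  if (!is.null(threshold)) {
    out$frs_call <- as.integer(records$frs_score >= threshold)
    out$chel_call <- as.integer(records$chel_score >= threshold)
  }
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path, call. = FALSE))
  on.exit(close(con))
  write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
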