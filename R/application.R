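#' Enumerate all subpeptides of a protein
#'
#' Every contiguous substring with length in `[min_len, max_len]`, with
#' 0-based half-open coordinates on the parent protein. Duplicate sequences
#' from different positions are retained (deduplication is an output option
#' of [screen()]).
#'
#' @param sequence Protein sequence (validated, alphabet only).
#' @param min_len,max_len Length bounds (2 and 30).
#' @return data.frame with `sequence`, `start`, `end`.
#' @examples
#' nrow(enumerate_peptides(strrep("A", 10)))  # 45
#' @export
enumerate_peptides <- function(sequence, min_len = 2L, max_len = 30L) {
  L <- nchar(sequence)
  if (L < min_len) {
    warning("protein shorter than min_len; no peptides enumerated", call. = FALSE)
    return(data.frame(sequence = character(0), start = integer(0), end = integer(0)))
  }
  rows <- lapply(min_len:min(max_len, L), function(k) {
    starts <- seq_len(L - k + 1L)
    data.frame(sequence = substring(sequence, starts, starts + k - 1L),
               start = starts - 1L, end = starts - 1L + k,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Protease cleavage rules
#'
#' A rule cleaves C-terminally to any residue in `cleave_after` unless the
#' next residue is in `blocked_by_next`. The built-in set covers
#' conventional proteases (user-editable; see [load_protease_rules()]).
#'
#' @param name Rule name; with no arguments, returns the built-in rule list.
#' @param cleave_after,blocked_by_next Residue sets.
#' @return A `protease_rule` (or named list of them).
#' @export
protease_rules <- function() {
  list(
    trypsin = protease_rule("trypsin", c("K", "R"), "P"),
    chymotrypsin = protease_rule("chymotrypsin", c("F", "W", "Y"), "P"),
    pepsin_ph2 = protease_rule("pepsin_ph2", c("F", "L"), character(0)),
    glu_c = protease_rule("glu_c", "E", character(0)),
    lys_c = protease_rule("lys_c", "K", character(0)),
    arg_c = protease_rule("arg_c", "R", character(0)),
    elastase = protease_rule("elastase", c("A", "V", "S", "G", "L", "I"),
                             character(0))
  )
}

#' @rdname protease_rules
#' @export
protease_rule <- function(name, cleave_after, blocked_by_next = character(0)) {
  cleave_after <- toupper(cleave_after)
  blocked_by_next <- toupper(blocked_by_next)
  if (!all(c(cleave_after, blocked_by_next) %in% aa_alphabet())) {
    stop("rule residues must be canonical amino acids", call. = FALSE)
  }
  structure(list(name = name, cleave_after = cleave_after,
                 blocked_by_next = blocked_by_next),
            class = "protease_rule")
}

#' Load / save protease rules as JSON
#'
#' @param path JSON file: an object mapping rule names to
#'   `{cleave_after: [...], blocked_by_next: [...]}`.
#' @return Named list of `protease_rule`s.
#' @export
load_protease_rules <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(names(raw), function(nm) {
    protease_rule(nm, as.character(raw[[nm]]$cleave_after),
                  as.character(raw[[nm]]$blocked_by_next %||% character(0)))
  })
  setNames(out, names(raw))
}

#' @rdname load_protease_rules
#' @param rules Named list of `protease_rule`s.
#' @export
save_protease_rules <- function(rules, path) {
  payload <- lapply(rules, function(r) {
    list(cleave_after = r$cleave_after, blocked_by_next = r$blocked_by_next)
  })
  jsonlite::write_json(payload, path, auto_unbox = FALSE)
  invisible(path)
}

#' In-silico proteolytic digestion
#'
#' Applies a cleavage rule to a protein; base fragments tile the protein
#' exactly. With `missed_cleavages = m`, all concatenations of up to `m + 1`
#' consecutive fragments are also emitted. Fragments are reported with
#' 0-based half-open coordinates; those outside `[min_len, max_len]` are
#' kept in the result but flagged out of range (they are not scored by
#' [screen()]).
#'
#' @param sequence Protein sequence.
#' @param rule A `protease_rule`.
#' @param missed_cleavages Maximum missed cleavages.
#' @param min_len,max_len Length filter for scoreable fragments.
#' @return A `digest_result`: list with `fragments` (data.frame `sequence`,
#'   `start`, `end`, `n_missed`, `in_range`) and the base fragment count.
#' @examples
#' digest("MKAYRPGLK", protease_rules()$trypsin)$fragments
#' @export
digest <- function(sequence, rule, missed_cleavages = 0L, min_len = 2L,
                   max_len = 30L) {
  L <- nchar(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  cuts <- integer(0)  # cut after position i (1-based)
  if (length(rule$cleave_after) && L > 1L) {
    for (i in seq_len(L - 1L)) {
      if (chars[i] %in% rule$cleave_after &&
          !chars[i + 1L] %in% rule$blocked_by_next) {
        cuts <- c(cuts, i)
      }
    }
  }
  bounds <- c(0L, cuts, L)  # fragment f spans (bounds[f], bounds[f+1]]
  nf <- length(bounds) - 1L
  rows <- list()
  for (f in seq_len(nf)) {
    for (g in f:min(nf, f + missed_cleavages)) {
      s <- bounds[f]; e <- bounds[g + 1L]
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = substr(sequence, s + 1L, e), start = s, end = e,
        n_missed = g - f, stringsAsFactors = FALSE)
    }
  }
  frags <- do.call(rbind, rows)
  frags$in_range <- nchar(frags$sequence) >= min_len & nchar(frags$sequence) <= max_len
  structure(list(fragments = frags, n_base_fragments = nf, rule = rule$name,
                 protein_length = L),
            class = "digest_result")
}

#' Score and rank candidate peptides from FASTA input
#'
#' The discovery front-end: reads proteins or peptides from FASTA, produces
#' candidates per mode (`"peptides"`: each record is one peptide; `"scan"`:
#' all 2-30-mers of each protein; `"digest"`: proteolytic fragments), scores
#' them with the model, and writes/returns them sorted by FRS score
#' descending (ties: chelator score, then sequence). Records that fail
#' peptide validation are skipped with a message. With `dedupe = TRUE` only
#' the first occurrence of each unique sequence is kept, so overlapping
#' duplicates collapse to a single highest-ranked row.
#'
#' @param input FASTA path, or a data.frame with `id` and `sequence`.
#' @param model A trained `antiox_model`.
#' @param mode `"peptides"`, `"scan"` or `"digest"`.
#' @param rule `protease_rule` for digest mode.
#' @param missed_cleavages Missed cleavages for digest mode.
#' @param min_len,max_len Candidate length bounds.
#' @param dedupe Collapse duplicate sequences.
#' @param output Optional CSV output path
#'   (`sequence,start,end,source,frs_score,chel_score`).
#' @return The ranked data.frame (invisibly written to `output` if given).
#' @export
screen <- function(input, model, mode = c("peptides", "scan", "digest"),
                   rule = protease_rules()$trypsin, missed_cleavages = 0L,
                   min_len = 2L, max_len = 30L, dedupe = FALSE, output = NULL) {
  mode <- match.arg(mode)
  recs <- if (is.character(input)) {
    read_fasta(input, mode = "protein")
  } else input
  if (!nrow(recs)) stop("no input records", call. = FALSE)
  cands <- switch(mode,
    peptides = data.frame(sequence = recs$sequence, start = 0L,
                          end = nchar(recs$sequence), source = recs$id,
                          stringsAsFactors = FALSE),
    scan = do.call(rbind, lapply(seq_len(nrow(recs)), function(i) {
      d <- enumerate_peptides(recs$sequence[i], min_len, max_len)
      if (nrow(d)) d$source <- recs$id[i]
      d
    })),
    digest = do.call(rbind, lapply(seq_len(nrow(recs)), function(i) {
      d <- digest(recs$sequence[i], rule, missed_cleavages, min_len, max_len)$fragments
      d <- d[d$in_range, c("sequence", "start", "end"), drop = FALSE]
      if (nrow(d)) d$source <- recs$id[i]
      d
    }))
  )
  if (is.null(cands) || !nrow(cands)) {
    warning("no scoreable peptides produced", call. = FALSE)
    return(data.frame(sequence = character(0), start = integer(0),
                      end = integer(0), source = character(0),
                      frs_score = numeric(0), chel_score = numeric(0)))
  }
  ok <- vapply(cands$sequence, function(s) {
    tryCatch({ validate_sequence(s, min_len = min_len, max_len = max_len); TRUE },
             error = function(e) FALSE)
  }, logical(1), USE.NAMES = FALSE)
  if (any(!ok)) message(sum(!ok), " candidate(s) skipped (validation failed)")
  cands <- cands[ok, , drop = FALSE]
  if (!nrow(cands)) {
    warning("no scoreable peptides after validation", call. = FALSE)
    return(cands)
  }
  sc <- predict(model, cands$sequence)
  cands$frs_score <- sc$frs_score
  cands$chel_score <- sc$chel_score
  cands <- cands[order(-cands$frs_score, -cands$chel_score, cands$sequence), ,
                 drop = FALSE]
  if (dedupe) cands <- cands[!duplicated(cands$sequence), , drop = FALSE]
  rownames(cands) <- NULL
  if (!is.null(output)) {
    write.csv(cands[, c("sequence", "start", "end", "source", "frs_score",
                        "chel_score")], output, row.names = FALSE, quote = FALSE)
  }
  cands
}

#' DPPH radical-scavenging inhibition percentage
#'
#' `(1 - (As - A0) / Ab) * 100`, where `As` is the absorbance of the
#' radical after reaction with the peptide, `A0` the peptide/solvent
#' control, and `Ab` the blank. Values outside `[0, 100]` are reported
#' as-is with an `out_of_range` attribute.
#'
#' @param As,A0,Ab Absorbances; `Ab` must be positive.
#' @return Inhibition percentage(s).
#' @examples
#' dpph_inhibition(0.5, 0.1, 0.8)  # 50
#' @export
dpph_inhibition <- function(As, A0, Ab) {
  if (any(Ab <= 0)) stop("blank absorbance Ab must be positive", call. = FALSE)
  out <- (1 - (As - A0) / Ab) * 100
  attr(out, "out_of_range") <- out < 0 | out > 100
  out
}

#' IC50 by linear interpolation
#'
#' Concentration at 50% inhibition, linearly interpolated between the two
#' measured concentrations bracketing 50%. Extrapolation outside the
#' measured range is refused.
#'
#' @param concentrations Concentrations (mg/ml), any order.
#' @param inhibitions Matching inhibition percentages.
#' @return IC50 in the same units as `concentrations`.
#' @examples
#' ic50_estimate(c(1, 2), c(40, 60))  # 1.5
#' @export
ic50_estimate <- function(concentrations, inhibitions) {
  if (length(concentrations) < 2L ||
      length(concentrations) != length(inhibitions)) {
    stop("need >= 2 matched (concentration, inhibition) points", call. = FALSE)
  }
  o <- order(concentrations)
  x <- concentrations[o]
  y <- inhibitions[o]
  hit <- which(y == 50)
  if (length(hit)) return(x[hit[1]])
  br <- which((head(y, -1) - 50) * (tail(y, -1) - 50) < 0)
  if (!length(br)) {
    stop("inhibition does not cross 50% within the measured range", call. = FALSE)
  }
  i <- br[1]
  x[i] + (50 - y[i]) * (x[i + 1] - x[i]) / (y[i + 1] - y[i])
}
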