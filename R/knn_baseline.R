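#' k-NN baseline configuration
#'
#' Sequence-identity k-nearest-neighbour reference predictor: a query's FRS
#' and chelator scores are the mean labels of its k most identical reference
#' peptides (the same k neighbours for both activities, under the assumption
#' that similar peptides share similar properties).
#'
#' @param k Number of neighbours (5).
#' @param params [alignment_params()].
#' @param tie_rule `"deterministic"` (ties at the k-th rank broken by higher
#'   raw NW score, then shorter reference, then lexicographic id) or
#'   `"average_ties"` (average over all references tied at the k-th
#'   identity).
#' @param normalize Identity normalization passed to the identity engine.
#' @return A `knn_config` list.
#' @export
knn_config <- function(k = 5L, params = alignment_params(),
                       tie_rule = c("deterministic", "average_ties"),
                       normalize = "longer") {
  tie_rule <- match.arg(tie_rule)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  structure(list(k = as.integer(k), params = params, tie_rule = tie_rule,
                 normalize = normalize),
            class = "knn_config")
}

knn_scores_from_identities <- function(ident, score, ref, cfg) {
  k <- cfg$k
  ord <- order(-ident, -score, nchar(ref$sequence), ref$id)
  if (cfg$tie_rule == "average_ties") {
    kth <- ident[ord[k]]
    sel <- which(ident >= kth)
  } else {
    sel <- ord[seq_len(k)]
  }
  c(frs = mean(ref$frs[sel]), chel = mean(ref$chel[sel]))
}

#' Predict one peptide's activity by k-NN over sequence identity
#'
#' @param query A single-row `peptide_set` or sequence string.
#' @param reference A labeled `peptide_set` (both labels required), size >= k.
#' @param cfg A [knn_config()].
#' @return data.frame with `sequence`, `frs_score`, `chel_score` (scores are
#'   multiples of 1/k under the deterministic tie rule).
#' @export
knn_predict <- function(query, reference, cfg = knn_config()) {
  qseq <- if (is.character(query)) query else query$sequence
  if (length(qseq) != 1L) stop("one query at a time", call. = FALSE)
  if (nrow(reference) < cfg$k) {
    stop("reference smaller than k = ", cfg$k, call. = FALSE)
  }
  if (anyNA(reference$frs) || anyNA(reference$chel)) {
    stop("reference peptides must carry both labels", call. = FALSE)
  }
  idm <- identity_cross(qseq, reference, cfg$params, cfg$normalize)
  sc <- knn_scores_from_identities(idm[1, ], attr(idm, "score")[1, ], reference, cfg)
  data.frame(sequence = qseq, frs_score = unname(sc["frs"]),
             chel_score = unname(sc["chel"]), stringsAsFactors = FALSE)
}

#' Cross-validated k-NN prediction over a partitioned benchmark
#'
#' Every peptide is predicted exactly once, from the reference set formed by
#' all folds except its own (audited: no self- or within-fold neighbours by
#' construction).
#'
#' @param dataset A `benchmark_dataset` from [partition_fivefold()].
#' @param cfg A [knn_config()].
#' @return data.frame with `id`, `sequence`, `fold`, labels and k-NN scores.
#' @export
knn_crossval <- function(dataset, cfg = knn_config()) {
  pep <- dataset$peptides
  if (is.null(pep$fold)) stop("dataset has no fold assignments", call. = FALSE)
  if (anyNA(pep$frs) || anyNA(pep$chel)) {
    stop("all peptides must carry both labels", call. = FALSE)
  }
  folds <- sort(unique(pep$fold))
  if (length(folds) < 2L) stop("need at least 2 folds", call. = FALSE)
  out <- vector("list", length(folds))
  for (fi in seq_along(folds)) {
    f <- folds[fi]
    q <- pep[pep$fold == f, , drop = FALSE]
    r <- pep[pep$fold != f, , drop = FALSE]
    if (nrow(r) < cfg$k) stop("reference smaller than k in fold ", f, call. = FALSE)
    idm <- identity_cross(q, r, cfg$params, cfg$normalize)
    scm <- attr(idm, "score")
    sc <- t(vapply(seq_len(nrow(q)), function(i) {
      knn_scores_from_identities(idm[i, ], scm[i, ], r, cfg)
    }, numeric(2)))
    out[[fi]] <- data.frame(id = q$id, sequence = q$sequence, fold = f,
                            frs = q$frs, chel = q$chel,
                            frs_score = sc[, 1], chel_score = sc[, 2],
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
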