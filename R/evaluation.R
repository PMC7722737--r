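#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a random positive
#' outranks a random negative, ties counted half.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (both classes must be present).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix metrics at a threshold
#'
#' Scores at or above the threshold are called positive. Zero-denominator
#' conventions: precision/recall with empty denominators are 0, F1 with zero
#' precision + recall is 0, MCC with any zero denominator factor is 0.
#'
#' @param scores,labels Predictions and binary labels.
#' @param threshold Operating threshold in `[0, 1]`.
#' @return List with `precision`, `recall`, `f1`, `mcc`, the confusion
#'   counts and `threshold`.
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  calls <- as.integer(scores >= threshold)
  labels <- as.integer(labels)
  # double precision: the MCC denominator product overflows integers
  tp <- as.numeric(sum(calls == 1L & labels == 1L))
  fp <- as.numeric(sum(calls == 1L & labels == 0L))
  tn <- as.numeric(sum(calls == 0L & labels == 0L))
  fn <- as.numeric(sum(calls == 0L & labels == 1L))
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / sqrt(den) else 0
  list(precision = precision, recall = recall, f1 = f1, mcc = mcc,
       tp = tp, fp = fp, tn = tn, fn = fn, threshold = threshold)
}

#' MCC-optimal operating threshold
#'
#' Scans candidate thresholds at the midpoints between consecutive sorted
#' unique scores, plus 0 and 1, and returns the smallest candidate attaining
#' the maximal MCC.
#'
#' @param scores,labels Predictions and binary labels (both classes present).
#' @return List with `threshold` and the `mcc` attained there.
#' @export
optimize_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("threshold optimization undefined for single-class labels", call. = FALSE)
  }
  u <- sort(unique(scores))
  cand <- unique(c(0, if (length(u) > 1L) (head(u, -1) + tail(u, -1)) / 2, 1))
  mccs <- vapply(cand, function(th) confusion_metrics(scores, labels, th)$mcc,
                 numeric(1))
  best <- which(mccs == max(mccs))[1]
  list(threshold = cand[best], mcc = mccs[best])
}

metric_set <- function(scores, labels, threshold, activity) {
  cm <- confusion_metrics(scores, labels, threshold)
  data.frame(activity = activity, auc = auc_score(scores, labels),
             f1 = cm$f1, mcc = cm$mcc, precision = cm$precision,
             recall = cm$recall, threshold_used = threshold,
             stringsAsFactors = FALSE)
}

# threshold fitted on `fit` scores/labels, fallback 0.5 if degenerate
fit_threshold <- function(scores, labels) {
  if (length(unique(as.integer(labels))) < 2L) return(0.5)
  optimize_threshold(scores, labels)$threshold
}

default_trainer <- function(mc, tc) {
  function(train_pep, val_pep, seed) {
    model <- build_model(mc, seed = seed)
    tci <- tc
    tci$seed <- seed
    model <- train_model(model, encode_batch(train_pep, mc$max_len),
                         encode_batch(val_pep, mc$max_len), tci)
    function(pep) predict(model, pep)
  }
}

#' Nested cross-validated evaluation of the network
#'
#' For each ordered pair (test fold i, validation fold j != i): train on the
#' remaining folds with early stopping on j, fit the MCC-optimal threshold
#' on fold j's predictions, and compute the metric set per activity on fold
#' i — 5 x 4 = 20 combinations whose arithmetic mean is the final metric.
#' Fitting the threshold on the validation fold avoids test-set leakage; a
#' flag reproduces the optimistic fit-on-test alternative.
#'
#' @param dataset A `benchmark_dataset` with 5 folds.
#' @param mc,tc Model and training configuration.
#' @param threshold_fit `"validation"` or `"test"`.
#' @param trainer Optional override `function(train_pep, val_pep, seed)`
#'   returning a predictor `function(pep) -> data.frame(frs_score,
#'   chel_score)`; used to plug in deterministic stubs.
#' @param seed Base seed; each combination uses `seed + combination index`.
#' @param verbose Print progress.
#' @return List with `per_combination` (one metric row per combination and
#'   activity, with `test_fold`/`val_fold`) and `mean` (per activity).
#' @export
nested_crossval <- function(dataset, mc = model_config(), tc = train_config(),
                            threshold_fit = c("validation", "test"),
                            trainer = NULL, seed = 1L, verbose = FALSE) {
  threshold_fit <- match.arg(threshold_fit)
  pep <- dataset$peptides
  folds <- sort(unique(pep$fold))
  if (length(folds) < 3L) stop("nested cross-validation needs >= 3 folds", call. = FALSE)
  if (is.null(trainer)) trainer <- default_trainer(mc, tc)
  rows <- list()
  combo <- 0L
  for (i in folds) {
    for (j in setdiff(folds, i)) {
      combo <- combo + 1L
      train_pep <- pep[!pep$fold %in% c(i, j), , drop = FALSE]
      val_pep <- pep[pep$fold == j, , drop = FALSE]
      test_pep <- pep[pep$fold == i, , drop = FALSE]
      stopifnot(!any(train_pep$id %in% c(val_pep$id, test_pep$id)),
                !any(val_pep$id %in% test_pep$id))
      predictor <- tryCatch(
        trainer(train_pep, val_pep, seed + combo),
        error = function(e) stop(sprintf("training failed for combination (test %d, val %d): %s",
                                         i, j, conditionMessage(e)), call. = FALSE))
      val_scores <- predictor(val_pep)
      test_scores <- predictor(test_pep)
      for (act in c("frs", "chel")) {
        col <- paste0(act, "_score")
        if (length(unique(test_pep[[act]])) < 2L) next  # metrics undefined
        thr <- if (threshold_fit == "validation") {
          fit_threshold(val_scores[[col]], val_pep[[act]])
        } else fit_threshold(test_scores[[col]], test_pep[[act]])
        ms <- metric_set(test_scores[[col]], test_pep[[act]], thr, toupper(act))
        ms$test_fold <- i
        ms$val_fold <- j
        rows[[length(rows) + 1L]] <- ms
      }
      if (verbose) message(sprintf("combination %d/%d done", combo,
                                   length(folds) * (length(folds) - 1L)))
    }
  }
  per <- do.call(rbind, rows)
  means <- do.call(rbind, lapply(split(per, per$activity), function(d) {
    data.frame(activity = d$activity[1], auc = mean(d$auc), f1 = mean(d$f1),
               mcc = mean(d$mcc), precision = mean(d$precision),
               recall = mean(d$recall), stringsAsFactors = FALSE)
  }))
  rownames(means) <- NULL
  list(per_combination = per, mean = means)
}

#' Cross-validated metrics for the k-NN baseline
#'
#' The k-NN has no validation fold, so its final metric is the mean of 5
#' fold metrics; the operating threshold is MCC-optimized on each fold's own
#' predictions by default (`threshold_fit = "test"`), or on the pooled
#' predictions of the other folds.
#'
#' @param dataset A `benchmark_dataset`.
#' @param cfg A [knn_config()].
#' @param threshold_fit `"test"` or `"other_folds"`.
#' @return List with `predictions`, `per_fold` metric rows and `mean`.
#' @export
knn_crossval_metrics <- function(dataset, cfg = knn_config(),
                                 threshold_fit = c("test", "other_folds")) {
  threshold_fit <- match.arg(threshold_fit)
  preds <- knn_crossval(dataset, cfg)
  folds <- sort(unique(preds$fold))
  rows <- list()
  for (f in folds) {
    d <- preds[preds$fold == f, , drop = FALSE]
    o <- preds[preds$fold != f, , drop = FALSE]
    for (act in c("frs", "chel")) {
      col <- paste0(act, "_score")
      if (length(unique(d[[act]])) < 2L) next  # metric undefined on this fold
      thr <- if (threshold_fit == "test") fit_threshold(d[[col]], d[[act]])
             else fit_threshold(o[[col]], o[[act]])
      ms <- metric_set(d[[col]], d[[act]], thr, toupper(act))
      ms$fold <- f
      rows[[length(rows) + 1L]] <- ms
    }
  }
  per <- do.call(rbind, rows)
  means <- do.call(rbind, lapply(split(per, per$activity), function(d) {
    data.frame(activity = d$activity[1], auc = mean(d$auc), f1 = mean(d$f1),
               mcc = mean(d$mcc), precision = mean(d$precision),
               recall = mean(d$recall), stringsAsFactors = FALSE)
  }))
  rownames(means) <- NULL
  list(predictions = preds, per_fold = per, mean = means)
}

#' Partition-threshold sweep
#'
#' For each identity threshold: build the fivefold homology partition,
#' record the cluster count and mean Gini impurity, the fold-balance Gini
#' coefficient, and the k-NN FRS MCC (optionally also the network's, which
#' is expensive). One row per threshold.
#'
#' @param peptides A labeled `peptide_set`.
#' @param thresholds Identity thresholds, default 0.9/0.8/0.7/0.6.
#' @param params [alignment_params()].
#' @param knn_cfg [knn_config()].
#' @param include_model Also run [nested_crossval()] per threshold.
#' @param mc,tc Model/training configs when `include_model`.
#' @param seed Seed forwarded to the network runs.
#' @return data.frame with columns `threshold`, `n_clusters`,
#'   `mean_gini_impurity`, `fold_gini`, `knn_frs_mcc` (and `model_frs_mcc`).
#' @export
threshold_sweep <- function(peptides, thresholds = c(0.9, 0.8, 0.7, 0.6),
                            params = alignment_params(), knn_cfg = knn_config(),
                            include_model = FALSE, mc = model_config(),
                            tc = train_config(), seed = 1L) {
  idm <- identity_matrix(peptides, params)
  rows <- lapply(thresholds, function(th) {
    ds <- partition_fivefold(peptides, th, params, idm = idm)
    knn <- knn_crossval_metrics(ds, knn_cfg)
    row <- data.frame(threshold = th, n_clusters = ds$cluster_report$n_clusters,
                      mean_gini_impurity = ds$cluster_report$mean_gini_impurity,
                      fold_gini = ds$fold_balance$gini_coefficient,
                      knn_frs_mcc = knn$mean$mcc[knn$mean$activity == "FRS"])
    if (include_model) {
      cv <- nested_crossval(ds, mc, tc, seed = seed)
      row$model_frs_mcc <- cv$mean$mcc[cv$mean$activity == "FRS"]
    }
    row
  })
  do.call(rbind, rows)
}

#' Published average amino-acid composition of UniProtKB/Swiss-Prot
#'
#' Standard released database-wide residue frequencies, shipped as an
#' editable default background for [composition_test()] on real data (tests
#' use synthetic backgrounds only).
#'
#' @return Named 20-vector of frequencies summing to 1.
#' @export
swissprot_frequencies <- function() {
  f <- c(A = 8.25, C = 1.38, D = 5.46, E = 6.72, F = 3.86, G = 7.07, H = 2.27,
         I = 5.91, K = 5.80, L = 9.65, M = 2.41, N = 4.06, P = 4.74, Q = 3.93,
         R = 5.53, S = 6.65, T = 5.36, V = 6.86, W = 1.10, Y = 2.92)
  f / sum(f)
}

#' One-sample proportion tests of residue composition
#'
#' Pools residue counts over all peptides and, for each amino acid, tests
#' the observed fraction against a background frequency with a one-sample
#' z-test of proportion (`z = (phat - p0) / sqrt(p0 (1 - p0) / n)`,
#' two-sided normal p-value, n = total residues).
#'
#' @param peptides A `peptide_set` or character vector of sequences.
#' @param background_freqs Named 20-vector of background frequencies (all
#'   strictly positive, summing to 1).
#' @param alpha Significance level for the `significant` flag.
#' @return data.frame with one row per residue: `residue`, `count`,
#'   `observed`, `expected`, `z`, `p_value`, `significant`.
#' @export
composition_test <- function(peptides, background_freqs = swissprot_frequencies(),
                             alpha = 0.05) {
  seqs <- if (is.character(peptides)) peptides else peptides$sequence
  if (length(background_freqs) != 20L || any(background_freqs <= 0) ||
      abs(sum(background_freqs) - 1) > 1e-6) {
    stop("background frequencies must be 20 positive values summing to 1",
         call. = FALSE)
  }
  if (is.null(names(background_freqs))) names(background_freqs) <- aa_alphabet()
  background_freqs <- background_freqs[aa_alphabet()]
  chars <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  n <- length(chars)
  counts <- table(factor(chars, levels = aa_alphabet()))
  phat <- as.numeric(counts) / n
  p0 <- as.numeric(background_freqs)
  z <- (phat - p0) / sqrt(p0 * (1 - p0) / n)
  p <- 2 * pnorm(-abs(z))
  data.frame(residue = aa_alphabet(), count = as.integer(counts),
             observed = phat, expected = p0, z = z, p_value = p,
             significant = p < alpha, stringsAsFactors = FALSE)
}
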