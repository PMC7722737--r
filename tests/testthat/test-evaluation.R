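test_that("AUC matches worked examples and handles degenerate input", {
  expect_equal(auc_score(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 0)), 1)
  expect_equal(auc_score(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 0.75)
  expect_equal(auc_score(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_error(auc_score(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("AUC agrees with pair-counting and trapezoid oracles to 1e-12", {
  set.seed(8)
  for (rep in 1:50) {
    n <- sample(10:60, 1)
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    a <- auc_score(scores, labels)
    expect_equal(a, brute_auc(scores, labels), tolerance = 1e-12)
    expect_equal(a, trapezoid_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("confusion metrics match direct formula evaluation", {
  # TP=3 FP=1 TN=4 FN=2 at threshold 0.5
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.2, 0.1, 0.15, 0.05)
  labels <- c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0)
  cm <- confusion_metrics(scores, labels, 0.5)
  expect_equal(c(cm$tp, cm$fp, cm$tn, cm$fn), c(3, 1, 4, 2))
  expect_equal(cm$precision, 0.75)
  expect_equal(cm$recall, 0.6)
  expect_equal(cm$f1, 2 / 3, tolerance = 1e-12)
  expect_equal(cm$mcc, 10 / sqrt(600), tolerance = 1e-12)

  perfect <- confusion_metrics(c(0.9, 0.1), c(1, 0), 0.5)
  expect_equal(c(perfect$precision, perfect$recall, perfect$f1, perfect$mcc),
               rep(1, 4))
  # all-negative calls: MCC 0 by convention
  degenerate <- confusion_metrics(c(0.1, 0.2), c(1, 0), 0.9)
  expect_equal(degenerate$mcc, 0)
  expect_equal(degenerate$f1, 0)
  # a score equal to the threshold is called positive
  expect_equal(confusion_metrics(0.5, 1, 0.5)$tp, 1)
})

test_that("MCC is invariant under a simultaneous 0/1 swap", {
  set.seed(14)
  for (rep in 1:20) {
    tp <- sample(0:20, 1); fp <- sample(0:20, 1)
    tn <- sample(0:20, 1); fn <- sample(0:20, 1)
    expect_equal(mcc_from_counts(tp, fp, tn, fn),
                 mcc_from_counts(tn, fn, tp, fp), tolerance = 1e-12)
  }
})

test_that("optimize_threshold scans midpoints and dominates a dense grid", {
  r <- optimize_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(r$threshold, 0.5)
  expect_equal(r$mcc, 1)
  expect_error(optimize_threshold(c(0.2, 0.8), c(1, 1)), "single-class")
  # single top-scoring positive: the midpoint below it gives TP=1, FP=0
  r2 <- optimize_threshold(c(0.9, 0.5, 0.4), c(1, 0, 0))
  expect_equal(r2$threshold, 0.7)
  expect_equal(r2$mcc, 1)

  set.seed(15)
  grid <- seq(0, 1, length.out = 1001)
  for (rep in 1:20) {
    n <- sample(8:40, 1)
    scores <- runif(n)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    best <- optimize_threshold(scores, labels)
    grid_best <- max(vapply(grid, function(t) confusion_metrics(scores, labels, t)$mcc,
                            numeric(1)))
    expect_gte(best$mcc + 1e-12, grid_best)
  }
})

test_that("nested cross-validation with a deterministic stub is exact bookkeeping", {
  ps <- separable_fixture(n_per_class = 25, seed = 19)
  ds <- suppressWarnings(partition_fivefold(ps, 0.9))
  seen <- new.env()
  stub <- function(train_pep, val_pep, seed) {
    # leakage audit: record what this combination was allowed to see
    assign(paste0("c", seed), c(train_pep$id, val_pep$id), envir = seen)
    function(pep) {
      s <- ifelse(grepl("W", pep$sequence), 0.9, 0.1)
      data.frame(frs_score = s, chel_score = s)
    }
  }
  cv <- nested_crossval(ds, trainer = stub, seed = 100)
  frs <- cv$per_combination[cv$per_combination$activity == "FRS", ]
  expect_equal(nrow(frs), 20)
  # the stub is perfect and deterministic: all 20 metric sets identical
  expect_true(all(frs$auc == 1) && all(frs$mcc == 1) && all(frs$f1 == 1))
  expect_equal(cv$mean$auc[cv$mean$activity == "FRS"], mean(frs$auc))
  expect_equal(cv$mean$mcc[cv$mean$activity == "FRS"], mean(frs$mcc))
})

test_that("composition test reproduces hand-computed z and calibrated error", {
  # observed equals expected: z = 0, p = 1
  onecopy <- paste(aa_alphabet(), collapse = "")
  ct0 <- composition_test(onecopy, rep(0.05, 20))
  expect_true(all(abs(ct0$z) < 1e-12))
  expect_true(all(ct0$p_value == 1))

  # n=100, phat(A)=0.3 vs p0(A)=0.2 -> z = 2.5, p ~= 0.0124
  seqs <- c(strrep("A", 30), strrep("C", 35), strrep("D", 35))
  bg <- c(0.2, rep(0.8 / 19, 19))
  names(bg) <- aa_alphabet()
  ct <- composition_test(seqs, bg)
  a <- ct[ct$residue == "A", ]
  expect_equal(a$z, 2.5, tolerance = 1e-12)
  expect_equal(a$p_value, 2 * pnorm(-2.5), tolerance = 1e-12)
  expect_true(a$significant)
  expect_error(composition_test("AAAA", c(0, rep(1 / 19, 19))), "positive")

  # type-I error calibration: ~5% of residues flagged under the null
  set.seed(77)
  flags <- replicate(150, {
    peps <- random_peptides(40, c(2, 10))
    mean(composition_test(peps, rep(0.05, 20))$significant)
  })
  expect_lt(abs(mean(flags) - 0.05), 0.02)
})

test_that("threshold sweep reports consistent cluster and fold columns", {
  ps <- peptide_set(c("AAAA", "CCCC", "DDDD", "EEEE", "FFFF",
                      "GGGG", "HHHH", "IIII", "KKKK", "LLLL"),
                    frs = rep(c(1L, 0L), 5), chel = 0L)
  sw <- threshold_sweep(ps, thresholds = c(0.9, 0.7))
  # no pair above 0.6 identity: cluster count constant across thresholds
  expect_equal(sw$n_clusters, c(10, 10))
  expect_equal(sw$mean_gini_impurity, c(0, 0))
  for (r in seq_len(nrow(sw))) {
    ds <- partition_fivefold(ps, sw$threshold[r])
    expect_equal(sw$fold_gini[r],
                 gini_coefficient(ds$fold_balance$per_fold_frs))
  }
})
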