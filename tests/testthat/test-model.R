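test_that("focal loss evaluates the stated formula and its BCE limit", {
  expect_equal(focal_loss(0.5, 1), 0.25 * 0.125 * log(2), tolerance = 1e-12)
  expect_lt(focal_loss(1 - 1e-8, 1), 1e-6)   # confident correct -> ~0 loss
  expect_gt(focal_loss(0.01, 1), focal_loss(0.5, 1))
  # gamma = 0, alpha = 0.5: focal is half the binary cross-entropy
  set.seed(13)
  p <- runif(50, 0.05, 0.95)
  y <- rbinom(50, 1, 0.5)
  bce <- mean(-(y * log(p) + (1 - y) * log(1 - p)))
  expect_equal(2 * focal_loss(p, y, gamma = 0, alpha = 0.5), bce,
               tolerance = 1e-12)
  # out-of-range input is clamped, not an error
  expect_true(is.finite(focal_loss(c(0, 1), c(0, 1))))
})

test_that("focal loss gradient matches finite differences", {
  grad <- antioxpep:::focal_loss_grad
  set.seed(17)
  for (i in 1:20) {
    p <- runif(1, 0.05, 0.95)
    y <- rbinom(1, 1, 0.5)
    num <- (focal_loss(p + 1e-6, y) - focal_loss(p - 1e-6, y)) / 2e-6
    expect_equal(grad(p, y), num, tolerance = 1e-5)
  }
})

test_that("network gradients match finite differences on a small net", {
  ns <- asNamespace("antioxpep")
  mc <- model_config(conv_filters = 4L, dense_units = 6L, conv_dropout = 0,
                     dense_dropout = 0)
  m <- build_model(mc, seed = 2)
  ps <- peptide_set(c("HWYD", "AAAA", "KLMNPQ"), frs = c(1, 0, 1), chel = c(0, 0, 1))
  eb <- encode_batch(ps)
  tg <- cbind(eb$frs, eb$chel)
  fw <- ns$forward_pass(m$weights, mc, eb$features, training = FALSE, cache = TRUE)
  gr <- ns$backward_pass(m$weights, mc, fw, tg, 3, 0.25)
  loss_at <- function(w) {
    focal_loss(ns$forward_pass(w, mc, eb$features), tg)
  }
  set.seed(4)
  for (nm in names(m$weights)) {
    k <- sample(length(m$weights[[nm]]), 2)
    for (i in k) {
      wp <- m$weights; wp[[nm]][i] <- wp[[nm]][i] + 1e-6
      wm <- m$weights; wm[[nm]][i] <- wm[[nm]][i] - 1e-6
      num <- (loss_at(wp) - loss_at(wm)) / 2e-6
      expect_equal(gr[[nm]][i], num, tolerance = 1e-5,
                   info = paste(nm, i))
    }
  }
})

test_that("architecture dimensions and parameter count follow the config", {
  mc <- model_config()
  expect_equal(mc$conv_out, 30L)
  expect_equal(mc$pooled_len, 10L)
  expect_equal(mc$flat_width, 1280L)
  m <- build_model(mc, seed = 1)
  expect_equal(n_parameters(m),
               (3 * 20 * 128 + 128) + (1280 * 256 + 256) + (256 * 2 + 2))
  mv <- model_config(padding = "valid")
  expect_equal(mv$conv_out, 28L)
  expect_equal(mv$flat_width, 9L * 128L)
  expect_equal(n_parameters(build_model(mv, seed = 1)),
               (3 * 20 * 128 + 128) + (1152 * 256 + 256) + (256 * 2 + 2))
})

test_that("initialization and prediction are deterministic under the seed", {
  ps <- peptide_set(c("HWYD", "VWYA"))
  p1 <- predict(build_model(seed = 7), ps)
  p2 <- predict(build_model(seed = 7), ps)
  expect_identical(p1, p2)
  expect_false(isTRUE(all.equal(p1$frs_score,
                                predict(build_model(seed = 8), ps)$frs_score)))
  expect_true(all(p1$frs_score > 0 & p1$frs_score < 1))
  # a zero input still yields finite scores in (0, 1)
  zero <- structure(list(features = array(0, c(1, 30, 20)), frs = 0L, chel = 0L,
                         ids = "z", sequences = ""), class = "encoded_batch")
  sz <- predict(build_model(seed = 1), zero)
  expect_true(all(sz$frs_score > 0 & sz$frs_score < 1))
})

test_that("prediction is order-preserving and batch-partition invariant", {
  m <- build_model(seed = 3)
  seqs <- random_peptides(8, c(2, 20), seed = 9)
  all_at_once <- predict(m, seqs)
  expect_equal(predict(m, seqs[3])$frs_score, all_at_once$frs_score[3],
               tolerance = 1e-12)
  one_by_one <- do.call(rbind, lapply(seqs, function(s) predict(m, s)))
  expect_equal(one_by_one$frs_score, all_at_once$frs_score, tolerance = 1e-12)
  dup <- predict(m, c("HWYD", "HWYD"))
  expect_equal(dup$frs_score[1], dup$frs_score[2])
})

test_that("one C++ training step equals the R reference step exactly", {
  ns <- asNamespace("antioxpep")
  mc <- model_config(conv_dropout = 0, dense_dropout = 0)
  ps <- peptide_set(c("HWYD", "VWYA", "AAAA", "KLMN", "PQRS", "TTVW"),
                    frs = c(1, 1, 0, 0, 1, 0), chel = c(0, 1, 0, 0, 0, 0))
  eb <- encode_batch(ps)
  m <- build_model(mc, seed = 5)
  trained <- train_model(m, eb, tc = train_config(seed = 9,
                                                  final_train_epochs = 1,
                                                  batch_size = 10))
  tg <- cbind(ps$frs, ps$chel)
  fw <- ns$forward_pass(m$weights, mc, eb$features, training = TRUE, cache = TRUE)
  gr <- ns$backward_pass(m$weights, mc, fw, tg, 3, 0.25)
  up <- ns$adam_step(m$weights, gr, ns$adam_init(m$weights), 3e-5)
  for (nm in names(m$weights)) {
    expect_equal(trained$weights[[nm]], up$weights[[nm]], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  expect_equal(trained$training_log$train_loss[1], focal_loss(fw$P3, tg),
               tolerance = 1e-12)
  expect_equal(nrow(trained$training_log), 1L)
})

test_that("training learns a separable fixture to perfection", {
  ps <- separable_fixture()
  eb <- encode_batch(ps)
  tm <- train_model(build_model(seed = 1), eb,
                    tc = train_config(seed = 1, final_train_epochs = 400,
                                      batch_size = 96L))
  # loss trends downward from the start (dropout makes the per-epoch
  # training loss stochastic, so strict per-epoch decrease is not asserted)
  tl <- tm$training_log$train_loss
  expect_lt(tl[10], tl[1])
  expect_lt(mean(tl[6:10]), mean(tl[1:5]))
  expect_lt(tl[400], tl[10])
  pr <- predict(tm, ps)
  expect_equal(auc_score(pr$frs_score, ps$frs), 1)
  expect_gt(mean(pr$frs_score[ps$frs == 1]), mean(pr$frs_score[ps$frs == 0]))

  # seeded retraining is reproducible
  tm2 <- train_model(build_model(seed = 1), eb,
                     tc = train_config(seed = 1, final_train_epochs = 400,
                                       batch_size = 96L))
  expect_equal(tm$weights, tm2$weights, tolerance = 1e-12)
})

test_that("early stopping restores the best validation epoch", {
  ps <- separable_fixture()
  train_pep <- ps[c(1:30, 41:70), ]
  val_pep <- ps[c(31:40, 71:80), ]
  class(train_pep) <- class(val_pep) <- c("peptide_set", "data.frame")
  tm <- train_model(build_model(seed = 2), encode_batch(train_pep),
                    encode_batch(val_pep),
                    tc = train_config(seed = 2, max_epochs = 60,
                                      early_stop_patience = 5))
  log <- tm$training_log
  expect_true(all(is.finite(log$val_loss)))
  best <- which.min(log$val_loss)
  # stopped no later than best + patience + 1, and kept the best epoch
  expect_lte(nrow(log), best + 6)
  # restored weights reproduce the best validation loss
  vp <- predict(tm, val_pep)
  vl <- focal_loss(cbind(vp$frs_score, vp$chel_score),
                   cbind(val_pep$frs, val_pep$chel))
  expect_equal(vl, min(log$val_loss), tolerance = 1e-10)
})

test_that("output heads are independent at the trunk's output", {
  ps <- separable_fixture(n_per_class = 30)
  eb1 <- encode_batch(ps)
  set.seed(99)
  ps2 <- ps
  ps2$chel <- sample(c(rep(1L, 10), rep(0L, 50)))  # scrambled chelator labels
  eb2 <- encode_batch(ps2)
  tc <- train_config(seed = 3, final_train_epochs = 300)
  a1 <- auc_score(predict(train_model(build_model(seed = 3), eb1, tc = tc), ps)$frs_score, ps$frs)
  a2 <- auc_score(predict(train_model(build_model(seed = 3), eb2, tc = tc), ps)$frs_score, ps$frs)
  expect_gte(a1, 0.95)
  expect_gte(a2, 0.95)  # FRS head converges regardless of chelator targets
})

test_that("checkpoints round-trip through JSON", {
  m <- build_model(seed = 11)
  f <- withr::local_tempfile(fileext = ".json")
  save_model(m, f)
  m2 <- load_model(f)
  seqs <- c("HWYD", "VWYAKL")
  expect_equal(predict(m, seqs), predict(m2, seqs), tolerance = 1e-12)
})
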