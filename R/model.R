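#' Architecture hyperparameters of the dual-output convolutional classifier
#'
#' One convolutional block (128 filters of width 3, stride 1, ELU, average
#' pooling of width 3 / stride 3, 10% dropout), a 256-unit ELU dense block
#' with 15% dropout, and a 2-unit sigmoid output head (FRS, chelator).
#' Convolution boundary handling is `"same"` by default (output length 30,
#' pooled length 10, flattened width 1280), preserving terminal-residue
#' features; `"valid"` (28 -> 9 -> 1152) is available.
#'
#' @param conv_filters,conv_kernel,conv_stride Convolution shape.
#' @param pool_size,pool_stride Average-pooling shape.
#' @param conv_dropout,dense_dropout Dropout probabilities.
#' @param dense_units Width of the dense block.
#' @param n_outputs Output heads (2: FRS and chelator).
#' @param padding `"same"` or `"valid"` convolution boundary handling.
#' @param max_len Padded input length.
#' @return A `model_config` list.
#' @export
model_config <- function(conv_filters = 128L, conv_kernel = 3L, conv_stride = 1L,
                         pool_size = 3L, pool_stride = 3L, conv_dropout = 0.10,
                         dense_units = 256L, dense_dropout = 0.15, n_outputs = 2L,
                         padding = c("same", "valid"), max_len = 30L) {
  padding <- match.arg(padding)
  if (conv_stride != 1L) stop("only conv_stride = 1 is implemented", call. = FALSE)
  if (pool_size != pool_stride) {
    stop("only non-overlapping pooling (pool_size == pool_stride) is implemented",
         call. = FALSE)
  }
  conv_out <- if (padding == "same") max_len else max_len - conv_kernel + 1L
  pooled <- conv_out %/% pool_stride
  if (pooled < 1L) stop("pooling collapses the sequence axis entirely", call. = FALSE)
  structure(list(conv_filters = as.integer(conv_filters),
                 conv_kernel = as.integer(conv_kernel),
                 conv_stride = as.integer(conv_stride),
                 pool_size = as.integer(pool_size),
                 pool_stride = as.integer(pool_stride),
                 conv_dropout = conv_dropout, dense_units = as.integer(dense_units),
                 dense_dropout = dense_dropout, n_outputs = as.integer(n_outputs),
                 padding = padding, max_len = as.integer(max_len),
                 conv_out = conv_out, pooled_len = pooled,
                 flat_width = pooled * as.integer(conv_filters)),
            class = "model_config")
}

#' Optimization hyperparameters
#'
#' Focal loss (gamma = 3, alpha = 0.25) with Adam (learning rate 3e-5,
#' inverse-time decay 0.005 per epoch: `lr_t = lr0 / (1 + decay * t)`),
#' mini-batches of 96. With a validation set, early stopping monitors the
#' validation focal loss with patience 20 and restores the best-epoch
#' weights under a `max_epochs` cap; without one, training runs exactly
#' `final_train_epochs` (400, the final-model budget).
#'
#' @param focal_gamma,focal_alpha Focal-loss parameters.
#' @param learning_rate,lr_decay Adam step size and inverse-time decay rate.
#' @param decay_mode `"lr"` (inverse-time learning-rate decay, the historical
#'   meaning of a `decay` argument) or `"l2"` (weight decay at the same rate).
#' @param batch_size Mini-batch size.
#' @param max_epochs Epoch cap when early stopping is active.
#' @param final_train_epochs Epochs when no validation set is given.
#' @param early_stop_patience Epochs without validation improvement tolerated.
#' @param seed RNG seed covering initialization, shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(focal_gamma = 3, focal_alpha = 0.25,
                         learning_rate = 0.00003, lr_decay = 0.005,
                         decay_mode = c("lr", "l2"), batch_size = 96L,
                         max_epochs = 400L, final_train_epochs = 400L,
                         early_stop_patience = 20L, seed = 1L) {
  decay_mode <- match.arg(decay_mode)
  structure(list(focal_gamma = focal_gamma, focal_alpha = focal_alpha,
                 learning_rate = learning_rate, lr_decay = lr_decay,
                 decay_mode = decay_mode, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 final_train_epochs = as.integer(final_train_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Focal loss
#'
#' `-alpha_t * (1 - p_t)^gamma * ln(p_t)` with `p_t = p` for positives and
#' `1 - p` for negatives, `alpha_t = alpha` for positives and `1 - alpha`
#' otherwise. Down-weights easy examples; at `gamma = 0, alpha = 0.5` it is
#' half the standard binary cross-entropy. Inputs are clamped to
#' `[1e-7, 1 - 1e-7]`. Returns the mean over all elements (the batch /
#' two-head aggregation used in training).
#'
#' @param p Predicted scores in (0, 1).
#' @param y Binary targets.
#' @param gamma,alpha Focal parameters.
#' @return Mean focal loss (non-negative scalar).
#' @examples
#' focal_loss(0.5, 1)  # 0.25 * 0.5^3 * log(2) ~= 0.021661
#' @export
focal_loss <- function(p, y, gamma = 3, alpha = 0.25) {
  mean(focal_loss_elements(p, y, gamma, alpha))
}

focal_loss_elements <- function(p, y, gamma = 3, alpha = 0.25) {
  eps <- 1e-7
  p <- pmin(pmax(p, eps), 1 - eps)
  pt <- ifelse(y == 1, p, 1 - p)
  at <- ifelse(y == 1, alpha, 1 - alpha)
  -at * (1 - pt)^gamma * log(pt)
}

# dL/dp of the elementwise focal loss (no mean factor)
focal_loss_grad <- function(p, y, gamma = 3, alpha = 0.25) {
  eps <- 1e-7
  p <- pmin(pmax(p, eps), 1 - eps)
  pos <- alpha * (gamma * (1 - p)^(gamma - 1) * log(p) - (1 - p)^gamma / p)
  neg <- (1 - alpha) * (-gamma * p^(gamma - 1) * log(1 - p) + p^gamma / (1 - p))
  ifelse(y == 1, pos, neg)
}

elu <- function(z) {
  neg <- z <= 0
  z[neg] <- expm1(z[neg])
  z
}
# a = elu(z): derivative is 1 for z > 0, exp(z) = a + 1 otherwise
elu_grad <- function(z, a) {
  g <- a + 1
  g[z > 0] <- 1
  g
}
sigmoid <- function(z) 1 / (1 + exp(-z))

init_weights <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  kin <- config$conv_kernel * 20L
  he <- function(nr, nc) matrix(rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)
  list(Wc = he(kin, config$conv_filters), bc = numeric(config$conv_filters),
       Wd = he(config$flat_width, config$dense_units), bd = numeric(config$dense_units),
       Wo = he(config$dense_units, config$n_outputs), bo = numeric(config$n_outputs))
}

#' Build an untrained model
#'
#' Seeded fan-in-scaled initialization; the forward pass maps a
#' `B x 30 x 20` batch to `B x 2` sigmoid scores.
#'
#' @param config A [model_config()].
#' @param seed Initialization seed.
#' @return An `antiox_model`.
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  structure(list(config = config, weights = init_weights(config, seed),
                 training_log = NULL, trained = FALSE),
            class = "antiox_model")
}

#' Number of trainable parameters
#'
#' @param model An `antiox_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$weights, length, integer(1)))
}

# im2col in sample-major layout: (B, L, 20) -> (B*Lout, kernel*20) with rows
# ordered position-fastest within each sample, so a training set's matrix can
# be built once and mini-batches taken as contiguous row blocks.
im2col <- function(A, kernel, padding) {
  B <- dim(A)[1]; L <- dim(A)[2]; C <- dim(A)[3]
  if (padding == "same") {
    off <- (kernel - 1L) %/% 2L
    Ap <- array(0, dim = c(B, L + kernel - 1L, C))
    Ap[, off + seq_len(L), ] <- A
    Lout <- L
  } else {
    Ap <- A
    Lout <- L - kernel + 1L
  }
  # slice t contributes columns ((t-1)C+1):(tC); batch-major slice reshaped
  # to sample-major via aperm
  out <- matrix(0, B * Lout, kernel * C)
  for (t in seq_len(kernel)) {
    sl <- Ap[, t:(t + Lout - 1L), , drop = FALSE]     # (B, Lout, C)
    out[, ((t - 1L) * C + 1L):(t * C)] <- matrix(aperm(sl, c(2L, 1L, 3L)),
                                                 B * Lout, C)
  }
  out
}
# Forward pass. `C1` (the im2col matrix for this batch, sample-major) may be
# supplied to avoid recomputation during training.
forward_pass <- function(weights, config, A, training = FALSE, cache = FALSE,
                         C1 = NULL) {
  B <- if (is.matrix(C1)) nrow(C1) %/% config$conv_out else dim(A)[1]
  if (is.null(C1)) C1 <- im2col(A, config$conv_kernel, config$padding)
  Lc <- config$conv_out
  W <- config$pooled_len
  nf <- config$conv_filters
  Z1 <- C1 %*% weights$Wc
  Z1 <- sweep(Z1, 2, weights$bc, "+")
  A1 <- elu(Z1)
  # non-overlapping average pooling via reshape: rows are (pos, sample) with
  # position fastest, so dim (pool, W*B*nf) averages each window in one pass
  ps <- config$pool_size
  v <- A1
  dim(v) <- c(ps, (Lc %/% ps) * B * nf)
  P <- .colMeans(v, ps, ncol(v))                     # (w, b, f) order
  if (training && config$conv_dropout > 0) {
    mask1 <- (runif(length(P)) >= config$conv_dropout) / (1 - config$conv_dropout)
    P <- P * mask1
  } else mask1 <- NULL
  Pw <- P
  dim(Pw) <- c(W, B, nf)
  Fm <- t(matrix(aperm(Pw, c(1L, 3L, 2L)), W * nf, B))   # B x flat, cols (w,f)
  Z2 <- sweep(Fm %*% weights$Wd, 2, weights$bd, "+")
  A2 <- elu(Z2)
  if (training && config$dense_dropout > 0) {
    mask2 <- matrix((runif(length(A2)) >= config$dense_dropout) /
                      (1 - config$dense_dropout), nrow(A2), ncol(A2))
    D2 <- A2 * mask2
  } else { mask2 <- NULL; D2 <- A2 }
  Z3 <- sweep(D2 %*% weights$Wo, 2, weights$bo, "+")
  P3 <- sigmoid(Z3)
  if (!cache) return(P3)
  list(P3 = P3, D2 = D2, A2 = A2, Z2 = Z2, Fm = Fm, mask1 = mask1,
       mask2 = mask2, A1 = A1, Z1 = Z1, C1 = C1, B = B)
}

backward_pass <- function(weights, config, fw, targets, gamma, alpha) {
  B <- fw$B
  W <- config$pooled_len
  nf <- config$conv_filters
  ps <- config$pool_size
  dP <- focal_loss_grad(fw$P3, targets, gamma, alpha) / length(fw$P3)
  dZ3 <- dP * fw$P3 * (1 - fw$P3)
  gWo <- crossprod(fw$D2, dZ3)
  gbo <- colSums(dZ3)
  dD2 <- tcrossprod(dZ3, weights$Wo)
  if (!is.null(fw$mask2)) dD2 <- dD2 * fw$mask2
  dZ2 <- dD2 * elu_grad(fw$Z2, fw$A2)
  gWd <- crossprod(fw$Fm, dZ2)
  gbd <- colSums(dZ2)
  dF <- tcrossprod(dZ2, weights$Wd)                  # B x (W*nf), cols (w,f)
  dPw <- array(t(dF), dim = c(W, nf, B))
  dPv <- as.vector(aperm(dPw, c(1L, 3L, 2L)))        # (w, b, f) order
  if (!is.null(fw$mask1)) dPv <- dPv * fw$mask1
  # un-pool: every source position in a window receives gradient / pool_size
  dA1 <- matrix(rep(dPv / ps, each = ps), B * config$conv_out, nf)
  dZ1 <- dA1 * elu_grad(fw$Z1, fw$A1)
  gWc <- crossprod(fw$C1, dZ1)
  gbc <- colSums(dZ1)
  list(Wc = gWc, bc = gbc, Wd = gWd, bd = gbd, Wo = gWo, bo = gbo)
}

adam_init <- function(weights) {
  list(m = lapply(weights, function(w) w * 0),
       v = lapply(weights, function(w) w * 0), t = 0L)
}

adam_step <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(weights)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    weights[[nm]] <- weights[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(weights = weights, state = state)
}

batch_targets <- function(batch, idx = NULL) {
  frs <- batch$frs; chel <- batch$chel
  if (!is.null(idx)) { frs <- frs[idx]; chel <- chel[idx] }
  frs[is.na(frs)] <- 0L
  chel[is.na(chel)] <- 0L
  cbind(frs, chel)
}

#' Train the classifier
#'
#' Mini-batch Adam on the focal loss over both heads. With `val_batch`,
#' early stopping monitors the validation focal loss (dropout off) and the
#' best-epoch weights are restored; without it, training runs exactly
#' `tc$final_train_epochs`. Fully reproducible under `tc$seed` on a single
#' thread.
#'
#' @param model An `antiox_model` from [build_model()].
#' @param train_batch An `encoded_batch` with labels.
#' @param val_batch Optional validation `encoded_batch` (activates early
#'   stopping).
#' @param tc A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return The trained `antiox_model` with a `training_log` data.frame
#'   (`epoch`, `train_loss`, `val_loss`).
#' @export
train_model <- function(model, train_batch, val_batch = NULL,
                        tc = train_config(), verbose = FALSE) {
  config <- model$config
  A <- train_batch$features
  n <- dim(A)[1]
  if (n < 1L) stop("empty training data", call. = FALSE)
  targets <- batch_targets(train_batch)
  set.seed(tc$seed)
  C1_all <- im2col(A, config$conv_kernel, config$padding)
  has_val <- !is.null(val_batch)
  val_C1 <- if (has_val) im2col(val_batch$features, config$conv_kernel, config$padding)
  val_targets <- if (has_val) batch_targets(val_batch)
  n_epochs <- if (has_val) tc$max_epochs else tc$final_train_epochs
  res <- cnn_train_cpp(C1_all, targets, val_C1, val_targets, model$weights,
                       config$conv_out, config$pool_size, config$conv_filters,
                       config$conv_dropout, config$dense_dropout,
                       tc$focal_gamma, tc$focal_alpha, tc$learning_rate,
                       tc$lr_decay, tc$decay_mode == "l2", tc$batch_size,
                       n_epochs, tc$early_stop_patience, has_val)
  ran <- length(res$train_loss)
  log <- data.frame(epoch = seq_len(ran), train_loss = res$train_loss,
                    val_loss = if (has_val) res$val_loss else NA_real_)
  if (verbose) {
    message(sprintf("trained %d epoch(s); final train loss %.5f", ran,
                    log$train_loss[ran]))
  }
  model$weights <- res$weights
  model$training_log <- log
  model$trained <- TRUE
  model
}

#' Predict activity scores
#'
#' Deterministic forward pass (dropout off); scores in (0, 1), input order
#' preserved, invariant to how the input is split into batches.
#'
#' @param object An `antiox_model`.
#' @param peptides A `peptide_set`, character vector of sequences, or
#'   `encoded_batch`.
#' @param ... Unused.
#' @return data.frame with `id`, `sequence`, `frs_score`, `chel_score`.
#' @export
predict.antiox_model <- function(object, peptides, ...) {
  batch <- if (inherits(peptides, "encoded_batch")) peptides
           else encode_batch(peptides, object$config$max_len)
  scores <- forward_pass(object$weights, object$config, batch$features)
  data.frame(id = batch$ids, sequence = batch$sequences,
             frs_score = scores[, 1], chel_score = scores[, 2],
             stringsAsFactors = FALSE)
}

#' @export
print.antiox_model <- function(x, ...) {
  cat(sprintf("antiox_model: conv %d x %d (%s) -> pool %d -> dense %d -> %d heads; %d parameters; %s\n",
              x$config$conv_filters, x$config$conv_kernel, x$config$padding,
              x$config$pool_size, x$config$dense_units, x$config$n_outputs,
              n_parameters(x), if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Plain-text JSON checkpoint: flattened weights plus the architecture
#' config, restorable with [load_model()].
#'
#' @param model An `antiox_model`.
#' @param path Output `.json` path.
#' @export
save_model <- function(model, path) {
  payload <- list(config = unclass(model$config),
                  weights = lapply(model$weights, function(w) {
                    list(dim = dim(w) %||% length(w), data = as.numeric(w))
                  }),
                  trained = model$trained)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname save_model
#' @param path Checkpoint path written by [save_model()].
#' @return An `antiox_model`.
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- payload$config
  config <- model_config(conv_filters = cfg$conv_filters, conv_kernel = cfg$conv_kernel,
                         conv_stride = cfg$conv_stride, pool_size = cfg$pool_size,
                         pool_stride = cfg$pool_stride, conv_dropout = cfg$conv_dropout,
                         dense_units = cfg$dense_units, dense_dropout = cfg$dense_dropout,
                         n_outputs = cfg$n_outputs, padding = cfg$padding,
                         max_len = cfg$max_len)
  weights <- lapply(payload$weights, function(w) {
    if (length(w$dim) == 2L) matrix(w$data, w$dim[1], w$dim[2]) else as.numeric(w$data)
  })
  structure(list(config = config, weights = weights, training_log = NULL,
                 trained = isTRUE(payload$trained)),
            class = "antiox_model")
}
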