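#' Training configuration
#'
#' Adam (beta1 = 0.9, beta2 = 0.999), initial learning rate 1e-3 with
#' reduce-on-plateau scheduling (factor 0.5, patience 3, monitoring
#' validation loss), batch size 32, up to 100 epochs with early stopping
#' (patience 10 on validation loss, best weights restored).
#'
#' @param lr initial learning rate.
#' @param beta1,beta2 Adam moment decay rates.
#' @param batch_size mini-batch size.
#' @param max_epochs epoch cap.
#' @param early_stop_patience epochs without validation-loss improvement
#'   before stopping.
#' @param plateau_factor,plateau_patience learning-rate schedule parameters.
#' @param seed integer seed driving shuffling and dropout.
#' @return A `train_config`.
#' @export
train_config <- function(lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         batch_size = 32L, max_epochs = 100L,
                         early_stop_patience = 10L, plateau_factor = 0.5,
                         plateau_patience = 3L, seed = 0L) {
  if (min(lr, beta1, beta2, batch_size, max_epochs, early_stop_patience,
          plateau_factor, plateau_patience) <= 0) {
    stop("all training parameters must be positive")
  }
  if (early_stop_patience >= max_epochs) {
    stop("early_stop_patience must be < max_epochs")
  }
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 seed = as.integer(seed)), class = "train_config")
}

#' Categorical cross-entropy
#'
#' `L = -(1/N) sum_i sum_c y_ic log p_ic`, with probabilities clipped to
#' `[1e-12, 1 - 1e-12]`. Non-negative; `log(C)` for uniform predictions.
#'
#' @param probs N x C matrix of predicted probabilities (rows sum to 1).
#' @param labels N x C one-hot matrix (or integer class vector, 0-based or
#'   1-based factor-like, converted internally).
#' @return Scalar loss.
#' @export
cross_entropy <- function(probs, labels) {
  probs <- as.matrix(probs)
  if (is.null(dim(labels))) labels <- one_hot(labels, ncol(probs))
  if (!all(dim(probs) == dim(labels))) stop("shape mismatch")
  p <- pmin(pmax(probs, 1e-12), 1 - 1e-12)
  -mean(rowSums(labels * log(p)))
}

one_hot <- function(y, C) {
  y <- as.integer(y)
  if (min(y) == 0L) y <- y + 1L
  m <- matrix(0, length(y), C)
  m[cbind(seq_along(y), y)] <- 1
  m
}

# one Adam step over the parameter list; state carries m, v, t
adam_step <- function(params, grads, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(dim(params[[nm]]))) g <- as.numeric(g)
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# dataset for the trainer: list(tokens = list of int vectors,
# fused = matrix or NULL, labels = integer 0/1 vector (1 = CML))
check_train_data <- function(d, spec, what) {
  if (!length(d$tokens)) stop("empty ", what, " split")
  if (length(d$labels) != length(d$tokens)) stop(what, ": labels mismatch")
  invisible(check_fused(spec, d$fused, length(d$tokens)))
}

#' Train a model
#'
#' Seeded mini-batch training with Adam, reduce-on-plateau learning-rate
#' scheduling and early stopping on validation loss (best weights
#' restored). Mini-batch order and dropout masks are fully determined by
#' `cfg$seed`, so a fixed config and seed reproduce the run exactly on the
#' same backend.
#'
#' @param model a built `seqfuse_model`.
#' @param train_data,val_data lists with `tokens` (list of integer
#'   vectors), `fused` (matrix or `NULL`) and `labels` (0/1, 1 = CML).
#' @param cfg a [train_config()].
#' @param verbose print per-epoch progress.
#' @return List with the trained `model` and a `history` data frame
#'   (per-epoch train/validation loss and accuracy, learning rate) carrying
#'   attributes `best_epoch`, `stopped_epoch`, `restored_best`.
#' @export
train_model <- function(model, train_data, val_data, cfg = train_config(),
                        verbose = FALSE) {
  stopifnot(inherits(model, "seqfuse_model"), inherits(cfg, "train_config"))
  spec <- model$spec
  check_train_data(train_data, spec, "train")
  check_train_data(val_data, spec, "validation")
  n <- length(train_data$tokens)
  params <- params_for_cpp(model$params)
  cspec <- spec_for_cpp(spec)
  state <- list(m = lapply(params, function(x) x * 0),
                v = lapply(params, function(x) x * 0), t = 0L)
  lr <- cfg$lr
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     train_acc = numeric(0), val_loss = numeric(0),
                     val_acc = numeric(0), lr = numeric(0))
  best_val <- Inf; best_epoch <- 0L; best_params <- params
  wait_stop <- 0L; wait_plateau <- 0L; stopped <- 0L
  fused_tr <- check_fused(spec, train_data$fused, n)

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- with_seed(cfg$seed + epoch, sample.int(n))
    starts <- seq(1L, n, by = cfg$batch_size)
    ep_loss <- 0; ep_correct <- 0L
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + cfg$batch_size - 1L, n)]
      bf <- if (is.null(fused_tr)) NULL else fused_tr[idx, , drop = FALSE]
      drop_seed <- as.integer((as.numeric(cfg$seed) * 1000003 +
                                 epoch * 1009 + bi) %% 2147483647)
      res <- cpp_batch_grad(params, cspec, train_data$tokens[idx], bf,
                            as.integer(train_data$labels[idx]), drop_seed)
      if (!is.finite(res$loss)) {
        stop(sprintf("non-finite loss at epoch %d batch %d", epoch, bi))
      }
      upd <- adam_step(params, res$grads, state, lr, cfg$beta1, cfg$beta2)
      params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + res$loss * length(idx)
      ep_correct <- ep_correct +
        sum(max.col(res$probs, ties.method = "first") - 1L == train_data$labels[idx])
    }
    ev <- evaluate_split(params, cspec, spec, val_data)
    hist <- rbind(hist, data.frame(
      epoch = epoch, train_loss = ep_loss / n, train_acc = ep_correct / n,
      val_loss = ev$loss, val_acc = ev$acc, lr = lr))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f/%.3f  val %.4f/%.3f  lr %.2g",
                      epoch, ep_loss / n, ep_correct / n, ev$loss, ev$acc, lr))
    }
    if (ev$loss < best_val - 1e-12) {
      best_val <- ev$loss; best_epoch <- epoch; best_params <- params
      wait_stop <- 0L; wait_plateau <- 0L
    } else {
      wait_stop <- wait_stop + 1L
      wait_plateau <- wait_plateau + 1L
      if (wait_plateau >= cfg$plateau_patience) {
        lr <- lr * cfg$plateau_factor
        wait_plateau <- 0L
      }
      if (wait_stop >= cfg$early_stop_patience) {
        stopped <- epoch
        break
      }
    }
  }
  if (stopped == 0L) stopped <- nrow(hist)
  model$params <- strip_cpp_params(best_params, model$params)
  attr(hist, "best_epoch") <- best_epoch
  attr(hist, "stopped_epoch") <- stopped
  attr(hist, "restored_best") <- TRUE
  attr(hist, "best_val_loss") <- best_val
  list(model = model, history = hist)
}

# convert 1-row matrices back to plain numeric biases
strip_cpp_params <- function(cpp_params, template) {
  out <- cpp_params
  for (nm in names(template)) {
    if (is.null(dim(template[[nm]]))) out[[nm]] <- as.numeric(out[[nm]])
  }
  out
}

evaluate_split <- function(params, cspec, spec, d) {
  fm <- check_fused(spec, d$fused, length(d$tokens))
  out <- cpp_predict(params, cspec, d$tokens, fm)
  loss <- cross_entropy(out$probs, one_hot(d$labels, spec$n_classes))
  acc <- mean(max.col(out$probs, ties.method = "first") - 1L == d$labels)
  list(loss = loss, acc = acc, probs = out$probs)
}

#' Predict class probabilities for a trainer-format dataset
#' @param model a `seqfuse_model`.
#' @param data list with `tokens` and optional `fused` (trainer format).
#' @return Matrix of probabilities, columns `Control`, `CML`.
#' @export
predict_proba <- function(model, data) {
  model_forward(model, data$tokens, data$fused)
}
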