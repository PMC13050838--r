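#' Architecture specification
#'
#' The dual-branch CNN -> BiLSTM -> global-average-pooling -> dense ->
#' softmax classifier: two parallel 1-D convolutions (kernel sizes 3 and 7,
#' 128 filters each, "same" zero-padding, ReLU), max-pooling (size 2,
#' stride 2) and dropout per branch, channel-wise concatenation, a
#' bidirectional LSTM (64 units per direction), mask-aware global average
#' pooling, optional late fusion with the 382-dimensional descriptor
#' vector, then dense(128, ReLU) -> dropout -> softmax over 2 classes.
#' Variant toggles (`use_branch_a/b`, `use_bilstm`, `use_late_fusion`)
#' express the ablation grid.
#'
#' @param embed_dim residue embedding width (default 128).
#' @param kernel_a,kernel_b odd positive kernel sizes (defaults 3, 7).
#' @param filters convolution filters per branch (default 128).
#' @param pool_size,pool_stride max-pooling geometry (fixed at 2/2).
#' @param bilstm_units LSTM units per direction (default 64).
#' @param dense_units dense layer width (default 128).
#' @param dropout dropout rate in `[0, 1)` (default 0.5).
#' @param n_classes number of classes (default 2).
#' @param use_late_fusion concatenate the fused descriptor vector after
#'   pooling (default `TRUE`).
#' @param fusion_dim width of the fused vector (default 382).
#' @param use_branch_a,use_branch_b,use_bilstm ablation toggles.
#' @return A `model_spec`.
#' @export
model_spec <- function(embed_dim = 128L, kernel_a = 3L, kernel_b = 7L,
                       filters = 128L, pool_size = 2L, pool_stride = 2L,
                       bilstm_units = 64L, dense_units = 128L, dropout = 0.5,
                       n_classes = 2L, use_late_fusion = TRUE,
                       fusion_dim = 382L, use_branch_a = TRUE,
                       use_branch_b = TRUE, use_bilstm = TRUE) {
  if (pool_size != 2L || pool_stride != 2L) {
    stop("only pool_size = pool_stride = 2 is supported")
  }
  for (k in c(kernel_a, kernel_b)) {
    if (k < 1L || k %% 2L == 0L) stop("kernel sizes must be odd and positive")
  }
  if (use_branch_a && use_branch_b && kernel_a == kernel_b) {
    warning("kernel_a == kernel_b: the dual branch is degenerate")
  }
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (!use_branch_a && !use_branch_b && !use_bilstm) {
    stop("at least one of the branches or the BiLSTM must be enabled")
  }
  if (min(embed_dim, filters, bilstm_units, dense_units, n_classes) < 1L) {
    stop("all unit counts must be positive")
  }
  structure(list(
    embed_dim = as.integer(embed_dim), kernel_a = as.integer(kernel_a),
    kernel_b = as.integer(kernel_b), filters = as.integer(filters),
    pool_size = 2L, pool_stride = 2L,
    bilstm_units = as.integer(bilstm_units),
    dense_units = as.integer(dense_units), dropout = dropout,
    n_classes = as.integer(n_classes),
    use_late_fusion = isTRUE(use_late_fusion),
    fusion_dim = if (isTRUE(use_late_fusion)) as.integer(fusion_dim) else 0L,
    use_branch_a = isTRUE(use_branch_a), use_branch_b = isTRUE(use_branch_b),
    use_bilstm = isTRUE(use_bilstm)), class = "model_spec")
}

n_branches <- function(spec) sum(spec$use_branch_a, spec$use_branch_b)

# channel width entering the BiLSTM (or the GAP when the BiLSTM is off)
lstm_input_dim <- function(spec) {
  if (n_branches(spec) > 0) spec$filters * n_branches(spec) else spec$embed_dim
}

gap_dim <- function(spec) {
  if (spec$use_bilstm) 2L * spec$bilstm_units else lstm_input_dim(spec)
}

#' Dense-head input width implied by a spec
#' @param spec a [model_spec()].
#' @return Integer: pooled width plus `fusion_dim` when late fusion is on.
#' @export
dense_input_dim <- function(spec) gap_dim(spec) + spec$fusion_dim

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# orthogonal H x 4H recurrent matrix: one orthogonal block per gate, the
# standard recurrent initialization
orthogonal_recurrent <- function(H) {
  do.call(cbind, lapply(1:4, function(i) {
    qr.Q(qr(matrix(stats::rnorm(H * H), H, H)))
  }))
}

#' Build and initialize a model
#'
#' Deterministic initialization from `seed` (identical seeds give
#' bit-identical parameters): Glorot-uniform weight matrices, zero biases
#' except the LSTM forget gate (1.0, the usual stabilizing choice), and a
#' standard-normal residue embedding table (the common embedding-layer
#' default; a much smaller scale makes the convolutional activations
#' vanish and the sequence stream untrainable at the fixed learning rate).
#'
#' @param spec a [model_spec()].
#' @param seed integer seed.
#' @return A `seqfuse_model` (list with `spec`, `params`, `seed`).
#' @export
build_model <- function(spec = model_spec(), seed = 0L) {
  stopifnot(inherits(spec, "model_spec"))
  E <- spec$embed_dim; F_ <- spec$filters; H <- spec$bilstm_units
  D <- spec$dense_units; C <- spec$n_classes
  cin <- lstm_input_dim(spec)
  p <- with_seed(seed, {
    p <- list(emb = matrix(stats::rnorm(20L * E), 20L, E))
    if (spec$use_branch_a) {
      p$Wa <- glorot(spec$kernel_a * E, F_); p$ba <- numeric(F_)
    }
    if (spec$use_branch_b) {
      p$Wb <- glorot(spec$kernel_b * E, F_); p$bb <- numeric(F_)
    }
    if (spec$use_bilstm) {
      forget_bias <- rep(c(0, 1, 0, 0), each = H)  # gate order [i | f | g | o]
      p$Wf <- glorot(cin, 4L * H); p$Uf <- orthogonal_recurrent(H)
      p$bf <- forget_bias
      p$Wr <- glorot(cin, 4L * H); p$Ur <- orthogonal_recurrent(H)
      p$br <- forget_bias
    }
    p$Wd <- glorot(dense_input_dim(spec), D); p$bd <- numeric(D)
    p$Ws <- glorot(D, C); p$bs <- numeric(C)
    p
  })
  structure(list(spec = spec, params = p, seed = as.integer(seed)),
            class = "seqfuse_model")
}

# spec as consumed by the C++ core
spec_for_cpp <- function(spec) {
  list(embed_dim = spec$embed_dim, kernel_a = spec$kernel_a,
       kernel_b = spec$kernel_b, filters = spec$filters,
       bilstm_units = spec$bilstm_units, dense_units = spec$dense_units,
       n_classes = spec$n_classes, fusion_dim = spec$fusion_dim,
       use_branch_a = spec$use_branch_a, use_branch_b = spec$use_branch_b,
       use_bilstm = spec$use_bilstm, dropout = spec$dropout)
}

# params as consumed by the C++ core (biases as 1-row matrices)
params_for_cpp <- function(params) {
  lapply(params, function(x) if (is.null(dim(x))) matrix(x, nrow = 1L) else x)
}

as_token_list <- function(tokens) {
  if (is.list(tokens)) lapply(tokens, as.integer) else list(as.integer(tokens))
}

#' Forward pass: class probabilities
#'
#' Inference-mode forward pass (dropout off, hence deterministic). Accepts
#' either a single token vector or a list of them; padding is unnecessary
#' because every stage is computed at the true sequence length (masked
#' positions therefore cannot influence pooling). If a padded matrix +
#' mask from [embed_tokens()] is in hand, pass `tokens = which(mask == 1)`
#' positions' tokens instead.
#'
#' @param model a built `seqfuse_model`.
#' @param tokens integer token vector (1..20) or list thereof.
#' @param fused optional fused descriptor matrix (rows match sequences) when
#'   the spec uses late fusion.
#' @return Matrix of class probabilities (rows sum to 1).
#' @export
model_forward <- function(model, tokens, fused = NULL) {
  stopifnot(inherits(model, "seqfuse_model"))
  tk <- as_token_list(tokens)
  fm <- check_fused(model$spec, fused, length(tk))
  out <- cpp_predict(params_for_cpp(model$params), spec_for_cpp(model$spec),
                     tk, fm)
  colnames(out$probs) <- class_levels()[seq_len(model$spec$n_classes)]
  out$probs
}

check_fused <- function(spec, fused, n) {
  if (spec$fusion_dim == 0L) return(NULL)
  if (is.null(fused)) stop("spec uses late fusion: `fused` is required")
  if (is.null(dim(fused))) fused <- matrix(fused, nrow = 1L)
  if (ncol(fused) != spec$fusion_dim) {
    stop(sprintf("fused width %d != fusion_dim %d", ncol(fused),
                 spec$fusion_dim))
  }
  if (nrow(fused) != n) stop("fused rows must match the number of sequences")
  as.matrix(fused)
}

# class order fixed as (Control = 0, CML = 1); column/index order everywhere
class_levels <- function() c("Control", "CML")

#' Count trainable parameters
#' @param model a `seqfuse_model`.
#' @return Integer total of all parameter array lengths.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "seqfuse_model"))
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.seqfuse_model <- function(x, ...) {
  s <- x$spec
  branches <- paste(c(if (s$use_branch_a) sprintf("k=%d", s$kernel_a),
                      if (s$use_branch_b) sprintf("k=%d", s$kernel_b)),
                    collapse = ", ")
  cat("<seqfuse_model>\n")
  cat(sprintf("  conv branches: %s (%d filters)\n",
              if (nzchar(branches)) branches else "none", s$filters))
  cat(sprintf("  bilstm: %s | late fusion: %d dims\n",
              if (s$use_bilstm) sprintf("%d/direction", s$bilstm_units)
              else "none", s$fusion_dim))
  cat(sprintf("  parameters: %d (seed %d)\n", count_parameters(x), x$seed))
  invisible(x)
}
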