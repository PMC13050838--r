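#' Integrated-gradients configuration
#'
#' @param steps number of Riemann steps m (midpoint rule); default 50.
#' @param target_class class whose pre-softmax logit is attributed
#'   (`"CML"` or `"Control"`, default `"CML"`). Attributing the logit
#'   rather than the probability avoids softmax saturation.
#' @return An `ig_config`.
#' @export
ig_config <- function(steps = 50L, target_class = "CML") {
  if (steps < 1L) stop("steps must be >= 1")
  if (!target_class %in% class_levels()) {
    stop("target_class must be 'Control' or 'CML'")
  }
  structure(list(steps = as.integer(steps), target_class = target_class),
            class = "ig_config")
}

#' Generic integrated gradients for any differentiable scalar function
#'
#' Midpoint-rule Riemann approximation of the path integral from
#' `baseline` to `x`:
#' `attr = (x - baseline) * mean_j grad(baseline + (j - 1/2)/m * (x - baseline))`.
#' Exact for linear functions at any m >= 1; the completeness gap
#' `|sum(attr) - (f(x) - f(baseline))|` shrinks as m grows.
#'
#' @param f scalar-valued function of `x`.
#' @param grad_f gradient function of `x` (same shape as `x`).
#' @param x input (vector or matrix).
#' @param baseline reference input (default all zeros).
#' @param steps number of Riemann steps.
#' @return List with `attributions` (shape of `x`) and `completeness_gap`.
#' @export
integrated_gradients_fn <- function(f, grad_f, x, baseline = x * 0,
                                    steps = 50L) {
  if (steps < 1L) stop("steps must be >= 1")
  delta <- x - baseline
  acc <- x * 0
  for (j in seq_len(steps)) {
    alpha <- (j - 0.5) / steps
    acc <- acc + grad_f(baseline + alpha * delta)
  }
  attributions <- delta * acc / steps
  gap <- abs(sum(attributions) - (f(x) - f(baseline)))
  list(attributions = attributions, completeness_gap = gap)
}

#' Integrated-gradients attribution for a trained model
#'
#' Attributes the target-class logit over the embedded input positions
#' (dropout off). The baseline is the all-zero embedding (the padding
#' vector). Per-position scores aggregate the embedding channels by signed
#' summation so that completeness holds; positions beyond the true
#' sequence length are excluded by construction.
#'
#' @param model a trained `seqfuse_model`.
#' @param tokens integer token vector for one sequence.
#' @param fused fused descriptor vector for that sequence (if the spec
#'   uses late fusion); held fixed along the path.
#' @param cfg an [ig_config()].
#' @return An `attribution_map`: per-position `scores` (1-based),
#'   `completeness_gap`, `target_class`, `steps`, and the channel-level
#'   `attributions` matrix.
#' @export
integrated_gradients <- function(model, tokens, fused = NULL,
                                 cfg = ig_config()) {
  stopifnot(inherits(model, "seqfuse_model"))
  tokens <- as.integer(tokens)
  params <- params_for_cpp(model$params)
  cspec <- spec_for_cpp(model$spec)
  fv <- if (model$spec$fusion_dim > 0) {
    as.numeric(check_fused(model$spec, fused, 1L))
  } else NULL
  target <- match(cfg$target_class, class_levels()) - 1L
  X <- model$params$emb[tokens, , drop = FALSE]
  f <- function(x) cpp_forward_X(params, cspec, x, fv)$logits[target + 1L]
  g <- function(x) cpp_input_grad(params, cspec, x, fv, target)$dX
  ig <- integrated_gradients_fn(f, g, X, baseline = X * 0,
                                steps = cfg$steps)
  structure(list(scores = rowSums(ig$attributions),
                 attributions = ig$attributions,
                 completeness_gap = ig$completeness_gap,
                 target_class = cfg$target_class, steps = cfg$steps,
                 n_positions = length(tokens)),
            class = "attribution_map")
}

#' Top-k attribution positions
#'
#' Positions ranked by attribution score descending, ties broken by
#' position ascending; reported 1-based.
#'
#' @param map an `attribution_map` (or plain numeric score vector).
#' @param k number of positions (1 <= k <= sequence length).
#' @return Integer vector of k positions.
#' @export
top_k_positions <- function(map, k) {
  scores <- if (inherits(map, "attribution_map")) map$scores else
    as.numeric(map)
  if (k <= 0) stop("k must be positive")
  if (k > length(scores)) stop("k exceeds sequence length")
  order(-scores, seq_along(scores))[seq_len(k)]
}

#' Write an attribution map as TSV
#' @param map an `attribution_map`.
#' @param residues residue string the map was computed on.
#' @param id sequence identifier for the output.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_attributions <- function(map, residues, id, path) {
  chars <- strsplit(as_residues(residues), "")[[1]][seq_len(map$n_positions)]
  df <- data.frame(id = id, position = seq_len(map$n_positions),
                   residue = chars, score = map$scores)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
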