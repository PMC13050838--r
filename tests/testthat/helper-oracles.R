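# Independent oracle implementations used to cross-check the package's fast
# paths. These deliberately use the most naive formulation available
# (exhaustive enumeration, direct loops) and share no code with R/ or src/.

# ---- alignment oracle: enumerate every global alignment recursively ----
# Returns the lexicographic optimum of (score, matches) over all alignments,
# with a gap run of length g costing gap_open + g * gap_extend.
brute_align <- function(a, b, p = alignment_params()) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  best <- c(score = -Inf, matches = -Inf)
  rec <- function(i, j, score, matches, prev_gap) {
    if (i > length(av) && j > length(bv)) {
      if (score > best["score"] ||
          (score == best["score"] && matches > best["matches"])) {
        best <<- c(score = score, matches = matches)
      }
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == bv[j]) p$match_score else p$mismatch_score
      rec(i + 1, j + 1, score + s, matches + (av[i] == bv[j]), 0L)
    }
    if (i <= length(av)) {  # gap in b, consume a
      open <- if (prev_gap == 1L) 0 else p$gap_open
      rec(i + 1, j, score + open + p$gap_extend, matches, 1L)
    }
    if (j <= length(bv)) {  # gap in a, consume b
      open <- if (prev_gap == 2L) 0 else p$gap_open
      rec(i, j + 1, score + open + p$gap_extend, matches, 2L)
    }
  }
  rec(1L, 1L, 0, 0L, 0L)
  best
}

# ---- neural-network stage oracles: direct loops over the definitions ----
ref_conv_same <- function(X, W, b, k) {
  # W: (k*E) x F laid out as k stacked E-blocks, offsets -(k-1)/2 .. +(k-1)/2
  T_ <- nrow(X); E <- ncol(X); F_ <- ncol(W); h <- (k - 1) / 2
  A <- matrix(0, T_, F_)
  for (t in seq_len(T_)) {
    for (f in seq_len(F_)) {
      acc <- b[f]
      for (dt in 0:(k - 1)) {
        src <- t + dt - h
        if (src >= 1 && src <= T_) {
          for (e in seq_len(E)) {
            acc <- acc + X[src, e] * W[dt * E + e, f]
          }
        }
      }
      A[t, f] <- acc
    }
  }
  A
}

ref_relu <- function(x) pmax(x, 0)

ref_maxpool2 <- function(H) {
  T2 <- floor(nrow(H) / 2)
  out <- matrix(0, T2, ncol(H))
  for (i in seq_len(T2)) {
    for (f in seq_len(ncol(H))) out[i, f] <- max(H[2 * i - 1, f], H[2 * i, f])
  }
  out
}

sigm <- function(x) 1 / (1 + exp(-x))

# single-direction LSTM, gate order [i | f | g | o], explicit per-step loops
ref_lstm <- function(Z, W, U, b, reverse = FALSE) {
  Tz <- nrow(Z); H <- nrow(U)
  Hs <- matrix(0, Tz, H)
  h <- rep(0, H); cs <- rep(0, H)
  steps <- if (reverse) rev(seq_len(Tz)) else seq_len(Tz)
  for (t in steps) {
    g <- as.numeric(Z[t, ] %*% W + h %*% U) + b
    gi <- sigm(g[1:H]); gf <- sigm(g[(H + 1):(2 * H)])
    gg <- tanh(g[(2 * H + 1):(3 * H)]); go <- sigm(g[(3 * H + 1):(4 * H)])
    cs <- gf * cs + gi * gg
    h <- go * tanh(cs)
    Hs[t, ] <- h
  }
  Hs
}

ref_softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# full inference-mode forward pass composed from the stage oracles
ref_forward <- function(model, tokens, fused = NULL) {
  s <- model$spec
  p <- model$params
  X <- p$emb[tokens, , drop = FALSE]
  parts <- list()
  if (s$use_branch_a) {
    A <- ref_conv_same(X, p$Wa, p$ba, s$kernel_a)
    parts <- c(parts, list(ref_maxpool2(ref_relu(A))))
  }
  if (s$use_branch_b) {
    A <- ref_conv_same(X, p$Wb, p$bb, s$kernel_b)
    parts <- c(parts, list(ref_maxpool2(ref_relu(A))))
  }
  Z <- if (length(parts)) do.call(cbind, parts) else X
  Gin <- if (s$use_bilstm) {
    cbind(ref_lstm(Z, p$Wf, p$Uf, p$bf, reverse = FALSE),
          ref_lstm(Z, p$Wr, p$Ur, p$br, reverse = TRUE))
  } else Z
  g <- colMeans(Gin)
  h0 <- if (s$fusion_dim > 0) c(g, fused) else g
  zd <- ref_relu(as.numeric(h0 %*% p$Wd) + p$bd)
  ref_softmax(as.numeric(zd %*% p$Ws) + p$bs)
}

# ---- metric oracles ----
# expand confusion counts into label/prediction vectors and compute every
# metric per-sample
ref_metrics_from_counts <- function(tp, tn, fp, fn) {
  yt <- c(rep(1, tp), rep(0, tn), rep(0, fp), rep(1, fn))
  yp <- c(rep(1, tp), rep(0, tn), rep(1, fp), rep(0, fn))
  per_class <- function(pos) {
    t_ <- as.integer(yt == pos); p_ <- as.integer(yp == pos)
    prec <- if (sum(p_) == 0) 0 else sum(t_ * p_) / sum(p_)
    rec <- if (sum(t_) == 0) 0 else sum(t_ * p_) / sum(t_)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(precision = prec, recall = rec, f1 = f1, support = sum(t_))
  }
  list(accuracy = mean(yt == yp),
       control = per_class(0), cml = per_class(1))
}

# AUC as the exhaustive proportion of correctly ordered class-crossing pairs
ref_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (sp in pos) for (sn in neg) {
    tot <- tot + if (sp > sn) 1 else if (sp == sn) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# silhouette by explicit double loops over point pairs
ref_silhouette <- function(points, labels) {
  n <- nrow(points)
  euclid <- function(i, j) sqrt(sum((points[i, ] - points[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(vapply(own, function(j) euclid(i, j), numeric(1)))
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      members <- which(labels == cl)
      b <- min(b, mean(vapply(members, function(j) euclid(i, j), numeric(1))))
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# independent percentile bootstrap (fresh RNG stream, loop formulation)
ref_bootstrap_acc <- function(y, pred, B, seed) {
  set.seed(seed)
  stats <- numeric(B)
  n <- length(y)
  for (b in seq_len(B)) {
    idx <- sample(n, n, replace = TRUE)
    stats[b] <- mean(y[idx] == pred[idx])
  }
  quantile(stats, c(0.025, 0.975), type = 7, names = FALSE)
}

# ---- shared fixtures ----
random_residues <- function(n, len, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                 len, replace = TRUE), collapse = "")
  }, character(1))
}

tiny_spec <- function(...) {
  model_spec(embed_dim = 6L, filters = 5L, bilstm_units = 4L,
             dense_units = 7L, fusion_dim = 3L, dropout = 0, ...)
}

tiny_data <- function(n, spec, seed = 1, len_range = c(8L, 16L)) {
  set.seed(seed)
  list(tokens = lapply(seq_len(n), function(i) {
         sample(1:20, sample(len_range[1]:len_range[2], 1), replace = TRUE)
       }),
       fused = if (spec$fusion_dim > 0) {
         matrix(rnorm(n * spec$fusion_dim), n)
       } else NULL,
       labels = rep_len(c(0L, 1L), n))
}
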