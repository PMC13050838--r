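#' Physicochemical property table for pseudo amino acid composition
#'
#' The three classic per-residue properties used by type-I pseudo amino
#' acid composition: hydrophobicity (Eisenberg consensus scale),
#' hydrophilicity (Hopp--Woods) and side-chain mass. Each column is
#' standardized to zero mean and unit (population) variance over the 20
#' canonical residues, as usual for sequence-order correlation factors.
#'
#' @param standardize standardize columns (default `TRUE`).
#' @return 20 x 3 numeric matrix, rows named by residue.
#' @export
pseaac_properties <- function(standardize = TRUE) {
  hydrophobicity <- c(
    A = 0.62, C = 0.29, D = -0.90, E = -0.74, F = 1.19, G = 0.48, H = -0.40,
    I = 1.38, K = -1.50, L = 1.06, M = 0.64, N = -0.78, P = 0.12, Q = -0.85,
    R = -2.53, S = -0.18, T = -0.05, V = 1.08, W = 0.81, Y = 0.26)
  hydrophilicity <- c(
    A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5, G = 0.0, H = -0.5,
    I = -1.8, K = 3.0, L = -1.8, M = -1.3, N = 0.2, P = 0.0, Q = 0.2,
    R = 3.0, S = 0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3)
  side_chain_mass <- c(
    A = 15, C = 47, D = 59, E = 73, F = 91, G = 1, H = 82,
    I = 57, K = 73, L = 57, M = 75, N = 58, P = 42, Q = 72,
    R = 101, S = 31, T = 45, V = 43, W = 130, Y = 107)
  m <- cbind(hydrophobicity = hydrophobicity[AA_ALPHABET],
             hydrophilicity = hydrophilicity[AA_ALPHABET],
             side_chain_mass = side_chain_mass[AA_ALPHABET])
  rownames(m) <- AA_ALPHABET
  if (standardize) {
    m <- apply(m, 2, function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2)))
    rownames(m) <- AA_ALPHABET
  }
  m
}

#' Pseudo amino acid composition configuration
#'
#' @param lambda_ sequence-order depth (number of correlation lags);
#'   default 5, giving the 25-dimensional descriptor 20 + lambda.
#' @param weight weight factor w for the correlation terms; default 0.05.
#' @param properties per-residue property matrix (rows = 20 residues); see
#'   [pseaac_properties()].
#' @return A `pseaac_config` list.
#' @export
pseaac_config <- function(lambda_ = 5L, weight = 0.05,
                          properties = pseaac_properties()) {
  if (lambda_ < 0) stop("`lambda_` must be >= 0")
  if (weight <= 0) stop("`weight` must be > 0")
  if (!all(AA_ALPHABET %in% rownames(properties))) {
    stop("`properties` must cover all 20 canonical residues")
  }
  structure(list(lambda_ = as.integer(lambda_), weight = weight,
                 properties = properties[AA_ALPHABET, , drop = FALSE]),
            class = "pseaac_config")
}

#' Type-I pseudo amino acid composition
#'
#' Components 1..20 are `f_a / (1 + w * sum(theta))` (normalized residue
#' frequencies); components `20 + k` are `w * theta_k / (1 + w * sum(theta))`
#' where `theta_k` is the mean over positions of the squared property
#' difference correlation at lag k. Output is non-negative and sums to 1.
#'
#' @param seq residue string (or single-row `protein_dataset`).
#' @param cfg a [pseaac_config()].
#' @return Named numeric vector of length `20 + lambda_` (25 by default).
#' @export
pseaac <- function(seq, cfg = pseaac_config()) {
  s <- as_residues(seq)
  n <- nchar(s)
  if (n <= cfg$lambda_) {
    stop("sequence length must exceed lambda_ (lag correlation undefined)")
  }
  idx <- match(strsplit(s, "")[[1]], AA_ALPHABET)
  if (anyNA(idx)) stop("sequence contains non-canonical residues")
  f <- tabulate(idx, nbins = 20L) / n
  P <- cfg$properties  # 20 x p, standardized
  theta <- numeric(cfg$lambda_)
  if (cfg$lambda_ > 0) {
    for (k in seq_len(cfg$lambda_)) {
      d <- P[idx[seq_len(n - k)], , drop = FALSE] -
           P[idx[(k + 1):n], , drop = FALSE]
      theta[k] <- mean(rowMeans(d^2))
    }
  }
  denom <- 1 + cfg$weight * sum(theta)
  out <- c(f / denom, cfg$weight * theta / denom)
  names(out) <- c(paste0("pse_", AA_ALPHABET),
                  if (cfg$lambda_ > 0) paste0("pse_lag", seq_len(cfg$lambda_)))
  out
}

#' Names of the 400 ordered dipeptides, lexicographic
#' @return Character vector `c("AA", "AC", ..., "YY")`.
#' @export
dpc_names <- function() {
  as.vector(t(outer(AA_ALPHABET, AA_ALPHABET, paste0)))
}

#' Dipeptide composition
#'
#' Frequencies of the 400 ordered dipeptides over the `|seq| - 1`
#' overlapping windows of length 2, in lexicographic order; sums to 1.
#'
#' @param seq residue string (length >= 2) or single-row `protein_dataset`.
#' @return Named numeric vector of length 400.
#' @export
dpc <- function(seq) {
  s <- as_residues(seq)
  n <- nchar(s)
  if (n < 2L) stop("sequence must have length >= 2")
  idx <- match(strsplit(s, "")[[1]], AA_ALPHABET)
  if (anyNA(idx)) stop("sequence contains non-canonical residues")
  pair <- 20L * (idx[-n] - 1L) + idx[-1L]
  out <- tabulate(pair, nbins = 400L) / (n - 1L)
  names(out) <- dpc_names()
  out
}

#' Fit a variance-ranked dipeptide feature selector
#'
#' Ranks the 400 dipeptide features by their variance over the training
#' rows (descending, ties broken lexicographically, i.e. by column order)
#' and freezes the top `keep`. The frozen selector is then applied
#' unchanged to validation/test rows.
#'
#' @param train_matrix numeric matrix with 400 columns (training rows only).
#' @param keep number of dipeptide features to retain; default 229.
#' @return A `dpc_selector` with `keep`, `selected_indices` and the
#'   corresponding `selected_names`.
#' @export
fit_dpc_selector <- function(train_matrix, keep = 229L) {
  train_matrix <- as.matrix(train_matrix)
  if (ncol(train_matrix) != 400L) stop("`train_matrix` must have 400 columns")
  if (nrow(train_matrix) < 2L) stop("need at least 2 training rows")
  if (keep < 1L || keep > 400L) stop("`keep` must be in 1..400")
  v <- apply(train_matrix, 2, stats::var)
  ord <- order(-v, seq_along(v))  # descending variance, lexicographic ties
  sel <- sort(ord[seq_len(keep)])
  structure(list(keep = as.integer(keep), selected_indices = sel,
                 selected_names = dpc_names()[sel], fitted = TRUE),
            class = "dpc_selector")
}

#' Apply a frozen dipeptide selector
#' @param selector a [fit_dpc_selector()] result.
#' @param rows numeric matrix (or vector) of 400-dimensional DPC rows.
#' @return Matrix restricted to the selected columns.
#' @export
apply_dpc_selector <- function(selector, rows) {
  stopifnot(inherits(selector, "dpc_selector"), isTRUE(selector$fitted))
  if (is.null(dim(rows))) rows <- matrix(rows, nrow = 1L)
  if (ncol(rows) != 400L) stop("rows must have 400 columns")
  rows[, selector$selected_indices, drop = FALSE]
}

#' Residue embedding backend
#'
#' Pluggable source of per-residue vectors. The offline default
#' (`"trainable"`) is a seeded per-residue lookup table of dimension
#' `token_dim` (128) that is trained jointly with the classifier and never
#' requires a model download; `"table"` wraps a user-supplied per-residue
#' matrix (e.g. rows pooled from a pre-trained 1024-dimensional protein
#' language model, projected downstream).
#'
#' @param name `"trainable"` or `"table"`.
#' @param token_dim per-residue vector width (128 for the trainable
#'   fallback; 1024 for a typical pre-trained backend).
#' @param max_len maximum sequence length L; longer sequences are truncated,
#'   shorter ones zero-padded. Default 512.
#' @param seed seed for the trainable table initialization.
#' @param table for `name = "table"`: a 20 x `token_dim` matrix with rows in
#'   alphabet order.
#' @return An `embedding_backend`.
#' @export
embedding_backend <- function(name = c("trainable", "table"), token_dim = 128L,
                              max_len = 512L, seed = 0L, table = NULL) {
  name <- match.arg(name)
  if (name == "trainable") {
    table <- with_seed(seed, matrix(stats::runif(20L * token_dim, -0.05, 0.05),
                                    nrow = 20L))
  } else {
    if (is.null(table) || nrow(table) != 20L) {
      stop("`table` must be a 20-row per-residue matrix")
    }
    token_dim <- ncol(table)
  }
  rownames(table) <- AA_ALPHABET
  structure(list(name = name, token_dim = as.integer(token_dim),
                 max_len = as.integer(max_len), table = table),
            class = "embedding_backend")
}

#' Integer-encode a residue string
#' @param seq residue string.
#' @param max_len truncate at this length (`NULL` = no truncation).
#' @return Integer vector of 1-based alphabet indices.
#' @export
tokenize <- function(seq, max_len = NULL) {
  s <- as_residues(seq)
  idx <- match(strsplit(s, "")[[1]], AA_ALPHABET)
  if (anyNA(idx)) stop("sequence contains non-canonical residues")
  if (!is.null(max_len) && length(idx) > max_len) idx <- idx[seq_len(max_len)]
  idx
}

#' Per-residue embedding with fixed-length padding
#'
#' Sequences longer than the backend's `max_len` are truncated (first L
#' residues kept); shorter ones are right-padded with zero vectors and mask
#' 0.
#'
#' @param seq residue string or single-row `protein_dataset`.
#' @param backend an [embedding_backend()].
#' @return List with `matrix` (`max_len` x `token_dim`) and binary `mask`
#'   (length `max_len`).
#' @export
embed_tokens <- function(seq, backend) {
  if (!inherits(backend, "embedding_backend")) stop("unknown backend")
  idx <- tokenize(seq, backend$max_len)
  L <- backend$max_len
  m <- matrix(0, nrow = L, ncol = backend$token_dim)
  m[seq_along(idx), ] <- backend$table[idx, , drop = FALSE]
  mask <- c(rep(1L, length(idx)), rep(0L, L - length(idx)))
  list(matrix = m, mask = mask)
}

#' Create a linear embedding projection
#'
#' A linear map `token_dim -> out_dim` applied per position, intended to be
#' trained jointly with the classifier (it becomes the model's `Wp`
#' parameter). `init = "identity"` requires `out_dim == in_dim`.
#'
#' @param in_dim input width.
#' @param out_dim output width (default 128).
#' @param seed seed for Glorot-uniform initialization.
#' @param init `"glorot"` or `"identity"`.
#' @return An `embedding_projection` with a `weights` matrix.
#' @export
make_projection <- function(in_dim, out_dim = 128L, seed = 0L,
                            init = c("glorot", "identity")) {
  init <- match.arg(init)
  W <- if (init == "identity") {
    if (in_dim != out_dim) stop("identity init requires in_dim == out_dim")
    diag(1, in_dim, out_dim)
  } else {
    lim <- sqrt(6 / (in_dim + out_dim))
    with_seed(seed, matrix(stats::runif(in_dim * out_dim, -lim, lim), in_dim))
  }
  structure(list(in_dim = as.integer(in_dim), out_dim = as.integer(out_dim),
                 weights = W),
            class = "embedding_projection")
}

#' Project a per-residue embedding matrix and pool it
#'
#' Applies the linear projection per position and returns the projected
#' matrix together with the mask-weighted mean over unmasked positions.
#'
#' @param matrix `L x in_dim` embedding matrix.
#' @param projection an [make_projection()] result (or `NULL` when the
#'   backend already emits `out_dim`-wide vectors: projection is bypassed).
#' @param mask binary vector of length `L` (1 = real position).
#' @return List with `projected` (`L x out_dim`) and `pooled` (`out_dim`).
#' @export
project_embedding <- function(matrix, projection = NULL,
                              mask = rep(1L, nrow(matrix))) {
  if (length(mask) != nrow(matrix)) stop("mask length must match rows")
  proj <- if (is.null(projection)) matrix else {
    if (ncol(matrix) != projection$in_dim) {
      stop("dimension mismatch: matrix has ", ncol(matrix),
           " columns, projection expects ", projection$in_dim)
    }
    matrix %*% projection$weights
  }
  n_real <- sum(mask)
  pooled <- if (n_real == 0) rep(0, ncol(proj)) else
    colSums(proj * as.numeric(mask)) / n_real
  list(projected = proj, pooled = as.numeric(pooled))
}

#' Fuse the three descriptor blocks into one 382-dimensional vector
#'
#' Fixed slice order: embedding (128), PseAAC (25), DPC (229). Slice ranges
#' are recorded in the `slices` attribute (1-based, inclusive).
#'
#' @param embedding128 pooled embedding slice (length 128 by default).
#' @param pseaac25 PseAAC slice (length 25 by default).
#' @param dpc229 selected DPC slice (length 229 by default).
#' @param dims expected slice lengths, named.
#' @return Numeric vector of class `fused_features` with a `slices`
#'   attribute.
#' @export
fuse <- function(embedding128, pseaac25, dpc229,
                 dims = c(embedding = 128L, pseaac = 25L, dpc = 229L)) {
  got <- c(embedding = length(embedding128), pseaac = length(pseaac25),
           dpc = length(dpc229))
  for (nm in names(dims)) {
    if (got[[nm]] != dims[[nm]]) {
      stop(sprintf("slice '%s' has length %d, expected %d",
                   nm, got[[nm]], dims[[nm]]))
    }
  }
  v <- c(as.numeric(embedding128), as.numeric(pseaac25), as.numeric(dpc229))
  ends <- cumsum(dims)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  slices <- Map(function(s, e) c(start = s, end = e),
                as.integer(starts), as.integer(ends))
  names(slices) <- names(dims)
  structure(v, slices = slices, class = "fused_features")
}

#' Extract a named slice from a fused vector
#' @param x a `fused_features` vector.
#' @param name one of `"embedding"`, `"pseaac"`, `"dpc"`.
#' @return The numeric sub-vector.
#' @export
fused_slice <- function(x, name) {
  sl <- attr(x, "slices")[[name]]
  if (is.null(sl)) stop("unknown slice: ", name)
  unclass(x)[sl["start"]:sl["end"]]
}

#' Fit a z-score normalizer on training rows
#'
#' Per-dimension `z = (x - mu) / sigma` with population standard deviation;
#' constant dimensions (`sigma = 0`) map to 0. Fit on the training split
#' only, then applied frozen to validation/test rows.
#'
#' @param train_rows numeric matrix (training rows only).
#' @return A `normalizer` with `mu`, `sigma`, `fitted`.
#' @export
fit_normalizer <- function(train_rows) {
  train_rows <- as.matrix(train_rows)
  mu <- colMeans(train_rows)
  sigma <- sqrt(colMeans(sweep(train_rows, 2, mu)^2))  # population sd
  structure(list(mu = mu, sigma = sigma, fitted = TRUE), class = "normalizer")
}

#' Apply a frozen z-score normalizer
#' @param n a fitted [fit_normalizer()] result.
#' @param rows numeric matrix (or vector) with matching columns.
#' @return Normalized matrix; `sigma = 0` columns are 0.
#' @export
apply_normalizer <- function(n, rows) {
  if (!inherits(n, "normalizer") || !isTRUE(n$fitted)) {
    stop("normalizer must be fitted before applying")
  }
  if (is.null(dim(rows))) rows <- matrix(rows, nrow = 1L)
  if (ncol(rows) != length(n$mu)) stop("column count mismatch")
  z <- sweep(rows, 2, n$mu)
  s <- ifelse(n$sigma == 0, 1, n$sigma)
  z <- sweep(z, 2, s, "/")
  z[, n$sigma == 0] <- 0
  z
}

#' Persist a selector or normalizer as JSON
#' @param x a `dpc_selector` or `normalizer`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_transform <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
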