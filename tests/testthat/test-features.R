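test_that("pseaac has the documented dimension, support and normalization", {
  s <- random_residues(1, 50, seed = 2)
  v <- pseaac(s)
  expect_length(v, 25L)
  expect_true(all(v >= 0))
  expect_equal(sum(v), 1, tolerance = 1e-9)

  # homopolymer: all property differences vanish, vector collapses to AAC
  vh <- pseaac("AAAAAAAAAA")
  expect_equal(unname(vh[1]), 1)        # residue A
  expect_equal(unname(vh[-1]), rep(0, 24))

  expect_error(pseaac("ACDEF", pseaac_config(lambda_ = 5)), "lambda")
  # lag terms respond to sequence order, not only composition
  v1 <- pseaac("ACACACACAC")
  v2 <- pseaac("AAAAACCCCC")
  expect_false(isTRUE(all.equal(v1[21:25], v2[21:25])))
})

test_that("pseaac matches a hand computation on a two-residue alphabet", {
  cfg <- pseaac_config(lambda_ = 2, weight = 0.1)
  s <- "ACA"
  P <- cfg$properties
  th1 <- mean(c(mean((P["A", ] - P["C", ])^2), mean((P["C", ] - P["A", ])^2)))
  th2 <- mean(mean((P["A", ] - P["A", ])^2))
  denom <- 1 + 0.1 * (th1 + th2)
  v <- pseaac(s, cfg)
  expect_length(v, 22L)
  expect_equal(unname(v[1]), (2 / 3) / denom)     # freq of A
  expect_equal(unname(v[2]), (1 / 3) / denom)     # freq of C
  expect_equal(unname(v[21]), 0.1 * th1 / denom)
  expect_equal(unname(v[22]), 0.1 * th2 / denom)
})

test_that("dpc enumerates overlapping dipeptides and normalizes", {
  v <- dpc("AA")
  expect_equal(unname(v["AA"]), 1)
  expect_equal(sum(v), 1)

  v <- dpc("ACA")
  expect_equal(unname(v[c("AC", "CA")]), c(0.5, 0.5))

  v <- dpc("ACDEACDE")
  expect_equal(unname(v[c("AC", "CD", "DE", "EA")]), c(2, 2, 2, 1) / 7)
  expect_equal(sum(v), 1)
  expect_error(dpc("A"), "length >= 2")
})

test_that("dpc selector ranks by variance with lexicographic ties", {
  # only three dipeptides vary
  m <- matrix(0.001, nrow = 6, ncol = 400)
  vary <- c(5L, 17L, 390L)
  set.seed(3)
  m[, vary] <- matrix(runif(18), 6)
  sel <- fit_dpc_selector(m, keep = 3)
  expect_setequal(sel$selected_indices, vary)

  # constant matrix: all ties -> first columns lexicographically
  sel0 <- fit_dpc_selector(matrix(1, 4, 400), keep = 2)
  expect_equal(sel0$selected_indices, c(1L, 2L))
  expect_equal(sel0$selected_names, c("AA", "AC"))

  # seeded random matrix vs an independent variance-sort oracle
  set.seed(9)
  m <- matrix(runif(50 * 400), 50)
  sel <- fit_dpc_selector(m, keep = 229)
  v <- apply(m, 2, function(col) sum((col - mean(col))^2) / (length(col) - 1))
  oracle <- sort(order(v, decreasing = TRUE)[1:229])
  expect_equal(sel$selected_indices, oracle)

  # frozen application ignores non-selected columns
  rows <- matrix(seq_len(800) / 800, 2)
  expect_equal(apply_dpc_selector(sel, rows),
               rows[, sel$selected_indices])
  expect_error(fit_dpc_selector(m, keep = 401), "1..400")
})

test_that("embed_tokens pads, truncates and masks per contract", {
  be <- embedding_backend("trainable", token_dim = 8, max_len = 16, seed = 1)
  s10 <- random_residues(1, 10, seed = 4)
  out <- embed_tokens(s10, be)
  expect_equal(dim(out$matrix), c(16L, 8L))
  expect_equal(out$mask, c(rep(1L, 10), rep(0L, 6)))
  expect_true(all(out$matrix[11:16, ] == 0))

  s16 <- random_residues(1, 16, seed = 5)
  expect_equal(embed_tokens(s16, be)$mask, rep(1L, 16))

  s66 <- random_residues(1, 66, seed = 6)
  out <- embed_tokens(s66, be)
  expect_equal(out$mask, rep(1L, 16))  # truncated to L, first L kept
  expect_equal(out$matrix[1, ],
               unname(be$table[substr(s66, 1, 1), ]))
  expect_error(embed_tokens(s10, list()), "unknown backend")
})

test_that("project_embedding: identity, zeros, and pooled-mean oracle", {
  X <- matrix(rnorm(12 * 6), 12)
  idp <- make_projection(6, 6, init = "identity")
  out <- project_embedding(X, idp)
  expect_equal(out$projected, X)

  z <- project_embedding(X * 0, make_projection(6, 4, seed = 2))
  expect_equal(z$pooled, rep(0, 4))
  expect_true(all(z$projected == 0))

  pr <- make_projection(6, 4, seed = 3)
  mask <- c(rep(1, 7), rep(0, 5))
  out <- project_embedding(X, pr, mask = mask)
  ref <- colMeans((X %*% pr$weights)[1:7, ])  # brute-force recomputation
  expect_equal(out$pooled, unname(ref))
  expect_error(project_embedding(X, make_projection(5, 4)), "mismatch")
})

test_that("fuse concatenates in fixed order with recorded slices", {
  f <- fuse(rep(1, 128), rep(2, 25), rep(3, 229))
  expect_length(f, 382L)
  expect_equal(attr(f, "slices")$pseaac, c(start = 129L, end = 153L))
  expect_equal(fused_slice(f, "pseaac"), rep(2, 25))
  expect_equal(fused_slice(f, "embedding"), rep(1, 128))
  expect_equal(fused_slice(f, "dpc"), rep(3, 229))
  expect_equal(sum(fuse(rep(0, 128), rep(0, 25), rep(0, 229))), 0)
  expect_error(fuse(rep(1, 127), rep(2, 25), rep(3, 229)), "embedding")
})

test_that("z-score normalizer follows Eq-style definition with sigma=0 rule", {
  n <- fit_normalizer(matrix(c(0, 2), 2, 1))
  expect_equal(as.numeric(n$mu), 1)
  expect_equal(as.numeric(n$sigma), 1)  # population sd
  expect_equal(as.numeric(apply_normalizer(n, matrix(c(0, 2), 2, 1))),
               c(-1, 1))

  # constant column maps to zero
  m <- cbind(rep(4, 5), rnorm(5))
  n <- fit_normalizer(m)
  z <- apply_normalizer(n, m)
  expect_true(all(z[, 1] == 0))
  expect_equal(mean(z[, 2]), 0, tolerance = 1e-9)
  expect_equal(mean(z[, 2]^2), 1, tolerance = 1e-9)

  un <- structure(list(fitted = FALSE), class = "normalizer")
  expect_error(apply_normalizer(un, m), "fitted")
})

test_that("descriptor invariants hold over random sequences", {
  set.seed(31)
  for (trial in 1:10) {
    s <- random_residues(1, sample(10:80, 1), seed = trial + 50)
    pv <- pseaac(s)
    dv <- dpc(s)
    expect_true(all(pv >= 0) && abs(sum(pv) - 1) < 1e-9)
    expect_true(all(dv >= 0) && abs(sum(dv) - 1) < 1e-9)
  }
})
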