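test_that("model_spec validates and derives dimensions", {
  spec <- model_spec()
  expect_equal(dense_input_dim(spec), 128L + 382L)
  expect_equal(dense_input_dim(model_spec(use_late_fusion = FALSE)), 128L)
  expect_equal(dense_input_dim(model_spec(use_bilstm = FALSE,
                                          use_late_fusion = FALSE)), 256L)
  expect_error(model_spec(kernel_a = 4), "odd")
  expect_error(model_spec(dropout = 1), "dropout")
  expect_warning(model_spec(kernel_a = 3, kernel_b = 3), "degenerate")
  expect_error(model_spec(use_branch_a = FALSE, use_branch_b = FALSE,
                          use_bilstm = FALSE), "at least one")
})

test_that("initialization is seed-deterministic and counted exactly", {
  m1 <- build_model(model_spec(), seed = 5)
  m2 <- build_model(model_spec(), seed = 5)
  expect_identical(m1$params, m2$params)   # bit-identical
  m3 <- build_model(model_spec(), seed = 6)
  expect_false(identical(m3$params$Wa, m1$params$Wa))

  # conv branch k=3, in 128, filters 128 -> 3*128*128 + 128 = 49,280
  expect_equal(length(m1$params$Wa) + length(m1$params$ba), 49280L)
  expect_equal(count_parameters(m1), count_parameters(m2))
  expect_equal(count_parameters(m1),
               sum(vapply(m1$params, length, integer(1))))
})

test_that("all-zero parameters give the symmetric softmax output", {
  spec <- tiny_spec()
  m <- build_model(spec, seed = 1)
  m$params <- lapply(m$params, function(x) x * 0)
  d <- tiny_data(3, spec, seed = 2)
  p <- model_forward(m, d$tokens, d$fused)
  expect_equal(unname(p), matrix(0.5, 3, 2))
})

test_that("forward pass matches the direct-loop stage oracle", {
  # several variants, random small tensors, tolerance 1e-5
  variants <- list(
    tiny_spec(),
    tiny_spec(use_bilstm = FALSE),
    tiny_spec(use_branch_b = FALSE),
    tiny_spec(use_branch_a = FALSE, use_branch_b = FALSE),
    tiny_spec(use_late_fusion = FALSE))
  for (vi in seq_along(variants)) {
    spec <- variants[[vi]]
    m <- build_model(spec, seed = vi)
    d <- tiny_data(4, spec, seed = vi + 10)
    got <- model_forward(m, d$tokens, d$fused)
    for (i in 1:4) {
      ref <- ref_forward(m, d$tokens[[i]],
                         if (is.null(d$fused)) NULL else d$fused[i, ])
      expect_equal(unname(got[i, ]), ref, tolerance = 1e-5,
                   info = sprintf("variant %d seq %d", vi, i))
    }
  }
})

test_that("single zero LSTM step gives sigmoid(0) gates and zero state", {
  # hand evaluation of the gate equations at W = U = b = 0
  Z <- matrix(rnorm(4), 1)
  H <- 3
  Hs <- ref_lstm(Z, matrix(0, 4, 4 * H), matrix(0, H, 4 * H), rep(0, 4 * H))
  # i = f = o = 0.5, c~ = tanh(0) = 0 => c = 0, h = 0
  expect_equal(as.numeric(Hs), rep(0, H))
})

test_that("intermediate shapes follow the stated padding and pooling rules", {
  spec <- model_spec()   # full-size: 100 x 128 -> 50 x 256 -> 50 x 128 -> 128
  m <- build_model(spec, seed = 0)
  X <- m$params$emb[sample(1:20, 100, replace = TRUE), ]
  A <- ref_conv_same(X[, 1:4, drop = FALSE], matrix(rnorm(12 * 7), 12), rep(0, 7), 3)
  expect_equal(dim(A), c(100L, 7L))                 # "same" padding keeps T
  expect_equal(dim(ref_maxpool2(A)), c(50L, 7L))    # floor(T/2)
  # via the real model: probabilities defined, so the chain is consistent
  fu <- matrix(rnorm(382), 1)
  p <- model_forward(m, list(sample(1:20, 100, replace = TRUE)), fu)
  expect_equal(dim(p), c(1L, 2L))
})

test_that("softmax rows sum to 1 and inference is deterministic", {
  spec <- tiny_spec()
  m <- build_model(spec, seed = 3)
  d <- tiny_data(6, spec, seed = 4)
  p1 <- model_forward(m, d$tokens, d$fused)
  p2 <- model_forward(m, d$tokens, d$fused)
  expect_identical(p1, p2)      # dropout off at inference
  expect_equal(rowSums(p1), rep(1, 6), tolerance = 1e-6)
  expect_true(all(p1 > 0 & p1 < 1))
})

test_that("training-mode gradients match finite differences", {
  spec <- tiny_spec()  # dropout 0 so the loss is deterministic
  m <- build_model(spec, seed = 2)
  pp <- seqfuse:::params_for_cpp(m$params)
  cs <- seqfuse:::spec_for_cpp(spec)
  d <- tiny_data(2, spec, seed = 9)
  g <- seqfuse:::cpp_batch_grad(pp, cs, d$tokens, d$fused, d$labels, 1L)
  loss_at <- function(p) {
    seqfuse:::cpp_batch_grad(p, cs, d$tokens, d$fused, d$labels, 1L)$loss
  }
  set.seed(41)
  for (nm in names(g$grads)) {
    for (rep in 1:2) {
      i <- sample(length(g$grads[[nm]]), 1)
      h <- 1e-6
      p2 <- pp; p2[[nm]][i] <- p2[[nm]][i] + h; up <- loss_at(p2)
      p2[[nm]][i] <- p2[[nm]][i] - 2 * h; dn <- loss_at(p2)
      num <- (up - dn) / (2 * h)
      ana <- g$grads[[nm]][i]
      expect_lt(abs(ana - num) / max(1e-8, abs(ana) + abs(num)), 1e-4)
    }
  }
})

test_that("padded positions cannot influence any pooled output", {
  # mask-aware pooling: perturbing padded rows leaves results unchanged
  be <- embedding_backend("trainable", token_dim = 6, max_len = 20, seed = 0)
  s <- random_residues(1, 11, seed = 8)
  emb <- embed_tokens(s, be)
  pooled1 <- project_embedding(emb$matrix, NULL, emb$mask)$pooled
  perturbed <- emb$matrix
  perturbed[12:20, ] <- matrix(rnorm(9 * 6), 9)  # garbage in padding
  pooled2 <- project_embedding(perturbed, NULL, emb$mask)$pooled
  expect_identical(pooled1, pooled2)

  # the network consumes true-length streams, so padding never reaches it:
  # a padded matrix and its mask reduce to exactly the unpadded tokens
  tk <- tokenize(s, be$max_len)
  expect_equal(emb$matrix[seq_len(sum(emb$mask)), ],
               unname(be$table[tk, ]))
})
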