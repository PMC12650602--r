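test_that("positional encoding evaluates the sinusoidal closed form", {
  pe <- positional_encoding(188, 128)
  expect_equal(dim(pe), c(188L, 128L))
  expect_true(all(pe[1, seq(1, 127, by = 2)] == 0))  # sin(0)
  expect_true(all(pe[1, seq(2, 128, by = 2)] == 1))  # cos(0)
  expect_equal(pe[2, 1], sin(1), tolerance = 1e-5)
  expect_equal(pe[2, 2], cos(1), tolerance = 1e-9)
  i <- 3  # dimension pair index 3 -> angle pos / 10000^(6/128)
  expect_equal(pe[5, 2 * i + 1], sin(4 / 10000^(2 * i / 128)),
               tolerance = 1e-9)
  expect_true(all(pe >= -1 & pe <= 1))
  expect_error(positional_encoding(10, 127), "even")
})

test_that("attention matches a brute-force evaluation of the scaled dot product", {
  set.seed(41)
  for (i in 1:10) {
    Q <- matrix(rnorm(12), 3, 4)
    K <- matrix(rnorm(12), 3, 4)
    V <- matrix(rnorm(12), 3, 4)
    expect_equal(attention(Q, K, V), attention_oracle(Q, K, V),
                 tolerance = 1e-6)
  }
  # sequence length 1: softmax of a scalar is 1, output is V
  q1 <- matrix(rnorm(4), 1, 4)
  v1 <- matrix(rnorm(4), 1, 4)
  expect_equal(attention(q1, matrix(rnorm(4), 1, 4), v1), v1)
  # zero queries: uniform attention, output = column means of V
  Z <- matrix(0, 3, 4)
  K <- matrix(rnorm(12), 3, 4); V <- matrix(rnorm(12), 3, 4)
  out <- attention(Z, K, V)
  expect_equal(out[1, ], colMeans(V))
  expect_equal(out[2, ], colMeans(V))
  expect_error(attention(matrix(NaN, 2, 2), matrix(0, 2, 2),
                         matrix(0, 2, 2)), "finite")
})

test_that("attention rows sum to one", {
  set.seed(42)
  Q <- matrix(rnorm(40), 10, 4); K <- matrix(rnorm(40), 10, 4)
  s <- Q %*% t(K) / sqrt(4)
  p <- exp(s - apply(s, 1, max)); p <- p / rowSums(p)
  expect_equal(rowSums(p), rep(1, 10), tolerance = 1e-12)
  # identity V exposes the row-stochastic weights through attention()
  expect_equal(rowSums(attention(Q, K, diag(10) %*% matrix(1, 10, 1))),
               rep(1, 10), tolerance = 1e-9)
})

test_that("residual blocks reproduce the configured shape contract", {
  m <- fix_model()
  x <- array(rnorm(2 * 64 * 188), c(2, 64, 188))
  y1 <- residual_block_forward(m, x, 1)
  expect_equal(dim(y1), c(2L, 64L, 188L))
  y2 <- residual_block_forward(m, x, 2)
  expect_equal(dim(y2), c(2L, 128L, 94L))
  y3 <- residual_block_forward(m, y2, 3)
  expect_equal(dim(y3), c(2L, 256L, 94L))
  expect_error(residual_block_forward(m, x, 3), "channels")
})

test_that("zeroing the residual transform leaves ReLU of the identity skip", {
  m <- fix_model()
  for (nm in c("res1.conv1.W", "res1.conv1.b", "res1.conv2.W", "res1.conv2.b")) {
    m$params[[nm]][] <- 0
  }
  x <- array(rnorm(2 * 64 * 188), c(2, 64, 188))
  y <- residual_block_forward(m, x, 1)
  expect_equal(y, array(pmax(x, 0), dim(x)), tolerance = 1e-12)
})

test_that("branch features have the configured dimensions and are deterministic", {
  m <- fix_model()
  set.seed(19)
  x <- matrix(rnorm(3 * 188), 3, 188)
  cfeat <- cnn_branch_forward(m, x)
  expect_equal(dim(cfeat), c(3L, 256L))
  expect_identical(cfeat, cnn_branch_forward(m, x))
  # batch equivariance
  perm <- c(3, 1, 2)
  expect_equal(cnn_branch_forward(m, x[perm, ]), cfeat[perm, ],
               tolerance = 1e-12)
  tfeat <- transformer_branch_forward(m, x)
  expect_equal(dim(tfeat), c(3L, 128L))
  expect_identical(tfeat, transformer_branch_forward(m, x))
  # identity-attention hook isolates the FFN path
  tid <- transformer_branch_forward(m, x,
                                    attention_hook = function(Q, K, V) V)
  expect_equal(dim(tid), c(3L, 128L))
  expect_false(isTRUE(all.equal(tid, tfeat)))
  expect_error(cnn_branch_forward(m, x[, 1:100]), "188")
})

test_that("the fusion gate is an open-interval convex combination", {
  m <- fix_model()
  set.seed(23)
  x <- matrix(rnorm(4 * 188), 4, 188)
  cfeat <- cnn_branch_forward(m, x)
  tfeat <- transformer_branch_forward(m, x)
  fus <- gated_fusion(m, cfeat, tfeat)
  expect_true(all(fus$g > 0 & fus$g < 1))
  expect_equal(fus$f, fus$g * fus$c_tilde + (1 - fus$g) * fus$t_tilde,
               tolerance = 1e-12)
  lo <- pmin(fus$c_tilde, fus$t_tilde); hi <- pmax(fus$c_tilde, fus$t_tilde)
  expect_true(all(fus$f >= lo - 1e-9 & fus$f <= hi + 1e-9))
  # gate hooks
  f1 <- gated_fusion(m, cfeat, tfeat, g_override = 1)
  expect_equal(f1$f, f1$c_tilde)
  f0 <- gated_fusion(m, cfeat, tfeat, g_override = 0)
  expect_equal(f0$f, f0$t_tilde)
})

test_that("the softmax head normalizes logits exactly as exp-normalization", {
  m <- fix_model()
  # force z = b2 by zeroing the output weights
  m$params[["clf2.W"]][] <- 0
  m$params[["clf2.b"]] <- rep(0, 5)
  out <- classify(m, matrix(rnorm(2 * 256), 2, 256))
  expect_equal(out$probabilities, matrix(0.2, 2, 5), ignore_attr = TRUE)
  expect_equal(as.character(out$predicted_class), c("N", "N"))  # tie -> lowest
  m$params[["clf2.b"]] <- c(3, 1, 0, 0, 0)
  out2 <- classify(m, matrix(rnorm(256), 1, 256))
  expect_equal(out2$probabilities[1, ],
               exp(c(3, 1, 0, 0, 0)) / sum(exp(c(3, 1, 0, 0, 0))),
               tolerance = 1e-9, ignore_attr = TRUE)
  # shift invariance
  m$params[["clf2.b"]] <- c(3, 1, 0, 0, 0) + 7
  out3 <- classify(m, matrix(rnorm(256), 1, 256))
  expect_equal(out3$probabilities, out2$probabilities, tolerance = 1e-9)
  expect_error(classify(m, matrix(Inf, 1, 256)), "finite")
})

test_that("all variants produce finite simplex outputs on the same batch", {
  set.seed(29)
  x <- matrix(rnorm(2 * 188), 2, 188)
  for (v in c("full", "cnn_only", "transformer_only", "concat_no_gate")) {
    mod <- hctg_model(model_config(variant = v), seed = 11)
    p <- forward(mod, x)
    expect_equal(dim(p), c(2L, 5L))
    expect_true(all(is.finite(p)))
    expect_equal(rowSums(p), c(1, 1), tolerance = 1e-6)
    expect_identical(p, forward(mod, x))  # evaluation-mode determinism
  }
})

test_that("the CNN-only variant ignores transformer-branch weights entirely", {
  mod <- hctg_model(model_config(variant = "cnn_only"), seed = 11)
  set.seed(31)
  x <- matrix(rnorm(2 * 188), 2, 188)
  p1 <- forward(mod, x)
  mod$params[["tr1.Wq.W"]] <- matrix(rnorm(128 * 128), 128, 128)
  mod$params[["embed.W"]] <- matrix(rnorm(128), 128, 1)
  expect_identical(forward(mod, x), p1)
})

test_that("the fast engine and the reference path agree", {
  set.seed(37)
  x <- matrix(rnorm(4 * 188), 4, 188)
  for (v in c("full", "cnn_only", "transformer_only", "concat_no_gate")) {
    mod <- hctg_model(model_config(variant = v), seed = 13)
    p_ref <- forward(mod, x, engine = "reference")
    p_fast <- forward(mod, x, engine = "fast")
    expect_lt(max(abs(p_ref - p_fast)), 1e-4)
  }
})

test_that("engine gradients match finite differences of the engine loss", {
  mod <- hctg_model(model_config(), seed = 3)
  set.seed(43)
  B <- 4
  x <- matrix(rnorm(B * 188), B, 188)
  y <- sample(0:4, B, replace = TRUE)
  run <- function(params) {
    hctgnet:::cpp_hctg_train_batch(params, mod$state, mod$pe, x, y, 0L, 2L,
                                   4L, 0, 0, 1L, 0.1)
  }
  res <- run(mod$params)
  for (nm in c("stem.W", "res3.conv2.W", "tr1.Wq.W", "tr2.ffn1.W",
               "fus.gate1.W", "clf1.W", "embed.W")) {
    gr <- res$grads[[nm]]
    i <- which.max(abs(gr))
    h <- 1e-3
    pp <- mod$params; pp[[nm]][i] <- pp[[nm]][i] + h
    pm <- mod$params; pm[[nm]][i] <- pm[[nm]][i] - h
    fd <- (run(pp)$loss - run(pm)$loss) / (2 * h)
    expect_equal(gr[i], fd, tolerance = 0.05)
  }
})

test_that("configuration invariants are enforced", {
  expect_error(model_config(d_model = 100, n_heads = 3), "divisible")
  expect_error(model_config(variant = "bogus"))
  expect_error(forward(fix_model(), matrix(0, 1, 100)), "188")
})
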