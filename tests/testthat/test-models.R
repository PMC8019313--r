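test_that("compiled forward pass equals the pure-R reference steps", {
  set.seed(42)
  lex <- tiny_lexicon()
  toks <- c("a", "b", "c", "d", "e", "f", "g", "a", "b")
  for (arch in c("rnn", "lstm", "fastweights", "dnc")) {
    set.seed(99)
    m <- tiny_model(arch)
    p_cpp <- drop(model_predict(m, matrix(match(toks, rownames(lex)), 1), lex))
    p_ref <- forward_reference(m, toks, lex)
    expect_equal(p_cpp, p_ref, tolerance = 1e-12, label = arch)
  }
  # and for the tanh fast-weights variant
  set.seed(99)
  m <- tiny_model("fastweights", fw_nonlin = "tanh")
  p_cpp <- drop(model_predict(m, matrix(match(toks, rownames(lex)), 1), lex))
  expect_equal(p_cpp, forward_reference(m, toks, lex), tolerance = 1e-12)
})

test_that("backpropagation matches finite differences for all architectures", {
  set.seed(7)
  lex <- tiny_lexicon()
  X <- matrix(sample(1:8, 3 * 9, replace = TRUE), 3, 9)
  tgt <- sample(1:8, 3)
  for (arch in c("rnn", "lstm", "fastweights", "dnc")) {
    set.seed(123)
    m <- tiny_model(arch)
    lg <- model_loss_grad(m, X, tgt, lex)
    h <- 1e-6
    for (nm in names(m$params)) {
      for (k in sample(length(m$params[[nm]]), min(3, length(m$params[[nm]])))) {
        m2 <- m
        m2$params[[nm]][k] <- m$params[[nm]][k] + h
        lp <- model_loss_grad(m2, X, tgt, lex)$loss
        m2$params[[nm]][k] <- m$params[[nm]][k] - h
        lm_ <- model_loss_grad(m2, X, tgt, lex)$loss
        num <- (lp - lm_) / (2 * h)
        expect_equal(lg$grads[[nm]][k], num, tolerance = 1e-4,
                     label = paste(arch, nm, k))
      }
    }
  }
})

test_that("layer-normalized RNN step has the stated fixed points", {
  set.seed(1)
  m <- tiny_model("rnn")
  # zero weights, zero gain: LayerNorm output is exactly the bias
  m$params$W[] <- 0; m$params$U[] <- 0; m$params$g[] <- 0
  m$params$b[] <- c(0.3, -0.2, 0.1, 0.5, -0.4)
  st <- rnn_step(m, NULL, rnorm(7))
  expect_equal(st$h, tanh(c(0.3, -0.2, 0.1, 0.5, -0.4)))
  # pre-gain LayerNorm output has mean ~0 and variance ~1
  set.seed(2)
  m2 <- tiny_model("rnn", hidden = 50L, dim = 50L)
  m2$params$g[] <- 1; m2$params$b[] <- 0
  st2 <- rnn_step(m2, NULL, rnorm(50))
  z <- atanh(st2$h)
  expect_equal(mean(z), 0, tolerance = 1e-6)
  expect_equal(mean(z^2), 1, tolerance = 1e-3)  # within LayerNorm's epsilon
  expect_error(rnn_step(m, NULL, rnorm(3)), "dimension")
})

test_that("LSTM gates control the cell as specified", {
  set.seed(3)
  m <- tiny_model("lstm")
  # force forget -> 1 and input -> 0 via zero gains and saturated biases
  m$params$g_f[] <- 0; m$params$b_f[] <- 30
  m$params$g_i[] <- 0; m$params$b_i[] <- -30
  st <- list(h = rnorm(5), c = rnorm(5))
  st2 <- lstm_step(m, st, rnorm(7))
  expect_equal(st2$c, st$c, tolerance = 1e-9)
  # bounded output under tanh and sigmoid
  for (i in 1:5) st2 <- lstm_step(m, st2, rnorm(7))
  expect_true(all(abs(st2$h) < 1))
})

test_that("fast-weight matrix follows the outer-product algebra", {
  set.seed(4)
  m <- tiny_model("fastweights", fw_nonlin = "tanh")
  h <- rnorm(5)
  # lambda = 0, eta = 1: stored pattern is an eigenvector with ||h||^2
  m$cfg$lambda <- 0; m$cfg$eta <- 1
  st <- list(h = h, A = matrix(rnorm(25), 5, 5))
  st2 <- fastweights_step(m, st, rnorm(7))
  expect_equal(drop(st2$A %*% h), sum(h^2) * h, tolerance = 1e-9)
  # lambda = 1, eta = 0: A constant
  m$cfg$lambda <- 1; m$cfg$eta <- 0
  A0 <- matrix(rnorm(25), 5, 5)
  st3 <- fastweights_step(m, list(h = h, A = A0), rnorm(7))
  expect_equal(st3$A, A0)
  # two orthogonal unit patterns at lambda = eta = 1: A h1 = h1
  m$cfg$lambda <- 1; m$cfg$eta <- 1
  h1 <- c(1, 0, 0, 0, 0); h2 <- c(0, 1, 0, 0, 0)
  st4 <- list(h = h1, A = matrix(0, 5, 5))
  st4 <- fastweights_step(m, st4, rnorm(7))   # stores h1
  st4$h <- h2
  st4 <- fastweights_step(m, st4, rnorm(7))   # stores h2
  expect_equal(drop(st4$A %*% h1), h1, tolerance = 1e-9)
})

test_that("fast-weight norm is bounded for lambda < 1 with tanh states", {
  set.seed(5)
  m <- tiny_model("fastweights", fw_nonlin = "tanh")
  st <- NULL
  maxh2 <- 0
  for (t in 1:50) {
    st <- fastweights_step(m, st, rnorm(7))
    maxh2 <- max(maxh2, sum(st$h^2))
  }
  bound <- m$cfg$eta * maxh2 / (1 - m$cfg$lambda)
  expect_lte(norm(st$A, "2"), bound + 1e-9)
})

test_that("DNC erase/add and content addressing act on single slots", {
  set.seed(6)
  m <- tiny_model("dnc")   # 6 slots x 4 word size
  W <- 4
  M <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0),
             c(0, 0, 0, 1), c(1, 1, 0, 0) / sqrt(2), c(0, 0, 1, 1) / sqrt(2))
  st <- list(h = numeric(5), c = numeric(5), M = M, u = rep(0.5, 6),
             p = numeric(6), link = matrix(0, 6, 6),
             w_r = numeric(6), w_w = numeric(6), r = numeric(4))
  # drive the interface directly: zero Wi, craft bi
  m$params$Wi[] <- 0
  bi <- numeric(nrow(m$params$bi))
  q <- 0
  bi[(q + 1):(q + W)] <- M[3, ] * 3; q <- q + W      # read key -> slot 3
  bi[q + 1] <- 40; q <- q + 1                        # sharp read strength
  bi[(q + 1):(q + W)] <- M[2, ] * 3; q <- q + W      # write key -> slot 2
  bi[q + 1] <- 40; q <- q + 1                        # sharp write strength
  bi[(q + 1):(q + W)] <- 40; q <- q + W              # erase ~ 1
  bi[(q + 1):(q + W)] <- c(9, 8, 7, 6); q <- q + W   # add vector
  bi[q + 1] <- -40                                   # free gate ~ 0
  bi[q + 2] <- -40                                   # allocation gate ~ 0 (content)
  bi[q + 3] <- 40                                    # write gate ~ 1
  bi[(q + 4):(q + 6)] <- c(-40, 40, -40)             # read mode: content
  m$params$bi[] <- bi
  st2 <- dnc_step(m, st, rnorm(7))
  # content write with sharp strength concentrates on the matching slot
  expect_gt(st2$w_w[2], 0.99)
  expect_equal(st2$M[2, ], c(9, 8, 7, 6), tolerance = 0.2)
  expect_equal(st2$M[1, ], M[1, ], tolerance = 1e-6)  # other slots untouched
  # content read returns the addressed row
  expect_gt(st2$w_r[3], 0.99)
  expect_equal(st2$r, M[3, ], tolerance = 0.05)
})

test_that("DNC read/write weightings stay on the non-negative simplex", {
  set.seed(8)
  m <- tiny_model("dnc")
  lex <- tiny_lexicon()
  st <- NULL
  for (t in 1:12) {
    st <- dnc_step(m, st, lex[sample(8, 1), ])
    expect_true(all(st$w_r >= -1e-12))
    expect_true(all(st$w_w >= -1e-12))
    expect_lte(sum(st$w_r), 1 + 1e-9)
    expect_lte(sum(st$w_w), 1 + 1e-9)
    expect_true(all(st$u >= -1e-12 & st$u <= 1 + 1e-12))
  }
})

test_that("forward pass is deterministic and traces cover every token", {
  set.seed(9)
  lex <- tiny_lexicon()
  toks <- c("a", "c", "e", "g", "b", "d")
  for (arch in c("rnn", "lstm", "fastweights", "dnc")) {
    set.seed(50)
    m <- tiny_model(arch)
    tr1 <- model_trace(m, toks, lex)
    tr2 <- model_trace(m, toks, lex)
    expect_identical(tr1$prediction, tr2$prediction)
    expect_equal(nrow(tr1$hidden), length(toks))
    if (arch == "fastweights") expect_equal(ncol(tr1$memory), 25)  # 5x5
    if (arch == "dnc") {
      expect_equal(ncol(tr1$memory), 24)  # 6 slots x 4
      expect_equal(nrow(tr1$read_weights), length(toks))
    }
  }
  expect_error(model_trace(tiny_model("rnn"), c("a", "zz"), lex), "unknown")
})

test_that("an untrained model retrieves at about the corpus chance rate", {
  set.seed(10)
  vocab <- sprintf("w%02d", 1:40)
  lex <- build_lexicon(vocab, dim = 20)
  m <- binding_model("rnn", hidden = 10, input_dim = 20, output_dim = 20)
  corpus <- build_corpus(lex)
  X <- matrix(sample(40, 200 * 6, replace = TRUE), 200, 6)
  preds <- model_predict(m, X, lex)
  got <- apply(preds, 1, nearest_word, corpus = corpus)
  tgt <- vocab[X[, 6]]
  acc <- mean(got == tgt)
  # chance = 1/40; untrained accuracy within Monte-Carlo error of it
  expect_lt(acc, 1 / 40 + 3 * sqrt((1 / 40) * (39 / 40) / 200) + 0.02)
})

test_that("one optimizer step decreases the loss on a small batch", {
  set.seed(12)
  lex <- tiny_lexicon()
  X <- matrix(sample(1:8, 2 * 6, replace = TRUE), 2, 6)
  tgt <- c(3L, 5L)
  for (arch in c("rnn", "lstm", "fastweights", "dnc")) {
    set.seed(60)
    m <- tiny_model(arch)
    before <- model_loss_grad(m, X, tgt, lex)$loss
    res <- schemabind:::sb_train_cpp(m$architecture, m$params, m$opt,
                                     X - 1L, tgt - 1L, lex, m$cfg, 1e-3, 2L, 3L,
                                     matrix(0L, 0, 0), 0L)
    m$params <- res$params
    after <- model_loss_grad(m, X, tgt, lex)$loss
    expect_lt(after, before, label = arch)
  }
})
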