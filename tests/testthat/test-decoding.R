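test_that("decoding sets share one frame and traces cover every token", {
  set.seed(22)
  dset <- build_decoding_set(n = 12, dim = 10)
  expect_length(dset$stories, 12)
  frame_text <- lapply(dset$stories, function(s) {
    toks <- s$tokens
    toks[!toks %in% unlist(s$binding)]
  })
  for (i in 2:12) expect_equal(frame_text[[i]], frame_text[[1]])
  bindings <- vapply(dset$stories, function(s) s$binding$Poet, character(1))
  expect_equal(anyDuplicated(bindings), 0L)

  m <- binding_model("fastweights", hidden = 50, input_dim = 10, output_dim = 10)
  tr <- record_traces(m, dset)
  L <- length(dset$stories[[1]]$tokens)
  expect_equal(dim(tr$hidden), c(12, L, 50))
  expect_equal(dim(tr$memory), c(12, L, 2500))   # 50 x 50 flattened

  set.seed(23)
  m2 <- binding_model("dnc", hidden = 10, input_dim = 10, output_dim = 10)
  tr2 <- record_traces(m2, build_decoding_set(n = 2, dim = 10))
  expect_equal(dim(tr2$memory)[3], 2560)         # 128 x 20 flattened
})

test_that("kernel-form ridge equals the primal solution and handles limits", {
  set.seed(24)
  n <- 15; p <- 40; alpha <- 1.0
  X <- matrix(rnorm(n * p), n, p)
  Y <- matrix(rnorm(n * 3), n, 3)
  xbar <- colMeans(X); ybar <- colMeans(Y)
  Xc <- sweep(X, 2, xbar); Yc <- sweep(Y, 2, ybar)
  # primal ridge on centered data
  W_primal <- solve(crossprod(Xc) + alpha * diag(p), crossprod(Xc, Yc))
  # package path: build a bank through the kernel form
  K <- tcrossprod(Xc); diag(K) <- diag(K) + alpha
  R <- chol(K)
  W_dual <- crossprod(Xc, backsolve(R, forwardsolve(t(R), Yc)))
  expect_equal(W_dual, W_primal, tolerance = 1e-8)

  # scalar case: (x'x + alpha)^-1 x'y computed by hand (no centering)
  x <- c(1, 2, 3); y <- c(2, 4, 7)
  expect_equal(sum(x * y) / (sum(x^2) + alpha),
               drop(solve(crossprod(x) + alpha, crossprod(x, y))))
})

test_that("decoder bank predicts constants exactly and shrinks under alpha", {
  set.seed(25)
  dset <- build_decoding_set(n = 20, dim = 8)
  m <- binding_model("rnn", hidden = 6, input_dim = 8, output_dim = 8)
  tr <- record_traces(m, dset)
  # identical targets across sequences -> decoder returns that constant
  const <- dset$lexicon[dset$stories[[1]]$binding$Poet, ]
  for (i in seq_along(dset$stories)) {
    dset$lexicon[dset$stories[[i]]$binding$Poet, ] <- const
  }
  bank <- fit_decoders(tr, dset, alpha = 1.0, n_train = 16)
  dec <- bank$bank$hidden[[3]][["Poet"]]
  pred <- schemabind:::decode_predict(dec, matrix(tr$hidden[17:20, 3, ], nrow = 4))
  expect_equal(pred, matrix(const, 4, 8, byrow = TRUE), tolerance = 1e-6)

  # very large alpha shrinks held-out predictions to the train mean
  set.seed(26)
  dset2 <- build_decoding_set(n = 20, dim = 8)
  tr2 <- record_traces(m, dset2)
  bank_big <- fit_decoders(tr2, dset2, alpha = 1e9, n_train = 16)
  dec_big <- bank_big$bank$hidden[[3]][["Friend"]]
  pred_big <- schemabind:::decode_predict(dec_big,
                                          matrix(tr2$hidden[17:20, 3, ], nrow = 4))
  expect_equal(pred_big, matrix(dec_big$ybar, 4, 8, byrow = TRUE),
               tolerance = 1e-4)
})

test_that("ridge fitting is deterministic and untrained scores sit at chance", {
  set.seed(27)
  dset <- build_decoding_set(n = 40, dim = 12)
  m <- binding_model("rnn", hidden = 10, input_dim = 12, output_dim = 12)
  tr <- record_traces(m, dset)
  bank1 <- fit_decoders(tr, dset, n_train = 32)
  bank2 <- fit_decoders(tr, dset, n_train = 32)
  expect_identical(bank1$bank$hidden[[5]][["Poet"]]$W,
                   bank2$bank$hidden[[5]][["Poet"]]$W)

  # decoding a filler from activity before it appears: chance (0.5)
  curve <- decoding_curve(bank1, tr, dset)
  early <- curve[curve$timestep == 1 & curve$role != "Subject", ]
  expect_lt(mean(abs(early$score - 0.5)), 0.15)
  expect_true(all(curve$score >= 0 & curve$score <= 1))
})

test_that("read/write-location analysis recovers hand-built strategies", {
  # role always written to slot 7 and read back at its query: point masses
  mk_story <- function(filler, qrole) {
    structure(list(tokens = c("kw", filler, "pad", query_token(qrole)),
                   query = query_token(qrole), target = filler,
                   binding = setNames(list(filler), "Poet"),
                   frame = "t"), class = "story_instance")
  }
  mk_trace <- function(wslot, rslot, L = 4, N = 10) {
    w <- matrix(0, L, N); r <- matrix(0, L, N)
    w[2, wslot] <- 1   # filler timestep
    r[L, rslot] <- 1   # query timestep
    list(write_weights = w, read_weights = r)
  }
  stories <- lapply(1:5, function(i) mk_story(paste0("f", i), "Poet"))
  traces <- lapply(1:5, function(i) mk_trace(7, 7))
  res <- dnc_rw_analysis(stories, traces, roles = "Poet")
  expect_equal(which.max(res$write_hist["Poet", ]), 7)
  expect_equal(unname(res$write_hist["Poet", 7]), 5)
  expect_equal(unname(res$read_hist["Poet", 7]), 5)
  expect_equal(res$correlation["Poet", "Poet"], 1)

  # consistent slot relabeling leaves the correlation matrix unchanged
  stories2 <- c(stories, lapply(6:9, function(i) mk_story(paste0("f", i), "Poet")))
  traces2 <- c(lapply(1:5, function(i) mk_trace(3, 3)),
               lapply(6:9, function(i) mk_trace(8, 8)))
  set.seed(28)
  perm <- sample(10)
  traces2_perm <- lapply(traces2, function(tr) {
    list(write_weights = tr$write_weights[, perm],
         read_weights = tr$read_weights[, perm])
  })
  r1 <- dnc_rw_analysis(stories2, traces2, roles = "Poet")
  r2 <- dnc_rw_analysis(stories2, traces2_perm, roles = "Poet")
  expect_equal(r1$correlation, r2$correlation, tolerance = 1e-12)
})
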