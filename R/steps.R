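# Pure-R single-step recurrences. These mirror the compiled training core
# exactly and serve two purposes: a readable specification of each
# architecture's update, and an independent oracle — the test suite checks
# that composing these steps reproduces the compiled forward pass to
# numerical precision.

layer_norm <- function(z, gain, bias, eps = 1e-5) {
  mu <- mean(z)
  v <- mean((z - mu)^2)
  gain * (z - mu) / sqrt(v + eps) + bias
}

sigmoid <- function(x) 1 / (1 + exp(-x))

new_state <- function(model) {
  n <- model$cfg$hidden
  st <- list(h = numeric(n))
  if (model$architecture == "lstm") st$c <- numeric(n)
  if (model$architecture == "fastweights") st$A <- matrix(0, n, n)
  if (model$architecture == "dnc") {
    N <- model$cfg$mem_slots; W <- model$cfg$mem_width
    st <- c(st, list(c = numeric(n), M = matrix(0, N, W), u = numeric(N),
                     p = numeric(N), link = matrix(0, N, N),
                     w_r = numeric(N), w_w = numeric(N), r = numeric(W)))
  }
  st
}

#' Single recurrence steps
#'
#' Advance one architecture's state by one input vector. `rnn_step` applies
#' `h <- tanh(LayerNorm(W h + U x))`; `lstm_step` the layer-normalized gate
#' equations; `fastweights_step` first updates the fast-weight matrix
#' `A <- lambda A + eta h h^T` from the incoming hidden state and then
#' settles the new state through `S` inner iterations
#' `h_s <- tanh(LayerNorm(W h + U x + A h_{s-1}))` (with `h_0 = tanh(W h +
#' U x)`); `dnc_step` runs the LSTM controller, parses the interface vector,
#' and performs one content-plus-allocation write and one
#' content-plus-temporal-linkage read on the external buffer.
#'
#' Fresh (all-zero) states come from `new_state(model)` internally; pass
#' `state = NULL` for the first token.
#'
#' @param model a `binding_model` of the matching architecture.
#' @param state recurrent state list, or `NULL` for the initial state.
#' @param x input vector (one word embedding).
#' @return The updated state list.
#' @name recurrence-steps
NULL

#' @rdname recurrence-steps
#' @export
rnn_step <- function(model, state, x) {
  stopifnot(model$architecture == "rnn")
  if (is.null(state)) state <- new_state(model)
  p <- model$params
  if (length(x) != model$cfg$input_dim) stop("input dimension mismatch")
  z <- drop(p$W %*% state$h + p$U %*% x)
  state$h <- tanh(layer_norm(z, drop(p$g), drop(p$b)))
  state
}

#' @rdname recurrence-steps
#' @export
lstm_step <- function(model, state, x) {
  stopifnot(model$architecture == "lstm")
  if (is.null(state)) state <- new_state(model)
  p <- model$params
  n <- model$cfg$hidden
  z <- drop(p$Wx %*% x + p$Wh %*% state$h)
  i <- sigmoid(layer_norm(z[1:n], drop(p$g_i), drop(p$b_i)))
  f <- sigmoid(layer_norm(z[(n + 1):(2 * n)], drop(p$g_f), drop(p$b_f)))
  g <- tanh(layer_norm(z[(2 * n + 1):(3 * n)], drop(p$g_g), drop(p$b_g)))
  o <- sigmoid(layer_norm(z[(3 * n + 1):(4 * n)], drop(p$g_o), drop(p$b_o)))
  state$c <- f * state$c + i * g
  state$h <- o * tanh(layer_norm(state$c, drop(p$g_c), drop(p$b_c)))
  state
}

#' @rdname recurrence-steps
#' @export
fastweights_step <- function(model, state, x) {
  stopifnot(model$architecture == "fastweights")
  if (is.null(state)) state <- new_state(model)
  p <- model$params
  cfg <- model$cfg
  act <- if (identical(cfg$fw_nonlin, "tanh")) tanh else function(z) pmax(z, 0)
  state$A <- cfg$lambda * state$A + cfg$eta * tcrossprod(state$h)
  z <- drop(p$W %*% state$h + p$U %*% x + p$b0)
  h <- act(z)
  for (s in seq_len(cfg$S)) {
    h <- act(layer_norm(z + drop(state$A %*% h), drop(p$g), drop(p$b)))
  }
  state$h <- h
  state
}

oneplus <- function(x) ifelse(x > 30, 1 + x, 1 + log1p(exp(x)))

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

cosine_rows <- function(M, k, eps = 1e-8) {
  drop(M %*% k) / (sqrt(rowSums(M^2)) * sqrt(sum(k^2)) + eps)
}

#' @rdname recurrence-steps
#' @export
dnc_step <- function(model, state, x) {
  stopifnot(model$architecture == "dnc")
  if (is.null(state)) state <- new_state(model)
  p <- model$params
  n <- model$cfg$hidden; N <- model$cfg$mem_slots; W <- model$cfg$mem_width
  inp <- c(x, state$r)
  z <- drop(p$Wx %*% inp + p$Wh %*% state$h + p$bg)
  i <- sigmoid(z[1:n]); f <- sigmoid(z[(n + 1):(2 * n)])
  g <- tanh(z[(2 * n + 1):(3 * n)]); o <- sigmoid(z[(3 * n + 1):(4 * n)])
  state$c <- f * state$c + i * g
  state$h <- o * tanh(state$c)
  xi <- drop(p$Wi %*% state$h + p$bi)
  q <- 0
  k_r <- xi[(q + 1):(q + W)]; q <- q + W
  b_r <- oneplus(xi[q + 1]); q <- q + 1
  k_w <- xi[(q + 1):(q + W)]; q <- q + W
  b_w <- oneplus(xi[q + 1]); q <- q + 1
  erase <- sigmoid(xi[(q + 1):(q + W)]); q <- q + W
  add <- xi[(q + 1):(q + W)]; q <- q + W
  free <- sigmoid(xi[q + 1]); g_a <- sigmoid(xi[q + 2]); g_w <- sigmoid(xi[q + 3])
  modes <- softmax(xi[(q + 4):(q + 6)])
  # retention, usage, allocation (stable ascending sort, lowest index first)
  psi <- 1 - free * state$w_r
  u <- (state$u + state$w_w - state$u * state$w_w) * psi
  phi <- order(u)  # order() is stable
  alloc <- numeric(N)
  run <- 1
  for (j in seq_len(N)) {
    alloc[phi[j]] <- (1 - u[phi[j]]) * run
    run <- run * u[phi[j]]
  }
  c_w <- softmax(b_w * cosine_rows(state$M, k_w))
  w_w <- g_w * (g_a * alloc + (1 - g_a) * c_w)
  M <- state$M * (1 - outer(w_w, erase)) + outer(w_w, add)
  link <- (1 - outer(w_w, rep(1, N)) - outer(rep(1, N), w_w)) * state$link +
    outer(w_w, state$p)
  diag(link) <- 0
  p_new <- (1 - sum(w_w)) * state$p + w_w
  fwd <- drop(link %*% state$w_r)
  bwd <- drop(t(link) %*% state$w_r)
  c_r <- softmax(b_r * cosine_rows(M, k_r))
  w_r <- modes[1] * bwd + modes[2] * c_r + modes[3] * fwd
  state$M <- M; state$link <- link; state$p <- p_new
  state$u <- u; state$w_w <- w_w; state$w_r <- w_r
  state$r <- drop(t(M) %*% w_r)
  state
}

#' Reference forward pass built from the single-step functions
#'
#' Composes [rnn_step()]/[lstm_step()]/[fastweights_step()]/[dnc_step()]
#' over a token sequence and applies the linear readout. Numerically
#' equivalent to the compiled forward pass; used as its oracle in tests.
#'
#' @param model a `binding_model`.
#' @param tokens character vector of tokens.
#' @param lexicon embedding matrix.
#' @return The 50-d prediction vector.
#' @export
forward_reference <- function(model, tokens, lexicon) {
  step_fn <- switch(model$architecture,
                    rnn = rnn_step, lstm = lstm_step,
                    fastweights = fastweights_step, dnc = dnc_step)
  state <- NULL
  for (tok in tokens) state <- step_fn(model, state, lexicon[tok, ])
  p <- model$params
  if (model$architecture == "dnc") {
    drop(p$Wy %*% state$h + p$Wr %*% state$r + p$by)
  } else {
    drop(p$Wo %*% state$h + p$bo)
  }
}
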