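#' Construct a recurrent binding model
#'
#' All four architectures share one contract: story tokens are fed one per
#' timestep as 50-d embeddings, and the prediction is a linear readout of
#' the state after the final (query) token — for the DNC, of the hidden
#' state and the current read vector. Training minimizes mean squared error
#' to the target filler embedding with Adam.
#'
#' Training maximizes retrieval of the target filler: by default the 50-d
#' prediction is scored against every lexicon word by inner product and
#' trained with softmax cross-entropy (whose argmax equals cosine
#' retrieval on unit-norm embeddings); plain squared error to the target
#' embedding is available via `loss = "mse"` but converges far more slowly
#' on the binding tasks.
#'
#' Architecture notes:
#' * `rnn` — layer-normalized tanh recurrence.
#' * `lstm` — LSTM with per-gate layer normalization (and on the cell
#'   before the output nonlinearity).
#' * `fastweights` — recurrent net augmented with an auto-associative matrix
#'   `A <- lambda A + eta h h^T` updated every step from the incoming
#'   hidden state and applied through `settle` layer-normalized inner
#'   iterations. `lambda = 0.95`, `eta = 0.5`, `settle = 1`, and the ReLU
#'   nonlinearity (default) are the canonical fast-weights values; tanh is
#'   available and gives bounded states (and a bounded fast-weight norm).
#' * `dnc` — differentiable neural computer: an LSTM controller reads and
#'   writes a 128 x 20 external buffer through content-based addressing
#'   (cosine keys, softplus strengths), usage-based dynamic allocation,
#'   and temporal linkage, with one write head and one read head.
#'
#' @param architecture one of `"rnn"`, `"lstm"`, `"fastweights"`, `"dnc"`.
#' @param hidden hidden units (50).
#' @param input_dim,output_dim embedding dimensions (50).
#' @param lr Adam learning rate (1e-4).
#' @param lambda,eta,settle fast-weights decay, fast learning rate, and
#'   number of settling iterations.
#' @param fw_nonlin fast-weights activation, `"relu"` (default, canonical)
#'   or `"tanh"` (bounded states).
#' @param clip optional global gradient-norm clip applied before each Adam
#'   update (`0`, the default, disables it).
#' @param loss training objective: `"ce"` (default; softmax cross-entropy
#'   over inner-product logits against every lexicon word — for unit-norm
#'   embeddings the logits' argmax coincides with cosine retrieval) or
#'   `"mse"` (squared error to the target embedding).
#' @param mem_slots,mem_width DNC memory geometry (128 slots x 20).
#' @return An object of class `binding_model`.
#' @export
binding_model <- function(architecture = c("rnn", "lstm", "fastweights", "dnc"),
                          hidden = 50L, input_dim = 50L, output_dim = 50L,
                          lr = 1e-4, lambda = 0.95, eta = 0.5, settle = 1L,
                          fw_nonlin = c("relu", "tanh"), clip = 0,
                          loss = c("ce", "mse"),
                          mem_slots = 128L, mem_width = 20L) {
  architecture <- match.arg(architecture)
  fw_nonlin <- match.arg(fw_nonlin)
  loss <- match.arg(loss)
  cfg <- list(hidden = as.integer(hidden), input_dim = as.integer(input_dim),
              output_dim = as.integer(output_dim), lr = lr,
              lambda = lambda, eta = eta, S = as.integer(settle),
              fw_nonlin = fw_nonlin, clip = clip, loss = loss,
              mem_slots = as.integer(mem_slots), mem_width = as.integer(mem_width))
  params <- init_params(architecture, cfg)
  structure(
    list(architecture = architecture, cfg = cfg, params = params,
         opt = list(m = zero_like(params), v = zero_like(params), step = 0L),
         curves = NULL),
    class = "binding_model"
  )
}

#' @export
print.binding_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat("<binding_model>", x$architecture, "-", x$cfg$hidden, "hidden units,",
      np, "parameters,", x$opt$step, "optimizer steps\n")
  invisible(x)
}

zero_like <- function(params) {
  lapply(params, function(m) matrix(0, nrow(m), ncol(m)))
}

gmat <- function(r, c, sd) matrix(rnorm(r * c, sd = sd), r, c)

init_params <- function(arch, cfg) {
  n <- cfg$hidden; d <- cfg$input_dim; o <- cfg$output_dim
  ones <- function(k) matrix(1, k, 1)
  zeros <- function(k) matrix(0, k, 1)
  if (arch == "rnn") {
    list(W = gmat(n, n, 1 / sqrt(n)), U = gmat(n, d, 1 / sqrt(d)),
         g = ones(n), b = zeros(n),
         Wo = gmat(o, n, 1 / sqrt(n)), bo = zeros(o))
  } else if (arch == "lstm") {
    p <- list(Wx = gmat(4 * n, d, 1 / sqrt(d)), Wh = gmat(4 * n, n, 1 / sqrt(n)),
              g_i = ones(n), b_i = zeros(n),
              g_f = ones(n), b_f = ones(n),   # positive forget bias
              g_g = ones(n), b_g = zeros(n),
              g_o = ones(n), b_o = zeros(n),
              g_c = ones(n), b_c = zeros(n),
              Wo = gmat(o, n, 1 / sqrt(n)), bo = zeros(o))
    p
  } else if (arch == "fastweights") {
    list(W = gmat(n, n, 1 / sqrt(n)), U = gmat(n, d, 1 / sqrt(d)),
         b0 = zeros(n), g = ones(n), b = zeros(n),
         Wo = gmat(o, n, 1 / sqrt(n)), bo = zeros(o))
  } else if (arch == "dnc") {
    wd <- cfg$mem_width
    din <- d + wd
    xi <- 4 * wd + 8
    bg <- zeros(4 * n)
    bg[(n + 1):(2 * n)] <- 1   # positive forget bias
    list(Wx = gmat(4 * n, din, 1 / sqrt(din)), Wh = gmat(4 * n, n, 1 / sqrt(n)),
         bg = bg,
         Wi = gmat(xi, n, 1 / sqrt(n)), bi = zeros(xi),
         Wy = gmat(o, n, 1 / sqrt(n)), Wr = gmat(o, wd, 1 / sqrt(wd)),
         by = zeros(o))
  } else stop("unknown architecture")
}

#' Encode stories as an index matrix against a lexicon
#'
#' @param stories list of `story_instance`s, all of one length `L`.
#' @param lexicon embedding matrix with token rownames covering every token.
#' @return list with `X` (stories x L integer matrix, 1-based rows of the
#'   lexicon), `target` (integer vector), `query` (character vector).
#' @export
encode_stories <- function(stories, lexicon) {
  toks <- rownames(lexicon)
  L <- length(stories[[1]]$tokens)
  flat <- unlist(lapply(stories, `[[`, "tokens"), use.names = FALSE)
  if (length(flat) != L * length(stories)) stop("stories have unequal lengths")
  idx <- match(flat, toks)   # one hash build for the whole batch
  if (anyNA(idx)) {
    stop("story token(s) missing from lexicon: ",
         paste(unique(flat[is.na(idx)])[1:5], collapse = ", "))
  }
  X <- matrix(idx, ncol = L, byrow = TRUE)
  target <- match(vapply(stories, `[[`, character(1), "target"), toks)
  if (anyNA(target)) stop("target token(s) missing from lexicon")
  list(X = X, target = target,
       query = vapply(stories, `[[`, character(1), "query"))
}

#' Predict filler embeddings for encoded stories
#'
#' @param model a `binding_model`.
#' @param X integer story matrix (1-based lexicon rows), or an encoded
#'   dataset as returned by [encode_stories()].
#' @param lexicon embedding matrix.
#' @return stories x 50 matrix of predicted vectors.
#' @export
model_predict <- function(model, X, lexicon) {
  if (is.list(X)) X <- X$X
  sb_predict_cpp(model$architecture, model$params, X - 1L, lexicon, model$cfg)
}

#' Run one story through a model and record its activation trace
#'
#' One record per input token: the hidden state and, for the external-memory
#' architectures, the flattened memory (50 x 50 fast-weight matrix as
#' 2,500-d; 128 x 20 DNC buffer as 2,560-d, slot-major) plus the DNC's
#' read/write weightings and read vector.
#'
#' @param model a `binding_model`.
#' @param tokens character vector of story tokens (or integer lexicon rows).
#' @param lexicon embedding matrix.
#' @return list with `prediction` and per-timestep matrices (`hidden`,
#'   and where applicable `memory`, `read_weights`, `write_weights`).
#' @export
model_trace <- function(model, tokens, lexicon) {
  idx <- if (is.character(tokens)) match(tokens, rownames(lexicon)) else as.integer(tokens)
  if (anyNA(idx)) stop("unknown token(s) in story")
  sb_trace_cpp(model$architecture, model$params, idx - 1L, lexicon, model$cfg)
}

#' Loss and gradients on a batch (testing/diagnostic interface)
#'
#' Mean over the batch of `0.5 * ||prediction - target embedding||^2`, with
#' gradients for every parameter. Used by the finite-difference gradient
#' checks in the test suite.
#'
#' @inheritParams model_predict
#' @param target integer vector of target lexicon rows.
#' @return list with `loss` and `grads`.
#' @export
model_loss_grad <- function(model, X, target, lexicon) {
  if (is.list(X)) { target <- X$target; X <- X$X }
  sb_loss_grad_cpp(model$architecture, model$params, X - 1L,
                   target - 1L, lexicon, model$cfg)
}
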