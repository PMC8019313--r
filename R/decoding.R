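#' Build a decoding set: many instantiations of one story frame
#'
#' Constructs `n` input sequences sharing one frame — identical frame text,
#' identical padding position, identical query — completed with distinct
#' freshly drawn fillers for every role. The default frame is the path that
#' traverses every role-bearing branch of the coffee-shop graph
#' (BEGIN, ORDER_DRINK, SIT, INTRO, POETRY, PERFORM, ORDER_DESSERT, END),
#' so all six roles can be decoded from one set.
#'
#' @param graph a `schema_graph`.
#' @param path path of state names (default: the all-roles path above).
#' @param query_role the query appended to every sequence.
#' @param n number of sequences (100).
#' @param L sequence length.
#' @param dim embedding dimension.
#' @return A `decoding_set`: stories, shared `lexicon`, per-role target
#'   token matrix, and the fixed frame layout.
#' @export
build_decoding_set <- function(graph = coffee_shop_graph(),
                               path = c("BEGIN", "ORDER_DRINK", "SIT", "INTRO",
                                        "POETRY", "PERFORM", "ORDER_DESSERT", "END"),
                               query_role = "Poet", n = 100L,
                               L = story_length(graph), dim = 50L) {
  roles <- path_roles(graph, path)
  base_vocab <- base_vocabulary(graph)
  base_lex <- build_lexicon(base_vocab, dim = dim)
  # one shared frame: fix the padding position by instantiating a skeleton
  skeleton <- instantiate_story(story_frame(path, query_role), graph,
                                setNames(as.list(paste0("SLOT.", roles)), roles),
                                L = L)
  stories <- vector("list", n)
  lex_rows <- vector("list", n)
  for (i in seq_len(n)) {
    toks <- setNames(sprintf("f%04d.%s", i, roles), roles)
    m <- sample_filler_vectors(length(roles), dim = dim)
    rownames(m) <- toks
    tokens <- skeleton$tokens
    for (r in roles) tokens[tokens == paste0("SLOT.", r)] <- toks[[r]]
    stories[[i]] <- structure(
      list(tokens = tokens, query = skeleton$query, target = toks[[query_role]],
           binding = as.list(toks), frame = skeleton$frame),
      class = "story_instance")
    lex_rows[[i]] <- m
  }
  lexicon <- rbind(base_lex, do.call(rbind, lex_rows))
  structure(list(stories = stories, lexicon = lexicon, roles = roles,
                 query_role = query_role, L = L,
                 base_vocab = base_vocab),
            class = "decoding_set")
}

#' Record activation traces for a decoding set
#'
#' Runs every sequence through the model and stacks per-timestep snapshots:
#' the hidden state (50-d) and, for the external-memory architectures, the
#' flattened memory (2,500-d fast-weight matrix or 2,560-d DNC buffer), one
#' record per input token.
#'
#' @param model a trained `binding_model`.
#' @param dset a `decoding_set`.
#' @return list of arrays `n x L x dims` per component (`hidden`, and
#'   `memory` where the architecture has one), plus DNC read/write
#'   weightings when applicable.
#' @export
record_traces <- function(model, dset) {
  n <- length(dset$stories)
  first <- model_trace(model, dset$stories[[1]]$tokens, dset$lexicon)
  out <- list()
  for (comp in intersect(names(first), c("hidden", "memory", "read_weights",
                                         "write_weights"))) {
    out[[comp]] <- array(NA_real_, dim = c(n, nrow(first[[comp]]),
                                           ncol(first[[comp]])))
  }
  for (i in seq_len(n)) {
    tr <- if (i == 1) first else model_trace(model, dset$stories[[i]]$tokens,
                                             dset$lexicon)
    for (comp in names(out)) out[[comp]][i, , ] <- tr[[comp]]
  }
  out
}

#' Fit ridge decoders from activations to filler embeddings
#'
#' For every (role, timestep, component) fits a closed-form ridge
#' regression (regularization strength `alpha`, intercept via centering)
#' from the activation vector to the 50-d embedding of that role's filler,
#' using the first `n_train` sequences. High-dimensional components use the
#' kernel (dual) form, so the solve is in the number of training sequences.
#'
#' @param traces output of [record_traces()].
#' @param dset the `decoding_set` the traces came from.
#' @param alpha ridge regularization strength (1.0).
#' @param n_train training sequences (80).
#' @param components components to decode (default `hidden` and `memory`).
#' @return A `decoder_bank`.
#' @export
fit_decoders <- function(traces, dset, alpha = 1.0, n_train = 80L,
                         components = intersect(names(traces),
                                                c("hidden", "memory"))) {
  roles <- dset$roles
  tr_idx <- seq_len(n_train)
  targets <- lapply(setNames(roles, roles), function(r) {
    toks <- vapply(dset$stories, function(s) s$binding[[r]], character(1))
    dset$lexicon[toks, , drop = FALSE]
  })
  bank <- list()
  for (comp in components) {
    L <- dim(traces[[comp]])[2]
    bank[[comp]] <- vector("list", L)
    for (t in seq_len(L)) {
      X <- traces[[comp]][tr_idx, t, , drop = TRUE]
      X <- matrix(X, nrow = length(tr_idx))
      xbar <- colMeans(X)
      Xc <- sweep(X, 2, xbar)
      K <- tcrossprod(Xc)
      diag(K) <- diag(K) + alpha
      Kinv_chol <- chol(K)
      per_role <- list()
      for (r in roles) {
        Y <- targets[[r]][tr_idx, , drop = FALSE]
        ybar <- colMeans(Y)
        Yc <- sweep(Y, 2, ybar)
        A <- backsolve(Kinv_chol, forwardsolve(t(Kinv_chol), Yc))
        per_role[[r]] <- list(W = crossprod(Xc, A), xbar = xbar, ybar = ybar)
      }
      bank[[comp]][[t]] <- per_role
    }
  }
  structure(list(bank = bank, roles = roles, alpha = alpha,
                 n_train = n_train), class = "decoder_bank")
}

decode_predict <- function(dec, X) {
  sweep(X, 2, dec$xbar) %*% dec$W + rep(1, nrow(X)) %o% dec$ybar
}

#' Held-out decoding ranking scores over time
#'
#' Applies the fitted decoders to the held-out sequences and scores each
#' prediction by the ranking of the true filler in the corpus (cosine
#' similarity): 1 is perfect, 0.5 is chance.
#'
#' @param bank a `decoder_bank`.
#' @param traces output of [record_traces()].
#' @param dset the `decoding_set`.
#' @param corpus retrieval corpus; default the decoding set's base
#'   vocabulary plus all of its fillers.
#' @return data.frame with columns `component`, `role`, `timestep`, `score`
#'   (mean held-out ranking score).
#' @export
decoding_curve <- function(bank, traces, dset, corpus = NULL) {
  if (is.null(corpus)) corpus <- build_corpus(dset$lexicon)
  n <- length(dset$stories)
  te_idx <- setdiff(seq_len(n), seq_len(bank$n_train))
  rows <- list()
  for (comp in names(bank$bank)) {
    L <- length(bank$bank[[comp]])
    for (t in seq_len(L)) {
      per_role <- bank$bank[[comp]][[t]]
      X <- matrix(traces[[comp]][te_idx, t, , drop = TRUE], nrow = length(te_idx))
      for (r in bank$roles) {
        preds <- decode_predict(per_role[[r]], X)
        toks <- vapply(dset$stories[te_idx], function(s) s$binding[[r]],
                       character(1))
        sc <- vapply(seq_along(te_idx), function(i) {
          ranking_score(preds[i, ], toks[i], corpus)
        }, numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(component = comp, role = r,
                                                timestep = t, score = mean(sc))
      }
    }
  }
  do.call(rbind, rows)
}

#' DNC read/write-location analysis
#'
#' For each role, takes the argmax of the write weighting at the timesteps
#' where that role's filler is in the input and histograms it over memory
#' slots; for each query, histograms the argmax of the read weighting at
#' the query timestep. The Pearson correlation between each role's
#' write-location distribution and each query's read-location distribution
#' shows whether the network stores and retrieves bindings by location.
#' Argmax ties break toward the lowest slot index.
#'
#' @param stories list of `story_instance`s.
#' @param traces matching list of per-story traces, each with
#'   `read_weights` and `write_weights` (timestep x slots matrices).
#' @param roles roles to analyze.
#' @return list with `write_hist`, `read_hist` (roles x slots counts), and
#'   `correlation` (queried role x written role Pearson matrix).
#' @export
dnc_rw_analysis <- function(stories, traces, roles = ROLES) {
  n_slots <- ncol(traces[[1]]$write_weights)
  write_hist <- matrix(0, length(roles), n_slots, dimnames = list(roles, NULL))
  read_hist <- matrix(0, length(roles), n_slots, dimnames = list(roles, NULL))
  for (i in seq_along(stories)) {
    s <- stories[[i]]
    tr <- traces[[i]]
    for (r in roles) {
      filler <- s$binding[[r]]
      if (is.null(filler)) next
      for (t in which(s$tokens == filler)) {
        slot <- which.max(tr$write_weights[t, ])
        write_hist[r, slot] <- write_hist[r, slot] + 1
      }
    }
    qrole <- roles[vapply(roles, function(r) query_token(r) == s$query, logical(1))]
    if (length(qrole) == 1L) {
      tq <- length(s$tokens)
      slot <- which.max(tr$read_weights[tq, ])
      read_hist[qrole, slot] <- read_hist[qrole, slot] + 1
    }
  }
  correlation <- matrix(NA_real_, length(roles), length(roles),
                        dimnames = list(query = roles, write = roles))
  for (q in roles) {
    for (w in roles) {
      if (sd(read_hist[q, ]) > 0 && sd(write_hist[w, ]) > 0) {
        correlation[q, w] <- stats::cor(read_hist[q, ], write_hist[w, ])
      }
    }
  }
  list(write_hist = write_hist, read_hist = read_hist,
       correlation = correlation)
}
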