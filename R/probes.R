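#' Correlation-violation experiment design
#'
#' A universe of fillers in which each filler is excluded from exactly one
#' of the four varied roles (Subject, Friend, Emcee, Poet) during training
#' — exclusion assigned round-robin by filler index — so each role trains
#' on 3/4 of the universe and is tested only on its excluded quarter,
#' deliberately breaking every role-filler correlation seen in training.
#' The Dessert and Drink words stay constant in every story.
#'
#' @param n_fillers filler universe size (1,000; must be divisible by 4).
#' @param varied the four varied roles.
#' @return A `violation_design`: filler tokens, per-role train/test pools,
#'   constant fillers.
#' @export
violation_design <- function(n_fillers = 1000L,
                             varied = c("Subject", "Friend", "Emcee", "Poet")) {
  if (n_fillers %% length(varied) != 0) {
    stop("n_fillers must be divisible by the number of varied roles")
  }
  fillers <- sprintf("filler%04d", seq_len(n_fillers))
  excluded <- varied[(seq_len(n_fillers) - 1L) %% length(varied) + 1L]
  structure(list(
    fillers = fillers,
    excluded = setNames(excluded, fillers),
    train_pools = lapply(setNames(varied, varied),
                         function(r) fillers[excluded != r]),
    test_pools = lapply(setNames(varied, varied),
                        function(r) fillers[excluded == r]),
    constants = c(Dessert = "dessert0", Drink = "drink0"),
    varied = varied), class = "violation_design")
}

#' Build correlation-violation train/test datasets
#'
#' Stories use the fixed linear frame with a fixed lexicon. The training
#' set is generative: every epoch draws fresh role-filler combinations,
#' binding each varied role only to its allowed pool (fillers are a fixed
#' finite pool; only the combinations are resampled). The test set binds
#' each varied role only to the fillers excluded from it during training.
#' Queries are drawn uniformly over the varied roles.
#'
#' @param design a `violation_design`.
#' @param epoch_size training stories per epoch.
#' @param n_test test stories.
#' @return list with `train` (a fixed-pool `generative_dataset`), `test`
#'   (a `story_dataset` on the shared lexicon), and the `design`.
#' @export
build_violation_datasets <- function(design, epoch_size = 512L, n_test = 500L) {
  template <- linear_frame()
  keywords <- template$value[template$kind == "word"]
  vocab <- c(keywords, vapply(ROLES, query_token, character(1)), PAD_TOKEN,
             unname(design$constants), design$fillers)
  lexicon <- build_lexicon(vocab)
  const_pools <- lapply(as.list(design$constants), identity)
  train <- structure(
    list(kind = "template", template = template,
         frames = lapply(seq_len(epoch_size), function(i) {
           list(query_role = design$varied[(i - 1L) %% length(design$varied) + 1L])
         }),
         base_lexicon = lexicon,
         pools = c(design$train_pools, const_pools),
         L = length(template$value) + 2L, batch_size = 16L,
         name = "violation/train"),
    class = "generative_dataset")
  test_stories <- lapply(seq_len(n_test), function(i) {
    binding <- lapply(design$test_pools, function(pl) pl[sample.int(length(pl), 1L)])
    binding <- c(binding, as.list(design$constants))
    qrole <- design$varied[sample.int(length(design$varied), 1L)]
    instantiate_template(template, binding, qrole)
  })
  list(train = train,
       test = new_story_dataset(test_stories, lexicon, "violation/test"),
       design = design)
}

#' Evaluate a model on the correlation-breaking test set
#'
#' @param model a trained `binding_model`.
#' @param datasets output of [build_violation_datasets()].
#' @return The test-set `eval_report` (accuracy with corpus-derived chance).
#' @export
run_violation_eval <- function(model, datasets) {
  evaluate_model(model, datasets$test)
}

#' Correlation-retention experiment datasets
#'
#' Training stories use the linear frame with freshly drawn filler vectors
#' per story: the Dessert, Emcee, and Poet roles draw from distribution X
#' (even coordinates usually shifted up) and Subject, Friend, and Drink
#' from distribution Y (usually shifted down); all frame words come from
#' distribution Z. The test suite varies the filler distribution: all X,
#' all Y, an equal X/Y mixture per filler, and all Z.
#'
#' @param reps stories per query role per epoch (epoch size = 6 x `reps`).
#' @param batch_size evaluation batch size.
#' @param dim embedding dimension.
#' @return list with `train` (a `generative_dataset`) and `tests` (named
#'   list of generative datasets `X`, `Y`, `XY`, `Z`).
#' @export
build_retention_datasets <- function(reps = 16L, batch_size = 16L, dim = 50L) {
  template <- linear_frame()
  train_dists <- c(Subject = "Y", Friend = "Y", Drink = "Y",
                   Dessert = "X", Emcee = "X", Poet = "X")
  keywords <- template$value[template$kind == "word"]
  base_vocab <- c(keywords, vapply(ROLES, query_token, character(1)), PAD_TOKEN)
  base_lex <- build_lexicon(base_vocab, dim = dim)  # frame words ~ Z
  mk <- function(dists, name) {
    frames <- rep(lapply(template_roles(template), function(r) {
      list(query_role = r)
    }), reps)
    structure(list(kind = "template", template = template, frames = frames,
                   base_lexicon = base_lex, role_dists = dists,
                   L = length(template$value) + 2L, batch_size = batch_size,
                   name = name),
              class = "generative_dataset")
  }
  all_roles <- function(d) setNames(rep(d, length(ROLES)), ROLES)
  list(train = mk(train_dists, "retention/train"),
       tests = list(X = mk(all_roles("X"), "retention/test-X"),
                    Y = mk(all_roles("Y"), "retention/test-Y"),
                    XY = mk(all_roles("XY"), "retention/test-XY"),
                    Z = mk(all_roles("Z"), "retention/test-Z")),
       train_dists = train_dists)
}

even_cols <- function(dim) seq(1L, dim, by = 2L)  # 0-based even coordinates

# Welch t between pooled even-coordinate and odd-coordinate values of the
# rows of `m` (positive = even coordinates elevated, i.e. X-like). Degenerate
# near-constant groups resolve to 0 (equal means) or signed infinity.
even_odd_t <- function(m) {
  dim <- ncol(m)
  ev <- as.vector(m[, even_cols(dim), drop = FALSE])
  od <- as.vector(m[, -even_cols(dim), drop = FALSE])
  degenerate <- function() {
    d <- mean(ev) - mean(od)
    if (abs(d) < 1e-12) 0 else sign(d) * Inf
  }
  t <- tryCatch(unname(stats::t.test(ev, od)$statistic),
                error = function(e) NaN)
  if (!is.finite(t)) degenerate() else t
}

#' Ambiguous-query probe of retained role statistics
#'
#' Draws a mixed X/Y test epoch, replaces the queried filler's input vector
#' with the all-zero vector (ambiguous: the input no longer identifies the
#' answer and carries no even/odd asymmetry), and pools the model's
#' predictions per queried role. The per-role Welch t-statistic between the
#' predictions' even and odd coordinates is positive when the model guesses
#' X-like vectors and negative when Y-like — revealing whichever
#' distribution the role had during training.
#'
#' @param model a trained `binding_model`.
#' @param dataset a mixed-XY `generative_dataset` (see
#'   [build_retention_datasets()]).
#' @param epochs how many fresh epochs to pool.
#' @return A `bias_report` data.frame with columns `role` and `statistic`.
#' @export
ambiguous_probe <- function(model, dataset, epochs = 2L) {
  preds <- list()
  qroles <- character(0)
  for (e in seq_len(epochs)) {
    ep <- sample_generative_epoch(dataset, zero_target = TRUE)
    enc <- encode_stories(ep$stories, ep$lexicon)
    preds[[e]] <- model_predict(model, enc$X, ep$lexicon)
    qroles <- c(qroles, vapply(ep$stories, `[[`, character(1), "query"))
  }
  preds <- do.call(rbind, preds)
  bias_report(preds, qroles)
}

bias_report <- function(m, qroles) {
  roles <- ROLES[vapply(ROLES, query_token, character(1)) %in% qroles]
  out <- data.frame(role = roles, statistic = NA_real_)
  for (i in seq_along(roles)) {
    rows <- qroles == query_token(roles[i])
    out$statistic[i] <- even_odd_t(m[rows, , drop = FALSE])
  }
  class(out) <- c("bias_report", "data.frame")
  out
}

#' Residual bias on correctly answerable all-Z queries
#'
#' Draws an all-Z test epoch (fillers with no even/odd asymmetry), computes
#' `prediction - target` per story, and reports the per-role even/odd
#' Welch t-statistic of the residual together with retrieval accuracy on
#' the same stories. A model that answers correctly but leans toward its
#' training statistics shows sign-consistent t-statistics with high
#' accuracy.
#'
#' @param model a trained `binding_model`.
#' @param dataset the all-Z `generative_dataset`.
#' @param epochs fresh epochs to pool.
#' @return list with `bias` (a `bias_report`) and `accuracy`, `chance`.
#' @export
residual_bias <- function(model, dataset, epochs = 2L) {
  resid <- list(); qroles <- character(0)
  hits <- logical(0); chance <- NA_real_
  base_vocab <- rownames(dataset$base_lexicon)
  for (e in seq_len(epochs)) {
    ep <- sample_generative_epoch(dataset)
    enc <- encode_stories(ep$stories, ep$lexicon)
    preds <- model_predict(model, enc$X, ep$lexicon)
    targets <- ep$lexicon[enc$target, , drop = FALSE]
    resid[[e]] <- preds - targets
    qroles <- c(qroles, vapply(ep$stories, `[[`, character(1), "query"))
    bs <- dataset$batch_size
    for (s in seq(1, length(ep$stories), by = bs)) {
      idx <- s:min(s + bs - 1L, length(ep$stories))
      corpus <- build_corpus(ep$lexicon, base_vocab = base_vocab,
                             batch = ep$stories[idx])
      if (length(idx) == bs || is.na(chance)) chance <- 1 / length(corpus$tokens)
      got <- nearest_words(preds[idx, , drop = FALSE], corpus)
      hits <- c(hits, got == vapply(ep$stories[idx], `[[`, character(1), "target"))
    }
  }
  list(bias = bias_report(do.call(rbind, resid), qroles),
       accuracy = mean(hits), chance = chance)
}

#' Evaluate a model on stage-shuffled stories
#'
#' Tests structural generalization by evaluating on the fixed shuffled
#' variant of the linear frame (same token multiset, stages reordered).
#' For a generative (retention-style) training set the shuffled dataset
#' keeps the same filler distributions; for a violation-style fixed-pool
#' training set it keeps the same lexicon and test pools.
#'
#' @param model a trained `binding_model`.
#' @param source the training source: a `generative_dataset` over the
#'   linear frame, or the list returned by [build_violation_datasets()].
#' @return list with `shuffled` and `control` `eval_report`s (control =
#'   unshuffled test distribution).
#' @export
shuffled_story_eval <- function(model, source) {
  if (inherits(source, "generative_dataset")) {
    shuf <- source
    shuf$template <- shuffle_stages(source$template)
    shuf$name <- paste0(source$name, "/shuffled")
    list(shuffled = evaluate_model(model, shuf),
         control = evaluate_model(model, source))
  } else {
    design <- source$design
    template <- shuffle_stages(linear_frame())
    lexicon <- source$test$lexicon
    stories <- lapply(seq_len(length(source$test$stories)), function(i) {
      binding <- lapply(design$test_pools, function(pl) pl[sample.int(length(pl), 1L)])
      binding <- c(binding, as.list(design$constants))
      qrole <- design$varied[sample.int(length(design$varied), 1L)]
      instantiate_template(template, binding, qrole)
    })
    shuf <- new_story_dataset(stories, lexicon, "violation/shuffled")
    list(shuffled = evaluate_model(model, shuf),
         control = evaluate_model(model, source$test))
  }
}
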