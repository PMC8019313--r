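#' Specify a training experiment
#'
#' Captures the study conditions of one experiment: the filler regime
#' (limited pool, tested with seen or unseen fillers, or unlimited fresh
#' fillers), the schema graph, and the sampling sizes. Defaults are the
#' full-scale conditions (5,000 stories per path, six fillers per role,
#' 80/20 split, 250 unseen-test stories per path, validation batches of 16);
#' reduced studies pass smaller `paths`/`stories_per_path`.
#'
#' @param regime `"limited_seen"`, `"limited_unseen"`, or `"unlimited"`.
#' @param graph a `schema_graph`.
#' @param paths optional list of paths (default: all paths of the graph).
#' @param stories_per_path stories sampled per path before deduplication.
#' @param fillers_per_role pool size per role in limited regimes.
#' @param test_stories_per_path unseen-pool test stories per path.
#' @param split train fraction for the seen-filler split.
#' @param batch_size evaluation batch size (corpus accounting for the
#'   unlimited regime uses this).
#' @return An `experiment_spec` list.
#' @export
experiment_spec <- function(regime = c("limited_seen", "limited_unseen", "unlimited"),
                            graph = coffee_shop_graph(), paths = NULL,
                            stories_per_path = 5000L, fillers_per_role = 6L,
                            test_stories_per_path = 250L, split = 0.8,
                            batch_size = 16L) {
  regime <- match.arg(regime)
  if (is.null(paths)) paths <- enumerate_paths(graph)
  structure(list(regime = regime, graph = graph, paths = paths,
                 stories_per_path = as.integer(stories_per_path),
                 fillers_per_role = as.integer(fillers_per_role),
                 test_stories_per_path = as.integer(test_stories_per_path),
                 split = split, batch_size = as.integer(batch_size),
                 L = story_length(graph)),
            class = "experiment_spec")
}

role_pool_tokens <- function(role, k, suffix = "") {
  sprintf("%s%s%02d", tolower(role), suffix, seq_len(k))
}

# Sample (path, binding) pairs for given paths, deduplicate on the exact
# body token sequence (states + fillers; padding position and query are not
# part of the identity), then attach a random answerable query per story.
sample_limited_stories <- function(spec, pools, n_per_path) {
  graph <- spec$graph
  out <- list()
  seen <- new.env(hash = TRUE)
  for (path in spec$paths) {
    roles <- path_roles(graph, path)
    for (i in seq_len(n_per_path)) {
      binding <- lapply(setNames(roles, roles), function(r) {
        pools[[r]][sample.int(length(pools[[r]]), 1L)]
      })
      key <- paste(c(path, unlist(binding)), collapse = "\r")
      if (!is.null(seen[[key]])) next
      assign(key, TRUE, envir = seen)
      qrole <- roles[sample.int(length(roles), 1L)]
      out[[length(out) + 1L]] <- instantiate_story(
        story_frame(path, qrole), graph, binding, L = spec$L)
    }
  }
  out
}

new_story_dataset <- function(stories, lexicon, name) {
  structure(list(stories = stories, lexicon = lexicon,
                 enc = encode_stories(stories, lexicon), name = name),
            class = "story_dataset")
}

#' @export
print.story_dataset <- function(x, ...) {
  cat("<story_dataset>", x$name, "-", length(x$stories), "stories,",
      nrow(x$lexicon), "vocabulary words\n")
  invisible(x)
}

#' Build limited-filler train/test datasets
#'
#' Draws stories per path with fillers from a small fixed pool,
#' deduplicates exact story sequences, and either splits them into
#' train/test (`limited_seen`) or pairs the full deduplicated train set
#' with a test set generated from a disjoint filler pool
#' (`limited_unseen`), so train and test share no token sequence — and, in
#' the unseen regime, no filler.
#'
#' @param spec an `experiment_spec` with a limited regime.
#' @return list with `train` and `test` (`story_dataset`s sharing one
#'   lexicon) plus `train_pool`/`test_pool` token sets.
#' @export
build_limited_datasets <- function(spec) {
  stopifnot(spec$regime %in% c("limited_seen", "limited_unseen"))
  k <- spec$fillers_per_role
  train_pools <- lapply(setNames(ROLES, ROLES), role_pool_tokens, k = k)
  test_pools <- lapply(setNames(ROLES, ROLES), role_pool_tokens, k = k, suffix = "u")
  vocab <- c(base_vocabulary(spec$graph),
             unlist(train_pools, use.names = FALSE),
             unlist(test_pools, use.names = FALSE))
  lexicon <- build_lexicon(vocab)
  stories <- sample_limited_stories(spec, train_pools, spec$stories_per_path)
  stories <- stories[sample.int(length(stories))]
  if (spec$regime == "limited_seen") {
    n_train <- floor(spec$split * length(stories))
    train <- stories[seq_len(n_train)]
    test <- stories[-seq_len(n_train)]
  } else {
    train <- stories
    test <- sample_limited_stories(spec, test_pools, spec$test_stories_per_path)
  }
  list(train = new_story_dataset(train, lexicon, paste0(spec$regime, "/train")),
       test = new_story_dataset(test, lexicon, paste0(spec$regime, "/test")),
       train_pool = unlist(train_pools, use.names = FALSE),
       test_pool = unlist(test_pools, use.names = FALSE))
}

#' Build unlimited-filler (generative) train/test datasets
#'
#' Both splits iterate over every answerable (path, query) frame of the
#' graph; fillers are freshly drawn unit-norm vectors in every epoch, for
#' all six roles of every story, so the retrieval corpus of a validation
#' batch is the base vocabulary plus six new words per story.
#'
#' @param spec an `experiment_spec` with regime `"unlimited"`.
#' @param role_dists optional named character vector mapping roles to
#'   filler distributions (`"X"`, `"Y"`, `"Z"`); default all `"Z"`.
#' @return list with `train` and `test` `generative_dataset`s.
#' @export
build_unlimited_datasets <- function(spec, role_dists = NULL) {
  stopifnot(spec$regime == "unlimited")
  frames <- enumerate_query_frames(spec$graph)
  frames <- Filter(function(f) any(vapply(spec$paths, identical, logical(1), f$path)),
                   frames)
  if (is.null(role_dists)) role_dists <- setNames(rep("Z", length(ROLES)), ROLES)
  base_vocab <- base_vocabulary(spec$graph)
  base_lex <- build_lexicon(base_vocab)
  mk <- function(name) {
    structure(list(kind = "graph", graph = spec$graph, frames = frames,
                   base_lexicon = base_lex, role_dists = role_dists,
                   L = spec$L, batch_size = spec$batch_size, name = name),
              class = "generative_dataset")
  }
  list(train = mk("unlimited/train"), test = mk("unlimited/test"))
}

#' @export
print.generative_dataset <- function(x, ...) {
  cat("<generative_dataset>", x$name, "-", length(x$frames),
      "frames per epoch, fresh fillers each epoch\n")
  invisible(x)
}

# Fast path for fixed-pool template datasets: draws one epoch directly in
# lexicon-index space (keyword columns constant, role columns sampled from
# pool indices, one pad column inserted at a uniformly random position,
# query index last), skipping per-story token construction entirely.
pool_epoch_cache <- function(ds) {
  toks <- rownames(ds$base_lexicon)
  tpl <- ds$template
  list(
    n_slots = length(tpl$value),
    kind = tpl$kind,
    word_idx = ifelse(tpl$kind == "word", match(tpl$value, toks), NA_integer_),
    slot_role = ifelse(tpl$kind == "role", tpl$value, NA_character_),
    pool_idx = lapply(ds$pools, function(pl) match(pl, toks)),
    pad_idx = match(PAD_TOKEN, toks),
    query_idx = setNames(match(vapply(ROLES, query_token, character(1)), toks),
                         ROLES),
    qroles = vapply(ds$frames, `[[`, character(1), "query_role")
  )
}

sample_pool_epoch_enc <- function(ds, cache) {
  n <- length(cache$qroles)
  k <- cache$n_slots
  body <- matrix(0L, n, k)
  draw <- lapply(cache$pool_idx, function(pi) pi[sample.int(length(pi), n,
                                                            replace = TRUE)])
  for (j in seq_len(k)) {
    body[, j] <- if (cache$kind[j] == "word") cache$word_idx[j]
                 else draw[[cache$slot_role[j]]]
  }
  X <- matrix(0L, n, k + 2L)
  pos <- sample.int(k + 1L, n, replace = TRUE) - 1L   # insert after `pos` tokens
  for (p in 0:k) {
    rows <- which(pos == p)
    if (length(rows) == 0) next
    if (p > 0) X[rows, 1:p] <- body[rows, 1:p, drop = FALSE]
    X[rows, p + 1L] <- cache$pad_idx
    if (p < k) X[rows, (p + 2L):(k + 1L)] <- body[rows, (p + 1L):k, drop = FALSE]
  }
  X[, k + 2L] <- cache$query_idx[cache$qroles]
  target <- vapply(seq_len(n), function(i) draw[[cache$qroles[i]]][i], integer(1))
  list(X = X, target = target)
}

# Instantiate one epoch of a generative dataset. Two flavors:
# * fresh-vector (unlimited/retention): per-story filler tokens
#   ("f0001.Subject", ...) with freshly drawn vectors appended to the base
#   lexicon; all six roles get a fresh vector per story (corpus accounting).
# * fixed-pool (`ds$pools` set, violation-style): bindings are drawn fresh
#   from fixed token pools each epoch; the lexicon never changes.
sample_generative_epoch <- function(ds, zero_target = FALSE) {
  n <- length(ds$frames)
  if (!is.null(ds$pools)) {
    stories <- lapply(seq_len(n), function(i) {
      fr <- ds$frames[[i]]
      binding <- lapply(ds$pools, function(pl) pl[sample.int(length(pl), 1L)])
      instantiate_template(ds$template, binding, fr$query_role, L = ds$L)
    })
    return(list(stories = stories, lexicon = ds$base_lexicon))
  }
  dim <- ncol(ds$base_lexicon)
  # fresh filler vectors drawn in bulk, one block per role
  vecs <- matrix(NA_real_, n * length(ROLES), dim)
  tok_mat <- outer(seq_len(n), ROLES,
                   function(i, r) sprintf("f%04d.%s", i, r))
  for (k in seq_along(ROLES)) {
    d <- ds$role_dists[[ROLES[k]]]
    rows <- (seq_len(n) - 1L) * length(ROLES) + k
    if (d == "XY") {                       # per-filler coin between X and Y
      nx <- rbinom(1L, n, 0.5)
      pick <- sample(rows)
      if (nx > 0) vecs[pick[seq_len(nx)], ] <- sample_filler_vectors(nx, "X", dim)
      if (nx < n) vecs[pick[(nx + 1L):n], ] <- sample_filler_vectors(n - nx, "Y", dim)
    } else {
      vecs[rows, ] <- sample_filler_vectors(n, d, dim)
    }
  }
  rownames(vecs) <- as.vector(t(tok_mat))  # story-major: f0001.Subject, ...
  stories <- vector("list", n)
  for (i in seq_len(n)) {
    fr <- ds$frames[[i]]
    toks <- setNames(tok_mat[i, ], ROLES)
    if (ds$kind == "graph") {
      roles <- path_roles(ds$graph, fr$path)
      stories[[i]] <- instantiate_story(fr, ds$graph, as.list(toks[roles]), L = ds$L)
      # fresh fillers exist for all six roles even off-path (corpus accounting)
      stories[[i]]$binding <- as.list(toks)
    } else {
      stories[[i]] <- instantiate_template(ds$template, as.list(toks), fr$query_role,
                                           L = ds$L)
    }
  }
  lexicon <- rbind(ds$base_lexicon, vecs)
  if (zero_target) {
    for (s in stories) lexicon[s$target, ] <- 0
  }
  list(stories = stories, lexicon = lexicon)
}

#' Train a binding model
#'
#' Minimizes mean squared error between the 50-d prediction and the target
#' filler embedding with Adam at the model's learning rate, in minibatches
#' of `batch_size`. For generative datasets every epoch draws fresh filler
#' vectors. Training accuracy is monitored every `eval_every` epochs;
#' training stops early once `stop_train_acc` is reached (if given), when
#' validation accuracy has not improved for `patience` evaluations, or
#' after `epochs` epochs. Learning curves are stored on the returned model.
#'
#' @param model a `binding_model`.
#' @param dataset a `story_dataset` or `generative_dataset`.
#' @param epochs maximum epochs.
#' @param batch_size minibatch size (16).
#' @param eval_every epochs between accuracy evaluations.
#' @param stop_train_acc optional early-stop threshold on train accuracy.
#' @param patience evaluations without validation improvement tolerated.
#' @param validation optional dataset for validation accuracy.
#' @param monitor_stories cap on stories used for the accuracy monitor.
#' @param passes training passes over each freshly generated epoch of a
#'   generative dataset before the next is drawn (amortizes generation).
#' @param verbose print progress.
#' @return The trained `binding_model` (with `$curves`).
#' @export
train_model <- function(model, dataset, epochs = 100L, batch_size = 16L,
                        eval_every = 10L, stop_train_acc = NULL,
                        patience = Inf, validation = NULL,
                        monitor_stories = 256L, passes = 1L, verbose = FALSE) {
  curves <- model$curves
  best_val <- -Inf
  stale <- 0L
  done <- 0L
  while (done < epochs) {
    chunk <- min(eval_every, epochs - done)
    no_cands <- matrix(0L, 0, 0)
    if (inherits(dataset, "story_dataset")) {
      res <- sb_train_cpp(model$architecture, model$params, model$opt,
                          dataset$enc$X - 1L, dataset$enc$target - 1L,
                          dataset$lexicon, model$cfg, model$cfg$lr,
                          as.integer(batch_size), as.integer(chunk),
                          no_cands, 0L)
      model$params <- res$params; model$opt <- res$opt
      losses <- res$losses
    } else {
      losses <- numeric(0)
      fresh <- is.null(dataset$pools)
      n_base <- nrow(dataset$base_lexicon)
      pool_cache <- if (!fresh && identical(dataset$kind, "template")) {
        pool_epoch_cache(dataset)
      }
      left <- chunk
      while (left > 0L) {
        e_now <- min(as.integer(passes), left)
        left <- left - e_now
        if (!is.null(pool_cache)) {
          enc <- sample_pool_epoch_enc(dataset, pool_cache)
          res <- sb_train_cpp(model$architecture, model$params, model$opt,
                              enc$X - 1L, enc$target - 1L, dataset$base_lexicon,
                              model$cfg, model$cfg$lr,
                              as.integer(batch_size), e_now, no_cands, 0L)
          model$params <- res$params; model$opt <- res$opt
          losses <- c(losses, res$losses)
          next
        }
        ep <- sample_generative_epoch(dataset)
        enc <- encode_stories(ep$stories, ep$lexicon)
        if (fresh) {
          # per-story fresh-filler rows; minibatch loss competes against the
          # batch corpus (base vocabulary + the batch's fresh fillers)
          n <- nrow(enc$X)
          cands <- matrix(n_base + rep((seq_len(n) - 1L) * 6L, each = 6L) +
                            rep(1:6, n) - 1L, nrow = n, byrow = TRUE)
          res <- sb_train_cpp(model$architecture, model$params, model$opt,
                              enc$X - 1L, enc$target - 1L, ep$lexicon,
                              model$cfg, model$cfg$lr,
                              as.integer(batch_size), e_now, cands, n_base)
        } else {
          res <- sb_train_cpp(model$architecture, model$params, model$opt,
                              enc$X - 1L, enc$target - 1L, ep$lexicon,
                              model$cfg, model$cfg$lr,
                              as.integer(batch_size), e_now, no_cands, 0L)
        }
        model$params <- res$params; model$opt <- res$opt
        losses <- c(losses, res$losses)
      }
    }
    done <- done + chunk
    rep_tr <- if (monitor_stories > 0) {
      evaluate_model(model, dataset, max_stories = monitor_stories)
    } else list(accuracy = NA_real_)
    val_acc <- NA_real_
    if (!is.null(validation)) {
      rep_val <- evaluate_model(model, validation, max_stories = monitor_stories)
      val_acc <- rep_val$accuracy
    }
    curves <- rbind(curves, data.frame(epoch = model$opt$step, loss = mean(losses),
                                       train_acc = rep_tr$accuracy,
                                       val_acc = val_acc))
    if (verbose) {
      message(sprintf("[%s] epoch %d  loss %.5f  train acc %.3f  val acc %s",
                      model$architecture, done, mean(losses), rep_tr$accuracy,
                      ifelse(is.na(val_acc), "-", sprintf("%.3f", val_acc))))
    }
    if (!is.null(stop_train_acc) && isTRUE(rep_tr$accuracy >= stop_train_acc)) break
    if (!is.null(validation)) {
      if (val_acc > best_val + 1e-9) { best_val <- val_acc; stale <- 0L }
      else { stale <- stale + 1L; if (stale >= patience) break }
    }
  }
  model$curves <- curves
  model
}

#' Evaluate retrieval accuracy of a model on a dataset
#'
#' Predictions are mapped to the nearest corpus word by cosine similarity;
#' accuracy is the fraction matching the target token, reported overall and
#' split by query, together with the corpus-derived chance rate
#' `1/|corpus|`. Fixed-lexicon datasets use the full experiment vocabulary
#' as the corpus; generative datasets are scored in batches whose corpus is
#' the base vocabulary plus the batch's fresh fillers.
#'
#' @param model a `binding_model`.
#' @param dataset a `story_dataset` or `generative_dataset`.
#' @param max_stories evaluate at most this many stories.
#' @param epochs for generative datasets, number of fresh epochs to score.
#' @return An `eval_report`: list with `accuracy`, `per_query`, `chance`,
#'   `n`, `predicted`, `targets`.
#' @export
evaluate_model <- function(model, dataset, max_stories = Inf, epochs = 1L) {
  if (inherits(dataset, "story_dataset")) {
    n <- length(dataset$stories)
    idx <- if (n > max_stories) sample.int(n, max_stories) else seq_len(n)
    corpus <- build_corpus(dataset$lexicon)
    preds <- model_predict(model, dataset$enc$X[idx, , drop = FALSE], dataset$lexicon)
    predicted <- nearest_words(preds, corpus)
    targets <- rownames(dataset$lexicon)[dataset$enc$target[idx]]
    queries <- dataset$enc$query[idx]
    chance <- 1 / length(corpus$tokens)
  } else {
    predicted <- character(0); targets <- character(0); queries <- character(0)
    chance <- NA_real_
    for (e in seq_len(epochs)) {
      ep <- sample_generative_epoch(dataset)
      n <- length(ep$stories)
      idx <- if (n > max_stories) sample.int(n, min(n, max_stories)) else seq_len(n)
      enc <- encode_stories(ep$stories, ep$lexicon)
      preds <- model_predict(model, enc$X[idx, , drop = FALSE], ep$lexicon)
      bs <- dataset$batch_size
      base_vocab <- rownames(dataset$base_lexicon)
      for (s in seq(1, length(idx), by = bs)) {
        bidx <- idx[s:min(s + bs - 1L, length(idx))]
        corpus <- build_corpus(ep$lexicon, base_vocab = base_vocab,
                               batch = ep$stories[bidx])
        if (length(bidx) == bs || is.na(chance)) {
          chance <- 1 / length(corpus$tokens)
        }
        rows <- match(bidx, idx)
        predicted <- c(predicted,
                       nearest_words(preds[rows, , drop = FALSE], corpus))
      }
      targets <- c(targets, vapply(ep$stories[idx], `[[`, character(1), "target"))
      queries <- c(queries, vapply(ep$stories[idx], `[[`, character(1), "query"))
    }
  }
  hit <- predicted == targets
  per_query <- tapply(hit, queries, mean)
  structure(list(accuracy = mean(hit),
                 per_query = per_query[order(names(per_query))],
                 chance = chance, n = length(hit),
                 predicted = predicted, targets = targets, queries = queries),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.3f (chance %.4f, n = %d)\n",
              x$accuracy, x$chance, x$n))
  pq <- format(round(x$per_query, 3))
  cat("  per query:", paste(names(pq), pq, sep = "=", collapse = "  "), "\n")
  invisible(x)
}
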