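test_that("violation design excludes each filler from exactly one role", {
  for (n in c(1000L, 100L)) {
    d <- violation_design(n)
    expect_length(d$fillers, n)
    for (r in d$varied) {
      expect_length(d$train_pools[[r]], n * 3 / 4)
      expect_length(d$test_pools[[r]], n / 4)
      expect_length(intersect(d$train_pools[[r]], d$test_pools[[r]]), 0)
    }
    # each filler appears in exactly 3 of the 4 train pools
    membership <- vapply(d$varied, function(r) d$fillers %in% d$train_pools[[r]],
                         logical(n))
    expect_true(all(rowSums(membership) == 3))
  }
  expect_error(violation_design(10), "divisible")
})

test_that("violation test stories bind only correlation-breaking fillers", {
  set.seed(30)
  d <- violation_design(100)
  ds <- build_violation_datasets(d, epoch_size = 60, n_test = 60)
  ep <- schemabind:::sample_generative_epoch(ds$train)
  for (s in ep$stories) {
    for (r in d$varied) expect_true(s$binding[[r]] %in% d$train_pools[[r]])
  }
  for (s in ds$test$stories) {
    for (r in d$varied) expect_true(s$binding[[r]] %in% d$test_pools[[r]])
    expect_equal(s$binding$Dessert, "dessert0")
    expect_equal(s$binding$Drink, "drink0")
  }
  # the two epochs differ in combinations but share the fixed lexicon
  ep2 <- schemabind:::sample_generative_epoch(ds$train)
  expect_identical(ep$lexicon, ep2$lexicon)
})

test_that("retention training fillers carry the role-assigned distributions", {
  set.seed(31)
  ret <- build_retention_datasets(reps = 24)
  expect_equal(unname(ret$train_dists[c("Poet", "Subject")]), c("X", "Y"))
  ep <- schemabind:::sample_generative_epoch(ret$train)
  ev <- seq(1, 50, by = 2)
  updown <- function(tok, lex) {
    v <- lex[tok, ]
    sum(v[ev]) - sum(v[-ev]) > 0
  }
  poet_up <- vapply(ep$stories, function(s) updown(s$binding$Poet, ep$lexicon),
                    logical(1))
  subj_up <- vapply(ep$stories, function(s) updown(s$binding$Subject, ep$lexicon),
                    logical(1))
  expect_equal(mean(poet_up), 0.9, tolerance = 0.12)   # distribution X
  expect_equal(mean(subj_up), 0.1, tolerance = 0.6)    # distribution Y (rarely up)
  expect_lt(mean(subj_up), 0.35)

  # all-Z test fillers show no systematic asymmetry
  epz <- schemabind:::sample_generative_epoch(ret$tests$Z)
  z_up <- vapply(epz$stories, function(s) updown(s$binding$Poet, epz$lexicon),
                 logical(1))
  expect_gt(mean(z_up), 0.2); expect_lt(mean(z_up), 0.8)
})

test_that("bias reports have the documented sign convention", {
  set.seed(32)
  qroles <- rep(c("qpoet", "qsubject"), each = 50)
  # a predictor that always emits X-like samples: positive t everywhere
  x_preds <- sample_filler_vectors(100, "X")
  bx <- schemabind:::bias_report(x_preds, qroles)
  expect_true(all(bx$statistic > 0))
  y_preds <- sample_filler_vectors(100, "Y")
  by <- schemabind:::bias_report(y_preds, qroles)
  expect_true(all(by$statistic < 0))
  # the zero predictor is exactly unbiased
  b0 <- schemabind:::bias_report(matrix(0, 100, 50), qroles)
  expect_equal(b0$statistic, c(0, 0))
})

test_that("residuals reveal bias without breaking nearest-neighbor accuracy", {
  set.seed(33)
  vecs <- sample_filler_vectors(60, "Z")
  rownames(vecs) <- sprintf("w%02d", 1:60)
  corpus <- build_corpus(vecs)
  ev <- seq(1, 50, by = 2)
  shift <- rep(0, 50); shift[ev] <- 1
  # perfect predictions: zero residual t, perfect accuracy
  resid_perfect <- vecs - vecs
  expect_equal(schemabind:::even_odd_t(resid_perfect), 0)
  # small X-like perturbation (with noise): positive residual t, accuracy intact
  eps <- 0.05
  perturbed <- vecs + eps * matrix(shift, 60, 50, byrow = TRUE) +
    0.01 * matrix(rnorm(60 * 50), 60, 50)
  expect_gt(schemabind:::even_odd_t(perturbed - vecs), 0)
  got <- unname(apply(perturbed, 1, nearest_word, corpus = corpus))
  expect_equal(got, rownames(vecs))
})

test_that("ambiguous probes zero the queried filler only", {
  set.seed(34)
  ret <- build_retention_datasets(reps = 4)
  ep <- schemabind:::sample_generative_epoch(ret$tests$XY, zero_target = TRUE)
  for (s in ep$stories) {
    expect_equal(unname(ep$lexicon[s$target, ]), rep(0, 50))
    others <- setdiff(unlist(s$binding), s$target)
    expect_true(all(abs(rowSums(ep$lexicon[others, , drop = FALSE]^2) - 1) < 1e-9))
  }
})

test_that("shuffled stories keep the token multiset but a new stage order", {
  set.seed(35)
  tpl <- linear_frame()
  sh <- shuffle_stages(tpl)
  fillers <- list(Subject = "s", Friend = "f", Emcee = "e", Poet = "p",
                  Dessert = "d", Drink = "k")
  a <- instantiate_template(tpl, fillers, "Emcee")
  b <- instantiate_template(sh, fillers, "Emcee")
  expect_equal(sort(a$tokens), sort(b$tokens))
  expect_false(identical(a$tokens[a$tokens != "pad"], b$tokens[b$tokens != "pad"]))
})
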