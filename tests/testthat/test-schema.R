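test_that("coffee-shop graph combinatorics match the brute-force oracle", {
  g <- coffee_shop_graph()
  paths <- enumerate_paths(g)
  expect_length(paths, 24)
  expect_equal(lapply(paths, unlist), lapply(oracle_paths(g), unlist))

  frames <- enumerate_query_frames(g)
  expect_length(frames, 112)
  counts <- table(vapply(frames, function(f) f$query_role, character(1)))
  oracle <- oracle_role_counts(g)
  expect_equal(counts[["Subject"]], 24)
  expect_equal(counts[["Friend"]], 24)
  expect_equal(counts[["Poet"]], 24)
  expect_equal(counts[["Emcee"]], 12)
  expect_equal(counts[["Drink"]], 16)
  expect_equal(counts[["Dessert"]], 12)
  for (r in names(oracle)) expect_equal(unname(counts[[r]]), unname(oracle[[r]]))

  # every path passes through the mandatory states
  for (p in paths) expect_true(all(c("BEGIN", "SIT", "POETRY", "END") %in% p))
  # frames querying Emcee are exactly the paths through INTRO
  emcee <- Filter(function(f) f$query_role == "Emcee", frames)
  expect_true(all(vapply(emcee, function(f) "INTRO" %in% f$path, logical(1))))
})

test_that("path enumeration handles toy graphs and rejects cycles", {
  expect_length(enumerate_paths(chain_graph()), 1)
  d <- enumerate_paths(diamond_graph())
  expect_length(d, 2)
  expect_equal(lapply(d, unlist), lapply(oracle_paths(diamond_graph()), unlist))
  expect_error(schema_graph(
    states = list(A = list(keyword = "a", roles = character(0)),
                  B = list(keyword = "b", roles = character(0))),
    edges = list(A = "B", B = "A"), start = "A", terminal = "B"),
    "cycle")
})

test_that("sampled paths follow the product-of-out-degree law", {
  g <- coffee_shop_graph()
  set.seed(101)
  expect_equal(sample_path(chain_graph()), c("A", "B", "C"))
  n <- 10000
  keys <- replicate(n, paste(sample_path(g), collapse = "|"))
  # fraction of paths skipping ORDER_DRINK: out-degree of BEGIN is 2
  frac_sit <- mean(grepl("^BEGIN\\|SIT", keys))
  expect_lt(abs(frac_sit - 0.5), 3 * sqrt(0.25 / n))
  # chi-squared goodness of fit against analytic path probabilities
  paths <- enumerate_paths(g)
  probs <- vapply(paths, function(p) {
    prod(vapply(p, function(v) 1 / max(1, length(g$edges[[v]])), numeric(1)))
  }, numeric(1))
  expect_equal(sum(probs), 1)
  obs <- table(factor(keys, levels = vapply(paths, paste, "", collapse = "|")))
  pval <- suppressWarnings(chisq.test(obs, p = probs)$p.value)
  expect_gt(pval, 0.01)
})

test_that("story instantiation reproduces the printed example and pads correctly", {
  g <- coffee_shop_graph()
  fr <- story_frame(c("BEGIN", "SIT", "POETRY", "PERFORM", "GOODBYE", "END"),
                    "Poet")
  fillers <- list(Subject = "alice", Friend = "bob", Poet = "chris")
  set.seed(5)
  s <- instantiate_story(fr, g, fillers, L = 25)
  body <- s$tokens[s$tokens != "pad"]
  expect_equal(body, c("begin", "alice", "sit", "alice", "bob",
                       "poet_performs", "chris", "subject_performs", "alice",
                       "bob", "say_goodbye", "alice", "bob", "end", "alice",
                       "qpoet"))
  expect_equal(s$query, "qpoet")
  expect_equal(s$target, "chris")
  expect_length(s$tokens, 25)
  expect_equal(s$tokens[25], "qpoet")

  # L exactly body + 2: one pad inside the body, nothing else
  s2 <- instantiate_story(fr, g, fillers, L = 17)
  expect_length(s2$tokens, 17)
  expect_equal(sum(s2$tokens == "pad"), 1)

  expect_error(instantiate_story(fr, g, list(Subject = "alice", Friend = "bob")),
               "no filler")
  expect_error(instantiate_story(fr, g, fillers, L = 16), "too short")
})

test_that("padding position is uniform over body insertion points", {
  g <- coffee_shop_graph()
  fr <- story_frame(c("BEGIN", "SIT", "POETRY", "DECLINE", "GOODBYE", "END"),
                    "Subject")
  fillers <- list(Subject = "s", Friend = "f", Poet = "p")
  set.seed(77)
  pos <- replicate(2000, {
    s <- instantiate_story(fr, g, fillers, L = 20)
    body_end <- max(which(s$tokens != "pad")[-length(s$tokens)])
    which(s$tokens == "pad")[1]
  })
  # insertion points: 0..body_len inclusive -> body_len + 1 equally likely slots
  obs <- table(factor(pos, levels = sort(unique(pos))))
  expect_length(obs, 15)  # body of 14 tokens -> 15 insertion points
  pval <- chisq.test(obs)$p.value
  expect_gt(pval, 0.01)
})

test_that("every instance has one in-body pad, fixed length, query last", {
  g <- coffee_shop_graph()
  set.seed(42)
  frames <- enumerate_query_frames(g)
  for (i in sample(length(frames), 20)) {
    fr <- frames[[i]]
    roles <- unique(unlist(lapply(g$states[fr$path], `[[`, "roles")))
    fillers <- setNames(as.list(paste0("x", seq_along(roles))), roles)
    s <- instantiate_story(fr, g, fillers)
    expect_length(s$tokens, story_length(g))
    expect_match(s$tokens[length(s$tokens)], "^q")
    body_region <- seq_len(max(which(!s$tokens %in% "pad")) )
    # exactly one pad strictly inside the emitted body (before tail padding)
    first_pad_run_start <- length(s$tokens) - 1
    non_pad <- which(s$tokens != "pad")
    body_last <- non_pad[length(non_pad) - 1]  # last body token before query
    expect_equal(sum(s$tokens[seq_len(body_last)] == "pad") <= 1, TRUE)
  }
})

test_that("linear frame and its stage shuffle match the fixed templates", {
  tpl <- linear_frame()
  expect_length(tpl$value, 13)
  expect_equal(sum(tpl$value == "Subject" & tpl$kind == "role"), 2)
  expect_equal(template_roles(tpl),
               c("Subject", "Friend", "Emcee", "Poet", "Drink", "Dessert"))
  fillers <- list(Subject = "s", Friend = "f", Emcee = "e", Poet = "p",
                  Dessert = "d", Drink = "k")
  set.seed(3)
  inst <- instantiate_template(tpl, fillers, "Poet")
  body <- inst$tokens[inst$tokens != "pad"]
  expect_equal(body, c("begin", "s", "sit", "s", "f", "announce", "e",
                       "perform", "p", "consume", "d", "k", "goodbye", "qpoet"))

  sh <- shuffle_stages(tpl)
  expect_equal(sh$value, c("consume", "Dessert", "Drink", "goodbye",
                           "begin", "Subject", "sit", "Subject", "Friend",
                           "announce", "Emcee", "perform", "Poet"))
  expect_equal(sort(sh$value), sort(tpl$value))
  expect_equal(sort(shuffle_stages(shuffle_stages(tpl))$value), sort(tpl$value))
})

test_that("stories round-trip through JSON lines", {
  g <- coffee_shop_graph()
  set.seed(9)
  fr <- story_frame(c("BEGIN", "SIT", "POETRY", "DECLINE", "GOODBYE", "END"),
                    "Friend")
  stories <- lapply(1:3, function(i) {
    instantiate_story(fr, g, list(Subject = "a", Friend = "b", Poet = "c"))
  })
  path <- tempfile(fileext = ".jsonl")
  write_stories_jsonl(stories, path)
  back <- read_stories_jsonl(path)
  expect_equal(length(back), 3)
  for (i in 1:3) {
    expect_equal(back[[i]]$tokens, stories[[i]]$tokens)
    expect_equal(back[[i]]$target, stories[[i]]$target)
  }
  unlink(path)
})
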