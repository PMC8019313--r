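#' Sample filler vectors from distributions X, Y, or Z
#'
#' All word vectors start from independent standard-normal coordinates and
#' are normalized to unit Euclidean norm. Distributions X and Y additionally
#' shift every even coordinate (0-based: coordinates 0, 2, ..., dim-2) of a
#' vector by +0.5 or -0.5 before normalization; the sign is a single coin
#' per vector, +0.5 with probability 0.9 under X and 0.1 under Y.
#' Distribution Z applies no shift. X- and Y-vectors therefore carry a
#' role-correlated even/odd asymmetry that the correlation-retention
#' experiments exploit.
#'
#' @param n number of vectors.
#' @param dist `"Z"` (default), `"X"`, or `"Y"`.
#' @param dim embedding dimension (50).
#' @return `n` x `dim` matrix with unit-norm rows.
#' @export
sample_filler_vectors <- function(n, dist = c("Z", "X", "Y"), dim = 50L) {
  dist <- match.arg(dist)
  m <- matrix(rnorm(n * dim), nrow = n, ncol = dim)
  if (dist != "Z") {
    p_plus <- if (dist == "X") 0.9 else 0.1
    sign <- ifelse(runif(n) < p_plus, 0.5, -0.5)
    even <- seq(1L, dim, by = 2L)  # 0-based even coordinates
    m[, even] <- m[, even] + sign
  }
  unit_rows(m)
}

unit_rows <- function(m) {
  m / sqrt(rowSums(m^2))
}

#' Build a lexicon of random unit-norm embeddings
#'
#' @param tokens character vector of vocabulary words.
#' @param dim embedding dimension.
#' @param dist distribution for every token (`"Z"`, `"X"`, `"Y"`); frame
#'   vocabularies use `"Z"`.
#' @return `length(tokens)` x `dim` matrix with `rownames = tokens`.
#' @export
build_lexicon <- function(tokens, dim = 50L, dist = "Z") {
  stopifnot(!anyDuplicated(tokens))
  m <- sample_filler_vectors(length(tokens), dist = dist, dim = dim)
  rownames(m) <- tokens
  m
}

#' Base (frame) vocabulary of a schema graph
#'
#' The non-filler words of a graph experiment: every state keyword, the six
#' query tokens, and the padding word. `n_total` pads the list with reserved
#' tokens so the base corpus has a fixed size; the unlimited-filler corpus
#' accounting (base 30 plus six fresh fillers per batch story) uses the
#' default of 30.
#'
#' @param graph a `schema_graph`.
#' @param n_total total base-vocabulary size (reserved tokens appended).
#' @return Character vector of tokens.
#' @export
base_vocabulary <- function(graph, n_total = 30L) {
  core <- c(vapply(graph$states, `[[`, character(1), "keyword"),
            vapply(ROLES, query_token, character(1)),
            PAD_TOKEN)
  core <- unname(core)
  if (n_total < length(core)) stop("n_total smaller than the core vocabulary")
  c(core, sprintf("reserved%02d", seq_len(n_total - length(core))))
}

#' Assemble a retrieval corpus
#'
#' The candidate set for nearest-neighbor retrieval. For fixed-embedding
#' experiments this is the whole experiment lexicon. For unlimited-filler
#' experiments pass the evaluation `batch`: the corpus is then the base
#' vocabulary plus the six freshly generated filler vectors of every story
#' in the batch (so a base vocabulary of 30 and a validation batch of 16
#' give 30 + 16 x 6 = 126 candidates).
#'
#' @param lexicon embedding matrix with token rownames.
#' @param base_vocab tokens always included (default: all of `lexicon`).
#' @param batch optional list of `story_instance`s whose per-story filler
#'   tokens (rows of `lexicon` outside `base_vocab`) are added.
#' @return A `retrieval_corpus`: list with `tokens` and `vectors`.
#' @export
build_corpus <- function(lexicon, base_vocab = rownames(lexicon), batch = NULL) {
  tokens <- base_vocab
  if (!is.null(batch)) {
    fresh <- unlist(lapply(batch, function(s) unlist(s$binding, use.names = FALSE)))
    tokens <- c(tokens, setdiff(unique(fresh), base_vocab))
  }
  missing <- setdiff(tokens, rownames(lexicon))
  if (length(missing) > 0) {
    stop("tokens absent from the lexicon: ", paste(head(missing, 5), collapse = ", "))
  }
  structure(list(tokens = tokens, vectors = lexicon[tokens, , drop = FALSE]),
            class = "retrieval_corpus")
}

#' @export
print.retrieval_corpus <- function(x, ...) {
  cat("<retrieval_corpus>", length(x$tokens), "candidates, chance rate",
      sprintf("%.3g%%", 100 / length(x$tokens)), "\n")
  invisible(x)
}

cosine_to_corpus <- function(prediction, corpus) {
  pn <- sqrt(sum(prediction^2))
  if (pn == 0) stop("prediction vector is zero; cosine similarity undefined")
  v <- corpus$vectors
  as.vector(v %*% prediction) / (sqrt(rowSums(v^2)) * pn)
}

#' Nearest corpus word by cosine similarity
#'
#' @param prediction a 50-d prediction vector (any positive scaling gives
#'   the same answer).
#' @param corpus a `retrieval_corpus`.
#' @return The token whose embedding has the highest cosine similarity;
#'   ties broken by lowest corpus index.
#' @export
nearest_word <- function(prediction, corpus) {
  corpus$tokens[which.max(cosine_to_corpus(prediction, corpus))]
}

# Vectorized retrieval for a matrix of predictions (rows). Cosine argmax
# per row; the per-row prediction norm does not change the argmax, so only
# candidate norms are divided out.
nearest_words <- function(preds, corpus) {
  v <- corpus$vectors
  sims <- preds %*% t(v / sqrt(rowSums(v^2)))
  corpus$tokens[max.col(sims, ties.method = "first")]
}

#' Ranking score of the true target under a prediction
#'
#' Corpus words are ranked by descending cosine similarity to the
#' prediction; the score is `1 - rank/|corpus|` with a 0-based rank, so a
#' prediction nearest to the target scores 1 and an uninformative prediction
#' scores 0.5 + 1/(2|corpus|), i.e. 0.5 for large corpora.
#'
#' @param prediction prediction vector.
#' @param target_token true token; must be in the corpus.
#' @param corpus a `retrieval_corpus`.
#' @return Score in (0, 1].
#' @export
ranking_score <- function(prediction, target_token, corpus) {
  pos <- match(target_token, corpus$tokens)
  if (is.na(pos)) stop("target token not in corpus: ", target_token)
  sims <- cosine_to_corpus(prediction, corpus)
  rank <- sum(sims > sims[pos])  # 0-based; ties rank the target first
  1 - rank / length(corpus$tokens)
}
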