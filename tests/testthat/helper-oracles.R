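# Independent brute-force oracles and small fixtures used across tests.

# Iterative stack-based path enumeration, independent of enumerate_paths()'s
# recursive implementation.
oracle_paths <- function(graph) {
  out <- list()
  stack <- list(graph$start)
  while (length(stack) > 0) {
    path <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    v <- path[length(path)]
    if (v == graph$terminal) {
      out[[length(out) + 1]] <- path
      next
    }
    # push in reverse so lexicographic order pops first
    for (w in rev(graph$edges[[v]])) stack[[length(stack) + 1]] <- c(path, w)
  }
  out
}

oracle_role_counts <- function(graph) {
  counts <- integer(0)
  for (path in oracle_paths(graph)) {
    roles <- unique(unlist(lapply(graph$states[path], `[[`, "roles")))
    for (r in roles) counts[r] <- if (is.na(counts[r])) 1L else counts[r] + 1L
  }
  counts
}

# A tiny model of any architecture, for contract/gradient tests.
tiny_model <- function(arch, hidden = 5L, dim = 7L, ...) {
  binding_model(arch, hidden = hidden, input_dim = dim, output_dim = dim,
                mem_slots = 6L, mem_width = 4L, ...)
}

tiny_lexicon <- function(dim = 7L, n = 8L) {
  build_lexicon(letters[seq_len(n)], dim = dim)
}

diamond_graph <- function() {
  schema_graph(
    states = list(A = list(keyword = "a", roles = "Subject"),
                  B = list(keyword = "b", roles = character(0)),
                  C = list(keyword = "c", roles = character(0)),
                  D = list(keyword = "d", roles = character(0))),
    edges = list(A = c("B", "C"), B = "D", C = "D"),
    start = "A", terminal = "D")
}

chain_graph <- function() {
  schema_graph(
    states = list(A = list(keyword = "a", roles = "Subject"),
                  B = list(keyword = "b", roles = character(0)),
                  C = list(keyword = "c", roles = character(0))),
    edges = list(A = "B", B = "C"),
    start = "A", terminal = "C")
}
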