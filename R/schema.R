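#' @useDynLib schemabind, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd setNames
#' @importFrom utils head tail
NULL

# Canonical role order used throughout (query tokens, reports, probes).
ROLES <- c("Subject", "Friend", "Emcee", "Poet", "Drink", "Dessert")

#' Construct an event-schema graph
#'
#' A schema is a directed acyclic graph of story states. Each state carries a
#' frame keyword (emitted verbatim into stories) and an ordered list of role
#' slots that are substituted with fillers in each story instance. Stories
#' are maximal start-to-terminal paths; at states with several outgoing
#' edges each transition is equally likely.
#'
#' @param states named list; each element is `list(keyword =, roles =)`
#'   where `roles` is a (possibly empty) character vector of role slots in
#'   emission order.
#' @param edges named list mapping a state name to the ordered character
#'   vector of its successor names. Terminal state has no entry.
#' @param start,terminal state names.
#' @return An object of class `schema_graph`.
#' @export
schema_graph <- function(states, edges, start, terminal) {
  stopifnot(is.list(states), !is.null(names(states)))
  for (nm in names(edges)) {
    bad <- setdiff(edges[[nm]], names(states))
    if (length(bad) > 0) {
      stop("edge from ", nm, " to unknown state(s): ", paste(bad, collapse = ", "))
    }
  }
  g <- structure(
    list(states = states, edges = edges, start = start, terminal = terminal),
    class = "schema_graph"
  )
  if (!is_acyclic(g)) stop("schema graph contains a cycle")
  g
}

#' @export
print.schema_graph <- function(x, ...) {
  cat("<schema_graph>", length(x$states), "states,",
      sum(lengths(x$edges)), "edges;",
      x$start, "->", x$terminal, "\n")
  invisible(x)
}

is_acyclic <- function(graph) {
  color <- setNames(rep(0L, length(graph$states)), names(graph$states))
  visit <- function(v) {
    if (color[[v]] == 1L) return(FALSE)     # back edge
    if (color[[v]] == 2L) return(TRUE)
    color[[v]] <<- 1L
    for (w in graph$edges[[v]]) if (!visit(w)) return(FALSE)
    color[[v]] <<- 2L
    TRUE
  }
  visit(graph$start)
}

#' The coffee-shop world schema
#'
#' The 11-state schema used by all graph-based experiments: a visit to a
#' coffee shop with an open-mic poetry reading. Role slots follow the story
#' states (e.g. SIT seats the Subject with a Friend, INTRO has an Emcee
#' introduce a Poet). The graph has exactly 24 start-to-terminal paths and
#' 112 answerable (path, queried role) pairs.
#'
#' @return A `schema_graph`.
#' @export
coffee_shop_graph <- function() {
  states <- list(
    BEGIN         = list(keyword = "begin",            roles = "Subject"),
    ORDER_DRINK   = list(keyword = "order_drink",      roles = c("Subject", "Drink")),
    EXPENSIVE     = list(keyword = "too_expensive",    roles = "Subject"),
    SIT           = list(keyword = "sit",              roles = c("Subject", "Friend")),
    INTRO         = list(keyword = "emcee_intro",      roles = c("Emcee", "Poet")),
    POETRY        = list(keyword = "poet_performs",    roles = "Poet"),
    DECLINE       = list(keyword = "subject_declines", roles = "Subject"),
    PERFORM       = list(keyword = "subject_performs", roles = c("Subject", "Friend")),
    GOODBYE       = list(keyword = "say_goodbye",      roles = c("Subject", "Friend")),
    ORDER_DESSERT = list(keyword = "order_dessert",    roles = c("Subject", "Dessert")),
    END           = list(keyword = "end",              roles = "Subject")
  )
  edges <- list(
    BEGIN         = c("ORDER_DRINK", "SIT"),
    ORDER_DRINK   = c("EXPENSIVE", "SIT"),
    EXPENSIVE     = "SIT",
    SIT           = c("INTRO", "POETRY"),
    INTRO         = "POETRY",
    POETRY        = c("DECLINE", "PERFORM"),
    DECLINE       = c("GOODBYE", "ORDER_DESSERT"),
    PERFORM       = c("GOODBYE", "ORDER_DESSERT"),
    GOODBYE       = "END",
    ORDER_DESSERT = "END"
  )
  schema_graph(states, edges, start = "BEGIN", terminal = "END")
}

#' Enumerate all start-to-terminal paths of a schema graph
#'
#' Depth-first enumeration, lexicographic in the order successors are listed
#' on each state, so the result is deterministic.
#'
#' @param graph a `schema_graph`.
#' @return List of character vectors of state names.
#' @export
enumerate_paths <- function(graph) {
  if (!is_acyclic(graph)) stop("schema graph contains a cycle")
  paths <- list()
  walk <- function(prefix) {
    v <- prefix[length(prefix)]
    if (v == graph$terminal) {
      paths[[length(paths) + 1L]] <<- prefix
      return(invisible())
    }
    for (w in graph$edges[[v]]) walk(c(prefix, w))
  }
  walk(graph$start)
  paths
}

#' Enumerate answerable query frames
#'
#' One frame per (path, role) pair where the role occurs in at least one
#' state on the path, i.e. the query can be answered from the story itself.
#'
#' @param graph a `schema_graph`.
#' @return List of `story_frame` objects (fields `path`, `query_role`).
#' @export
enumerate_query_frames <- function(graph) {
  frames <- list()
  for (path in enumerate_paths(graph)) {
    present <- unique(unlist(lapply(graph$states[path], `[[`, "roles")))
    for (role in ROLES[ROLES %in% present]) {
      frames[[length(frames) + 1L]] <- story_frame(path, role)
    }
  }
  frames
}

#' @rdname enumerate_query_frames
#' @param path character vector of state names.
#' @param query_role the role the query asks for.
#' @export
story_frame <- function(path, query_role) {
  structure(list(path = path, query_role = query_role), class = "story_frame")
}

#' Sample one path through a schema graph
#'
#' Starts at the start state and repeatedly picks a uniformly random
#' outgoing edge until the terminal state is reached, so each path is drawn
#' with probability equal to the product of 1/out-degree over its states.
#' Uses the R random number generator; seed with [set.seed()].
#'
#' @param graph a `schema_graph`.
#' @return Character vector of state names.
#' @export
sample_path <- function(graph) {
  path <- graph$start
  v <- graph$start
  while (v != graph$terminal) {
    succ <- graph$edges[[v]]
    v <- if (length(succ) == 1L) succ else succ[sample.int(length(succ), 1L)]
    path <- c(path, v)
  }
  path
}

PAD_TOKEN <- "pad"

query_token <- function(role) paste0("q", tolower(role))

#' Instantiate a story frame into a token sequence
#'
#' Walks the frame's path emitting each state's keyword followed by that
#' state's fillers in slot order, inserts the padding word at one uniformly
#' random position inside the body (ends included), right-pads the sequence
#' so every instance has the same total length `L`, and appends the query
#' token last.
#'
#' @param frame a `story_frame`.
#' @param graph the `schema_graph` the frame was drawn from.
#' @param fillers named character vector or list mapping each role on the
#'   path to a filler token.
#' @param L total sequence length including the query token. Default:
#'   [story_length()] of the graph.
#' @return A `story_instance`: list with `tokens` (length `L`), `query`,
#'   `target`, `binding`, and `frame`.
#' @export
instantiate_story <- function(frame, graph, fillers, L = story_length(graph)) {
  fillers <- as.list(fillers)
  body <- character(0)
  for (state_name in frame$path) {
    st <- graph$states[[state_name]]
    body <- c(body, st$keyword)
    for (role in st$roles) {
      if (is.null(fillers[[role]])) {
        stop("no filler supplied for role ", role, " on state ", state_name)
      }
      body <- c(body, fillers[[role]])
    }
  }
  finish_story(body, frame$query_role, fillers, L,
               frame_id = paste(c(frame$path, frame$query_role), collapse = "|"))
}

# Shared tail: insert one pad inside the body, tail-pad to L-1, append query.
finish_story <- function(body, query_role, fillers, L, frame_id) {
  if (length(body) + 2L > L) {
    stop("sequence length L = ", L, " too short for a body of ",
         length(body), " tokens plus padding and query")
  }
  pos <- sample.int(length(body) + 1L, 1L) - 1L  # insert after `pos` tokens
  body <- append(body, PAD_TOKEN, after = pos)
  tokens <- c(body, rep(PAD_TOKEN, L - 1L - length(body)), query_token(query_role))
  structure(
    list(tokens = tokens,
         query = query_token(query_role),
         target = fillers[[query_role]],
         binding = fillers,
         frame = frame_id),
    class = "story_instance"
  )
}

#' @export
print.story_instance <- function(x, ...) {
  cat("<story_instance>", paste(x$tokens, collapse = " "),
      "=>", x$target, "\n")
  invisible(x)
}

#' Smallest common sequence length for a schema graph
#'
#' Longest path body plus one inserted padding word plus the query token.
#'
#' @param graph a `schema_graph`.
#' @return Integer length `L`.
#' @export
story_length <- function(graph) {
  body_len <- function(path) {
    sum(vapply(graph$states[path],
               function(s) 1L + length(s$roles), integer(1)))
  }
  max(vapply(enumerate_paths(graph), body_len, integer(1))) + 2L
}

#' The fixed linear story template
#'
#' The single-path, 13-slot story used by the correlation-violation and
#' correlation-retention experiments:
#' `begin [Subject] sit [Subject] [Friend] announce [Emcee] perform [Poet]
#' consume [Dessert] [Drink] goodbye`. The Subject slot occurs twice.
#'
#' @return A `story_template`: list with parallel vectors `kind`
#'   (`"word"`/`"role"`) and `value` (keyword or role name).
#' @export
linear_frame <- function() {
  slots <- c("begin", "<Subject>", "sit", "<Subject>", "<Friend>",
             "announce", "<Emcee>", "perform", "<Poet>",
             "consume", "<Dessert>", "<Drink>", "goodbye")
  template_from_slots(slots)
}

template_from_slots <- function(slots) {
  is_role <- grepl("^<.*>$", slots)
  structure(
    list(kind = ifelse(is_role, "role", "word"),
         value = ifelse(is_role, gsub("[<>]", "", slots), slots)),
    class = "story_template"
  )
}

#' Shuffle the stages of the linear template
#'
#' Returns the fixed stage-shuffled variant used by the shuffled-story
#' stress test: the final `consume ... goodbye` stage is moved to the front
#' (`consume [Dessert] [Drink] goodbye begin [Subject] sit [Subject]
#' [Friend] announce [Emcee] perform [Poet]`). The token multiset is
#' unchanged; only stage order differs.
#'
#' @param template a `story_template` (the linear frame).
#' @return A `story_template`.
#' @export
shuffle_stages <- function(template) {
  n <- length(template$value)
  # stage boundary before "consume" (slot 10 of 13 in the linear frame)
  cut <- which(template$kind == "word" & template$value == "consume")
  if (length(cut) != 1L) stop("template is not the linear frame")
  idx <- c(seq(cut, n), if (cut > 1L) seq_len(cut - 1L))
  structure(list(kind = template$kind[idx], value = template$value[idx]),
            class = "story_template")
}

#' Instantiate a story template
#'
#' Same contract as [instantiate_story()] but for fixed templates: keywords
#' are emitted verbatim, role slots are substituted from `fillers`, one
#' padding word is inserted at a uniformly random body position, the body
#' is right-padded to length `L - 1`, and the query token comes last.
#'
#' @param template a `story_template`.
#' @param fillers named character vector/list mapping roles to filler tokens.
#' @param query_role role to query.
#' @param L total sequence length; default body + 2 (no slack padding).
#' @return A `story_instance`.
#' @export
instantiate_template <- function(template, fillers, query_role,
                                 L = length(template$value) + 2L) {
  fillers <- as.list(fillers)
  body <- character(length(template$value))
  for (i in seq_along(template$value)) {
    if (template$kind[i] == "word") {
      body[i] <- template$value[i]
    } else {
      role <- template$value[i]
      if (is.null(fillers[[role]])) stop("no filler supplied for role ", role)
      body[i] <- fillers[[role]]
    }
  }
  if (!query_role %in% template$value[template$kind == "role"]) {
    stop("query role ", query_role, " does not occur in the template")
  }
  finish_story(body, query_role, fillers, L,
               frame_id = paste(template$value, collapse = "|"))
}

#' Roles present on a template or path
#' @param x a `story_template` or `schema_graph` path with graph.
#' @return Character vector of role names in canonical order.
#' @export
template_roles <- function(x) {
  ROLES[ROLES %in% x$value[x$kind == "role"]]
}

path_roles <- function(graph, path) {
  present <- unique(unlist(lapply(graph$states[path], `[[`, "roles")))
  ROLES[ROLES %in% present]
}

#' Serialize stories as JSON lines
#'
#' One JSON object per story instance with fields `tokens`, `query`,
#' `target`, `binding`, and `frame`.
#'
#' @param stories list of `story_instance` objects.
#' @param path output file path.
#' @export
write_stories_jsonl <- function(stories, path) {
  lines <- vapply(stories, function(s) {
    jsonlite::toJSON(list(tokens = s$tokens, query = s$query,
                          target = s$target, binding = s$binding,
                          frame = s$frame),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
}

#' @rdname write_stories_jsonl
#' @return `read_stories_jsonl` returns a list of `story_instance` objects.
#' @export
read_stories_jsonl <- function(path) {
  lapply(readLines(path), function(line) {
    rec <- jsonlite::fromJSON(line)
    structure(list(tokens = unlist(rec$tokens), query = rec$query,
                   target = rec$target, binding = as.list(rec$binding),
                   frame = rec$frame),
              class = "story_instance")
  })
}
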