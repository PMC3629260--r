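#' Sentence dependency graph
#'
#' A `dep_graph` models the dependency parse of one sentence as a labeled,
#' directed multigraph: nodes are the sentence tokens, edges are
#' governor-to-dependent grammatical relations. Parallel edges with distinct
#' labels and cycles are permitted (collapsed Stanford dependencies produce
#' both), and the graph may be disconnected. Token indices are 1-based
#' sentence positions and need not be contiguous: a graph built from a parse
#' fragment keeps the original positions.
#'
#' @param tokens data.frame with columns `index` (integer, unique, >= 1),
#'   `surface` (non-empty character), and optionally `lemma`, `pos`,
#'   `is_entity`, `entity_ref`, `start`, `end` (character offsets into the
#'   enclosing document, 0-based half-open). Missing optional columns are
#'   filled with defaults.
#' @param edges data.frame with columns `governor`, `dependent` (token
#'   indices) and `label` (non-empty character). May have zero rows.
#' @param sentence_id character scalar identifying the sentence.
#' @return An object of class `dep_graph`.
#' @export
dep_graph <- function(tokens = NULL, edges = NULL, sentence_id = "s1") {
  if (is.null(tokens)) {
    tokens <- data.frame(index = integer(), surface = character())
  }
  tokens <- as.data.frame(tokens, stringsAsFactors = FALSE)
  if (nrow(tokens)) {
    if (is.null(tokens$index) || is.null(tokens$surface)) {
      integrity_error("tokens must carry 'index' and 'surface' columns")
    }
  }
  tokens$index <- as.integer(tokens$index %||% integer())
  tokens$surface <- as.character(tokens$surface %||% character())
  n <- nrow(tokens)
  fill <- function(col, default) {
    if (is.null(tokens[[col]])) rep(default, n) else tokens[[col]]
  }
  tokens$lemma <- as.character(fill("lemma", ""))
  tokens$pos <- as.character(fill("pos", ""))
  tokens$is_entity <- as.logical(fill("is_entity", FALSE))
  tokens$entity_ref <- as.character(fill("entity_ref", NA_character_))
  tokens$start <- as.integer(fill("start", NA_integer_))
  tokens$end <- as.integer(fill("end", NA_integer_))
  tokens <- tokens[order(tokens$index),
                   c("index", "surface", "lemma", "pos", "is_entity",
                     "entity_ref", "start", "end"),
                   drop = FALSE]
  rownames(tokens) <- NULL
  if (anyDuplicated(tokens$index)) {
    integrity_error("duplicate token indices in dep_graph")
  }
  if (n && any(tokens$index < 1L)) integrity_error("token indices must be >= 1")
  if (n && any(!nzchar(tokens$surface))) {
    integrity_error("token surfaces must be non-empty")
  }
  if (any(tokens$is_entity != !is.na(tokens$entity_ref))) {
    integrity_error("is_entity must be true iff entity_ref is set")
  }

  if (is.null(edges)) {
    edges <- data.frame(governor = integer(), dependent = integer(),
                        label = character())
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) && (is.null(edges$governor) || is.null(edges$dependent) ||
                      is.null(edges$label))) {
    integrity_error("edges must carry 'governor', 'dependent', 'label'")
  }
  edges$governor <- as.integer(edges$governor %||% integer())
  edges$dependent <- as.integer(edges$dependent %||% integer())
  edges$label <- as.character(edges$label %||% character())
  edges <- edges[, c("governor", "dependent", "label"), drop = FALSE]
  rownames(edges) <- NULL
  if (nrow(edges)) {
    bad <- !(edges$governor %in% tokens$index) |
      !(edges$dependent %in% tokens$index)
    if (any(bad)) {
      integrity_error(sprintf(
        "edge %d references a token absent from the graph", which(bad)[1]))
    }
    if (any(!nzchar(edges$label))) integrity_error("edge labels must be non-empty")
  }

  structure(
    list(sentence_id = as.character(sentence_id), tokens = tokens,
         edges = edges, cache = new.env(parent = emptyenv())),
    class = "dep_graph")
}

#' @export
print.dep_graph <- function(x, ...) {
  cat(sprintf("<dep_graph '%s': %d tokens, %d edges, %d entity tokens>\n",
              x$sentence_id, nrow(x$tokens), nrow(x$edges),
              sum(x$tokens$is_entity)))
  invisible(x)
}

#' Number of tokens in a dependency graph
#' @param g a `dep_graph`.
#' @return integer count.
#' @export
n_tokens <- function(g) nrow(g$tokens)

token_row <- function(g, index) {
  i <- match(index, g$tokens$index)
  if (is.na(i)) lookup_error(sprintf("token index %s not in graph", index))
  g$tokens[i, , drop = FALSE]
}

has_token <- function(g, index) index %in% g$tokens$index

## Internal index structures, memoized on the graph's cache environment.
## pos: token index -> 1..n rank; adj: per node, matrix of (neighbour rank,
## edge row, +1 if the node is the governor of that edge).
dg_index <- function(g) {
  if (!is.null(g$cache$idx)) return(g$cache$idx)
  idx_vec <- g$tokens$index
  n <- length(idx_vec)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- matrix(integer(), ncol = 3)
  if (nrow(g$edges)) {
    gv <- match(g$edges$governor, idx_vec)
    dp <- match(g$edges$dependent, idx_vec)
    for (e in seq_len(nrow(g$edges))) {
      adj[[gv[e]]] <- rbind(adj[[gv[e]]], c(dp[e], e, 1L))
      adj[[dp[e]]] <- rbind(adj[[dp[e]]], c(gv[e], e, 0L))
    }
  }
  g$cache$idx <- list(index = idx_vec, adj = adj)
  g$cache$idx
}

## Undirected all-pairs shortest path length matrix (igraph backend);
## parallel edges do not change lengths. Inf marks disconnected pairs.
dg_dist_matrix <- function(g) {
  if (!is.null(g$cache$dist)) return(g$cache$dist)
  n <- nrow(g$tokens)
  labels <- as.character(g$tokens$index)
  if (n == 0) {
    d <- matrix(numeric(), 0, 0)
  } else if (nrow(g$edges) == 0) {
    d <- matrix(Inf, n, n, dimnames = list(labels, labels))
    diag(d) <- 0
  } else {
    ig <- igraph::graph_from_data_frame(
      data.frame(from = as.character(g$edges$governor),
                 to = as.character(g$edges$dependent)),
      directed = FALSE, vertices = labels)
    d <- igraph::distances(ig)
    d <- d[labels, labels, drop = FALSE]
  }
  g$cache$dist <- d
  d
}

dg_dist <- function(g, u, v) {
  d <- dg_dist_matrix(g)
  d[as.character(u), as.character(v)]
}

#' Undirected shortest-path length between two tokens
#'
#' Path lengths are computed on the undirected view of the graph; edge
#' directionality is scored separately during matching.
#'
#' @param g a `dep_graph`.
#' @param u,v token indices present in `g`.
#' @return A non-negative integer, `0` iff `u == v`, or the string
#'   `"disconnected"` when the tokens lie in different components.
#' @export
shortest_path_length <- function(g, u, v) {
  if (!has_token(g, u)) lookup_error(sprintf("token %s not in graph", u))
  if (!has_token(g, v)) lookup_error(sprintf("token %s not in graph", v))
  d <- dg_dist(g, u, v)
  if (is.infinite(d)) "disconnected" else as.integer(d)
}

#' All shortest undirected paths between two tokens
#'
#' Enumerates every shortest path between `u` and `v` in the undirected view
#' of the graph at edge resolution: parallel edges between the same pair of
#' tokens yield one path each, matching the worked rule-induction example
#' where two length-1 paths connect a trigger to its cause. For `u == v` the
#' single zero-length path is returned; for disconnected pairs the result is
#' empty.
#'
#' @param g a `dep_graph`.
#' @param u,v token indices present in `g`.
#' @return A list of paths; each path is a list with `nodes` (token index
#'   sequence from `u` to `v`) and `edges` (row numbers into `g$edges`).
#' @export
all_shortest_dep_paths <- function(g, u, v) {
  if (!has_token(g, u)) lookup_error(sprintf("token %s not in graph", u))
  if (!has_token(g, v)) lookup_error(sprintf("token %s not in graph", v))
  if (u == v) return(list(list(nodes = as.integer(u), edges = integer())))
  ix <- dg_index(g)
  n <- length(ix$index)
  su <- match(u, ix$index); sv <- match(v, ix$index)
  ## BFS distances from u over ranks
  dist <- rep(NA_integer_, n)
  dist[su] <- 0L
  frontier <- su
  while (length(frontier) && is.na(dist[sv])) {
    nxt <- integer()
    for (x in frontier) {
      nb <- ix$adj[[x]][, 1]
      nb <- nb[is.na(dist[nb])]
      if (length(nb)) {
        nb <- unique(nb)
        dist[nb] <- dist[x] + 1L
        nxt <- c(nxt, nb)
      }
    }
    frontier <- unique(nxt)
  }
  if (is.na(dist[sv])) return(list())
  ## Backtrack from v collecting all edge-resolved shortest paths.
  walk <- function(x) {
    if (x == su) return(list(list(nodes = su, edges = integer())))
    out <- list()
    adj <- ix$adj[[x]]
    if (nrow(adj)) {
      ord <- order(adj[, 1], adj[, 2])
      adj <- adj[ord, , drop = FALSE]
      for (r in seq_len(nrow(adj))) {
        w <- adj[r, 1]
        if (!is.na(dist[w]) && dist[w] == dist[x] - 1L) {
          for (p in walk(w)) {
            out[[length(out) + 1L]] <-
              list(nodes = c(p$nodes, x), edges = c(p$edges, adj[r, 2]))
          }
        }
      }
    }
    out
  }
  lapply(walk(sv), function(p) {
    list(nodes = ix$index[p$nodes], edges = as.integer(p$edges))
  })
}

#' Union of dependency paths as a subgraph
#'
#' Builds the subgraph of `g` containing exactly the tokens and the original
#' directed, labeled edges traversed by any of the given paths. This is the
#' dependency path union used to assemble rule graphs from per-argument
#' shortest paths.
#'
#' @param g a `dep_graph`.
#' @param paths list of paths as returned by [all_shortest_dep_paths()].
#' @return A `dep_graph` whose tokens and edges are subsets of `g`'s; empty
#'   when `paths` is empty.
#' @export
path_union <- function(g, paths) {
  if (!length(paths)) return(dep_graph(sentence_id = g$sentence_id))
  nodes <- sort(unique(unlist(lapply(paths, `[[`, "nodes"))))
  eids <- sort(unique(unlist(lapply(paths, `[[`, "edges"))))
  if (!all(nodes %in% g$tokens$index)) {
    lookup_error("path references a token absent from the graph")
  }
  dep_graph(g$tokens[match(nodes, g$tokens$index), , drop = FALSE],
            g$edges[eids, , drop = FALSE], g$sentence_id)
}

#' Mark tokens as generalized biological entities
#'
#' Flags the head tokens of pre-annotated entities so that matching treats
#' them as the generic BIO_Entity tag: their surface, lemma and POS are
#' ignored by node comparison while the original fields are retained for
#' reporting. Re-application is idempotent.
#'
#' @param g a `dep_graph`.
#' @param entities data.frame with columns `id` and `head` (token index), or
#'   a list of `(id, head)` pairs. May be empty.
#' @return The graph with the flagged tokens.
#' @export
generalize_entities <- function(g, entities) {
  if (is.null(entities) || (is.data.frame(entities) && !nrow(entities)) ||
      (!is.data.frame(entities) && !length(entities))) {
    return(g)
  }
  if (!is.data.frame(entities)) {
    entities <- data.frame(
      id = vapply(entities, function(e) as.character(e$id %||% e[[1]]), ""),
      head = vapply(entities, function(e) as.integer(e$head %||% e[[2]]), 0L))
  }
  tok <- g$tokens
  pos <- match(entities$head, tok$index)
  if (anyNA(pos)) {
    lookup_error(sprintf("entity head token %s not in graph",
                         entities$head[which(is.na(pos))[1]]))
  }
  tok$is_entity[pos] <- TRUE
  tok$entity_ref[pos] <- as.character(entities$id)
  dep_graph(tok, g$edges, g$sentence_id)
}
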