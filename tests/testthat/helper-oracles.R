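## Independent brute-force oracles, coded without reusing the package's
## shortest-path or matching internals.

## Exhaustive enumeration of ALL simple paths between u and v by DFS over
## edge occurrences, then filtering to the minimal length.
bf_all_shortest_paths <- function(g, u, v) {
  if (u == v) return(list(list(nodes = as.integer(u), edges = integer())))
  ed <- g$edges
  found <- list()
  dfs <- function(node, visited, enodes, eids) {
    if (node == v) {
      found[[length(found) + 1L]] <<- list(nodes = enodes, edges = eids)
      return()
    }
    for (e in seq_len(nrow(ed))) {
      nxt <- if (ed$governor[e] == node) ed$dependent[e] else
        if (ed$dependent[e] == node) ed$governor[e] else NA
      if (!is.na(nxt) && !(nxt %in% visited)) {
        dfs(nxt, c(visited, nxt), c(enodes, nxt), c(eids, e))
      }
    }
  }
  dfs(u, u, as.integer(u), integer())
  if (!length(found)) return(list())
  lens <- vapply(found, function(p) length(p$edges), 0L)
  found[lens == min(lens)]
}

path_set_key <- function(paths) {
  sort(vapply(paths, function(p) {
    paste(paste(p$nodes, collapse = ","), paste(p$edges, collapse = ","),
          sep = "|")
  }, ""))
}

## All injective feature-compatible assignments, built from per-node
## candidate lists (via the exported single-pair match_node) and a plain
## product filter.
bf_injective_mappings <- function(rule, sentence, params,
                                  subevent_tokens = NULL) {
  rt <- rule$graph$tokens
  st <- sentence$tokens
  sub_nodes <- rule$slots$node[rule$slots$filler_kind == "sub_event"]
  cand <- lapply(seq_len(nrow(rt)), function(i) {
    if (!is.null(subevent_tokens) && rt$index[i] %in% sub_nodes) {
      return(sort(intersect(st$index, subevent_tokens)))
    }
    keep <- vapply(seq_len(nrow(st)), function(j) {
      match_node(rt[i, ], st[j, ], params$criteria,
                 rt$index[i] %in% rule$trigger_nodes, params$trigger_lexicon)
    }, TRUE)
    sort(st$index[keep])
  })
  if (any(lengths(cand) == 0)) return(list())
  grid <- expand.grid(cand, KEEP.OUT.ATTRS = FALSE)
  keep <- apply(grid, 1, function(r) !anyDuplicated(r))
  grid <- grid[keep, , drop = FALSE]
  lapply(seq_len(nrow(grid)), function(r) {
    m <- as.integer(grid[r, ])
    names(m) <- as.character(rt$index)
    m[order(as.integer(names(m)))]
  })
}

## multiset label counting, independent implementation
bf_count_diff <- function(a, b) {
  u <- unique(c(a, b))
  s <- 0L
  for (x in u) s <- s + abs(sum(a == x) - sum(b == x))
  s
}

bf_path_labels <- function(g, p) g$edges$label[p$edges]

bf_path_dirs <- function(g, p) {
  if (!length(p$edges)) return(character())
  out <- character(length(p$edges))
  for (k in seq_along(p$edges)) {
    from <- p$nodes[k]
    out[k] <- if (g$edges$governor[p$edges[k]] == from) "fwd" else "bwd"
  }
  out
}

## lexicographically smallest node sequence (ties by first enumeration in
## sorted order, matching the deterministic rule-path choice)
bf_lex_first <- function(paths) {
  keys <- vapply(paths, function(p) {
    paste(formatC(p$nodes, width = 8, flag = "0"), collapse = ",")
  }, "")
  paths[[order(keys)[1]]]
}

## Exact (distance-, label- and orientation-preserving) embedding check:
## every node pair keeps its undirected distance, and some sentence
## shortest path reproduces both the label multiset and the traversal
## orientation multiset of the rule's reference shortest path.
bf_is_exact_embedding <- function(rule, sentence, mapping) {
  rg <- rule$graph
  nodes <- sort(as.integer(names(mapping)))
  if (length(nodes) <= 1) return(TRUE)
  for (i in seq_len(length(nodes) - 1)) {
    for (j in seq(i + 1, length(nodes))) {
      ru <- nodes[i]; rv <- nodes[j]
      su <- mapping[[as.character(ru)]]; sv <- mapping[[as.character(rv)]]
      rp_all <- bf_all_shortest_paths(rg, min(ru, rv), max(ru, rv))
      sp_all <- bf_all_shortest_paths(sentence, min(su, sv), max(su, sv))
      if (!length(rp_all) || !length(sp_all)) return(FALSE)
      if (length(rp_all[[1]]$edges) != length(sp_all[[1]]$edges)) return(FALSE)
      rp <- bf_lex_first(rp_all)
      rl <- bf_path_labels(rg, rp); rd <- bf_path_dirs(rg, rp)
      ok <- FALSE
      for (sp in sp_all) {
        if (bf_count_diff(rl, bf_path_labels(sentence, sp)) == 0 &&
            bf_count_diff(rd, bf_path_dirs(sentence, sp)) == 0) {
          ok <- TRUE
          break
        }
      }
      if (!ok) return(FALSE)
    }
  }
  TRUE
}

mapping_key <- function(m) paste(names(m), m, sep = ":", collapse = ",")

## -- random instance generators -------------------------------------------

LAB_POOL <- c("nsubj", "dobj", "prep_of", "prep_in", "amod", "conj_and")
LEMMA_POOL <- c("bind", "induce", "expression", "level", "complex", "signal",
                "activity", "response", "kinase", "domain")
POS_POOL <- c("NN", "NNS", "VBZ", "JJ")

## random connected multigraph: tree plus extra (possibly parallel) edges
rand_graph <- function(n, extra = 1, entities = integer(), id = "s1") {
  lem <- sample(LEMMA_POOL, n, replace = TRUE)
  pos <- sample(POS_POOL, n, replace = TRUE)
  tokens <- data.frame(index = seq_len(n), surface = lem, lemma = lem,
                       pos = pos, is_entity = seq_len(n) %in% entities,
                       entity_ref = ifelse(seq_len(n) %in% entities,
                                           sprintf("T%d", seq_len(n)), NA))
  edges <- NULL
  if (n > 1) {
    gov <- vapply(2:n, function(i) sample.int(i - 1L, 1), 0L)
    edges <- data.frame(governor = gov, dependent = 2:n,
                        label = sample(LAB_POOL, n - 1, replace = TRUE))
    for (k in seq_len(extra)) {
      ab <- sample.int(n, 2)
      edges <- rbind(edges, data.frame(governor = ab[1], dependent = ab[2],
                                       label = sample(LAB_POOL, 1)))
    }
  }
  dep_graph(tokens, edges, id)
}

## A matching instance: a sentence graph and a rule graph. Half of the
## instances plant the rule as a verbatim copy of a connected sentence
## fragment (so exact embeddings exist); the others draw an unrelated rule
## graph. Rule graphs avoid parallel edges so the reference rule path is
## unambiguous.
make_instance <- function(seed) {
  set.seed(seed)
  ns <- sample(6:25, 1)
  n_ent <- sample(1:4, 1)
  sentence <- rand_graph(ns, extra = sample(0:3, 1),
                         entities = sample.int(ns, n_ent),
                         id = sprintf("inst%d", seed))
  nr <- sample(2:8, 1)
  if (runif(1) < 0.5) {
    ## planted: contiguous fragment of the sentence
    start <- sample.int(ns, 1)
    nodes <- start
    while (length(nodes) < nr) {
      nbr <- unique(c(
        sentence$edges$dependent[sentence$edges$governor %in% nodes],
        sentence$edges$governor[sentence$edges$dependent %in% nodes]))
      nbr <- setdiff(nbr, nodes)
      if (!length(nbr)) break
      nodes <- c(nodes, nbr[sample.int(length(nbr), 1)])
    }
    nodes <- sort(nodes)
    keep <- sentence$edges$governor %in% nodes &
      sentence$edges$dependent %in% nodes
    edges <- sentence$edges[keep, , drop = FALSE]
    ## no parallel undirected connections in rule graphs: the reference
    ## rule path must be unambiguous for the oracle comparison
    pair_key <- paste(pmin(edges$governor, edges$dependent),
                      pmax(edges$governor, edges$dependent))
    edges <- edges[!duplicated(pair_key), , drop = FALSE]
    toks <- sentence$tokens[match(nodes, sentence$tokens$index), ,
                            drop = FALSE]
    rg <- dep_graph(toks, edges, "rule")
  } else {
    ne <- sample(0:2, 1)
    rg <- rand_graph(nr, extra = 0,
                     entities = if (ne) sample.int(nr, min(ne, nr)) else integer(),
                     id = "rule")
    ## ground rule lemmas in the sentence half the time so candidates exist
    sw <- runif(nr) < 0.5
    pick <- sample.int(nrow(sentence$tokens), nr, replace = TRUE)
    rg$tokens$lemma[sw] <- sentence$tokens$lemma[pick[sw]]
    rg$tokens$surface[sw] <- sentence$tokens$surface[pick[sw]]
    rg$tokens$pos[sw] <- sentence$tokens$pos[pick[sw]]
  }
  ## keep the rule connected (drop stray components from random trees)
  slot_node <- rg$tokens$index[which.max(rg$tokens$index)]
  rule <- event_rule(rg, "Test_event",
                     trigger_nodes = rg$tokens$index[1],
                     slots = data.frame(role = "Theme", node = slot_node,
                                        filler_kind = "entity"),
                     variant = "individual")
  list(rule = rule, sentence = sentence)
}
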