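## Rule induction: each annotated event is generalized into graph rules
## built from shortest dependency paths between trigger and arguments.

#' Event rule
#'
#' A graph rule learned from one annotated event: a connected fragment of a
#' sentence dependency graph in which participating entities are flagged as
#' generic BIO_Entity nodes, plus role descriptors mapping graph nodes to
#' argument slots. `variant` records whether the rule is a dependency path
#' union over all arguments (joint representation) or an individual
#' trigger-to-argument path.
#'
#' @param graph a [dep_graph()] fragment.
#' @param event_type event type string.
#' @param trigger_nodes integer vector of trigger token indices.
#' @param slots data.frame with columns `role`, `node`, `filler_kind`
#'   (`"entity"` or `"sub_event"`).
#' @param variant `"union"` or `"individual"`.
#' @param provenance list of `list(doc_id, sentence_id, event_id)` records.
#' @param rule_id rule identifier.
#' @return An object of class `event_rule`.
#' @export
event_rule <- function(graph, event_type, trigger_nodes, slots,
                       variant = "individual", provenance = list(),
                       rule_id = NA_character_) {
  if (!all(trigger_nodes %in% graph$tokens$index)) {
    integrity_error("rule trigger nodes must belong to the rule graph")
  }
  if (!all(slots$node %in% graph$tokens$index)) {
    integrity_error("rule slot nodes must belong to the rule graph")
  }
  if (identical(variant, "individual") && nrow(slots) != 1) {
    integrity_error("an individual-path rule carries exactly one slot")
  }
  structure(list(rule_id = rule_id, event_type = event_type, graph = graph,
                 trigger_nodes = sort(as.integer(trigger_nodes)),
                 slots = slots, variant = variant, provenance = provenance),
            class = "event_rule")
}

#' @export
print.event_rule <- function(x, ...) {
  cat(sprintf("<event_rule %s %s (%s): %d nodes, %d edges, slots %s>\n",
              x$rule_id, x$event_type, x$variant, nrow(x$graph$tokens),
              nrow(x$graph$edges),
              paste(sprintf("%s:%s@%d", x$slots$role, x$slots$filler_kind,
                            x$slots$node), collapse = " ")))
  invisible(x)
}

is_complex_rule <- function(rule) any(rule$slots$filler_kind == "sub_event")

## Canonical serialization used for corpus-wide deduplication: node ranks
## replace token positions, entity nodes are interchangeable, theme slots
## are order-insensitive, and the union/individual variant is ignored.
canonical_rule_key <- function(event_type, graph, trigger_nodes, slots) {
  idx <- graph$tokens$index
  rank <- match(idx, sort(idx))
  node_desc <- vapply(seq_along(idx), function(i) {
    t <- graph$tokens[i, ]
    feat <- if (t$is_entity) "BIO_Entity" else paste(t$lemma, t$pos, sep = "/")
    srows <- which(slots$node == idx[i])
    sdesc <- if (length(srows)) {
      roles <- ifelse(is_theme_role(slots$role[srows]), "Theme",
                      slots$role[srows])
      paste(sort(paste(roles, slots$filler_kind[srows], sep = ":")),
            collapse = ",")
    } else ""
    sprintf("%d|%s|%s|%s", rank[i], feat,
            if (idx[i] %in% trigger_nodes) "TRG" else "", sdesc)
  }, "")
  edge_desc <- if (nrow(graph$edges)) {
    sort(sprintf("%d>%d:%s", rank[match(graph$edges$governor, idx)],
                 rank[match(graph$edges$dependent, idx)], graph$edges$label))
  } else character()
  paste(event_type, paste(node_desc, collapse = "&"),
        paste(edge_desc, collapse = "&"), sep = "#")
}

#' Shortest trigger-to-argument paths for rule induction
#'
#' For a single-token trigger, returns every shortest undirected path from
#' the trigger to the argument token. For multi-token triggers, the
#' shortest path from each trigger token to the argument is extracted and
#' one path choice per trigger token is merged (Cartesian product across
#' per-token path sets), so each returned element connects the whole
#' trigger to the argument. For sub-event arguments, `arg_token` is the
#' sub-event's trigger token.
#'
#' @param g a [dep_graph()].
#' @param trigger_tokens integer vector of trigger token indices.
#' @param arg_token argument token index.
#' @return A list of path elements (`nodes`, `edges`); empty when trigger
#'   and argument are disconnected (a message is logged).
#' @export
argument_paths <- function(g, trigger_tokens, arg_token) {
  per_token <- lapply(trigger_tokens, function(t) {
    all_shortest_dep_paths(g, t, arg_token)
  })
  connected <- lengths(per_token) > 0
  if (!any(connected)) {
    message(sprintf("no path between trigger {%s} and argument %d in %s",
                    paste(trigger_tokens, collapse = ","), arg_token,
                    g$sentence_id))
    return(list())
  }
  per_token <- per_token[connected]
  combos <- expand.grid(lapply(per_token, seq_along))
  out <- lapply(seq_len(nrow(combos)), function(r) {
    chosen <- lapply(seq_along(per_token), function(j) {
      per_token[[j]][[combos[r, j]]]
    })
    list(nodes = sort(unique(unlist(lapply(chosen, `[[`, "nodes")))),
         edges = sort(unique(unlist(lapply(chosen, `[[`, "edges")))))
  })
  unique_paths(out)
}

unique_paths <- function(paths) {
  keys <- vapply(paths, function(p) {
    paste(paste(p$nodes, collapse = ","), paste(p$edges, collapse = ","),
          sep = "|")
  }, "")
  paths[!duplicated(keys)]
}

path_is_degenerate <- function(p) length(p$edges) == 0

#' Build rule variants from per-argument path sets
#'
#' Union variants jointly depict all arguments: one rule per element of the
#' Cartesian product across the arguments' path sets, its graph being the
#' dependency path union of one path choice per argument. Individual
#' variants determine each argument independently: one rule per (argument,
#' path). Duplicates (identical generalized graph and slot structure)
#' collapse, so single-argument events yield individual variants only.
#'
#' @param trigger_tokens integer vector of trigger token indices.
#' @param per_arg_paths list (one element per argument) of path sets as
#'   returned by [argument_paths()].
#' @param g the (entity-generalized) sentence graph.
#' @param event_type event type string.
#' @param args list of `list(role, token, filler_kind)` parallel to
#'   `per_arg_paths`.
#' @param provenance provenance record for the rules.
#' @return List of [event_rule()] objects (possibly empty).
#' @export
rule_variants <- function(trigger_tokens, per_arg_paths, g, event_type,
                          args, provenance = list()) {
  stopifnot(length(per_arg_paths) == length(args))
  multi_arg <- length(args) > 1
  ## degenerate zero-length paths (trigger == argument token) carry no
  ## context; keep them only for events with no other argument
  per_arg_paths <- lapply(per_arg_paths, function(ps) {
    if (multi_arg) ps[!vapply(ps, path_is_degenerate, TRUE)] else ps
  })
  live <- lengths(per_arg_paths) > 0
  if (!any(live)) return(list())

  slot_for <- function(j) {
    data.frame(role = args[[j]]$role, node = args[[j]]$token,
               filler_kind = args[[j]]$filler_kind)
  }
  rules <- list()
  add <- function(graph, slots, variant) {
    rules[[length(rules) + 1L]] <<- event_rule(
      graph, event_type, trigger_tokens, slots, variant, provenance)
  }
  live_idx <- which(live)
  if (length(live_idx) > 1) {
    combos <- expand.grid(lapply(per_arg_paths[live_idx], seq_along))
    for (r in seq_len(nrow(combos))) {
      chosen <- lapply(seq_along(live_idx), function(jj) {
        per_arg_paths[[live_idx[jj]]][[combos[r, jj]]]
      })
      slots <- do.call(rbind, lapply(live_idx, slot_for))
      add(path_union(g, chosen), slots, "union")
    }
  }
  for (j in live_idx) {
    for (p in per_arg_paths[[j]]) {
      add(path_union(g, list(p)), slot_for(j), "individual")
    }
  }
  dedup_rules(rules)
}

dedup_rules <- function(rules) {
  keys <- vapply(rules, function(r) {
    canonical_rule_key(r$event_type, r$graph, r$trigger_nodes, r$slots)
  }, "")
  keep <- !duplicated(keys)
  out <- rules[keep]
  ## merge provenances of collapsed duplicates
  for (i in seq_along(out)) {
    dups <- which(keys == keys[keep][i])
    if (length(dups) > 1) {
      prov <- unlist(lapply(rules[dups], `[[`, "provenance"),
                     recursive = FALSE)
      out[[i]]$provenance <- prov[!duplicated(vapply(prov, function(p) {
        paste(p$doc_id, p$sentence_id, sep = "/")
      }, ""))]
    }
  }
  out
}

## Rules for one annotated event on one (entity-generalized) sentence graph.
event_rules <- function(g, event_type, trigger_tokens, args, provenance) {
  per_arg <- lapply(args, function(a) argument_paths(g, trigger_tokens, a$token))
  rule_variants(trigger_tokens, per_arg, g, event_type, args, provenance)
}

#' Induce event rules from annotated documents
#'
#' Runs rule induction over every gold event of the given documents: the
#' sentence graph is entity-generalized, shortest trigger-to-argument paths
#' are extracted for each argument (sub-event arguments anchor at the
#' sub-event's trigger token and are flagged so the matcher can relax
#' them), and union plus individual path variants are built. The rule set
#' is deduplicated corpus-wide on (event type, canonical graph form, slot
#' structure) while retaining all provenances.
#'
#' @param docs an `annotated_document` or a list of them.
#' @return A list of [event_rule()] objects with ids `R1`, `R2`, ...
#' @export
induce_rules <- function(docs) {
  if (inherits(docs, "annotated_document")) docs <- list(docs)
  all_rules <- list()
  for (doc in docs) {
    sent_entities <- split(doc$entities, doc$entities$sentence)
    gen_sentences <- lapply(seq_along(doc$sentences), function(s) {
      es <- sent_entities[[as.character(s)]]
      if (is.null(es) || !nrow(es)) return(doc$sentences[[s]])
      generalize_entities(doc$sentences[[s]],
                          data.frame(id = es$id, head = es$head_token))
    })
    for (ev_id in names(doc$events)) {
      ev <- doc$events[[ev_id]]
      s <- ev$sentence
      g <- gen_sentences[[s]]
      trig <- doc$trigger_tokens[[ev$trigger]]
      args <- lapply(ev$args, function(a) {
        if (grepl("^E", a$ref)) {
          sub_trig_id <- doc$events[[a$ref]]$trigger
          cov <- doc$trigger_tokens[[sub_trig_id]]
          list(role = a$role, token = cov[length(cov)],
               filler_kind = "sub_event")
        } else {
          r <- match(a$ref, doc$entities$id)
          list(role = a$role, token = doc$entities$head_token[r],
               filler_kind = "entity")
        }
      })
      prov <- list(list(doc_id = doc$doc_id, sentence_id = g$sentence_id,
                        event_id = ev_id))
      all_rules <- c(all_rules,
                     event_rules(g, ev$event_type, trig, args, prov))
    }
  }
  out <- dedup_rules(all_rules)
  for (i in seq_along(out)) out[[i]]$rule_id <- sprintf("R%d", i)
  out
}

#' Read or write rules as JSON lines
#'
#' One rule per line: nodes with generalization flags, directed labeled
#' edges, argument slots, event type, variant and provenance.
#'
#' @param rules list of [event_rule()] objects.
#' @param path file path.
#' @return `read_rules` returns the rule list.
#' @export
write_rules <- function(rules, path) {
  lines <- vapply(rules, function(r) {
    jsonlite::toJSON(list(
      rule_id = r$rule_id, event_type = r$event_type, variant = r$variant,
      tokens = r$graph$tokens[, c("index", "surface", "lemma", "pos",
                                  "is_entity", "entity_ref")],
      edges = r$graph$edges, trigger_nodes = r$trigger_nodes,
      slots = r$slots, provenance = r$provenance,
      sentence_id = r$graph$sentence_id
    ), auto_unbox = TRUE, na = "null")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  lapply(readLines(path), function(l) {
    x <- jsonlite::fromJSON(l, simplifyDataFrame = TRUE)
    tok <- as.data.frame(x$tokens)
    tok$entity_ref <- if (is.null(tok$entity_ref)) NA_character_ else {
      as.character(tok$entity_ref)
    }
    g <- dep_graph(tok, as.data.frame(x$edges), x$sentence_id %||% "rule")
    prov <- if (is.data.frame(x$provenance)) {
      lapply(seq_len(nrow(x$provenance)), function(i) as.list(x$provenance[i, ]))
    } else {
      x$provenance
    }
    event_rule(g, x$event_type, x$trigger_nodes, as.data.frame(x$slots),
               x$variant, prov, x$rule_id)
  })
}
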