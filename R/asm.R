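## Approximate subgraph matching: candidate start nodes, node-match
## criteria, exhaustive injective mapping enumeration.

POS_CLASSES <- list(c("NN", "NNS"), c("NNP", "NNPS"),
                    c("VB", "VBD", "VBG", "VBN", "VBP", "VBZ"),
                    c("JJ", "JJR", "JJS"), c("RB", "RBR", "RBS"))

relaxed_pos <- function(pos) {
  for (cl in POS_CLASSES) if (pos %in% cl) return(cl[1])
  pos
}

#' Start node of a rule graph
#'
#' Each rule has a single start node: the BIO_Entity node with the lowest
#' original token index if the rule contains any, otherwise the node with
#' the lowest token index (the case of regulatory rules whose only
#' arguments are sub-events). Fixing one start node does not reduce the set
#' of found mappings.
#'
#' @param rule an [event_rule()].
#' @return A token index.
#' @export
start_node <- function(rule) {
  tok <- rule$graph$tokens
  if (!nrow(tok)) integrity_error("rule graph is empty")
  ent <- tok$index[tok$is_entity]
  if (length(ent)) min(ent) else min(tok$index)
}

#' Candidate start nodes of a sentence for a rule
#'
#' If the rule's start node is a BIO_Entity node, every entity token of the
#' sentence is an alternate start node; otherwise every sentence token is a
#' candidate. Returned in ascending token order.
#'
#' @param sentence a [dep_graph()] (entity-generalized).
#' @param rule an [event_rule()].
#' @return Integer vector of token indices (possibly empty).
#' @export
candidate_start_nodes <- function(sentence, rule) {
  s <- start_node(rule)
  entity_start <- token_row(rule$graph, s)$is_entity
  tok <- sentence$tokens
  if (entity_start) sort(tok$index[tok$is_entity]) else sort(tok$index)
}

#' Compare a rule node with a sentence token
#'
#' BIO_Entity rule nodes match exactly the entity-flagged sentence tokens,
#' with all feature checks skipped (and non-entity rule nodes never match
#' masked entity tokens). Otherwise every selected feature must agree:
#' `P` exact POS tag, `P*` relaxed POS class (singular/plural nouns match,
#' verb conjugations match), `L` lemma, `A` exact token, `T` membership of
#' the sentence lemma in the known-trigger lexicon (applied when the rule
#' node is a trigger node).
#'
#' @param rule_node one-row token data.frame from a rule graph.
#' @param sent_node one-row token data.frame from a sentence graph.
#' @param criteria criteria string (e.g. `"P*+L"`) or feature vector.
#' @param rule_is_trigger is the rule node a trigger node (for `T`)?
#' @param trigger_lexicon lemma lexicon backing `T`.
#' @return logical.
#' @export
match_node <- function(rule_node, sent_node, criteria = "P*+L",
                       rule_is_trigger = FALSE,
                       trigger_lexicon = character()) {
  feats <- if (length(criteria) == 1 &&
               !criteria %in% c("P", "P*", "L", "A", "T")) {
    parse_criteria(criteria)
  } else {
    criteria
  }
  if (rule_node$is_entity) return(isTRUE(sent_node$is_entity))
  if (isTRUE(sent_node$is_entity)) return(FALSE)
  for (f in feats) {
    ok <- switch(f,
      "P" = identical(rule_node$pos, sent_node$pos),
      "P*" = identical(relaxed_pos(rule_node$pos), relaxed_pos(sent_node$pos)),
      "L" = {
        if (!nzchar(rule_node$lemma) || !nzchar(sent_node$lemma)) {
          config_error("criterion L requires lemmas on both nodes")
        }
        identical(rule_node$lemma, sent_node$lemma)
      },
      "A" = identical(rule_node$surface, sent_node$surface),
      "T" = !rule_is_trigger || sent_node$lemma %in% trigger_lexicon)
    if (!ok) return(FALSE)
  }
  TRUE
}

relaxed_pos_vec <- function(pos) {
  out <- pos
  for (cl in POS_CLASSES) out[pos %in% cl] <- cl[1]
  out
}

## Per-rule-node candidate sentence tokens (vectorized match_node over the
## sentence). Sub-event slot nodes, when a set of extracted-event trigger
## tokens is supplied, match exactly those tokens with lexical features
## ignored (the sub-event relaxation).
node_candidates <- function(rule, sentence, params, subevent_tokens = NULL) {
  rt <- rule$graph$tokens
  st <- sentence$tokens
  sub_nodes <- rule$slots$node[rule$slots$filler_kind == "sub_event"]
  feats <- params$features
  if (is.null(sentence$cache$rpos)) {
    sentence$cache$rpos <- relaxed_pos_vec(st$pos)
  }
  srpos <- sentence$cache$rpos
  lapply(seq_len(nrow(rt)), function(i) {
    if (!is.null(subevent_tokens) && rt$index[i] %in% sub_nodes) {
      return(sort(intersect(st$index, subevent_tokens)))
    }
    if (rt$is_entity[i]) return(sort(st$index[st$is_entity]))
    ok <- !st$is_entity
    for (f in feats) {
      ok <- ok & switch(f,
        "P" = st$pos == rt$pos[i],
        "P*" = srpos == relaxed_pos(rt$pos[i]),
        "L" = {
          if (!nzchar(rt$lemma[i])) {
            config_error("criterion L requires lemmas on both nodes")
          }
          nzchar(st$lemma) & st$lemma == rt$lemma[i]
        },
        "A" = st$surface == rt$surface[i],
        "T" = if (rt$index[i] %in% rule$trigger_nodes) {
          st$lemma %in% params$trigger_lexicon
        } else {
          TRUE
        })
    }
    sort(st$index[ok])
  })
}

#' Enumerate candidate injective node mappings
#'
#' Recursively generates every complete injective mapping from rule nodes
#' to sentence tokens that assembles one feature-compatible sentence token
#' per rule node, anchored at the given start pair. The result is
#' deterministic (lexicographic in rule-node order by ascending mapped
#' index). If the number of complete schemes would exceed
#' `params$scheme_cap` the start pair is abandoned with a warning.
#'
#' @param rule an [event_rule()].
#' @param sentence a [dep_graph()].
#' @param params an [asm_params()] (criteria + scheme cap).
#' @param start_pair integer vector `c(rule_node, sentence_node)`; the pair
#'   must itself be node-compatible.
#' @param subevent_tokens optional token set for the sub-event relaxation.
#' @return A list of named integer vectors (names = rule token indices).
#' @export
enumerate_mappings <- function(rule, sentence, params, start_pair,
                               subevent_tokens = NULL) {
  cand <- node_candidates(rule, sentence, params, subevent_tokens)
  enumerate_with_candidates(rule, cand, params, start_pair)
}

enumerate_with_candidates <- function(rule, cand, params, start_pair) {
  rule_idx <- rule$graph$tokens$index
  s <- match(start_pair[1], rule_idx)
  if (is.na(s)) lookup_error("start pair rule node not in rule graph")
  if (!(start_pair[2] %in% cand[[s]])) return(list())
  cand[[s]] <- start_pair[2]
  if (any(lengths(cand) == 0)) return(list())
  ord <- order(rule_idx)  # ascending rule node order -> lexicographic output
  nn <- length(ord)
  out <- vector("list", 0)
  cap <- params$scheme_cap
  overflow <- FALSE
  acc <- integer(nn)
  assign_next <- function(k) {
    if (overflow) return()
    if (k > nn) {
      if (length(out) + 1L > cap) {
        overflow <<- TRUE
        return()
      }
      m <- acc
      names(m) <- as.character(rule_idx[ord])
      out[[length(out) + 1L]] <<- m
      return()
    }
    for (v in cand[[ord[k]]]) {
      if (!(v %in% acc[seq_len(k - 1L)])) {
        acc[k] <<- v
        assign_next(k + 1L)
      }
    }
  }
  assign_next(1L)
  if (overflow) {
    warning(sprintf(
      "rule %s: more than %d candidate matching schemes for start pair (%d,%d); start pair abandoned",
      rule$rule_id, cap, start_pair[1], start_pair[2]), call. = FALSE)
    return(list())
  }
  out
}

#' Match a rule against a sentence graph
#'
#' Runs the approximate subgraph matching algorithm: for every candidate
#' start pair, all injective candidate mappings are enumerated and scored
#' with the weighted subgraph distance; mappings whose total distance is
#' within the rule type's threshold (inclusive) are kept. At threshold 0
#' this reduces to exact subgraph matching; at very large thresholds it
#' degenerates to co-occurrence of the rule nodes.
#'
#' @param rule an [event_rule()].
#' @param sentence an entity-generalized [dep_graph()].
#' @param params an [asm_params()].
#' @param subevent_tokens optional integer vector of tokens that trigger
#'   already-extracted events (enables the sub-event relaxation).
#' @param eta optional threshold override; defaults to the rule type's
#'   threshold in `params`.
#' @return A list of match results, each with fields `rule_id`, `mapping`,
#'   `struct_d`, `label_d`, `dir_d`, `total`.
#' @export
asm_match <- function(rule, sentence, params = asm_params(),
                      subevent_tokens = NULL, eta = NULL) {
  eta <- eta %||% eta_for(params, rule$event_type)
  s_r <- start_node(rule)
  starts <- candidate_start_nodes(sentence, rule)
  ## sub-event relaxation also applies to a start node that is a slot node
  cand <- node_candidates(rule, sentence, params, subevent_tokens)
  s_pos <- match(s_r, rule$graph$tokens$index)
  starts <- starts[starts %in% cand[[s_pos]]]
  results <- list()
  seen <- character()
  for (s_s in starts) {
    maps <- enumerate_with_candidates(rule, cand, params, c(s_r, s_s))
    for (m in maps) {
      key <- paste(m, collapse = ",")
      if (key %in% seen) next
      d <- subgraph_distance_components(rule, sentence, m, params, eta)
      if (is.finite(d$total) && d$total <= eta) {
        seen <- c(seen, key)
        results[[length(results) + 1L]] <- structure(
          list(rule_id = rule$rule_id, event_type = rule$event_type,
               mapping = m, struct_d = d$struct, label_d = d$label,
               dir_d = d$dir, total = d$total),
          class = "asm_match")
      }
    }
  }
  results
}

#' @export
print.asm_match <- function(x, ...) {
  cat(sprintf("<asm_match %s: total %.3f (s %.3f, l %.3f, d %.3f); %s>\n",
              x$rule_id, x$total, x$struct_d, x$label_d, x$dir_d,
              paste(names(x$mapping), x$mapping, sep = "->", collapse = " ")))
  invisible(x)
}
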