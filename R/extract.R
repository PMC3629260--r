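## Iterative bottom-up event assembly from rule matches.

## Anchor records produced by applying a rule's slot descriptors to a match
## mapping: where the trigger and each argument landed in the sentence.
match_anchors <- function(rule, m) {
  trig <- sort(unname(m$mapping[as.character(rule$trigger_nodes)]))
  slots <- rule$slots
  lapply(seq_len(nrow(slots)), function(k) {
    list(event_type = rule$event_type, trigger_tokens = trig,
         role = slots$role[k],
         token = unname(m$mapping[[as.character(slots$node[k])]]),
         filler_kind = slots$filler_kind[k], rule_id = rule$rule_id)
  })
}

## Expand an anchor set into concrete events: entity anchors bind to the
## sentence token's entity annotation; sub-event anchors bind to each
## already-extracted event triggered at the anchored token (Cartesian
## across sub-event slots).
build_events <- function(anchors, sentence, events_by_token, rule_ids) {
  if (!length(anchors)) return(list())
  fillers_per_anchor <- lapply(anchors, function(a) {
    if (a$filler_kind == "entity") {
      t <- token_row(sentence, a$token)
      list(list(kind = "entity",
                id = if (is.na(t$entity_ref)) sprintf("tok%d", a$token) else t$entity_ref,
                token = a$token))
    } else {
      evs <- events_by_token[[as.character(a$token)]]
      if (is.null(evs)) list() else {
        lapply(evs, function(e) list(kind = "event", event = e))
      }
    }
  })
  if (any(lengths(fillers_per_anchor) == 0)) return(list())
  combos <- expand.grid(lapply(fillers_per_anchor, seq_along))
  out <- list()
  for (r in seq_len(nrow(combos))) {
    args <- lapply(seq_along(anchors), function(k) {
      list(role = anchors[[k]]$role,
           filler = fillers_per_anchor[[k]][[combos[r, k]]])
    })
    ev <- new_event(anchors[[1]]$event_type, anchors[[1]]$trigger_tokens,
                    args, rule_ids)
    if (has_theme(ev)) out[[length(out) + 1L]] <- ev
  }
  out
}

#' Group individual-path match anchors into candidate events
#'
#' Arguments determined independently by individual-path rules are grouped
#' when they share the same event type and trigger tokens: all matched
#' Theme and Cause anchors merge into one potential event (so the multiple
#' themes of a Binding join a single multi-theme event). Duplicate anchors
#' collapse; groups without a Theme produce nothing.
#'
#' @param anchors list of anchor records (internal form carrying
#'   `event_type`, `trigger_tokens`, `role`, `token`, `filler_kind`).
#' @param sentence the sentence [dep_graph()].
#' @param events_by_token named list mapping trigger tokens to
#'   already-extracted events (for sub-event fillers).
#' @return List of candidate [new_event()] objects.
#' @export
group_arguments <- function(anchors, sentence, events_by_token = list()) {
  if (!length(anchors)) return(list())
  keys <- vapply(anchors, function(a) {
    paste(a$event_type, paste(a$trigger_tokens, collapse = ","), sep = "|")
  }, "")
  out <- list()
  for (key in unique(keys)) {
    grp <- anchors[keys == key]
    akey <- vapply(grp, function(a) {
      paste(a$role, a$token, a$filler_kind, sep = ":")
    }, "")
    ## interchangeable theme slots: merge Theme/Theme2 anchors on token
    akey[vapply(grp, function(a) is_theme_role(a$role), TRUE)] <-
      vapply(grp[vapply(grp, function(a) is_theme_role(a$role), TRUE)],
             function(a) paste("Theme", a$token, a$filler_kind, sep = ":"), "")
    ## every contributing rule keeps credit, including those whose anchor
    ## duplicates another rule's
    rule_ids <- unique(vapply(grp, `[[`, "", "rule_id"))
    grp <- grp[!duplicated(akey)]
    out <- c(out, build_events(grp, sentence, events_by_token, rule_ids))
  }
  out
}

#' Extract events from one sentence
#'
#' Iterative bottom-up matching: simple rules (no sub-event slot) are
#' matched first; in subsequent rounds complex rules are matched with the
#' sub-event relaxation, their sub-event slots allowed to map onto any
#' token that triggers an already-extracted event regardless of that
#' node's lexical features. Complete events come from union-variant
#' matches directly, while arguments from individual-variant matches
#' sharing a trigger are grouped ([group_arguments()]). Candidates without
#' a Theme are discarded and exact duplicates collapse. The process stops
#' when an iteration generates no new candidate event (safety cap of 20
#' rounds).
#'
#' @param sentence an entity-generalized [dep_graph()].
#' @param ruleset list of [event_rule()] objects.
#' @param params an [asm_params()].
#' @return List of extracted events (deduplicated, deterministic order).
#' @export
extract_sentence <- function(sentence, ruleset, params = asm_params()) {
  if (!length(ruleset) || !nrow(sentence$tokens)) return(list())
  simple <- ruleset[!vapply(ruleset, is_complex_rule, TRUE)]
  complex <- ruleset[vapply(ruleset, is_complex_rule, TRUE)]
  events <- list()          # signature -> event
  events_by_token <- list() # trigger token -> list of events

  add_events <- function(cands) {
    added <- FALSE
    for (ev in cands) {
      sig <- event_signature(ev)
      if (is.null(events[[sig]])) {
        events[[sig]] <<- ev
        for (t in ev$trigger_tokens) {
          k <- as.character(t)
          events_by_token[[k]] <<- c(events_by_token[[k]], list(ev))
        }
        added <- TRUE
      } else {
        merged <- unique(c(events[[sig]]$source_rules, ev$source_rules))
        events[[sig]]$source_rules <<- merged
      }
    }
    added
  }

  collect_candidates <- function(rules, subevent_tokens) {
    union_events <- list()
    ind_anchors <- list()
    for (rule in rules) {
      ms <- asm_match(rule, sentence, params,
                      subevent_tokens = subevent_tokens)
      for (m in ms) {
        anchors <- match_anchors(rule, m)
        if (rule$variant == "union") {
          union_events <- c(union_events,
                            build_events(anchors, sentence, events_by_token,
                                         rule$rule_id))
        } else {
          ind_anchors <- c(ind_anchors, anchors)
        }
      }
    }
    c(union_events, group_arguments(ind_anchors, sentence, events_by_token))
  }

  add_events(collect_candidates(simple, NULL))
  for (round in seq_len(20)) {
    if (!length(complex)) break
    subevent_tokens <- unique(unlist(lapply(events, `[[`, "trigger_tokens")))
    if (!length(subevent_tokens)) break
    if (!add_events(collect_candidates(complex, subevent_tokens))) break
  }
  if (!length(events)) return(list())
  unname(events[order(names(events))])
}

## Entity-generalize each sentence of a document from its .a1 annotations.
generalized_sentences <- function(doc) {
  lapply(seq_along(doc$sentences), function(s) {
    es <- doc$entities[doc$entities$sentence == s, , drop = FALSE]
    if (!nrow(es)) return(doc$sentences[[s]])
    generalize_entities(doc$sentences[[s]],
                        data.frame(id = es$id, head = es$head_token))
  })
}

#' Extract events from annotated documents
#'
#' Applies [extract_sentence()] to every sentence of every document (after
#' entity generalization). Deterministic across runs.
#'
#' @param docs an `annotated_document` or list of them.
#' @param ruleset list of [event_rule()] objects.
#' @param params an [asm_params()].
#' @param rule_filter optional function `(doc, sentence_index) -> rule
#'   subset` used e.g. for leave-origin-out evaluation.
#' @return A list with one element per document: `list(doc_id, sentences =
#'   list of per-sentence event lists)`.
#' @export
extract_corpus <- function(docs, ruleset, params = asm_params(),
                           rule_filter = NULL) {
  if (inherits(docs, "annotated_document")) docs <- list(docs)
  lapply(docs, function(doc) {
    gens <- generalized_sentences(doc)
    sent_events <- lapply(seq_along(gens), function(s) {
      rs <- if (is.null(rule_filter)) ruleset else rule_filter(doc, s)
      extract_sentence(gens[[s]], rs, params)
    })
    list(doc_id = doc$doc_id, sentences = sent_events)
  })
}

## -- scoring ---------------------------------------------------------------

trigger_span_close <- function(a, b) {
  abs(min(a) - min(b)) <= 1 && abs(max(a) - max(b)) <= 1
}

## recursive event equality with trigger spans relaxed by <= 1 token
approx_match <- function(p, g) {
  if (!identical(p$event_type, g$event_type)) return(FALSE)
  if (!trigger_span_close(p$trigger_tokens, g$trigger_tokens)) return(FALSE)
  if (length(p$args) != length(g$args)) return(FALSE)
  role_of <- function(a) if (is_theme_role(a$role)) "Theme" else a$role
  gs <- g$args
  used <- logical(length(gs))
  for (pa in p$args) {
    hit <- FALSE
    for (k in seq_along(gs)) {
      if (used[k] || !identical(role_of(pa), role_of(gs[[k]]))) next
      pf <- pa$filler; gf <- gs[[k]]$filler
      ok <- if (identical(pf$kind, "entity") && identical(gf$kind, "entity")) {
        identical(pf$id, gf$id)
      } else if (identical(pf$kind, "event") && identical(gf$kind, "event")) {
        approx_match(pf$event, gf$event)
      } else {
        FALSE
      }
      if (ok) { used[k] <- TRUE; hit <- TRUE; break }
    }
    if (!hit) return(FALSE)
  }
  TRUE
}

#' Score predicted events against gold annotations
#'
#' In `strict` mode an event counts as a true positive iff its type,
#' trigger token set and full recursive argument structure match a gold
#' event of the same sentence. In `approx_span` mode trigger spans (of the
#' event and of nested events) may differ by up to one token on each side.
#' Matching is one-to-one per sentence.
#'
#' @param predicted output of [extract_corpus()].
#' @param docs the gold `annotated_document` list (same order).
#' @param mode `"strict"` or `"approx_span"`.
#' @return A data.frame with one row per event type plus a `TOTAL` row:
#'   counts and precision/recall/F-score.
#' @export
score_events <- function(predicted, docs, mode = c("strict", "approx_span")) {
  mode <- match.arg(mode)
  if (inherits(docs, "annotated_document")) docs <- list(docs)
  pred_ids <- vapply(predicted, `[[`, "", "doc_id")
  if (anyDuplicated(pred_ids)) {
    integrity_error("duplicate document ids in predictions")
  }
  rows <- list()
  for (doc in docs) {
    gold <- gold_events(doc)
    p <- predicted[[match(doc$doc_id, pred_ids)]]
    for (s in seq_along(doc$sentences)) {
      gevs <- gold[[s]]
      pevs <- if (!is.null(p)) p$sentences[[s]] else list()
      if (mode == "strict") {
        gsig <- vapply(gevs, event_signature, "")
        psig <- vapply(pevs, event_signature, "")
        gused <- logical(length(gevs))
        for (k in seq_along(pevs)) {
          hit <- which(!gused & gsig == psig[k])
          tp <- length(hit) > 0
          if (tp) gused[hit[1]] <- TRUE
          rows[[length(rows) + 1L]] <- c(pevs[[k]]$event_type,
                                         if (tp) "tp" else "fp")
        }
      } else {
        gused <- logical(length(gevs))
        for (k in seq_along(pevs)) {
          tp <- FALSE
          for (j in seq_along(gevs)) {
            if (!gused[j] && approx_match(pevs[[k]], gevs[[j]])) {
              gused[j] <- TRUE; tp <- TRUE; break
            }
          }
          rows[[length(rows) + 1L]] <- c(pevs[[k]]$event_type,
                                         if (tp) "tp" else "fp")
        }
      }
      for (j in which(!gused)) {
        rows[[length(rows) + 1L]] <- c(gevs[[j]]$event_type, "fn")
      }
    }
  }
  types <- sort(unique(vapply(rows, `[[`, "", 1)))
  tab <- do.call(rbind, lapply(c(types, "TOTAL"), function(ty) {
    sel <- if (ty == "TOTAL") rows else rows[vapply(rows, `[[`, "", 1) == ty]
    outcomes <- vapply(sel, `[[`, "", 2)
    cbind(data.frame(event_type = ty),
          prf(sum(outcomes == "tp"), sum(outcomes == "fp"),
              sum(outcomes == "fn")))
  }))
  if (is.null(tab)) {
    tab <- cbind(data.frame(event_type = "TOTAL"), prf(0, 0, 0))
  }
  rownames(tab) <- NULL
  tab
}
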