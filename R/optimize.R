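## Rule set optimization: leave-origin-out TP:FP accounting and iterative
## pruning, plus parameter search.

rule_origins <- function(rule) {
  vapply(rule$provenance, function(p) {
    paste(p$doc_id, p$sentence_id, sep = "/")
  }, "")
}

sentence_key <- function(doc, s) {
  paste(doc$doc_id, doc$sentences[[s]]$sentence_id, sep = "/")
}

## Candidate events produced by a single rule on one sentence (its own
## matches only; individual anchors group within the rule).
rule_sentence_events <- function(rule, sentence, params, events_by_token) {
  subevent_tokens <- if (is_complex_rule(rule)) {
    as.integer(names(events_by_token))
  } else {
    NULL
  }
  ms <- asm_match(rule, sentence, params, subevent_tokens = subevent_tokens)
  if (!length(ms)) return(list())
  anchors <- unlist(lapply(ms, function(m) match_anchors(rule, m)),
                    recursive = FALSE)
  if (rule$variant == "union") {
    out <- list()
    per_match <- lapply(ms, function(m) match_anchors(rule, m))
    for (a in per_match) {
      out <- c(out, build_events(a, sentence, events_by_token, rule$rule_id))
    }
    unique_events(out)
  } else {
    unique_events(group_arguments(anchors, sentence, events_by_token))
  }
}

unique_events <- function(evs) {
  evs[!duplicated(vapply(evs, event_signature, ""))]
}

#' Leave-origin-out accuracy of a single rule
#'
#' Matches the rule against every training sentence except the sentence(s)
#' it was learned from, and counts predictions that strictly match a gold
#' event (TP) versus the rest (FP). For complex rules the gold sub-events
#' of each sentence stand in as substitutable sub-events, isolating the
#' rule's own quality from other rules' errors.
#'
#' @param rule an [event_rule()].
#' @param docs gold `annotated_document` list.
#' @param params an [asm_params()].
#' @return A list with `rule_id`, `tp`, `fp`, `ratio` (`Inf` when `fp` is
#'   0 and `tp` positive; `NaN` for silent rules) and `made_prediction`.
#' @export
rule_stats <- function(rule, docs, params = asm_params()) {
  if (inherits(docs, "annotated_document")) docs <- list(docs)
  origins <- rule_origins(rule)
  tp <- 0L; fp <- 0L
  for (doc in docs) {
    gens <- generalized_sentences(doc)
    gold <- gold_events(doc)
    for (s in seq_along(gens)) {
      if (sentence_key(doc, s) %in% origins) next
      events_by_token <- list()
      for (gev in gold[[s]]) {
        for (t in gev$trigger_tokens) {
          k <- as.character(t)
          events_by_token[[k]] <- c(events_by_token[[k]], list(gev))
        }
      }
      preds <- rule_sentence_events(rule, gens[[s]], params, events_by_token)
      if (!length(preds)) next
      gsig <- vapply(gold[[s]], event_signature, "")
      for (ev in preds) {
        if (event_signature(ev) %in% gsig) tp <- tp + 1L else fp <- fp + 1L
      }
    }
  }
  list(rule_id = rule$rule_id, tp = tp, fp = fp, ratio = tp / fp,
       made_prediction = tp + fp > 0L)
}

## Per-rule TP/FP from a full leave-origin-out pipeline pass: each sentence
## is extracted with the current rule set minus the rules induced from it,
## and every prediction is credited or blamed on its source rules. This is
## what the pruning iterations use, so that removing a rule propagates to
## complex rules that relied on its sub-events.
pipeline_rule_stats <- function(ruleset, docs, params) {
  if (inherits(docs, "annotated_document")) docs <- list(docs)
  ids <- vapply(ruleset, `[[`, "", "rule_id")
  tp <- setNames(integer(length(ids)), ids)
  fp <- setNames(integer(length(ids)), ids)
  origin_map <- lapply(ruleset, rule_origins)
  for (doc in docs) {
    gens <- generalized_sentences(doc)
    gold <- gold_events(doc)
    for (s in seq_along(gens)) {
      key <- sentence_key(doc, s)
      rs <- ruleset[!vapply(origin_map, function(o) key %in% o, TRUE)]
      preds <- extract_sentence(gens[[s]], rs, params)
      if (!length(preds)) next
      gsig <- vapply(gold[[s]], event_signature, "")
      for (ev in preds) {
        good <- event_signature(ev) %in% gsig
        for (rid in ev$source_rules) {
          if (good) tp[rid] <- tp[rid] + 1L else fp[rid] <- fp[rid] + 1L
        }
      }
    }
  }
  list(tp = tp, fp = fp)
}

#' Iteratively prune unreliable rules
#'
#' Each iteration performs sentence matching (leave-origin-out, with the
#' current rule set), ranks every rule by its TP:FP ratio, and removes the
#' predicting rules whose ratio falls below `params$rho` (default 1:4).
#' Rules that make no prediction are kept, as they may contribute on
#' unseen text. Because removing a rule can silence or degrade complex
#' rules that relied on its sub-events, iterations continue until one
#' removes nothing; convergence takes at most `length(ruleset)`
#' iterations.
#'
#' @param ruleset list of [event_rule()] objects.
#' @param docs gold training documents.
#' @param params an [asm_params()].
#' @param verbose log iteration summaries.
#' @return The pruned rule list (a subset of the input).
#' @export
optimize_ruleset <- function(ruleset, docs, params = asm_params(),
                             verbose = FALSE) {
  repeat {
    if (!length(ruleset)) return(ruleset)
    st <- pipeline_rule_stats(ruleset, docs, params)
    ids <- vapply(ruleset, `[[`, "", "rule_id")
    predicted <- (st$tp + st$fp)[ids] > 0
    ratio <- (st$tp / st$fp)[ids]
    drop <- predicted & !is.na(ratio) & ratio < params$rho
    if (verbose) {
      message(sprintf("pruning iteration: %d rules, removing %d",
                      length(ruleset), sum(drop)))
    }
    if (!any(drop)) return(ruleset)
    ruleset <- ruleset[!drop]
  }
}
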