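## Shared fixtures: the worked rule-induction example, small hand graphs,
## and builders for standoff documents assembled in code.

## The three-token fragment with the parallel trigger-to-cause connections:
## nsubj(lead-20, ligation-6), rcmod(ligation-6, lead-20),
## prep_to(lead-20, phosphorylation-23).
ligation_graph <- function() {
  g <- parse_sd(c("nsubj(lead-20/VBP, ligation-6/NN)",
                  "rcmod(ligation-6/NN, lead-20/VBP)",
                  "prep_to(lead-20/VBP, phosphorylation-23/NN)"))
  g$tokens$lemma <- tolower(g$tokens$surface)
  g
}

## Standoff document around the fragment: a Positive_regulation whose
## Theme and Cause are sub-events (with their own protein themes).
ligation_document <- function() {
  toks <- c("UPRTase", "ligation", "CTP", "lead", "phosphorylation", "PRPP")
  text <- paste(toks, collapse = " ")
  off <- c(0L, cumsum(nchar(toks) + 1L))
  sp <- function(i) sprintf("%d %d", off[i], off[i] + nchar(toks[i]))
  parse <- dep_graph(
    data.frame(index = 1:6, surface = toks, lemma = tolower(toks),
               pos = c("NN", "NN", "NN", "VBP", "NN", "NN")),
    data.frame(governor = c(4L, 2L, 4L, 2L, 5L),
               dependent = c(2L, 4L, 5L, 1L, 6L),
               label = c("nsubj", "rcmod", "prep_to", "prep_of", "prep_of")))
  a1 <- c(sprintf("T1\tProtein %s\tUPRTase", sp(1)),
          sprintf("T2\tProtein %s\tPRPP", sp(6)))
  a2 <- c(sprintf("T3\tBinding %s\tligation", sp(2)),
          sprintf("T4\tPositive_regulation %s\tlead", sp(4)),
          sprintf("T5\tPhosphorylation %s\tphosphorylation", sp(5)),
          "E1\tBinding:T3 Theme:T1",
          "E2\tPhosphorylation:T5 Theme:T2",
          "E3\tPositive_regulation:T4 Theme:E2 Cause:E1")
  read_standoff(text, a1, a2, list(parse), "PMC-example")
}

## quick graph builder: edges as "gov,dep,label" strings
mk_graph <- function(tokens, edge_spec, sentence_id = "s1") {
  es <- strsplit(edge_spec, ",", fixed = TRUE)
  dep_graph(tokens,
            data.frame(governor = as.integer(vapply(es, `[[`, "", 1)),
                       dependent = as.integer(vapply(es, `[[`, "", 2)),
                       label = vapply(es, `[[`, "", 3)),
            sentence_id)
}

tok_df <- function(n, lemmas = NULL, pos = NULL, entities = integer()) {
  lemmas <- lemmas %||% sprintf("w%d", seq_len(n))
  pos <- pos %||% rep("NN", n)
  data.frame(index = seq_len(n), surface = lemmas, lemma = lemmas, pos = pos,
             is_entity = seq_len(n) %in% entities,
             entity_ref = ifelse(seq_len(n) %in% entities,
                                 sprintf("T%d", seq_len(n)), NA))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Standoff document builder from per-sentence specs:
## list(tokens=data.frame(surface,lemma,pos), edges, entities=token idx,
##      events=list(list(type, trigger=token idx,
##                       args=list(list(role, entity=tok | event=local ev idx)))))
build_doc <- function(doc_id, sentences) {
  sent_text <- character(); parses <- list()
  a1 <- character(); trig_lines <- character(); ev_lines <- character()
  ent_n <- 0L; ev_n <- 0L
  offset <- 0L
  trig_n <- sum(vapply(sentences, function(s) length(s$events %||% list()), 0L))
  ent_total <- sum(vapply(sentences, function(s) length(s$entities %||% integer()), 0L))
  trig_next <- ent_total
  for (s in seq_along(sentences)) {
    sp <- sentences[[s]]
    n <- nrow(sp$tokens)
    starts <- integer(n); ends <- integer(n); pos <- offset
    for (i in seq_len(n)) {
      starts[i] <- pos; ends[i] <- pos + nchar(sp$tokens$surface[i])
      pos <- ends[i] + 1L
    }
    sent_text <- c(sent_text, paste(sp$tokens$surface, collapse = " "))
    parses[[s]] <- dep_graph(
      cbind(data.frame(index = seq_len(n)), sp$tokens), sp$edges,
      sprintf("%s.s%d", doc_id, s))
    ent_id <- character(n)
    for (t in sp$entities %||% integer()) {
      ent_n <- ent_n + 1L
      ent_id[t] <- sprintf("T%d", ent_n)
      a1 <- c(a1, sprintf("%s\tProtein %d %d\t%s", ent_id[t], starts[t],
                          ends[t], sp$tokens$surface[t]))
    }
    ev_ids <- character(length(sp$events %||% list()))
    for (k in seq_along(sp$events %||% list())) {
      ev <- sp$events[[k]]
      trig_next <- trig_next + 1L
      tid <- sprintf("T%d", trig_next)
      t <- ev$trigger
      trig_lines <- c(trig_lines, sprintf("%s\t%s %d %d\t%s", tid, ev$type,
                                          starts[t], ends[t],
                                          sp$tokens$surface[t]))
      ev_n <- ev_n + 1L
      ev_ids[k] <- sprintf("E%d", ev_n)
      args <- vapply(ev$args, function(a) {
        ref <- if (!is.null(a$event)) ev_ids[a$event] else ent_id[a$entity]
        sprintf("%s:%s", a$role, ref)
      }, "")
      ev_lines <- c(ev_lines, sprintf("%s\t%s:%s %s", ev_ids[k], ev$type, tid,
                                      paste(args, collapse = " ")))
    }
    offset <- offset + nchar(sent_text[s]) + 1L
  }
  read_standoff(sent_text, a1, c(trig_lines, ev_lines), parses, doc_id)
}

## -- the nested-propagation pruning fixture --------------------------------
## Rule families: "synthesis" gene-expression rules are unreliable (their
## contexts recur unannotated), "production" rules are reliable, and two
## regulation rules depend on the extracted sub-events. Removing the
## synthesis rules in iteration 1 starves one regulation rule of its true
## positives, so it is removed in iteration 2.
propagation_corpus <- function() {
  ge_sentence <- function(trig, prep, ent, reg = FALSE, annotate = TRUE) {
    n <- if (reg) 4L else 3L
    tokens <- data.frame(
      surface = c(trig, "amount", ent, if (reg) "lead"),
      lemma = c(trig, "amount", ent, if (reg) "lead"),
      pos = c("NN", "NN", "NN", if (reg) "VBZ"))
    edges <- data.frame(governor = c(1L, 2L, if (reg) 4L),
                        dependent = c(2L, 3L, if (reg) 1L),
                        label = c("dobj", prep, if (reg) "prep_to"))
    events <- if (annotate) {
      evs <- list(list(type = "Gene_expression", trigger = 1L,
                       args = list(list(role = "Theme", entity = 3L))))
      if (reg) {
        evs <- c(evs, list(list(type = "Positive_regulation", trigger = 4L,
                                args = list(list(role = "Theme", event = 1L)))))
      }
      evs
    } else {
      list()
    }
    list(tokens = tokens, edges = edges, entities = 3L, events = events)
  }
  reg_fp_sentence <- function(ent) {
    ## gold production event plus an unannotated regulation structure
    s <- ge_sentence("production", "prep_in", ent, reg = TRUE)
    s$events <- s$events[1]
    s
  }
  c(
    list(build_doc("PX01", list(ge_sentence("synthesis", "prep_in", "IL2")))),
    list(build_doc("PX02", list(ge_sentence("synthesis", "prep_of", "TNF",
                                            reg = TRUE)))),
    list(build_doc("PX03", list(ge_sentence("production", "prep_of", "STAT3",
                                            reg = TRUE)))),
    list(build_doc("PX04", list(ge_sentence("production", "prep_of", "JAK2")))),
    list(build_doc("PX05", list(ge_sentence("production", "prep_in", "CD28")))),
    list(build_doc("PX06", list(reg_fp_sentence("FOXP3")))),
    list(build_doc("PX07", list(reg_fp_sentence("GATA3")))),
    lapply(1:5, function(k) {
      build_doc(sprintf("PXD%d", k),
                list(ge_sentence("synthesis", "prep_in", "SOCS1",
                                 annotate = FALSE)))
    })
  )
}
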