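## A six-token sentence expressing a regulation over a gene expression:
## "STAT3 induces expression of IL2 strongly"
nested_doc <- function() {
  build_doc("ND1", list(list(
    tokens = data.frame(
      surface = c("STAT3", "induces", "expression", "of", "IL2", "strongly"),
      lemma = c("STAT3", "induce", "expression", "of", "IL2", "strongly"),
      pos = c("NN", "VBZ", "NN", "IN", "NN", "RB")),
    edges = data.frame(governor = c(2L, 2L, 3L, 2L),
                       dependent = c(1L, 3L, 5L, 6L),
                       label = c("nsubj", "dobj", "prep_of", "advmod")),
    entities = c(1L, 5L),
    events = list(
      list(type = "Gene_expression", trigger = 3L,
           args = list(list(role = "Theme", entity = 5L))),
      list(type = "Positive_regulation", trigger = 2L,
           args = list(list(role = "Theme", event = 1L),
                       list(role = "Cause", entity = 1L)))))))
}

test_that("bottom-up extraction assembles the nested regulation", {
  doc <- nested_doc()
  rules <- induce_rules(doc)
  sent <- asmevents:::generalized_sentences(doc)[[1]]
  events <- extract_sentence(sent, rules, asm_params(eta = 0))
  sigs <- vapply(events, event_signature, "")
  gold <- vapply(gold_events(doc)[[1]], event_signature, "")
  expect_true(all(gold %in% sigs))
  reg <- events[[grep("Positive_regulation", sigs)[1]]]
  kinds <- vapply(reg$args, function(a) a$filler$kind, "")
  expect_setequal(kinds, c("event", "entity"))
  sub <- reg$args[[which(kinds == "event")]]$filler$event
  expect_equal(sub$event_type, "Gene_expression")

  expect_length(extract_sentence(sent, list(), asm_params()), 0L)
})

test_that("extraction is deterministic and dedup is idempotent", {
  doc <- nested_doc()
  rules <- induce_rules(doc)
  sent <- asmevents:::generalized_sentences(doc)[[1]]
  a <- extract_sentence(sent, rules, asm_params(eta = 0))
  b <- extract_sentence(sent, rules, asm_params(eta = 0))
  expect_equal(vapply(a, event_signature, ""), vapply(b, event_signature, ""))
  ## two rule copies with different ids produce one event
  rules2 <- c(rules, lapply(rules, function(r) {
    r$rule_id <- paste0(r$rule_id, "bis")
    r
  }))
  c_ <- extract_sentence(sent, rules2, asm_params(eta = 0))
  expect_equal(sort(vapply(c_, event_signature, "")),
               sort(vapply(a, event_signature, "")))
})

test_that("group_arguments merges role anchors per trigger and drops theme-less groups", {
  sent <- mk_graph(tok_df(4, lemmas = c("t", "a", "b", "c")),
                   c("1,2,x", "1,3,y", "1,4,z"))
  anchor <- function(role, token, type = "Binding") {
    list(event_type = type, trigger_tokens = 1L, role = role, token = token,
         filler_kind = "entity", rule_id = "R")
  }
  ## three binding themes at one trigger -> one three-theme event
  evs <- group_arguments(list(anchor("Theme", 2L), anchor("Theme2", 3L),
                              anchor("Theme", 4L)), sent)
  expect_length(evs, 1L)
  expect_length(evs[[1]]$args, 3L)
  ## theme plus cause merge into one regulation
  evs2 <- group_arguments(list(anchor("Theme", 2L, "Regulation"),
                               anchor("Cause", 3L, "Regulation")), sent)
  expect_length(evs2, 1L)
  expect_setequal(vapply(evs2[[1]]$args, `[[`, "", "role"),
                  c("Theme", "Cause"))
  ## a lone cause yields nothing
  expect_length(group_arguments(list(anchor("Cause", 2L)), sent), 0L)
  ## duplicate anchors collapse
  evs3 <- group_arguments(list(anchor("Theme", 2L), anchor("Theme", 2L)),
                          sent)
  expect_length(evs3[[1]]$args, 1L)
})

test_that("extract_corpus recovers planted events and repeats identically", {
  docs <- generate_corpus(synth_config(n_docs = 6, seed = 5))
  rules <- induce_rules(docs)
  p0 <- asm_params(eta = 0)
  preds <- extract_corpus(docs, rules, p0)
  tab <- score_events(preds, docs, "strict")
  expect_equal(tab$recall[tab$event_type == "TOTAL"], 1)
  preds2 <- extract_corpus(docs, rules, p0)
  expect_identical(
    lapply(preds, function(d) lapply(d$sentences, function(s) {
      vapply(s, event_signature, "")
    })),
    lapply(preds2, function(d) lapply(d$sentences, function(s) {
      vapply(s, event_signature, "")
    })))
  expect_length(extract_corpus(list(), rules, p0), 0L)
})

test_that("strict and approximate-span scoring behave per contract", {
  doc <- nested_doc()
  gold <- gold_events(doc)
  pred_exact <- list(list(doc_id = "ND1", sentences = gold))
  tab <- score_events(pred_exact, doc, "strict")
  tot <- tab[tab$event_type == "TOTAL", ]
  expect_equal(c(tot$precision, tot$recall, tot$f_score), c(1, 1, 1))

  empty <- list(list(doc_id = "ND1",
                     sentences = rep(list(list()), length(doc$sentences))))
  tab0 <- score_events(empty, doc, "strict")
  expect_equal(tab0$recall[tab0$event_type == "TOTAL"], 0)

  ## one-token trigger offset: TP only under approx_span
  shifted <- gold
  shifted[[1]] <- lapply(shifted[[1]], function(ev) {
    if (ev$event_type == "Gene_expression") {
      ev$trigger_tokens <- ev$trigger_tokens + 1L
    }
    ev
  })
  pred_shift <- list(list(doc_id = "ND1", sentences = shifted))
  strict <- score_events(pred_shift, doc, "strict")
  approx <- score_events(pred_shift, doc, "approx_span")
  expect_lt(strict$recall[strict$event_type == "Gene_expression"], 1)
  expect_equal(approx$recall[approx$event_type == "TOTAL"], 1)
})

test_that("predictions serialize to a2 and read back equivalently", {
  docs <- generate_corpus(synth_config(n_docs = 2, seed = 9))
  rules <- induce_rules(docs)
  preds <- extract_corpus(docs, rules, asm_params(eta = 0))
  for (k in seq_along(docs)) {
    lines <- predictions_to_a2(docs[[k]], preds[[k]])
    a1 <- sprintf("%s\t%s %d %d\t%s", docs[[k]]$entities$id,
                  docs[[k]]$entities$type, docs[[k]]$entities$start,
                  docs[[k]]$entities$end, docs[[k]]$entities$text)
    back <- read_standoff(sub("\n$", "", docs[[k]]$text), a1, lines,
                          docs[[k]]$sentences, docs[[k]]$doc_id)
    got <- gold_events(back)
    for (s in seq_along(got)) {
      expect_setequal(vapply(got[[s]], event_signature, ""),
                      vapply(preds[[k]]$sentences[[s]], event_signature, ""))
    }
  }
})
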