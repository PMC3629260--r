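test_that("rule_stats counts leave-origin-out predictions", {
  ## a gene-expression rule, evaluated over a corpus where its context
  ## recurs in three gold sentences and one unannotated distractor
  ge_sent <- function(annotate) {
    list(tokens = data.frame(surface = c("expression", "IL2"),
                             lemma = c("expression", "IL2"),
                             pos = c("NN", "NN")),
         edges = data.frame(governor = 1L, dependent = 2L, label = "prep_of"),
         entities = 2L,
         events = if (annotate) {
           list(list(type = "Gene_expression", trigger = 1L,
                     args = list(list(role = "Theme", entity = 2L))))
         } else {
           list()
         })
  }
  docs <- c(lapply(1:4, function(k) {
    build_doc(sprintf("G%d", k), list(ge_sent(TRUE)))
  }), list(build_doc("G5", list(ge_sent(FALSE)))))
  rule <- induce_rules(docs[[1]])[[1]]
  rule$rule_id <- "R1"
  st <- rule_stats(rule, docs, asm_params(eta = 0))
  expect_equal(st$tp, 3L)  # G1 is the origin, G2..G4 are gold
  expect_equal(st$fp, 1L)  # the unannotated distractor
  expect_true(st$made_prediction)

  ## matching nothing, and matching only the origin sentence
  st0 <- rule_stats(rule, list(docs[[1]]), asm_params(eta = 0))
  expect_equal(c(st0$tp, st0$fp), c(0L, 0L))
  expect_false(st0$made_prediction)
  lone <- mk_graph(tok_df(2, lemmas = c("binding", "JAK2")), "1,2,prep_of")
  other <- build_doc("G9", list(list(
    tokens = data.frame(surface = c("analysis", "role"),
                        lemma = c("analysis", "role"), pos = c("NN", "NN")),
    edges = data.frame(governor = 1L, dependent = 2L, label = "prep_of"),
    entities = integer(), events = list())))
  st1 <- rule_stats(rule, list(other), asm_params(eta = 0))
  expect_false(st1$made_prediction)
})

test_that("complex rule_stats substitutes gold sub-events", {
  docs <- propagation_corpus()
  rules <- induce_rules(docs)
  reg <- Filter(function(r) r$event_type == "Positive_regulation", rules)
  ## slot lemma "production" (learned in PX03): gold sub-events make it
  ## fire on PX02 (TP) and on the two unannotated regulation structures
  prod_reg <- Filter(function(r) {
    "production" %in% r$graph$tokens$lemma
  }, reg)[[1]]
  st <- rule_stats(prod_reg, docs, asm_params())
  expect_equal(st$tp, 1L)
  expect_equal(st$fp, 2L)
})

test_that("pruning removes low-ratio rules, keeps silent ones, and converges", {
  ## silent ruleset is unchanged
  doc <- build_doc("S1", list(list(
    tokens = data.frame(surface = c("expression", "IL2"),
                        lemma = c("expression", "IL2"), pos = c("NN", "NN")),
    edges = data.frame(governor = 1L, dependent = 2L, label = "prep_of"),
    entities = 2L,
    events = list(list(type = "Gene_expression", trigger = 1L,
                       args = list(list(role = "Theme", entity = 2L)))))))
  rules <- induce_rules(doc)
  kept <- optimize_ruleset(rules, list(doc), asm_params(eta = 0))
  expect_length(kept, length(rules))  # only its origin matches: silent

  ## a rule with tp=1, fp=9 at rho = 0.25 is removed
  ge_sent <- function(annotate, trig = "expression") {
    list(tokens = data.frame(surface = c(trig, "IL2"), lemma = c(trig, "IL2"),
                             pos = c("NN", "NN")),
         edges = data.frame(governor = 1L, dependent = 2L, label = "prep_of"),
         entities = 2L,
         events = if (annotate) {
           list(list(type = "Gene_expression", trigger = 1L,
                     args = list(list(role = "Theme", entity = 2L))))
         } else {
           list()
         })
  }
  docs <- c(lapply(1:2, function(k) {
    build_doc(sprintf("H%d", k), list(ge_sent(TRUE)))
  }), lapply(1:9, function(k) {
    build_doc(sprintf("HD%d", k), list(ge_sent(FALSE)))
  }))
  pruned <- optimize_ruleset(induce_rules(docs), docs, asm_params(eta = 0))
  expect_length(pruned, 0L)
})

test_that("pruning propagates through nested dependencies over iterations", {
  docs <- propagation_corpus()
  rules <- induce_rules(docs)
  expect_length(rules, 6L)
  params <- asm_params()

  ## iteration 1 statistics identify exactly the unreliable synthesis rules
  st <- asmevents:::pipeline_rule_stats(rules, docs, params)
  ratio <- st$tp / st$fp
  bad1 <- names(ratio)[!is.nan(ratio) & ratio < params$rho]
  id2lemma <- function(ids) {
    vapply(ids, function(id) {
      r <- rules[[match(id, vapply(rules, `[[`, "", "rule_id"))]]
      paste(sort(setdiff(r$graph$tokens$lemma, c("amount", ""))),
            collapse = "+")
    }, "")
  }
  expect_length(bad1, 2L)
  expect_true(all(grepl("synthesis", id2lemma(bad1))))

  kept <- optimize_ruleset(rules, docs, params)
  kept_ids <- vapply(kept, `[[`, "", "rule_id")
  removed <- setdiff(vapply(rules, `[[`, "", "rule_id"), kept_ids)
  ## both synthesis rules and the dependent regulation rule are gone
  expect_length(removed, 3L)
  expect_true(any(grepl("lead", id2lemma(removed))))
  ## the dependent regulation rule was NOT removable in iteration 1
  dep_rule <- removed[grepl("lead", id2lemma(removed))]
  expect_false(dep_rule %in% bad1)

  ## post-pruning contract: no retained predicting rule below rho
  st2 <- asmevents:::pipeline_rule_stats(kept, docs, params)
  pred <- (st2$tp + st2$fp)[kept_ids] > 0
  ratio2 <- (st2$tp / st2$fp)[kept_ids]
  expect_true(all(!pred | is.nan(ratio2) | ratio2 >= params$rho))
})

test_that("pruning never lowers training precision on the fixture", {
  docs <- propagation_corpus()
  rules <- induce_rules(docs)
  params <- asm_params()
  p_before <- score_events(extract_corpus(docs, rules, params), docs,
                           "strict")
  kept <- optimize_ruleset(rules, docs, params)
  p_after <- score_events(extract_corpus(docs, kept, params), docs, "strict")
  pb <- p_before$precision[p_before$event_type == "TOTAL"]
  pa <- p_after$precision[p_after$event_type == "TOTAL"]
  expect_gte(pa, pb)
})

test_that("grid tuning returns the F-maximizing threshold with low tie-break", {
  docs <- generate_corpus(synth_config(n_docs = 8, seed = 21))
  train <- docs[1:5]
  dev <- docs[6:8]
  rules <- induce_rules(train)
  base <- asm_params()
  best <- tune_params(rules, dev, base = base, method = "grid", grid = 0:6)
  ## exhaustive oracle over the same grid
  fs <- vapply(0:6, function(eta) {
    types <- sort(unique(vapply(rules, `[[`, "", "event_type")))
    p <- asm_params(eta = setNames(rep(eta, length(types)), types))
    tab <- score_events(extract_corpus(dev, rules, p), dev, "strict")
    f <- tab$f_score[tab$event_type == "TOTAL"]
    if (is.na(f)) 0 else f
  }, 0)
  expect_equal(unname(best$eta[1]), (0:6)[which.max(fs)])

  ## degenerate dev corpus without events: lowest threshold wins
  nodev <- build_doc("NE1", list(list(
    tokens = data.frame(surface = c("analysis", "role"),
                        lemma = c("analysis", "role"), pos = c("NN", "NN")),
    edges = data.frame(governor = 1L, dependent = 2L, label = "prep_of"),
    entities = integer(), events = list())))
  expect_message(
    flat <- tune_params(rules, list(nodev), base = base, method = "grid",
                        grid = c(2, 0, 5)),
    "no gold events")
  expect_equal(unname(flat$eta[1]), 0)
})

test_that("the genetic search is reproducible and beats nothing less than random", {
  docs <- generate_corpus(synth_config(n_docs = 6, seed = 31))
  train <- docs[1:4]
  dev <- docs[5:6]
  rules <- induce_rules(train)
  sc <- search_config(generations = 2, population = 4, seed = 99)
  a <- tune_params(rules, dev, sc, method = "ga")
  b <- tune_params(rules, dev, sc, method = "ga")
  expect_equal(a$eta, b$eta)
  expect_equal(c(a$w_s, a$w_l, a$w_d), c(b$w_s, b$w_l, b$w_d))
  expect_error(tune_params(rules, list(), sc), class = "asm_config_error")
})
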