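simple_rule <- function(g, trigger = g$tokens$index[1],
                        slot = g$tokens$index[nrow(g$tokens)],
                        kind = "entity", type = "Test_event") {
  event_rule(g, type, trigger,
             data.frame(role = "Theme", node = slot, filler_kind = kind),
             "individual")
}

test_that("start nodes follow the lowest-index entity-first policy", {
  g <- mk_graph(tok_df(3, lemmas = c("a", "b", "c")), c("1,2,x", "2,3,y"))
  ge <- generalize_entities(g, data.frame(id = c("T1", "T2"),
                                          head = c(2L, 3L)))
  expect_equal(start_node(simple_rule(ge)), 2L)
  expect_equal(start_node(simple_rule(g)), 1L)
  one <- path_union(g, all_shortest_dep_paths(g, 2, 2))
  expect_equal(start_node(simple_rule(one, trigger = 2L, slot = 2L)), 2L)

  ## sentence candidates: entity tokens for entity-start rules, all others
  sent <- generalize_entities(
    mk_graph(tok_df(5), c("1,2,x", "2,3,y", "3,4,z", "4,5,w")),
    data.frame(id = c("T1", "T2", "T3"), head = c(1L, 3L, 5L)))
  expect_equal(candidate_start_nodes(sent, simple_rule(ge)), c(1L, 3L, 5L))
  expect_equal(candidate_start_nodes(sent, simple_rule(g)), 1:5)
  no_ent <- mk_graph(tok_df(3), c("1,2,x", "2,3,y"))
  expect_equal(candidate_start_nodes(no_ent, simple_rule(ge)), integer())
})

test_that("match_node honors the criteria, POS relaxation and entity masking", {
  tok <- function(surface, lemma, pos, entity = FALSE) {
    data.frame(surface = surface, lemma = lemma, pos = pos,
               is_entity = entity, entity_ref = if (entity) "T1" else NA)
  }
  ## plural noun matches singular under P*
  expect_true(match_node(tok("ligation", "ligation", "NN"),
                         tok("ligations", "ligation", "NNS"), "P*+L"))
  expect_false(match_node(tok("ligation", "ligation", "NN"),
                          tok("ligations", "ligation", "NNS"), "P+L"))
  ## verb conjugations share a class; verb vs noun do not
  expect_true(match_node(tok("lead", "lead", "VBP"),
                         tok("leads", "lead", "VBZ"), "P*+L"))
  expect_false(match_node(tok("lead", "lead", "VBP"),
                          tok("lead", "lead", "NN"), "P*+L"))
  ## entity mask: entity rule nodes match entity tokens only
  expect_true(match_node(tok("IL2", "IL2", "NN", TRUE),
                         tok("STAT3", "STAT3", "NN", TRUE), "P*+L"))
  expect_false(match_node(tok("IL2", "IL2", "NN", TRUE),
                          tok("binding", "binding", "NN"), "P*+L"))
  expect_false(match_node(tok("binding", "binding", "NN"),
                          tok("STAT3", "STAT3", "NN", TRUE), "P*+L"))
  ## exact-token criterion and missing-lemma error
  expect_false(match_node(tok("leads", "lead", "VBZ"),
                          tok("lead", "lead", "VBP"), "A"))
  expect_error(match_node(tok("x", "", "NN"), tok("x", "", "NN"), "L"),
               class = "asm_config_error")
  ## trigger lexicon criterion
  expect_true(match_node(tok("binding", "binding", "NN"),
                         tok("binding", "binding", "NN"), "T",
                         rule_is_trigger = TRUE,
                         trigger_lexicon = "binding"))
  expect_false(match_node(tok("binding", "binding", "NN"),
                          tok("binding", "binding", "NN"), "T",
                          rule_is_trigger = TRUE,
                          trigger_lexicon = "expression"))
})

test_that("enumerate_mappings yields exactly the injective schemes", {
  p <- asm_params()
  ## 2 rule nodes, candidate sets of sizes 1 and 2 -> 2 mappings
  rule <- simple_rule(mk_graph(tok_df(2, lemmas = c("induce", "level")),
                               "1,2,dobj"))
  sent <- mk_graph(tok_df(4, lemmas = c("induce", "level", "level", "cell")),
                   c("1,2,dobj", "1,3,dobj", "3,4,nn"))
  maps <- enumerate_mappings(rule, sent, p, c(1L, 1L))
  expect_length(maps, 2L)
  expect_equal(vapply(maps, function(m) m[["2"]], 0L), c(2L, 3L))
  ## injectivity: both rule nodes wanting the same sole candidate -> none
  rule2 <- simple_rule(mk_graph(tok_df(2, lemmas = c("induce", "induce")),
                                "1,2,dobj"))
  sent2 <- mk_graph(tok_df(2, lemmas = c("induce", "cell")), "1,2,dobj")
  expect_length(enumerate_mappings(rule2, sent2, p, c(1L, 1L)), 0L)
  ## empty candidate list for any rule node -> empty result
  rule3 <- simple_rule(mk_graph(tok_df(2, lemmas = c("induce", "kinase")),
                                "1,2,dobj"))
  expect_length(enumerate_mappings(rule3, sent2, p, c(1L, 1L)), 0L)
  ## scheme cap abandons the start pair with a warning
  tight <- asm_params(scheme_cap = 3)
  big_sent <- mk_graph(tok_df(7, lemmas = c("induce", rep("level", 6))),
                       sprintf("1,%d,dobj", 2:7))
  big_rule <- simple_rule(mk_graph(tok_df(3, lemmas = c("induce", "level",
                                                        "level")),
                                   c("1,2,dobj", "1,3,dobj")))
  expect_warning(capped <- enumerate_mappings(big_rule, big_sent, tight,
                                              c(1L, 1L)),
                 "abandoned")
  expect_length(capped, 0L)
})

test_that("enumerate_mappings equals the brute-force assignment set on random instances", {
  p <- asm_params()
  for (seed in 1:40) {
    inst <- make_instance(seed)
    want <- bf_injective_mappings(inst$rule, inst$sentence, p)
    s_r <- start_node(inst$rule)
    got <- list()
    for (s_s in candidate_start_nodes(inst$sentence, inst$rule)) {
      got <- c(got, enumerate_mappings(inst$rule, inst$sentence, p,
                                       c(s_r, s_s)))
    }
    ## the brute-force set restricted to compatible start assignments
    want <- Filter(function(m) {
      m[[as.character(s_r)]] %in% vapply(want, function(w) {
        w[[as.character(s_r)]]
      }, 0L)
    }, want)
    expect_setequal(vapply(got, mapping_key, ""),
                    vapply(want, mapping_key, ""))
  }
})

test_that("struct_dist matches the pairwise formula", {
  ## single-edge rule mapped onto a distance-3 pair: |1-3| / 1 = 2
  rule <- simple_rule(mk_graph(tok_df(2, lemmas = c("a", "d")), "1,2,x"))
  sent <- mk_graph(tok_df(4, lemmas = c("a", "b", "c", "d")),
                   c("1,2,x", "2,3,x", "3,4,x"))
  expect_equal(struct_dist(rule, sent, c(`1` = 1L, `2` = 4L)), 2)
  ## distance-preserving mapping scores 0
  expect_equal(struct_dist(rule, sent, c(`1` = 1L, `2` = 2L)), 0)
  ## disconnected pair rejects the candidate
  sent2 <- mk_graph(tok_df(3), "1,2,x")
  expect_equal(struct_dist(rule, sent2, c(`1` = 1L, `2` = 3L)), Inf)
  ## single-node rules score 0
  one <- path_union(sent, all_shortest_dep_paths(sent, 2, 2))
  r1 <- simple_rule(one, trigger = 2L, slot = 2L)
  expect_equal(struct_dist(r1, sent, c(`2` = 1L)), 0)
  ## random instances against an independent pairwise loop
  for (seed in 41:60) {
    inst <- make_instance(seed)
    maps <- bf_injective_mappings(inst$rule, inst$sentence, asm_params())
    if (!length(maps)) next
    m <- maps[[1]]
    nodes <- sort(as.integer(names(m)))
    num <- 0; den <- 0; inf <- FALSE
    for (i in seq_along(nodes)) {
      for (j in seq_along(nodes)) {
        if (i < j) {
          pr <- bf_all_shortest_paths(inst$rule$graph, nodes[i], nodes[j])
          ps <- bf_all_shortest_paths(inst$sentence,
                                      m[[as.character(nodes[i])]],
                                      m[[as.character(nodes[j])]])
          if (!length(pr) || !length(ps)) { inf <- TRUE; next }
          num <- num + abs(length(pr[[1]]$edges) - length(ps[[1]]$edges))
          den <- den + length(pr[[1]]$edges)
        }
      }
    }
    want <- if (inf) Inf else if (den > 0) num / den else 0
    expect_equal(struct_dist(inst$rule, inst$sentence, m), want,
                 info = sprintf("seed %d", seed))
  }
})

test_that("label_dist counts multiset symmetric differences over paths", {
  mk_pair <- function(rule_lab, sent_lab) {
    n <- length(rule_lab) + 1L
    rule <- simple_rule(mk_graph(tok_df(n), sprintf("%d,%d,%s", 1:(n - 1),
                                                    2:n, rule_lab)))
    m <- length(sent_lab) + 1L
    sent <- mk_graph(tok_df(m), sprintf("%d,%d,%s", 1:(m - 1), 2:m,
                                        sent_lab))
    list(rule = rule, sent = sent)
  }
  ## identical labels -> 0
  x <- mk_pair(c("nsubj", "dobj"), c("nsubj", "dobj"))
  expect_equal(label_dist(x$rule, x$sent, c(`1` = 1L, `3` = 3L)), 0)
  ## prep_of vs prep_in: a difference of two labels, normalized to 1
  x <- mk_pair("prep_of", "prep_in")
  expect_equal(label_dist(x$rule, x$sent, c(`1` = 1L, `2` = 2L)), 1)
  ## {nsubj, dobj} vs {nsubj, prep_of}: 2 / 4
  x <- mk_pair(c("nsubj", "dobj"), c("nsubj", "prep_of"))
  expect_equal(label_dist(x$rule, x$sent, c(`1` = 1L, `3` = 3L)), 0.5)
})

test_that("directionality_dist scores forward/backward multisets", {
  ## identical orientations -> 0
  rule <- simple_rule(mk_graph(tok_df(2), "1,2,x"))
  sent <- mk_graph(tok_df(2), "1,2,x")
  expect_equal(directionality_dist(rule, sent, c(`1` = 1L, `2` = 2L)), 0)
  ## one edge forward vs backward -> 2/(1+1) = 1
  sent_r <- mk_graph(tok_df(2), "2,1,x")
  expect_equal(directionality_dist(rule, sent_r, c(`1` = 1L, `2` = 2L)), 1)
  ## mixed two-edge paths differing in one slot -> 2/4 = 0.5 per pair,
  ## here on the endpoints pair of a chain
  rule2 <- simple_rule(mk_graph(tok_df(3), c("1,2,x", "2,3,y")))
  sent2 <- mk_graph(tok_df(3), c("1,2,x", "3,2,y"))
  m2 <- c(`1` = 1L, `2` = 2L, `3` = 3L)
  ## pairs (1,2): 0/2, (2,3): 2/2, (1,3): 2/4 -> total (0+2+2)/(2+2+4)
  expect_equal(directionality_dist(rule2, sent2, m2), 0.5)
})

test_that("subgraph_distance is the weighted sum and validates weights", {
  expect_equal(subgraph_distance(0, 0, 0, asm_params(w_s = 3, w_l = 9,
                                                     w_d = 27)), 0)
  expect_equal(subgraph_distance(0.2, 0.5, 0, asm_params()), 7)
  expect_equal(subgraph_distance(0.3, 0.9, 0.9,
                                 asm_params(w_s = 1, w_l = 0, w_d = 0)), 0.3)
  expect_error(asm_params(w_s = -1), class = "asm_config_error")
})

test_that("an exact context matches with zero distance at threshold 0", {
  ## the prep_to individual rule against a sentence containing its context
  doc <- ligation_document()
  rules <- induce_rules(doc)
  ## trigger "lead" is token 4, sub-event trigger "phosphorylation" token 5
  reg_ind <- Filter(function(r) {
    r$event_type == "Positive_regulation" && r$variant == "individual" &&
      r$slots$node == 5
  }, rules)[[1]]
  sent <- mk_graph(tok_df(4, lemmas = c("this", "lead", "phosphorylation",
                                        "cell"),
                          pos = c("DT", "VBP", "NN", "NN")),
                   c("2,3,prep_to", "2,1,det", "3,4,nn"))
  res <- asm_match(reg_ind, sent, asm_params(eta = 0))
  expect_length(res, 1L)
  expect_equal(res[[1]]$total, 0)
  expect_equal(unname(res[[1]]$mapping[c("4", "5")]), c(2L, 3L))
})

test_that("at threshold 0 matching equals the exact-embedding oracle (sampled)", {
  p0 <- asm_params(eta = 0)
  hits <- 0L
  for (seed in 101:140) {
    inst <- make_instance(seed)
    got <- asm_match(inst$rule, inst$sentence, p0)
    want <- Filter(function(m) {
      bf_is_exact_embedding(inst$rule, inst$sentence, m)
    }, bf_injective_mappings(inst$rule, inst$sentence, p0))
    expect_setequal(vapply(got, function(r) mapping_key(r$mapping), ""),
                    vapply(want, mapping_key, ""))
    hits <- hits + length(want)
  }
  expect_gt(hits, 0L)  # the planted instances guarantee real matches
})

test_that("match sets are monotone in the threshold and components stay bounded", {
  etas <- c(0, 2, 5, 10, 25)
  for (seed in 201:225) {
    inst <- make_instance(seed)
    prev <- character()
    for (eta in etas) {
      res <- asm_match(inst$rule, inst$sentence, asm_params(eta = eta))
      keys <- sort(vapply(res, function(r) mapping_key(r$mapping), ""))
      expect_true(all(prev %in% keys),
                  info = sprintf("seed %d eta %g", seed, eta))
      prev <- keys
      for (r in res) {
        expect_gte(r$struct_d, 0)
        expect_true(r$label_d >= 0 && r$label_d <= 1)
        expect_true(r$dir_d >= 0 && r$dir_d <= 1)
        expect_equal(r$total,
                     subgraph_distance(r$struct_d, r$label_d, r$dir_d,
                                       asm_params()))
        if (r$total == 0) {
          expect_true(bf_is_exact_embedding(inst$rule, inst$sentence,
                                            r$mapping))
        }
      }
    }
  }
})

test_that("a huge threshold reduces matching to node co-occurrence", {
  inst <- make_instance(7)
  p <- asm_params(eta = 1e6)
  got <- asm_match(inst$rule, inst$sentence, p)
  want <- bf_injective_mappings(inst$rule, inst$sentence, p)
  ## co-occurrence still requires pairwise connectivity in the sentence
  want <- Filter(function(m) {
    is.finite(struct_dist(inst$rule, inst$sentence, m))
  }, want)
  expect_setequal(vapply(got, function(r) mapping_key(r$mapping), ""),
                  vapply(want, mapping_key, ""))
})
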