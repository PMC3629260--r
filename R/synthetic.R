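## Seeded generator of dependency corpora with planted (possibly nested)
## events, distractor contexts and controlled graph perturbations, so the
## whole induction / matching / pruning pipeline is testable without any
## external corpus.

default_vocab <- function() {
  list(
    filler = data.frame(
      lemma = c("the", "a", "this", "protein", "cell", "level", "activity",
                "result", "analysis", "role", "factor", "pathway",
                "response", "signal", "effect", "study", "model", "region",
                "domain", "complex"),
      pos = c("DT", "DT", "DT", "NN", "NN", "NN", "NN", "NN", "NN", "NN",
              "NN", "NN", "NN", "NN", "NN", "NN", "NN", "NN", "NN", "NN")),
    entities = c("IL2", "TNF", "STAT3", "NFKB1", "FOXP3", "GATA3", "JAK2",
                 "SOCS1", "CD28", "TGFB1", "IFNG", "CCL2"),
    mid = data.frame(
      lemma = c("amount", "degree", "extent", "fraction"),
      pos = c("NN", "NN", "NN", "NN")),
    filler_labels = c("det", "amod", "nn", "conj_and", "appos", "advmod"),
    perturb_labels = c("prep_at", "conj_or", "rcmod_alt", "dep_x"))
}

#' Synthetic event templates
#'
#' Each template plants one event context in a sentence: a trigger token
#' (lemma drawn from the template pool) connected to each argument by a
#' chain of labeled dependency edges. Entity arguments end at a
#' pre-annotated protein token; event arguments end at the trigger of a
#' recursively planted sub-event. The default set mirrors the canonical
#' event flavors: two simple single-theme types, a two-theme binding and a
#' regulation nesting a simple event with an entity cause. Argument paths
#' are two edges long so that, under equal component weights of 10, a
#' single edge relabel or flip on a context costs a subgraph distance of 5
#' and a single node insertion 9 — perturbed contexts are therefore
#' recoverable by raising the threshold, the desk-scale analogue of
#' approximate versus exact matching.
#'
#' @return A list of template specifications.
#' @export
default_event_templates <- function() {
  list(
    list(type = "Gene_expression", trigger_lemmas = c("expression", "production"),
         trigger_pos = "NN",
         args = list(list(role = "Theme", kind = "entity",
                          path = c("prep_of", "prep_in")))),
    list(type = "Phosphorylation", trigger_lemmas = "phosphorylation",
         trigger_pos = "NN",
         args = list(list(role = "Theme", kind = "entity",
                          path = c("prep_of", "nn")))),
    list(type = "Binding", trigger_lemmas = c("interaction", "binding"),
         trigger_pos = "NN",
         args = list(list(role = "Theme", kind = "entity",
                          path = c("prep_between", "nn")),
                     list(role = "Theme2", kind = "entity",
                          path = c("prep_with", "nn")))),
    list(type = "Positive_regulation", trigger_lemmas = c("induce", "enhance"),
         trigger_pos = "VBZ",
         args = list(list(role = "Theme", kind = "event", sub_template = 1L,
                          path = c("dobj", "prep_of")),
                     list(role = "Cause", kind = "entity",
                          path = c("nsubj", "nn"))))
  )
}

#' Configuration of the synthetic corpus generator
#'
#' @param n_docs number of documents.
#' @param sentences_per_doc sentences per document.
#' @param n_filler filler (non-context) tokens per sentence, joined into a
#'   random dependency tree.
#' @param extra_edges extra random edges among filler tokens per sentence,
#'   creating cycles and multiple shortest paths.
#' @param templates event templates ([default_event_templates()]).
#' @param vocab lemma/POS/label pools.
#' @param p_insert,p_relabel,p_flip per-edge perturbation rates applied to
#'   the sentence graphs after gold annotation (rates in `[0, 1]`).
#' @param distractor_rate probability that a sentence additionally carries
#'   an unannotated copy of a template context (a designed false-positive
#'   context for rule pruning).
#' @param seed RNG seed; fixes the corpus byte-for-byte.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_docs = 10, sentences_per_doc = 2, n_filler = 5,
                         extra_edges = 1, templates = default_event_templates(),
                         vocab = default_vocab(), p_insert = 0, p_relabel = 0,
                         p_flip = 0, distractor_rate = 0.25, seed = 1L) {
  rates <- c(p_insert, p_relabel, p_flip, distractor_rate)
  if (any(rates < 0 | rates > 1)) config_error("rates must lie in [0, 1]")
  structure(list(n_docs = n_docs, sentences_per_doc = sentences_per_doc,
                 n_filler = n_filler, extra_edges = extra_edges,
                 templates = templates, vocab = vocab, p_insert = p_insert,
                 p_relabel = p_relabel, p_flip = p_flip,
                 distractor_rate = distractor_rate, seed = as.integer(seed)),
            class = "synth_config")
}

## One sentence plan: token table, edge list, entity records and gold event
## records (with token anchors); offsets are resolved later by the standoff
## reader.
plan_sentence <- function(cfg, sent_no) {
  v <- cfg$vocab
  tokens <- data.frame(surface = character(), lemma = character(),
                       pos = character(), entity = logical())
  edges <- data.frame(governor = integer(), dependent = integer(),
                      label = character())
  add_token <- function(surface, lemma, pos, entity = FALSE) {
    tokens <<- rbind(tokens, data.frame(surface = surface, lemma = lemma,
                                        pos = pos, entity = entity))
    nrow(tokens)
  }
  add_edge <- function(g, d, label) {
    edges <<- rbind(edges, data.frame(governor = g, dependent = d,
                                      label = label))
  }
  ## filler backbone: random tree plus extra edges
  nf <- cfg$n_filler
  fill_rows <- sample.int(nrow(v$filler), nf, replace = TRUE)
  for (r in fill_rows) {
    add_token(v$filler$lemma[r], v$filler$lemma[r], v$filler$pos[r])
  }
  if (nf > 1) {
    for (i in 2:nf) {
      add_edge(sample.int(i - 1, 1), i, sample(v$filler_labels, 1))
    }
    for (k in seq_len(cfg$extra_edges)) {
      ab <- sample.int(nf, 2)
      add_edge(ab[1], ab[2], sample(v$filler_labels, 1))
    }
  }
  attach_to_backbone <- function(node) {
    if (nf > 0) add_edge(sample.int(nf, 1), node, sample(v$filler_labels, 1))
  }

  entities <- list()   # list(token)
  events <- list()     # list(type, trigger_token, args = list(role, kind, anchor))
  plant <- function(tmpl, annotate) {
    tl <- sample(tmpl$trigger_lemmas, 1)
    trig <- add_token(tl, tl, tmpl$trigger_pos)
    attach_to_backbone(trig)
    args <- list()
    for (a in tmpl$args) {
      if (a$kind == "event") {
        sub_ev <- plant(cfg$templates[[a$sub_template]], annotate)
        target <- sub_ev$trigger_token
        anchor <- list(kind = "event", event_index = sub_ev$index)
      } else {
        name <- sample(cfg$vocab$entities, 1)
        target <- add_token(name, name, "NN", entity = TRUE)
        entities[[length(entities) + 1L]] <<- list(token = target)
        anchor <- list(kind = "entity", token = target)
      }
      ## chain trigger -> mid ... -> target
      prev <- trig
      np <- length(a$path)
      if (np > 1) {
        for (k in seq_len(np - 1)) {
          mr <- sample.int(nrow(v$mid), 1)
          mid <- add_token(v$mid$lemma[mr], v$mid$lemma[mr], v$mid$pos[mr])
          add_edge(prev, mid, a$path[k])
          prev <- mid
        }
      }
      add_edge(prev, target, a$path[np])
      args[[length(args) + 1L]] <- c(list(role = a$role), anchor)
    }
    idx <- NA_integer_
    if (annotate) {
      events[[length(events) + 1L]] <<- list(type = tmpl$type,
                                             trigger_token = trig, args = args)
      idx <- length(events)
    }
    list(trigger_token = trig, index = idx)
  }

  tmpl <- cfg$templates[[sample.int(length(cfg$templates), 1)]]
  plant(tmpl, annotate = TRUE)
  if (stats::runif(1) < cfg$distractor_rate) {
    ## unannotated copy of a (simple) template context: a designed FP
    simple <- Filter(function(t) !any(vapply(t$args, function(a) {
      a$kind == "event"
    }, TRUE)), cfg$templates)
    plant(simple[[sample.int(length(simple), 1)]], annotate = FALSE)
  }
  list(tokens = tokens, edges = edges, entities = entities, events = events)
}

#' Generate a synthetic annotated corpus
#'
#' Produces documents with consistent text and character offsets, sentence
#' dependency graphs, `.a1` entity annotations and `.a2` gold events, all
#' derived from the planted templates. With all perturbation rates zero,
#' every planted event's rule context is exactly recoverable; non-zero
#' rates perturb the sentence graphs after annotation (gold unchanged),
#' emulating parse variation.
#'
#' @param cfg a [synth_config()].
#' @return List of `annotated_document` objects.
#' @export
generate_corpus <- function(cfg) {
  if (cfg$n_docs == 0) return(list())
  docs <- with_seed(cfg$seed, {
    lapply(seq_len(cfg$n_docs), function(d) {
      doc_id <- sprintf("SYN%03d", d)
      plans <- lapply(seq_len(cfg$sentences_per_doc), function(s) {
        plan_sentence(cfg, s)
      })
      build_document(doc_id, plans)
    })
  })
  if (cfg$p_insert > 0 || cfg$p_relabel > 0 || cfg$p_flip > 0) {
    docs <- perturb_corpus(docs, cfg)
  }
  docs
}

## Assemble text / a1 / a2 lines from sentence plans and anchor them via
## the standoff reader (one reader path for real and synthetic data).
build_document <- function(doc_id, plans) {
  sent_text <- character()
  parses <- list()
  a1 <- character(); a2 <- character()
  ent_n <- 0L
  trig_ids <- list()  # per sentence: event index -> trigger id
  ev_n <- 0L
  offset <- 0L
  trig_n_total <- sum(vapply(plans, function(p) length(p$events), 0L))
  ent_total <- sum(vapply(plans, function(p) length(p$entities), 0L))
  trig_next <- ent_total
  ev_lines <- character()
  for (s in seq_along(plans)) {
    p <- plans[[s]]
    n <- nrow(p$tokens)
    starts <- integer(n); ends <- integer(n)
    pos <- offset
    for (i in seq_len(n)) {
      starts[i] <- pos
      ends[i] <- pos + nchar(p$tokens$surface[i])
      pos <- ends[i] + 1L
    }
    sent_text <- c(sent_text, paste(p$tokens$surface, collapse = " "))
    parses[[s]] <- dep_graph(
      data.frame(index = seq_len(n), surface = p$tokens$surface,
                 lemma = p$tokens$lemma, pos = p$tokens$pos),
      p$edges, sprintf("%s.s%d", doc_id, s))
    ent_ids <- character(length(p$entities))
    for (k in seq_along(p$entities)) {
      t <- p$entities[[k]]$token
      ent_n <- ent_n + 1L
      ent_ids[k] <- sprintf("T%d", ent_n)
      a1 <- c(a1, sprintf("%s\tProtein %d %d\t%s", ent_ids[k], starts[t],
                          ends[t], p$tokens$surface[t]))
    }
    ent_id_of_token <- setNames(ent_ids,
                                vapply(p$entities, `[[`, 0L, "token"))
    ev_ids <- character(length(p$events))
    for (k in seq_along(p$events)) {
      ev <- p$events[[k]]
      trig_next <- trig_next + 1L
      tid <- sprintf("T%d", trig_next)
      t <- ev$trigger_token
      a2 <- c(a2, sprintf("%s\t%s %d %d\t%s", tid, ev$type, starts[t],
                          ends[t], p$tokens$surface[t]))
      ev_n <- ev_n + 1L
      ev_ids[k] <- sprintf("E%d", ev_n)
      args <- vapply(ev$args, function(a) {
        ref <- if (a$kind == "event") ev_ids[a$event_index] else {
          ent_id_of_token[[as.character(a$token)]]
        }
        sprintf("%s:%s", a$role, ref)
      }, "")
      ev_lines <- c(ev_lines, sprintf("%s\t%s:%s %s", ev_ids[k], ev$type,
                                      tid, paste(args, collapse = " ")))
    }
    offset <- offset + nchar(sent_text[s]) + 1L
  }
  read_standoff(sent_text, a1, c(a2, ev_lines), parses, doc_id)
}

#' Perturb a dependency graph
#'
#' Applies three independent per-edge Bernoulli perturbations: `p_relabel`
#' swaps the edge label for a different one from the perturbation pool,
#' `p_flip` reverses the edge direction, and `p_insert` splices a fresh
#' token into the edge (the original label stays on the first half, the
#' second half is labeled `dep`), lengthening the path through that edge
#' by one. Gold annotations are untouched; token offsets of inserted
#' tokens are undefined.
#'
#' @param g a [dep_graph()].
#' @param rates list or vector with `p_insert`, `p_relabel`, `p_flip`.
#' @param seed RNG seed.
#' @param label_pool labels available for relabeling.
#' @return The perturbed `dep_graph`.
#' @export
perturb <- function(g, rates, seed = 1L,
                    label_pool = default_vocab()$perturb_labels) {
  p_insert <- rates[["p_insert"]] %||% 0
  p_relabel <- rates[["p_relabel"]] %||% 0
  p_flip <- rates[["p_flip"]] %||% 0
  ne <- nrow(g$edges)
  if (!ne) return(g)
  with_seed(seed, {
    edges <- g$edges
    tokens <- g$tokens
    relab <- stats::runif(ne) < p_relabel
    flip <- stats::runif(ne) < p_flip
    ins <- stats::runif(ne) < p_insert
    for (e in which(relab)) {
      pool <- setdiff(label_pool, edges$label[e])
      edges$label[e] <- pool[sample.int(length(pool), 1)]
    }
    if (any(flip)) {
      tmp <- edges$governor[flip]
      edges$governor[flip] <- edges$dependent[flip]
      edges$dependent[flip] <- tmp
    }
    next_idx <- max(tokens$index) + 1L
    for (e in which(ins)) {
      new_tok <- data.frame(index = next_idx,
                            surface = sprintf("ins%d", next_idx),
                            lemma = sprintf("ins%d", next_idx), pos = "NN",
                            is_entity = FALSE, entity_ref = NA_character_,
                            start = NA_integer_, end = NA_integer_)
      tokens <- rbind(tokens, new_tok)
      edges <- rbind(edges,
                     data.frame(governor = next_idx,
                                dependent = edges$dependent[e],
                                label = "dep"))
      edges$dependent[e] <- next_idx
      next_idx <- next_idx + 1L
    }
    dep_graph(tokens, edges, g$sentence_id)
  })
}

#' Perturb every sentence graph of a corpus
#'
#' @param docs list of `annotated_document` objects.
#' @param cfg a [synth_config()] (or any list with the three rates and a
#'   seed).
#' @return The documents with perturbed sentence graphs; annotations are
#'   unchanged.
#' @export
perturb_corpus <- function(docs, cfg) {
  rates <- list(p_insert = cfg$p_insert, p_relabel = cfg$p_relabel,
                p_flip = cfg$p_flip)
  counter <- 0L
  lapply(docs, function(doc) {
    doc$sentences <- lapply(doc$sentences, function(g) {
      counter <<- counter + 1L
      perturb(g, rates, seed = cfg$seed + 7919L * counter)
    })
    doc
  })
}

#' Write a corpus as standoff + parse files
#'
#' Writes per document: `<id>.txt`, `<id>.a1`, `<id>.a2`, `<id>.sd`
#' (Stanford-dependency triples, one blank-line-separated block per
#' sentence), `<id>.tok` (sidecar token tables) and `<id>.conll`.
#'
#' @param docs list of `annotated_document` objects.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(docs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (doc in docs) {
    base <- file.path(dir, doc$doc_id)
    writeLines(sub("\n$", "", doc$text), paste0(base, ".txt"), sep = "\n")
    a1 <- sprintf("%s\t%s %d %d\t%s", doc$entities$id, doc$entities$type,
                  doc$entities$start, doc$entities$end, doc$entities$text)
    writeLines(a1, paste0(base, ".a1"))
    a2 <- character()
    if (nrow(doc$triggers)) {
      a2 <- sprintf("%s\t%s %d %d\t%s", doc$triggers$id, doc$triggers$type,
                    doc$triggers$start, doc$triggers$end, doc$triggers$text)
    }
    for (id in names(doc$events)) {
      ev <- doc$events[[id]]
      args <- vapply(ev$args, function(a) sprintf("%s:%s", a$role, a$ref), "")
      a2 <- c(a2, sprintf("%s\t%s:%s %s", id, ev$event_type, ev$trigger,
                          paste(args, collapse = " ")))
    }
    writeLines(a2, paste0(base, ".a2"))
    blocks <- function(fmt) {
      unlist(lapply(doc$sentences, function(g) c(fmt(g), "")))
    }
    writeLines(blocks(format_sd), paste0(base, ".sd"))
    writeLines(blocks(format_token_table), paste0(base, ".tok"))
    writeLines(blocks(format_conll), paste0(base, ".conll"))
  }
  invisible(dir)
}

#' Read a corpus directory written by [write_corpus()]
#'
#' @param dir corpus directory containing `.txt`, `.a1`, optional `.a2`
#'   and parse files (`.sd` + `.tok`, or `.conll`).
#' @param dialect parse dialect to prefer: `"sd"` or `"conll"`.
#' @return List of `annotated_document` objects.
#' @export
read_corpus <- function(dir, dialect = c("sd", "conll")) {
  dialect <- match.arg(dialect)
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  lapply(txts, function(tf) {
    base <- sub("\\.txt$", "", tf)
    doc_id <- basename(base)
    text <- readLines(tf)
    a1 <- if (file.exists(paste0(base, ".a1"))) readLines(paste0(base, ".a1")) else character()
    a2 <- if (file.exists(paste0(base, ".a2"))) readLines(paste0(base, ".a2")) else NULL
    parses <- NULL
    sd_f <- paste0(base, ".sd")
    co_f <- paste0(base, ".conll")
    if (dialect == "sd" && file.exists(sd_f)) {
      sd_blocks <- read_blocks(sd_f)
      tok_blocks <- if (file.exists(paste0(base, ".tok"))) {
        read_blocks(paste0(base, ".tok"))
      } else {
        NULL
      }
      parses <- lapply(seq_along(sd_blocks), function(s) {
        tt <- if (!is.null(tok_blocks)) parse_token_table(tok_blocks[[s]]) else NULL
        parse_sd(sd_blocks[[s]], tt, sprintf("%s.s%d", doc_id, s))
      })
    } else if (file.exists(co_f)) {
      co_blocks <- read_blocks(co_f)
      parses <- lapply(seq_along(co_blocks), function(s) {
        parse_conll(co_blocks[[s]], sprintf("%s.s%d", doc_id, s))
      })
    }
    read_standoff(text, a1, a2, parses, doc_id)
  })
}
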