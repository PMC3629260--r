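## Parameter search: integer genetic algorithm maximizing the strict
## F-score on development data, with an exhaustive grid fallback.

#' Search configuration for parameter tuning
#'
#' @param generations number of GA generations (default 50).
#' @param population population size per generation (default 100).
#' @param range integer search range for every gene (default `c(0, 50)`).
#' @param seed RNG seed; fixes the whole search.
#' @param equal_weights constrain `w_s = w_l = w_d` to a single gene.
#' @return An object of class `search_config`.
#' @export
search_config <- function(generations = 50, population = 100,
                          range = c(0L, 50L), seed = 1L,
                          equal_weights = TRUE) {
  if (population < 2) config_error("population must be >= 2")
  if (range[1] > range[2]) config_error("invalid search range")
  structure(list(generations = generations, population = population,
                 range = as.integer(range), seed = as.integer(seed),
                 equal_weights = equal_weights),
            class = "search_config")
}

params_from_genes <- function(genes, types, base) {
  nt <- length(types)
  eta <- setNames(as.numeric(genes[seq_len(nt)]), types)
  w <- as.numeric(genes[-seq_len(nt)])
  if (length(w) == 1) w <- rep(w, 3)
  asm_params(w_s = w[1], w_l = w[2], w_d = w[3], eta = eta,
             default_eta = base$default_eta, criteria = base$criteria,
             rho = base$rho, scheme_cap = base$scheme_cap,
             trigger_lexicon = base$trigger_lexicon)
}

strict_f <- function(dev_docs, ruleset, params) {
  preds <- extract_corpus(dev_docs, ruleset, params)
  tab <- score_events(preds, dev_docs, "strict")
  f <- tab$f_score[tab$event_type == "TOTAL"]
  if (!length(f) || is.na(f)) 0 else f
}

## conservative tie-break: prefer smaller thresholds, then smaller weights
genes_less <- function(a, b, nt) {
  ka <- c(sum(a[seq_len(nt)]), sum(a[-seq_len(nt)]), a)
  kb <- c(sum(b[seq_len(nt)]), sum(b[-seq_len(nt)]), b)
  for (i in seq_along(ka)) {
    if (ka[i] < kb[i]) return(TRUE)
    if (ka[i] > kb[i]) return(FALSE)
  }
  FALSE
}

#' Tune matching parameters against development data
#'
#' Learns rules from the training documents, then searches integer-valued
#' per-type thresholds and distance weights (range `[0, 50]`) maximizing
#' the overall strict F-score of extraction on the development documents.
#' The default search is a seeded genetic algorithm (tournament selection
#' of size 2, uniform crossover, per-gene mutation 0.1, elitism 1); for
#' small spaces `method = "grid"` evaluates an exhaustive threshold grid
#' with the base weights. Ties prefer the smallest thresholds, then the
#' smallest weights.
#'
#' @param train_docs training documents (rules are induced from these), or
#'   a pre-induced rule list.
#' @param dev_docs development documents with gold events.
#' @param search a [search_config()].
#' @param base an [asm_params()] supplying criteria and fixed settings.
#' @param method `"ga"` or `"grid"`.
#' @param grid for `method = "grid"`: integer vector of thresholds to try
#'   (applied to all types).
#' @return The best [asm_params()] found.
#' @export
tune_params <- function(train_docs, dev_docs, search = search_config(),
                        base = asm_params(), method = c("ga", "grid"),
                        grid = 0:10) {
  method <- match.arg(method)
  if (inherits(dev_docs, "annotated_document")) dev_docs <- list(dev_docs)
  if (!length(dev_docs)) config_error("empty development corpus")
  if (!any(vapply(dev_docs, function(d) length(d$events) > 0, TRUE))) {
    message("development corpus has no gold events; F is 0 everywhere")
  }
  ruleset <- if (length(train_docs) && inherits(train_docs[[1]], "event_rule")) {
    train_docs
  } else {
    induce_rules(train_docs)
  }
  types <- sort(unique(vapply(ruleset, `[[`, "", "event_type")))
  if (!length(types)) config_error("no rules could be induced from training data")
  nt <- length(types)

  if (method == "grid") {
    best <- NULL; best_f <- -1
    for (eta in sort(grid)) {
      genes <- c(rep(as.integer(eta), nt),
                 if (search$equal_weights) base$w_s else c(base$w_s, base$w_l, base$w_d))
      f <- strict_f(dev_docs, ruleset,
                    params_from_genes(genes, types, base))
      if (f > best_f) { best_f <- f; best <- genes }
    }
    return(params_from_genes(best, types, base))
  }

  ngene <- nt + if (search$equal_weights) 1L else 3L
  lo <- search$range[1]; hi <- search$range[2]
  with_seed(search$seed, {
    pop <- lapply(seq_len(search$population), function(i) {
      sample(lo:hi, ngene, replace = TRUE)
    })
    fit <- vapply(pop, function(g) {
      strict_f(dev_docs, ruleset, params_from_genes(g, types, base))
    }, 0)
    best <- pop[[which.max(fit)]]; best_f <- max(fit)
    for (gen in seq_len(search$generations)) {
      newpop <- list(best)  # elitism
      while (length(newpop) < search$population) {
        pick <- function() {
          c2 <- sample.int(search$population, 2)
          if (fit[c2[1]] >= fit[c2[2]]) pop[[c2[1]]] else pop[[c2[2]]]
        }
        p1 <- pick(); p2 <- pick()
        mask <- stats::runif(ngene) < 0.5
        child <- ifelse(mask, p1, p2)
        mut <- stats::runif(ngene) < 0.1
        if (any(mut)) child[mut] <- sample(lo:hi, sum(mut), replace = TRUE)
        newpop[[length(newpop) + 1L]] <- as.integer(child)
      }
      pop <- newpop
      fit <- vapply(pop, function(g) {
        strict_f(dev_docs, ruleset, params_from_genes(g, types, base))
      }, 0)
      gi <- which.max(fit)
      if (fit[gi] > best_f ||
          (fit[gi] == best_f && genes_less(pop[[gi]], best, nt))) {
        best <- pop[[gi]]; best_f <- fit[gi]
      }
    }
    params_from_genes(best, types, base)
  })
}
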