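## Matching parameters: distance weights, per-type thresholds, node-match
## criteria, pruning ratio.

GE_EVENT_TYPES <- c("Gene_expression", "Transcription", "Protein_catabolism",
                    "Phosphorylation", "Localization", "Binding",
                    "Regulation", "Positive_regulation", "Negative_regulation")

## Optimized thresholds and weights for the GENIA event task (the shipped
## default profile).
ge_default_eta <- c(
  Gene_expression = 7, Transcription = 5, Protein_catabolism = 7,
  Phosphorylation = 10, Localization = 10, Binding = 7,
  Regulation = 3, Positive_regulation = 3, Negative_regulation = 3)

#' Matching parameter set
#'
#' Bundles everything the approximate subgraph matcher needs: the three
#' non-negative distance weights, a per-event-type distance threshold map,
#' the node-match criteria, the rule-pruning ratio and a guard on the
#' number of candidate mapping schemes explored per start pair. The shipped
#' defaults are the optimized profile for the GENIA event task: thresholds
#' 7/5/7/10/10/7 for the simple and binding types, 3 for the regulation
#' types, and equal weights \eqn{w_s = w_l = w_d = 10} with criteria
#' `"P*+L"` (relaxed POS class plus lemma).
#'
#' @param w_s,w_l,w_d non-negative weights of the structural, edge-label and
#'   edge-direction distance components.
#' @param eta named numeric vector mapping event types to distance
#'   thresholds, or a single unnamed value applied to every type.
#' @param default_eta threshold for event types absent from `eta`.
#' @param criteria node-match criteria string: `+`-separated subset of
#'   `P` (exact POS), `P*` (relaxed POS class), `L` (lemma), `A` (exact
#'   token), `T` (known-trigger lexicon).
#' @param rho pruning ratio: predicting rules with TP:FP below `rho` are
#'   removed (default `0.25`, the 1:4 ratio).
#' @param scheme_cap maximum candidate node matching schemes explored per
#'   start pair before the pair is abandoned with a warning.
#' @param trigger_lexicon character vector of known trigger lemmas backing
#'   the `T` criterion.
#' @return An object of class `asm_params`.
#' @export
asm_params <- function(w_s = 10, w_l = 10, w_d = 10, eta = ge_default_eta,
                       default_eta = 7, criteria = "P*+L", rho = 0.25,
                       scheme_cap = 100000, trigger_lexicon = character()) {
  if (any(c(w_s, w_l, w_d) < 0)) config_error("distance weights must be >= 0")
  if (any(eta < 0) || default_eta < 0) config_error("thresholds must be >= 0")
  if (length(eta) > 1 && is.null(names(eta))) {
    config_error("a multi-valued eta must be named by event type")
  }
  feats <- parse_criteria(criteria)
  structure(list(w_s = w_s, w_l = w_l, w_d = w_d, eta = eta,
                 default_eta = default_eta, criteria = criteria,
                 features = feats, rho = rho, scheme_cap = scheme_cap,
                 trigger_lexicon = trigger_lexicon),
            class = "asm_params")
}

parse_criteria <- function(criteria) {
  feats <- strsplit(criteria, "+", fixed = TRUE)[[1]]
  bad <- setdiff(feats, c("P", "P*", "L", "A", "T"))
  if (length(bad) || !length(feats)) {
    config_error(sprintf("unknown node-match criteria '%s'", criteria))
  }
  feats
}

#' @export
print.asm_params <- function(x, ...) {
  cat(sprintf("<asm_params: w=(%g,%g,%g), criteria %s, rho %g>\n",
              x$w_s, x$w_l, x$w_d, x$criteria, x$rho))
  if (length(x$eta) > 1) {
    cat("  thresholds:", paste(sprintf("%s=%g", names(x$eta), x$eta),
                               collapse = ", "), "\n")
  } else {
    cat(sprintf("  threshold: %g (all types)\n", x$eta))
  }
  invisible(x)
}

eta_for <- function(params, event_type) {
  if (is.null(names(params$eta))) return(params$eta[[1]])
  v <- params$eta[[event_type]] %||% NULL
  if (is.null(v) || is.na(v)) params$default_eta else v
}

#' Read or write a parameter file
#'
#' Parameter files are flat YAML key-value maps with keys `w_s`, `w_l`,
#' `w_d`, `criteria`, `rho`, `scheme_cap`, `default_eta` and an `eta` map
#' from event type to threshold.
#'
#' @param path file path.
#' @return `read_params` returns an [asm_params()] object.
#' @export
read_params <- function(path) {
  y <- yaml::read_yaml(path)
  eta <- if (is.null(y$eta)) ge_default_eta else unlist(y$eta)
  asm_params(w_s = y$w_s %||% 10, w_l = y$w_l %||% 10, w_d = y$w_d %||% 10,
             eta = eta, default_eta = y$default_eta %||% 7,
             criteria = y$criteria %||% "P*+L", rho = y$rho %||% 0.25,
             scheme_cap = y$scheme_cap %||% 100000,
             trigger_lexicon = as.character(y$trigger_lexicon %||% character()))
}

#' @rdname read_params
#' @param params an [asm_params()] object.
#' @export
write_params <- function(params, path) {
  y <- list(w_s = params$w_s, w_l = params$w_l, w_d = params$w_d,
            eta = as.list(params$eta), default_eta = params$default_eta,
            criteria = params$criteria, rho = params$rho,
            scheme_cap = params$scheme_cap)
  if (length(params$trigger_lexicon)) y$trigger_lexicon <- params$trigger_lexicon
  yaml::write_yaml(y, path)
  invisible(path)
}
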