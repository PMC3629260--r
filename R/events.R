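## Event objects: a predicted or gold event is a typed trigger token set
## plus role-labeled arguments whose fillers are entities or nested events.

#' Construct an event
#'
#' @param event_type event type string.
#' @param trigger_tokens integer vector of sentence token indices.
#' @param args list of `list(role, filler)`; a filler is either
#'   `list(kind = "entity", id, token)` or `list(kind = "event", event)`.
#' @param source_rules character vector of rule ids that produced the event.
#' @return An object of class `asm_event`.
#' @export
new_event <- function(event_type, trigger_tokens, args,
                      source_rules = character()) {
  structure(list(event_type = event_type,
                 trigger_tokens = sort(as.integer(trigger_tokens)),
                 args = args, source_rules = source_rules),
            class = "asm_event")
}

#' @export
print.asm_event <- function(x, ...) {
  cat(event_signature(x), "\n")
  invisible(x)
}

#' Canonical signature of an event
#'
#' A deterministic serialization of the recursive event structure (type,
#' trigger token set, sorted role/filler pairs). Two events are strictly
#' equal iff their signatures are equal; signatures drive deduplication and
#' strict scoring.
#'
#' @param ev an `asm_event`.
#' @return character scalar.
#' @export
event_signature <- function(ev) {
  args <- vapply(ev$args, function(a) {
    f <- a$filler
    fs <- if (identical(f$kind, "entity")) {
      sprintf("ent:%s@%d", f$id %||% "?", f$token)
    } else {
      sprintf("[%s]", event_signature(f$event))
    }
    ## Theme/Theme2/... are interchangeable slots of one multi-theme event
    role <- if (is_theme_role(a$role)) "Theme" else a$role
    paste0(role, "=", fs)
  }, "")
  sprintf("%s<%s>(%s)", ev$event_type,
          paste(ev$trigger_tokens, collapse = ","),
          paste(sort(args), collapse = ";"))
}

has_theme <- function(ev) {
  any(is_theme_role(vapply(ev$args, `[[`, "", "role")))
}

#' Precision / recall / F-score carrier
#'
#' @param tp,fp,fn non-negative counts.
#' @return A one-row data.frame with counts and ratios; precision, recall
#'   and F are `NA` when undefined (zero denominators).
#' @export
prf <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  r <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f <- if (!is.na(p) && !is.na(r) && (p + r) > 0) 2 * p * r / (p + r) else {
    if (tp + fp + fn == 0) NA_real_ else 0
  }
  data.frame(tp = tp, fp = fp, fn = fn, precision = p, recall = r,
             f_score = f)
}
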