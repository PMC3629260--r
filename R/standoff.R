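## BioNLP-ST standoff annotations (.txt / .a1 / .a2) and their anchoring to
## dependency-graph tokens. Character offsets are 0-based, half-open.

#' Tokens covered by a character span
#'
#' Returns the minimal set of tokens of a sentence graph whose character
#' offsets intersect `[start, end)`. A span that splits a token expands to
#' the covering token, since graph nodes are whole tokens.
#'
#' @param sentence a `dep_graph` whose tokens carry `start`/`end` offsets.
#' @param start,end 0-based half-open character offsets.
#' @return Integer vector of token indices (ascending), never empty.
#' @export
anchor_span <- function(sentence, start, end) {
  tok <- sentence$tokens
  known <- !is.na(tok$start)
  if (!any(known)) range_error("sentence tokens carry no character offsets")
  lo <- min(tok$start[known]); hi <- max(tok$end[known])
  if (start < lo || end > hi || start >= end) {
    range_error(sprintf("span [%d,%d) outside sentence [%d,%d)",
                        start, end, lo, hi))
  }
  hit <- known & tok$start < end & tok$end > start
  if (!any(hit)) range_error(sprintf("span [%d,%d) covers no token", start, end))
  sort(tok$index[hit])
}

is_theme_role <- function(role) grepl("^Theme[0-9]*$", role)

parse_a1_lines <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  out <- data.frame(id = character(), type = character(), start = integer(),
                    end = integer(), text = character())
  for (l in lines) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3 || !grepl("^T", f[1])) {
      parse_error(sprintf("malformed entity line '%s'", l))
    }
    m <- strsplit(f[2], " ", fixed = TRUE)[[1]]
    out <- rbind(out, data.frame(id = f[1], type = m[1],
                                 start = as.integer(m[2]),
                                 end = as.integer(m[3]), text = f[3]))
  }
  out
}

parse_a2_lines <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  triggers <- data.frame(id = character(), type = character(),
                         start = integer(), end = integer(), text = character())
  events <- list()
  for (l in lines) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (grepl("^T", f[1])) {
      m <- strsplit(f[2], " ", fixed = TRUE)[[1]]
      triggers <- rbind(triggers, data.frame(
        id = f[1], type = m[1], start = as.integer(m[2]),
        end = as.integer(m[3]), text = f[3]))
    } else if (grepl("^E", f[1])) {
      parts <- strsplit(trimws(f[2]), " +")[[1]]
      kv <- strsplit(parts, ":", fixed = TRUE)
      ev <- list(id = f[1], event_type = kv[[1]][1], trigger = kv[[1]][2],
                 args = lapply(kv[-1], function(x) list(role = x[1], ref = x[2])))
      events[[length(events) + 1L]] <- ev
    } else if (grepl("^[ME*]", f[1])) {
      next  # modification/equivalence annotations are out of scope
    } else {
      parse_error(sprintf("malformed a2 line '%s'", l))
    }
  }
  list(triggers = triggers, events = events)
}

## Assign document-level character offsets to the tokens of each sentence
## graph by aligning surfaces left-to-right within the sentence text.
## Collapsed-dependency copy tokens inherit the offsets of their originals.
align_offsets <- function(g, sent_text, sent_offset) {
  tok <- g$tokens
  base <- tok$index < sd_copy_offset
  ord <- order(tok$index[base])
  cursor <- 0L
  starts <- rep(NA_integer_, nrow(tok)); ends <- rep(NA_integer_, nrow(tok))
  rows <- which(base)[ord]
  for (i in rows) {
    hit <- regexpr(tok$surface[i], substring(sent_text, cursor + 1L),
                   fixed = TRUE)
    if (hit < 0) {
      integrity_error(sprintf(
        "token '%s' not found in sentence text of %s", tok$surface[i],
        g$sentence_id))
    }
    s <- cursor + as.integer(hit) - 1L
    starts[i] <- sent_offset + s
    ends[i] <- sent_offset + s + nchar(tok$surface[i])
    cursor <- s + nchar(tok$surface[i])
  }
  copy <- which(!base)
  if (length(copy)) {
    j <- match(tok$index[copy] %% sd_copy_offset, tok$index)
    starts[copy] <- starts[j]; ends[copy] <- ends[j]
  }
  tok$start <- starts; tok$end <- ends
  dep_graph(tok, g$edges, g$sentence_id)
}

whitespace_graph <- function(sent_text, sentence_id) {
  if (!nzchar(trimws(sent_text))) return(dep_graph(sentence_id = sentence_id))
  m <- gregexpr("[^ \t]+", sent_text)[[1]]
  dep_graph(data.frame(index = seq_along(m),
                       surface = regmatches(sent_text, gregexpr("[^ \t]+", sent_text))[[1]]),
            sentence_id = sentence_id)
}

#' Read a BioNLP-ST standoff-annotated document
#'
#' Combines document text, given entities (`.a1`), optional triggers and
#' events (`.a2`) and per-sentence dependency parses into an annotated
#' document. Each line of the text is one sentence; `parses[[i]]` is the
#' dependency graph of sentence `i` (whitespace tokenization is used when no
#' parse is supplied). All annotations are anchored to tokens by character
#' offset overlap; events whose participants span multiple sentences are
#' dropped with a warning, since extraction operates within sentence
#' boundaries.
#'
#' @param text document text: a single string with newlines or a character
#'   vector of sentence lines.
#' @param a1 character vector of entity lines.
#' @param a2 optional character vector of trigger/event lines.
#' @param parses optional list of [dep_graph()] objects, one per sentence.
#' @param doc_id document identifier.
#' @return An object of class `annotated_document` with fields `doc_id`,
#'   `text`, `sentences` (offset-aligned graphs), `entities`, `triggers`
#'   (data.frames with `sentence` and `head_token`/`tokens` anchors) and
#'   `events` (list with resolved, possibly nested argument references).
#' @export
read_standoff <- function(text, a1 = character(), a2 = NULL, parses = NULL,
                          doc_id = "doc") {
  if (length(text) == 1 && grepl("\n", text)) {
    sent_text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    sent_text <- as.character(text)
  }
  full_text <- paste0(paste(sent_text, collapse = "\n"), "\n")
  offsets <- c(0L, cumsum(nchar(sent_text) + 1L))
  ns <- length(sent_text)
  sentences <- vector("list", ns)
  for (i in seq_len(ns)) {
    g <- if (!is.null(parses) && length(parses) >= i && !is.null(parses[[i]])) {
      parses[[i]]
    } else {
      whitespace_graph(sent_text[i], sprintf("%s.s%d", doc_id, i))
    }
    sentences[[i]] <- align_offsets(g, sent_text[i], offsets[i])
  }
  locate_sentence <- function(start, end, id) {
    s <- findInterval(start, offsets)
    if (s < 1 || s > ns || end > offsets[s] + nchar(sent_text[s])) {
      integrity_error(sprintf("annotation %s crosses a sentence boundary", id))
    }
    s
  }
  check_text <- function(id, start, end, expected) {
    got <- substring(full_text, start + 1L, end)
    if (!identical(got, expected)) {
      integrity_error(sprintf(
        "annotation %s: text '%s' does not match document slice '%s'",
        id, expected, got))
    }
  }

  entities <- parse_a1_lines(a1)
  if (nrow(entities)) {
    entities$sentence <- NA_integer_
    entities$head_token <- NA_integer_
    for (r in seq_len(nrow(entities))) {
      check_text(entities$id[r], entities$start[r], entities$end[r],
                 entities$text[r])
      s <- locate_sentence(entities$start[r], entities$end[r], entities$id[r])
      entities$sentence[r] <- s
      cov <- anchor_span(sentences[[s]], entities$start[r], entities$end[r])
      entities$head_token[r] <- cov[length(cov)]
    }
  } else {
    entities$sentence <- integer(); entities$head_token <- integer()
  }

  triggers <- data.frame(id = character(), type = character(),
                         start = integer(), end = integer(),
                         text = character(), sentence = integer(),
                         head_token = integer())
  tok_cov <- list()
  events <- list()
  if (!is.null(a2)) {
    ann <- parse_a2_lines(a2)
    triggers <- ann$triggers
    if (nrow(triggers)) {
      triggers$sentence <- NA_integer_; triggers$head_token <- NA_integer_
      for (r in seq_len(nrow(triggers))) {
        check_text(triggers$id[r], triggers$start[r], triggers$end[r],
                   triggers$text[r])
        s <- locate_sentence(triggers$start[r], triggers$end[r], triggers$id[r])
        triggers$sentence[r] <- s
        cov <- anchor_span(sentences[[s]], triggers$start[r], triggers$end[r])
        tok_cov[[triggers$id[r]]] <- cov
        triggers$head_token[r] <- cov[length(cov)]
      }
    }
    events <- ann$events
    names(events) <- vapply(events, `[[`, "", "id")
    ## resolve references and drop cross-sentence events (transitively)
    ev_sentence <- new.env(parent = emptyenv())
    visiting <- new.env(parent = emptyenv())
    sentence_of <- function(ref) {
      if (grepl("^T", ref)) {
        r <- match(ref, entities$id)
        if (!is.na(r)) return(entities$sentence[r])
        r <- match(ref, triggers$id)
        if (!is.na(r)) return(triggers$sentence[r])
        integrity_error(sprintf("dangling reference %s", ref))
      }
      ev <- events[[ref]]
      if (is.null(ev)) integrity_error(sprintf("dangling reference %s", ref))
      if (!is.null(visiting[[ref]])) integrity_error(
        sprintf("event nesting cycle at %s", ref))
      if (!is.null(ev_sentence[[ref]])) return(ev_sentence[[ref]])
      visiting[[ref]] <- TRUE
      s <- sentence_of(ev$trigger)
      for (a in ev$args) {
        sa <- sentence_of(a$ref)
        if (is.na(sa) || is.na(s) || sa != s) s <- NA_integer_
      }
      rm(list = ref, envir = visiting)
      ev_sentence[[ref]] <- s
      s
    }
    keep <- logical(length(events))
    for (k in seq_along(events)) {
      ev <- events[[k]]
      if (!any(is_theme_role(vapply(ev$args, `[[`, "", "role")))) {
        integrity_error(sprintf("event %s lacks a Theme argument", ev$id))
      }
      s <- sentence_of(ev$id)
      keep[k] <- !is.na(s)
      if (!keep[k]) {
        warning(sprintf("dropping cross-sentence event %s in %s",
                        ev$id, doc_id), call. = FALSE)
      } else {
        events[[k]]$sentence <- s
      }
    }
    ## also drop events whose arguments reference dropped events
    repeat {
      kept_ids <- vapply(events[keep], `[[`, "", "id")
      drop_more <- FALSE
      for (k in which(keep)) {
        refs <- vapply(events[[k]]$args, `[[`, "", "ref")
        evrefs <- refs[grepl("^E", refs)]
        if (length(evrefs) && !all(evrefs %in% kept_ids)) {
          keep[k] <- FALSE; drop_more <- TRUE
          warning(sprintf("dropping event %s: argument event was dropped",
                          events[[k]]$id), call. = FALSE)
        }
      }
      if (!drop_more) break
    }
    events <- events[keep]
  }

  structure(list(doc_id = doc_id, text = full_text, sentences = sentences,
                 entities = entities, triggers = triggers,
                 trigger_tokens = tok_cov, events = events),
            class = "annotated_document")
}

#' @export
print.annotated_document <- function(x, ...) {
  cat(sprintf("<annotated_document '%s': %d sentences, %d entities, %d events>\n",
              x$doc_id, length(x$sentences), nrow(x$entities),
              length(x$events)))
  invisible(x)
}

#' Serialize triggers and events as BioNLP-ST a2 lines
#'
#' Emits trigger (`T`) lines followed by event (`E`) lines with
#' deterministic identifiers: triggers are numbered after the last `.a1`
#' entity id in order of first emission, events in emission order. Reading
#' the output back with [read_standoff()] reproduces the same event
#' structures.
#'
#' @param doc an `annotated_document` supplying text offsets and entities.
#' @param events list of events in the resolved standoff form (fields
#'   `event_type`, `trigger` (trigger id), `args`); defaults to the
#'   document's gold events.
#' @param triggers trigger data.frame; defaults to the document's triggers.
#' @return Character vector of a2 lines.
#' @export
write_a2 <- function(doc, events = doc$events, triggers = doc$triggers) {
  if (!length(events)) return(character())
  used_trig <- unique(unlist(lapply(events, function(e) {
    c(e$trigger, vapply(e$args, `[[`, "", "ref"))
  })))
  used_trig <- used_trig[grepl("^T", used_trig)]
  used_trig <- used_trig[used_trig %in% triggers$id]
  a1_nums <- suppressWarnings(as.integer(sub("^T", "", doc$entities$id)))
  next_t <- max(0L, a1_nums, na.rm = TRUE) + 1L
  tmap <- character(); lines <- character()
  ord <- order(match(used_trig, triggers$id))
  for (tid in used_trig[ord]) {
    r <- match(tid, triggers$id)
    if (is.na(r)) integrity_error(sprintf("unanchored trigger %s", tid))
    new_id <- sprintf("T%d", next_t); next_t <- next_t + 1L
    tmap[tid] <- new_id
    lines <- c(lines, sprintf("%s\t%s %d %d\t%s", new_id, triggers$type[r],
                              triggers$start[r], triggers$end[r],
                              triggers$text[r]))
  }
  emap <- character()
  for (k in seq_along(events)) {
    emap[events[[k]]$id %||% sprintf("E%d", k)] <- sprintf("E%d", k)
  }
  ref_out <- function(ref) {
    if (grepl("^E", ref)) {
      out <- emap[ref]
      if (is.na(out)) integrity_error(sprintf("unanchored argument %s", ref))
      return(out)
    }
    if (ref %in% doc$entities$id) return(ref)
    out <- tmap[ref]
    if (is.na(out)) integrity_error(sprintf("unanchored argument %s", ref))
    out
  }
  for (k in seq_along(events)) {
    ev <- events[[k]]
    args <- vapply(ev$args, function(a) {
      sprintf("%s:%s", a$role, ref_out(a$ref))
    }, "")
    lines <- c(lines, sprintf("E%d\t%s:%s %s", k, ev$event_type,
                              tmap[ev$trigger], paste(args, collapse = " ")))
  }
  lines
}

#' Gold events of a document as sentence-level event structures
#'
#' Converts the standoff gold events into the recursive event form used by
#' the extractor and scorer: triggers become sentence-local token index
#' sets, entity arguments keep their `.a1` identifiers, and event arguments
#' nest recursively.
#'
#' @param doc an `annotated_document`.
#' @return A list with one element per sentence, each a list of events.
#' @export
gold_events <- function(doc) {
  out <- rep(list(list()), length(doc$sentences))
  conv <- function(id) {
    ev <- doc$events[[id]]
    trig_tokens <- doc$trigger_tokens[[ev$trigger]]
    args <- lapply(ev$args, function(a) {
      if (grepl("^E", a$ref)) {
        list(role = a$role, filler = list(kind = "event", event = conv(a$ref)))
      } else {
        r <- match(a$ref, doc$entities$id)
        list(role = a$role,
             filler = list(kind = "entity", id = a$ref,
                           token = doc$entities$head_token[r]))
      }
    })
    new_event(ev$event_type, trig_tokens, args)
  }
  for (id in names(doc$events)) {
    s <- doc$events[[id]]$sentence
    out[[s]][[length(out[[s]]) + 1L]] <- conv(id)
  }
  out
}
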