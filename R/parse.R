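## Parse-format readers: Stanford-dependency triples and CoNLL columns.

SD_LINE_RE <- "^\\s*([^()\\s]+)\\(\\s*(.*?)\\s*,\\s*(.*?)\\s*\\)\\s*$"
SD_TOKEN_RE <- "^(.+)-([0-9]+)('*)(?:/([^/]+))?$"

## "word-6''" copy tokens are materialized as distinct tokens sharing the
## surface: copy k of token i receives index i + k * 10000 (sentences are
## far shorter than 10000 tokens).
sd_copy_offset <- 10000L

parse_sd_token <- function(form, lineno) {
  m <- regmatches(form, regexec(SD_TOKEN_RE, form, perl = TRUE))[[1]]
  if (!length(m)) {
    parse_error(sprintf("line %d: malformed token '%s'", lineno, form))
  }
  ncopy <- nchar(m[4])
  list(index = as.integer(m[3]) + ncopy * sd_copy_offset,
       surface = m[2],
       pos = if (nzchar(m[5])) m[5] else NA_character_)
}

#' Read Stanford-dependency triples into a dependency graph
#'
#' Parses the one-relation-per-line collapsed Stanford dependency dialect,
#' e.g. `prep_to(lead-20, phosphorylation-23)`. Token forms may carry a
#' `/POS` suffix (`lead-20/VBP`) and a trailing apostrophe marking a
#' collapsed-dependency copy node; copies become distinct tokens sharing the
#' surface. A sidecar token table (`index<TAB>surface<TAB>lemma<TAB>POS`)
#' supplies lemmas and POS tags for tokens, including tokens that take part
#' in no dependency.
#'
#' @param lines character vector of dependency lines (blank lines ignored).
#' @param token_table optional data.frame with columns `index`, `surface`,
#'   `lemma`, `pos`.
#' @param sentence_id sentence identifier.
#' @return A [dep_graph()].
#' @export
parse_sd <- function(lines, token_table = NULL, sentence_id = "s1") {
  lines <- lines[nzchar(trimws(lines))]
  toks <- list()
  edges <- data.frame(governor = integer(), dependent = integer(),
                      label = character())
  add_token <- function(t, lineno) {
    key <- as.character(t$index)
    prev <- toks[[key]]
    if (is.null(prev)) {
      toks[[key]] <<- t
    } else if (!identical(prev$surface, t$surface)) {
      integrity_error(sprintf(
        "line %d: token %d seen with conflicting surfaces '%s' and '%s'",
        lineno, t$index, prev$surface, t$surface))
    } else if (is.na(prev$pos) && !is.na(t$pos)) {
      toks[[key]]$pos <<- t$pos
    }
  }
  for (i in seq_along(lines)) {
    m <- regmatches(lines[i], regexec(SD_LINE_RE, lines[i], perl = TRUE))[[1]]
    if (!length(m)) parse_error(sprintf("line %d: malformed dependency '%s'",
                                        i, lines[i]))
    gov <- parse_sd_token(m[3], i)
    dep <- parse_sd_token(m[4], i)
    add_token(gov, i)
    add_token(dep, i)
    edges <- rbind(edges, data.frame(governor = gov$index,
                                     dependent = dep$index, label = m[2]))
  }
  tok_df <- data.frame(
    index = vapply(toks, `[[`, 0L, "index"),
    surface = vapply(toks, `[[`, "", "surface"),
    pos = vapply(toks, function(t) if (is.na(t$pos)) "" else t$pos, ""),
    lemma = character(length(toks)))
  if (!is.null(token_table)) {
    token_table <- as.data.frame(token_table, stringsAsFactors = FALSE)
    j <- match(tok_df$index %% sd_copy_offset, as.integer(token_table$index))
    hit <- !is.na(j)
    tok_df$lemma[hit] <- as.character(token_table$lemma[j[hit]])
    blank <- hit & !nzchar(tok_df$pos)
    tok_df$pos[blank] <- as.character(token_table$pos[j[blank]])
    extra <- !(as.integer(token_table$index) %in% (tok_df$index %% sd_copy_offset))
    if (any(extra)) {
      tok_df <- rbind(tok_df, data.frame(
        index = as.integer(token_table$index[extra]),
        surface = as.character(token_table$surface[extra]),
        pos = as.character(token_table$pos[extra]),
        lemma = as.character(token_table$lemma[extra])))
    }
  }
  dep_graph(tok_df, edges, sentence_id)
}

#' Read CoNLL-X / CoNLL-U rows into a dependency graph
#'
#' Accepts either the bare six-column layout `ID FORM LEMMA POS HEAD DEPREL`
#' or full ten-column CoNLL-X / CoNLL-U rows (columns ID, FORM, LEMMA,
#' UPOS/CPOS, XPOS, FEATS, HEAD, DEPREL, ...; the XPOS column is preferred
#' as the Penn tag when non-empty). Rows with `HEAD == 0` are roots and
#' produce no edge. Multiword-token and empty-node rows of CoNLL-U
#' (`1-2`, `1.1`) are skipped.
#'
#' @param lines character vector of tab- or whitespace-separated rows.
#' @param sentence_id sentence identifier.
#' @return A [dep_graph()].
#' @export
parse_conll <- function(lines, sentence_id = "s1") {
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  rows <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (grepl("^[0-9]+[-.][0-9]+$", f[1])) next
    if (length(f) < 6) parse_error(sprintf("line %d: expected >= 6 columns", i))
    if (length(f) >= 8) {
      pos <- if (nzchar(f[5]) && f[5] != "_") f[5] else f[4]
      row <- list(id = f[1], form = f[2], lemma = f[3], pos = pos,
                  head = f[7], deprel = f[8])
    } else {
      row <- list(id = f[1], form = f[2], lemma = f[3], pos = f[4],
                  head = f[5], deprel = f[6])
    }
    if (!grepl("^[0-9]+$", row$id) || !grepl("^[0-9]+$", row$head)) {
      parse_error(sprintf("line %d: non-integer ID or HEAD", i))
    }
    rows[[length(rows) + 1L]] <- row
  }
  ids <- vapply(rows, function(r) as.integer(r$id), 0L)
  heads <- vapply(rows, function(r) as.integer(r$head), 0L)
  bad <- heads != 0L & !(heads %in% ids)
  if (any(bad)) {
    integrity_error(sprintf("HEAD %d references an absent ID",
                            heads[which(bad)[1]]))
  }
  tok_df <- data.frame(
    index = ids,
    surface = vapply(rows, `[[`, "", "form"),
    lemma = vapply(rows, function(r) if (r$lemma == "_") "" else r$lemma, ""),
    pos = vapply(rows, function(r) if (r$pos == "_") "" else r$pos, ""))
  keep <- heads != 0L
  edges <- data.frame(governor = heads[keep], dependent = ids[keep],
                      label = vapply(rows[keep], `[[`, "", "deprel"))
  dep_graph(tok_df, edges, sentence_id)
}

## Write one sentence graph as SD lines; copies regain their apostrophes.
format_sd <- function(g) {
  if (!nrow(g$edges)) return(character())
  form <- function(i) {
    t <- token_row(g, i)
    copies <- strrep("'", i %/% sd_copy_offset)
    sprintf("%s-%d%s", t$surface, i %% sd_copy_offset, copies)
  }
  sprintf("%s(%s, %s)", g$edges$label,
          vapply(g$edges$governor, form, ""),
          vapply(g$edges$dependent, form, ""))
}

format_token_table <- function(g) {
  sprintf("%d\t%s\t%s\t%s", g$tokens$index, g$tokens$surface,
          g$tokens$lemma, g$tokens$pos)
}

format_conll <- function(g) {
  heads <- rep(0L, nrow(g$tokens))
  rels <- rep("root", nrow(g$tokens))
  ## CoNLL is tree-shaped: keep the first incoming edge per dependent.
  if (nrow(g$edges)) {
    for (e in seq_len(nrow(g$edges))) {
      i <- match(g$edges$dependent[e], g$tokens$index)
      if (heads[i] == 0L) {
        heads[i] <- g$edges$governor[e]
        rels[i] <- g$edges$label[e]
      }
    }
  }
  blank <- function(x) ifelse(nzchar(x), x, "_")
  sprintf("%d\t%s\t%s\t%s\t%d\t%s", g$tokens$index, g$tokens$surface,
          blank(g$tokens$lemma), blank(g$tokens$pos), heads, rels)
}

read_blocks <- function(path) {
  lines <- readLines(path)
  blocks <- list()
  cur <- character()
  for (l in lines) {
    if (nzchar(trimws(l))) {
      cur <- c(cur, l)
    } else if (length(cur)) {
      blocks[[length(blocks) + 1L]] <- cur
      cur <- character()
    }
  }
  if (length(cur)) blocks[[length(blocks) + 1L]] <- cur
  blocks
}

parse_token_table <- function(lines) {
  f <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(index = vapply(f, function(x) as.integer(x[1]), 0L),
             surface = vapply(f, `[[`, "", 2),
             lemma = vapply(f, function(x) if (length(x) >= 3) x[3] else "", ""),
             pos = vapply(f, function(x) if (length(x) >= 4) x[4] else "", ""))
}
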