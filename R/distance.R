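## The subgraph distance: weighted sum of structural, edge-label and
## edge-direction penalties accumulated over all pairs of matched nodes.

## Memoized all-shortest-path enumeration between a token pair.
cached_paths <- function(g, u, v) {
  key <- sprintf("p:%d:%d", min(u, v), max(u, v))
  hit <- g$cache[[key]]
  if (!is.null(hit)) return(hit)
  p <- all_shortest_dep_paths(g, min(u, v), max(u, v))
  g$cache[[key]] <- p
  p
}

## Multiset difference count between two label vectors (the number of
## labels of either path without a counterpart on the other).
multiset_diff <- function(a, b) {
  labs <- unique(c(a, b))
  ca <- table(factor(a, levels = labs))
  cb <- table(factor(b, levels = labs))
  sum(abs(ca - cb))
}

## forward/backward orientation of each edge of a path, traversed from the
## lower-token-index endpoint to the higher.
path_directions <- function(g, p) {
  if (!length(p$edges)) return(character())
  gov <- g$edges$governor[p$edges]
  ifelse(gov == p$nodes[-length(p$nodes)], "forward", "backward")
}

path_labels <- function(g, p) g$edges$label[p$edges]

path_key <- function(p) paste(p$nodes, collapse = ",")

## For one matched node pair, choose the rule path (lexicographically
## smallest node sequence) and the sentence path minimizing the combined
## label + orientation difference against it (ties lexicographic), and
## return the per-pair contributions.
pair_penalties <- function(rule_g, sent_g, ru, rv, su, sv) {
  rpaths <- cached_paths(rule_g, ru, rv)
  spaths <- cached_paths(sent_g, su, sv)
  if (!length(rpaths) || !length(spaths)) return(NULL)
  rp <- rpaths[[order(vapply(rpaths, path_key, ""))[1]]]
  rlab <- path_labels(rule_g, rp)
  rdir <- path_directions(rule_g, rp)
  best <- NULL; best_score <- Inf; best_key <- ""
  for (sp in spaths) {
    ld <- multiset_diff(rlab, path_labels(sent_g, sp))
    dd <- multiset_diff(rdir, path_directions(sent_g, sp))
    sc <- ld + dd
    k <- path_key(sp)
    if (sc < best_score || (sc == best_score && k < best_key)) {
      best <- list(label_diff = ld, dir_diff = dd)
      best_score <- sc; best_key <- k
    }
  }
  list(label_diff = best$label_diff, dir_diff = best$dir_diff,
       rule_len = length(rp$edges), sent_len = length(spaths[[1]]$nodes) - 1L)
}

uid_counter <- new.env(parent = emptyenv())
uid_counter$n <- 0L

dg_uid <- function(g) {
  if (is.null(g$cache$uid)) {
    uid_counter$n <- uid_counter$n + 1L
    g$cache$uid <- uid_counter$n
  }
  g$cache$uid
}

## pair_penalties with memoization on the sentence cache (keyed by the
## rule graph identity and the two node pairs).
pair_penalties_cached <- function(rule_g, sent_g, ru, rv, su, sv) {
  key <- sprintf("pp:%d:%d:%d:%d:%d", dg_uid(rule_g), ru, rv, su, sv)
  hit <- sent_g$cache[[key]]
  if (!is.null(hit)) return(hit)
  pen <- pair_penalties(rule_g, sent_g, ru, rv, su, sv)
  sent_g$cache[[key]] <- pen
  pen
}

## All component distances for a complete injective mapping; Inf when a
## mapped pair is disconnected in the sentence. Since all components are
## non-negative, a candidate whose weighted structural component alone
## exceeds `eta` is rejected without scoring paths.
subgraph_distance_components <- function(rule, sentence, mapping, params,
                                         eta = Inf) {
  rg <- rule$graph
  nodes <- sort(as.integer(names(mapping)))
  n <- length(nodes)
  if (n <= 1) {
    return(list(struct = 0, label = 0, dir = 0, total = 0))
  }
  mapped <- mapping[as.character(nodes)]
  rdist <- dg_dist_matrix(rg)
  sdist <- dg_dist_matrix(sentence)
  up <- upper.tri(matrix(0, n, n))
  rd <- rdist[as.character(nodes), as.character(nodes)][up]
  sd <- sdist[as.character(mapped), as.character(mapped)][up]
  if (any(is.infinite(rd)) || any(is.infinite(sd))) {
    return(list(struct = Inf, label = Inf, dir = Inf, total = Inf))
  }
  struct_den <- sum(rd)
  struct <- if (struct_den > 0) sum(abs(rd - sd)) / struct_den else 0
  if (params$w_s * struct > eta) {
    return(list(struct = struct, label = NA_real_, dir = NA_real_,
                total = Inf))
  }
  label_num <- 0; dir_num <- 0; den <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      pen <- pair_penalties_cached(rg, sentence, nodes[i], nodes[j],
                                   mapped[[i]], mapped[[j]])
      label_num <- label_num + pen$label_diff
      dir_num <- dir_num + pen$dir_diff
      den <- den + pen$rule_len + pen$sent_len
    }
  }
  label <- if (den > 0) label_num / den else 0
  dir <- if (den > 0) dir_num / den else 0
  list(struct = struct, label = label, dir = dir,
       total = subgraph_distance(struct, label, dir, params))
}

#' Structural distance of a candidate mapping
#'
#' Compares, over every unordered pair of distinct rule nodes, the
#' undirected shortest-path length in the rule graph with the length
#' between the corresponding mapped tokens in the sentence graph,
#' accumulates the absolute differences and normalizes by the sum of
#' rule-side lengths. Single-node rules score 0; a mapped pair that is
#' disconnected in the sentence yields `Inf` (the candidate is rejected).
#'
#' @param rule an [event_rule()].
#' @param sentence a [dep_graph()].
#' @param mapping named integer vector: rule token index -> sentence token.
#' @return Non-negative number (possibly `Inf`).
#' @export
struct_dist <- function(rule, sentence, mapping) {
  rg <- rule$graph
  nodes <- sort(as.integer(names(mapping)))
  if (length(nodes) <= 1) return(0)
  rdist <- dg_dist_matrix(rg)
  sdist <- dg_dist_matrix(sentence)
  num <- 0; den <- 0
  for (i in seq_len(length(nodes) - 1)) {
    for (j in seq(i + 1, length(nodes))) {
      dr <- rdist[as.character(nodes[i]), as.character(nodes[j])]
      ds <- sdist[as.character(mapping[[as.character(nodes[i])]]),
                  as.character(mapping[[as.character(nodes[j])]])]
      if (is.infinite(dr) || is.infinite(ds)) return(Inf)
      num <- num + abs(dr - ds)
      den <- den + dr
    }
  }
  if (den > 0) num / den else 0
}

#' Edge-label distance of a candidate mapping
#'
#' For every pair of matched nodes, the multisets of edge labels on the
#' rule path and on the selected sentence shortest path are compared; the
#' per-pair difference is the multiset symmetric-difference size (so
#' `prep_of` against `prep_in` records a difference of two labels). The
#' total is normalized by the summed path lengths of both sides and lies
#' in `[0, 1]`.
#'
#' @inheritParams struct_dist
#' @return Number in `[0, 1]` (or `Inf` for a disconnected pair).
#' @export
label_dist <- function(rule, sentence, mapping) {
  pairwise_path_dist(rule, sentence, mapping, "label_diff")
}

#' Edge-direction distance of a candidate mapping
#'
#' As [label_dist()], but each path edge is encoded as forward or backward
#' relative to a traversal from the lower-token-index endpoint to the
#' higher, and the forward/backward multisets are compared.
#'
#' @inheritParams struct_dist
#' @return Number in `[0, 1]` (or `Inf` for a disconnected pair).
#' @export
directionality_dist <- function(rule, sentence, mapping) {
  pairwise_path_dist(rule, sentence, mapping, "dir_diff")
}

pairwise_path_dist <- function(rule, sentence, mapping, which_diff) {
  rg <- rule$graph
  nodes <- sort(as.integer(names(mapping)))
  if (length(nodes) <= 1) return(0)
  num <- 0; den <- 0
  for (i in seq_len(length(nodes) - 1)) {
    for (j in seq(i + 1, length(nodes))) {
      ru <- nodes[i]; rv <- nodes[j]
      su <- mapping[[as.character(ru)]]; sv <- mapping[[as.character(rv)]]
      pen <- pair_penalties(rg, sentence, ru, rv, su, sv)
      if (is.null(pen)) return(Inf)
      num <- num + pen[[which_diff]]
      den <- den + pen$rule_len + pen$sent_len
    }
  }
  if (den > 0) num / den else 0
}

#' Weighted subgraph distance
#'
#' The total transformation cost of a candidate match:
#' `w_s * struct + w_l * label + w_d * direction`.
#'
#' @param struct_d,label_d,dir_d non-negative component distances.
#' @param params an [asm_params()] carrying the weights.
#' @return Non-negative number.
#' @export
subgraph_distance <- function(struct_d, label_d, dir_d, params = asm_params()) {
  if (any(c(params$w_s, params$w_l, params$w_d) < 0)) {
    config_error("distance weights must be >= 0")
  }
  params$w_s * struct_d + params$w_l * label_d + params$w_d * dir_d
}
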