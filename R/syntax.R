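#' Shortest dependency path between two tokens
#'
#' The unique path between `a` and `b` in the undirected view of the sentence's
#' dependency tree. The lowest common ancestor (LCA) is the path node closest
#' to the root. For each consecutive node pair on the path, the edge label is
#' the dependency relation of the child side of that edge.
#'
#' @param sentence A [parsed_sentence()].
#' @param a,b Distinct token indices.
#' @return `list(nodes, edges, lca)`: token indices from `a` to `b`, the
#'   dependency labels of the traversed edges, and the LCA token index.
#' @export
shortest_path <- function(sentence, a, b) {
  n <- length(sentence$form)
  stopifnot(a >= 1, a <= n, b >= 1, b <= n)
  if (a == b) stop("degenerate path: the two endpoints are the same token")
  anc <- function(i) {
    out <- i
    while (!is.na(sentence$head[i])) { i <- sentence$head[i]; out <- c(out, i) }
    out
  }
  pa <- anc(a); pb <- anc(b)
  common <- intersect(pa, pb)
  lca <- common[1]  # ancestor lists are ordered leaf -> root
  up <- pa[seq_len(match(lca, pa))]
  down <- rev(pb[seq_len(match(lca, pb) - 1L)])
  nodes <- c(up, down)
  edges <- character(length(nodes) - 1L)
  for (k in seq_along(edges)) {
    u <- nodes[k]; v <- nodes[k + 1L]
    edges[k] <- if (!is.na(sentence$head[u]) && sentence$head[u] == v)
      sentence$deprel[u] else sentence$deprel[v]
  }
  list(nodes = nodes, edges = edges, lca = lca)
}

#' Render a shortest-path pattern string
#'
#' Three dialects of the shortest-dependency-path pattern between two entities:
#' `POS_DT` interleaves node part-of-speech tags and edge dependency labels
#' (e.g. `"NN nsubj *JJ* nmod NN nmod NN"`); `POS` keeps only the node tags
#' (`"NN *JJ* NN NN"`); `DT` keeps only the edge labels with the LCA position
#' rendered as `"**"` (`"nsubj ** nmod nmod"`). In the POS dialects the
#' lowest-common-ancestor node's tag is wrapped in asterisks.
#'
#' @param sentence A [parsed_sentence()].
#' @param path A path from [shortest_path()].
#' @param dialect One of `"POS_DT"`, `"POS"`, `"DT"`.
#' @return A pattern string (space-separated symbols).
#' @export
render_pattern <- function(sentence, path, dialect = c("POS_DT", "POS", "DT")) {
  dialect <- match.arg(dialect)
  pos <- sentence$pos[path$nodes]
  lca_pos <- match(path$lca, path$nodes)
  marked <- pos
  marked[lca_pos] <- paste0("*", pos[lca_pos], "*")
  if (dialect == "POS") return(paste(marked, collapse = " "))
  if (dialect == "POS_DT") {
    out <- character(2L * length(marked) - 1L)
    out[seq_along(marked) * 2L - 1L] <- marked
    if (length(path$edges)) out[seq_along(path$edges) * 2L] <- path$edges
    return(paste(out, collapse = " "))
  }
  # DT: edge labels with "**" inserted at the LCA's position along the path
  before <- if (lca_pos > 1L) path$edges[seq_len(lca_pos - 1L)] else character(0)
  after <- if (lca_pos <= length(path$edges))
    path$edges[lca_pos:length(path$edges)] else character(0)
  paste(c(before, "**", after), collapse = " ")
}

instance_pattern <- function(instance, dialect, canonical_mirror = FALSE) {
  s <- instance$sentence
  a <- entity_head(s, instance$e1)
  b <- entity_head(s, instance$e2)
  if (a == b) return(NA_character_)  # one entity head dominates the other's head token
  pat <- render_pattern(s, shortest_path(s, a, b), dialect)
  if (canonical_mirror) {
    rev_pat <- render_pattern(s, shortest_path(s, b, a), dialect)
    pat <- min(pat, rev_pat)
  }
  pat
}

#' Shortest-path pattern distribution of a corpus
#'
#' Extracts one pattern per true-relation instance (instances carrying
#' `exclude_labels`, e.g. an auto-generated FALSE class, are skipped -- the
#' distribution describes paths between *related* entities) and normalizes the
#' pattern counts to relative frequencies. Multi-token entities are anchored
#' at their syntactic heads.
#'
#' @param corpus An [re_corpus()].
#' @param dialect One of `"POS_DT"`, `"POS"`, `"DT"`.
#' @param exclude_labels Labels excluded from extraction (default none).
#' @param canonical_mirror When `TRUE`, each path is rendered in both reading
#'   directions and the lexicographically smaller string is kept, so a
#'   pattern and its mirror collapse; default `FALSE` reads from the left
#'   entity to the right one.
#' @return A tibble of class `pattern_distribution` with columns `pattern`,
#'   `n`, `freq` (descending), and the dialect as attribute `dialect`.
#' @export
pattern_distribution <- function(corpus, dialect = c("POS_DT", "POS", "DT"),
                                 exclude_labels = character(0),
                                 canonical_mirror = FALSE) {
  dialect <- match.arg(dialect)
  insts <- corpus$instances[!vapply(corpus$instances, function(i)
    i$label %in% exclude_labels, TRUE)]
  pats <- vapply(insts, instance_pattern, "", dialect = dialect,
                 canonical_mirror = canonical_mirror)
  pats <- pats[!is.na(pats)]
  if (!length(pats)) {
    out <- tibble::tibble(pattern = character(0), n = integer(0), freq = numeric(0))
  } else {
    tab <- sort(table(pats), decreasing = TRUE)
    out <- tibble::tibble(pattern = names(tab), n = as.integer(tab),
                          freq = as.integer(tab) / sum(tab))
  }
  attr(out, "dialect") <- dialect
  class(out) <- c("pattern_distribution", class(out))
  out
}

#' Cosine similarity of two pattern distributions
#'
#' Dot product over the union of pattern strings divided by the product of the
#' Euclidean norms of the frequency vectors; 0 when either distribution is
#' empty. Both distributions must use the same pattern dialect.
#'
#' @param d1,d2 [pattern_distribution()] tibbles (or any data frames with
#'   `pattern` and `freq` columns).
#' @return Cosine similarity in `[0, 1]`.
#' @export
pattern_cosine <- function(d1, d2) {
  a1 <- attr(d1, "dialect"); a2 <- attr(d2, "dialect")
  if (!is.null(a1) && !is.null(a2) && !identical(a1, a2))
    stop(sprintf("dialect mismatch: %s vs %s", a1, a2))
  if (!nrow(d1) || !nrow(d2)) return(0)
  keys <- union(d1$pattern, d2$pattern)
  v1 <- d1$freq[match(keys, d1$pattern)]; v1[is.na(v1)] <- 0
  v2 <- d2$freq[match(keys, d2$pattern)]; v2[is.na(v2)] <- 0
  sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
}

#' Dictionary coverage of a target corpus by a source corpus
#'
#' Percentage of the target corpus's word types present in the source corpus's
#' vocabulary (type level, lowercased).
#'
#' @param target,source [re_corpus()] objects.
#' @return Coverage percentage in `[0, 100]`.
#' @export
dictionary_coverage <- function(target, source) {
  if (!length(target$vocabulary))
    stop(sprintf("coverage undefined: target corpus '%s' has an empty vocabulary",
                 target$name))
  100 * length(intersect(target$vocabulary, source$vocabulary)) /
    length(target$vocabulary)
}

#' Most frequent lowest-common-ancestor terms of a corpus
#'
#' For every true-relation instance, takes the lowercased surface form of the
#' LCA token of the shortest path between the two entities, replaced by the
#' placeholder `"entity"` when the LCA lies inside either entity span, and
#' ranks terms by relative frequency over instances.
#'
#' @param corpus An [re_corpus()].
#' @param top_n Number of terms to return.
#' @param exclude_labels Labels excluded from extraction.
#' @return A tibble with columns `term` and `freq` (percent), descending.
#' @export
lca_term_table <- function(corpus, top_n = 8L, exclude_labels = character(0)) {
  insts <- corpus$instances[!vapply(corpus$instances, function(i)
    i$label %in% exclude_labels, TRUE)]
  terms <- vapply(insts, function(i) {
    s <- i$sentence
    a <- entity_head(s, i$e1); b <- entity_head(s, i$e2)
    if (a == b) return(NA_character_)
    lca <- shortest_path(s, a, b)$lca
    inside <- (lca >= i$e1[1] && lca <= i$e1[2]) ||
      (lca >= i$e2[1] && lca <= i$e2[2])
    if (inside) "entity" else tolower(s$form[lca])
  }, "")
  terms <- terms[!is.na(terms)]
  if (!length(terms))
    return(tibble::tibble(term = character(0), freq = numeric(0)))
  tab <- sort(table(terms), decreasing = TRUE)
  utils::head(tibble::tibble(term = names(tab),
                             freq = 100 * as.integer(tab) / sum(tab)), top_n)
}

#' Transfer-compatibility report between a target and a source corpus
#'
#' Bundles the three syntactic similarity scores (pattern-distribution cosine
#' per dialect), the dictionary coverage, and the top LCA terms of both
#' corpora -- the quantities used to anticipate whether joint training on the
#' source is likely to help the target.
#'
#' @param target,source [re_corpus()] objects.
#' @param exclude_labels Labels excluded from pattern extraction (e.g. a
#'   FALSE class).
#' @param top_n LCA terms to keep.
#' @return An object of class `similarity_report`; `tidy()` returns the
#'   per-dialect cosine tibble.
#' @export
similarity_report <- function(target, source, exclude_labels = character(0),
                              top_n = 8L) {
  cos <- purrr::map_dfr(c("POS_DT", "POS", "DT"), function(d) {
    tibble::tibble(
      dialect = d,
      cosine = pattern_cosine(
        pattern_distribution(target, d, exclude_labels),
        pattern_distribution(source, d, exclude_labels)))
  })
  structure(list(target = target$name, source = source$name, cosines = cos,
                 coverage = dictionary_coverage(target, source),
                 lca_target = lca_term_table(target, top_n, exclude_labels),
                 lca_source = lca_term_table(source, top_n, exclude_labels)),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf("<similarity_report: target '%s' vs source '%s'>\n",
              x$target, x$source))
  print(x$cosines)
  cat(sprintf("dictionary coverage: %.1f%%\n", x$coverage))
  invisible(x)
}

#' @export
tidy.similarity_report <- function(x, ...) {
  dplyr::mutate(x$cosines, target = x$target, source = x$source,
                coverage = x$coverage)
}

#' Pattern-distribution plot
#'
#' @param object A [pattern_distribution()] tibble.
#' @param top_n Patterns to display.
#' @param ... Unused.
#' @return A ggplot bar chart of the most frequent patterns.
#' @export
autoplot.pattern_distribution <- function(object, top_n = 15L, ...) {
  d <- utils::head(object, top_n)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$pattern, .data$freq),
                                  y = .data$freq)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "relative frequency",
                  title = paste0("SDP patterns (", attr(object, "dialect"), ")"))
}
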