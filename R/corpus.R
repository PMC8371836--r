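#' Construct a dependency-parsed sentence
#'
#' A parsed sentence is the atomic syntactic object of the package: a vector of
#' surface forms with part-of-speech tags, plus a head pointer and a dependency
#' relation label per token. Head pointers use 1-based token indices; the single
#' root token carries `NA` as its head. The head assignment must form one rooted
#' tree (connected and acyclic) over all tokens.
#'
#' @param sentence_id Character scalar identifying the sentence.
#' @param form Character vector of surface forms.
#' @param pos Character vector of part-of-speech tags (same length as `form`).
#' @param head Integer vector of head indices, `NA` for the root token.
#' @param deprel Character vector of dependency-relation labels.
#' @return An object of class `parsed_sentence`.
#' @examples
#' s <- parsed_sentence("ex1", c("dog", "barks"), c("NN", "VBZ"),
#'                      c(2L, NA), c("nsubj", "root"))
#' @export
parsed_sentence <- function(sentence_id, form, pos, head, deprel) {
  n <- length(form)
  stopifnot(length(pos) == n, length(head) == n, length(deprel) == n, n >= 1)
  head <- as.integer(head)
  validate_tree(head, sentence_id)
  structure(
    list(sentence_id = as.character(sentence_id),
         form = as.character(form), pos = as.character(pos),
         head = head, deprel = as.character(deprel)),
    class = "parsed_sentence"
  )
}

#' Validate a dependency head assignment
#'
#' Checks that `head` encodes a single rooted tree: exactly one `NA` (the root),
#' no self-loops, all indices in range, and every token reaches the root by
#' following head pointers (which rules out cycles and disconnection together).
#'
#' @param head Integer vector of head indices, `NA` marking the root.
#' @param sentence_id Identifier used in error messages.
#' @return `TRUE` invisibly; signals an error of class `synre_tree_error` otherwise.
#' @export
validate_tree <- function(head, sentence_id = "<sentence>") {
  n <- length(head)
  fail <- function(msg) {
    stop(structure(class = c("synre_tree_error", "error", "condition"),
                   list(message = sprintf("sentence '%s': %s", sentence_id, msg),
                        call = NULL)))
  }
  root <- which(is.na(head))
  if (length(root) != 1L)
    fail(sprintf("expected exactly one root token, found %d", length(root)))
  idx <- which(!is.na(head))
  if (any(head[idx] < 1L | head[idx] > n))
    fail("head index out of range")
  if (any(head[idx] == idx))
    fail("token is its own head")
  # every token must reach the root; a cycle never does
  for (i in seq_len(n)) {
    j <- i; steps <- 0L
    while (!is.na(head[j])) {
      j <- head[j]; steps <- steps + 1L
      if (steps > n) fail("cycle in head assignment")
    }
  }
  invisible(TRUE)
}

#' @export
print.parsed_sentence <- function(x, ...) {
  cat(sprintf("<parsed_sentence '%s': %d tokens>\n", x$sentence_id, length(x$form)))
  print(sentence_tokens(x))
  invisible(x)
}

#' Tokens of a sentence as a tibble
#'
#' One row per token: `index`, `form`, `pos`, `head` (`NA` for root), `deprel`.
#'
#' @param sentence A `parsed_sentence`.
#' @return A tibble with one row per token.
#' @export
sentence_tokens <- function(sentence) {
  tibble::tibble(index = seq_along(sentence$form), form = sentence$form,
                 pos = sentence$pos, head = sentence$head, deprel = sentence$deprel)
}

#' Construct a relation instance
#'
#' The unit of classification: one parsed sentence, an ordered pair of entity
#' mentions, and a relation label. Spans are closed 1-based token intervals
#' `c(start, end)`; the two spans must not overlap, and `e1` is by convention
#' the mention with the smaller start offset.
#'
#' @param sentence A `parsed_sentence`.
#' @param e1,e2 Integer vectors `c(start, end)`, closed 1-based token intervals.
#' @param label Relation-type string.
#' @param e1_type,e2_type Entity-type strings.
#' @return An object of class `relation_instance`.
#' @export
relation_instance <- function(sentence, e1, e2, label,
                              e1_type = "ENTITY", e2_type = "ENTITY") {
  stopifnot(inherits(sentence, "parsed_sentence"))
  check_span(e1, length(sentence$form))
  check_span(e2, length(sentence$form))
  if (max(e1[1], e2[1]) <= min(e1[2], e2[2]))
    stop("entity spans overlap")
  structure(
    list(sentence = sentence, e1 = as.integer(e1), e2 = as.integer(e2),
         e1_type = as.character(e1_type), e2_type = as.character(e2_type),
         label = as.character(label)),
    class = "relation_instance"
  )
}

check_span <- function(span, n) {
  if (length(span) != 2L || anyNA(span) || span[1] < 1L || span[2] > n ||
      span[1] > span[2])
    stop(sprintf("invalid entity span [%s] for sentence of length %d",
                 paste(span, collapse = ", "), n))
  invisible(TRUE)
}

#' Construct an annotated relation-extraction corpus
#'
#' A corpus bundles a name, an ordered relation-label set, and a list of
#' [relation_instance()] objects. The vocabulary (the set of lowercased forms
#' occurring in the instances' sentences) is derived at construction time.
#'
#' @param name Corpus name.
#' @param instances List of `relation_instance` objects.
#' @param label_set Ordered character vector of relation types; defaults to the
#'   sorted set of labels present in `instances`.
#' @param entity_types Character vector of entity types; derived by default.
#' @return An object of class `re_corpus`.
#' @export
re_corpus <- function(name, instances, label_set = NULL, entity_types = NULL) {
  stopifnot(is.list(instances))
  labs <- vapply(instances, function(i) i$label, character(1))
  if (is.null(label_set)) label_set <- sort(unique(labs))
  if (length(instances) && !all(labs %in% label_set))
    stop(sprintf("instance labels outside label set: %s",
                 paste(setdiff(labs, label_set), collapse = ", ")))
  if (is.null(entity_types))
    entity_types <- sort(unique(unlist(lapply(instances, function(i)
      c(i$e1_type, i$e2_type)))))
  structure(
    list(name = as.character(name), label_set = as.character(label_set),
         entity_types = as.character(entity_types), instances = instances,
         vocabulary = corpus_vocabulary_build(instances)),
    class = "re_corpus"
  )
}

corpus_vocabulary_build <- function(instances) {
  if (!length(instances)) return(character(0))
  sort(unique(tolower(unlist(lapply(instances, function(i) i$sentence$form)))))
}

#' @export
print.re_corpus <- function(x, ...) {
  cat(sprintf("<re_corpus '%s': %d instances, %d labels (%s), %d vocabulary types>\n",
              x$name, length(x$instances), length(x$label_set),
              paste(x$label_set, collapse = ", "), length(x$vocabulary)))
  invisible(x)
}

#' @export
length.re_corpus <- function(x) length(x$instances)

#' Instance-level view of a corpus
#'
#' @param x An `re_corpus`.
#' @param ... Unused.
#' @return A tibble with one row per relation instance: sentence id, the two
#'   entity surface strings and types, span boundaries, and the label.
#' @importFrom generics tidy
#' @export
tidy.re_corpus <- function(x, ...) {
  purrr::map_dfr(x$instances, function(i) {
    tibble::tibble(
      sentence_id = i$sentence$sentence_id,
      e1_text = paste(i$sentence$form[i$e1[1]:i$e1[2]], collapse = " "),
      e2_text = paste(i$sentence$form[i$e2[1]:i$e2[2]], collapse = " "),
      e1_type = i$e1_type, e2_type = i$e2_type,
      e1_start = i$e1[1], e1_end = i$e1[2],
      e2_start = i$e2[1], e2_end = i$e2[2],
      n_tokens = length(i$sentence$form),
      label = i$label)
  })
}

#' Read dependency parses from a CoNLL-U file
#'
#' Parses the standard 10-column CoNLL-U format. Comment lines, multiword-token
#' ranges (`1-2`) and empty nodes (`1.1`) are skipped. The 1-based `ID`/`HEAD`
#' columns map directly onto the package's 1-based token indices; `HEAD = 0`
#' becomes the `NA` root marker. `UPOS` is used as the part-of-speech tag and
#' `DEPREL` as the dependency relation.
#'
#' @param path Path to a UTF-8 CoNLL-U file.
#' @return A list of [parsed_sentence()] objects. Sentence ids come from
#'   `# sent_id =` comments when present, else `s1`, `s2`, ...
#' @export
read_conllu <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sentences <- list()
  cur <- NULL
  sent_id <- NULL
  n_sent <- 0L
  flush <- function() {
    if (is.null(cur) || !nrow(cur)) return()
    n_sent <<- n_sent + 1L
    id <- if (!is.null(sent_id)) sent_id else paste0("s", n_sent)
    head <- ifelse(cur$head == 0L, NA_integer_, cur$head)
    sentences[[length(sentences) + 1L]] <<-
      parsed_sentence(id, cur$form, cur$pos, head, cur$deprel)
    cur <<- NULL
    sent_id <<- NULL
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (line == "") { flush(); next }
    if (startsWith(line, "#")) {
      m <- regmatches(line, regexec("^#\\s*sent_id\\s*=\\s*(\\S+)", line))[[1]]
      if (length(m) == 2) sent_id <- m[2]
      next
    }
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 10L)
      stop(sprintf("line %d: expected 10 tab-separated fields, found %d",
                   ln, length(fields)))
    if (grepl("[-.]", fields[1])) next  # multiword token range or empty node
    id <- suppressWarnings(as.integer(fields[1]))
    head <- suppressWarnings(as.integer(fields[7]))
    if (is.na(id) || is.na(head))
      stop(sprintf("line %d: non-integer ID or HEAD field", ln))
    row <- tibble::tibble(id = id, form = fields[2], pos = fields[4],
                          head = head, deprel = fields[8])
    cur <- if (is.null(cur)) row else rbind(cur, row)
  }
  flush()
  sentences
}

#' Expand entity mentions of a sentence into relation instances
#'
#' Builds one [relation_instance()] per unordered pair of mentions. Pairs listed
#' in `gold` receive their annotated label; pairs absent from `gold` receive
#' `negative_label` when one is supplied (the co-occurrence negative class) and
#' are dropped otherwise. Within each instance `e1` is the mention with the
#' smaller start offset. When `type_pairs` is given, only mention pairs whose
#' unordered type pair appears in it are emitted.
#'
#' @param sentence A `parsed_sentence`.
#' @param mentions A data frame with columns `start`, `end` (closed 1-based
#'   token spans) and `type`; mentions must be pairwise non-overlapping.
#' @param gold A data frame with columns `e1`, `e2` (row indices into
#'   `mentions`, order irrelevant) and `label`; may be `NULL` or empty.
#' @param negative_label Label for unannotated co-occurring pairs, or `NULL`.
#' @param type_pairs Optional data frame with columns `type1`, `type2` listing
#'   the pairable unordered entity-type combinations.
#' @return A list of `relation_instance` objects.
#' @export
expand_pairs <- function(sentence, mentions, gold = NULL,
                         negative_label = NULL, type_pairs = NULL) {
  mentions <- as.data.frame(mentions)
  m <- nrow(mentions)
  if (m < 2L) return(list())
  for (i in seq_len(m)) check_span(c(mentions$start[i], mentions$end[i]),
                                   length(sentence$form))
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i < j && max(mentions$start[i], mentions$start[j]) <=
        min(mentions$end[i], mentions$end[j]))
      stop(sprintf("mentions %d and %d overlap", i, j))
  }
  gold_key <- character(0)
  gold_lab <- character(0)
  if (!is.null(gold) && nrow(as.data.frame(gold))) {
    gold <- as.data.frame(gold)
    if (any(gold$e1 < 1 | gold$e1 > m | gold$e2 < 1 | gold$e2 > m))
      stop("gold relation references a mention not in the mention list")
    gold_key <- paste(pmin(gold$e1, gold$e2), pmax(gold$e1, gold$e2))
    gold_lab <- as.character(gold$label)
  }
  out <- list()
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    if (!is.null(type_pairs)) {
      tp <- as.data.frame(type_pairs)
      ok <- any((tp$type1 == mentions$type[i] & tp$type2 == mentions$type[j]) |
                (tp$type1 == mentions$type[j] & tp$type2 == mentions$type[i]))
      if (!ok) next
    }
    hit <- match(paste(i, j), gold_key)
    lab <- if (!is.na(hit)) gold_lab[hit] else negative_label
    if (is.null(lab)) next
    # e1 = mention with the smaller start offset
    a <- if (mentions$start[i] <= mentions$start[j]) i else j
    b <- if (a == i) j else i
    out[[length(out) + 1L]] <- relation_instance(
      sentence,
      e1 = c(mentions$start[a], mentions$end[a]),
      e2 = c(mentions$start[b], mentions$end[b]),
      label = lab,
      e1_type = mentions$type[a], e2_type = mentions$type[b])
  }
  out
}

#' Syntactic head token of an entity span
#'
#' Returns the index of the unique span token whose head lies outside the span
#' (the span's syntactic head); if several tokens escape the span, the leftmost
#' wins. A single-token span returns that token. Used to anchor shortest-path
#' endpoints for multi-token entities.
#'
#' @param sentence A `parsed_sentence`.
#' @param span Closed 1-based interval `c(start, end)`.
#' @return Integer token index.
#' @export
entity_head <- function(sentence, span) {
  check_span(span, length(sentence$form))
  toks <- span[1]:span[2]
  if (length(toks) == 1L) return(toks)
  escapes <- toks[is.na(sentence$head[toks]) | !(sentence$head[toks] %in% toks)]
  if (!length(escapes)) return(toks[1])  # degenerate: internal cycle-free span
  escapes[1]
}
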