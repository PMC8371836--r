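#' Read and write annotated corpora as JSON Lines
#'
#' The on-disk dialect is self-contained: the first line is a header object
#' with keys `name`, `label_set` and `entity_types`; every following line is
#' one sentence object with keys `sentence_id`, `tokens` (objects with `form`,
#' `pos`, `head`, `deprel`), `entities` (objects with `id`, `start`, `end`,
#' `type`) and `relations` (objects with `e1`, `e2`, `label` referencing entity
#' ids). On disk, token indices are 0-based, entity spans are half-open
#' `[start, end)` and the root token has `head = -1`; these are converted to
#' the package's 1-based closed-span convention on read and back on write, so
#' `read_corpus_jsonl(write_corpus_jsonl(x, path))` is the identity.
#'
#' @param path File path.
#' @return `read_corpus_jsonl()` returns an [re_corpus()];
#'   `write_corpus_jsonl()` returns `path` invisibly.
#' @name corpus_jsonl
NULL

jsonl_schema_error <- function(line, msg) {
  stop(structure(class = c("synre_schema_error", "error", "condition"),
                 list(message = sprintf("line %d: %s", line, msg), call = NULL)))
}

need_key <- function(obj, key, line) {
  if (!key %in% names(obj)) jsonl_schema_error(line, sprintf("missing key '%s'", key))
  obj[[key]]
}

#' @rdname corpus_jsonl
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty corpus file: no header line")
  header <- jsonlite::fromJSON(lines[1], simplifyVector = TRUE)
  name <- need_key(header, "name", 1L)
  label_set <- as.character(need_key(header, "label_set", 1L))
  entity_types <- as.character(need_key(header, "entity_types", 1L))
  instances <- list()
  for (ln in seq_along(lines)[-1]) {
    obj <- jsonlite::fromJSON(lines[ln], simplifyVector = FALSE)
    sid <- need_key(obj, "sentence_id", ln)
    toks <- need_key(obj, "tokens", ln)
    if (!length(toks)) jsonl_schema_error(ln, "sentence has no tokens")
    form <- vapply(toks, function(t) as.character(need_key(t, "form", ln)), "")
    pos <- vapply(toks, function(t) as.character(need_key(t, "pos", ln)), "")
    head0 <- vapply(toks, function(t) as.integer(need_key(t, "head", ln)), 0L)
    deprel <- vapply(toks, function(t) as.character(need_key(t, "deprel", ln)), "")
    head <- ifelse(head0 < 0L, NA_integer_, head0 + 1L)
    sent <- parsed_sentence(sid, form, pos, head, deprel)
    ents <- need_key(obj, "entities", ln)
    ent_tab <- list()
    for (e in ents) {
      id <- as.character(need_key(e, "id", ln))
      start0 <- as.integer(need_key(e, "start", ln))
      end0 <- as.integer(need_key(e, "end", ln))
      if (end0 <= start0)
        jsonl_schema_error(ln, sprintf("empty entity span [%d, %d)", start0, end0))
      if (start0 < 0L || end0 > length(form))
        jsonl_schema_error(ln, sprintf("entity span [%d, %d) out of range", start0, end0))
      ent_tab[[id]] <- list(span = c(start0 + 1L, end0),  # closed 1-based
                            type = as.character(need_key(e, "type", ln)))
    }
    for (r in need_key(obj, "relations", ln)) {
      e1_id <- as.character(need_key(r, "e1", ln))
      e2_id <- as.character(need_key(r, "e2", ln))
      lab <- as.character(need_key(r, "label", ln))
      if (is.null(ent_tab[[e1_id]]) || is.null(ent_tab[[e2_id]]))
        jsonl_schema_error(ln, sprintf("relation references unknown entity id '%s'",
                                       if (is.null(ent_tab[[e1_id]])) e1_id else e2_id))
      if (!lab %in% label_set)
        jsonl_schema_error(ln, sprintf("label '%s' not in header label_set", lab))
      instances[[length(instances) + 1L]] <- relation_instance(
        sent, ent_tab[[e1_id]]$span, ent_tab[[e2_id]]$span, lab,
        ent_tab[[e1_id]]$type, ent_tab[[e2_id]]$type)
    }
  }
  re_corpus(name, instances, label_set = label_set, entity_types = entity_types)
}

#' @param corpus An [re_corpus()].
#' @rdname corpus_jsonl
#' @export
write_corpus_jsonl <- function(corpus, path) {
  stopifnot(inherits(corpus, "re_corpus"))
  to_json <- function(x) jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  out <- character(1L + 0L)
  out[1] <- to_json(list(name = corpus$name,
                         label_set = as.list(corpus$label_set),
                         entity_types = as.list(corpus$entity_types)))
  # group instances by sentence in first-appearance order
  sids <- vapply(corpus$instances, function(i) i$sentence$sentence_id, "")
  for (sid in unique(sids)) {
    insts <- corpus$instances[sids == sid]
    sent <- insts[[1]]$sentence
    tokens <- lapply(seq_along(sent$form), function(k) list(
      form = sent$form[k], pos = sent$pos[k],
      head = if (is.na(sent$head[k])) -1L else sent$head[k] - 1L,
      deprel = sent$deprel[k]))
    ent_key <- character(0); ent_objs <- list()
    ent_id_of <- function(span, type) {
      key <- paste(span[1], span[2], type)
      hit <- match(key, ent_key)
      if (!is.na(hit)) return(ent_objs[[hit]]$id)
      id <- paste0("T", length(ent_key) + 1L)
      ent_key[[length(ent_key) + 1L]] <<- key
      ent_objs[[length(ent_objs) + 1L]] <<- list(
        id = id, start = span[1] - 1L, end = span[2], type = type)
      id
    }
    rels <- lapply(insts, function(i) list(
      e1 = ent_id_of(i$e1, i$e1_type), e2 = ent_id_of(i$e2, i$e2_type),
      label = i$label))
    out[[length(out) + 1L]] <- to_json(list(
      sentence_id = sid, tokens = tokens, entities = ent_objs, relations = rels))
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Read word vectors in word2vec text format
#'
#' The first line holds the vocabulary size and vector dimension; each
#' following line is a word and its vector components, space-separated.
#'
#' @param path Path to a word2vec text-format file.
#' @return A numeric matrix with one row per word, forms as rownames.
#' @export
read_word2vec_text <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2L || anyNA(hdr))
    stop("malformed word2vec header: expected 'count dim'")
  n <- hdr[1]; d <- hdr[2]
  mat <- matrix(0, n, d)
  words <- character(n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(parts) != d + 1L)
      stop(sprintf("line %d: expected %d vector components", i + 1L, d))
    words[i] <- parts[1]
    mat[i, ] <- as.numeric(parts[-1])
  }
  rownames(mat) <- words
  mat
}
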