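#' Create shared embedding tables
#'
#' The input layer of both encoders: a word lookup table over the union
#' vocabulary of all training corpora plus an `<unk>` row absorbing unseen
#' forms, and a 3-row entity-role table distinguishing tokens of the first
#' entity, the second entity, and all other tokens. Word and entity-role
#' vectors are concatenated to form the per-token input of width `d_w + d_e`.
#'
#' Rows are initialized uniformly in `(-a, a)` with `a = sqrt(1/d)` from the
#' current RNG state; rows whose lowercased form appears in `pretrained`
#' (a matrix with forms as rownames, e.g. from [read_word2vec_text()]) are
#' overwritten with the pre-trained vector.
#'
#' @param vocabulary Character vector of (lowercased) word types.
#' @param d_w Word-embedding width.
#' @param d_e Entity-role embedding width.
#' @param pretrained Optional numeric matrix of pre-trained word vectors with
#'   forms as rownames and `d_w` columns.
#' @return An object of class `embedding_tables`: list with `vocab`,
#'   `word_table` (`(|vocab|+1) x d_w`, last row = unknown word), and
#'   `entity_table` (`3 x d_e`, rows first/second/other).
#' @export
embedding_tables <- function(vocabulary, d_w = 100L, d_e = 10L, pretrained = NULL) {
  stopifnot(d_w > 0, d_e > 0)
  vocabulary <- unique(tolower(as.character(vocabulary)))
  nw <- length(vocabulary) + 1L  # + <unk>
  aw <- sqrt(1 / d_w)
  ae <- sqrt(1 / d_e)
  word_table <- matrix(stats::runif(nw * d_w, -aw, aw), nw, d_w)
  entity_table <- matrix(stats::runif(3L * d_e, -ae, ae), 3L, d_e)
  if (!is.null(pretrained)) {
    stopifnot(ncol(pretrained) == d_w)
    hit <- match(vocabulary, tolower(rownames(pretrained)))
    ok <- which(!is.na(hit))
    if (length(ok)) word_table[ok, ] <- pretrained[hit[ok], , drop = FALSE]
  }
  structure(list(vocab = vocabulary, word_table = word_table,
                 entity_table = entity_table, d_w = as.integer(d_w),
                 d_e = as.integer(d_e)),
            class = "embedding_tables")
}

# word-row indices (UNK = last row) and entity-role indices (1 first, 2 second,
# 3 other) for one instance; precomputed once per instance during training
instance_indices <- function(instance, tables) {
  forms <- tolower(instance$sentence$form)
  widx <- match(forms, tables$vocab)
  widx[is.na(widx)] <- length(tables$vocab) + 1L
  role <- rep(3L, length(forms))
  role[instance$e1[1]:instance$e1[2]] <- 1L
  role[instance$e2[1]:instance$e2[2]] <- 2L
  list(widx = widx, role = role)
}

#' Embed a relation instance as a sequence of input vectors
#'
#' Applies the lookup-table operation token by token: the word part is the
#' word-table row for the token's lowercased form (the unknown-word row when
#' absent from the vocabulary), and the entity part is the first-entity row for
#' tokens inside the first entity's span, the second-entity row inside the
#' second entity's span, and the other row elsewhere.
#'
#' @param instance A [relation_instance()].
#' @param tables An [embedding_tables()] object.
#' @return A numeric matrix of shape `(d_w + d_e) x N` whose columns are the
#'   per-token input vectors `x_1 ... x_N`.
#' @export
embed_instance <- function(instance, tables) {
  ix <- instance_indices(instance, tables)
  rbind(t(tables$word_table[ix$widx, , drop = FALSE]),
        t(tables$entity_table[ix$role, , drop = FALSE]))
}
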