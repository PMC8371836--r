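#' Define a sentence template for the synthetic generator
#'
#' A template is a dependency-tree skeleton: per-token POS tags, head indices
#' (1-based, `NA` for the root) and dependency labels, two designated entity
#' slots, a relation label and a sampling weight. Surface forms are drawn at
#' generation time from per-POS vocabulary pools, so every sentence generated
#' from one template shares its tree shape (hence its shortest-path pattern)
#' while varying lexically.
#'
#' @param id Template identifier.
#' @param pos,head,deprel Parallel vectors describing the skeleton.
#' @param e1,e2 Entity slots: a token index or a closed span `c(start, end)`.
#' @param label Relation label emitted for instances of this template.
#' @param weight Positive sampling weight.
#' @param e1_type,e2_type Entity-type strings.
#' @param pools Optional named list (POS -> character vector) overriding the
#'   generator's vocabulary pools for this template only.
#' @return A `syn_template` list.
#' @export
syn_template <- function(id, pos, head, deprel, e1, e2, label, weight = 1,
                         e1_type = "ENTITY", e2_type = "ENTITY", pools = NULL) {
  stopifnot(length(pos) == length(head), length(pos) == length(deprel),
            weight > 0, is.finite(weight))
  validate_tree(as.integer(head), id)
  if (length(e1) == 1L) e1 <- c(e1, e1)
  if (length(e2) == 1L) e2 <- c(e2, e2)
  check_span(e1, length(pos)); check_span(e2, length(pos))
  if (max(e1[1], e2[1]) <= min(e1[2], e2[2])) stop("entity slots overlap")
  structure(list(id = as.character(id), pos = as.character(pos),
                 head = as.integer(head), deprel = as.character(deprel),
                 e1 = as.integer(e1), e2 = as.integer(e2),
                 label = as.character(label), weight = as.numeric(weight),
                 e1_type = e1_type, e2_type = e2_type, pools = pools),
            class = "syn_template")
}

#' Generator configuration
#'
#' @param templates List of [syn_template()] objects.
#' @param vocabulary_pools Named list mapping POS tag to a character vector of
#'   surface forms.
#' @param n_sentences Number of sentences (= instances) to generate.
#' @param seed Integer seed; generation is fully deterministic given the seed.
#' @param label_noise Probability of flipping an instance's label to a
#'   uniformly chosen *other* label of the label set.
#' @param name Corpus name.
#' @return A `generator_config` list.
#' @export
generator_config <- function(templates, vocabulary_pools, n_sentences,
                             seed = 1L, label_noise = 0, name = "synthetic") {
  stopifnot(length(templates) >= 1, n_sentences >= 1,
            label_noise >= 0, label_noise <= 1)
  for (tp in templates) {
    stopifnot(inherits(tp, "syn_template"))
    for (p in unique(tp$pos)) {
      pool <- (tp$pools %||% list())[[p]] %||% vocabulary_pools[[p]]
      if (!length(pool))
        stop(sprintf("template '%s': empty vocabulary pool for POS '%s'", tp$id, p))
    }
  }
  structure(list(templates = templates, vocabulary_pools = vocabulary_pools,
                 n_sentences = as.integer(n_sentences), seed = as.integer(seed),
                 label_noise = label_noise, name = as.character(name),
                 label_set = sort(unique(vapply(templates, function(t) t$label, "")))),
            class = "generator_config")
}

#' Generate a synthetic annotated corpus
#'
#' Draws `n_sentences` sentences: each samples a template by weight,
#' instantiates every skeleton node with a form drawn uniformly from the
#' node's POS pool, emits the two entity slots as mentions, and labels the
#' instance with the template's label (flipped to a random other label with
#' probability `label_noise`). Deterministic for a fixed seed.
#'
#' @param config A [generator_config()].
#' @return An [re_corpus()].
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  w <- vapply(config$templates, function(t) t$weight, 0)
  labels <- config$label_set
  instances <- vector("list", config$n_sentences)
  for (i in seq_len(config$n_sentences)) {
    tp <- config$templates[[sample.int(length(w), 1L, prob = w)]]
    forms <- vapply(seq_along(tp$pos), function(k) {
      pool <- (tp$pools %||% list())[[tp$pos[k]]] %||%
        config$vocabulary_pools[[tp$pos[k]]]
      pool[sample.int(length(pool), 1L)]
    }, "")
    lab <- tp$label
    if (config$label_noise > 0 && length(labels) > 1L &&
        stats::runif(1) < config$label_noise) {
      others <- setdiff(labels, lab)
      lab <- others[sample.int(length(others), 1L)]
    }
    sent <- parsed_sentence(sprintf("%s_%05d", config$name, i),
                            forms, tp$pos, tp$head, tp$deprel)
    instances[[i]] <- relation_instance(sent, tp$e1, tp$e2, lab,
                                        tp$e1_type, tp$e2_type)
  }
  re_corpus(config$name, instances, label_set = labels)
}

# programmatic per-POS vocabulary pools; a prefix keeps pools of different
# corpora lexically disjoint
default_pools <- function(prefix = "", n = 40L) {
  list(NN = sprintf("%snoun%02d", prefix, seq_len(n)),
       JJ = sprintf("%sadj%02d", prefix, seq_len(n)),
       VBZ = sprintf("%sverb%02d", prefix, seq_len(n)),
       IN = sprintf("%sprep%02d", prefix, seq_len(max(4L, n %/% 4L))))
}

# two disjoint libraries of tree skeletons with distinct POS+DT path patterns;
# set "a" is the target family, set "b" a structurally different family
template_library <- function(set = c("a", "b"), label_prefix = "rel") {
  set <- match.arg(set)
  lab <- function(k) sprintf("%s_%d", label_prefix, k)
  if (set == "a") {
    list(
      # NN nsubj *VBZ* dobj NN
      syn_template("a1", c("JJ", "NN", "VBZ", "NN", "JJ", "IN", "NN"),
                   c(2L, 3L, NA, 3L, 4L, 7L, 3L),
                   c("nmod", "nsubj", "root", "dobj", "nmod", "case", "nmod"),
                   e1 = 2L, e2 = 4L, label = lab(1)),
      # NN nsubj *JJ* nmod NN nmod NN
      syn_template("a2", c("NN", "JJ", "NN", "NN", "JJ", "IN", "NN"),
                   c(2L, NA, 2L, 3L, 4L, 3L, 2L),
                   c("nsubj", "root", "nmod", "nmod", "nmod", "case", "nmod"),
                   e1 = 1L, e2 = 4L, label = lab(2)),
      # NN nmod NN nsubj *VBZ* dobj NN
      syn_template("a3", c("NN", "NN", "VBZ", "NN", "JJ", "IN", "NN", "JJ"),
                   c(2L, 3L, NA, 3L, 2L, 1L, 3L, 4L),
                   c("nmod", "nsubj", "root", "dobj", "nmod", "case", "nmod", "nmod"),
                   e1 = 1L, e2 = 4L, label = lab(3)),
      # NN nsubj *VBZ* dobj NN nmod NN
      syn_template("a4", c("NN", "VBZ", "NN", "NN", "IN", "JJ", "NN", "JJ"),
                   c(2L, NA, 2L, 3L, 4L, 3L, 2L, 1L),
                   c("nsubj", "root", "dobj", "nmod", "case", "nmod", "nmod", "nmod"),
                   e1 = 1L, e2 = 4L, label = lab(4)))
  } else {
    list(
      # NN nmod NN nmod *NN* nmod NN nmod NN
      syn_template("b1", c("NN", "NN", "NN", "NN", "NN", "JJ", "IN"),
                   c(2L, 3L, NA, 3L, 4L, 2L, 5L),
                   c("nmod", "nmod", "root", "nmod", "nmod", "nmod", "case"),
                   e1 = 1L, e2 = 5L, label = lab(1)),
      # NN dobj *VBZ* nsubj NN
      syn_template("b2", c("NN", "VBZ", "NN", "JJ", "IN", "NN", "JJ"),
                   c(2L, NA, 2L, 1L, 3L, 2L, 6L),
                   c("dobj", "root", "nsubj", "nmod", "case", "nmod", "nmod"),
                   e1 = 1L, e2 = 3L, label = lab(2)),
      # NN nmod *VBZ* nmod JJ nmod NN
      syn_template("b3", c("NN", "VBZ", "JJ", "NN", "IN", "NN", "JJ", "IN"),
                   c(2L, NA, 2L, 3L, 4L, 2L, 6L, 1L),
                   c("nmod", "root", "nmod", "nmod", "case", "nmod", "nmod", "case"),
                   e1 = 1L, e2 = 4L, label = lab(3)),
      # NN nmod NN nsubj *JJ* nmod NN nmod NN
      syn_template("b4", c("NN", "NN", "JJ", "NN", "NN", "IN", "JJ", "NN"),
                   c(2L, 3L, NA, 3L, 4L, 5L, 2L, 3L),
                   c("nmod", "nsubj", "root", "nmod", "nmod", "case", "nmod", "nmod"),
                   e1 = 1L, e2 = 5L, label = lab(4)))
  }
}

#' Generate a target/source corpus pair with controlled pattern overlap
#'
#' Emulates the transfer-learning setting where a small target corpus may or
#' may not share syntactic structure with a large source corpus: the source
#' puts a fraction `overlap` of its template weight mass on the target's tree
#' skeletons and the rest on a structurally disjoint family, while the two
#' corpora use lexically disjoint vocabulary pools and disjoint label sets
#' (so lexical overlap stays at zero while syntactic similarity varies).
#'
#' @param overlap Fraction in `[0, 1]` of source weight mass on target-family
#'   skeletons.
#' @param n_target,n_source Corpus sizes.
#' @param seed Integer seed (the source corpus uses `seed + 1`).
#' @param label_noise Label-flip probability applied to both corpora.
#' @return `list(target = , source = )` of [re_corpus()] objects.
#' @export
generate_transfer_pair <- function(overlap, n_target, n_source, seed = 1L,
                                   label_noise = 0) {
  stopifnot(overlap >= 0, overlap <= 1)
  a_t <- template_library("a", "t_rel")
  target_cfg <- generator_config(a_t, default_pools("t"), n_target,
                                 seed = seed, label_noise = label_noise,
                                 name = "syn_target")
  a_s <- template_library("a", "s_rel")
  b_s <- template_library("b", "s_relx")
  src_templates <- list()
  for (tp in a_s) { tp$weight <- overlap / length(a_s); src_templates <- c(src_templates, list(tp)) }
  for (tp in b_s) { tp$weight <- (1 - overlap) / length(b_s); src_templates <- c(src_templates, list(tp)) }
  src_templates <- Filter(function(tp) tp$weight > 0, src_templates)
  source_cfg <- generator_config(src_templates, default_pools("s"), n_source,
                                 seed = seed + 1L, label_noise = label_noise,
                                 name = "syn_source")
  list(target = generate_corpus(target_cfg), source = generate_corpus(source_cfg))
}

#' Generate a trigger-word corpus for learnability checks
#'
#' All sentences share one tree skeleton; the relation label is a
#' deterministic function of a single trigger verb, with one disjoint trigger
#' pool per label. A model that attends to the trigger token can classify
#' perfectly; the corpus is linearly separable by construction.
#'
#' @param n Number of instances.
#' @param seed Integer seed.
#' @param n_labels Number of relation labels (2-4).
#' @param label_noise Label-flip probability.
#' @return An [re_corpus()].
#' @export
generate_trigger_corpus <- function(n, seed = 1L, n_labels = 3L, label_noise = 0) {
  stopifnot(n_labels >= 2L, n_labels <= 4L)
  pools <- default_pools("g", n = 20L)
  templates <- lapply(seq_len(n_labels), function(k) {
    syn_template(
      sprintf("trig%d", k), c("NN", "VBZ", "NN", "JJ", "IN", "NN"),
      c(2L, NA, 2L, 3L, 6L, 2L), c("nsubj", "root", "dobj", "nmod", "case", "nmod"),
      e1 = 1L, e2 = 3L, label = sprintf("rel_%d", k),
      pools = list(VBZ = sprintf("trigger%d%s", k, letters[1:3])))
  })
  generate_corpus(generator_config(templates, pools, n, seed = seed,
                                   label_noise = label_noise, name = "syn_trigger"))
}
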