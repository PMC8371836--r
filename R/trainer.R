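#' Initialize a linear scorer for one corpus
#'
#' The scoring layer maps a sentence representation to one score per relation
#' type of the owning corpus: `s(r_s) = W_s r_s + b_s`. Scores are turned into
#' probabilities with a softmax when computing the training loss.
#'
#' @param d_s Sentence-representation width.
#' @param label_set Ordered character vector of relation types (length >= 2).
#' @return An object of class `scorer_parameters`.
#' @export
scorer_params <- function(d_s, label_set) {
  label_set <- as.character(label_set)
  if (length(label_set) < 2L) stop("label set must contain at least 2 labels")
  structure(list(W = init_mat(length(label_set), d_s),
                 b = rep(0, length(label_set)), label_set = label_set,
                 d_s = as.integer(d_s)),
            class = "scorer_parameters")
}

#' Score a sentence representation
#'
#' @param r_s Numeric sentence representation.
#' @param scorer A [scorer_params()] object.
#' @return Named numeric vector of raw (pre-softmax) scores, one per label.
#' @export
score <- function(r_s, scorer) {
  if (length(r_s) != scorer$d_s)
    stop(sprintf("representation length %d does not match scorer d_s = %d",
                 length(r_s), scorer$d_s))
  stats::setNames(drop(scorer$W %*% r_s) + scorer$b, scorer$label_set)
}

#' Softmax over a score vector
#'
#' Shift-invariant, numerically stable softmax.
#' @param s Numeric vector of scores.
#' @return Probability vector summing to 1.
#' @export
softmax <- function(s) {
  e <- exp(s - max(s))
  e / sum(e)
}

#' Training configuration
#'
#' Batch size is fixed at 1 (pure stochastic gradient descent); each update
#' draws one instance uniformly at random from the pooled target + source
#' training instances. Dropout is applied after the embedding layers of both
#' encoders and after every TreeLSTM unit, and disabled at evaluation time
#' (inverted dropout). The parameter snapshot with the best target-validation
#' macro-F over the epochs is returned.
#'
#' @param learning_rate SGD step size.
#' @param epochs Number of passes over the pooled training instances.
#' @param seed Integer seed controlling initialization, splits and sampling.
#' @param dropout_p Dropout probability in `[0, 1)`.
#' @param validation_fraction Fraction of the target corpus held out for
#'   epoch selection, in `(0, 1)`.
#' @param d_w,d_e Word and entity-role embedding widths.
#' @param d_h Hidden width; defaults to 200 for the TreeLSTM and 100 per
#'   kernel for the MCCNN when `NULL`.
#' @param kernel_sizes MCCNN window widths.
#' @param channels MCCNN channel count.
#' @param readout TreeLSTM root readout, `"h"` or `"o"`.
#' @param negative_label Label excluded from macro-averaged validation and
#'   evaluation (e.g. an auto-generated FALSE class), or `NULL`.
#' @param target_oversample Integer replication factor for target instances in
#'   the mixed training pool (1 = the literal uniform mixing).
#' @param pretrained Optional pre-trained word-vector matrix
#'   (see [embedding_tables()]).
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.05, epochs = 100L, seed = 1L,
                         dropout_p = 0.25, validation_fraction = 0.1,
                         d_w = 100L, d_e = 10L, d_h = NULL,
                         kernel_sizes = c(3L, 5L), channels = 2L,
                         readout = c("h", "o"), negative_label = NULL,
                         target_oversample = 1L, pretrained = NULL) {
  stopifnot(learning_rate > 0, epochs >= 1, dropout_p >= 0, dropout_p < 1,
            validation_fraction > 0, validation_fraction < 1,
            target_oversample >= 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 seed = as.integer(seed), dropout_p = dropout_p,
                 validation_fraction = validation_fraction,
                 d_w = as.integer(d_w), d_e = as.integer(d_e),
                 d_h = if (is.null(d_h)) NULL else as.integer(d_h),
                 kernel_sizes = as.integer(kernel_sizes),
                 channels = as.integer(channels),
                 readout = match.arg(readout),
                 negative_label = negative_label,
                 target_oversample = as.integer(target_oversample),
                 pretrained = pretrained),
            class = "train_config")
}

drop_mask <- function(nr, nc, p) {
  if (p <= 0) return(matrix(1, nr, nc))
  matrix(stats::rbinom(nr * nc, 1L, 1 - p) / (1 - p), nr, nc)
}

# one SGD step; returns list(loss, tables, enc, scorer) with updated values
sgd_step <- function(kind, item, tables, frozen, enc, scorer, lr, p_drop, readout) {
  d_w <- tables$d_w
  N <- length(item$widx)
  Xw <- t(tables$word_table[item$widx, , drop = FALSE])
  Xe <- t(tables$entity_table[item$role, , drop = FALSE])
  y <- item$y

  if (kind == "treelstm") {
    X <- rbind(Xw, Xe)
    xmask <- drop_mask(nrow(X), N, p_drop)
    hmask <- drop_mask(enc$d_h, N, p_drop)
    Xd <- X * xmask
    fw <- cpp_treelstm_forward(Xd, item$parent, unclass(enc), hmask, readout)
    r <- drop(fw$r)
  } else {
    xmask <- lapply(seq_len(enc$channels), function(ch)
      drop_mask(d_w + tables$d_e, N, p_drop))
    chans <- vector("list", enc$channels)
    for (ch in seq_len(enc$channels)) {
      wt <- if (ch == enc$trainable_channel) tables$word_table else
        frozen[[frozen_slot(ch, enc$trainable_channel)]]
      chans[[ch]] <- rbind(t(wt[item$widx, , drop = FALSE]), Xe) * xmask[[ch]]
    }
    fw <- cpp_mccnn_forward(chans, enc$W, enc$b, enc$kernel_sizes)
    r <- drop(fw$r)
  }

  s <- drop(scorer$W %*% r) + scorer$b
  pr <- softmax(s)
  loss <- -log(max(pr[y], 1e-12))
  ds <- pr
  ds[y] <- ds[y] - 1
  dr <- drop(crossprod(scorer$W, ds))
  scorer$W <- scorer$W - lr * tcrossprod(ds, r)
  scorer$b <- scorer$b - lr * ds

  if (kind == "treelstm") {
    bw <- cpp_treelstm_backward(Xd, item$parent, unclass(enc), fw, hmask, dr, readout)
    for (nm in grep("^[WUb]_", names(enc), value = TRUE))
      enc[[nm]] <- enc[[nm]] - lr * bw[[nm]]
    dX <- bw$X * xmask
    dXw <- dX[seq_len(d_w), , drop = FALSE]
    dXe <- dX[-seq_len(d_w), , drop = FALSE]
  } else {
    bw <- cpp_mccnn_backward(chans, enc$W, enc$b, enc$kernel_sizes, fw, dr)
    for (q in seq_along(enc$kernel_sizes)) {
      for (ch in seq_len(enc$channels))
        enc$W[[q]][[ch]] <- enc$W[[q]][[ch]] - lr * bw$W[[q]][[ch]]
      enc$b[[q]] <- enc$b[[q]] - lr * bw$b[[q]]
    }
    tc <- enc$trainable_channel
    dX <- bw$X[[tc]] * xmask[[tc]]
    dXw <- dX[seq_len(d_w), , drop = FALSE]
    dXe <- dX[-seq_len(d_w), , drop = FALSE]
  }

  gw <- rowsum(t(dXw), group = item$widx)
  rows <- as.integer(rownames(gw))
  tables$word_table[rows, ] <- tables$word_table[rows, ] - lr * gw
  ge <- rowsum(t(dXe), group = item$role)
  erows <- as.integer(rownames(ge))
  tables$entity_table[erows, ] <- tables$entity_table[erows, ] - lr * ge

  list(loss = loss, tables = tables, enc = enc, scorer = scorer)
}

frozen_slot <- function(ch, trainable) if (ch > trainable) ch - 1L else ch

encode_item <- function(kind, item, tables, frozen, enc, readout) {
  Xe <- t(tables$entity_table[item$role, , drop = FALSE])
  if (kind == "treelstm") {
    X <- rbind(t(tables$word_table[item$widx, , drop = FALSE]), Xe)
    mask <- matrix(1, enc$d_h, ncol(X))
    drop(cpp_treelstm_forward(X, item$parent, unclass(enc), mask, readout)$r)
  } else {
    chans <- vector("list", enc$channels)
    for (ch in seq_len(enc$channels)) {
      wt <- if (ch == enc$trainable_channel) tables$word_table else
        frozen[[frozen_slot(ch, enc$trainable_channel)]]
      chans[[ch]] <- rbind(t(wt[item$widx, , drop = FALSE]), Xe)
    }
    drop(cpp_mccnn_forward(chans, enc$W, enc$b, enc$kernel_sizes)$r)
  }
}

prep_items <- function(corpus, tables, scorer_idx, label_set) {
  lapply(corpus$instances, function(inst) {
    ix <- instance_indices(inst, tables)
    list(widx = ix$widx, role = ix$role,
         parent = parent_vector(inst$sentence$head),
         y = match(inst$label, label_set),
         scorer = scorer_idx, label = inst$label,
         sentence_id = inst$sentence$sentence_id)
  })
}

#' Train a relation-extraction model with multi-corpus transfer
#'
#' Trains one shared encoder (embedding tables plus a Child-Sum TreeLSTM or
#' MCCNN) together with one linear scorer per corpus, by stochastic gradient
#' descent on the negative log-likelihood. Each update draws one instance
#' uniformly at random from the mixed pool of target and source training
#' instances, encodes it with the shared stack, scores it with its own
#' corpus's scorer, and backpropagates through both. With `sources = list()`
#' this reduces exactly to single-corpus training. A fraction of the target
#' corpus is held out for validation; the parameter snapshot with the best
#' validation macro-F is returned.
#'
#' @param target Target [re_corpus()].
#' @param sources List of source [re_corpus()] objects; label sets may differ
#'   freely from the target's.
#' @param encoder One of `"treelstm"`, `"mccnn"`.
#' @param config A [train_config()].
#' @param val_indices Optional integer indices of target instances to use as
#'   the validation slice (otherwise sampled from `validation_fraction`).
#' @return An object of class `re_model` with elements `tables`, `encoder`
#'   (parameters), `scorers` (one per corpus, target first), `history`
#'   (per-epoch tibble with loss and validation macro-F), `best_epoch`.
#' @export
train_transfer <- function(target, sources = list(), encoder = c("treelstm", "mccnn"),
                           config = train_config(), val_indices = NULL) {
  encoder <- match.arg(encoder)
  stopifnot(inherits(target, "re_corpus"), length(target$instances) >= 2)
  for (s in sources) stopifnot(inherits(s, "re_corpus"), length(s$instances) >= 1)
  corpora <- c(list(target), sources)
  nms <- vapply(corpora, function(x) x$name, "")
  if (anyDuplicated(nms)) stop("corpus names must be unique")
  for (x in corpora) if (length(x$label_set) < 2L)
    stop(sprintf("corpus '%s' has fewer than 2 labels", x$name))

  set.seed(config$seed)
  vocab <- sort(unique(unlist(lapply(corpora, function(x) x$vocabulary))))
  tables <- embedding_tables(vocab, config$d_w, config$d_e, config$pretrained)
  d_in <- config$d_w + config$d_e
  d_h <- config$d_h
  if (encoder == "treelstm") {
    enc <- treelstm_params(d_in, d_h %||% 200L)
    frozen <- NULL
  } else {
    enc <- mccnn_params(d_in, d_h %||% 100L, config$kernel_sizes, config$channels)
    frozen <- if (enc$channels > 1L)
      rep(list(tables$word_table), enc$channels - 1L) else NULL
  }
  d_s <- enc$d_s
  scorers <- lapply(corpora, function(x) scorer_params(d_s, x$label_set))
  names(scorers) <- nms

  n_t <- length(target$instances)
  if (is.null(val_indices)) {
    n_val <- max(1L, floor(config$validation_fraction * n_t))
    val_indices <- sample.int(n_t, n_val)
  }
  train_idx <- setdiff(seq_len(n_t), val_indices)
  if (!length(train_idx)) stop("no target training instances left after validation split")

  target_items <- prep_items(target, tables, 1L, target$label_set)
  pool <- rep(target_items[train_idx], config$target_oversample)
  for (k in seq_along(sources))
    pool <- c(pool, prep_items(sources[[k]], tables, k + 1L, sources[[k]]$label_set))
  val_items <- target_items[val_indices]
  val_gold <- vapply(val_items, function(it) it$label, "")
  pos_labels <- setdiff(target$label_set, config$negative_label)

  history <- vector("list", config$epochs)
  best <- list(f = -Inf, epoch = 0L)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(length(pool))
    tot <- 0
    for (i in ord) {
      it <- pool[[i]]
      st <- sgd_step(encoder, it, tables, frozen, enc, scorers[[it$scorer]],
                     config$learning_rate, config$dropout_p, config$readout)
      tables <- st$tables; enc <- st$enc; scorers[[it$scorer]] <- st$scorer
      tot <- tot + st$loss
    }
    val_pred <- vapply(val_items, function(it) {
      r <- encode_item(encoder, it, tables, frozen, enc, config$readout)
      target$label_set[which.max(score(r, scorers[[1L]]))]
    }, "")
    rep_v <- evaluate(val_gold, val_pred, target$label_set,
                      positive_labels = pos_labels)
    f <- glance(rep_v)$macro_f
    history[[ep]] <- tibble::tibble(epoch = ep, loss = tot / length(pool),
                                    val_macro_f = f)
    if (f > best$f) {
      best <- list(f = f, epoch = ep, tables = tables, enc = enc,
                   scorers = scorers)
    }
  }

  structure(list(encoder_kind = encoder, config = config,
                 tables = best$tables, encoder = best$enc,
                 frozen_words = frozen, scorers = best$scorers,
                 target_name = target$name,
                 label_sets = lapply(corpora, function(x) x$label_set),
                 history = dplyr::bind_rows(history),
                 best_epoch = best$epoch,
                 best_val_macro_f = best$f),
            class = "re_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.re_model <- function(x, ...) {
  cat(sprintf("<re_model: %s encoder, d_s = %d, target '%s', %d scorer(s)>\n",
              x$encoder_kind, x$encoder$d_s, x$target_name, length(x$scorers)))
  cat(sprintf("  best epoch %d, validation macro-F %.1f\n",
              x$best_epoch, x$best_val_macro_f))
  invisible(x)
}

model_scores <- function(model, instances, corpus_name = NULL) {
  scorer <- model$scorers[[corpus_name %||% model$target_name]]
  if (is.null(scorer)) stop(sprintf("no scorer for corpus '%s'", corpus_name))
  out <- matrix(NA_real_, length(instances), length(scorer$label_set),
                dimnames = list(NULL, scorer$label_set))
  for (i in seq_along(instances)) {
    it <- c(instance_indices(instances[[i]], model$tables),
            list(parent = parent_vector(instances[[i]]$sentence$head)))
    r <- encode_item(model$encoder_kind, it, model$tables, model$frozen_words,
                     model$encoder, model$config$readout)
    out[i, ] <- score(r, scorer)
  }
  out
}

#' Predict relation labels
#'
#' @param object A fitted `re_model`.
#' @param newdata An [re_corpus()] or list of [relation_instance()] objects.
#' @param corpus_name Which corpus's scorer to use (default: the target's).
#' @param type `"label"` for a tibble of predictions, `"scores"` for the raw
#'   score matrix.
#' @param ... Unused.
#' @return A tibble with `sentence_id`, `gold` (if available) and `.pred`, or
#'   a score matrix.
#' @export
predict.re_model <- function(object, newdata, corpus_name = NULL,
                             type = c("label", "scores"), ...) {
  type <- match.arg(type)
  instances <- if (inherits(newdata, "re_corpus")) newdata$instances else newdata
  sc <- model_scores(object, instances, corpus_name)
  if (type == "scores") return(sc)
  labs <- colnames(sc)[apply(sc, 1L, which.max)]
  tibble::tibble(
    sentence_id = vapply(instances, function(i) i$sentence$sentence_id, ""),
    gold = vapply(instances, function(i) i$label, ""),
    .pred = labs)
}

#' Predict by score-averaging ensemble
#'
#' Averages the raw (pre-softmax) score vectors of several models sharing the
#' target label set and predicts the argmax of the mean; ties break toward the
#' lowest label index.
#'
#' @param models List of fitted `re_model` objects.
#' @param newdata An [re_corpus()] or list of instances.
#' @param corpus_name Which corpus's scorer to use (default: the target's).
#' @return A tibble as in [predict.re_model()].
#' @export
ensemble_predict <- function(models, newdata, corpus_name = NULL) {
  stopifnot(length(models) >= 1)
  instances <- if (inherits(newdata, "re_corpus")) newdata$instances else newdata
  mats <- lapply(models, function(m) model_scores(m, instances, corpus_name))
  ls0 <- colnames(mats[[1]])
  for (m in mats) if (!identical(colnames(m), ls0))
    stop("ensemble members do not share a label set")
  avg <- Reduce(`+`, mats) / length(mats)
  labs <- ls0[apply(avg, 1L, which.max)]
  tibble::tibble(
    sentence_id = vapply(instances, function(i) i$sentence$sentence_id, ""),
    gold = vapply(instances, function(i) i$label, ""),
    .pred = labs)
}

#' Evaluate predictions with per-class and macro precision/recall/F
#'
#' One-vs-rest counts per label give precision, recall and F (`F = 2PR/(P+R)`,
#' 0 when `P + R = 0`), reported as percentages. The macro average is the
#' unweighted mean over `positive_labels` (default: every label except
#' `negative_label`, e.g. the co-occurrence FALSE class).
#'
#' @param gold,predicted Character vectors of equal length with labels from
#'   `label_set`.
#' @param label_set Ordered label set.
#' @param positive_labels Labels entering the macro average; default all but
#'   `negative_label`.
#' @param negative_label Designated negative label, or `NULL`.
#' @return An object of class `eval_report`; see [tidy.eval_report()] and
#'   [glance.eval_report()].
#' @export
evaluate <- function(gold, predicted, label_set, positive_labels = NULL,
                     negative_label = NULL) {
  stopifnot(length(gold) == length(predicted))
  bad <- setdiff(unique(c(gold, predicted)), label_set)
  if (length(bad))
    stop(sprintf("labels outside label set: %s", paste(bad, collapse = ", ")))
  if (is.null(positive_labels)) positive_labels <- setdiff(label_set, negative_label)
  per <- purrr::map_dfr(label_set, function(lab) {
    tp <- sum(gold == lab & predicted == lab)
    fp <- sum(gold != lab & predicted == lab)
    fn <- sum(gold == lab & predicted != lab)
    p <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
    r <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    tibble::tibble(label = lab, precision = p, recall = r, f = f,
                   support = sum(gold == lab))
  })
  pos <- per[per$label %in% positive_labels, ]
  structure(list(per_label = per,
                 macro_precision = mean(pos$precision),
                 macro_recall = mean(pos$recall),
                 macro_f = mean(pos$f),
                 positive_labels = positive_labels),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  print(x$per_label)
  cat(sprintf("macro (over %s): P %.1f  R %.1f  F %.1f\n",
              paste(x$positive_labels, collapse = ", "),
              x$macro_precision, x$macro_recall, x$macro_f))
  invisible(x)
}

#' Per-label metrics of an evaluation report
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return Tibble with one row per label: precision, recall, F, support (percent).
#' @export
tidy.eval_report <- function(x, ...) x$per_label

#' Macro-averaged metrics of an evaluation report
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return One-row tibble with `macro_precision`, `macro_recall`, `macro_f`.
#' @importFrom generics glance
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(macro_precision = x$macro_precision,
                 macro_recall = x$macro_recall, macro_f = x$macro_f)
}

#' Cross-validate a relation-extraction model
#'
#' Instance-level k-fold cross-validation with a fixed seed. For each fold and
#' repeat, the model trains on the remaining target data plus all sources
#' (validation slice drawn inside [train_transfer()]) and is tested on the
#' held-out fold. When `test_corpus` is supplied (the fixed-test-set mode),
#' every run tests on that corpus and the folds rotate only the validation
#' slice. Each (fold, repeat) run uses a distinct derived seed.
#'
#' @param corpus Target [re_corpus()].
#' @param sources List of source corpora.
#' @param encoder `"treelstm"` or `"mccnn"`.
#' @param config A [train_config()].
#' @param folds Number of folds (>= 2).
#' @param repeats Random restarts per fold.
#' @param test_corpus Optional fixed test [re_corpus()].
#' @return An object of class `cv_result`: tibble of per-run reports plus mean
#'   and population standard deviation of macro-F.
#' @export
cross_validate <- function(corpus, sources = list(), encoder = c("treelstm", "mccnn"),
                           config = train_config(), folds = 10L, repeats = 1L,
                           test_corpus = NULL) {
  encoder <- match.arg(encoder)
  stopifnot(folds >= 2L, repeats >= 1L)
  n <- length(corpus$instances)
  set.seed(config$seed)
  fold_of <- sample(rep_len(seq_len(folds), n))
  if (min(table(factor(fold_of, levels = seq_len(folds)))) < 1L)
    stop("a fold has no test instance; reduce the number of folds")
  pos_labels <- setdiff(corpus$label_set, config$negative_label)
  runs <- list()
  for (f in seq_len(folds)) for (r in seq_len(repeats)) {
    cfg <- config
    cfg$seed <- as.integer(config$seed + 7919L * r + f)
    if (is.null(test_corpus)) {
      tr <- re_corpus(corpus$name, corpus$instances[fold_of != f],
                      label_set = corpus$label_set,
                      entity_types = corpus$entity_types)
      test_instances <- corpus$instances[fold_of == f]
      model <- train_transfer(tr, sources, encoder, cfg)
    } else {
      test_instances <- test_corpus$instances
      model <- train_transfer(corpus, sources, encoder, cfg,
                              val_indices = which(fold_of == f))
    }
    pred <- predict(model, test_instances)
    repo <- evaluate(pred$gold, pred$.pred, corpus$label_set,
                     positive_labels = pos_labels)
    g <- glance(repo)
    runs[[length(runs) + 1L]] <- tibble::tibble(
      fold = f, repeat_ = r, macro_precision = g$macro_precision,
      macro_recall = g$macro_recall, macro_f = g$macro_f,
      val_macro_f = model$best_val_macro_f,
      report = list(repo))
  }
  runs <- dplyr::bind_rows(runs)
  structure(list(runs = runs, mean_f = mean(runs$macro_f),
                 sd_f = sd_pop(runs$macro_f), folds = folds, repeats = repeats),
            class = "cv_result")
}

sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: %d folds x %d repeats, macro-F %.1f (sd %.1f)>\n",
              x$folds, x$repeats, x$mean_f, x$sd_f))
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, ...) x$runs[, setdiff(names(x$runs), "report")]

#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(folds = x$folds, repeats = x$repeats,
                 mean_macro_f = x$mean_f, sd_macro_f = x$sd_f)
}

#' Save / load a fitted model
#'
#' The model directory holds `config.json` (encoder kind, label sets, scalar
#' hyper-parameters), `vocabulary.txt`, and `parameters.rds` with every
#' trainable tensor; reloading is bit-exact.
#'
#' @param model A fitted `re_model`.
#' @param dir Directory path (created if missing).
#' @return `write_model()` returns `dir` invisibly; `read_model()` the model.
#' @export
write_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- model$config
  cfg$pretrained <- NULL
  jsonlite::write_json(
    list(encoder_kind = model$encoder_kind, target_name = model$target_name,
         label_sets = model$label_sets, config = unclass(cfg),
         best_epoch = model$best_epoch),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(model$tables$vocab, file.path(dir, "vocabulary.txt"), useBytes = TRUE)
  saveRDS(model, file.path(dir, "parameters.rds"))
  invisible(dir)
}

#' @rdname write_model
#' @export
read_model <- function(dir) readRDS(file.path(dir, "parameters.rds"))

#' Training-history plot
#'
#' @param object A fitted `re_model`.
#' @param ... Unused.
#' @return A ggplot of per-epoch mean training loss and validation macro-F.
#' @export
autoplot.re_model <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("loss", "val_macro_f"),
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}
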