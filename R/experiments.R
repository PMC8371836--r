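#' Transfer-learning experiment on synthetic corpus pairs
#'
#' For each syntactic-overlap level and seed, generates a small target corpus
#' and a 10x larger source corpus with [generate_transfer_pair()], trains the
#' chosen encoder with and without the source, and measures macro-F on a
#' freshly generated target test set, alongside the POS+DT pattern-distribution
#' cosine between target and source. The transfer *gain* (joint minus baseline
#' macro-F) can then be related to the syntactic similarity of the pair.
#'
#' Defaults are the package's desk-scale study conditions: target n = 60,
#' source n = 600, hidden width 32, 30 epochs of SGD at learning rate 0.1
#' with regularization off.
#'
#' @param overlaps Numeric vector of overlap levels in `[0, 1]`.
#' @param seeds Integer vector of replicate seeds.
#' @param n_target,n_source,n_test Corpus sizes.
#' @param encoder `"treelstm"` or `"mccnn"`.
#' @param epochs,learning_rate,d_w,d_e,d_h,dropout_p Training hyper-parameters.
#' @return A tibble with one row per (overlap, seed): `cosine_pos_dt`,
#'   `baseline_f`, `transfer_f`, `gain`.
#' @export
transfer_experiment <- function(overlaps = c(0, 0.25, 0.5, 0.75, 1),
                                seeds = 1:5, n_target = 60L, n_source = 600L,
                                n_test = 240L, encoder = "treelstm",
                                epochs = 30L, learning_rate = 0.1,
                                d_w = 16L, d_e = 8L, d_h = 32L,
                                dropout_p = 0) {
  rows <- list()
  for (ov in overlaps) for (sd in seeds) {
    run_seed <- as.integer(sd * 1009L + round(100 * ov))
    pair <- generate_transfer_pair(ov, n_target, n_source, seed = run_seed)
    test <- generate_transfer_pair(ov, n_test, 1L, seed = run_seed + 500L)$target
    cosine <- pattern_cosine(pattern_distribution(pair$target, "POS_DT"),
                             pattern_distribution(pair$source, "POS_DT"))
    cfg <- train_config(learning_rate = learning_rate, epochs = epochs,
                        seed = run_seed, dropout_p = dropout_p,
                        d_w = d_w, d_e = d_e, d_h = d_h)
    f_of <- function(model) {
      pred <- predict(model, test)
      glance(evaluate(pred$gold, pred$.pred, pair$target$label_set))$macro_f
    }
    base_f <- f_of(train_transfer(pair$target, list(), encoder, cfg))
    joint_f <- f_of(train_transfer(pair$target, list(pair$source), encoder, cfg))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      overlap = ov, seed = sd, cosine_pos_dt = cosine,
      baseline_f = base_f, transfer_f = joint_f, gain = joint_f - base_f)
  }
  dplyr::bind_rows(rows)
}

#' Summarize a transfer experiment by overlap level
#'
#' @param runs Output of [transfer_experiment()].
#' @return A tibble with per-overlap mean cosine, baseline/transfer macro-F
#'   and gain, plus the Spearman correlation between mean cosine and mean
#'   gain across levels as attribute `spearman`.
#' @export
summarize_transfer <- function(runs) {
  out <- runs |>
    dplyr::group_by(.data$overlap) |>
    dplyr::summarise(cosine = mean(.data$cosine_pos_dt),
                     baseline_f = mean(.data$baseline_f),
                     transfer_f = mean(.data$transfer_f),
                     gain = mean(.data$gain), .groups = "drop")
  attr(out, "spearman") <- stats::cor(out$cosine, out$gain, method = "spearman")
  out
}

#' Learnability experiment on a separable trigger corpus
#'
#' Trains an encoder on a noiseless corpus whose label is a deterministic
#' function of one trigger token and reports held-out macro-F per seed.
#'
#' @param encoder `"treelstm"` or `"mccnn"`.
#' @param seeds Integer vector of seeds.
#' @param n_train,n_test Corpus sizes.
#' @param epochs,learning_rate,d_w,d_e,d_h Training hyper-parameters.
#' @return A tibble with one row per seed: `macro_f` on the held-out corpus.
#' @export
learnability_experiment <- function(encoder, seeds = 1:3, n_train = 200L,
                                    n_test = 120L, epochs = 50L,
                                    learning_rate = 0.1, d_w = 16L, d_e = 8L,
                                    d_h = 32L) {
  purrr::map_dfr(seeds, function(sd) {
    train <- generate_trigger_corpus(n_train, seed = sd * 211L)
    test <- generate_trigger_corpus(n_test, seed = sd * 211L + 97L)
    cfg <- train_config(learning_rate = learning_rate, epochs = epochs,
                        seed = sd, dropout_p = 0, d_w = d_w, d_e = d_e,
                        d_h = d_h)
    model <- train_transfer(train, list(), encoder, cfg)
    pred <- predict(model, test)
    tibble::tibble(seed = sd,
                   macro_f = glance(evaluate(pred$gold, pred$.pred,
                                             train$label_set))$macro_f)
  })
}
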