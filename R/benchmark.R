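# End-to-end phantom benchmark: generate a balanced corpus, preprocess both
# entropy channels, train, and score on a held-out set. This is the
# package's reference experiment; it exercises every module.

#' Generate the balanced benchmark corpus
#'
#' `n_per_class` non-referable phantoms split evenly over grades 0-1 and
#' `n_per_class` referable phantoms split near-evenly over grades 2-4.
#'
#' @param n_per_class Phantoms per class (default 1000).
#' @param side Image side in pixels (default 100).
#' @param seed Master corpus seed.
#' @return As [generate_corpus()].
#' @export
benchmark_corpus <- function(n_per_class = 1000L, side = 100L, seed = 1L) {
  n_per_class <- as.integer(n_per_class)
  half <- n_per_class %/% 2L
  third <- n_per_class %/% 3L
  counts <- c("0" = n_per_class - half, "1" = half,
              "2" = n_per_class - 2L * third, "3" = third, "4" = third)
  generate_corpus(counts, side = side, seed = seed)
}

#' Preprocess a corpus into paired network inputs
#'
#' Runs [make_channel_input()] for the gray (luminance) and green paths on
#' every image and stacks the unit-rescaled entropy images into
#' `side x side x n` arrays.
#'
#' @param corpus A list from [generate_corpus()] (fields `images`,
#'   `manifest`).
#' @param channels Channels to compute.
#' @param sigma,amount,block_size,bins Preprocessing parameters; see
#'   [make_channel_input()].
#' @return List with `inputs` (named list of arrays), `labels` (0/1
#'   referable), `grades`.
#' @export
preprocess_corpus <- function(corpus, channels = c("gray", "green"),
                              sigma = 2, amount = 1, block_size = 9L,
                              bins = 256L) {
  n <- length(corpus$images)
  if (n == 0L) stop("empty corpus")
  side <- dim(corpus$images[[1]])[1]
  inputs <- lapply(channels, function(ch) {
    a <- array(0, dim = c(side, side, n))
    for (i in seq_len(n)) {
      a[, , i] <- unclass(make_channel_input(corpus$images[[i]], channel = ch,
                                             sigma = sigma, amount = amount,
                                             block_size = block_size,
                                             bins = bins))
    }
    a
  })
  names(inputs) <- channels
  list(inputs = inputs, labels = as.integer(corpus$manifest$referable),
       grades = corpus$manifest$grade)
}

# stratified-by-grade index split
stratified_split <- function(grades, test_fraction, seed) {
  with_seed(as.integer(seed), {
    test_idx <- integer()
    for (g in sort(unique(grades))) {
      rows <- which(grades == g)
      test_idx <- c(test_idx, sample(rows, round(length(rows) * test_fraction)))
    }
    sort(test_idx)
  })
}

#' Desk-scale benchmark configuration
#'
#' The reference architecture (filters 32/64/64/128, lr 1e-4, 50 epochs) is
#' sized for tens of thousands of photographs; on a 2,000-phantom corpus a
#' scaled-down stack trains in minutes on one CPU and the task remains the
#' same. Defaults: filters 6/12/12/24, dense 32, dropout 0.3, Adam at 1e-3
#' with decoupled weight decay 1e-4 and a 10x step learning-rate decay over
#' the final quarter of training, batch 32, 14 epochs.
#'
#' @param channels Input channels (default bichannel).
#' @param seed Training seed.
#' @param epochs Training epochs.
#' @param input_side Input side in pixels.
#' @param conv_filters Per-stack filter counts.
#' @return A [model_config()].
#' @export
benchmark_config <- function(channels = c("gray", "green"), seed = 1L,
                             epochs = 14L, input_side = 100L,
                             conv_filters = c(6L, 12L, 12L, 24L)) {
  model_config(input_side = input_side, channels = channels,
               conv_filters = conv_filters, dense_units = 32L,
               dropout = 0.3, learning_rate = 1e-3, batch_size = 32L,
               epochs = epochs, weight_decay = 1e-4, lr_decay_factor = 0.1,
               seed = seed)
}

#' Run the phantom screening benchmark end to end
#'
#' Generates (or reuses) a balanced phantom corpus, computes both entropy
#' channels, holds out a stratified test fraction, trains the configured
#' model and reports screening metrics on the held-out set.
#'
#' @param n_per_class Phantoms per class.
#' @param side Image side in pixels.
#' @param corpus_seed Seed for corpus generation and the split.
#' @param config A [model_config()]; default [benchmark_config()].
#' @param test_fraction Held-out fraction per grade (default 0.2).
#' @param data Optional precomputed result of [preprocess_corpus()] (with
#'   `grades`), to share preprocessing across several training runs.
#' @param augment_train Lossless transforms applied to enlarge the training
#'   split (entropy images flip exactly like their photographs); `NULL`
#'   disables augmentation.
#' @param verbose Print training progress.
#' @return List with `report` (an `eval_report`), `model`, `history`, and
#'   `n_train` / `n_test`.
#' @export
run_benchmark <- function(n_per_class = 1000L, side = 100L, corpus_seed = 1L,
                          config = benchmark_config(), test_fraction = 0.2,
                          data = NULL, augment_train = "hflip",
                          verbose = FALSE) {
  if (is.null(data)) {
    corpus <- benchmark_corpus(n_per_class, side, corpus_seed)
    data <- preprocess_corpus(corpus)
  }
  keep <- names(data$inputs)[names(data$inputs) %in% config$channels]
  if (!setequal(keep, config$channels))
    stop("preprocessed data lacks a configured channel")
  test_idx <- stratified_split(data$grades, test_fraction, corpus_seed + 7L)
  train_idx <- setdiff(seq_along(data$labels), test_idx)
  tr_in <- lapply(data$inputs[config$channels], function(a) a[, , train_idx, drop = FALSE])
  te_in <- lapply(data$inputs[config$channels], function(a) a[, , test_idx, drop = FALSE])
  tr_labels <- data$labels[train_idx]
  if (length(augment_train)) {
    flip_plane <- function(m, tr) switch(tr,
      hflip = m[, ncol(m):1, drop = FALSE],
      vflip = m[nrow(m):1, , drop = FALSE],
      rot180 = m[nrow(m):1, ncol(m):1, drop = FALSE],
      stop("unsupported training transform: ", tr))
    n_tr <- length(train_idx)
    for (ch in names(tr_in)) {
      base <- tr_in[[ch]]
      pieces <- c(list(base), lapply(augment_train, function(tr) {
        flipped <- array(0, dim = dim(base))
        for (i in seq_len(n_tr)) flipped[, , i] <- flip_plane(base[, , i], tr)
        flipped
      }))
      tr_in[[ch]] <- array(unlist(pieces),
                           dim = c(dim(base)[1:2],
                                   n_tr * (length(augment_train) + 1L)))
    }
    tr_labels <- rep(tr_labels, length(augment_train) + 1L)
  }
  model <- build_model(config)
  model <- train_model(model, tr_in, tr_labels,
                       validation = list(inputs = te_in,
                                         labels = data$labels[test_idx]),
                       verbose = verbose)
  probs <- predict(model, te_in)
  report <- evaluate_predictions(data$labels[test_idx], probs)
  list(report = report, model = model, history = model$history,
       n_train = length(train_idx), n_test = length(test_idx))
}
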