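# Small-input configs keep these tests fast; the architecture logic (four
# conv/pool blocks per stack, merged dense head) is identical at any side.

tiny_config <- function(channels = c("gray", "green"), seed = 1L,
                        dropout = 0, ...) {
  model_config(input_side = 16L, channels = channels,
               conv_filters = c(2L, 3L, 3L, 4L), dense_units = 6L,
               dropout = dropout, learning_rate = 3e-3, batch_size = 8L,
               epochs = 5L, seed = seed, ...)
}

rand_inputs <- function(channels, n, side = 16L, seed = 1L) {
  set.seed(seed)
  ins <- lapply(channels, function(ch) array(runif(side * side * n),
                                             c(side, side, n)))
  names(ins) <- channels
  ins
}

test_that("configuration validates the architecture constraints", {
  expect_error(model_config(input_side = 15), ">= 16")
  expect_error(model_config(conv_filters = c(8, 8)), "length 4")
  expect_error(model_config(dropout = 1), "dropout")
  expect_error(model_config(learning_rate = 0), "learning_rate")
  cfg <- model_config()
  expect_equal(cfg$pool_sides, c(50L, 25L, 12L, 6L))
  expect_equal(cfg$conv_filters, c(32L, 64L, 64L, 128L))
})

test_that("model builds are seed-deterministic and emit probabilities in [0,1]", {
  cfg <- tiny_config(seed = 11)
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(tiny_config(seed = 12))
  expect_false(identical(m1$params, m3$params))

  ins <- rand_inputs(cfg$channels, 7)
  p <- predict(m1, ins)
  expect_length(p, 7)
  expect_true(all(p >= 0 & p <= 1))

  # single-channel ablation accepts one input
  mg <- build_model(tiny_config(channels = "green"))
  pg <- predict(mg, rand_inputs("green", 4))
  expect_length(pg, 4)

  expect_error(predict(m1, rand_inputs("gray", 4)), "named list")
  bad <- rand_inputs(cfg$channels, 4, side = 16)
  bad$gray <- bad$gray[1:15, , , drop = FALSE]
  expect_error(predict(m1, bad), "16 x 16")
})

test_that("prediction is batch-order invariant and duplicates score identically", {
  m <- build_model(tiny_config(seed = 3))
  ins <- rand_inputs(m$config$channels, 6, seed = 4)
  dup <- lapply(ins, function(a) a[, , c(1:6, 1L), drop = FALSE])
  p <- predict(m, dup)
  expect_equal(p[7], p[1])

  perm <- c(4, 2, 6, 1, 5, 3)
  p_perm <- predict(m, lapply(ins, function(a) a[, , perm, drop = FALSE]))
  expect_equal(p_perm, predict(m, ins)[perm])

  # evaluation-mode forward is deterministic even with nonzero dropout
  md <- build_model(tiny_config(seed = 5, dropout = 0.4))
  expect_identical(predict(md, ins), predict(md, ins))
})

test_that("training descends, zero epochs is a no-op, and a tiny set is overfit to 100%", {
  cfg <- tiny_config(seed = 21)
  n <- 32
  labels <- rep(c(0, 1), each = 16)
  ins <- rand_inputs(cfg$channels, n, seed = 6)
  # separable toy set: positives get a bright block
  for (ch in names(ins)) ins[[ch]][4:12, 4:12, labels == 1] <-
    ins[[ch]][4:12, 4:12, labels == 1] + 0.8

  m0 <- build_model(cfg)
  same <- train_model(m0, ins, labels, epochs = 0)
  expect_identical(same$params, m0$params)

  m <- train_model(m0, ins, labels, epochs = 40)
  expect_equal(nrow(m$history), 40)
  expect_lte(m$history$loss[10], m$history$loss[1])
  pr <- predict(m, ins)
  expect_equal(mean((pr >= 0.5) == (labels == 1)), 1)

  # same seed, same data -> identical trained parameters
  m_b <- train_model(build_model(cfg), ins, labels, epochs = 3)
  m_c <- train_model(build_model(cfg), ins, labels, epochs = 3)
  expect_identical(m_b$params, m_c$params)

  expect_error(train_model(m0, ins, labels[-1]), "labels")
  expect_error(train_model(m0, ins, c(labels[-1], 3)), "binary")
})

test_that("analytic gradients match finite differences", {
  cfg <- tiny_config(seed = 31)
  model <- build_model(cfg)
  ins <- rand_inputs(cfg$channels, 3, seed = 7)
  labels <- c(1, 0, 1)
  fwd <- entropyDR:::forward_pass
  cache <- fwd(model, ins, train = FALSE, keep_cache = TRUE)
  grads <- entropyDR:::backward_pass(model, cache, labels)
  loss_of <- function(m) entropyDR:::bce_loss(fwd(m, ins), labels)
  # the convolution kernels compute in single precision, so finite
  # differences carry float-level noise; compare at a matching tolerance
  eps <- 1e-4
  set.seed(8)
  for (nm in c("gray_W1", "green_W3", "gray_b4", "dense_W", "out_W", "out_b")) {
    p <- model$params[[nm]]
    for (k in sample(length(p), min(3, length(p)))) {
      m2 <- model
      m2$params[[nm]][k] <- p[k] + eps; up <- loss_of(m2)
      m2$params[[nm]][k] <- p[k] - eps; dn <- loss_of(m2)
      num <- (up - dn) / (2 * eps)
      expect_lt(abs(grads[[nm]][k] - num),
                0.05 * (abs(num) + abs(grads[[nm]][k])) + 1e-5)
    }
  }
})

test_that("checkpoints round-trip through disk", {
  m <- build_model(tiny_config(seed = 41))
  ins <- rand_inputs(m$config$channels, 4, seed = 9)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  back <- load_checkpoint(path)
  expect_identical(predict(back, ins), predict(m, ins))
  p2 <- withr::local_tempfile(fileext = ".rds")
  saveRDS(1:3, p2)
  expect_error(load_checkpoint(p2), "not a model checkpoint")
})
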