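# Two-input ("bichannel") convolutional network for referable-retinopathy
# detection. Each input stack is four [conv 5x5 -> ReLU -> maxpool 2x2]
# blocks; the flattened stacks are concatenated and passed through a ReLU
# dense layer with dropout to a single sigmoid output. Training is
# binary cross-entropy with Adam. Convolution/pooling kernels live in
# compiled code; everything is driven by one seed for reproducibility.

#' Network and training configuration
#'
#' Reference values mirror the published architecture: four 5x5
#' convolutional layers with 32/64/64/128 filters per stack, dropout 0.3,
#' Adam at learning rate 1e-4. All of it is configurable; desk-scale
#' experiments typically shrink the filter counts and epochs.
#'
#' @param input_side Input side in pixels (default 100); must be >= 16 so
#'   four pooling stages survive.
#' @param channels Input channel names, e.g. `c("gray", "green")` for the
#'   bichannel model or a single name for an ablation.
#' @param conv_filters Four filter counts per stack.
#' @param kernel_size Convolution kernel side (odd), default 5.
#' @param dropout Dropout rate in `[0, 1)`, default 0.3, applied after the
#'   hidden dense layer (inverted dropout, so evaluation-mode logits are
#'   expectation-exact).
#' @param dense_units Width of the hidden dense layer, default 128.
#' @param learning_rate Adam step size, > 0, default 1e-4.
#' @param batch_size Minibatch size, default 64.
#' @param epochs Training epochs, default 50.
#' @param weight_decay Decoupled L2 weight decay applied with the Adam
#'   update (AdamW-style), default 0.
#' @param lr_decay_factor Multiplier applied to the learning rate for the
#'   final quarter of training (default 1 = constant rate). A step decay
#'   stabilises the end-of-training parameters, which otherwise oscillate
#'   between epochs at desk-scale sample sizes.
#' @param average_tail Number of trailing epochs whose parameters are
#'   averaged into the returned model (stochastic weight averaging; 0 =
#'   keep the final-epoch parameters). Averaging across the low-rate tail
#'   epochs removes the residual epoch-to-epoch jitter of the endpoint.
#' @param seed Integer seed driving initialisation, shuffling and dropout.
#' @return Object of class `model_config`.
#' @export
model_config <- function(input_side = 100L, channels = c("gray", "green"),
                         conv_filters = c(32L, 64L, 64L, 128L),
                         kernel_size = 5L, dropout = 0.3, dense_units = 128L,
                         learning_rate = 1e-4, batch_size = 64L,
                         epochs = 50L, weight_decay = 0,
                         lr_decay_factor = 1, average_tail = 0L, seed = 1L) {
  input_side <- as.integer(input_side)
  if (length(conv_filters) != 4L) stop("conv_filters must have length 4")
  if (input_side < 16L)
    stop("input_side must be >= 16 to survive four 2x2 pooling stages")
  if (kernel_size %% 2L == 0L) stop("kernel_size must be odd")
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (weight_decay < 0) stop("weight_decay must be >= 0")
  if (lr_decay_factor <= 0 || lr_decay_factor > 1)
    stop("lr_decay_factor must lie in (0, 1]")
  if (average_tail < 0) stop("average_tail must be >= 0")
  if (length(channels) < 1L) stop("at least one channel is required")
  sides <- Reduce(function(s, .) s %/% 2L, 1:4, accumulate = TRUE,
                  init = input_side)[-1]
  structure(list(
    input_side = input_side, channels = channels,
    conv_filters = as.integer(conv_filters),
    kernel_size = as.integer(kernel_size), dropout = dropout,
    dense_units = as.integer(dense_units), learning_rate = learning_rate,
    batch_size = as.integer(batch_size), epochs = as.integer(epochs),
    weight_decay = weight_decay, lr_decay_factor = lr_decay_factor,
    average_tail = as.integer(average_tail),
    seed = as.integer(seed), pool_sides = as.integer(sides)),
    class = "model_config")
}

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

#' Build an (untrained) bichannel model
#'
#' Parameters are He-initialised under the config seed, so two builds from
#' the same config are bit-identical.
#'
#' @param config A [model_config()].
#' @return Object of class `bichannel_model`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  K <- config$kernel_size
  nf <- config$conv_filters
  flat_side <- config$pool_sides[4]
  flat_per_stack <- flat_side^2 * nf[4]
  D <- flat_per_stack * length(config$channels)
  params <- with_seed(config$seed, {
    p <- list()
    for (st in config$channels) {
      cin <- 1L
      for (l in 1:4) {
        p[[paste0(st, "_W", l)]] <- he_init(c(K, K, cin, nf[l]), K * K * cin)
        p[[paste0(st, "_b", l)]] <- numeric(nf[l])
        cin <- nf[l]
      }
    }
    p$dense_W <- matrix(rnorm(D * config$dense_units, sd = sqrt(2 / D)),
                        D, config$dense_units)
    p$dense_b <- numeric(config$dense_units)
    p$out_W <- matrix(rnorm(config$dense_units, sd = sqrt(1 / config$dense_units)),
                      config$dense_units, 1L)
    p$out_b <- 0
    p
  })
  structure(list(config = config, params = params, opt = NULL,
                 norm = NULL, trained_epochs = 0L,
                 history = data.frame(epoch = integer(), loss = numeric(),
                                      accuracy = numeric(),
                                      val_loss = numeric(),
                                      val_accuracy = numeric())),
            class = "bichannel_model")
}

#' @export
print.bichannel_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<bichannel_model: %s input %dx%d, filters %s, dense %d, %d epoch(s) trained>\n",
    paste(cfg$channels, collapse = "+"), cfg$input_side, cfg$input_side,
    paste(cfg$conv_filters, collapse = "/"), cfg$dense_units,
    x$trained_epochs))
  invisible(x)
}

check_inputs <- function(inputs, config) {
  if (!is.list(inputs) || !all(config$channels %in% names(inputs)))
    stop("inputs must be a named list with an array per channel: ",
         paste(config$channels, collapse = ", "))
  n <- NULL
  for (st in config$channels) {
    d <- dim(inputs[[st]])
    if (length(d) != 3L || d[1] != config$input_side || d[2] != config$input_side)
      stop("channel '", st, "' must be a ", config$input_side, " x ",
           config$input_side, " x n array")
    if (is.null(n)) n <- d[3] else if (n != d[3])
      stop("channels disagree on the number of samples")
  }
  n
}

relu_keep <- function(z) { z[z < 0] <- 0; z }

# Forward pass over a batch. `inputs` is a named list of (H, W, n) arrays.
# In training mode dropout masks are sampled from the current RNG stream and
# cached; in evaluation mode dropout is disabled (inverted scaling already
# applied at train time).
forward_pass <- function(model, inputs, train = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  n <- check_inputs(inputs, cfg)
  drate <- if (train) cfg$dropout else 0
  cache <- list(stacks = list())
  flat <- NULL
  for (st in cfg$channels) {
    # standardize with the training-set statistics (stored at train time) so
    # the weak entropy contrasts reach the filters at unit scale; before
    # training, fall back to centring the unit interval
    if (!is.null(model$norm)) {
      xs <- (inputs[[st]] - model$norm[[st]]$center) / model$norm[[st]]$scale
    } else {
      xs <- inputs[[st]] - 0.5
    }
    x <- array(xs, dim = c(cfg$input_side, cfg$input_side, 1L, n))
    layers <- list()
    for (l in 1:4) {
      W <- p[[paste0(st, "_W", l)]]
      b <- p[[paste0(st, "_b", l)]]
      a <- conv2d_forward_cpp(x, W, b, relu = TRUE)
      mp <- maxpool2_forward_cpp(a)
      layers[[l]] <- list(x = x, a = a, idx = mp$idx)
      x <- mp$y
    }
    fs <- matrix(x, nrow = prod(dim(x)[1:3]), ncol = n)
    flat <- if (is.null(flat)) fs else rbind(flat, fs)
    cache$stacks[[st]] <- layers
  }
  Fm <- t(flat)                                   # n x D
  z1 <- sweep(Fm %*% p$dense_W, 2L, p$dense_b, "+")
  h <- relu_keep(z1)
  mask_d <- NULL
  if (drate > 0) {
    mask_d <- matrix((runif(length(h)) >= drate) / (1 - drate), nrow(h), ncol(h))
    h <- h * mask_d
  }
  logit <- drop(h %*% p$out_W) + p$out_b
  prob <- plogis(logit)
  if (keep_cache) {
    cache$Fm <- Fm; cache$z1 <- z1; cache$h <- h; cache$mask_d <- mask_d
    cache$logit <- logit; cache$prob <- prob; cache$n <- n
    cache
  } else {
    prob
  }
}

backward_pass <- function(model, cache, labels) {
  cfg <- model$config
  p <- model$params
  n <- cache$n
  g <- list()
  dlogit <- (cache$prob - labels) / n            # BCE through the sigmoid
  g$out_W <- t(cache$h) %*% matrix(dlogit, n, 1L)
  g$out_b <- sum(dlogit)
  dh <- matrix(dlogit, n, 1L) %*% t(p$out_W)
  if (!is.null(cache$mask_d)) dh <- dh * cache$mask_d
  dz1 <- dh
  dz1[cache$z1 <= 0] <- 0
  g$dense_W <- t(cache$Fm) %*% dz1
  g$dense_b <- colSums(dz1)
  dF <- dz1 %*% t(p$dense_W)                     # n x D
  dflat <- t(dF)                                 # D x n
  offset <- 0L
  flat_per_stack <- cfg$pool_sides[4]^2 * cfg$conv_filters[4]
  for (st in cfg$channels) {
    layers <- cache$stacks[[st]]
    s4 <- cfg$pool_sides[4]
    dy <- array(dflat[offset + seq_len(flat_per_stack), , drop = FALSE],
                dim = c(s4, s4, cfg$conv_filters[4], n))
    offset <- offset + flat_per_stack
    for (l in 4:1) {
      lay <- layers[[l]]
      # post-activation a is zero exactly where the ReLU was inactive
      da <- maxpool2_backward_cpp(lay$idx, dy, dim(lay$a))
      da <- relu_backward_cpp(da, lay$a)
      dim(da) <- dim(lay$a)
      gr <- conv2d_backward_cpp(lay$x, p[[paste0(st, "_W", l)]], da,
                                need_dx = l > 1L)
      g[[paste0(st, "_W", l)]] <- gr$dw
      g[[paste0(st, "_b", l)]] <- gr$db
      dy <- gr$dx
    }
  }
  g
}

bce_loss <- function(prob, labels) {
  eps <- 1e-12
  -mean(labels * log(pmax(prob, eps)) + (1 - labels) * log(pmax(1 - prob, eps)))
}

adam_step <- function(model, grads, lr = NULL) {
  cfg <- model$config
  if (is.null(lr)) lr <- cfg$learning_rate
  if (is.null(model$opt)) {
    model$opt <- list(t = 0L,
                      m = lapply(model$params, function(x) x * 0),
                      v = lapply(model$params, function(x) x * 0))
  }
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  model$opt$t <- model$opt$t + 1L
  t <- model$opt$t
  for (nm in names(model$params)) {
    gmat <- grads[[nm]]
    model$opt$m[[nm]] <- b1 * model$opt$m[[nm]] + (1 - b1) * gmat
    model$opt$v[[nm]] <- b2 * model$opt$v[[nm]] + (1 - b2) * gmat^2
    mhat <- model$opt$m[[nm]] / (1 - b1^t)
    vhat <- model$opt$v[[nm]] / (1 - b2^t)
    step <- mhat / (sqrt(vhat) + eps)
    wd <- if (is.null(cfg$weight_decay)) 0 else cfg$weight_decay
    if (wd > 0 && !grepl("_b[0-9]*$|_b$", nm) && !nm %in% c("dense_b", "out_b")) {
      step <- step + wd * model$params[[nm]]
    }
    model$params[[nm]] <- model$params[[nm]] - lr * step
  }
  model
}

slice_inputs <- function(inputs, idx) {
  lapply(inputs, function(a) a[, , idx, drop = FALSE])
}

#' Train a bichannel model
#'
#' Minimises binary cross-entropy with Adam. Shuffling, dropout and
#' initialisation all derive from the config seed, so training is
#' deterministic for a fixed thread count.
#'
#' @param model A `bichannel_model` from [build_model()].
#' @param inputs Named list with one `side x side x n` array per configured
#'   channel (unit-rescaled entropy images).
#' @param labels Binary vector of length `n` (1 = referable).
#' @param epochs Number of epochs; defaults to the config value. `0` returns
#'   the model unchanged.
#' @param validation Optional `list(inputs =, labels =)` evaluated after
#'   each epoch.
#' @param verbose Print per-epoch progress.
#' @return The trained model with `history` filled in (one row per epoch:
#'   running train loss/accuracy and, if given, validation loss/accuracy).
#' @export
train_model <- function(model, inputs, labels, epochs = NULL,
                        validation = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "bichannel_model"))
  cfg <- model$config
  n <- check_inputs(inputs, cfg)
  labels <- as.numeric(labels)
  if (length(labels) != n) stop("labels must match the number of samples")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  if (is.null(epochs)) epochs <- cfg$epochs
  epochs <- as.integer(epochs)
  if (epochs == 0L) return(model)
  if (is.null(model$norm)) {
    model$norm <- lapply(inputs[cfg$channels], function(a) {
      s <- stats::sd(a)
      list(center = mean(a), scale = if (s > 0) s else 1)
    })
  }
  with_seed(cfg$seed + 1L, {
    decay_from <- floor(0.75 * epochs) + 1L
    tail_k <- if (is.null(cfg$average_tail)) 0L else min(cfg$average_tail, epochs)
    swa <- NULL
    for (ep in seq_len(epochs)) {
      fac <- if (is.null(cfg$lr_decay_factor)) 1 else cfg$lr_decay_factor
      lr_now <- cfg$learning_rate * ifelse(ep >= decay_from, fac, 1)
      ord <- sample.int(n)
      losses <- c(); correct <- 0L
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        xb <- slice_inputs(inputs, idx)
        yb <- labels[idx]
        cache <- forward_pass(model, xb, train = TRUE, keep_cache = TRUE)
        losses <- c(losses, bce_loss(cache$prob, yb))
        correct <- correct + sum((cache$prob >= 0.5) == (yb == 1))
        grads <- backward_pass(model, cache, yb)
        model <- adam_step(model, grads, lr = lr_now)
      }
      row <- data.frame(epoch = model$trained_epochs + ep,
                        loss = mean(losses), accuracy = correct / n,
                        val_loss = NA_real_, val_accuracy = NA_real_)
      if (!is.null(validation)) {
        vp <- forward_pass(model, validation$inputs)
        row$val_loss <- bce_loss(vp, validation$labels)
        row$val_accuracy <- mean((vp >= 0.5) == (validation$labels == 1))
      }
      if (tail_k > 0L && ep > epochs - tail_k) {
        swa <- if (is.null(swa)) model$params else
          mapply(function(a, b) a + b, swa, model$params, SIMPLIFY = FALSE)
      }
      model$history <- rbind(model$history, row)
      if (verbose)
        message(sprintf("epoch %d: loss %.4f acc %.3f%s", row$epoch, row$loss,
                        row$accuracy,
                        if (!is.null(validation))
                          sprintf(" val_acc %.3f", row$val_accuracy) else ""))
    }
    if (tail_k > 0L) {
      model$params <- lapply(swa, function(a) a / tail_k)
    }
    model$trained_epochs <- model$trained_epochs + epochs
    model
  })
}

#' Predict referable-retinopathy probabilities
#'
#' Evaluation-mode forward pass (dropout disabled): deterministic for a
#' fixed model and independent of batch order.
#'
#' @param object A `bichannel_model`.
#' @param inputs Named list of input arrays, as in [train_model()].
#' @param batch_size Samples per forward chunk.
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict.bichannel_model <- function(object, inputs, batch_size = 256L, ...) {
  n <- check_inputs(inputs, object$config)
  out <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    out[idx] <- forward_pass(object, slice_inputs(inputs, idx))
  }
  out
}

#' Save / load a model checkpoint
#'
#' Checkpoints use R's native serialisation. Training history can be
#' exported separately as CSV.
#'
#' @param model A `bichannel_model`.
#' @param path Checkpoint path (`.rds`).
#' @return `path` invisibly, or the restored model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "bichannel_model")) stop("not a model checkpoint: ", path)
  m
}
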