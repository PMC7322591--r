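# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's own compiled kernels.

# symmetric (edge-inclusive) reflection of 1-based indices onto 1..n
reflect1 <- function(i, n) {
  while (any(bad <- i < 1 | i > n)) {
    i[i < 1] <- 1 - i[i < 1]
    i[i > n] <- 2 * n + 1 - i[i > n]
  }
  i
}

# naive per-pixel histogram local entropy (bits), reflective padding
entropy_oracle <- function(plane, n) {
  r <- n %/% 2
  H <- nrow(plane); W <- ncol(plane)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      vals <- plane[reflect1(i + (-r:r), H), reflect1(j + (-r:r), W)]
      pr <- table(vals) / n^2
      out[i, j] <- -sum(pr * log2(pr))
    }
  }
  out
}

# dense 2-D Gaussian convolution with the same truncated kernel and
# reflective padding, then the unsharp-mask arithmetic
unsharp_oracle <- function(plane, sigma, amount) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  w <- dnorm(seq(-r, r), sd = sigma); w <- w / sum(w)
  K <- outer(w, w)
  H <- nrow(plane); W <- ncol(plane)
  g <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      g[i, j] <- sum(K * plane[reflect1(i + (-r:r), H), reflect1(j + (-r:r), W)])
    }
  }
  pmin(pmax(floor(plane + amount * (plane - g) + 0.5), 0), 255)
}

# exhaustive pairwise Mann-Whitney AUC with ties counted 1/2
auc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# small deterministic RGB test image
random_rgb <- function(side = 10L, seed = 1L) {
  set.seed(seed)
  as_rgb_image(array(sample(0:255, side * side * 3, replace = TRUE),
                     dim = c(side, side, 3L)))
}

# tiny records table for dataset tests
make_records <- function(counts) {
  do.call(rbind, lapply(names(counts), function(g) {
    n <- counts[[g]]
    if (n == 0) return(NULL)
    data.frame(image_id = sprintf("g%s_%04d", g, seq_len(n)),
               grade = as.integer(g), stringsAsFactors = FALSE)
  }))
}
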