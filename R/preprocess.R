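# Unsharp masking and local-entropy images: the texture features fed to the
# bichannel network.

# Edge-inclusive symmetric reflection indices for padding a length-n axis by
# r on both sides (matches the C++ entropy window padding).
reflect_indices <- function(n, r) {
  vapply(seq.int(-r, n + r - 1L), function(i) {
    while (i < 0L || i >= n) {
      if (i < 0L) i <- -i - 1L
      if (i >= n) i <- 2L * n - i - 1L
    }
    i + 1L
  }, integer(1))
}

# Discrete Gaussian kernel, truncated at 3 sigma (radius >= 1), normalised.
gaussian_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  w <- dnorm(seq(-r, r), sd = sigma)
  w / sum(w)
}

#' Gaussian blur of a gray plane
#'
#' Separable Gaussian convolution with reflective (symmetric) boundary
#' handling; kernel truncated at 3 sigma. Used internally by
#' [unsharp_mask()] and exported for inspection.
#'
#' @param plane Numeric matrix.
#' @param sigma Gaussian standard deviation in pixels, > 0.
#' @return Blurred numeric matrix of the same dimension.
#' @export
gaussian_blur <- function(plane, sigma) {
  if (!is.matrix(plane)) stop("plane must be a matrix")
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
  w <- gaussian_kernel(sigma)
  r <- (length(w) - 1L) %/% 2L
  H <- nrow(plane); W <- ncol(plane)
  # rows pass
  xp <- plane[reflect_indices(H, r), , drop = FALSE]
  out <- matrix(0, H, W)
  for (k in seq_along(w)) out <- out + w[k] * xp[k:(k + H - 1L), , drop = FALSE]
  # columns pass
  xp <- out[, reflect_indices(W, r), drop = FALSE]
  out <- matrix(0, H, W)
  for (k in seq_along(w)) out <- out + w[k] * xp[, k:(k + W - 1L), drop = FALSE]
  out
}

#' Unsharp masking
#'
#' Sharpens a gray plane by adding back a scaled high-frequency residual:
#' `clip(round(plane + amount * (plane - gaussian_blur(plane, sigma))), 0,
#' 255)`. The residual ("unsharp mask") is the original minus its Gaussian
#' blur, so edges and small lesions are amplified before the entropy stage.
#'
#' @param plane Numeric matrix with values in `[0, 255]`.
#' @param sigma Gaussian standard deviation of the blur, in pixels (> 0).
#'   Default 2, chosen for the 100 x 100 working resolution.
#' @param amount Non-negative scale of the mask; 0 is the identity.
#' @return Integer-valued matrix in `[0, 255]`.
#' @export
unsharp_mask <- function(plane, sigma = 2, amount = 1) {
  if (!is.matrix(plane)) stop("plane must be a matrix")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a single value > 0")
  if (!is.numeric(amount) || length(amount) != 1L || amount < 0)
    stop("amount must be >= 0")
  if (amount == 0) return(plane)
  g <- gaussian_blur(plane, sigma)
  clip255(round_half_up(plane + amount * (plane - g)))
}

#' Local Shannon-entropy image
#'
#' For every pixel, builds the histogram of integer intensities in the
#' centred `block_size x block_size` window (reflective padding at the
#' borders) and returns the Shannon entropy in bits,
#' `-sum_i P(i) log2 P(i)` with `0 log2 0 = 0`. High values mark
#' heterogeneous neighbourhoods (vessels, lesions); constant regions give 0.
#'
#' @param plane Numeric matrix in `[0, 255]`; values are rounded to integers
#'   before binning.
#' @param block_size Odd window side `n >= 3`; default 9, the block size
#'   that maximises detection accuracy in this pipeline.
#' @param bins Number of intensity levels used for the histogram, in
#'   `[2, 256]`; default 256 (one bin per 8-bit level).
#' @return A matrix of class `entropy_image` (same size as `plane`) with
#'   attributes `block_size`, `bins`, and `rescaled = FALSE`; values in
#'   `[0, log2(min(block_size^2, bins))]` bits.
#' @export
local_entropy <- function(plane, block_size = 9L, bins = 256L) {
  if (!is.matrix(plane)) stop("plane must be a matrix")
  block_size <- as.integer(block_size)
  bins <- as.integer(bins)
  if (block_size < 3L || block_size %% 2L == 0L)
    stop("block_size must be an odd integer >= 3")
  if (bins < 2L || bins > 256L) stop("bins must lie in [2, 256]")
  if (nrow(plane) < block_size || ncol(plane) < block_size)
    stop("plane must be at least block_size x block_size")
  v <- pmin(pmax(as.integer(round(plane)), 0L), 255L)
  binned <- matrix((v * bins) %/% 256L, nrow(plane), ncol(plane))
  e <- local_entropy_cpp(binned, block_size, bins)
  structure(e, class = c("entropy_image", "matrix"),
            block_size = block_size, bins = bins, rescaled = FALSE)
}

#' Rescale an entropy image to the unit interval
#'
#' Divides by the fixed theoretical maximum `log2(min(block_size^2, bins))`
#' so that entropy images from different photographs stay on a common scale
#' (per-image min-max scaling would destroy cross-image comparability).
#'
#' @param entropy An `entropy_image` from [local_entropy()].
#' @return The entropy image with values in `[0, 1]` and `rescaled = TRUE`.
#' @export
rescale_unit <- function(entropy) {
  if (!inherits(entropy, "entropy_image"))
    stop("entropy must come from local_entropy()")
  if (isTRUE(attr(entropy, "rescaled")))
    stop("entropy image is already unit-rescaled")
  n <- attr(entropy, "block_size")
  bins <- attr(entropy, "bins")
  emax <- log2(min(n^2, bins))
  out <- unclass(entropy) / emax
  structure(pmin(out, 1), class = c("entropy_image", "matrix"),
            block_size = n, bins = bins, rescaled = TRUE)
}

#' @export
print.entropy_image <- function(x, ...) {
  cat(sprintf("<entropy_image %d x %d, n = %d, bins = %d, %s, range [%.4f, %.4f]>\n",
              nrow(x), ncol(x), attr(x, "block_size"), attr(x, "bins"),
              if (isTRUE(attr(x, "rescaled"))) "unit-rescaled" else "bits",
              min(x), max(x)))
  invisible(x)
}

#' Build one network input channel from an RGB image
#'
#' Chains the full preprocessing path for one channel: channel extraction
#' (luminance for `"gray"`, green plane for `"green"`), unsharp masking,
#' local entropy, unit rescaling. The result is one of the two inputs of the
#' bichannel network.
#'
#' @param image An `rgb_image`, already at working resolution.
#' @param channel `"gray"` (luminance) or `"green"`.
#' @param sigma,amount Unsharp-mask parameters, see [unsharp_mask()].
#' @param block_size,bins Entropy parameters, see [local_entropy()].
#' @return A unit-rescaled `entropy_image`.
#' @export
make_channel_input <- function(image, channel = c("gray", "green"),
                               sigma = 2, amount = 1,
                               block_size = 9L, bins = 256L) {
  channel <- match.arg(channel)
  plane <- if (channel == "gray") to_luminance(image) else extract_green(image)
  um <- unsharp_mask(plane, sigma = sigma, amount = amount)
  rescale_unit(local_entropy(um, block_size = block_size, bins = bins))
}

#' Export an entropy image as an 8-bit PNG
#'
#' Writes `round(value * 255)` for visual inspection of the texture maps.
#'
#' @param entropy A unit-rescaled `entropy_image`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
export_entropy_png <- function(entropy, path) {
  if (!isTRUE(attr(entropy, "rescaled")))
    stop("export expects a unit-rescaled entropy image")
  png::writePNG(round(unclass(entropy) * 255) / 255, target = path)
  invisible(path)
}
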