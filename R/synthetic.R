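# Seeded fundus phantoms: a bright retina disc on a dark background, an
# optic disc, curvilinear dark vessels, and grade-dependent bright
# (exudate-like) and dark (hemorrhage-like) lesions. The generator's job is
# to reproduce two statistical facts the screening pipeline exploits: local
# heterogeneity (hence local entropy) grows with grade, and the green plane
# carries the strongest vessel/lesion contrast.

#' Specify a fundus phantom
#'
#' Defaults define the package's reference study conditions. Mean lesion
#' count per grade is `0, 2, 6, 12, 20` (strictly increasing, Poisson), so
#' severer retinopathy yields more heterogeneous images. Vessel and lesion
#' intensity offsets are largest in the green plane.
#'
#' @param side Image side in pixels, >= 32.
#' @param grade Severity grade 0-4.
#' @param seed Integer seed; the phantom is deterministic given the spec.
#' @param lesion_means Mean lesion count per grade (length 5, strictly
#'   increasing).
#' @param vessel_count Range (min, max) of vessels per image.
#' @param vessel_width Range of vessel half-widths in pixels.
#' @param bright_lesion_radius,dark_lesion_radius Radius ranges in pixels
#'   for exudate-like and hemorrhage-like lesions.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(side = 100L, grade = 0L, seed = 1L,
                         lesion_means = c(0, 2, 6, 12, 20),
                         vessel_count = c(6L, 10L),
                         vessel_width = c(1L, 2L),
                         bright_lesion_radius = c(2, 6),
                         dark_lesion_radius = c(1, 4)) {
  side <- as.integer(side)
  grade <- as.integer(grade)
  if (side < 32L) stop("side must be at least 32 pixels")
  if (grade < 0L || grade > 4L) stop("grade must be in 0..4")
  if (length(lesion_means) != 5L || any(diff(lesion_means) <= 0))
    stop("lesion_means must be 5 strictly increasing values")
  structure(list(side = side, grade = grade, seed = as.integer(seed),
                 lesion_means = lesion_means, vessel_count = vessel_count,
                 vessel_width = vessel_width,
                 bright_lesion_radius = bright_lesion_radius,
                 dark_lesion_radius = dark_lesion_radius),
            class = "phantom_spec")
}

# channel deltas: green carries the strongest contrast, as in real fundus
# photographs where retinal pigments reflect green light preferentially
VESSEL_DELTA <- c(r = 18, g = 55, b = 12)
BRIGHT_DELTA <- c(r = 30, g = 90, b = 15)
DARK_DELTA <- c(r = 25, g = 75, b = 12)

# stamp an additive radial profile onto the three planes at (cy, cx)
stamp_blob <- function(planes, cy, cx, radius, deltas) {
  s <- nrow(planes[[1]])
  r <- ceiling(2 * radius)
  ys <- max(1, round(cy) - r):min(s, round(cy) + r)
  xs <- max(1, round(cx) - r):min(s, round(cx) + r)
  prof <- exp(-outer((ys - cy)^2, (xs - cx)^2, "+") / (2 * (radius / 1.2)^2))
  for (k in 1:3) planes[[k]][ys, xs] <- planes[[k]][ys, xs] + deltas[k] * prof
  planes
}

#' Generate a fundus phantom
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (an `rgb_image`) and `record` (one-row data
#'   frame: `image_id`, `grade`, `referable`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  s <- spec$side
  with_seed(spec$seed, {
    ax <- seq_len(s)
    cx <- s / 2 + 0.5
    d2 <- outer((ax - cx)^2, (ax - cx)^2, "+")
    d <- sqrt(d2)
    R0 <- 0.46 * s
    disc <- d <= R0
    falloff <- pmax(0, 1 - 0.35 * (d / R0)^2)

    r_pl <- matrix(8, s, s); g_pl <- matrix(6, s, s); b_pl <- matrix(5, s, s)
    r_pl[disc] <- (175 * falloff)[disc]
    g_pl[disc] <- (120 * falloff)[disc]
    b_pl[disc] <- (55 * falloff)[disc]
    # mild sensor/texture noise
    r_pl <- r_pl + matrix(rnorm(s * s, 0, 2), s, s)
    g_pl <- g_pl + matrix(rnorm(s * s, 0, 2), s, s)
    b_pl <- b_pl + matrix(rnorm(s * s, 0, 2), s, s)
    planes <- list(r_pl, g_pl, b_pl)

    # optic disc: bright blob offset from centre
    ang <- runif(1, 0, 2 * pi)
    od_y <- cx + 0.55 * R0 * sin(ang)
    od_x <- cx + 0.55 * R0 * cos(ang)
    planes <- stamp_blob(planes, od_y, od_x, 0.09 * s, c(70, 60, 30))

    # vessels: quadratic Bezier strokes from the optic disc outward,
    # subtracted once through a mask so crossings do not double-darken
    n_ves <- sample(spec$vessel_count[1]:spec$vessel_count[2], 1)
    vmask <- matrix(FALSE, s, s)
    for (v in seq_len(n_ves)) {
      a2 <- runif(1, 0, 2 * pi)
      end_y <- cx + R0 * 0.95 * sin(a2)
      end_x <- cx + R0 * 0.95 * cos(a2)
      ctl_y <- (od_y + end_y) / 2 + rnorm(1, 0, 0.15 * s)
      ctl_x <- (od_x + end_x) / 2 + rnorm(1, 0, 0.15 * s)
      t <- seq(0, 1, length.out = 3L * s)
      py <- (1 - t)^2 * od_y + 2 * (1 - t) * t * ctl_y + t^2 * end_y
      px <- (1 - t)^2 * od_x + 2 * (1 - t) * t * ctl_x + t^2 * end_x
      w <- sample(spec$vessel_width[1]:spec$vessel_width[2], 1)
      off <- expand.grid(dy = -w:w, dx = -w:w)
      off <- off[off$dy^2 + off$dx^2 <= w^2, , drop = FALSE]
      for (k in seq_len(nrow(off))) {
        iy <- round(py) + off$dy[k]
        ix <- round(px) + off$dx[k]
        ok <- iy >= 1 & iy <= s & ix >= 1 & ix <= s
        vmask[cbind(iy[ok], ix[ok])] <- TRUE
      }
    }
    vmask <- vmask & disc
    planes[[1]][vmask] <- planes[[1]][vmask] - VESSEL_DELTA["r"]
    planes[[2]][vmask] <- planes[[2]][vmask] - VESSEL_DELTA["g"]
    planes[[3]][vmask] <- planes[[3]][vmask] - VESSEL_DELTA["b"]

    # lesions: counts ~ Poisson(mean by grade); positions uniform in the
    # inner disc; bright exudate-like or dark hemorrhage-like blobs
    n_les <- rpois(1, spec$lesion_means[spec$grade + 1L])
    for (l in seq_len(n_les)) {
      rr <- 0.8 * R0 * sqrt(runif(1))
      aa <- runif(1, 0, 2 * pi)
      ly <- cx + rr * sin(aa)
      lx <- cx + rr * cos(aa)
      if (runif(1) < 0.5) {
        rad <- runif(1, spec$bright_lesion_radius[1], spec$bright_lesion_radius[2])
        planes <- stamp_blob(planes, ly, lx, rad, BRIGHT_DELTA)
      } else {
        rad <- runif(1, spec$dark_lesion_radius[1], spec$dark_lesion_radius[2])
        planes <- stamp_blob(planes, ly, lx, rad, -DARK_DELTA)
      }
    }

    img <- array(0, dim = c(s, s, 3L))
    for (k in 1:3) img[, , k] <- clip255(round_half_up(planes[[k]]))
    record <- data.frame(
      image_id = sprintf("phantom_g%d_s%d", spec$grade, spec$seed),
      grade = spec$grade, referable = spec$grade >= 2L,
      stringsAsFactors = FALSE)
    list(image = as_rgb_image(img), record = record)
  })
}

#' Generate a labelled phantom corpus
#'
#' Child seeds are drawn deterministically from the master seed, so the
#' whole corpus is reproducible and individual phantoms are distinct.
#'
#' @param counts Named numeric vector, grade (`"0"`..`"4"`) -> number of
#'   phantoms.
#' @param side Image side in pixels.
#' @param seed Master integer seed.
#' @param ... Further arguments passed to [phantom_spec()].
#' @return List with `images` (list of `rgb_image`) and `manifest` (data
#'   frame `image_id`, `grade`, `referable`).
#' @export
generate_corpus <- function(counts, side = 100L, seed = 1L, ...) {
  counts <- counts[counts > 0]
  grades <- rep(as.integer(names(counts)), times = as.integer(counts))
  n <- length(grades)
  if (n == 0L) return(list(images = list(), manifest = data.frame(
    image_id = character(), grade = integer(), referable = logical())))
  child_seeds <- with_seed(as.integer(seed),
                           sample.int(.Machine$integer.max - 1L, n))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- generate_phantom(phantom_spec(side = side, grade = grades[i],
                                              seed = child_seeds[i], ...))
  }
  manifest <- do.call(rbind, lapply(out, `[[`, "record"))
  manifest$image_id <- sprintf("%s_%04d", manifest$image_id, seq_len(n))
  rownames(manifest) <- NULL
  list(images = lapply(out, `[[`, "image"), manifest = manifest)
}
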