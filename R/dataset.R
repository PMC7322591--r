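# Flip/rotation augmentation, class balancing to target counts, and
# leakage-safe stratified train/test splitting.

AUG_TRANSFORMS <- c("hflip", "vflip", "rot90", "rot180", "rot270")

#' Apply a lossless geometric transform to an RGB image
#'
#' Flips and multiples-of-90-degree rotations preserve pixel values exactly
#' (no interpolation), which is why they are the augmentation vocabulary for
#' class balancing. `"identity"` is accepted and returns the input.
#'
#' @param image An `rgb_image` (square for rotations).
#' @param transform One of `"identity"`, `"hflip"`, `"vflip"`, `"rot90"`,
#'   `"rot180"`, `"rot270"` (rotations are clockwise).
#' @return The transformed `rgb_image`.
#' @export
augment_image <- function(image, transform) {
  image <- as_rgb_image(unclass(image))
  if (!transform %in% c("identity", AUG_TRANSFORMS))
    stop("unknown transform: ", transform)
  a <- unclass(image)
  H <- dim(a)[1]; W <- dim(a)[2]
  rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])
  per_plane <- function(f) {
    planes <- lapply(1:3, function(k) f(a[, , k]))
    array(unlist(planes), dim = c(dim(planes[[1]]), 3L))
  }
  out <- switch(transform,
    identity = a,
    hflip = a[, W:1, , drop = FALSE],
    vflip = a[H:1, , , drop = FALSE],
    rot90 = per_plane(rot90cw),
    rot180 = a[H:1, W:1, , drop = FALSE],
    rot270 = per_plane(function(m) rot90cw(rot90cw(rot90cw(m)))))
  as_rgb_image(out)
}

#' Define an augmentation and balancing plan
#'
#' @param targets Named numeric vector mapping grade (`"0"`..`"4"`) to the
#'   desired record count after balancing. Targets above the source count
#'   trigger augmentation; below, seeded subsampling without replacement.
#' @param transforms Allowed transforms, a subset of
#'   `c("hflip", "vflip", "rot90", "rot180", "rot270")`.
#' @param seed Integer seed driving all random choices of the plan.
#' @return An object of class `augmentation_plan`.
#' @export
augmentation_plan <- function(targets, transforms = AUG_TRANSFORMS, seed = 1L) {
  if (is.null(names(targets)) || anyNA(suppressWarnings(as.integer(names(targets)))))
    stop("targets must be named by grade")
  if (!all(transforms %in% AUG_TRANSFORMS))
    stop("transforms must be a subset of ", paste(AUG_TRANSFORMS, collapse = ", "))
  if (any(targets < 0)) stop("targets must be non-negative")
  structure(list(targets = targets, transforms = transforms,
                 seed = as.integer(seed)),
            class = "augmentation_plan")
}

#' Balance classes by augmentation or subsampling
#'
#' Brings every grade to its target count. Grades above target are
#' subsampled without replacement; grades below target keep every source
#' once (`transform = "identity"`) and add augmented copies by cycling the
#' allowed transforms over the (seeded, shuffled) sources, so no
#' `(source, transform)` pair repeats until all pairs are exhausted.
#' Deterministic given `(records, plan)`.
#'
#' @param records Data frame with at least `image_id` and `grade` columns
#'   (a `path` column is carried through if present).
#' @param plan An [augmentation_plan()].
#' @return A manifest data frame with columns `image_id`, `source_id`,
#'   `transform`, `grade`, `referable`, `split` (all `NA` until
#'   [split_train_test()]), sorted by `image_id`.
#' @export
balance_classes <- function(records, plan) {
  stopifnot(inherits(plan, "augmentation_plan"))
  if (!all(c("image_id", "grade") %in% names(records)))
    stop("records must have image_id and grade columns")
  records$grade <- as.integer(records$grade)
  out <- list()
  with_seed(plan$seed, {
    for (g_chr in names(plan$targets)) {
      g <- as.integer(g_chr)
      target <- as.integer(plan$targets[[g_chr]])
      src <- records$image_id[records$grade == g]
      n <- length(src)
      if (target == 0L) next
      if (n == 0L) stop("no source records for grade ", g, " with target ", target)
      if (target <= n) {
        keep <- if (target == n) src else sort(sample(src, target))
        out[[g_chr]] <- data.frame(image_id = keep, source_id = keep,
                                   transform = "identity", grade = g,
                                   stringsAsFactors = FALSE)
      } else {
        extra <- target - n
        n_tr <- length(plan$transforms)
        if (n_tr == 0L)
          stop("grade ", g, " needs augmentation but no transforms are allowed")
        # rounds cycle over transforms; sources reshuffled once per round
        pair_src <- character(extra)
        pair_tr <- character(extra)
        round_id <- integer(extra)
        filled <- 0L
        round <- 0L
        while (filled < extra) {
          tr <- plan$transforms[round %% n_tr + 1L]
          cycle <- round %/% n_tr   # > 0 once every pair has been used
          order_src <- sample(src, n)
          take <- min(n, extra - filled)
          sel <- seq_len(take)
          pair_src[filled + sel] <- order_src[sel]
          pair_tr[filled + sel] <- tr
          round_id[filled + sel] <- cycle
          filled <- filled + take
          round <- round + 1L
        }
        suffix <- ifelse(round_id > 0L, paste0("_r", round_id + 1L), "")
        aug <- data.frame(
          image_id = paste0(pair_src, "_", pair_tr, suffix),
          source_id = pair_src, transform = pair_tr, grade = g,
          stringsAsFactors = FALSE)
        base <- data.frame(image_id = src, source_id = src,
                           transform = "identity", grade = g,
                           stringsAsFactors = FALSE)
        out[[g_chr]] <- rbind(base, aug)
      }
    }
  })
  m <- do.call(rbind, out)
  m$referable <- m$grade >= 2L
  m$split <- NA_character_
  if ("path" %in% names(records)) {
    m$path <- records$path[match(m$source_id, records$image_id)]
  }
  m <- m[order(m$image_id), , drop = FALSE]
  rownames(m) <- NULL
  m
}

# Greedy whole-group fill with single-swap repair: pick shuffled groups while
# they fit, then try to exchange an included group for an excluded one whose
# size exceeds it by the remaining deficit.
assign_groups <- function(group_sizes, target) {
  n <- length(group_sizes)
  taken <- logical(n)
  remaining <- target
  for (k in sample.int(n)) {
    if (group_sizes[k] <= remaining) {
      taken[k] <- TRUE
      remaining <- remaining - group_sizes[k]
    }
  }
  guard <- 0L
  while (remaining > 0L && guard < 1000L) {
    guard <- guard + 1L
    fixed <- FALSE
    for (d in remaining:1) {
      ins <- which(taken)
      outs <- which(!taken)
      for (i in ins) {
        j <- outs[group_sizes[outs] == group_sizes[i] + d][1]
        if (!is.na(j)) {
          taken[i] <- FALSE; taken[j] <- TRUE
          remaining <- remaining - d
          fixed <- TRUE
          break
        }
      }
      if (fixed) break
    }
    if (!fixed) break
  }
  if (remaining > 0L)
    stop("cannot honour per-stratum counts without splitting a source group; ",
         "use record_level = TRUE splitting")
  taken
}

#' Assign train/test splits to a balanced manifest
#'
#' Stratified by grade. In the default (strict) mode, all records sharing a
#' source image move together, so an augmented copy can never leak across
#' the split from its source; per-stratum train counts are honoured exactly
#' by a greedy group assignment with swap repair. `record_level = TRUE`
#' instead samples individual records per stratum — the augment-then-split
#' order used by screening studies that balance classes before splitting,
#' needed to reproduce their count arithmetic but allowing near-duplicate
#' leakage.
#'
#' @param manifest A manifest from [balance_classes()].
#' @param train_counts Named numeric vector, grade -> number of training
#'   records for that grade.
#' @param seed Integer seed for the assignment.
#' @param record_level Logical; see above. Default `FALSE` (strict).
#' @return The manifest with `split` filled in (`"train"` or `"test"`).
#' @export
split_train_test <- function(manifest, train_counts, seed = 1L,
                             record_level = FALSE) {
  if (!all(c("image_id", "source_id", "grade") %in% names(manifest)))
    stop("manifest must come from balance_classes()")
  manifest$split <- NA_character_
  with_seed(as.integer(seed), {
    for (g_chr in names(train_counts)) {
      g <- as.integer(g_chr)
      want <- as.integer(train_counts[[g_chr]])
      rows <- which(manifest$grade == g)
      if (want > length(rows))
        stop("grade ", g, ": requested ", want, " train records but only ",
             length(rows), " available")
      if (record_level) {
        tr <- sample(rows, want)
      } else {
        groups <- split(rows, manifest$source_id[rows])
        taken <- assign_groups(lengths(groups), want)
        tr <- unlist(groups[taken], use.names = FALSE)
      }
      manifest$split[rows] <- "test"
      manifest$split[tr] <- "train"
    }
  })
  manifest$split[is.na(manifest$split)] <- "test"
  if (!any(manifest$split == "test"))
    warning("empty test set: every record was assigned to training")
  manifest
}

#' Materialise a manifest record as pixels
#'
#' Loads the source image referenced by a manifest row and applies its
#' recorded transform, yielding the augmented image the record stands for.
#'
#' @param row One-row slice of a manifest (needs `path` and `transform`).
#' @param side Optional working resolution; if given, the source is resized
#'   before the transform.
#' @return An `rgb_image`.
#' @export
materialize_record <- function(row, side = NULL) {
  img <- load_image(row$path)
  if (!is.null(side)) img <- resize_image(img, side)
  augment_image(img, row$transform)
}
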