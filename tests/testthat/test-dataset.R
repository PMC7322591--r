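test_that("geometric transforms satisfy their group identities", {
  img <- random_rgb(8, seed = 13)
  expect_equal(augment_image(augment_image(img, "hflip"), "hflip"), img)
  expect_equal(augment_image(augment_image(img, "vflip"), "vflip"), img)

  r <- img
  for (k in 1:4) r <- augment_image(r, "rot90")
  expect_equal(r, img)

  expect_equal(augment_image(img, "rot180"),
               augment_image(augment_image(img, "hflip"), "vflip"))
  expect_equal(augment_image(augment_image(img, "rot90"), "rot90"),
               augment_image(img, "rot180"))
  expect_equal(augment_image(augment_image(img, "rot270"), "rot90"), img)
  expect_equal(augment_image(img, "identity"), img)
  expect_error(augment_image(img, "rot45"), "unknown transform")
})

test_that("class balancing hits targets exactly and cycles transforms without duplicates", {
  records <- make_records(c("0" = 5, "2" = 2))
  plan <- augmentation_plan(c("0" = 5, "2" = 7), seed = 3)
  m <- balance_classes(records, plan)
  expect_equal(as.vector(table(m$grade)), c(5L, 7L))
  # unchanged class is passed through untouched
  expect_true(all(m$transform[m$grade == 0] == "identity"))

  # 2 sources to target 7 with 5 transforms: every source used >= 3 times,
  # no (source, transform) pair repeats before all pairs are exhausted
  g2 <- m[m$grade == 2, ]
  expect_true(all(table(g2$source_id) >= 3))
  expect_equal(anyDuplicated(g2[c("source_id", "transform")]), 0L)

  # subsampling without replacement when the target is below the source count
  m2 <- balance_classes(records, augmentation_plan(c("0" = 3), seed = 3))
  expect_equal(nrow(m2), 3L)
  expect_equal(anyDuplicated(m2$image_id), 0L)

  # determinism in the full manifest, and referable flags match grade >= 2
  m3 <- balance_classes(records, plan)
  expect_identical(m, m3)
  expect_equal(sum(m$referable), sum(m$grade >= 2))

  expect_error(balance_classes(make_records(c("0" = 3)),
                               augmentation_plan(c("1" = 5), seed = 1)),
               "no source records")
})

test_that("the published per-grade arithmetic reproduces 33,000 balanced and 30,000/3,000 split records", {
  counts <- c("0" = 16500, "1" = 1333, "2" = 2000, "3" = 645, "4" = 645)
  records <- make_records(counts)
  expect_equal(nrow(records), 21123L)
  expect_equal(sum(records$grade >= 2) / nrow(records), 0.156, tolerance = 0.005)

  plan <- augmentation_plan(
    c("0" = 16500, "1" = 4375, "2" = 4375, "3" = 3875, "4" = 3875), seed = 11)
  m <- balance_classes(records, plan)
  expect_equal(nrow(m), 33000L)
  expect_equal(mean(m$grade == 0), 0.5)
  expect_equal(as.vector(table(m$grade)), c(16500L, 4375L, 4375L, 3875L, 3875L))

  m <- split_train_test(m, c("0" = 15000, "1" = 4000, "2" = 4000,
                             "3" = 3500, "4" = 3500),
                        seed = 12, record_level = TRUE)
  expect_equal(sum(m$split == "train"), 30000L)
  expect_equal(sum(m$split == "test"), 3000L)
  tst <- table(m$grade[m$split == "test"])
  expect_equal(as.vector(tst), c(1500L, 375L, 375L, 375L, 375L))
})

test_that("strict splitting keeps augmented copies with their sources and is seed-deterministic", {
  records <- make_records(c("1" = 40, "2" = 30))
  plan <- augmentation_plan(c("1" = 100, "2" = 90), seed = 5)
  m <- balance_classes(records, plan)
  out <- split_train_test(m, c("1" = 80, "2" = 60), seed = 6)
  expect_equal(sum(out$split == "train" & out$grade == 1), 80L)
  expect_equal(sum(out$split == "train" & out$grade == 2), 60L)

  # no-leakage: every source group lives in exactly one split
  by_src <- tapply(out$split, out$source_id, function(s) length(unique(s)))
  expect_true(all(by_src == 1L))

  out2 <- split_train_test(m, c("1" = 80, "2" = 60), seed = 6)
  expect_identical(out, out2)
  out3 <- split_train_test(m, c("1" = 80, "2" = 60), seed = 7)
  expect_false(identical(out$split, out3$split))
  expect_equal(sum(out3$split == "train"), sum(out$split == "train"))

  expect_error(split_train_test(m, c("1" = 1000), seed = 1), "requested")

  expect_warning(split_train_test(m, c("1" = 100, "2" = 90), seed = 8),
                 "empty test set")
})

test_that("materialized augmented records equal the transform of the source pixels", {
  dir <- withr::local_tempdir()
  img <- random_rgb(16, seed = 23)
  src_path <- file.path(dir, "src.png")
  write_image(img, src_path)
  row <- data.frame(path = src_path, transform = "rot90")
  got <- materialize_record(row)
  expect_equal(got, augment_image(img, "rot90"))
})
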