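test_that("phantom generation is deterministic and class-consistent", {
  a <- generate_phantom("malignant", 128, 7)
  b <- generate_phantom("malignant", 128, 7)
  expect_identical(a$image, b$image)
  expect_identical(a$annotation, b$annotation)

  n <- generate_phantom("normal", 128, 3)
  expect_true(is.na(n$annotation$diameter_mm))
  expect_true(is.na(n$annotation$spiculation))

  ben <- generate_phantom("benign", 128, 3)$annotation
  mal <- generate_phantom("malignant", 128, 3)$annotation
  expect_lte(ben$spiculation, 2)
  expect_gte(mal$spiculation, 4)

  expect_error(generate_phantom("normal", 32), "at least 64")
  expect_error(generate_phantom("cyst", 128))
})

test_that("malignant phantoms are larger than benign on average", {
  d_mal <- vapply(1:50, function(i)
    generate_phantom("malignant", 64, i)$annotation$diameter_mm, numeric(1))
  d_ben <- vapply(1:50, function(i)
    generate_phantom("benign", 64, i)$annotation$diameter_mm, numeric(1))
  expect_gt(mean(d_mal), mean(d_ben))
  expect_true(all(d_ben >= 4 & d_ben <= 10))
  expect_true(all(d_mal >= 12 & d_mal <= 25))
})

test_that("phantom datasets are balanced, seeded and non-degenerate", {
  ds <- generate_phantom_dataset(5, 64, seed = 2)
  expect_length(ds$images, 15)
  labs <- vapply(ds$annotations, `[[`, character(1), "label")
  expect_equal(unname(table(labs)), rep(5L, 3), ignore_attr = TRUE)

  ds2 <- generate_phantom_dataset(5, 64, seed = 2)
  expect_identical(vapply(ds2$annotations, `[[`, character(1), "label"),
                   labs)
  # distinct per-item seeds: no two images identical
  for (i in 1:14) for (j in (i + 1):15) {
    expect_false(identical(ds$images[[i]], ds$images[[j]]))
  }
})

test_that("planted feature tables have the promised structure", {
  pt <- generate_feature_table(300, 10, 3, 3, seed = 5)
  expect_s3_class(pt, "planted_table")
  expect_identical(pt$informative_indices, 1:3)
  expect_identical(pt$noise_indices, 4:10)
  expect_identical(generate_feature_table(300, 10, 3, 3, seed = 5)$table,
                   pt$table)

  # with a strong effect every informative between-class gap beats every
  # noise gap, across seeds
  for (s in 1:10) {
    pt <- generate_feature_table(300, 8, 2, 3, seed = s)
    gap <- function(j) {
      m <- tapply(pt$table$features[, j], pt$table$labels, mean)
      max(m) - min(m)
    }
    gaps <- vapply(1:8, gap, numeric(1))
    expect_gt(min(gaps[1:2]), max(gaps[3:8]))
  }
  expect_error(generate_feature_table(100, 5, 6, 1), "exceed")
})

test_that("null tables carry no class signal", {
  # effect = 0: per-feature location tests reject at roughly alpha
  rejections <- 0L
  total <- 0L
  for (s in 1:5) {
    pt <- generate_feature_table(120, 8, 4, 0, seed = s)
    for (j in 1:8) {
      g1 <- pt$table$features[pt$table$labels == 1, j]
      g2 <- pt$table$features[pt$table$labels == 3, j]
      p <- stats::t.test(g1, g2)$p.value
      rejections <- rejections + (p < 0.01)
      total <- total + 1L
    }
  }
  expect_gte((total - rejections) / total, 0.95)
})

test_that("degrade_pair block means match a direct oracle", {
  img <- matrix(runif(64 * 64, 0, 255), 64, 64)
  dp <- degrade_pair(img, 2, noise_sd = 0)
  expect_identical(dim(dp$low), c(32L, 32L))
  expect_identical(dp$high, img)
  # brute-force block average oracle
  oracle <- matrix(0, 32, 32)
  for (i in 1:32) for (j in 1:32) {
    oracle[i, j] <- mean(img[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  }
  expect_equal(unclass(dp$low), oracle, tolerance = 1e-12,
               ignore_attr = TRUE)

  const <- matrix(5, 8, 8)
  expect_true(all(degrade_pair(const, 2, 0)$low == 5))
  expect_error(degrade_pair(matrix(0, 9, 9), 2), "divisible")
})

test_that("annotation CSV round-trips and rejects malformed rows", {
  recs <- data.frame(seriesuid = c("a", "b", "c"),
                     coordX = c(-1.5, 2, 3.25), coordY = c(0, 1, 2),
                     coordZ = c(-100.125, 50, 0.5),
                     diameter_mm = c(4.2, 12.75, 25))
  path <- tempfile(fileext = ".csv")
  write_annotations(recs, path)
  expect_identical(readLines(path)[1],
                   "seriesuid,coordX,coordY,coordZ,diameter_mm")
  back <- read_annotations(path)
  expect_equal(back$coordX, recs$coordX, tolerance = 1e-6)
  expect_equal(back$diameter_mm, recs$diameter_mm, tolerance = 1e-6)
  expect_identical(back$seriesuid, recs$seriesuid)

  # empty list -> header only
  write_annotations(recs[0, ], path)
  expect_length(readLines(path), 1)
  expect_identical(nrow(read_annotations(path)), 0L)

  writeLines(c("seriesuid,coordX,coordY,coordZ,diameter_mm",
               "a,1,2,3,4", "b,1,2,3,abc"), path)
  expect_error(read_annotations(path), "line 3")
  writeLines(c("wrong,header", "a,1,2,3,4"), path)
  expect_error(read_annotations(path), "header")
})

test_that("gray images round-trip exactly at their bit depth", {
  set.seed(1)
  img8 <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
  p <- tempfile(fileext = ".png")
  write_gray_image(img8, p, 8L)
  back <- read_gray_image(p)
  expect_equal(unclass(back), img8, ignore_attr = TRUE)

  img16 <- matrix(sample(0:65535, 256, TRUE), 16, 16)
  p2 <- tempfile(fileext = ".tsv")
  write_gray_image(img16, p2, 16L)
  back16 <- read_gray_image(p2)
  expect_equal(unclass(back16), img16, ignore_attr = TRUE)
  expect_identical(attr(back16, "bit_depth"), 16L)
})
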