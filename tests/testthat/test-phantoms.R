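test_that("phantom scenes are deterministic functions of the seed", {
  a <- desk_phantom(42, n = 3)
  b <- desk_phantom(42, n = 3)
  expect_identical(a, b)
  c <- desk_phantom(43, n = 3)
  expect_false(identical(a$image, c$image))
})

test_that("requested follicle count appears as 8-connected components", {
  for (s in 1:8) {
    n <- s %% 6
    sc <- desk_phantom(600 + s, n = n)
    expect_equal(max(label_components(sc$follicle_mask, 8)), n)
    expect_equal(nrow(sc$follicles), n)
  }
})

test_that("follicles lie inside the ovary; anechoic < hypoechoic < background", {
  for (s in c(611, 612)) {
    sc <- desk_phantom(s, n = 5)
    expect_true(all(sc$ovary_mask[sc$follicle_mask == 1] == 1))
    mf <- mean(sc$image[sc$follicle_mask == 1])
    mo <- mean(sc$image[sc$ovary_mask == 1 & sc$follicle_mask == 0])
    mb <- mean(sc$image[sc$ovary_mask == 0])
    expect_lt(mf, mo)
    expect_lt(mo, mb)
    expect_true(all(sc$image >= 0 & sc$image <= 1))
  }
})

test_that("true counts round-trip through the counting stage", {
  # n_real from the ground-truth mask equals the generator's truth after the
  # same 2-10 mm filter on true diameters, for every non-overlapping scene
  for (s in 1:25) {
    sc <- desk_phantom(700 + s, n = s %% 9)
    rep <- counting_report(sc$follicle_mask, sc$follicle_mask, sc$spacing_mm)
    truth <- sum(sc$follicles$diameter_mm >= 2 & sc$follicles$diameter_mm <= 10)
    expect_equal(rep$n_real, truth, info = paste("seed", 700 + s))
  }
})

test_that("measured diameters track the generator's true diameters", {
  sc <- generate_phantom(6, size_px = 384, spacing_mm = 0.1, seed = 808)
  fs <- extract_follicles(sc$follicle_mask, sc$spacing_mm)
  expect_equal(nrow(fs$records), 6)
  # match records to truth by centroid proximity
  for (i in seq_len(nrow(sc$follicles))) {
    d2 <- (fs$records$centroid_row - sc$follicles$center_row[i])^2 +
      (fs$records$centroid_col - sc$follicles$center_col[i])^2
    j <- which.min(d2)
    expect_lt(abs(fs$records$diameter_mm[j] - sc$follicles$diameter_mm[i]),
              2 * sc$spacing_mm)
  }
})

test_that("shadow and contrast artifact options stay in range", {
  sc <- generate_phantom(3, size_px = 96, spacing_mm = 0.4, shadow = TRUE,
                         contrast = 0.7, seed = 901)
  expect_true(all(sc$image >= 0 & sc$image <= 1))
  expect_true(sc$shadow)
})

test_that("diameter draws span the antral and dominant ranges across seeds", {
  dd <- unlist(lapply(1:120, function(s)
    desk_phantom(9000 + s, n = 1 + s %% 8)$follicles$diameter_mm))
  expect_true(all(dd >= 2 & dd <= 28))
  expect_lt(min(dd), 3)
  expect_gt(max(dd), 15)
  expect_gt(mean(dd >= 2 & dd <= 10), 0.6)   # mostly antral
})

test_that("dataset generation writes a reproducible manifest", {
  dir <- file.path(tempdir(), "phantom_ds")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  man <- generate_dataset(10, dir, seed = 5, size_px = 96, spacing_mm = 0.4)
  expect_equal(nrow(man), 10)
  expect_equal(unname(table(man$split)[c("train", "val", "test")]),
               c(6L, 2L, 2L), ignore_attr = TRUE)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "dataset.json")))
  # regenerating from the manifest row reproduces the stored image exactly
  i <- 3
  sc <- generate_phantom(man$n_follicles[i], size_px = man$size_px[i],
                         spacing_mm = man$spacing_mm[i],
                         shadow = man$shadow[i], seed = man$seed[i])
  img_disk <- png::readPNG(file.path(dir, man$image[i]))
  expect_identical(round(img_disk * 255), round(sc$image * 255))
  msk_disk <- read_mask(file.path(dir, man$follicle_mask[i]))
  expect_identical(msk_disk, sc$follicle_mask)
  # loading pairs
  pairs <- load_dataset(dir, split = "train", target = "follicle")
  expect_length(pairs, 6)
  expect_true(is_binary_matrix <- all(pairs[[1]]$mask %in% c(0L, 1L)))
  expect_error(generate_dataset(2, dir, seed = 1), "per split")
  expect_error(generate_dataset(10, dir, split_fractions = c(0.5, 0.2)),
               "sum to 1")
})
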