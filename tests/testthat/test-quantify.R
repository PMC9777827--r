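test_that("component labelling: count, connectivity, empty mask", {
  m <- matrix(0L, 8, 8)
  expect_equal(max(label_components(m)), 0)
  expect_equal(nrow(extract_follicles(m, 0.1)$records), 0)
  # two diagonal-touching pixels: one component at 8-connectivity, two at 4
  m[2, 2] <- 1L; m[3, 3] <- 1L
  expect_equal(max(label_components(m, 8)), 1)
  expect_equal(max(label_components(m, 4)), 2)
})

test_that("moment-based diameter of a rasterized disk is accurate", {
  # radius 25 px at 0.1 mm/px: true diameter 5.0 mm
  fs <- extract_follicles(disk_mask(120, 60, 60, 25), 0.1)
  expect_equal(nrow(fs$records), 1)
  expect_equal(fs$records$diameter_mm, 5.0, tolerance = 0.1 / 5)  # 1 px spacing
  expect_equal(fs$records$major_axis_px, fs$records$minor_axis_px,
               tolerance = 0.02)
  # convergence: radius >= 10 px keeps the error within one pixel spacing
  for (R in c(10, 15, 40)) {
    fs <- extract_follicles(disk_mask(2 * R + 20, R + 10, R + 10, R), 0.1)
    expect_lt(abs(fs$records$diameter_mm - 2 * R * 0.1), 0.1)
  }
})

test_that("equivalent-ellipse axes agree with the EBImage moments oracle", {
  msk <- ovaquant:::ellipse_mask(128, 63.5, 63.5, 30, 20, 0.4)
  fs <- extract_follicles(matrix(as.integer(msk), 128), 0.1)
  ft <- EBImage::computeFeatures.moment(msk)
  expect_equal(fs$records$major_axis_px, unname(ft[1, "m.majoraxis"]),
               tolerance = 1e-6)
  minor_oracle <- ft[1, "m.majoraxis"] * sqrt(1 - ft[1, "m.eccentricity"]^2)
  expect_equal(fs$records$minor_axis_px, unname(minor_oracle),
               tolerance = 1e-6)
  # requested semi-axes (30, 20) px at 0.1 mm/px -> diameter 5.0 mm
  expect_equal(fs$records$diameter_mm, 5.0, tolerance = 0.1 / 5)
})

test_that("two separated disks give two records with distinct centroids", {
  m <- disk_mask(100, 25, 25, 10) + disk_mask(100, 70, 70, 12)
  fs <- extract_follicles(matrix(as.integer(m), 100), 0.2)
  expect_equal(nrow(fs$records), 2)
  expect_false(isTRUE(all.equal(fs$records$centroid_row[1],
                                fs$records$centroid_row[2])))
  expect_error(extract_follicles(m, 0), "positive")
})

test_that("recruitable filter keeps 2-10 mm and blanks excluded components", {
  m <- disk_mask(300, 60, 60, 25) +      # 5.0 mm at 0.1 mm/px -> kept
    disk_mask(300, 200, 200, 75) +       # 15.0 mm -> dominant, excluded
    disk_mask(300, 60, 230, 7)           # 1.4 mm -> too small, excluded
  fs <- extract_follicles(matrix(as.integer(m), 300), 0.1)
  expect_equal(nrow(fs$records), 3)
  filt <- recruitable_filter(fs)
  expect_equal(nrow(filt$records), 1)
  expect_equal(filt$records$diameter_mm, 5.0, tolerance = 0.1)
  # excluded components removed from the working label matrix
  expect_equal(sort(unique(as.integer(filt$labels))),
               c(0L, filt$records$label))
  expect_error(recruitable_filter(fs, low = 11, high = 10), "exceed")
})

test_that("matching is one-to-one, greedy, with a strict Dice threshold", {
  sp <- 0.1
  # identical masks with k components -> k perfect matches
  m <- disk_mask(200, 50, 50, 20) + disk_mask(200, 140, 140, 25)
  m <- matrix(as.integer(m), 200)
  a <- extract_follicles(m, sp); b <- extract_follicles(m, sp)
  mt <- match_follicles(a, b)
  expect_equal(nrow(mt), 2)
  expect_true(all(mt$dice == 1))
  expect_true(all(mt$correct))

  # overlap at exactly Dice = 0.5 is NOT counted (strict >)
  g <- matrix(0L, 20, 20); g[5:8, 5:10] <- 1L       # 24 px
  p <- matrix(0L, 20, 20); p[5:8, 8:13] <- 1L       # 24 px, overlap 12
  gf <- extract_follicles(g, 1); pf <- extract_follicles(p, 1)
  mt <- match_follicles(gf, pf)
  expect_equal(mt$dice, 0.5)
  expect_false(mt$correct)

  # one prediction straddling two gt components: one-to-one enforced
  g2 <- matrix(0L, 40, 40)
  g2[10:18, 10:18] <- 1L; g2[10:18, 24:32] <- 1L; g2[30:36, 10:16] <- 1L
  p2 <- matrix(0L, 40, 40)
  p2[10:18, 10:32] <- 1L                            # covers gt 1 and 2
  p2[30:36, 10:16] <- 1L                            # matches gt 3 exactly
  mt2 <- match_follicles(extract_follicles(g2, 1), extract_follicles(p2, 1))
  expect_lte(sum(mt2$correct), 2)
  expect_equal(length(unique(mt2$pred_label)), nrow(mt2))
  expect_equal(length(unique(mt2$gt_label)), nrow(mt2))
})

test_that("counting_report runs the full stage list with safe degenerate cases", {
  sc <- desk_phantom(7101, n = 5)
  rep <- counting_report(sc$follicle_mask, sc$follicle_mask, sc$spacing_mm)
  expect_equal(rep$n_real, rep$n_detected)
  expect_equal(rep$n_correct, rep$n_real)
  if (rep$n_real > 0) {
    expect_equal(rep$precision, 1)
    expect_equal(rep$recall, 1)
  }
  # empty prediction: recall 0, precision flagged 0
  e <- matrix(0L, 96, 96)
  rep2 <- counting_report(sc$follicle_mask, e, sc$spacing_mm)
  expect_equal(rep2$n_correct, 0)
  expect_equal(rep2$precision, 0)
  expect_equal(rep2$recall, 0)
  expect_true(rep2$flagged)
  expect_error(counting_report(sc$follicle_mask, matrix(0L, 10, 10), 0.4),
               "same shape")
})

test_that("counting is intensity-invariant: depends only on masks and spacing", {
  sc <- desk_phantom(7102, n = 6)
  r1 <- counting_report(sc$follicle_mask, sc$follicle_mask, sc$spacing_mm)
  # the image never enters: permuting it cannot change anything (structural
  # property of the API), and rescaling spacing rescales diameters
  r2 <- counting_report(sc$follicle_mask, sc$follicle_mask, sc$spacing_mm)
  expect_identical(r1$n_real, r2$n_real)
  fs1 <- extract_follicles(sc$follicle_mask, 0.4)
  fs2 <- extract_follicles(sc$follicle_mask, 0.8)
  expect_equal(fs2$records$diameter_mm, 2 * fs1$records$diameter_mm,
               tolerance = 1e-12)
})

test_that("printed-table counting arithmetic", {
  # 344 correct of 378 real -> recall 91.01%; 315 of 447 detected -> 70.47%
  expect_equal(round(counting_rates(344, 448, 378)$recall_pct, 2), 91.01)
  expect_equal(round(counting_rates(315, 447, 378)$precision_pct, 2), 70.47)
  expect_error(counting_rates(10, 5, 20))
})
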