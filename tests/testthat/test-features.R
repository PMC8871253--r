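test_that("the default manifest has 377 uniquely named features with the documented subtotals", {
  mf <- feature_manifest()
  expect_equal(nrow(mf), 377)
  expect_false(anyDuplicated(mf$feature) > 0)
  counts <- table(mf$family)
  expect_equal(unname(counts[c("histogram", "gradient", "cooccurrence",
    "runlength", "ar_model", "wavelet", "geometry")]),
    c(9, 5, 220, 20, 5, 20, 98), ignore_attr = TRUE)
  # published feature names appear verbatim
  for (nm in c("GeoF", "GeoSxL", "GeoW3", "GeoW5b", "GeoW12", "GeoEl",
    "S(1,0)DifEntrp", "S(1,-1)DifEntrp", "S(5,-5)DifEntrp",
    "Horzl_RLNonUni", "Vertl_RLNonUni", "45dgr_RLNonUni", "135dr_RLNonUni",
    "GrNonZeros", "WavEnLH_s-4")) {
    expect_true(nm %in% mf$feature, label = nm)
  }
  offs <- dplyr::distinct(dplyr::filter(mf, family == "cooccurrence"), dx, dy)
  expect_equal(nrow(offs), 20)
})

test_that("co-occurrence matrix matches the hand-worked example", {
  lv <- matrix(c(1L, 1L, 1L, 2L, 2L, 2L), 2, 3)
  # levels [[1,1,2],[1,2,2]] with offset (1,0): symmetric counts 2/4/2
  p <- glcm(lv, 1, 0, 2)
  expect_equal(p, matrix(c(0.25, 0.25, 0.25, 0.25), 2, 2))
  f <- glcm_features(p)
  expect_equal(unname(f["DifEntrp"]), log(2))
  # any random input sums to 1 and is symmetric
  set.seed(31)
  lv2 <- random_level_image(6, 6, 3)
  p2 <- glcm(lv2, 1, 1, 3)
  expect_equal(sum(p2), 1)
  expect_equal(p2, t(p2))
})

test_that("degenerate co-occurrence inputs behave as specified", {
  lv <- matrix(2L, 4, 4)
  p <- glcm(lv, 1, 0, 4)
  expect_equal(p[2, 2], 1)
  f <- glcm_features(p)
  expect_equal(unname(f["Entropy"]), 0)
  expect_equal(unname(f["DifEntrp"]), 0)
  expect_equal(unname(f["AngScMom"]), 1)
  # checkerboard: every horizontal pair differs by exactly one level
  cb <- matrix(rep_len(c(1L, 2L), 25), 5, 5)
  expect_equal(unname(glcm_features(glcm(cb, 1, 0, 2))["Contrast"]), 1)
  # offset larger than the image: no pairs
  expect_null(glcm(matrix(1L, 2, 2), 5, 0, 2))
})

test_that("run-length statistics match the hand-worked single-row example", {
  lv <- matrix(c(1L, 1L, 2L, 2L, 2L), 1, 5)
  f <- rlm_features(lv, "horizontal")
  expect_equal(unname(f["RLNonUni"]), 1)
  expect_equal(unname(f["GLevNonU"]), 1)
  expect_equal(unname(f["Fraction"]), 2 / 5)
  expect_equal(unname(f["LngREmph"]), (4 + 9) / 2)
  expect_equal(unname(f["ShrtREmp"]), (1 / 4 + 1 / 9) / 2)
  const <- matrix(3L, 1, 7)
  fc <- rlm_features(const, "horizontal")
  expect_equal(unname(fc["RLNonUni"]), 1)
  expect_equal(unname(fc["LngREmph"]), 49)
})

test_that("transposition swaps horizontal and vertical run-length features", {
  set.seed(32)
  lv <- random_level_image(10, 8, 3, mask_frac = 0.2)
  expect_equal(rlm_features(t(lv), "horizontal"), rlm_features(lv, "vertical"))
  expect_equal(rlm_features(t(lv), "vertical"), rlm_features(lv, "horizontal"))
  # 90-degree rotation exchanges the diagonal directions
  rot <- t(lv)[, nrow(lv):1]
  expect_equal(unname(rlm_features(rot, "d45")), unname(rlm_features(lv, "d135")))
})

test_that("histogram statistics follow the stated conventions", {
  lv <- matrix(c(1L, 2L, 3L, 4L), 2, 2)
  f <- histogram_features(lv)
  expect_equal(unname(f["Mean"]), 2.5)
  expect_equal(unname(f["Variance"]), 1.25) # population convention
  p50 <- histogram_features(matrix(c(1L, 1L, 2L, 2L), 2, 2))["Perc50"]
  expect_equal(unname(p50), 1) # nearest-rank
  fc <- histogram_features(matrix(5L, 3, 3))
  expect_equal(unname(fc["Variance"]), 0)
  expect_equal(unname(fc["Skewness"]), 0)
})

test_that("gradient features distinguish constant, ramp and noisy ROIs", {
  const <- matrix(4L, 6, 6)
  expect_equal(unname(gradient_features(const)["GrNonZeros"]), 0)
  ramp <- matrix(rep(1:8, each = 6), 6, 8)
  fr <- gradient_features(ramp)
  expect_equal(unname(fr["GrNonZeros"]), 1)
  expect_equal(unname(fr["GrVariance"]), 0)
  expect_equal(unname(fr["GrMean"]), 1)
  # too-small ROI: flagged missing
  expect_true(all(is.na(gradient_features(matrix(1L, 2, 2)))))
})

test_that("the causal AR fit recovers exact and null structures", {
  # each pixel equals its left neighbor exactly
  lv <- matrix(rep(c(3, 7, 5, 9, 4, 8), times = 8), 6, 8)
  f <- ar_features(lv)
  expect_equal(unname(f["Teta1"]), 1, tolerance = 1e-10)
  expect_equal(unname(f["Sigma"]), 0, tolerance = 1e-10)
  expect_true(all(abs(f[c("Teta2", "Teta3", "Teta4")]) < 1e-8))
  # white noise: all coefficients near zero (averaged over replicates)
  set.seed(33)
  thetas <- replicate(5, {
    lvn <- matrix(rnorm(2500), 50, 50)
    ar_features(lvn)[1:4]
  })
  expect_true(all(abs(rowMeans(thetas)) < 0.1))
  # insufficient support is flagged missing
  expect_true(all(is.na(ar_features(matrix(1, 3, 3)))))
})

test_that("AR least squares agrees with the normal-equation oracle", {
  set.seed(34)
  for (i in 1:10) {
    lv <- matrix(rnorm(400, 10, 3), 20, 20)
    f <- ar_features(lv)
    o <- oracle_ar(lv)
    expect_equal(unname(f[1:4]), o$theta, tolerance = 1e-8)
    expect_equal(unname(f["Sigma"]), o$sigma, tolerance = 1e-8)
  }
})

test_that("Haar energies respond to the expected orientations and scale quadratically", {
  mask <- matrix(TRUE, 16, 16)
  const <- matrix(5, 16, 16)
  fc <- wavelet_features(const, mask)
  expect_equal(unname(fc[c("WavEnLH_s-1", "WavEnHL_s-1", "WavEnHH_s-1")]),
    c(0, 0, 0))
  # horizontal stripes (variation down the rows) excite LH
  stripes <- matrix(rep(c(1, 3), times = 8), 16, 16)
  fs <- wavelet_features(stripes, mask)
  expect_gt(fs[["WavEnLH_s-1"]], 0)
  expect_equal(fs[["WavEnHL_s-1"]], 0)
  expect_equal(fs[["WavEnHH_s-1"]], 0)
  expect_equal(wavelet_features(2 * stripes, mask), 4 * fs)
})

test_that("masked Haar energies equal the closed-form block-sum oracle", {
  set.seed(35)
  for (i in 1:10) {
    lv <- matrix(rnorm(1024, 20, 5), 32, 32)
    mask <- matrix(TRUE, 32, 32)
    mask[sample.int(1024, 200)] <- FALSE
    lv[!mask] <- NA
    f <- wavelet_features(lv, mask)
    for (s in 1:3) {
      o <- oracle_haar_energy(lv, mask, s)
      if (is.null(o)) {
        expect_true(is.na(f[sprintf("WavEnLL_s-%d", s)]))
      } else {
        for (b in c("LL", "LH", "HL", "HH")) {
          expect_equal(f[[sprintf("WavEn%s_s-%d", b, s)]], o[[b]],
            tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("geometry descriptors match closed-form shapes", {
  sq <- matrix(FALSE, 20, 20); sq[5:14, 3:12] <- TRUE
  g <- geometry_features(sq)
  expect_equal(g[["GeoF"]], 100)
  expect_equal(g[["GeoEl"]], 1)
  expect_equal(g[["GeoPerim"]], 40)
  expect_equal(g[["GeoSxL"]], 100)
  expect_equal(g[["GeoExtent"]], 1)
  rect <- matrix(FALSE, 50, 20); rect[6:45, 4:13] <- TRUE # 40 x 10
  gr <- geometry_features(rect)
  expect_equal(gr[["GeoEl"]], 4) # continuous second moments of a rectangle
  expect_equal(gr[["GeoF"]], 400)
  # translation and 90-degree rotation invariance of area/elongation
  rect2 <- matrix(FALSE, 50, 20); rect2[2:41, 8:17] <- TRUE
  expect_equal(geometry_features(rect2)[["GeoEl"]], gr[["GeoEl"]])
  rot <- t(rect)[, nrow(rect):1]
  expect_equal(geometry_features(rot)[["GeoF"]], gr[["GeoF"]])
  expect_equal(geometry_features(rot)[["GeoEl"]], gr[["GeoEl"]],
    tolerance = 1e-10)
  expect_equal(length(g), 98)
})

test_that("feature vectors are complete, deterministic and normalization-invariant", {
  co <- small_cohort(n = 2, seed = 36, image_size = 64)
  v1 <- extract_all(co$image[[1]], co$roi[[1]])
  v2 <- extract_all(co$image[[1]], co$roi[[1]])
  expect_length(v1, 377)
  expect_identical(v1, v2)
  expect_identical(names(v1), feature_manifest()$feature)
  # affine gray-level change leaves quantized-level families unchanged
  v3 <- extract_all(co$image[[1]] * 2 + 50, co$roi[[1]])
  mf <- feature_manifest()
  lev_fams <- mf$feature[mf$family %in% c("cooccurrence", "runlength",
    "histogram", "gradient", "ar_model", "geometry")]
  expect_equal(v1[lev_fams], v3[lev_fams])
})

test_that("HTN cohorts show the published direction of effect", {
  co <- small_cohort(n = 20, seed = 37, image_size = 64)
  ft <- extract_features(co)
  is_htn <- ft$group == "HTN"
  for (f in c("Horzl_RLNonUni", "Vertl_RLNonUni", "45dgr_RLNonUni",
    "135dr_RLNonUni", "GeoF", "GeoEl")) {
    expect_gt(mean(ft[[f]][is_htn]), mean(ft[[f]][!is_htn]), label = f)
  }
  # noisy CT-like ROIs keep almost all gradients nonzero
  expect_true(all(ft$GrNonZeros > 0.9 & ft$GrNonZeros <= 1))
})
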