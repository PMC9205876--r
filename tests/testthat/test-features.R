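test_that("the registry enumerates the full inventory by class", {
  fr <- feature_registry()
  expect_equal(nrow(fr), 98L)
  counts <- table(fr$feature_class)
  expect_equal(unname(counts[c("shape", "firstorder", "glcm", "glrlm",
                               "glszm", "gldm", "ngtdm")]),
               table(factor(c(rep("a", 9), rep("b", 16), rep("c", 22),
                              rep("d", 16), rep("e", 16), rep("f", 14),
                              rep("g", 5)))) |> unname())
  expect_false(anyDuplicated(paste(fr$feature_class, fr$feature_name)) > 0)
})

test_that("first-order statistics match hand values on a tiny ROI", {
  vals <- matrix(c(1, 1, 1, 2, 2, 2, 3, 3, 3), 1)
  m <- toy_map(vals)
  k <- roi_mask(matrix(TRUE, 1, 9))
  d <- discretize_roi(m, k, 1)
  fo <- firstorder_features(m, k, d)
  get <- function(nm) fo$value[fo$feature_name == nm]
  expect_equal(get("Mean"), 2)
  expect_equal(get("Minimum"), 1)
  expect_equal(get("Maximum"), 3)
  expect_equal(get("Median"), 2)
  expect_equal(get("Energy"), sum(vals^2))
  expect_equal(get("RootMeanSquared"), sqrt(mean(vals^2)))
})

test_that("two equiprobable levels give Uniformity 1/2 and Entropy 1 bit", {
  vals <- matrix(c(rep(0.5, 5), rep(1.5, 5)), 1)
  m <- toy_map(vals)
  k <- roi_mask(matrix(TRUE, 1, 10))
  d <- discretize_roi(m, k, 1)
  fo <- firstorder_features(m, k, d)
  expect_equal(fo$value[fo$feature_name == "Uniformity"], 0.5)
  expect_equal(fo$value[fo$feature_name == "Entropy"], 1)
})

test_that("kurtosis is reported in Pearson form (excess + 3)", {
  set.seed(30)
  for (rep in 1:5) {
    x <- rnorm(60, 1000, 40)
    m <- toy_map(matrix(x, 1))
    k <- roi_mask(matrix(TRUE, 1, 60))
    fo <- firstorder_features(m, k, discretize_roi(m, k, 5))
    mu <- mean(x); m2 <- mean((x - mu)^2)
    excess <- mean((x - mu)^4) / m2^2 - 3
    expect_equal(fo$value[fo$feature_name == "Kurtosis"] - excess, 3,
                 tolerance = 1e-12)
  }
})

test_that("constant ROI flags moment ratios as undefined", {
  m <- toy_map(matrix(5, 3, 3))
  k <- roi_mask(matrix(TRUE, 3, 3))
  fo <- firstorder_features(m, k, discretize_roi(m, k, 1))
  expect_true(is.na(fo$value[fo$feature_name == "Skewness"]))
  expect_true(is.na(fo$value[fo$feature_name == "Kurtosis"]))
})

test_that("a solid square has the expected shape geometry", {
  k <- rect_mask(12, 12, 2, 11, 2, 11)   # 10x10 square
  sh <- shape_features(k, 1)
  get <- function(nm) sh$value[sh$feature_name == nm]
  expect_equal(get("PixelSurface"), 100)
  # marching squares at iso-level 0.5: 81 interior cells + 36 half cells +
  # 4 corner eighths; perimeter 4*9 + 4*sqrt(1/2)
  expect_equal(get("MeshSurface"), 99.5)
  expect_equal(get("Perimeter"), 36 + 4 * sqrt(0.5))
  expect_equal(get("Elongation"), 1)
  expect_lte(get("Sphericity"), 1.01)
})

test_that("elongation of a rectangle matches the eigen oracle", {
  k <- rect_mask(10, 10, 3, 5, 3, 6)   # 3 x 4 rectangle
  sh <- shape_features(k, 1.5)
  idx <- which(k$mask, arr.ind = TRUE) * 1.5
  ev <- sort(eigen(cov(idx))$values, decreasing = TRUE)
  expect_equal(sh$value[sh$feature_name == "Elongation"],
               sqrt(ev[2] / ev[1]), tolerance = 1e-12)
  expect_equal(sh$value[sh$feature_name == "MajorAxisLength"],
               4 * sqrt(ev[1]), tolerance = 1e-12)
})

test_that("shape features ignore map intensities", {
  co <- generate_cohort(small_cohort_spec(n_subjects = 2L, seed = 31L))
  sh1 <- shape_features(co$mask[[1]], co$spacing_mm[1])
  # same mask, unrelated intensities: identical shape rows by construction
  expect_identical(sh1, shape_features(co$mask[[1]], co$spacing_mm[1]))
  f1 <- extract_features(co$map[[1]], co$mask[[1]], 5)
  v2 <- co$map[[1]]$values * 3 + 100
  f2 <- extract_features(quant_map(v2, co$map[[1]]$spacing_mm,
                                   "T1", "x"), co$mask[[1]], 5)
  expect_equal(f1$value[f1$feature_class == "shape"],
               f2$value[f2$feature_class == "shape"])
})

test_that("sphericity approaches 1 for a disk", {
  n <- 41
  d2 <- outer((1:n - 21)^2, (1:n - 21)^2, "+")
  k <- roi_mask(d2 <= 15^2)
  sh <- shape_features(k, 1)
  sphericity <- sh$value[sh$feature_name == "Sphericity"]
  # the staircase contour of a digital disk keeps the mesh perimeter a few
  # percent above the ideal circle, so sphericity saturates below 1
  expect_gt(sphericity, 0.9)
  expect_lte(sphericity, 1.01)
})

test_that("texture features agree with naive formula evaluation", {
  set.seed(32)
  for (rep in 1:25) {
    lv <- random_droi()
    d <- make_droi(lv)
    np <- sum(!is.na(lv))
    # GLCM formulas on the implementation's own matrix
    M <- glcm_matrix(d, sample(c(0, 45, 90, 135), 1))
    if (!M$degenerate) {
      mine <- cmradiomics:::glcm_feature_values(M)
      ref <- naive_glcm_features(M$values)
      for (nm in names(ref)) {
        expect_equal(mine[[nm]], ref[[nm]], tolerance = 1e-9, label = nm)
      }
    }
    # run-length-style formulas
    R <- glrlm_matrix(d, 0)
    if (sum(R$values) > 0) {
      mine <- cmradiomics:::glrlm_feature_values(R, np)
      ref <- naive_rl_features(R$values, np)
      expect_equal(mine[["ShortRunEmphasis"]], ref$short_, tolerance = 1e-9)
      expect_equal(mine[["GrayLevelNonUniformity"]], ref$gln, tolerance = 1e-9)
      expect_equal(mine[["RunEntropy"]], ref$ent, tolerance = 1e-9)
      expect_equal(mine[["RunVariance"]], ref$sv, tolerance = 1e-9)
      expect_equal(mine[["LongRunLowGrayLevelEmphasis"]], ref$ll,
                   tolerance = 1e-9)
      expect_equal(mine[["RunPercentage"]], ref$pct, tolerance = 1e-9)
    }
    Z <- glszm_matrix(d)
    mineZ <- cmradiomics:::glszm_feature_values(Z, np)
    refZ <- naive_rl_features(Z$values, np)
    expect_equal(mineZ[["LargeAreaEmphasis"]], refZ$long_, tolerance = 1e-9)
    expect_equal(mineZ[["ZoneEntropy"]], refZ$ent, tolerance = 1e-9)
    expect_equal(mineZ[["SizeZoneNonUniformityNormalized"]], refZ$snn,
                 tolerance = 1e-9)
    G <- gldm_matrix(d)
    mineG <- cmradiomics:::gldm_feature_values(G)
    refG <- naive_rl_features(G$values, np)
    expect_equal(mineG[["DependenceEntropy"]], refG$ent, tolerance = 1e-9)
    expect_equal(mineG[["LargeDependenceHighGrayLevelEmphasis"]], refG$lh,
                 tolerance = 1e-9)
    expect_equal(mineG[["SmallDependenceEmphasis"]], refG$short_,
                 tolerance = 1e-9)
    N <- ngtdm_matrix(d)
    mineN <- cmradiomics:::ngtdm_feature_values(N)
    refN <- naive_ngtdm_features(N$values)
    for (nm in names(refN)) {
      expect_equal(mineN[[nm]], refN[[nm]], tolerance = 1e-9, label = nm)
    }
  }
})

test_that("a constant ROI degenerates the expected texture features", {
  m <- toy_map(matrix(7, 4, 4))
  k <- roi_mask(matrix(TRUE, 4, 4))
  f <- extract_features(m, k, 1)
  get <- function(cl, nm) f$value[f$feature_class == cl & f$feature_name == nm]
  expect_equal(get("glcm", "Contrast"), 0)
  expect_equal(get("glcm", "JointEnergy"), 1)
  expect_true(is.na(get("glcm", "Correlation")))
  expect_equal(get("ngtdm", "Contrast"), 0)
})

test_that("GLCM features average over the four directions", {
  set.seed(33)
  lv <- random_droi()
  d <- make_droi(lv)
  per_angle <- sapply(c(0, 45, 90, 135), function(a) {
    cmradiomics:::glcm_feature_values(glcm_matrix(d, a))[["Contrast"]]
  })
  tex <- texture_features(d)
  expect_equal(tex$value[tex$feature_class == "glcm" &
                           tex$feature_name == "Contrast"],
               mean(per_angle))
})

test_that("run percentage lies in (0, 1] for any ROI", {
  set.seed(34)
  for (rep in 1:10) {
    tex <- texture_features(make_droi(random_droi()))
    rp <- tex$value[tex$feature_class == "glrlm" &
                      tex$feature_name == "RunPercentage"]
    expect_gt(rp, 0)
    expect_lte(rp, 1)
  }
})

test_that("extraction yields 98 records unfiltered and 89 filtered", {
  co <- generate_cohort(small_cohort_spec(n_subjects = 2L, seed = 35L))
  f98 <- extract_features(co$map[[1]], co$mask[[1]], 5)
  expect_equal(nrow(f98), 98L)
  expect_identical(f98[c("feature_class", "feature_name")],
                   feature_registry())
  for (flt in c("gradient", "wavelet-HH", "square")) {
    f89 <- extract_features(co$map[[1]], co$mask[[1]], 5, filter = flt)
    expect_equal(nrow(f89), 89L)
    expect_false("shape" %in% f89$feature_class)
  }
})

test_that("extraction is deterministic", {
  co <- generate_cohort(small_cohort_spec(n_subjects = 2L, seed = 36L))
  a <- extract_at(co$map[[1]], co$mask[[1]], 2.1, 5)
  b <- extract_at(co$map[[1]], co$mask[[1]], 2.1, 5)
  expect_identical(a, b)
})
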