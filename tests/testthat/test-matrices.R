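test_that("GLCM matches hand-enumerated pairs on a 2x2 block", {
  d <- make_droi(matrix(c(1L, 2L, 1L, 2L), 2))   # rows: [1,1] / [2,2]
  M <- glcm_matrix(d, 0)
  expect_equal(M$values, matrix(c(0.5, 0, 0, 0.5), 2))
})

test_that("a constant ROI co-occurs only with itself", {
  d <- make_droi(matrix(1L, 3, 3))
  for (a in c(0, 45, 90, 135)) {
    M <- glcm_matrix(d, a)
    expect_equal(sum(M$values), 1)
    expect_equal(M$values[1, 1], 1)
  }
})

test_that("GLCM is symmetric and normalised for random ROIs", {
  set.seed(20)
  for (rep in 1:10) {
    d <- make_droi(random_droi())
    for (a in c(0, 45, 90, 135)) {
      M <- glcm_matrix(d, a)
      expect_equal(M$values, t(M$values))
      if (!M$degenerate) expect_equal(sum(M$values), 1)
    }
  }
})

test_that("an isolated-pair-free direction yields a degenerate GLCM", {
  lv <- matrix(NA_integer_, 3, 3)
  lv[1, 1] <- 1L; lv[3, 3] <- 2L   # no 0-degree neighbours
  M <- glcm_matrix(make_droi(lv), 0)
  expect_true(M$degenerate)
  expect_true(all(M$values == 0))
})

test_that("GLRLM reproduces hand-counted runs", {
  d <- make_droi(matrix(c(1L, 1L, 2L, 2L), 1))
  M <- glrlm_matrix(d, 0)
  expect_equal(M$values[1, 2], 1)   # level 1, length 2
  expect_equal(M$values[2, 2], 1)
  expect_equal(sum(M$values), 2)
})

test_that("a constant line is a single maximal run", {
  d <- make_droi(matrix(1L, 1, 6))
  M <- glrlm_matrix(d, 0)
  expect_equal(M$values[1, 6], 1)
  expect_equal(sum(M$values), 1)
})

test_that("runs partition the ROI pixels along every direction", {
  set.seed(21)
  for (rep in 1:10) {
    lv <- random_droi()
    np <- sum(!is.na(lv))
    for (a in c(0, 45, 90, 135)) {
      M <- glrlm_matrix(make_droi(lv), a)
      lens <- matrix(seq_len(ncol(M$values)), nrow(M$values),
                     ncol(M$values), byrow = TRUE)
      expect_equal(sum(M$values * lens), np)
    }
  }
})

test_that("GLSZM finds the hand-labelled zones", {
  d <- make_droi(matrix(c(1L, 2L, 1L, 3L), 2))   # [[1,1],[2,3]]
  M <- glszm_matrix(d)
  expect_equal(M$values[1, 2], 1)   # level 1: one zone of size 2
  expect_equal(M$values[2, 1], 1)
  expect_equal(M$values[3, 1], 1)
})

test_that("a constant ROI is one zone and diagonals join zones", {
  d <- make_droi(matrix(1L, 3, 4))
  expect_equal(glszm_matrix(d)$values[1, 12], 1)
  # two-level checkerboard: all same-level cells touch diagonally
  cb <- (outer(1:4, 1:4, "+") %% 2L) + 1L
  M <- glszm_matrix(make_droi(cb))
  oracle <- naive_glszm(cb)
  expect_equal(M$values, oracle)
})

test_that("GLDM dependence counts follow the 3x3 neighbour geometry", {
  d <- make_droi(matrix(1L, 3, 3))
  M <- gldm_matrix(d)
  # constant 3x3: corners have 3 equal neighbours, edges 5, centre 8
  expect_equal(M$values[1, 4], 4)
  expect_equal(M$values[1, 6], 4)
  expect_equal(M$values[1, 9], 1)
  # all-distinct levels: every pixel has dependence 0
  d2 <- make_droi(matrix(1:9, 3))
  expect_equal(sum(gldm_matrix(d2)$values[, 1]), 9)
})

test_that("NGTDM matches the hand computation on a 1x3 line", {
  d <- make_droi(matrix(c(1L, 2L, 1L), 1))
  M <- ngtdm_matrix(d)
  expect_equal(unname(M$values[2, "s"]), 1)   # |2 - mean(1,1)|
  expect_equal(unname(M$values[1, "s"]), 2)   # two end pixels each |1 - 2|
  expect_equal(sum(M$values[, "p"]), 1)
})

test_that("matrix mass is conserved for GLSZM and GLDM", {
  set.seed(22)
  for (rep in 1:10) {
    lv <- random_droi()
    np <- sum(!is.na(lv))
    Z <- glszm_matrix(make_droi(lv))
    sizes <- matrix(seq_len(ncol(Z$values)), nrow(Z$values),
                    ncol(Z$values), byrow = TRUE)
    expect_equal(sum(Z$values * sizes), np)
    expect_equal(sum(gldm_matrix(make_droi(lv))$values), np)
  }
})

test_that("rotating the ROI by 90 degrees permutes the directional matrices", {
  set.seed(23)
  for (rep in 1:5) {
    lv <- random_droi()
    rot <- t(lv[nrow(lv):1, , drop = FALSE])   # 90-degree rotation
    pairs <- list(c(0, 90), c(90, 0), c(45, 135), c(135, 45))
    for (p in pairs) {
      a <- glcm_matrix(make_droi(lv), p[1])$values
      b <- glcm_matrix(make_droi(rot), p[2])$values
      expect_equal(a, b)
    }
  }
})
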