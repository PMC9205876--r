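# Texture feature formulas for the five gray-level matrix families,
# evaluated over the sparse triplet form of each matrix (every formula is a
# weighted sum over nonzero entries plus marginal aggregates, so zero cells
# never need to be materialised). Conventions: log base 2 throughout;
# features whose defining formula divides by zero or takes log(0) on
# degenerate input return NA ("flagged undefined"), never a silent 0. GLCM
# and GLRLM features are computed per direction and then arithmetically
# averaged over the four 2D angles.

entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# weighted aggregation of w by integer key; returns (key, total) vectors
agg_by <- function(key, w) {
  a <- rowsum(w, key)
  list(key = as.numeric(rownames(a)), w = as.vector(a))
}

glcm_feature_values <- function(M) {
  if (M$degenerate) {
    return(stats::setNames(rep(NA_real_, 22L), glcm_feature_names()))
  }
  i <- M$df$i; j <- M$df$j; p <- M$df$w
  ng <- M$n_levels
  mx <- agg_by(i, p); my <- agg_by(j, p)   # marginals (present levels only)
  mux <- sum(mx$key * mx$w); muy <- sum(my$key * my$w)
  sigx <- sqrt(sum((mx$key - mux)^2 * mx$w))
  sigy <- sqrt(sum((my$key - muy)^2 * my$w))
  pd <- agg_by(abs(i - j), p)              # difference distribution
  ps <- agg_by(i + j, p)                   # sum distribution
  da <- sum(pd$key * pd$w)
  hxy <- entropy2(p)
  px_i <- mx$w[match(i, mx$key)]
  py_j <- my$w[match(j, my$key)]
  hxy1 <- -sum(p * log2(px_i * py_j))
  hx <- entropy2(mx$w); hy <- entropy2(my$w)
  hxy2 <- hx + hy   # entropy of the product distribution is additive
  corr <- if (sigx * sigy > 0) {
    (sum(p * i * j) - mux * muy) / (sigx * sigy)
  } else {
    NA_real_
  }
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else NA_real_
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  off <- i != j
  c(
    Autocorrelation = sum(p * i * j),
    ClusterProminence = sum(p * (i + j - mux - muy)^4),
    ClusterShade = sum(p * (i + j - mux - muy)^3),
    ClusterTendency = sum(p * (i + j - mux - muy)^2),
    Contrast = sum(p * (i - j)^2),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = entropy2(pd$w),
    DifferenceVariance = sum((pd$key - da)^2 * pd$w),
    Id = sum(p / (1 + abs(i - j))),
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + (i - j)^2 / ng^2)),
    Idn = sum(p / (1 + abs(i - j) / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(p[off] / (i - j)[off]^2),
    JointAverage = mux,
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MaximumProbability = max(p),
    SumEntropy = entropy2(ps$w),
    SumSquares = sum(p * (i - mux)^2)
  )
}

glcm_feature_names <- function() {
  fr <- feature_registry()
  fr$feature_name[fr$feature_class == "glcm"]
}

# shared structure for the run-length / size-zone / dependence families:
# triplets of counts indexed by gray level i and size/length/dependence j;
# np = ROI pixel count
rl_style_values <- function(df, np) {
  ns <- sum(df$w)
  if (ns == 0) return(NULL)
  i <- df$i; j <- df$j
  pn <- df$w / ns
  gi <- agg_by(i, df$w); gj <- agg_by(j, df$w)
  mu_i <- sum(pn * i); mu_j <- sum(pn * j)
  list(
    gln = sum(gi$w^2) / ns,
    glnn = sum(gi$w^2) / ns^2,
    glv = sum(pn * (i - mu_i)^2),
    high = sum(pn * i^2),
    low = sum(pn / i^2),
    long_ = sum(pn * j^2),
    short_ = sum(pn / j^2),
    lh = sum(pn * j^2 * i^2),
    ll = sum(pn * j^2 / i^2),
    sh = sum(pn * i^2 / j^2),
    sl = sum(pn / (i^2 * j^2)),
    sn = sum(gj$w^2) / ns,
    snn = sum(gj$w^2) / ns^2,
    sv = sum(pn * (j - mu_j)^2),
    ent = entropy2(pn),
    pct = ns / np
  )
}

glrlm_feature_values <- function(M, np) {
  v <- rl_style_values(M$df, np)
  nm <- c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
          "GrayLevelVariance", "HighGrayLevelRunEmphasis",
          "LongRunEmphasis", "LongRunHighGrayLevelEmphasis",
          "LongRunLowGrayLevelEmphasis", "LowGrayLevelRunEmphasis",
          "RunEntropy", "RunLengthNonUniformity",
          "RunLengthNonUniformityNormalized", "RunPercentage",
          "RunVariance", "ShortRunEmphasis",
          "ShortRunHighGrayLevelEmphasis", "ShortRunLowGrayLevelEmphasis")
  if (is.null(v)) return(stats::setNames(rep(NA_real_, 16L), nm))
  stats::setNames(
    c(v$gln, v$glnn, v$glv, v$high, v$long_, v$lh, v$ll, v$low, v$ent,
      v$sn, v$snn, v$pct, v$sv, v$short_, v$sh, v$sl),
    nm
  )
}

glszm_feature_values <- function(M, np) {
  v <- rl_style_values(M$df, np)
  nm <- c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
          "GrayLevelVariance", "HighGrayLevelZoneEmphasis",
          "LargeAreaEmphasis", "LargeAreaHighGrayLevelEmphasis",
          "LargeAreaLowGrayLevelEmphasis", "LowGrayLevelZoneEmphasis",
          "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
          "SmallAreaEmphasis", "SmallAreaHighGrayLevelEmphasis",
          "SmallAreaLowGrayLevelEmphasis", "ZoneEntropy",
          "ZonePercentage", "ZoneVariance")
  if (is.null(v)) return(stats::setNames(rep(NA_real_, 16L), nm))
  stats::setNames(
    c(v$gln, v$glnn, v$glv, v$high, v$long_, v$lh, v$ll, v$low,
      v$sn, v$snn, v$short_, v$sh, v$sl, v$ent, v$pct, v$sv),
    nm
  )
}

gldm_feature_values <- function(M) {
  v <- rl_style_values(M$df, sum(M$df$w))
  nm <- c("DependenceEntropy", "DependenceNonUniformity",
          "DependenceNonUniformityNormalized", "DependenceVariance",
          "GrayLevelNonUniformity", "GrayLevelVariance",
          "HighGrayLevelEmphasis", "LargeDependenceEmphasis",
          "LargeDependenceHighGrayLevelEmphasis",
          "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
          "SmallDependenceEmphasis",
          "SmallDependenceHighGrayLevelEmphasis",
          "SmallDependenceLowGrayLevelEmphasis")
  if (is.null(v)) return(stats::setNames(rep(NA_real_, 14L), nm))
  stats::setNames(
    c(v$ent, v$sn, v$snn, v$sv, v$gln, v$glv, v$high, v$long_, v$lh,
      v$ll, v$low, v$short_, v$sh, v$sl),
    nm
  )
}

ngtdm_feature_values <- function(M) {
  nm <- c("Busyness", "Coarseness", "Complexity", "Contrast", "Strength")
  if (M$degenerate) return(stats::setNames(rep(NA_real_, 5L), nm))
  iv <- M$df$i; p_i <- M$df$p; s_i <- M$df$s
  nvp <- sum(M$df$n)
  ngp <- length(iv)      # triplets hold present levels only
  ps <- sum(p_i * s_i)
  ii <- rep(seq_len(ngp), times = ngp)
  jj <- rep(seq_len(ngp), each = ngp)
  li <- iv[ii]; lj <- iv[jj]
  busy_den <- sum(abs(li * p_i[ii] - lj * p_i[jj]))
  contrast <- if (ngp > 1) {
    sum(p_i[ii] * p_i[jj] * (li - lj)^2) / (ngp * (ngp - 1)) *
      sum(s_i) / nvp
  } else {
    0
  }
  complexity <- sum(abs(li - lj) *
                      (p_i[ii] * s_i[ii] + p_i[jj] * s_i[jj]) /
                      (p_i[ii] + p_i[jj])) / nvp
  strength <- if (sum(s_i) > 0) {
    sum((p_i[ii] + p_i[jj]) * (li - lj)^2) / sum(s_i)
  } else {
    NA_real_
  }
  c(
    Busyness = if (busy_den > 0) ps / busy_den else NA_real_,
    Coarseness = if (ps > 0) 1 / ps else NA_real_,
    Complexity = complexity,
    Contrast = contrast,
    Strength = strength
  )
}

#' Texture features from a discretized ROI
#'
#' Builds all five gray-level matrix families from the discretized ROI and
#' evaluates the 73 texture features. GLCM and GLRLM features are computed
#' per direction (0, 45, 90, 135 degrees) and averaged over directions;
#' GLSZM, GLDM and NGTDM features come from their single matrix.
#'
#' @param d A [discretize_roi()] result.
#' @return A tibble with 73 rows (`feature_class`, `feature_name`, `value`).
#' @export
texture_features <- function(d) {
  np <- sum(!is.na(d$levels))
  angles <- c(0, 45, 90, 135)
  avg_over_angles <- function(per_angle) {
    m <- do.call(rbind, per_angle)
    out <- colMeans(m, na.rm = TRUE)
    out[is.nan(out)] <- NA_real_
    out
  }
  glcm_vals <- avg_over_angles(
    lapply(angles, function(a) glcm_feature_values(glcm_matrix(d, a)))
  )
  glrlm_vals <- avg_over_angles(
    lapply(angles, function(a) glrlm_feature_values(glrlm_matrix(d, a), np))
  )
  glszm_vals <- glszm_feature_values(glszm_matrix(d), np)
  gldm_vals <- gldm_feature_values(gldm_matrix(d))
  ngtdm_vals <- ngtdm_feature_values(ngtdm_matrix(d))
  tibble::tibble(
    feature_class = rep(c("glcm", "glrlm", "glszm", "gldm", "ngtdm"),
                        times = c(22L, 16L, 16L, 14L, 5L)),
    feature_name = c(names(glcm_vals), names(glrlm_vals),
                     names(glszm_vals), names(gldm_vals),
                     names(ngtdm_vals)),
    value = unname(c(glcm_vals, glrlm_vals, glszm_vals, gldm_vals,
                     ngtdm_vals))
  )
}

#' Extract the full feature inventory at one preprocessing coordinate
#'
#' Applies the spatial filter, discretizes the (filtered) ROI intensities
#' with the given fixed bin width, and evaluates the feature registry:
#' 98 features for the unfiltered map, 89 (shape dropped) for filtered maps.
#' First-order statistics are computed on the continuous filtered values;
#' Entropy/Uniformity and all texture features use the discretized levels.
#'
#' @param map A [quant_map()] (already resampled if desired; see
#'   [extract_at()]).
#' @param mask A [roi_mask()] congruent with `map`.
#' @param bin_width_ms Fixed bin width (ms) for discretization.
#' @param filter One of [filter_names()]; default `"original"`.
#' @param anchor Discretization anchoring rule, see [discretize_roi()].
#' @return A tibble with columns `feature_class`, `feature_name`, `value`
#'   in registry order.
#' @export
extract_features <- function(map, mask, bin_width_ms, filter = "original",
                             anchor = "multiples") {
  check_congruent(map, mask)
  fmap <- apply_filter(map, filter)
  d <- discretize_roi(fmap, mask, bin_width_ms, anchor)
  parts <- list()
  if (filter == "original") {
    parts$shape <- shape_features(mask, map$spacing_mm)
  }
  parts$fo <- firstorder_features(fmap, mask, d)
  parts$tex <- texture_features(d)
  dplyr::bind_rows(parts)
}

#' Resample, filter, discretize and extract in one call
#'
#' The full per-coordinate pipeline: B-spline resampling to the target
#' isotropic voxel size, spatial filtering, fixed-bin-width discretization
#' and feature extraction, with the coordinate recorded on every row.
#'
#' @inheritParams extract_features
#' @param voxel_size_mm Target isotropic spacing (mm).
#' @return A tibble with columns `subject_id`, `modality`, `voxel_size_mm`,
#'   `bin_width_ms`, `filter`, `feature_class`, `feature_name`, `value`.
#' @export
extract_at <- function(map, mask, voxel_size_mm, bin_width_ms,
                       filter = "original", anchor = "multiples") {
  rs <- resample_map(map, mask, voxel_size_mm)
  feats <- extract_features(rs$map, rs$mask, bin_width_ms, filter, anchor)
  tibble::tibble(
    subject_id = map$subject_id,
    modality = map$modality,
    voxel_size_mm = voxel_size_mm,
    bin_width_ms = bin_width_ms,
    filter = filter,
    feats
  )
}
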