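#' The closed 98-feature radiomic registry
#'
#' Enumerates, in a stable order, the full 2D feature inventory: 9 shape
#' features, 16 first-order features (14 intensity-based statistics plus the
#' two intensity-histogram features Entropy and Uniformity), and 73 texture
#' features from the five gray-level matrix families (22 GLCM, 16 GLRLM,
#' 16 GLSZM, 14 GLDM, 5 NGTDM). Filtered-map extraction drops the shape
#' class, leaving 89 features.
#'
#' @return A tibble with columns `feature_class` and `feature_name`.
#' @export
feature_registry <- function() {
  shape <- c("Elongation", "MajorAxisLength", "MaximumDiameter",
             "MeshSurface", "MinorAxisLength", "Perimeter",
             "PerimeterSurfaceRatio", "PixelSurface", "Sphericity")
  firstorder <- c("Mean", "Variance", "Skewness", "Kurtosis", "Median",
                  "Minimum", "10Percentile", "90Percentile", "Maximum",
                  "InterquartileRange", "MeanAbsoluteDeviation",
                  "RobustMeanAbsoluteDeviation", "Energy",
                  "RootMeanSquared", "Entropy", "Uniformity")
  glcm <- c("Autocorrelation", "ClusterProminence", "ClusterShade",
            "ClusterTendency", "Contrast", "Correlation",
            "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
            "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2", "InverseVariance",
            "JointAverage", "JointEnergy", "JointEntropy",
            "MaximumProbability", "SumEntropy", "SumSquares")
  glrlm <- c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
             "GrayLevelVariance", "HighGrayLevelRunEmphasis",
             "LongRunEmphasis", "LongRunHighGrayLevelEmphasis",
             "LongRunLowGrayLevelEmphasis", "LowGrayLevelRunEmphasis",
             "RunEntropy", "RunLengthNonUniformity",
             "RunLengthNonUniformityNormalized", "RunPercentage",
             "RunVariance", "ShortRunEmphasis",
             "ShortRunHighGrayLevelEmphasis", "ShortRunLowGrayLevelEmphasis")
  glszm <- c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
             "GrayLevelVariance", "HighGrayLevelZoneEmphasis",
             "LargeAreaEmphasis", "LargeAreaHighGrayLevelEmphasis",
             "LargeAreaLowGrayLevelEmphasis", "LowGrayLevelZoneEmphasis",
             "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
             "SmallAreaEmphasis", "SmallAreaHighGrayLevelEmphasis",
             "SmallAreaLowGrayLevelEmphasis", "ZoneEntropy",
             "ZonePercentage", "ZoneVariance")
  gldm <- c("DependenceEntropy", "DependenceNonUniformity",
            "DependenceNonUniformityNormalized", "DependenceVariance",
            "GrayLevelNonUniformity", "GrayLevelVariance",
            "HighGrayLevelEmphasis", "LargeDependenceEmphasis",
            "LargeDependenceHighGrayLevelEmphasis",
            "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
            "SmallDependenceEmphasis",
            "SmallDependenceHighGrayLevelEmphasis",
            "SmallDependenceLowGrayLevelEmphasis")
  ngtdm <- c("Busyness", "Coarseness", "Complexity", "Contrast", "Strength")
  tibble::tibble(
    feature_class = rep(c("shape", "firstorder", "glcm", "glrlm", "glszm",
                          "gldm", "ngtdm"),
                        times = c(length(shape), length(firstorder),
                                  length(glcm), length(glrlm),
                                  length(glszm), length(gldm),
                                  length(ngtdm))),
    feature_name = c(shape, firstorder, glcm, glrlm, glszm, gldm, ngtdm)
  )
}
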