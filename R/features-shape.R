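# 2D shape features. Mesh-based surface and perimeter come from a marching-
# squares contour of the binary mask at iso-level 0.5 (crossings at edge
# midpoints for a binary image); the saddle configurations keep diagonal
# corners separated. Axis features come from the eigendecomposition of the
# physical pixel-centre coordinate covariance (denominator n - 1).

# Per-configuration boundary segments and inside area on the unit square.
# Corners: a=(0,0) b=(0,1) c=(1,0) d=(1,1) in (row, col); config bit order
# a + 2b + 4c + 8d. Edge midpoints: t=(0,.5) bo=(1,.5) l=(.5,0) r=(.5,1).
marching_square_table <- function() {
  t_ <- c(0, .5); bo <- c(1, .5); l <- c(.5, 0); r <- c(.5, 1)
  seg <- function(p, q) list(rbind(p, q))
  list(
    `0` = list(segs = list(), area = 0),
    `1` = list(segs = seg(t_, l), area = 1 / 8),
    `2` = list(segs = seg(t_, r), area = 1 / 8),
    `3` = list(segs = seg(l, r), area = 1 / 2),
    `4` = list(segs = seg(l, bo), area = 1 / 8),
    `5` = list(segs = seg(t_, bo), area = 1 / 2),
    `6` = list(segs = c(seg(t_, r), seg(l, bo)), area = 1 / 4),
    `7` = list(segs = seg(r, bo), area = 7 / 8),
    `8` = list(segs = seg(r, bo), area = 1 / 8),
    `9` = list(segs = c(seg(t_, l), seg(r, bo)), area = 1 / 4),
    `10` = list(segs = seg(t_, bo), area = 1 / 2),
    `11` = list(segs = seg(l, bo), area = 7 / 8),
    `12` = list(segs = seg(l, r), area = 1 / 2),
    `13` = list(segs = seg(t_, r), area = 7 / 8),
    `14` = list(segs = seg(t_, l), area = 7 / 8),
    `15` = list(segs = list(), area = 1)
  )
}

# marching squares over the zero-padded mask; returns physical perimeter,
# mesh area, and the contour vertex coordinates (mm)
mask_mesh <- function(mask, spacing) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  tab <- marching_square_table()
  n <- nrow(m); p <- ncol(m)
  cfg <- m[-n, -p] + 2L * m[-n, -1] + 4L * m[-1, -p] + 8L * m[-1, -1]
  sr <- spacing[1]; sc <- spacing[2]
  area <- 0; perim <- 0
  verts <- list()
  hit <- which(cfg > 0, arr.ind = TRUE)
  for (k in seq_len(nrow(hit))) {
    i <- hit[k, 1]; j <- hit[k, 2]
    entry <- tab[[cfg[i, j] + 1L]]
    area <- area + entry$area
    for (s in entry$segs) {
      pts <- cbind((s[, 1] + i - 1) * sr, (s[, 2] + j - 1) * sc)
      perim <- perim + sqrt(sum((pts[1, ] - pts[2, ])^2))
      verts[[length(verts) + 1L]] <- pts
    }
  }
  list(area = area * sr * sc, perimeter = perim,
       vertices = unique(do.call(rbind, c(verts, list(matrix(0, 0, 2))))))
}

#' 2D shape features of a ROI mask
#'
#' Shape features depend only on the mask and the pixel spacing, never on
#' the map intensities, and are therefore invariant to discretization and
#' intensity filtering.
#'
#' @param mask A [roi_mask()].
#' @param spacing_mm Pixel spacing (single number or `c(row, col)`, mm).
#' @return A tibble with 9 rows (`feature_class = "shape"`).
#' @export
shape_features <- function(mask, spacing_mm) {
  spacing <- as.numeric(spacing_mm)
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  m <- mask$mask
  mesh <- mask_mesh(m, spacing)
  idx <- which(m, arr.ind = TRUE)
  coords <- cbind((idx[, 1] - 1) * spacing[1], (idx[, 2] - 1) * spacing[2])
  if (nrow(coords) >= 2L) {
    ev <- sort(eigen(stats::cov(coords), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
    major <- 4 * sqrt(ev[1])
    minor <- 4 * sqrt(ev[2])
    elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else NA_real_
  } else {
    major <- minor <- elong <- NA_real_
  }
  v <- mesh$vertices
  max_diam <- if (nrow(v) >= 2L) {
    hull <- grDevices::chull(v[, 2], v[, 1])
    hv <- v[hull, , drop = FALSE]
    sqrt(max(as.numeric(stats::dist(hv))^2))
  } else {
    NA_real_
  }
  pixel_surface <- mask$pixel_count * spacing[1] * spacing[2]
  vals <- c(
    Elongation = elong,
    MajorAxisLength = major,
    MaximumDiameter = max_diam,
    MeshSurface = mesh$area,
    MinorAxisLength = minor,
    Perimeter = mesh$perimeter,
    PerimeterSurfaceRatio = mesh$perimeter / mesh$area,
    PixelSurface = pixel_surface,
    Sphericity = 2 * sqrt(pi * mesh$area) / mesh$perimeter
  )
  tibble::tibble(feature_class = "shape",
                 feature_name = names(vals),
                 value = unname(vals))
}
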