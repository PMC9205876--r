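# Gray-level matrix builders. All operate on a `discretized_roi` (integer
# levels, NA outside the ROI) with the Chebyshev-1 neighbourhood and, for the
# directional families, the four 2D angles. Empty gray levels (1..N_g with no
# pixels) are retained in the indexing so fixed-bin-width semantics survive.
#
# The canonical representation is a sparse triplet table (i, j, w): literal
# per-pixel filters (notably `square`) can push N_g into the tens of
# thousands, where a dense N_g x N_g array is not representable while the
# nonzero entries remain few. A dense `values` matrix is materialised
# alongside whenever it is small enough to be useful.

DENSE_LIMIT <- 2^22  # max cells for materialising the dense form

gl_matrix <- function(kind, df, n_levels, n_cols, angle = NA,
                      distance = 1L) {
  n_levels <- as.integer(n_levels)
  dense <- NULL
  if (as.double(n_levels) * n_cols <= DENSE_LIMIT) {
    dense <- matrix(0, n_levels, n_cols)
    if (nrow(df) > 0) dense[cbind(df$i, df$j)] <- df$w
  }
  structure(
    list(kind = kind, df = df, values = dense, n_levels = n_levels,
         n_cols = as.integer(n_cols), angle = angle, distance = distance,
         degenerate = nrow(df) == 0L || sum(df$w) == 0),
    class = "gl_matrix"
  )
}

#' @export
print.gl_matrix <- function(x, ...) {
  cat(sprintf("<gl_matrix> %s%s: %d levels x %d, %d nonzero, total %g\n",
              x$kind,
              if (!is.na(x$angle)) paste0(" @", x$angle, "°") else "",
              x$n_levels, x$n_cols, nrow(x$df), sum(x$df$w)))
  invisible(x)
}

# aggregate parallel (i, j) keys into triplets; weights default to 1
triplets <- function(i, j, w = rep(1, length(i))) {
  if (length(i) == 0L) {
    return(tibble::tibble(i = integer(0), j = integer(0), w = numeric(0)))
  }
  key <- as.double(i) + (as.double(j) - 1) * 2^26   # exact in doubles
  agg <- rowsum(w, key)
  keys <- as.double(rownames(agg))
  jj <- floor((keys - 1) / 2^26) + 1
  tibble::tibble(i = as.integer(keys - (jj - 1) * 2^26), j = as.integer(jj),
                 w = as.vector(agg))
}

# (row, col) offset for an image-plane angle; delta = 1
angle_offset <- function(angle) {
  switch(as.character(angle),
         "0" = c(0L, 1L), "45" = c(-1L, 1L), "90" = c(-1L, 0L),
         "135" = c(-1L, -1L),
         stop("angle must be one of 0, 45, 90, 135", call. = FALSE))
}

shift_matrix <- function(m, dr, dc) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(NA_integer_, n, p)
  rs <- seq_len(n) + dr; cs <- seq_len(p) + dc
  ok_r <- rs >= 1 & rs <= n; ok_c <- cs >= 1 & cs <= p
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c], drop = FALSE]
  out
}

#' Gray level co-occurrence matrix (GLCM)
#'
#' Symmetric co-occurrence of gray levels over in-ROI pixel pairs at
#' Chebyshev distance 1 along one of the four 2D directions, normalised to a
#' probability distribution. If the ROI admits no pixel pair along the
#' direction, an all-zero matrix flagged degenerate is returned.
#'
#' @param d A [discretize_roi()] result.
#' @param angle One of 0, 45, 90, 135 (degrees).
#' @return A `gl_matrix` of kind `"GLCM"` (probabilities summing to 1).
#' @export
glcm_matrix <- function(d, angle) {
  off <- angle_offset(angle)
  a <- d$levels
  b <- shift_matrix(a, off[1], off[2])
  ok <- !is.na(a) & !is.na(b)
  # count each ordered pair along +offset, then add the transpose
  df <- triplets(c(a[ok], b[ok]), c(b[ok], a[ok]))
  df$w <- df$w / sum(df$w)
  gl_matrix("GLCM", df, d$n_levels, d$n_levels, angle)
}

# split the level matrix into scan lines along a direction; NA breaks runs
direction_lines <- function(levels, angle) {
  ri <- row(levels); ci <- col(levels)
  key <- switch(as.character(angle),
                "0" = ri,                 # along rows
                "90" = ci,                # along columns
                "45" = ri + ci,           # anti-diagonals, step (-1,+1)
                "135" = ri - ci)          # diagonals, step (-1,-1)
  ord <- switch(as.character(angle),
                "0" = order(ri, ci), "90" = order(ci, ri),
                "45" = order(ri + ci, ci), "135" = order(ri - ci, ci))
  split(levels[ord], key[ord])
}

#' Gray level run length matrix (GLRLM)
#'
#' Counts maximal collinear runs of equal gray level along one direction,
#' restricted to ROI pixels (out-of-ROI pixels break runs).
#'
#' @inheritParams glcm_matrix
#' @return A `gl_matrix` of kind `"GLRLM"` with counts indexed by
#'   gray level x run length.
#' @export
glrlm_matrix <- function(d, angle) {
  lv <- c(); ln <- c()
  for (line in direction_lines(d$levels, angle)) {
    r <- rle(line)
    keep <- !is.na(r$values)
    lv <- c(lv, r$values[keep])
    ln <- c(ln, r$lengths[keep])
  }
  gl_matrix("GLRLM", triplets(lv, ln), d$n_levels, max(dim(d$levels)),
            angle)
}

# BFS over 8-connected components among the given pixel coordinates;
# neighbours outside [1, nrow] x [1, ncol] are discarded before keying so a
# row-0 neighbour cannot alias the last row of the previous column
connected_zone_sizes <- function(coords, nrow_total, ncol_total) {
  if (nrow(coords) == 0L) return(integer(0))
  key <- coords[, 1] + (coords[, 2] - 1L) * nrow_total
  present <- new.env(hash = TRUE, size = length(key))
  for (i in seq_along(key)) assign(as.character(key[i]), i, envir = present)
  visited <- logical(length(key))
  sizes <- integer(0)
  offs <- cbind(rep(-1:1, 3), rep(-1:1, each = 3))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), , drop = FALSE]
  for (start in seq_along(key)) {
    if (visited[start]) next
    queue <- start; head <- 1L; visited[start] <- TRUE
    while (head <= length(queue)) {
      cur <- queue[[head]]; head <- head + 1L
      rr <- coords[cur, 1] + offs[, 1]
      cc <- coords[cur, 2] + offs[, 2]
      ok <- rr >= 1L & rr <= nrow_total & cc >= 1L & cc <= ncol_total
      for (k in as.character(rr[ok] + (cc[ok] - 1L) * nrow_total)) {
        j <- get0(k, envir = present, ifnotfound = NULL)
        if (!is.null(j) && !visited[j]) {
          visited[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
    sizes <- c(sizes, length(queue))
  }
  sizes
}

#' Gray level size zone matrix (GLSZM)
#'
#' A zone is a maximal 8-connected region of equal gray level within the
#' ROI; the matrix counts zones by (gray level, zone size). Zone sizes
#' account for every ROI pixel exactly once.
#'
#' @inheritParams glcm_matrix
#' @return A `gl_matrix` of kind `"GLSZM"`.
#' @export
glszm_matrix <- function(d) {
  roi <- !is.na(d$levels)
  by_level <- split(which(roi), d$levels[roi])
  lv <- c(); sz <- c()
  nr <- nrow(d$levels)
  for (lev_chr in names(by_level)) {
    idx <- by_level[[lev_chr]]
    coords <- cbind(((idx - 1L) %% nr) + 1L, ((idx - 1L) %/% nr) + 1L)
    sizes <- connected_zone_sizes(coords, nr, ncol(d$levels))
    lv <- c(lv, rep(as.integer(lev_chr), length(sizes)))
    sz <- c(sz, sizes)
  }
  gl_matrix("GLSZM", triplets(lv, sz), d$n_levels, max(sz, 1L))
}

# per-pixel count of in-ROI Chebyshev-1 neighbours with equal level
equal_neighbour_counts <- function(levels) {
  cnt <- matrix(0L, nrow(levels), ncol(levels))
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nb <- shift_matrix(levels, dr, dc)
      cnt <- cnt + (!is.na(levels) & !is.na(nb) & levels == nb)
    }
  }
  cnt
}

#' Gray level dependence matrix (GLDM), alpha = 0
#'
#' For each ROI pixel the dependence is the number of Chebyshev-distance-1
#' in-ROI neighbours whose level equals the centre level (coarseness
#' parameter alpha = 0); the matrix counts pixels by
#' (gray level, dependence + 1), so its entries sum to the ROI pixel count.
#'
#' @inheritParams glcm_matrix
#' @return A `gl_matrix` of kind `"GLDM"`.
#' @export
gldm_matrix <- function(d) {
  dep <- equal_neighbour_counts(d$levels)
  ok <- !is.na(d$levels)
  gl_matrix("GLDM", triplets(d$levels[ok], dep[ok] + 1L), d$n_levels, 9L)
}

#' Neighbourhood gray tone difference matrix (NGTDM)
#'
#' Per gray level i: the pixel count n_i, probability p_i, and
#' s_i = sum over pixels of level i of |i - mean of its in-ROI
#' Chebyshev-1 neighbours| (the centre pixel excluded from the mean).
#' Pixels without any in-ROI neighbour are excluded from the counts.
#' Levels absent from the ROI carry p_i = 0 and s_i = 0.
#'
#' @inheritParams glcm_matrix
#' @return A `gl_matrix` of kind `"NGTDM"` whose triplet table holds, per
#'   present gray level `i`, `j = 1` and columns `n`, `p`, `s`; the dense
#'   `values` form has one row per gray level with those three columns.
#' @export
ngtdm_matrix <- function(d) {
  ng <- d$n_levels
  lv <- d$levels
  nb_sum <- matrix(0, nrow(lv), ncol(lv))
  nb_n <- matrix(0L, nrow(lv), ncol(lv))
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nb <- shift_matrix(lv, dr, dc)
      ok <- !is.na(nb)
      nb_sum[ok] <- nb_sum[ok] + nb[ok]
      nb_n <- nb_n + ok
    }
  }
  ok <- !is.na(lv) & nb_n > 0
  lev <- lv[ok]
  diffs <- abs(lev - nb_sum[ok] / nb_n[ok])
  n_agg <- rowsum(rep(1, length(lev)), lev)
  s_agg <- rowsum(diffs, lev)
  nvp <- sum(n_agg)
  df <- tibble::tibble(
    i = as.integer(rownames(n_agg)), j = 1L,
    n = as.vector(n_agg), p = as.vector(n_agg) / nvp,
    s = as.vector(s_agg), w = as.vector(n_agg)
  )
  out <- structure(
    list(kind = "NGTDM", df = df, values = NULL, n_levels = as.integer(ng),
         n_cols = 3L, angle = NA, distance = 1L,
         degenerate = nvp == 0),
    class = "gl_matrix"
  )
  if (ng <= DENSE_LIMIT / 4) {
    vals <- matrix(0, ng, 3, dimnames = list(NULL, c("n", "p", "s")))
    vals[df$i, "n"] <- df$n
    vals[df$i, "p"] <- df$p
    vals[df$i, "s"] <- df$s
    out$values <- vals
  }
  out
}
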