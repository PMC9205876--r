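# Independent brute-force oracles, deliberately written in naive scalar-loop
# style so they share no code path with the package implementation.

oracle_offset <- function(angle) {
  switch(as.character(angle),
         "0" = c(0L, 1L), "45" = c(-1L, 1L), "90" = c(-1L, 0L),
         "135" = c(-1L, -1L))
}

in_grid <- function(r, c, lv) r >= 1 && r <= nrow(lv) && c >= 1 && c <= ncol(lv)

naive_glcm <- function(lv, angle, ng = max(lv, na.rm = TRUE)) {
  off <- oracle_offset(angle)
  cnt <- matrix(0, ng, ng)
  for (r in seq_len(nrow(lv))) {
    for (c in seq_len(ncol(lv))) {
      if (is.na(lv[r, c])) next
      for (s in c(1L, -1L)) {
        rr <- r + s * off[1]; cc <- c + s * off[2]
        if (in_grid(rr, cc, lv) && !is.na(lv[rr, cc])) {
          cnt[lv[r, c], lv[rr, cc]] <- cnt[lv[r, c], lv[rr, cc]] + 1
        }
      }
    }
  }
  if (sum(cnt) > 0) cnt / sum(cnt) else cnt
}

naive_glrlm <- function(lv, angle, ng = max(lv, na.rm = TRUE)) {
  off <- oracle_offset(angle)
  cnt <- matrix(0, ng, max(dim(lv)))
  for (r in seq_len(nrow(lv))) {
    for (c in seq_len(ncol(lv))) {
      if (is.na(lv[r, c])) next
      pr <- r - off[1]; pc <- c - off[2]
      if (in_grid(pr, pc, lv) && !is.na(lv[pr, pc]) &&
          lv[pr, pc] == lv[r, c]) next  # not a run start
      len <- 1L
      rr <- r + off[1]; cc <- c + off[2]
      while (in_grid(rr, cc, lv) && !is.na(lv[rr, cc]) &&
             lv[rr, cc] == lv[r, c]) {
        len <- len + 1L
        rr <- rr + off[1]; cc <- cc + off[2]
      }
      cnt[lv[r, c], len] <- cnt[lv[r, c], len] + 1
    }
  }
  cnt
}

naive_glszm <- function(lv, ng = max(lv, na.rm = TRUE)) {
  seen <- matrix(FALSE, nrow(lv), ncol(lv))
  zones <- list()
  for (r in seq_len(nrow(lv))) {
    for (c in seq_len(ncol(lv))) {
      if (is.na(lv[r, c]) || seen[r, c]) next
      stack <- list(c(r, c)); seen[r, c] <- TRUE; size <- 0L
      while (length(stack) > 0L) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        size <- size + 1L
        for (dr in -1:1) for (dc in -1:1) {
          rr <- p[1] + dr; cc <- p[2] + dc
          if ((dr != 0 || dc != 0) && in_grid(rr, cc, lv) &&
              !is.na(lv[rr, cc]) && !seen[rr, cc] &&
              lv[rr, cc] == lv[r, c]) {
            seen[rr, cc] <- TRUE
            stack[[length(stack) + 1L]] <- c(rr, cc)
          }
        }
      }
      zones[[length(zones) + 1L]] <- c(lv[r, c], size)
    }
  }
  max_sz <- max(vapply(zones, `[`, integer(1), 2))
  cnt <- matrix(0, ng, max_sz)
  for (z in zones) cnt[z[1], z[2]] <- cnt[z[1], z[2]] + 1
  cnt
}

naive_gldm <- function(lv, ng = max(lv, na.rm = TRUE)) {
  deps <- c()
  levs <- c()
  for (r in seq_len(nrow(lv))) {
    for (c in seq_len(ncol(lv))) {
      if (is.na(lv[r, c])) next
      dep <- 0L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if ((dr != 0 || dc != 0) && in_grid(rr, cc, lv) &&
            !is.na(lv[rr, cc]) && lv[rr, cc] == lv[r, c]) {
          dep <- dep + 1L
        }
      }
      deps <- c(deps, dep); levs <- c(levs, lv[r, c])
    }
  }
  cnt <- matrix(0, ng, max(deps) + 1L)
  for (i in seq_along(deps)) {
    cnt[levs[i], deps[i] + 1L] <- cnt[levs[i], deps[i] + 1L] + 1
  }
  cnt
}

naive_ngtdm <- function(lv, ng = max(lv, na.rm = TRUE)) {
  n_i <- rep(0, ng); s_i <- rep(0, ng)
  for (r in seq_len(nrow(lv))) {
    for (c in seq_len(ncol(lv))) {
      if (is.na(lv[r, c])) next
      nb <- c()
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if ((dr != 0 || dc != 0) && in_grid(rr, cc, lv) &&
            !is.na(lv[rr, cc])) {
          nb <- c(nb, lv[rr, cc])
        }
      }
      if (length(nb) == 0L) next
      n_i[lv[r, c]] <- n_i[lv[r, c]] + 1
      s_i[lv[r, c]] <- s_i[lv[r, c]] + abs(lv[r, c] - mean(nb))
    }
  }
  cbind(n = n_i, p = if (sum(n_i) > 0) n_i / sum(n_i) else n_i, s = s_i)
}

# naive GLCM feature formulas: plain double loops over the probability matrix
naive_glcm_features <- function(P) {
  ng <- nrow(P)
  px <- sapply(1:ng, function(i) sum(P[i, ]))
  py <- sapply(1:ng, function(j) sum(P[, j]))
  mux <- sum((1:ng) * px); muy <- sum((1:ng) * py)
  sx <- sqrt(sum((1:ng - mux)^2 * px)); sy <- sqrt(sum((1:ng - muy)^2 * py))
  acc <- function(f) {
    tot <- 0
    for (i in 1:ng) for (j in 1:ng) tot <- tot + f(i, j, P[i, j])
    tot
  }
  pd <- sapply(0:(ng - 1), function(k) acc(function(i, j, p) if (abs(i - j) == k) p else 0))
  ps <- sapply(2:(2 * ng), function(k) acc(function(i, j, p) if (i + j == k) p else 0))
  ent <- function(v) { v <- v[v > 0]; -sum(v * log2(v)) }
  da <- sum((0:(ng - 1)) * pd)
  hxy <- acc(function(i, j, p) if (p > 0) -p * log2(p) else 0)
  hxy1 <- acc(function(i, j, p) if (p > 0 && px[i] * py[j] > 0) -p * log2(px[i] * py[j]) else 0)
  hxy2 <- ent(as.vector(outer(px, py)))
  hx <- ent(px); hy <- ent(py)
  list(
    Autocorrelation = acc(function(i, j, p) p * i * j),
    ClusterProminence = acc(function(i, j, p) p * (i + j - mux - muy)^4),
    ClusterShade = acc(function(i, j, p) p * (i + j - mux - muy)^3),
    ClusterTendency = acc(function(i, j, p) p * (i + j - mux - muy)^2),
    Contrast = acc(function(i, j, p) p * (i - j)^2),
    Correlation = if (sx * sy > 0) (acc(function(i, j, p) p * i * j) - mux * muy) / (sx * sy) else NA_real_,
    DifferenceAverage = da,
    DifferenceEntropy = ent(pd),
    DifferenceVariance = sum((0:(ng - 1) - da)^2 * pd),
    Id = acc(function(i, j, p) p / (1 + abs(i - j))),
    Idm = acc(function(i, j, p) p / (1 + (i - j)^2)),
    Idmn = acc(function(i, j, p) p / (1 + (i - j)^2 / ng^2)),
    Idn = acc(function(i, j, p) p / (1 + abs(i - j) / ng)),
    Imc1 = if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else NA_real_,
    Imc2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy)))),
    InverseVariance = acc(function(i, j, p) if (i != j) p / (i - j)^2 else 0),
    JointAverage = mux,
    JointEnergy = acc(function(i, j, p) p^2),
    JointEntropy = hxy,
    MaximumProbability = max(P),
    SumEntropy = ent(ps),
    SumSquares = acc(function(i, j, p) p * (i - mux)^2)
  )
}

# naive run-length-style feature formulas (GLRLM / GLSZM / GLDM share them)
naive_rl_features <- function(P, np) {
  ns <- sum(P)
  ng <- nrow(P); L <- ncol(P)
  acc <- function(f) {
    tot <- 0
    for (i in 1:ng) for (j in 1:L) tot <- tot + f(i, j, P[i, j] / ns)
    tot
  }
  mu_i <- acc(function(i, j, p) p * i); mu_j <- acc(function(i, j, p) p * j)
  list(
    gln = sum(sapply(1:ng, function(i) sum(P[i, ]))^2) / ns,
    glnn = sum(sapply(1:ng, function(i) sum(P[i, ]))^2) / ns^2,
    glv = acc(function(i, j, p) p * (i - mu_i)^2),
    high = acc(function(i, j, p) p * i^2),
    low = acc(function(i, j, p) p / i^2),
    long_ = acc(function(i, j, p) p * j^2),
    short_ = acc(function(i, j, p) p / j^2),
    lh = acc(function(i, j, p) p * i^2 * j^2),
    ll = acc(function(i, j, p) p * j^2 / i^2),
    sh = acc(function(i, j, p) p * i^2 / j^2),
    sl = acc(function(i, j, p) p / (i^2 * j^2)),
    sn = sum(sapply(1:L, function(j) sum(P[, j]))^2) / ns,
    snn = sum(sapply(1:L, function(j) sum(P[, j]))^2) / ns^2,
    sv = acc(function(i, j, p) p * (j - mu_j)^2),
    ent = { pn <- P / ns; pn <- pn[pn > 0]; -sum(pn * log2(pn)) },
    pct = ns / np
  )
}

naive_ngtdm_features <- function(tab, nvp = sum(tab[, "n"])) {
  p <- tab[, "p"]; s <- tab[, "s"]
  act <- which(p > 0); ngp <- length(act)
  ps <- sum(p * s)
  busy_den <- 0; contrast_num <- 0; complexity <- 0; strength_num <- 0
  for (i in act) for (j in act) {
    busy_den <- busy_den + abs(i * p[i] - j * p[j])
    contrast_num <- contrast_num + p[i] * p[j] * (i - j)^2
    complexity <- complexity + abs(i - j) * (p[i] * s[i] + p[j] * s[j]) / (p[i] + p[j])
    strength_num <- strength_num + (p[i] + p[j]) * (i - j)^2
  }
  list(
    Busyness = if (busy_den > 0) ps / busy_den else NA_real_,
    Coarseness = if (ps > 0) 1 / ps else NA_real_,
    Complexity = complexity / nvp,
    Contrast = if (ngp > 1) contrast_num / (ngp * (ngp - 1)) * sum(s) / nvp else 0,
    Strength = if (sum(s) > 0) strength_num / sum(s) else NA_real_
  )
}

# Eq.-1 ICC via stats::aov sums of squares (independent of the package's
# row/column-mean decomposition)
oracle_icc <- function(X) {
  n <- nrow(X); k <- ncol(X)
  df <- data.frame(y = as.vector(X),
                   r = factor(rep(seq_len(n), k)),
                   c = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ r + c, data = df))[[1]]
  msr <- tab["r", "Mean Sq"]; msc <- tab["c", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# rmcorr via explicit normal equations on a subject-dummy + slope design
oracle_rmcorr <- function(subject, x, y) {
  subject <- factor(subject)
  D <- stats::model.matrix(~ 0 + subject)
  Xf <- cbind(D, x)
  bf <- solve(t(Xf) %*% Xf, t(Xf) %*% y)
  rss_full <- sum((y - Xf %*% bf)^2)
  br <- solve(t(D) %*% D, t(D) %*% y)
  rss_red <- sum((y - D %*% br)^2)
  ss_x <- rss_red - rss_full
  slope <- bf[length(bf)]
  sign(slope) * sqrt(ss_x / (ss_x + rss_full))
}

# construct a discretized_roi directly from an integer level matrix
# (NA outside the ROI)
make_droi <- function(levels, spacing = c(1, 1)) {
  structure(
    list(levels = levels, n_levels = as.integer(max(levels, na.rm = TRUE)),
         bin_width_ms = 1, anchor = "multiples", spacing_mm = spacing),
    class = "discretized_roi"
  )
}

# random small discretized ROI for property tests
random_droi <- function(max_dim = 12L, max_ng = 6L) {
  nr <- sample(3:max_dim, 1); nc <- sample(3:max_dim, 1)
  ng <- sample(2:max_ng, 1)
  lv <- matrix(sample(seq_len(ng), nr * nc, replace = TRUE), nr, nc)
  roi <- matrix(stats::runif(nr * nc) < 0.8, nr, nc)
  while (sum(roi) < 2) roi <- matrix(stats::runif(nr * nc) < 0.8, nr, nc)
  lv[!roi] <- NA_integer_
  # re-index levels so the max level is attained
  lv[!is.na(lv)] <- as.integer(factor(lv[!is.na(lv)]))
  lv
}
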