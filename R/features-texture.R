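# Texture feature families. Each family function takes a quantized level
# matrix (NA outside the ROI mask) and returns a named numeric vector whose
# names match the default manifest. Undefined features are returned as NA
# ("missing") and handled by the screening stage.

#' Gray-level co-occurrence matrix for one offset
#'
#' Counts pairs of gray levels at displacement `(dx, dy)` (x = column,
#' y = row pointing up), accumulated symmetrically (each pair contributes in
#' both directions) and normalized to sum 1. Pairs with either pixel outside
#' the mask are discarded.
#'
#' @param levels Integer matrix of gray levels in `1..n_levels`, `NA`
#'   outside the ROI.
#' @param dx,dy Offset in columns / rows (y up).
#' @param n_levels Number of gray levels.
#' @return `n_levels x n_levels` probability matrix, or `NULL` when the
#'   offset yields no valid pair.
#' @export
glcm <- function(levels, dx, dy, n_levels = max(levels, na.rm = TRUE)) {
  nr <- nrow(levels)
  nc <- ncol(levels)
  r1 <- max(1L, 1L + dy)
  r2 <- min(nr, nr + dy)
  c1 <- max(1L, 1L - dx)
  c2 <- min(nc, nc - dx)
  if (r1 > r2 || c1 > c2) return(NULL)
  a <- levels[r1:r2, c1:c2, drop = FALSE]
  b <- levels[(r1:r2) - dy, (c1:c2) + dx, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NULL)
  a <- a[ok]
  b <- b[ok]
  counts <- tabulate((a - 1L) * n_levels + b, nbins = n_levels^2) +
    tabulate((b - 1L) * n_levels + a, nbins = n_levels^2)
  p <- matrix(counts, n_levels, n_levels, byrow = TRUE)
  p / sum(p)
}

#' Haralick statistics of a co-occurrence matrix
#'
#' Computes the 11 co-occurrence statistics of the default manifest
#' (angular second moment, contrast, correlation, sum of squares, inverse
#' difference moment, sum average/variance/entropy, entropy, difference
#' variance/entropy). Natural logarithms; `0 * log 0 = 0`. Correlation is
#' defined as 0 when either marginal SD is 0.
#'
#' @param p Normalized co-occurrence probability matrix (or `NULL`).
#' @return Named numeric vector of length 11 (all `NA` for `NULL` input).
#' @export
glcm_features <- function(p) {
  out <- setNames(rep(NA_real_, length(glcm_stat_names)), glcm_stat_names)
  if (is.null(p)) return(out)
  ng <- nrow(p)
  i <- row(p)
  j <- col(p)
  px <- rowSums(p)
  lev <- seq_len(ng)
  mu_x <- sum(lev * px)
  s_x <- sqrt(sum((lev - mu_x)^2 * px))
  psum <- tapply(as.vector(p), as.vector(i + j), sum)           # k = 2..2Ng
  pdiff <- tapply(as.vector(p), as.vector(abs(i - j)), sum)     # k = 0..Ng-1
  ksum <- as.numeric(names(psum))
  kdiff <- as.numeric(names(pdiff))
  ent <- function(q) -sum(q[q > 0] * log(q[q > 0]))
  sum_avg <- sum(ksum * psum)
  mu_d <- sum(kdiff * pdiff)

  out["AngScMom"] <- sum(p^2)
  out["Contrast"] <- sum((i - j)^2 * p)
  out["Correlat"] <- if (s_x > 0) (sum(i * j * p) - mu_x^2) / s_x^2 else 0
  out["SumOfSqs"] <- sum((i - mu_x)^2 * p)
  out["InvDfMom"] <- sum(p / (1 + (i - j)^2))
  out["SumAverg"] <- sum_avg
  out["SumVarnc"] <- sum((ksum - sum_avg)^2 * psum)
  out["SumEntrp"] <- ent(psum)
  out["Entropy"] <- ent(p)
  out["DifVarnc"] <- sum((kdiff - mu_d)^2 * pdiff)
  out["DifEntrp"] <- ent(pdiff)
  out
}

# Decompose a vector (with NA breaks) into maximal constant runs.
runs_in_line <- function(v) {
  v[is.na(v)] <- -1L
  r <- rle(v)
  keep <- r$values != -1L
  list(level = r$values[keep], length = r$lengths[keep])
}

# All lines of a level matrix along a run direction. Runs are truncated at
# the mask boundary (NA entries split lines).
direction_lines <- function(levels, direction) {
  switch(direction,
    horizontal = lapply(seq_len(nrow(levels)), function(r) levels[r, ]),
    vertical = lapply(seq_len(ncol(levels)), function(c) levels[, c]),
    # column-major order within each (anti)diagonal gives ascending column:
    # i + j constant -> up-right (45 degrees); i - j constant -> down-right.
    d45 = split(levels, row(levels) + col(levels)),
    d135 = split(levels, row(levels) - col(levels)),
    abort("unknown run direction", class = "cardiotex_parameter_error")
  )
}

#' Run-length statistics for one direction
#'
#' Decomposes the ROI into maximal constant-gray-level runs along the given
#' direction (runs truncated at the mask boundary) and computes short-run
#' emphasis, long-run emphasis, gray-level non-uniformity, run-length
#' non-uniformity and fraction (runs per ROI pixel).
#'
#' @inheritParams glcm
#' @param direction One of `"horizontal"`, `"vertical"`, `"d45"`, `"d135"`.
#' @return Named numeric vector of length 5.
#' @export
rlm_features <- function(levels, direction) {
  if (all(is.na(levels))) abort("empty mask", class = "cardiotex_parameter_error")
  runs <- purrr::map(direction_lines(levels, direction), runs_in_line)
  g <- unlist(purrr::map(runs, "level"))
  l <- unlist(purrr::map(runs, "length"))
  n_runs <- length(l)
  n_pix <- sum(!is.na(levels))
  c(
    ShrtREmp = sum(1 / l^2) / n_runs,
    LngREmph = sum(l^2) / n_runs,
    GLevNonU = sum(tabulate(g)^2) / n_runs,
    RLNonUni = sum(tabulate(l)^2) / n_runs,
    Fraction = n_runs / n_pix
  )
}

#' Histogram statistics of the quantized ROI
#'
#' Mean, population variance, skewness, excess kurtosis (both defined as 0
#' for constant input) and nearest-rank percentiles (1, 10, 50, 90, 99) of
#' the gray levels inside the ROI.
#'
#' @inheritParams glcm
#' @return Named numeric vector of length 9.
#' @export
histogram_features <- function(levels) {
  v <- levels[!is.na(levels)]
  if (length(v) == 0) abort("empty mask", class = "cardiotex_parameter_error")
  ms <- moment_stats(v)
  pc <- nearest_rank(v, c(0.01, 0.1, 0.5, 0.9, 0.99))
  c(
    Mean = unname(ms["mean"]), Variance = unname(ms["variance"]),
    Skewness = unname(ms["skewness"]), Kurtosis = unname(ms["kurtosis"]),
    Perc01 = pc[1], Perc10 = pc[2], Perc50 = pc[3], Perc90 = pc[4],
    Perc99 = pc[5]
  )
}

#' Gradient statistics of the quantized ROI
#'
#' Central-difference gradient magnitude on interior pixels (all four
#' 4-neighbors inside the mask): mean, population variance, skewness,
#' excess kurtosis, and the fraction of interior pixels with nonzero
#' gradient. All `NA` when the ROI has no interior pixel.
#'
#' @inheritParams glcm
#' @return Named numeric vector of length 5.
#' @export
gradient_features <- function(levels) {
  nr <- nrow(levels)
  nc <- ncol(levels)
  out <- c(GrMean = NA_real_, GrVariance = NA_real_, GrSkewness = NA_real_,
    GrKurtosis = NA_real_, GrNonZeros = NA_real_)
  if (nr < 3 || nc < 3) return(out)
  core <- levels[2:(nr - 1), 2:(nc - 1), drop = FALSE]
  left <- levels[2:(nr - 1), 1:(nc - 2), drop = FALSE]
  right <- levels[2:(nr - 1), 3:nc, drop = FALSE]
  up <- levels[1:(nr - 2), 2:(nc - 1), drop = FALSE]
  down <- levels[3:nr, 2:(nc - 1), drop = FALSE]
  ok <- !is.na(core) & !is.na(left) & !is.na(right) & !is.na(up) & !is.na(down)
  if (!any(ok)) return(out)
  gx <- (right[ok] - left[ok]) / 2
  gy <- (down[ok] - up[ok]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ms <- moment_stats(mag)
  c(GrMean = unname(ms["mean"]), GrVariance = unname(ms["variance"]),
    GrSkewness = unname(ms["skewness"]), GrKurtosis = unname(ms["kurtosis"]),
    GrNonZeros = mean(mag > 0))
}

#' First-order causal autoregressive model of the ROI
#'
#' Least-squares fit of each (mean-centered) pixel on its four causal
#' neighbors: left, upper-left, upper, upper-right. Only pixels with all
#' four neighbors inside the mask enter the fit; fewer than `min_support`
#' such pixels yields `NA` ("missing"). Aliased (collinear) coefficients are
#' reported as 0. `Sigma` is the residual standard deviation.
#'
#' @inheritParams glcm
#' @param min_support Minimum number of usable pixels (default 20).
#' @return Named numeric vector `Teta1..Teta4`, `Sigma`.
#' @export
ar_features <- function(levels, min_support = 20) {
  nr <- nrow(levels)
  nc <- ncol(levels)
  out <- setNames(rep(NA_real_, 5), c(paste0("Teta", 1:4), "Sigma"))
  if (nr < 2 || nc < 3) return(out)
  core <- levels[2:nr, 2:(nc - 1), drop = FALSE]
  lf <- levels[2:nr, 1:(nc - 2), drop = FALSE]
  ul <- levels[1:(nr - 1), 1:(nc - 2), drop = FALSE]
  up <- levels[1:(nr - 1), 2:(nc - 1), drop = FALSE]
  ur <- levels[1:(nr - 1), 3:nc, drop = FALSE]
  ok <- !is.na(core) & !is.na(lf) & !is.na(ul) & !is.na(up) & !is.na(ur)
  if (sum(ok) < min_support) return(out)
  mu <- mean(levels, na.rm = TRUE)
  y <- core[ok] - mu
  x <- cbind(lf[ok], ul[ok], up[ok], ur[ok]) - mu
  fit <- lm.fit(x, y)
  theta <- fit$coefficients
  theta[is.na(theta)] <- 0
  out[1:4] <- theta
  out["Sigma"] <- sqrt(mean(fit$residuals^2))
  out
}

# One orthonormal 2x2 Haar analysis step. Subband letters: first = filter
# along x (columns), second = along y (rows); LH therefore responds to
# variation down the rows (horizontal stripes).
haar_step <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  if (nr %% 2L == 1L) m <- rbind(m, m[nr, ])
  if (nc %% 2L == 1L) m <- cbind(m, m[, nc])
  ro <- seq(1, nrow(m), by = 2)
  co <- seq(1, ncol(m), by = 2)
  p <- m[ro, co, drop = FALSE]       # top-left
  q <- m[ro, co + 1, drop = FALSE]   # top-right
  r <- m[ro + 1, co, drop = FALSE]   # bottom-left
  s <- m[ro + 1, co + 1, drop = FALSE]
  list(
    LL = (p + q + r + s) / 2, LH = (p + q - r - s) / 2,
    HL = (p - q + r - s) / 2, HH = (p - q - r + s) / 2
  )
}

haar_support_step <- function(supp) {
  nr <- nrow(supp)
  nc <- ncol(supp)
  if (nr %% 2L == 1L) supp <- rbind(supp, FALSE)
  if (nc %% 2L == 1L) supp <- cbind(supp, FALSE)
  ro <- seq(1, nrow(supp), by = 2)
  co <- seq(1, ncol(supp), by = 2)
  supp[ro, co, drop = FALSE] & supp[ro, co + 1, drop = FALSE] &
    supp[ro + 1, co, drop = FALSE] & supp[ro + 1, co + 1, drop = FALSE]
}

#' Haar wavelet subband energies
#'
#' Iterated orthonormal Haar decomposition of the ROI bounding box (values
#' outside the mask filled with the ROI mean). At each scale the energy of
#' a subband is the mean squared coefficient over coefficients whose full
#' dyadic support lies inside the mask; scales with no fully supported
#' coefficient (or a bounding box smaller than `2^scale`) are `NA`.
#'
#' @inheritParams glcm
#' @param mask Logical ROI mask matching `levels`.
#' @param n_scales Number of dyadic scales (default 5).
#' @return Named numeric vector `WavEn<Sub>_s-<scale>` of length
#'   `4 * n_scales`.
#' @export
wavelet_features <- function(levels, mask, n_scales = 5) {
  nm <- as.vector(vapply(seq_len(n_scales), function(s) {
    sprintf("WavEn%s_s-%d", c("LL", "LH", "HL", "HH"), s)
  }, character(4)))
  out <- setNames(rep(NA_real_, length(nm)), nm)
  if (!any(mask)) return(out)
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  cur <- levels[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  supp <- mask[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  cur[is.na(cur)] <- mean(levels, na.rm = TRUE)
  for (s in seq_len(n_scales)) {
    if (min(dim(cur)) < 2) break
    bands <- haar_step(cur)
    supp <- haar_support_step(supp)
    if (any(supp)) {
      for (b in c("LL", "LH", "HL", "HH")) {
        out[sprintf("WavEn%s_s-%d", b, s)] <- mean(bands[[b]][supp]^2)
      }
    }
    cur <- bands$LL
  }
  out
}
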