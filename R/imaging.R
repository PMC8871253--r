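#' Rasterize a polygonal ROI to a pixel mask
#'
#' A pixel belongs to the mask when its center lies inside the polygon under
#' the even-odd rule. Pixel `(row r, col c)` (1-based matrix indices) has its
#' center at continuous coordinates `(x, y) = (c - 0.5, r - 0.5)` in the
#' 0-based vertex coordinate system (x = column, y = row), i.e. centers sit
#' at `i + 0.5` on each axis. The polygon is closed implicitly.
#'
#' @param roi Two-column matrix of vertices (`x`, `y`), at least 3 rows.
#' @param shape Integer vector `c(rows, cols)` of the target image.
#' @return Logical matrix of dimension `shape`.
#' @examples
#' sq <- cbind(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10))
#' sum(rasterize(sq, c(20, 20))) # 100
#' @export
rasterize <- function(roi, shape) {
  roi <- as.matrix(roi)
  if (nrow(roi) < 3) {
    abort("polygon needs at least 3 vertices", class = "cardiotex_geometry_error")
  }
  px <- roi[, 1]
  py <- roi[, 2]
  # Shoelace area; degenerate polygons carry no pixels.
  area2 <- abs(sum(px * c(py[-1], py[1]) - c(px[-1], px[1]) * py))
  if (area2 < .Machine$double.eps) {
    abort("degenerate polygon with zero area", class = "cardiotex_geometry_error")
  }
  nr <- shape[1]
  nc <- shape[2]
  mask <- matrix(FALSE, nr, nc)
  qx <- c(px[-1], px[1])
  qy <- c(py[-1], py[1])
  centers_x <- seq_len(nc) - 0.5
  for (r in seq_len(nr)) {
    y0 <- r - 0.5
    crosses <- (py > y0) != (qy > y0)
    if (!any(crosses)) next
    xint <- px[crosses] +
      (y0 - py[crosses]) * (qx[crosses] - px[crosses]) / (qy[crosses] - py[crosses])
    # Even-odd: inside iff an odd number of edge crossings lies left of the center.
    mask[r, ] <- (findInterval(centers_x, sort(xint)) %% 2L) == 1L
  }
  if (!any(mask)) {
    abort("polygon encloses no pixel centers", class = "cardiotex_geometry_error")
  }
  mask
}

#' Gray-level normalization within mean +/- 3 SD
#'
#' Computes the mean `mu` and standard deviation `sigma` of the pixel values
#' inside the mask, clips values to `[mu - 3 sigma, mu + 3 sigma]`, and maps
#' them linearly onto integer gray levels `1..n_levels`:
#' `level = 1 + floor((clip(v) - (mu - 3 sigma)) / (6 sigma) * n_levels)`,
#' with the upper edge closed (`v = mu + 3 sigma` maps to `n_levels`). This
#' removes brightness/contrast variation before texture quantification.
#' A constant ROI (`sigma = 0`) maps every pixel to the middle level with a
#' warning.
#'
#' @param image Numeric matrix of pixel values.
#' @param mask Logical matrix of the same dimension; must select >= 1 pixel.
#' @param n_levels Number of quantized gray levels (>= 2); 64 is the default
#'   used for co-occurrence/run-length analysis, 256 for histogram/gradient.
#' @return An object of class `normalized_roi`: list with `levels` (integer
#'   matrix, `NA` outside the mask), `mask`, `n_levels`, `mu`, `sigma`.
#' @export
normalize_mu3sigma <- function(image, mask, n_levels = 64) {
  if (!any(mask)) abort("empty mask", class = "cardiotex_parameter_error")
  if (n_levels < 2) abort("n_levels must be >= 2", class = "cardiotex_parameter_error")
  n_levels <- as.integer(n_levels)
  v <- image[mask]
  mu <- mean(v)
  sigma <- sd(v)
  lev <- matrix(NA_integer_, nrow(image), ncol(image))
  if (is.na(sigma) || sigma == 0) {
    warn("constant ROI: all pixels mapped to the middle gray level")
    lev[mask] <- as.integer(ceiling(n_levels / 2))
  } else {
    lo <- mu - 3 * sigma
    clipped <- pmin(pmax(v, lo), mu + 3 * sigma)
    q <- 1L + as.integer(floor((clipped - lo) / (6 * sigma) * n_levels))
    lev[mask] <- pmin(q, n_levels)
  }
  structure(
    list(levels = lev, mask = mask, n_levels = as.integer(n_levels),
      mu = mu, sigma = sigma),
    class = "normalized_roi"
  )
}

#' @export
print.normalized_roi <- function(x, ...) {
  cat("<normalized_roi>", sum(x$mask), "pixels,", x$n_levels,
    "levels, mu =", round(x$mu, 2), ", sigma =", round(x$sigma, 2), "\n")
  invisible(x)
}
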