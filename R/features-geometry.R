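# Shape descriptors of the binary ROI mask (intensity-independent). The
# family reproduces the naming scheme of the published feature list (GeoF,
# GeoEl, GeoSxL, GeoW*, ...); descriptors without a public definition are
# documented reconstructions (see the methods vignette).

#' Geometry descriptors of a binary mask
#'
#' 98 shape features of the ROI mask: area (`GeoF`), crack-length perimeter,
#' bounding-box descriptors (`GeoSxL` = width x height), second-moment
#' elongation (`GeoEl`, major/minor axis ratio >= 1, pixel-extent
#' corrected), orientation, compactness, Feret diameters at 15-degree steps
#' (`GeoW1..GeoW12`, perimeter-normalized `b` variants), convex-hull
#' descriptors, normalized central moments and Hu invariants, radial
#' (centroid-to-boundary) signature statistics and Fourier descriptors, and
#' projection-profile statistics.
#'
#' @param mask Logical matrix; must contain at least one `TRUE` pixel.
#' @return Named numeric vector of length 98.
#' @examples
#' m <- matrix(FALSE, 20, 20); m[5:14, 5:14] <- TRUE
#' geometry_features(m)[c("GeoF", "GeoEl")] # 100, 1
#' @export
geometry_features <- function(mask) {
  if (!any(mask)) abort("empty mask", class = "cardiotex_parameter_error")
  out <- setNames(rep(NA_real_, 98), geometry_feature_names())
  area <- sum(mask)
  rc <- which(mask, arr.ind = TRUE)
  x <- rc[, 2] - 0.5 # pixel centers, x = column
  y <- rc[, 1] - 0.5

  # Crack-length perimeter: exposed unit edges of the pixel set.
  nr <- nrow(mask)
  nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  nb_up <- pad[1:nr, 2:(nc + 1)]
  nb_dn <- pad[3:(nr + 2), 2:(nc + 1)]
  nb_lf <- pad[2:(nr + 1), 1:nc]
  nb_rt <- pad[2:(nr + 1), 3:(nc + 2)]
  exposed <- core & !(nb_up & nb_dn & nb_lf & nb_rt)
  perim <- sum(core & !nb_up) + sum(core & !nb_dn) +
    sum(core & !nb_lf) + sum(core & !nb_rt)

  bb_w <- diff(range(x)) + 1
  bb_h <- diff(range(y)) + 1

  # Central moments (pixel-extent corrected second moments for the axes).
  cx <- mean(x)
  cy <- mean(y)
  dx <- x - cx
  dy <- y - cy
  mu <- function(p, q) sum(dx^p * dy^q)
  m20 <- mu(2, 0) / area + 1 / 12
  m02 <- mu(0, 2) / area + 1 / 12
  m11 <- mu(1, 1) / area
  common <- sqrt((m20 - m02)^2 + 4 * m11^2)
  l1 <- (m20 + m02 + common) / 2
  l2 <- (m20 + m02 - common) / 2
  elong <- if (l2 > 0) sqrt(l1 / l2) else 1

  out["GeoF"] <- area
  out["GeoPerim"] <- perim
  out["GeoSxL"] <- bb_w * bb_h
  out["GeoEl"] <- elong
  out["GeoOrient"] <- 0.5 * atan2(2 * m11, m20 - m02) * 180 / pi
  out["GeoCompact"] <- perim^2 / (4 * pi * area)
  out["GeoCirc"] <- 4 * pi * area / perim^2
  out["GeoEqDiam"] <- 2 * sqrt(area / pi)
  out["GeoExtent"] <- area / (bb_w * bb_h)
  out["GeoAspect"] <- max(bb_w, bb_h) / min(bb_w, bb_h)
  out["GeoBbW"] <- bb_w
  out["GeoBbH"] <- bb_h
  out["GeoMajAx"] <- 4 * sqrt(l1)
  out["GeoMinAx"] <- 4 * sqrt(max(l2, 0))
  out["GeoEcc"] <- if (l1 > 0) sqrt(1 - max(l2, 0) / l1) else 0

  # Convex hull of boundary pixel centers.
  brc <- which(exposed, arr.ind = TRUE)
  bx <- brc[, 2] - 0.5
  by <- brc[, 1] - 0.5
  hull_ok <- length(bx) >= 3 && diff(range(bx)) > 0 && diff(range(by)) > 0
  if (hull_ok) {
    h <- grDevices::chull(bx, by)
    hx <- bx[h]
    hy <- by[h]
    conv_a <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
    conv_p <- sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))
    out["GeoConvA"] <- conv_a
    out["GeoConvP"] <- conv_p
    out["GeoSolidity"] <- if (conv_a > 0) area / conv_a else NA_real_
    out["GeoRough"] <- if (conv_p > 0) perim / conv_p else NA_real_
    fer <- function(theta) {
      pr <- hx * cos(theta) + hy * sin(theta)
      diff(range(pr)) + 1
    }
    ang12 <- (0:11) * pi / 12
    w <- vapply(ang12, fer, numeric(1))
    out[paste0("GeoW", 1:12)] <- w
    out[paste0("GeoW", 1:12, "b")] <- w / perim
    fine <- seq(0, pi, length.out = 91)[-91]
    df <- vapply(fine, fer, numeric(1))
    out["GeoFerMin"] <- min(df)
    out["GeoFerMax"] <- max(df)
    out["GeoFerMean"] <- mean(df)
    out["GeoFerRatio"] <- max(df) / min(df)
    out["GeoFerAng"] <- fine[which.max(df)] * 180 / pi
  }

  # Normalized central moments and Hu invariants.
  eta <- function(p, q) mu(p, q) / area^(1 + (p + q) / 2)
  e <- list(
    `11` = eta(1, 1), `20` = eta(2, 0), `02` = eta(0, 2), `21` = eta(2, 1),
    `12` = eta(1, 2), `30` = eta(3, 0), `03` = eta(0, 3), `22` = eta(2, 2),
    `31` = eta(3, 1), `13` = eta(1, 3), `40` = eta(4, 0), `04` = eta(0, 4)
  )
  out[paste0("GeoM", names(e))] <- unlist(e)
  n20 <- e$`20`; n02 <- e$`02`; n11 <- e$`11`
  n30 <- e$`30`; n03 <- e$`03`; n21 <- e$`21`; n12 <- e$`12`
  out["GeoHu1"] <- n20 + n02
  out["GeoHu2"] <- (n20 - n02)^2 + 4 * n11^2
  out["GeoHu3"] <- (n30 - 3 * n12)^2 + (3 * n21 - n03)^2
  out["GeoHu4"] <- (n30 + n12)^2 + (n21 + n03)^2
  out["GeoHu5"] <- (n30 - 3 * n12) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
    (3 * n21 - n03) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2)
  out["GeoHu6"] <- (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
    4 * n11 * (n30 + n12) * (n21 + n03)
  out["GeoHu7"] <- (3 * n21 - n03) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
    (n30 - 3 * n12) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2)

  # Radial signature of the boundary around the centroid.
  rd <- sqrt((bx - cx)^2 + (by - cy)^2)
  if (length(rd) >= 3 && mean(rd) > 0) {
    ms <- moment_stats(rd)
    out["GeoRdMean"] <- ms["mean"]
    out["GeoRdSD"] <- sqrt(ms["variance"])
    out["GeoRdCV"] <- sqrt(ms["variance"]) / ms["mean"]
    out["GeoRdMin"] <- min(rd)
    out["GeoRdMax"] <- max(rd)
    out["GeoRdRatio"] <- min(rd) / max(rd)
    out["GeoRdSkew"] <- ms["skewness"]
    out["GeoRdKurt"] <- ms["kurtosis"]
    hcount <- tabulate(pmin(10L,
      1L + floor(10 * (rd - min(rd)) / max(diff(range(rd)), 1e-12))), 10)
    ph <- hcount / sum(hcount)
    out["GeoRdEntropy"] <- -sum(ph[ph > 0] * log(ph[ph > 0]))
    # Fourier descriptors of the angle-ordered, mean-normalized signature.
    ord <- order(atan2(by - cy, bx - cx))
    sig <- rd[ord] / mean(rd) - 1
    fmag <- Mod(stats::fft(sig)) / length(sig)
    nfd <- min(10L, length(sig) - 1L)
    out[paste0("GeoFd", seq_len(nfd))] <- fmag[1 + seq_len(nfd)]
  }

  # Projection profiles (nonzero support only).
  proj_stats <- function(v) {
    v <- v[v > 0]
    ms <- moment_stats(v)
    c(ms["mean"], sqrt(ms["variance"]), max(v), ms["skewness"], length(v))
  }
  out[paste0("GeoPrH", c("Mean", "SD", "Max", "Skew", "Len"))] <-
    proj_stats(colSums(mask))
  out[paste0("GeoPrV", c("Mean", "SD", "Max", "Skew", "Len"))] <-
    proj_stats(rowSums(mask))

  out["GeoNBnd"] <- sum(exposed)
  out["GeoBndFrac"] <- sum(exposed) / area
  out
}
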