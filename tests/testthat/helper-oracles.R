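# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles (explicit loops, closed forms, normal
# equations) and never share code with the implementation under test.

# Ray-casting point-in-polygon (even-odd), one point at a time.
oracle_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py)) {
      xcross <- xi + (py - yi) * (xj - xi) / (yj - yi)
      if (px < xcross) inside <- !inside
    }
    j <- i
  }
  inside
}

oracle_rasterize <- function(roi, shape) {
  m <- matrix(FALSE, shape[1], shape[2])
  for (r in seq_len(shape[1])) {
    for (c in seq_len(shape[2])) {
      m[r, c] <- oracle_point_in_polygon(c - 0.5, r - 0.5, roi)
    }
  }
  m
}

# Explicit pair enumeration for the co-occurrence matrix; (dx, dy) with the
# y axis pointing up (partner of [r, c] is [r - dy, c + dx]).
oracle_glcm <- function(levels, dx, dy, ng) {
  counts <- matrix(0, ng, ng)
  nr <- nrow(levels); nc <- ncol(levels)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      r2 <- r - dy; c2 <- c + dx
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
          !is.na(levels[r, c]) && !is.na(levels[r2, c2])) {
        a <- levels[r, c]; b <- levels[r2, c2]
        counts[a, b] <- counts[a, b] + 1
        counts[b, a] <- counts[b, a] + 1
      }
    }
  }
  if (sum(counts) == 0) return(NULL)
  counts / sum(counts)
}

oracle_glcm_stats <- function(p) {
  ng <- nrow(p)
  angscmom <- 0; contrast <- 0; invdfmom <- 0; entropy <- 0; sumofsqs <- 0
  px <- rowSums(p)
  mux <- sum(seq_len(ng) * px)
  sx2 <- sum((seq_len(ng) - mux)^2 * px)
  cross <- 0
  psum <- numeric(2 * ng); pdiff <- numeric(ng)
  for (i in seq_len(ng)) for (j in seq_len(ng)) {
    v <- p[i, j]
    angscmom <- angscmom + v^2
    contrast <- contrast + (i - j)^2 * v
    invdfmom <- invdfmom + v / (1 + (i - j)^2)
    sumofsqs <- sumofsqs + (i - mux)^2 * v
    cross <- cross + i * j * v
    if (v > 0) entropy <- entropy - v * log(v)
    psum[i + j] <- psum[i + j] + v
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + v
  }
  sumaverg <- sum(seq_along(psum) * psum)
  sumvarnc <- sum((seq_along(psum) - sumaverg)^2 * psum)
  sumentrp <- -sum(psum[psum > 0] * log(psum[psum > 0]))
  kd <- seq_along(pdiff) - 1
  mud <- sum(kd * pdiff)
  difvarnc <- sum((kd - mud)^2 * pdiff)
  difentrp <- -sum(pdiff[pdiff > 0] * log(pdiff[pdiff > 0]))
  c(AngScMom = angscmom, Contrast = contrast,
    Correlat = if (sx2 > 0) (cross - mux^2) / sx2 else 0,
    SumOfSqs = sumofsqs, InvDfMom = invdfmom, SumAverg = sumaverg,
    SumVarnc = sumvarnc, SumEntrp = sumentrp, Entropy = entropy,
    DifVarnc = difvarnc, DifEntrp = difentrp)
}

# Walk every line of a direction pixel by pixel and collect maximal runs.
oracle_runs <- function(levels, direction) {
  nr <- nrow(levels); nc <- ncol(levels)
  step <- switch(direction,
    horizontal = c(0, 1), vertical = c(1, 0),
    d45 = c(-1, 1), d135 = c(1, 1))
  starts <- switch(direction,
    horizontal = cbind(seq_len(nr), 1),
    vertical = cbind(1, seq_len(nc)),
    d45 = rbind(cbind(seq_len(nr), 1), cbind(nr, seq(2, nc))),
    d135 = rbind(cbind(seq(nr, 1), 1), cbind(1, seq(2, nc))))
  runs <- list()
  for (k in seq_len(nrow(starts))) {
    r <- starts[k, 1]; c <- starts[k, 2]
    cur_lev <- NA; cur_len <- 0
    while (r >= 1 && r <= nr && c >= 1 && c <= nc) {
      v <- levels[r, c]
      if (!is.na(v) && !is.na(cur_lev) && v == cur_lev) {
        cur_len <- cur_len + 1
      } else {
        if (!is.na(cur_lev)) runs[[length(runs) + 1]] <- c(cur_lev, cur_len)
        cur_lev <- v; cur_len <- if (is.na(v)) 0 else 1
      }
      r <- r + step[1]; c <- c + step[2]
    }
    if (!is.na(cur_lev)) runs[[length(runs) + 1]] <- c(cur_lev, cur_len)
  }
  do.call(rbind, runs)
}

oracle_rlm_stats <- function(levels, direction) {
  ru <- oracle_runs(levels, direction)
  g <- ru[, 1]; l <- ru[, 2]
  nr <- nrow(ru); np <- sum(!is.na(levels))
  glev <- sapply(unique(g), function(gg) sum(g == gg))
  rlen <- sapply(unique(l), function(ll) sum(l == ll))
  c(ShrtREmp = sum(1 / l^2) / nr, LngREmph = sum(l^2) / nr,
    GLevNonU = sum(glev^2) / nr, RLNonUni = sum(rlen^2) / nr,
    Fraction = nr / np)
}

oracle_gradient <- function(levels) {
  nr <- nrow(levels); nc <- ncol(levels)
  mags <- c()
  for (r in 2:(nr - 1)) for (c in 2:(nc - 1)) {
    vals <- c(levels[r, c], levels[r, c - 1], levels[r, c + 1],
      levels[r - 1, c], levels[r + 1, c])
    if (!anyNA(vals)) {
      gx <- (levels[r, c + 1] - levels[r, c - 1]) / 2
      gy <- (levels[r + 1, c] - levels[r - 1, c]) / 2
      mags <- c(mags, sqrt(gx^2 + gy^2))
    }
  }
  mags
}

oracle_moments <- function(v) {
  m <- mean(v); m2 <- mean((v - m)^2)
  if (m2 == 0) return(c(m, 0, 0, 0))
  c(m, m2, mean((v - m)^3) / m2^1.5, mean((v - m)^4) / m2^2 - 3)
}

# AR(1) causal fit through the normal equations.
oracle_ar <- function(levels) {
  nr <- nrow(levels); nc <- ncol(levels)
  ys <- c(); xs <- NULL
  mu <- mean(levels, na.rm = TRUE)
  for (r in 2:nr) for (c in 2:(nc - 1)) {
    vals <- c(levels[r, c], levels[r, c - 1], levels[r - 1, c - 1],
      levels[r - 1, c], levels[r - 1, c + 1])
    if (!anyNA(vals)) {
      ys <- c(ys, vals[1] - mu)
      xs <- rbind(xs, vals[2:5] - mu)
    }
  }
  theta <- solve(t(xs) %*% xs, t(xs) %*% ys)
  res <- ys - xs %*% theta
  list(theta = as.numeric(theta), sigma = sqrt(mean(res^2)), n = length(ys))
}

# Closed-form Haar coefficients from dyadic block sums over the mask
# bounding box; energies over fully mask-supported blocks only.
oracle_haar_energy <- function(levels, mask, scale) {
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  lv <- levels[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  mk <- mask[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  lv[is.na(lv)] <- mean(levels, na.rm = TRUE)
  side <- 2^scale
  nbr <- nrow(lv) %/% side
  nbc <- ncol(lv) %/% side
  coefs <- list(LL = c(), LH = c(), HL = c(), HH = c())
  for (bi in seq_len(nbr)) for (bj in seq_len(nbc)) {
    rows <- ((bi - 1) * side + 1):(bi * side)
    cols <- ((bj - 1) * side + 1):(bj * side)
    if (!all(mk[rows, cols])) next
    blk <- lv[rows, cols, drop = FALSE]
    top <- rows_half <- seq_len(side / 2)
    tl <- sum(blk[rows_half, rows_half]); tr <- sum(blk[rows_half, -rows_half])
    bl <- sum(blk[-rows_half, rows_half]); br <- sum(blk[-rows_half, -rows_half])
    coefs$LL <- c(coefs$LL, (tl + tr + bl + br) / side)
    coefs$LH <- c(coefs$LH, (tl + tr - bl - br) / side)
    coefs$HL <- c(coefs$HL, (tl - tr + bl - br) / side)
    coefs$HH <- c(coefs$HH, (tl - tr - bl + br) / side)
  }
  if (length(coefs$LL) == 0) return(NULL)
  sapply(coefs, function(x) mean(x^2))
}

# Mann-Whitney pair counting (ties as 1/2).
oracle_auc <- function(scores, labels) {
  xs <- scores[labels == "HTN"]; ys <- scores[labels == "NC"]
  tot <- 0
  for (a in xs) for (b in ys) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(xs) * length(ys))
}

# Exhaustive threshold search for the maximal Youden index.
oracle_best_youden <- function(scores, labels) {
  cand <- sort(unique(c(scores - 1e-9, scores + 1e-9,
    min(scores) - 1, max(scores) + 1)))
  best <- -Inf
  for (ct in cand) {
    sens <- mean(scores[labels == "HTN"] > ct)
    spec <- mean(scores[labels == "NC"] <= ct)
    best <- max(best, sens + spec - 1)
  }
  best
}

# --- fixture builders ---------------------------------------------------

random_level_image <- function(nr = 8, nc = 8, ng = 4, mask_frac = 0) {
  lv <- matrix(sample.int(ng, nr * nc, replace = TRUE), nr, nc)
  if (mask_frac > 0) {
    drop <- sample.int(nr * nc, ceiling(mask_frac * nr * nc))
    lv[drop] <- NA_integer_
  }
  lv
}

# A minimal ctx_zoo-shaped object for testing ensemble mechanics directly.
fake_zoo <- function(models, cv_acc, pred_list) {
  tbl <- tibble::tibble(
    model = models, status = "ok", cv_accuracy = cv_acc,
    params = replicate(length(models), list(NULL)),
    predictions = pred_list,
    metrics = purrr::map(pred_list, function(p) {
      tibble::tibble(tp = 0, fp = 0, tn = 0, fn = 0, sensitivity = NA,
        specificity = NA, ppv = NA, npv = NA, plr = NA, nlr = NA,
        accuracy = NA)
    })
  )
  structure(tbl, class = c("ctx_zoo", class(tibble::tibble())))
}

# Linearly separable two-class feature table.
separable_table <- function(n_per_class = 40, p = 6, shift = 4, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(rnorm(n * p), n, p)
  x[seq_len(n_per_class), 1:2] <- x[seq_len(n_per_class), 1:2] + shift
  colnames(x) <- paste0("f", seq_len(p))
  tibble::as_tibble(x) |>
    dplyr::mutate(
      subject_id = sprintf("S%03d", seq_len(n)),
      group = rep(c("HTN", "NC"), each = n_per_class),
      .before = 1
    )
}

small_cohort <- function(n = 6, seed = 1, image_size = 64, effect_size = 1) {
  generate_cohort(cohort_spec(n_htn = n, n_nc = n, seed = seed,
    image_size = image_size, effect_size = effect_size))
}
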