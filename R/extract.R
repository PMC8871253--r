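#' Extract the full radiomics vector from one image + ROI
#'
#' Rasterizes the polygon, applies mean +/- 3 SD gray-level normalization
#' (64 levels for co-occurrence, run-length, autoregressive and wavelet
#' families; 256 for histogram and gradient), and evaluates every feature
#' of the manifest. Geometry features are computed on the binary mask and
#' are intensity-independent. Features undefined for the ROI (e.g. a
#' wavelet scale larger than the mask support) are returned as `NA`.
#'
#' @param image Numeric matrix of pixel values.
#' @param roi Two-column vertex matrix (`x`, `y`).
#' @param manifest Feature manifest (default [feature_manifest()]).
#' @param n_levels_cooc,n_levels_hist Quantization depths.
#' @return Named numeric vector aligned to the manifest (length 377 by
#'   default).
#' @export
extract_all <- function(image, roi, manifest = feature_manifest(),
                        n_levels_cooc = 64, n_levels_hist = 256) {
  mask <- rasterize(roi, dim(image))
  n64 <- normalize_mu3sigma(image, mask, n_levels_cooc)
  n256 <- normalize_mu3sigma(image, mask, n_levels_hist)

  vals <- c(
    histogram_features(n256$levels),
    gradient_features(n256$levels)
  )
  offs <- dplyr::distinct(dplyr::filter(manifest, .data$family == "cooccurrence"),
    .data$dx, .data$dy)
  for (k in seq_len(nrow(offs))) {
    p <- glcm(n64$levels, offs$dx[k], offs$dy[k], n_levels_cooc)
    f <- glcm_features(p)
    names(f) <- sprintf("S(%d,%d)%s", offs$dx[k], offs$dy[k], names(f))
    vals <- c(vals, f)
  }
  for (dir in names(rlm_direction_prefix)) {
    f <- rlm_features(n64$levels, dir)
    names(f) <- paste0(rlm_direction_prefix[[dir]], "_", names(f))
    vals <- c(vals, f)
  }
  vals <- c(
    vals,
    ar_features(n64$levels),
    wavelet_features(n64$levels, mask),
    geometry_features(mask)
  )
  vals[manifest$feature]
}

#' Extract the feature table for a whole cohort
#'
#' Applies [extract_all()] to every subject of a cohort tibble and returns
#' the subjects-by-features table used by all downstream stages.
#'
#' @param cohort Cohort tibble from [generate_cohort()] / [read_cohort()]
#'   (columns `subject_id`, `group`, `image`, `roi`).
#' @inheritParams extract_all
#' @return A tibble: `subject_id`, `group`, then one column per manifest
#'   feature.
#' @export
extract_features <- function(cohort, manifest = feature_manifest(),
                             n_levels_cooc = 64, n_levels_hist = 256) {
  feats <- purrr::map2(cohort$image, cohort$roi, function(img, roi) {
    extract_all(img, roi, manifest, n_levels_cooc, n_levels_hist)
  })
  dplyr::bind_cols(
    tibble(subject_id = cohort$subject_id, group = cohort$group),
    as_tibble(do.call(rbind, feats))
  )
}

feature_columns <- function(tbl) {
  setdiff(names(tbl), c("subject_id", "group"))
}
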