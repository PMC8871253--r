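glcm_stat_names <- c(
  "AngScMom", "Contrast", "Correlat", "SumOfSqs", "InvDfMom", "SumAverg",
  "SumVarnc", "SumEntrp", "Entropy", "DifVarnc", "DifEntrp"
)

rlm_stat_names <- c("ShrtREmp", "LngREmph", "GLevNonU", "RLNonUni", "Fraction")

rlm_direction_prefix <- c(
  horizontal = "Horzl", vertical = "Vertl", d45 = "45dgr", d135 = "135dr"
)

# The 20 co-occurrence offsets: 5 distances x 4 directions, (dx, dy) with y
# pointing up, so (d, -d) is the 45-degree and (d, d) the 135-degree offset.
glcm_offsets <- function() {
  purrr::map_dfr(1:5, function(d) {
    tibble(dx = c(d, 0L, d, d), dy = c(0L, d, d, -d))
  })
}

geometry_feature_names <- function() {
  c(
    "GeoF", "GeoPerim", "GeoSxL", "GeoEl", "GeoOrient", "GeoCompact",
    "GeoCirc", "GeoEqDiam", "GeoExtent", "GeoAspect",
    "GeoBbW", "GeoBbH",
    "GeoMajAx", "GeoMinAx", "GeoEcc",
    "GeoConvA", "GeoConvP", "GeoSolidity", "GeoRough",
    paste0("GeoW", 1:12),
    paste0("GeoW", 1:12, "b"),
    "GeoFerMin", "GeoFerMax", "GeoFerMean", "GeoFerRatio", "GeoFerAng",
    paste0("GeoM", c("11", "20", "02", "21", "12", "30", "03", "22", "31",
      "13", "40", "04")),
    paste0("GeoHu", 1:7),
    paste0("GeoRd", c("Mean", "SD", "CV", "Min", "Max", "Ratio", "Skew",
      "Kurt", "Entropy")),
    paste0("GeoFd", 1:10),
    paste0("GeoPrH", c("Mean", "SD", "Max", "Skew", "Len")),
    paste0("GeoPrV", c("Mean", "SD", "Max", "Skew", "Len")),
    "GeoNBnd", "GeoBndFrac"
  )
}

#' The default 377-feature radiomics manifest
#'
#' Names and orders the full feature vector: 9 histogram + 5 gradient +
#' 220 co-occurrence (11 Haralick statistics x 5 distances x 4 directions,
#' named `S(dx,dy)<Stat>`) + 20 run-length (5 statistics x 4 directions,
#' named `<Dir>_<Stat>`) + 5 autoregressive (`Teta1..4`, `Sigma`) +
#' 20 wavelet (Haar subband energies `WavEn<Sub>_s-<scale>`, scales 1..5) +
#' 98 geometry descriptors = 377. The naming scheme follows the MaZda
#' convention so that published feature names (e.g. `S(1,0)DifEntrp`,
#' `Horzl_RLNonUni`, `WavEnLH_s-4`, `GeoEl`) appear verbatim. This is
#' manifest version `manifest_v1`; geometry descriptors beyond area,
#' elongation and the moment family are documented reconstructions.
#'
#' @return A tibble with columns `feature`, `family`, and the defining
#'   parameters (`dx`, `dy`, `direction`, `subband`, `scale`).
#' @examples
#' nrow(feature_manifest()) # 377
#' @export
feature_manifest <- function() {
  hist_tbl <- tibble(
    feature = c("Mean", "Variance", "Skewness", "Kurtosis",
      "Perc01", "Perc10", "Perc50", "Perc90", "Perc99"),
    family = "histogram"
  )
  grad_tbl <- tibble(
    feature = c("GrMean", "GrVariance", "GrSkewness", "GrKurtosis",
      "GrNonZeros"),
    family = "gradient"
  )
  offs <- glcm_offsets()
  cooc_tbl <- purrr::pmap_dfr(offs, function(dx, dy) {
    tibble(
      feature = sprintf("S(%d,%d)%s", dx, dy, glcm_stat_names),
      family = "cooccurrence", dx = dx, dy = dy
    )
  })
  rlm_tbl <- purrr::imap_dfr(rlm_direction_prefix, function(prefix, dir) {
    tibble(
      feature = paste0(prefix, "_", rlm_stat_names),
      family = "runlength", direction = dir
    )
  })
  ar_tbl <- tibble(
    feature = c(paste0("Teta", 1:4), "Sigma"), family = "ar_model"
  )
  wav_tbl <- purrr::map_dfr(1:5, function(s) {
    tibble(
      feature = sprintf("WavEn%s_s-%d", c("LL", "LH", "HL", "HH"), s),
      family = "wavelet", subband = c("LL", "LH", "HL", "HH"), scale = s
    )
  })
  geo_tbl <- tibble(feature = geometry_feature_names(), family = "geometry")
  out <- dplyr::bind_rows(hist_tbl, grad_tbl, cooc_tbl, rlm_tbl, ar_tbl,
    wav_tbl, geo_tbl)
  attr(out, "manifest_version") <- "manifest_v1"
  out
}

#' Serialize the feature manifest to JSON
#'
#' @param manifest A manifest tibble from [feature_manifest()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(
    list(
      version = attr(manifest, "manifest_version") %||% "manifest_v1",
      features = manifest
    ),
    path, digits = NA, na = "null"
  )
  invisible(path)
}
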