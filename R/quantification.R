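#' Background-corrected band ratio
#'
#' Normalizes an aptamer band against the U6 snoRNA loading-control band of
#' the same lane: `(aptamer - aptamer_background) / (u6 - u6_background)`.
#' Band volumes are in arbitrary densitometry units, so the ratio is scale
#' invariant.  A non-positive net U6 volume means the loading control
#' failed and is an error; a non-positive net aptamer volume is allowed
#' here (no detectable band) and yields a ratio <= 0.
#'
#' @param aptamer_volume,aptamer_background Aptamer band volume and its
#'   background.
#' @param u6_volume,u6_background Loading-control (U6) band volume and its
#'   background.
#' @return Numeric ratio(s); vectorized.
#' @examples
#' band_ratio(50, 10, 30, 10)
#' @export
band_ratio <- function(aptamer_volume, aptamer_background,
                       u6_volume, u6_background) {
  stopifnot(all(aptamer_volume >= 0), all(aptamer_background >= 0),
            all(u6_volume >= 0), all(u6_background >= 0))
  u6_net <- u6_volume - u6_background
  if (any(u6_net <= 0)) {
    abort("loading control failed: net U6 volume must be > 0")
  }
  (aptamer_volume - aptamer_background) / u6_net
}

#' Enrichment of an aptamer's binding relative to the starting library
#'
#' Divides an aptamer's background-corrected band ratio by the ratio of the
#' unselected library measured on the same blot, giving a fold change in
#' cell binding.
#'
#' @param aptamer_ratio Band ratio(s) of the aptamer lane(s), from
#'   [band_ratio()].
#' @param library_ratio Band ratio of the starting-library lane; must be
#'   positive.
#' @return Numeric fold enrichment(s); vectorized over `aptamer_ratio`.
#' @examples
#' relative_enrichment(2.4, 0.1)
#' @export
relative_enrichment <- function(aptamer_ratio, library_ratio) {
  if (any(library_ratio <= 0)) {
    abort("library band ratio must be > 0")
  }
  aptamer_ratio / library_ratio
}

#' Percentage of cell-bound aptamer protected from RNase
#'
#' The internalized fraction is the ratio of the normalized aptamer signal
#' in RNase-treated (RS+) cells to untreated (RS-) cells, as a percentage:
#' `100 * ratio(RS+) / ratio(RS-)`.  Internalized aptamer survives the
#' RNase treatment; surface-bound aptamer does not.
#'
#' @param rs_plus_ratio Band ratio from the RNase-treated lane.
#' @param rs_minus_ratio Band ratio from the untreated lane; must be
#'   positive.
#' @return Percentage(s); 100 when treatment changes nothing.
#' @examples
#' internalized_fraction(0.27, 1.0)
#' @export
internalized_fraction <- function(rs_plus_ratio, rs_minus_ratio) {
  if (any(rs_minus_ratio <= 0)) {
    abort("untreated (RS-) band ratio must be > 0")
  }
  100 * rs_plus_ratio / rs_minus_ratio
}

#' Quantify a table of Northern-blot lanes
#'
#' Data-frame-first wrapper around [band_ratio()]: takes one row per lane
#' and appends the background-corrected ratio.  Net aptamer volumes below
#' zero are clamped to a zero ratio with a warning — signal below
#' background means no detectable band, not negative material.
#'
#' @param lanes A data frame with columns `condition`, `aptamer_volume`,
#'   `aptamer_background`, `u6_volume`, `u6_background`.
#' @return The input as a tibble with an added `ratio` column.
#' @export
quantify_lanes <- function(lanes) {
  stopifnot(is.data.frame(lanes),
            all(c("condition", "aptamer_volume", "aptamer_background",
                  "u6_volume", "u6_background") %in% names(lanes)))
  out <- as_tibble(lanes)
  out$ratio <- band_ratio(out$aptamer_volume, out$aptamer_background,
                          out$u6_volume, out$u6_background)
  neg <- out$ratio < 0
  if (any(neg)) {
    warn(paste0(sum(neg), " lane(s) had aptamer signal below background; ",
                "ratio clamped to 0"))
    out$ratio[neg] <- 0
  }
  out
}
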