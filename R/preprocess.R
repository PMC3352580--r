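#' Percentile of a set of intensities
#'
#' Linear-interpolation-between-closest-ranks percentile (the definition
#' used throughout the package, identical to `stats::quantile(type = 7)`):
#' `p = 0` gives the minimum, `p = 100` the maximum.
#'
#' @param values Non-empty numeric vector.
#' @param p Percentile in `[0, 100]`.
#' @return The percentile value, a single number.
#' @export
percentile <- function(values, p) {
  if (length(values) == 0L) stop("empty sequence")
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 100)
    stop("p must be a single number in [0, 100]")
  unname(stats::quantile(as.numeric(values), probs = p / 100,
                         type = 7, names = FALSE))
}

#' Clamp and rescale intensities onto the 0--100 working scale
#'
#' The final intensity-preprocessing step before standardization: computes
#' low and high percentile anchors over the whole image (all voxels,
#' background included), maps everything at or below the low anchor to 0,
#' everything at or above the high anchor to 100, and rescales linearly in
#' between. This removes low/high intensity outliers and puts any raw
#' volume on the common 0--100 scale the standardization methods assume.
#'
#' @param volume An [intensity_volume()] with arbitrary intensity range.
#' @param low_percentile,high_percentile Anchor percentiles; defaults 0.01
#'   and 99.99. Must satisfy `0 <= low < high <= 100`.
#' @return A new [intensity_volume()] with intensities in `[0, 100]` and
#'   `intensity_scale = c(0, 100)`.
#' @export
clamp_intensities <- function(volume, low_percentile = 0.01,
                              high_percentile = 99.99) {
  stopifnot(inherits(volume, "intensity_volume"))
  if (!(low_percentile >= 0 && low_percentile < high_percentile &&
        high_percentile <= 100))
    stop("need 0 <= low_percentile < high_percentile <= 100")
  x <- volume$data
  lo <- percentile(x, low_percentile)
  hi <- percentile(x, high_percentile)
  if (hi <= lo)
    stop("degenerate intensity range: percentile anchors coincide (",
         format(lo), ")")
  y <- (x - lo) / (hi - lo) * 100
  y[y < 0] <- 0
  y[y > 100] <- 100
  intensity_volume(y, spacing = volume$spacing,
                   intensity_scale = c(0, 100))
}
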