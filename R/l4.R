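#' L4 parameters
#'
#' Parameters of the decile-landmark histogram-matching comparator:
#' percentile landmarks computed within each image's foreground (FRG),
#' plus a whole-image upper-percentile landmark.
#'
#' @param deciles Strictly increasing percentiles in (0, 100) used as FRG
#'   landmarks; default the deciles 10, 20, ..., 90.
#' @param upper_percentile Whole-image upper landmark percentile, default
#'   99.8 (deliberately less tolerant than the 99.99 used at clamping).
#' @return An object of class `l4_params`.
#' @export
l4_params <- function(deciles = seq(10, 90, by = 10),
                      upper_percentile = 99.8) {
  deciles <- as.numeric(deciles)
  stopifnot(length(deciles) >= 1L, all(diff(deciles) > 0),
            all(deciles > 0), all(deciles < 100),
            upper_percentile > 0, upper_percentile < 100)
  structure(list(deciles = deciles, upper_percentile = upper_percentile),
            class = "l4_params")
}

#' Compute the foreground (FRG) mask of a volume
#'
#' The foreground is the set of voxels whose intensity is (1) greater than
#' or equal to the whole-image mean intensity and (2) strictly below the
#' whole-image upper-percentile intensity (default 99.8). This crops away
#' the background and the high-intensity outliers before landmark
#' extraction, and is also used as an evaluation voxel set.
#'
#' @param volume An [intensity_volume()].
#' @param upper_percentile Upper cutoff percentile, default 99.8.
#' @return A [voxel_set()] named `"FRG"`.
#' @export
compute_frg_mask <- function(volume, upper_percentile = 99.8) {
  stopifnot(inherits(volume, "intensity_volume"))
  x <- volume$data
  mu <- mean(x)
  hi <- percentile(x, upper_percentile)
  m <- (x >= mu) & (x < hi)
  if (!any(m))
    stop("empty FRG: no voxel with intensity in [mean, P",
         upper_percentile, ") -- degenerate volume?")
  voxel_set(m, name = "FRG")
}

#' Estimate the L4 landmark set
#'
#' Builds the decile-matching landmark set between an input and a standard
#' image: for each image the deciles are computed within that image's own
#' FRG, the upper-percentile (99.8) landmark over the whole image, and the
#' boundary pairs (0, 0) and (100, 100) are added. Landmarks are ordered
#' by input intensity; coincident input-side values (heavily quantized
#' images) raise a landmark-conflict error rather than being deduplicated.
#'
#' @param input_vol,standard_vol Aligned-scale [intensity_volume()]s with
#'   intensities in `[0, 100]`. (Spatial alignment is not required here:
#'   only marginal histograms are used.)
#' @param params An [l4_params()].
#' @return A [landmark_set()] with one pair per decile plus the upper and
#'   boundary pairs (12 pairs under the defaults).
#' @export
estimate_l4_landmarks <- function(input_vol, standard_vol,
                                  params = l4_params()) {
  frg_in <- compute_frg_mask(input_vol, params$upper_percentile)
  frg_st <- compute_frg_mask(standard_vol, params$upper_percentile)
  xi_fg <- input_vol$data[frg_in$mask]
  xs_fg <- standard_vol$data[frg_st$mask]
  dx <- vapply(params$deciles, function(p) percentile(xi_fg, p), 0)
  dy <- vapply(params$deciles, function(p) percentile(xs_fg, p), 0)
  ux <- percentile(input_vol$data, params$upper_percentile)
  uy <- percentile(standard_vol$data, params$upper_percentile)
  x <- c(dx, ux); y <- c(dy, uy)
  labels <- c(paste0("p", params$deciles), paste0("p", params$upper_percentile))
  ord <- order(x)
  landmark_set(c(0, x[ord], 100), c(0, y[ord], 100),
               c("min", labels[ord], "max"))
}

#' Standardize a volume with L4 decile matching
#'
#' Estimates the L4 piecewise-linear transfer from `mapping_source_input`
#' against the standard image and applies it voxel-wise to `apply_to`
#' (mirrors [standardize_sti()]).
#'
#' @param apply_to [intensity_volume()] the mapping is applied to.
#' @param standard_vol The standard [intensity_volume()].
#' @param mapping_source_input Volume the mapping is estimated from;
#'   defaults to `apply_to`.
#' @param params An [l4_params()].
#' @return A list with `volume`, `landmarks` and `mapping`.
#' @export
standardize_l4 <- function(apply_to, standard_vol,
                           mapping_source_input = apply_to,
                           params = l4_params()) {
  lset <- estimate_l4_landmarks(mapping_source_input, standard_vol, params)
  f <- build_mapping(lset)
  list(volume = apply_mapping(apply_to, f), landmarks = lset, mapping = f)
}
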