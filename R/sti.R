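#' STI parameters
#'
#' Parameters of the tissue-mode standardization algorithm. The search
#' order is fixed (BKG, then WM, then GM, i.e. largest to smallest tissue
#' component) and each later search is restricted by the modes already
#' found: voxels with input intensity up to `bkg_exclusion_above` units
#' above the BKG mode are removed before the WM search, and voxels within
#' `gm_window_below_wm` units below the WM mode -- as well as everything
#' above it -- are removed before the GM search. By default the offsets
#' are absolute distances on the 0--100 intensity scale (10 and 25 units);
#' setting `exclusion_relative = TRUE` interprets them as percentages of
#' the mode value instead. Exclusions are evaluated on the input image's
#' intensity axis, where scanner-dependent overlap lives.
#'
#' @param histogram A [histogram_params()].
#' @param bkg_exclusion_above Width (intensity units, or percent of the
#'   mode when relative) of the exclusion zone above the BKG mode.
#' @param gm_window_below_wm Width of the window below the WM mode outside
#'   which (and above which) voxels are excluded from the GM search.
#' @param exclusion_relative Interpret the two widths multiplicatively
#'   relative to the mode value instead of as absolute offsets.
#' @return An object of class `sti_params`.
#' @export
sti_params <- function(histogram = histogram_params(),
                       bkg_exclusion_above = 10,
                       gm_window_below_wm = 25,
                       exclusion_relative = FALSE) {
  stopifnot(inherits(histogram, "histogram_params"),
            bkg_exclusion_above > 0, bkg_exclusion_above < 100,
            gm_window_below_wm > 0, gm_window_below_wm < 100)
  structure(list(histogram = histogram,
                 bkg_exclusion_above = bkg_exclusion_above,
                 gm_window_below_wm = gm_window_below_wm,
                 exclusion_relative = isTRUE(exclusion_relative),
                 tissue_order = c("BKG", "WM", "GM")),
            class = "sti_params")
}

tissue_mode <- function(input_vol, standard_vol, mask_arr, params) {
  h <- compute_joint_histogram(input_vol, standard_vol, mask_arr,
                               params$histogram)
  find_mode(smooth_histogram(h))
}

#' Estimate the STI tissue landmarks
#'
#' Runs the ordered per-tissue mode search. For each tissue in turn (BKG,
#' WM, GM) the standard-versus-input joint intensity histogram of the
#' surviving tissue-masked voxels is computed fresh, Gaussian-smoothed,
#' and its mode taken as that tissue's (input, standard) intensity
#' correspondence. After the BKG mode, voxels whose input intensity is at
#' most `bkg_exclusion_above` above it are removed from the WM search;
#' after the WM mode, voxels whose input intensity reaches into the window
#' `gm_window_below_wm` below it (or above it) are removed from the GM
#' search. The three mode pairs plus (0, 0) and (100, 100) form the STI
#' landmark set, ordered BKG < GM < WM on both axes.
#'
#' When the assembled modes violate monotonicity (a known failure mode
#' when a tissue histogram has multiple peaks) the report carries a
#' `failure` message and a `NULL` landmark set instead of a silently
#' reordered one.
#'
#' @param input_vol The (nonlinearly registered) input
#'   [intensity_volume()], intensities in `[0, 100]`.
#' @param standard_vol The standard [intensity_volume()] on the same grid.
#' @param masks A [tissue_mask_set()] on the standard grid.
#' @param params An [sti_params()].
#' @return An object of class `sti_landmark_report`: fields `modes` (list
#'   of `mode_pair` per tissue), `landmarks` (a [landmark_set()] or
#'   `NULL`), `failure` (`NULL` or a message), `voxel_counts` (data frame
#'   of per-tissue counts before/after exclusion) and `params`.
#' @export
estimate_tissue_landmarks <- function(input_vol, standard_vol, masks,
                                      params = sti_params()) {
  stopifnot(inherits(masks, "tissue_mask_set"))
  validate_aligned(input_vol, standard_vol)
  validate_aligned(input_vol, masks)
  inp <- input_vol$data

  # BKG: full mask
  n_bkg <- sum(masks$bkg)
  mode_bkg <- tissue_mode(input_vol, standard_vol, masks$bkg, params)

  # WM: remove input intensities up to the exclusion limit above the BKG mode
  wm_limit <- if (params$exclusion_relative)
    mode_bkg$m_r * (1 + params$bkg_exclusion_above / 100)
  else mode_bkg$m_r + params$bkg_exclusion_above
  wm_keep <- masks$wm & (inp > wm_limit)
  n_wm <- sum(masks$wm); n_wm_kept <- sum(wm_keep)
  if (n_wm_kept == 0L)
    stop("WM search emptied: no WM voxel with input intensity above ",
         format(wm_limit), " (BKG exclusion)")
  mode_wm <- tissue_mode(input_vol, standard_vol, wm_keep, params)

  # GM: keep only input intensities in the window below the WM mode
  gm_limit <- if (params$exclusion_relative)
    mode_wm$m_r * (1 - params$gm_window_below_wm / 100)
  else mode_wm$m_r - params$gm_window_below_wm
  gm_keep <- masks$gm & (inp < gm_limit)
  n_gm <- sum(masks$gm); n_gm_kept <- sum(gm_keep)
  if (n_gm_kept == 0L)
    stop("GM search emptied: no GM voxel with input intensity below ",
         format(gm_limit), " (WM exclusion)")
  mode_gm <- tissue_mode(input_vol, standard_vol, gm_keep, params)

  modes <- list(BKG = mode_bkg, WM = mode_wm, GM = mode_gm)
  lset <- tryCatch(
    landmark_set(
      x = c(0, mode_bkg$m_r, mode_gm$m_r, mode_wm$m_r, 100),
      y = c(0, mode_bkg$m_s, mode_gm$m_s, mode_wm$m_s, 100),
      labels = c("min", "BKG", "GM", "WM", "max")),
    error = function(e) e)
  failure <- NULL
  if (inherits(lset, "error")) {
    failure <- conditionMessage(lset)
    lset <- NULL
  }
  structure(list(
    modes = modes, landmarks = lset, failure = failure,
    voxel_counts = data.frame(
      tissue = c("BKG", "WM", "GM"),
      before = c(n_bkg, n_wm, n_gm),
      after = c(n_bkg, n_wm_kept, n_gm_kept)),
    exclusion_limits = c(wm_above = wm_limit, gm_below = gm_limit),
    params = params),
    class = "sti_landmark_report")
}

#' @export
print.sti_landmark_report <- function(x, ...) {
  cat("<sti_landmark_report>\n")
  for (t in names(x$modes))
    cat(sprintf("  %-3s mode: input %7.3f  standard %7.3f\n",
                t, x$modes[[t]]$m_r, x$modes[[t]]$m_s))
  if (!is.null(x$failure)) cat("  FAILED:", x$failure, "\n")
  invisible(x)
}

#' Standardize a volume with STI
#'
#' Estimates the STI transfer function from `mapping_source_input` against
#' the standard image and applies it voxel-wise to `apply_to`. In the full
#' pipeline the mapping is estimated on the nonlinearly registered input
#' (best spatial correspondence with the standard masks) and applied to
#' the linearly registered input; when only one aligned input exists the
#' two arguments are the same volume, which is the default.
#'
#' @param apply_to [intensity_volume()] the mapping is applied to.
#' @param standard_vol The standard [intensity_volume()].
#' @param masks A [tissue_mask_set()] on the standard grid.
#' @param mapping_source_input Volume the mapping is estimated from;
#'   defaults to `apply_to`.
#' @param params An [sti_params()].
#' @return A list with `volume` (the standardized [intensity_volume()]),
#'   `report` (the [estimate_tissue_landmarks()] report) and `mapping`
#'   (the `mapping_function`).
#' @export
standardize_sti <- function(apply_to, standard_vol, masks,
                            mapping_source_input = apply_to,
                            params = sti_params()) {
  report <- estimate_tissue_landmarks(mapping_source_input, standard_vol,
                                      masks, params)
  if (!is.null(report$failure))
    stop("STI landmark estimation failed: ", report$failure)
  f <- build_mapping(report$landmarks)
  list(volume = apply_mapping(apply_to, f), report = report, mapping = f)
}
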