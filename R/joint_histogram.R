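#' Joint histogram parameters
#'
#' Binning and smoothing parameters for the standard-versus-input joint
#' intensity histogram. Defaults follow the STI method: bin width 0.25
#' intensity units, i.e. 400 bins per axis covering the 0--100 scale, and a
#' Gaussian smoothing kernel of 10 bins full width at half maximum.
#'
#' @param bin_width Bin width in intensity units.
#' @param n_bins Number of bins per axis; `n_bins * bin_width` must span
#'   the full 0--100 intensity scale.
#' @param smoothing_fwhm_bins Full width at half maximum of the Gaussian
#'   smoothing kernel, in bins. Sigma is `fwhm / (2 * sqrt(2 * log(2)))`.
#' @return An object of class `histogram_params`.
#' @export
histogram_params <- function(bin_width = 0.25, n_bins = 400L,
                             smoothing_fwhm_bins = 10) {
  n_bins <- as.integer(n_bins)
  stopifnot(bin_width > 0, n_bins > 0, smoothing_fwhm_bins > 0)
  if (abs(n_bins * bin_width - 100) > 1e-9)
    stop("n_bins * bin_width must span the [0, 100] intensity scale, got ",
         n_bins * bin_width)
  structure(list(bin_width = bin_width, n_bins = n_bins,
                 smoothing_fwhm_bins = smoothing_fwhm_bins),
            class = "histogram_params")
}

# 0-based bin index of an intensity; bins are [k*w, (k+1)*w) with the final
# bin closed so that intensity 100 lands in bin n_bins-1.
bin_index <- function(x, params) {
  pmin(as.integer(floor(x / params$bin_width)), params$n_bins - 1L)
}

bin_centers <- function(params) {
  (seq_len(params$n_bins) - 0.5) * params$bin_width
}

#' Compute the standard-versus-input joint intensity histogram
#'
#' Counts spatially corresponding voxel pairs by (input intensity, standard
#' intensity) bin over the voxels of a mask. The first axis (rows) is input
#' intensity, the second (columns) standard intensity. Bins are half-open
#' `[k*w, (k+1)*w)` with the last bin closed to include intensity 100, so
#' the counts always sum to the number of masked voxels. Smoothing is a
#' separate step ([smooth_histogram()]).
#'
#' @param input_vol,standard_vol Aligned [intensity_volume()]s with
#'   intensities in `[0, 100]`.
#' @param mask A [voxel_set()] (or binary 3D array) selecting the
#'   contributing voxels; must be non-empty and aligned with the volumes.
#' @param params A [histogram_params()].
#' @return An object of class `joint_histogram` with fields `counts`
#'   (n_bins x n_bins matrix), `params`, `n_voxels` and `smoothed`.
#' @export
compute_joint_histogram <- function(input_vol, standard_vol, mask,
                                    params = histogram_params()) {
  validate_aligned(input_vol, standard_vol)
  m <- if (inherits(mask, "voxel_set")) mask$mask else coerce_mask(mask)
  validate_aligned(input_vol, m)
  if (!any(m)) stop("empty mask")
  xi <- input_vol$data[m]; xs <- standard_vol$data[m]
  if (any(xi < 0 | xi > 100) || any(xs < 0 | xs > 100))
    stop("intensities outside [0, 100]; run clamp_intensities() first")
  bi <- bin_index(xi, params)  # 0-based input bin
  bs <- bin_index(xs, params)  # 0-based standard bin
  n <- params$n_bins
  counts <- matrix(tabulate(bi + n * bs + 1L, nbins = n * n), nrow = n)
  structure(list(counts = counts, params = params, n_voxels = length(xi),
                 smoothed = FALSE),
            class = "joint_histogram")
}

# Banded Toeplitz matrix applying a zero-padded 1D convolution with the
# given symmetric kernel to a length-n vector. Zero-padding deliberately
# attenuates mass sitting against the scale boundaries (e.g. the clipping
# atom at intensity 0) instead of re-injecting it, so edge spikes cannot
# outgrow an interior tissue peak.
conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (off in -r:r) {
    idx <- seq_len(max(0L, n - abs(off)))
    if (off >= 0) K[cbind(idx + off, idx)] <- kernel[off + r + 1L]
    else K[cbind(idx, idx - off)] <- kernel[off + r + 1L]
  }
  K
}

gaussian_kernel <- function(fwhm_bins, truncate = 4) {
  sigma <- fwhm_bins / (2 * sqrt(2 * log(2)))
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k / sum(k)
}

#' Gaussian-smooth a joint histogram
#'
#' Isotropic 2D Gaussian low-pass filtering of the joint histogram counts,
#' implemented as two separable 1D passes. Sigma (in bins) is derived from
#' the FWHM in the histogram's parameters; the kernel is truncated at 4
#' sigma and zero-padded at the boundaries, after which the counts are
#' globally renormalized so their total still equals the number of
#' contributing voxels. Zero-padding attenuates mass lying against the
#' intensity boundaries rather than folding it back in; interior structure
#' (anything more than a kernel radius from the edges) is untouched up to
#' the global factor.
#'
#' @param hist A `joint_histogram` from [compute_joint_histogram()].
#' @return A smoothed `joint_histogram` (field `smoothed` set to `TRUE`).
#' @export
smooth_histogram <- function(hist) {
  stopifnot(inherits(hist, "joint_histogram"))
  k <- gaussian_kernel(hist$params$smoothing_fwhm_bins)
  K <- conv_matrix(hist$params$n_bins, k)
  sm <- K %*% hist$counts %*% t(K)  # rows: input axis; cols: standard axis
  tot <- sum(hist$counts)
  s <- sum(sm)
  if (s > 0) sm <- sm * (tot / s)
  hist$counts <- sm
  hist$smoothed <- TRUE
  hist
}

#' @export
print.joint_histogram <- function(x, ...) {
  cat("<joint_histogram> ", x$params$n_bins, " x ", x$params$n_bins,
      " bins (width ", x$params$bin_width, "), ", x$n_voxels, " voxels",
      if (x$smoothed) ", smoothed", "\n", sep = "")
  invisible(x)
}

#' Write a joint histogram as a plain-text grid
#'
#' Dumps the counts as a CSV grid (rows = input-intensity bins, columns =
#' standard-intensity bins, both annotated with bin-center intensities) for
#' external inspection.
#'
#' @param hist A `joint_histogram`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_histogram_csv <- function(hist, path) {
  centers <- bin_centers(hist$params)
  df <- as.data.frame(hist$counts)
  names(df) <- paste0("std_", format(centers, trim = TRUE))
  df <- cbind(input_center = centers, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

normalize_intervals <- function(input_exclusion) {
  if (is.null(input_exclusion)) return(list())
  if (is.numeric(input_exclusion) && length(input_exclusion) == 2L)
    input_exclusion <- list(input_exclusion)
  lapply(input_exclusion, function(iv) {
    stopifnot(is.numeric(iv), length(iv) == 2L, iv[1] <= iv[2])
    iv
  })
}

#' Find the mode of a joint histogram
#'
#' Returns the bin-center coordinates of the global maximum count,
#' optionally restricted to input-intensity bins outside one or more
#' excluded intervals (a bin is excluded when its center lies inside a
#' closed interval). Ties are broken deterministically: smallest input-bin
#' index first, then smallest standard-bin index.
#'
#' @param hist A `joint_histogram` (usually smoothed).
#' @param input_exclusion Optional interval `c(lo, hi)` or list of such
#'   intervals of input intensities to exclude from the search.
#' @return An object of class `mode_pair` with fields `m_r` (input
#'   intensity at the mode), `m_s` (standard intensity) and `peak_count`.
#' @export
find_mode <- function(hist, input_exclusion = NULL) {
  stopifnot(inherits(hist, "joint_histogram"))
  centers <- bin_centers(hist$params)
  keep <- rep(TRUE, hist$params$n_bins)
  for (iv in normalize_intervals(input_exclusion))
    keep <- keep & !(centers >= iv[1] & centers <= iv[2])
  counts <- hist$counts
  counts[!keep, ] <- -Inf
  peak <- max(counts)
  if (!is.finite(peak) || peak <= 0)
    stop("no mode in search region: all mass excluded or histogram empty")
  hits <- which(counts == peak, arr.ind = TRUE)
  hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
  i <- unname(hits[1L, 1L]); j <- unname(hits[1L, 2L])
  structure(list(m_r = centers[i], m_s = centers[j], peak_count = peak,
                 bin = c(input = i - 1L, standard = j - 1L)),
            class = "mode_pair")
}
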