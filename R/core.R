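#' Construct an intensity volume
#'
#' The basic data container of the package: a 3D grid of real-valued
#' intensities on a common scale (by default the 0--100 working scale that
#' all standardization operations assume), plus grid metadata. Intensities
#' are carried as doubles throughout; binning happens only inside the
#' joint-histogram operations.
#'
#' @param data Numeric 3D array of voxel intensities. All values must be
#'   finite (no NA/NaN/Inf).
#' @param spacing Optional numeric vector of length 3, voxel size per axis
#'   in mm.
#' @param intensity_scale Declared (min, max) intensity bounds. Default
#'   `c(0, 100)`, the working scale produced by [clamp_intensities()].
#' @return An object of class `intensity_volume`.
#' @seealso [read_volume()], [write_volume()], [validate_aligned()]
#' @export
intensity_volume <- function(data, spacing = NULL, intensity_scale = c(0, 100)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("non-3D data: 'data' must be a 3-dimensional array, got ",
         paste(dim(data), collapse = "x"))
  storage.mode(data) <- "double"
  n_bad <- sum(!is.finite(data))
  if (n_bad > 0L)
    stop("volume contains ", n_bad, " non-finite voxel(s) (NaN/Inf/NA)")
  if (!is.null(spacing)) {
    spacing <- as.numeric(spacing)
    stopifnot(length(spacing) == 3L, all(spacing > 0))
  }
  structure(
    list(data = data, shape = dim(data), spacing = spacing,
         intensity_scale = as.numeric(intensity_scale)),
    class = "intensity_volume")
}

#' @export
print.intensity_volume <- function(x, ...) {
  cat("<intensity_volume> ", paste(x$shape, collapse = " x "),
      if (!is.null(x$spacing))
        paste0(" (", paste(format(x$spacing), collapse = " x "), " mm)"),
      "\n", sep = "")
  cat("  range [", format(min(x$data)), ", ", format(max(x$data)),
      "], declared scale [", x$intensity_scale[1], ", ",
      x$intensity_scale[2], "]\n", sep = "")
  invisible(x)
}

as_volume_data <- function(x) {
  if (inherits(x, "intensity_volume")) x$data else x
}

coerce_mask <- function(m, what = "mask") {
  m <- as_volume_data(m)
  if (!is.array(m) || length(dim(m)) != 3L)
    stop(what, " must be a 3D array")
  if (is.numeric(m)) {
    if (!all(m %in% c(0, 1)))
      stop(what, " must be binary (values in {0,1})")
    m <- m > 0
  }
  if (!is.logical(m)) stop(what, " must be logical or 0/1 numeric")
  m[is.na(m)] <- FALSE
  m
}

#' Construct a tissue mask set
#'
#' Binary masks for background (BKG), white matter (WM) and grey matter (GM)
#' defined on the standard image grid. The masks must share one shape, be
#' pairwise disjoint and each be non-empty. An optional CSF mask may be
#' supplied; because CSF intensity on T1-weighted images is close to
#' background, it is by default absorbed into the BKG mask so that CSF is
#' corrected through background standardization.
#'
#' @param bkg,wm,gm Binary 3D arrays (logical or 0/1), or `intensity_volume`s
#'   holding such arrays.
#' @param csf Optional binary CSF mask on the same grid.
#' @param csf_to_bkg If `TRUE` (default) and `csf` is given, CSF voxels are
#'   merged into the BKG mask; if `FALSE` the CSF mask is carried along
#'   unmerged in field `csf`.
#' @param provenance Free-text label recording where the masks came from.
#' @return An object of class `tissue_mask_set` with logical fields
#'   `bkg`, `wm`, `gm` (and possibly `csf`).
#' @export
tissue_mask_set <- function(bkg, wm, gm, csf = NULL, csf_to_bkg = TRUE,
                            provenance = "") {
  bkg <- coerce_mask(bkg, "bkg"); wm <- coerce_mask(wm, "wm")
  gm <- coerce_mask(gm, "gm")
  if (!is.null(csf)) {
    csf <- coerce_mask(csf, "csf")
    if (csf_to_bkg) { bkg <- bkg | csf; csf <- NULL }
  }
  shapes <- lapply(Filter(Negate(is.null), list(bkg, wm, gm, csf)), dim)
  if (length(unique(lapply(shapes, as.integer))) != 1L)
    stop("all masks must share one shape")
  if (any(bkg & wm) || any(bkg & gm) || any(wm & gm) ||
      (!is.null(csf) && any(csf & (bkg | wm | gm))))
    stop("masks are not pairwise disjoint")
  for (nm in c("bkg", "wm", "gm"))
    if (!any(get(nm))) stop("mask '", toupper(nm), "' is empty")
  structure(list(bkg = bkg, wm = wm, gm = gm, csf = csf,
                 shape = dim(bkg), provenance = provenance),
            class = "tissue_mask_set")
}

#' @export
print.tissue_mask_set <- function(x, ...) {
  cat("<tissue_mask_set> ", paste(x$shape, collapse = " x "),
      "  BKG=", sum(x$bkg), " WM=", sum(x$wm), " GM=", sum(x$gm),
      if (!is.null(x$csf)) paste0(" CSF=", sum(x$csf)),
      if (nzchar(x$provenance)) paste0("  [", x$provenance, "]"),
      "\n", sep = "")
  invisible(x)
}

#' Construct a named voxel set
#'
#' A voxel set is a named binary mask over the standard grid on which
#' per-voxel statistics (e.g. the MAE of [mean_absolute_error()]) are
#' computed. Canonical names are `FRG`, `WM`, `GM` and `BKG`; any other
#' name is treated as custom.
#'
#' @param mask Binary 3D array (logical or 0/1) or `intensity_volume`.
#' @param name Set label.
#' @return An object of class `voxel_set`.
#' @export
voxel_set <- function(mask, name = "custom") {
  mask <- coerce_mask(mask, "voxel set mask")
  if (!any(mask)) stop("voxel set '", name, "' is empty")
  structure(list(name = name, mask = mask, shape = dim(mask)),
            class = "voxel_set")
}

#' Read a 3D scalar volume from disk
#'
#' Reads a NIfTI-1 (`.nii` / `.nii.gz`) scalar volume into an
#' [intensity_volume()]. The file must contain a single 3D scalar image;
#' 4D data and non-finite voxels are rejected with informative errors.
#'
#' All standardization operations assume inputs already spatially aligned to
#' the standard image grid; registration is upstream of this package (e.g.
#' FSL FLIRT/FNIRT, ANTs, or minctracc pipelines).
#'
#' @param path Path to the volume file.
#' @param format `"auto"` (from the extension) or `"nifti"`.
#' @return An [intensity_volume()].
#' @export
read_volume <- function(path, format = c("auto", "nifti")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("non-3D data: '", path, "' has dimensions ",
         paste(d, collapse = "x"))
  spacing <- tryCatch(RNifti::pixdim(img)[seq_len(3L)],
                      error = function(e) NULL)
  intensity_volume(array(as.numeric(img), dim = d), spacing = spacing)
}

#' Write a 3D scalar volume to disk
#'
#' Writes an [intensity_volume()] as NIfTI-1 with double-precision voxels,
#' so that `read_volume(write_volume(v))` round-trips exactly.
#'
#' @param volume An [intensity_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param format Only `"nifti"` is supported.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, format = "nifti") {
  format <- match.arg(format, "nifti")
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  img <- RNifti::asNifti(volume$data)
  if (!is.null(volume$spacing))
    RNifti::pixdim(img) <- volume$spacing
  status <- try(RNifti::writeNifti(img, path, datatype = "double"),
                silent = TRUE)
  if (inherits(status, "try-error") || !file.exists(path))
    stop("could not write volume to ", path)
  invisible(path)
}

shape_of <- function(x) {
  if (inherits(x, "intensity_volume")) x$shape
  else if (inherits(x, c("tissue_mask_set", "voxel_set"))) x$shape
  else if (is.array(x)) dim(x)
  else stop("cannot determine grid shape of a ", class(x)[1])
}

#' Validate that two objects share the standard grid
#'
#' All comparisons and joint histograms in this package are voxelwise, so
#' every pair of objects entering them must live on the same grid. This
#' check passes iff the shapes are identical and raises an error naming
#' both shapes otherwise. It is symmetric in its arguments.
#'
#' @param a,b `intensity_volume`, `tissue_mask_set`, `voxel_set` or plain
#'   3D arrays.
#' @return `TRUE`, invisibly, on success.
#' @export
validate_aligned <- function(a, b) {
  sa <- shape_of(a); sb <- shape_of(b)
  if (!identical(as.integer(sa), as.integer(sb)))
    stop("shape mismatch: ", paste(sa, collapse = "x"), " vs ",
         paste(sb, collapse = "x"))
  invisible(TRUE)
}
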