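#' Construct a landmark set
#'
#' An ordered sequence of (input intensity, standard intensity) pairs
#' through which an intensity transfer function must pass. The first pair
#' must be (0, 0) and the last (100, 100); x must be strictly increasing
#' (the transfer must be a function of input intensity) and y
#' nondecreasing (the transfer must be monotone). Violations are reported
#' as errors, never silently repaired: a non-monotone landmark set is a
#' symptom of a failed estimation (e.g. multiple histogram peaks) and must
#' surface.
#'
#' @param x,y Numeric vectors of input / standard intensities.
#' @param labels Optional per-pair tags (e.g. `min`, `BKG`, `GM`, `WM`,
#'   `max` for STI; `min`, `p10` ... `p90`, `p99.8`, `max` for L4).
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(x, y, labels = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (is.null(labels)) labels <- rep("", length(x))
  stopifnot(length(labels) == length(x))
  if (abs(x[1]) > 1e-12 || abs(y[1]) > 1e-12 ||
      abs(x[length(x)] - 100) > 1e-12 || abs(y[length(y)] - 100) > 1e-12)
    stop("landmark set must start at (0,0) and end at (100,100)")
  if (any(diff(x) <= 0))
    stop("landmark conflict: input intensities must be strictly ",
         "increasing (got ", paste(format(x), collapse = ", "), ")")
  if (any(diff(y) < 0))
    stop("non-monotone mapping: standard intensities must be ",
         "nondecreasing (got ", paste(format(y), collapse = ", "), ")")
  structure(list(x = x, y = y, labels = as.character(labels)),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> ", length(x$x), " pairs\n", sep = "")
  print(data.frame(label = x$labels, input = x$x, standard = x$y),
        row.names = FALSE)
  invisible(x)
}

#' Build a piecewise-linear intensity mapping
#'
#' Returns the unique continuous piecewise-linear function through the
#' landmark pairs. The function is total on `[0, 100]` and maps onto
#' `[0, 100]`; evaluating it at a landmark's input intensity returns that
#' landmark's standard intensity exactly.
#'
#' @param landmarks A [landmark_set()].
#' @return An object of class `mapping_function`; evaluate with
#'   [evaluate_mapping()] or apply to a volume with [apply_mapping()].
#' @export
build_mapping <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  structure(list(landmarks = landmarks), class = "mapping_function")
}

#' Evaluate a mapping at scalar intensities
#'
#' @param f A `mapping_function`.
#' @param x Numeric vector of input intensities in `[0, 100]`.
#' @return Mapped intensities, same length as `x`.
#' @export
evaluate_mapping <- function(f, x) {
  stopifnot(inherits(f, "mapping_function"))
  if (any(x < 0 | x > 100, na.rm = TRUE))
    stop("input intensity outside [0, 100]")
  lm <- f$landmarks
  # exact hits first so landmark inputs map to landmark outputs bit-exactly
  out <- stats::approx(lm$x, lm$y, xout = x, method = "linear",
                       ties = "ordered")$y
  hit <- match(x, lm$x)
  has <- !is.na(hit)
  out[has] <- lm$y[hit[has]]
  out
}

#' @export
print.mapping_function <- function(x, ...) {
  cat("<mapping_function> piecewise linear through",
      length(x$landmarks$x), "landmarks\n")
  invisible(x)
}

#' Apply an intensity mapping to a volume
#'
#' Voxel-wise application of a piecewise-linear transfer function.
#'
#' @param volume An [intensity_volume()] with intensities in `[0, 100]`.
#' @param f A `mapping_function` from [build_mapping()].
#' @return A new [intensity_volume()] with mapped intensities in
#'   `[0, 100]`.
#' @export
apply_mapping <- function(volume, f) {
  stopifnot(inherits(volume, "intensity_volume"))
  y <- evaluate_mapping(f, as.vector(volume$data))
  intensity_volume(array(y, dim = volume$shape), spacing = volume$spacing,
                   intensity_scale = c(0, 100))
}

#' Invert a strictly increasing mapping
#'
#' For landmark sets whose y values are strictly increasing the transfer
#' is a bijection of `[0, 100]`; this returns the piecewise-linear inverse
#' (landmarks with axes swapped).
#'
#' @param f A `mapping_function` with strictly increasing y.
#' @return The inverse `mapping_function`.
#' @export
invert_mapping <- function(f) {
  lm <- f$landmarks
  if (any(diff(lm$y) <= 0))
    stop("mapping is not strictly increasing; no piecewise-linear inverse")
  build_mapping(landmark_set(lm$y, lm$x, lm$labels))
}

#' Serialize a mapping to JSON
#'
#' Writes the landmark pairs as an ordered list of `[x, y, label]` triples
#' for provenance and later re-application; [read_mapping_json()] reads it
#' back.
#'
#' @param f A `mapping_function`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_mapping_json <- function(f, path) {
  lm <- f$landmarks
  doc <- list(type = "piecewise_linear_intensity_mapping",
              landmarks = Map(function(x, y, l) list(x, y, l),
                              lm$x, lm$y, lm$labels))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mapping_json
#' @export
read_mapping_json <- function(path) {
  doc <- jsonlite::read_json(path)
  x <- vapply(doc$landmarks, function(t) as.numeric(t[[1]]), 0)
  y <- vapply(doc$landmarks, function(t) as.numeric(t[[2]]), 0)
  labels <- vapply(doc$landmarks, function(t) as.character(t[[3]]), "")
  build_mapping(landmark_set(x, y, labels))
}
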