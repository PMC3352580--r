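#' Phantom specification
#'
#' Geometry and intensity parameters of the synthetic brain phantom that
#' stands in for a standard image: nested ellipsoids on a cubic grid with
#' WM at the core, a GM shell around it, a thin CSF shell, and background
#' outside. Each tissue gets Gaussian intensities around its class mean on
#' the 0--100 scale, clipped to `[0, 100]`. Defaults emulate a
#' T1-weighted contrast: BKG 3, CSF 10 (dark, close to background), GM 45,
#' WM 75, with residual noise sd 2 per tissue (denoising is assumed
#' upstream). CSF is absorbed into the BKG mask by default, matching the
#' STI policy of correcting CSF through background standardization.
#'
#' @param shape Grid dimensions, default `c(64, 64, 64)`.
#' @param tissue_means Named means (`bkg`, `csf`, `gm`, `wm`) on the
#'   0--100 scale; must be ordered BKG < GM < WM.
#' @param noise_sd Per-tissue noise standard deviations (same names), or
#'   one number for all tissues.
#' @param csf_shell Generate the thin CSF shell (default `TRUE`).
#' @param csf_to_bkg Absorb CSF voxels into the BKG mask (default `TRUE`).
#' @param anatomy_jitter Relative jitter of ellipsoid axes/radii across
#'   subjects (default 0.05); set 0 for identical anatomy.
#' @param seed Integer seed making the phantom reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64),
                         tissue_means = c(bkg = 3, csf = 10, gm = 45, wm = 75),
                         noise_sd = c(bkg = 2, csf = 2, gm = 2, wm = 2),
                         csf_shell = TRUE, csf_to_bkg = TRUE,
                         anatomy_jitter = 0.05, seed = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 16L))
  if (length(noise_sd) == 1L)
    noise_sd <- stats::setNames(rep(noise_sd, 4), c("bkg", "csf", "gm", "wm"))
  need <- c("bkg", "csf", "gm", "wm")
  stopifnot(all(need %in% names(tissue_means)),
            all(need %in% names(noise_sd)), all(noise_sd >= 0))
  if (!(tissue_means["bkg"] < tissue_means["gm"] &&
        tissue_means["gm"] < tissue_means["wm"]))
    stop("tissue means must be strictly ordered BKG < GM < WM")
  structure(list(shape = shape, tissue_means = tissue_means[need],
                 noise_sd = noise_sd[need], csf_shell = isTRUE(csf_shell),
                 csf_to_bkg = isTRUE(csf_to_bkg),
                 anatomy_jitter = anatomy_jitter, seed = seed),
            class = "phantom_spec")
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  code
}

#' Generate a tissue-labeled brain phantom
#'
#' Builds the phantom volume and its tissue masks from a [phantom_spec()].
#' Every voxel belongs to exactly one tissue; the returned
#' [tissue_mask_set()] is inherently aligned with the volume, so
#' phantom-based pipelines need no registration.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `volume` (an [intensity_volume()]), `masks` (a
#'   [tissue_mask_set()]) and `labels` (integer array: 0 BKG, 1 CSF, 2 GM,
#'   3 WM).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    sh <- spec$shape
    jit <- function(x) x * (1 + stats::runif(length(x), -1, 1) *
                              spec$anatomy_jitter)
    semi <- jit(c(0.42, 0.45, 0.40)) * sh      # head ellipsoid semi-axes
    ctr <- (sh + 1) / 2 + stats::runif(3, -1, 1) * spec$anatomy_jitter * 4
    # jitter the radial increments so the nesting order is always preserved
    r_wm <- jit(0.55); r_gm <- r_wm + jit(0.30); r_csf <- r_gm + jit(0.07)
    cx <- (seq_len(sh[1]) - ctr[1]) / semi[1]
    cy <- (seq_len(sh[2]) - ctr[2]) / semi[2]
    cz <- (seq_len(sh[3]) - ctr[3]) / semi[3]
    r2 <- outer(outer(cx^2, cy^2, `+`), cz^2, `+`)
    r <- sqrt(r2)
    labels <- array(0L, dim = sh)               # 0 = BKG
    labels[r <= r_csf] <- 1L                    # CSF shell (outermost brain)
    if (!spec$csf_shell) labels[labels == 1L] <- 0L
    labels[r <= r_gm] <- 2L                     # GM shell
    labels[r <= r_wm] <- 3L                     # WM core
    need <- if (spec$csf_shell) c("csf", "gm", "wm") else c("gm", "wm")
    for (t in need)
      if (!any(labels == match(t, c("csf", "gm", "wm"))))
        stop("degenerate geometry: tissue '", t, "' is empty")
    vol <- array(0, dim = sh)
    key <- c(bkg = 0L, csf = 1L, gm = 2L, wm = 3L)
    for (t in names(key)) {
      idx <- labels == key[[t]]
      n <- sum(idx)
      if (n > 0L)
        vol[idx] <- stats::rnorm(n, spec$tissue_means[[t]],
                                 spec$noise_sd[[t]])
    }
    vol[vol < 0] <- 0; vol[vol > 100] <- 100
    masks <- tissue_mask_set(bkg = labels == 0L, wm = labels == 3L,
                             gm = labels == 2L, csf = labels == 1L,
                             csf_to_bkg = spec$csf_to_bkg,
                             provenance = "stimri synthetic phantom")
    list(volume = intensity_volume(vol), masks = masks, labels = labels)
  })
}

as_transfer_function <- function(transfer) {
  if (is.function(transfer)) return(transfer)
  if (is.matrix(transfer) && ncol(transfer) == 2L) {
    x <- transfer[, 1]; y <- transfer[, 2]
    stopifnot(all(diff(x) > 0))
    return(function(v) stats::approx(x, y, xout = v, method = "linear",
                                     rule = 2, ties = "ordered")$y)
  }
  stop("transfer must be a function or a 2-column control-point matrix")
}

check_monotone_transfer <- function(g) {
  grid <- seq(0, 100, by = 0.1)
  vals <- g(grid)
  if (any(!is.finite(vals)) || any(vals < -1e-9) || any(vals > 100 + 1e-9))
    stop("transfer must map [0,100] into [0,100]")
  if (any(diff(vals) < -1e-9))
    stop("non-monotone transfer")
  invisible(TRUE)
}

#' Distortion specification
#'
#' A known, monotone intensity distortion emulating scanner-dependent
#' intensity variation: a nondecreasing transfer `g` mapping `[0, 100]`
#' into itself (smooth function or piecewise-linear control points),
#' followed by additive Gaussian noise and clipping to `[0, 100]`. The
#' transfer is retained so recovery tests can compare estimated landmarks
#' against the ground truth.
#'
#' @param transfer A monotone function on `[0, 100]`, or a 2-column matrix
#'   of `(x, y)` control points interpolated linearly.
#' @param noise_sd Additive Gaussian noise sd (intensity units).
#' @param seed Integer seed for the noise.
#' @param name Free-text label (e.g. a site name).
#' @return An object of class `distortion_spec`.
#' @export
distortion_spec <- function(transfer, noise_sd = 2, seed = NULL,
                            name = "") {
  g <- as_transfer_function(transfer)
  check_monotone_transfer(g)
  stopifnot(noise_sd >= 0)
  structure(list(transfer = g, transfer_points =
                   if (is.matrix(transfer)) transfer else NULL,
                 noise_sd = noise_sd, seed = seed, name = name),
            class = "distortion_spec")
}

#' Apply a known intensity distortion to a volume
#'
#' Voxel-wise application of the spec's monotone transfer, then additive
#' Gaussian noise, then clipping to `[0, 100]`.
#'
#' @param volume An [intensity_volume()] with intensities in `[0, 100]`.
#' @param spec A [distortion_spec()].
#' @return The distorted [intensity_volume()].
#' @export
distort_volume <- function(volume, spec) {
  stopifnot(inherits(volume, "intensity_volume"),
            inherits(spec, "distortion_spec"))
  with_seed(spec$seed, {
    y <- spec$transfer(as.vector(volume$data))
    if (spec$noise_sd > 0)
      y <- y + stats::rnorm(length(y), 0, spec$noise_sd)
    y[y < 0] <- 0; y[y > 100] <- 100
    intensity_volume(array(y, dim = volume$shape),
                     spacing = volume$spacing)
  })
}

#' Default site transfer functions
#'
#' Seven monotone transfers emulating distinct scanners after intensity
#' clamping: an identity reference site, three gamma-style curves and
#' three piecewise-linear contrast changes. Because clamping maps every
#' real input onto the full 0--100 range, realistic site distortions are
#' monotone bijections of `[0, 100]`; all defaults are. They also keep
#' the WM-to-GM separation on the input axis above the 25-unit GM
#' exclusion window, i.e. within the operating envelope the exclusion
#' heuristic assumes (a transfer compressing that gap below the window
#' makes the heuristic itself truncate the GM peak -- a documented
#' limitation, not a scanner the generator should emulate by default).
#'
#' @param n_sites Number of transfers to return (recycled beyond 7).
#' @return A list of transfer objects accepted by [distortion_spec()].
#' @export
default_site_transfers <- function(n_sites = 7) {
  pool <- list(
    identity = function(v) v,
    gamma_dark = function(v) 100 * (v / 100)^1.25,
    gamma_dim = function(v) 100 * (v / 100)^1.1,
    gamma_bright = function(v) 100 * (v / 100)^0.95,
    pwl_sigmoid = rbind(c(0, 0), c(30, 20), c(70, 80), c(100, 100)),
    pwl_shadow = rbind(c(0, 0), c(50, 45), c(80, 78), c(100, 100)),
    pwl_stretch = rbind(c(0, 0), c(20, 15), c(80, 85), c(100, 100)))
  pool[((seq_len(n_sites) - 1L) %% length(pool)) + 1L]
}

#' Generate a multisite phantom suite
#'
#' Emulates a multicenter study design: `n_subjects` phantoms (anatomy
#' varies by subject seed) each "scanned" at `n_sites` sites, where a site
#' is a shared known intensity distortion plus site noise. Every case is
#' an aligned (input, standard, masks) triple -- distortions are
#' intensity-only and geometry is shared within a subject, emulating the
#' post-registration state of a real pipeline. The default design is 3
#' subjects x 7 sites = 21 cases.
#'
#' @param n_subjects,n_sites Positive integers; defaults 3 and 7.
#' @param base A [phantom_spec()] used for every subject (its seed field
#'   is replaced by per-subject seeds derived from `seed`).
#' @param site_transfers List of transfers, one per site; default
#'   [default_site_transfers()].
#' @param site_noise_sd Additive noise sd applied at every site.
#' @param seed Master seed; all subject and site seeds derive from it.
#' @return An object of class `phantom_suite`: a list with `cases` (each
#'   case: `id`, `subject`, `site`, `input`, `standard`, `masks`,
#'   `distortion`) and the generating parameters.
#' @export
generate_multisite_suite <- function(n_subjects = 3, n_sites = 7,
                                     base = phantom_spec(),
                                     site_transfers = NULL,
                                     site_noise_sd = 2, seed = 1) {
  stopifnot(n_subjects >= 1, n_sites >= 1)
  if (is.null(site_transfers))
    site_transfers <- default_site_transfers(n_sites)
  stopifnot(length(site_transfers) == n_sites)
  seeds <- with_seed(seed, matrix(sample.int(.Machine$integer.max - 1L,
                                             n_subjects * (n_sites + 1L)),
                                  nrow = n_subjects))
  cases <- list()
  for (s in seq_len(n_subjects)) {
    spec_s <- base; spec_s$seed <- seeds[s, 1L]
    ph <- generate_phantom(spec_s)
    for (g in seq_len(n_sites)) {
      dspec <- distortion_spec(site_transfers[[g]],
                               noise_sd = site_noise_sd,
                               seed = seeds[s, g + 1L],
                               name = paste0("site", g))
      cases[[length(cases) + 1L]] <- list(
        id = sprintf("sub%d_site%d", s, g), subject = s, site = g,
        input = distort_volume(ph$volume, dspec),
        standard = ph$volume, masks = ph$masks, distortion = dspec)
    }
  }
  structure(list(cases = cases, n_subjects = n_subjects,
                 n_sites = n_sites, base = base, seed = seed),
            class = "phantom_suite")
}

#' @export
print.phantom_suite <- function(x, ...) {
  cat("<phantom_suite> ", x$n_subjects, " subject(s) x ", x$n_sites,
      " site(s) = ", length(x$cases), " cases, grid ",
      paste(x$base$shape, collapse = "x"), "\n", sep = "")
  invisible(x)
}

#' Write a phantom suite to disk
#'
#' Writes each case's input and standard volumes and the tissue masks as
#' NIfTI files plus a manifest JSON recording seeds and ground-truth
#' transfer control points (sampled on a grid for functional transfers).
#'
#' @param suite A `phantom_suite`.
#' @param out_dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_phantom_suite <- function(suite, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(n_subjects = suite$n_subjects, n_sites = suite$n_sites,
                   seed = suite$seed, cases = list())
  written_masks <- character()
  for (cs in suite$cases) {
    stub <- file.path(out_dir, cs$id)
    write_volume(cs$input, paste0(stub, "_input.nii.gz"))
    sub_tag <- paste0("sub", cs$subject)
    if (!(sub_tag %in% written_masks)) {
      write_volume(cs$standard,
                   file.path(out_dir, paste0(sub_tag, "_standard.nii.gz")))
      for (m in c("bkg", "wm", "gm"))
        write_volume(intensity_volume(array(as.numeric(cs$masks[[m]]),
                                            dim = cs$masks$shape)),
                     file.path(out_dir, paste0(sub_tag, "_", m, ".nii.gz")))
      written_masks <- c(written_masks, sub_tag)
    }
    pts <- cs$distortion$transfer_points
    if (is.null(pts)) {
      xs <- seq(0, 100, by = 1)
      pts <- cbind(xs, cs$distortion$transfer(xs))
    }
    manifest$cases[[cs$id]] <- list(
      subject = cs$subject, site = cs$site,
      noise_sd = cs$distortion$noise_sd, seed = cs$distortion$seed,
      transfer_points = apply(unname(pts), 1, as.list))
  }
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
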