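#' Voxelwise mean absolute error over a voxel set
#'
#' `MAE = (1/N) * sum_v |I_o,v - I_s,v|` over the N voxels of the set,
#' where `I_o` is the (standardized) output image and `I_s` the standard
#' image. Since both intensity scales run from 0 to 100, the MAE can be
#' read as a percentage.
#'
#' @param output_vol,standard_vol Aligned [intensity_volume()]s with
#'   intensities in `[0, 100]`.
#' @param voxel_set A [voxel_set()] (or binary 3D array) on the same grid.
#' @return The MAE, a single number in `[0, 100]`.
#' @export
mean_absolute_error <- function(output_vol, standard_vol, voxel_set) {
  validate_aligned(output_vol, standard_vol)
  m <- if (inherits(voxel_set, "voxel_set")) voxel_set$mask
       else coerce_mask(voxel_set)
  validate_aligned(output_vol, m)
  if (!any(m)) stop("empty voxel set")
  mean(abs(output_vol$data[m] - standard_vol$data[m]))
}

#' Paired comparison of two MAE samples
#'
#' Two-sided paired t-test on matched per-image MAE values (each element
#' of `mae_a` and `mae_b` comes from the same image under two conditions).
#'
#' @param mae_a,mae_b Equal-length numeric vectors, `n >= 2`, matched by
#'   image.
#' @return A list with `t` (statistic for a - b), `df` and `p`.
#' @export
compare_paired <- function(mae_a, mae_b) {
  if (length(mae_a) != length(mae_b)) stop("length mismatch")
  if (length(mae_a) < 2L) stop("need at least 2 matched pairs")
  d <- mae_a - mae_b
  if (stats::sd(d) == 0)
    return(list(t = 0, df = length(d) - 1L, p = 1))
  tt <- stats::t.test(mae_a, mae_b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Fraction of images worsened by standardization
#'
#' Percentage of matched images for which the standardized MAE is strictly
#' higher than the unstandardized (original) MAE.
#'
#' @param mae_standardized,mae_original Equal-length matched numeric
#'   vectors.
#' @return Percentage in `[0, 100]`.
#' @export
worsened_fraction <- function(mae_standardized, mae_original) {
  if (length(mae_standardized) != length(mae_original))
    stop("length mismatch")
  100 * sum(mae_standardized > mae_original) / length(mae_original)
}

#' Evaluate a batch of standardized cases
#'
#' Computes the MAE of every condition of every case on three voxel sets
#' -- the standard image's FRG (recomputed per standard volume and
#' cached), WM and GM from the tissue masks -- and summarizes: paired
#' t-tests between all condition pairs and, when an `"Original"`
#' condition is present, the worsened fraction of each other condition
#' against it, per voxel set.
#'
#' @param cases A list of cases; each case is a list with fields
#'   `standard` (an [intensity_volume()]), `masks` (a
#'   [tissue_mask_set()]), `outputs` (named list of condition label ->
#'   aligned output [intensity_volume()]) and optionally `id`.
#' @param original_label Condition treated as "no standardization" for
#'   the worsened-fraction summary; default `"Original"`.
#' @return An object of class `mae_report`: `mae` (long data frame: case,
#'   voxel_set, condition, mae), `tests` (paired t-tests per voxel set and
#'   condition pair) and `worsened` (percent per condition and voxel set),
#'   plus `conditions` and `voxel_sets`.
#' @export
evaluate_batch <- function(cases, original_label = "Original") {
  stopifnot(is.list(cases), length(cases) >= 1L)
  frg_cache <- new.env(parent = emptyenv())
  rows <- list()
  for (k in seq_along(cases)) {
    cs <- cases[[k]]
    id <- if (!is.null(cs$id)) as.character(cs$id) else paste0("case", k)
    stopifnot(inherits(cs$standard, "intensity_volume"),
              inherits(cs$masks, "tissue_mask_set"),
              is.list(cs$outputs), length(cs$outputs) >= 1L,
              !is.null(names(cs$outputs)))
    key <- paste0("v", format(sum(cs$standard$data), digits = 17), "_",
                  paste(cs$standard$shape, collapse = "x"))
    if (is.null(frg_cache[[key]]))
      frg_cache[[key]] <- compute_frg_mask(cs$standard)
    sets <- list(FRG = frg_cache[[key]],
                 WM = voxel_set(cs$masks$wm, "WM"),
                 GM = voxel_set(cs$masks$gm, "GM"))
    for (cond in names(cs$outputs)) {
      out <- cs$outputs[[cond]]
      validate_aligned(out, cs$standard)
      for (vs in names(sets))
        rows[[length(rows) + 1L]] <- data.frame(
          case = id, voxel_set = vs, condition = cond,
          mae = mean_absolute_error(out, cs$standard, sets[[vs]]))
    }
  }
  mae <- do.call(rbind, rows)
  conditions <- unique(mae$condition)
  voxel_sets <- unique(mae$voxel_set)

  wide <- function(vs, cond) mae$mae[mae$voxel_set == vs &
                                     mae$condition == cond]
  tests <- NULL
  if (length(conditions) >= 2L && length(unique(mae$case)) >= 2L) {
    pairs <- utils::combn(conditions, 2L, simplify = FALSE)
    tests <- do.call(rbind, lapply(voxel_sets, function(vs) {
      do.call(rbind, lapply(pairs, function(pr) {
        ct <- compare_paired(wide(vs, pr[1]), wide(vs, pr[2]))
        data.frame(voxel_set = vs, condition_a = pr[1],
                   condition_b = pr[2], t = ct$t, df = ct$df, p = ct$p)
      }))
    }))
  }
  worsened <- NULL
  if (original_label %in% conditions) {
    others <- setdiff(conditions, original_label)
    if (length(others) > 0L)
      worsened <- do.call(rbind, lapply(voxel_sets, function(vs) {
        do.call(rbind, lapply(others, function(cond) data.frame(
          voxel_set = vs, condition = cond,
          worsened_pct = worsened_fraction(wide(vs, cond),
                                           wide(vs, original_label)))))
      }))
  }
  structure(list(mae = mae, tests = tests, worsened = worsened,
                 conditions = conditions, voxel_sets = voxel_sets),
            class = "mae_report")
}

#' @export
print.mae_report <- function(x, ...) {
  cat("<mae_report> ", length(unique(x$mae$case)), " case(s), conditions: ",
      paste(x$conditions, collapse = ", "), "\n", sep = "")
  med <- stats::aggregate(mae ~ voxel_set + condition, data = x$mae,
                          FUN = stats::median)
  names(med)[3] <- "median_mae"
  print(med, row.names = FALSE)
  if (!is.null(x$tests)) { cat("paired t-tests:\n"); print(x$tests, row.names = FALSE) }
  if (!is.null(x$worsened)) { cat("worsened fraction (%):\n"); print(x$worsened, row.names = FALSE) }
  invisible(x)
}

#' Boxplots of per-case MAE by condition and voxel set
#'
#' One panel per voxel set, one box per condition.
#'
#' @param x An `mae_report`.
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot.mae_report <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, length(x$voxel_sets)))
  on.exit(graphics::par(old))
  for (vs in x$voxel_sets) {
    d <- x$mae[x$mae$voxel_set == vs, ]
    graphics::boxplot(mae ~ factor(condition, levels = x$conditions),
                      data = d, main = vs, xlab = "", ylab = "MAE (%)",
                      ...)
  }
  invisible(x)
}

#' Write an MAE report to disk
#'
#' CSV with one row per case x voxel set x condition, plus a JSON summary
#' (median MAE per voxel set and condition, paired tests, worsened
#' fractions).
#'
#' @param report An `mae_report`.
#' @param csv_path,json_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, the list written as JSON.
#' @export
write_mae_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(report$mae, csv_path, row.names = FALSE)
  med <- stats::aggregate(mae ~ voxel_set + condition, data = report$mae,
                          FUN = stats::median)
  summary <- list(median_mae = med, tests = report$tests,
                  worsened = report$worsened)
  if (!is.null(json_path))
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  invisible(summary)
}
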