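#' Standardize a difference image into a z-map
#'
#' Converts a subtraction image into SD units using its own global mean and
#' standard deviation computed over the inclusion mask only (stroke areas are
#' excluded by the caller). Voxels outside the mask carry values but are
#' flagged excluded.
#'
#' @param diff A difference [volume()].
#' @param include Logical inclusion mask on the same grid.
#' @param sd_type `"population"` (divide by N, the default: the map's own
#'   global statistics) or `"sample"` (divide by N - 1).
#' @param mid_index Optional 1-based left-right index of the mid-sagittal
#'   plane (defaults to the grid centre when the LR dimension is odd).
#' @return An object of class `perf_zmap` with fields `values`, `include`,
#'   `mean_used`, `sd_used`, `grid`, `mid_index`.
#' @export
zscore_map <- function(diff, include, sd_type = c("population", "sample"),
                       mid_index = NULL) {
  stopifnot(inherits(diff, "perf_volume"))
  sd_type <- match.arg(sd_type)
  if (!any(include)) stop("inclusion mask is empty", call. = FALSE)
  vals <- diff$data[include]
  m <- mean(vals)
  s <- if (sd_type == "population") sqrt(mean((vals - m)^2)) else stats::sd(vals)
  if (!is.finite(s) || s < 1e-12)
    stop(errorCondition(
      "degenerate z-map: zero variance over the inclusion mask",
      class = c("perfusym_degenerate_map", "error", "condition")))
  d1 <- dim(diff$data)[1L]
  if (is.null(mid_index))
    mid_index <- if (d1 %% 2L == 1L) (d1 + 1L) / 2L else NA_real_
  structure(list(values = (diff$data - m) / s,
                 include = include,
                 mean_used = m, sd_used = s, sd_type = sd_type,
                 grid = as_grid(diff), mid_index = mid_index),
            class = "perf_zmap")
}

#' @export
print.perf_zmap <- function(x, ...) {
  cat(sprintf("<perf_zmap> %s voxels in inclusion mask, mean_used %.4g, sd_used %.4g\n",
              format(sum(x$include)), x$mean_used, x$sd_used))
  invisible(x)
}
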