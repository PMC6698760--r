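# Cumulative dose-volume histograms and the clinical metrics computed from
# them. A DVH gives, for each dose D, the fraction of a structure's volume
# receiving at least that dose:
#
#   DVH(D) = 1 - integral_0^D p_D(x) dx        (predicted, from a density)
#   DVH(D) = #{voxels with x > D} / M          (achieved, from dose samples)
#
# Vd cut-points use the strict "received dose higher than d" convention.

#' Construct a DVH curve
#'
#' @param dose_axis ascending Gy values starting at 0, uniform bin.
#' @param volume_fraction values in `[0, 1]`, non-increasing, `= 1` at dose 0.
#' @param structure structure label.
#' @param kind `"predicted"` or `"achieved"`.
#' @export
dvh_curve <- function(dose_axis, volume_fraction, structure = NA_character_,
                      kind = c("predicted", "achieved")) {
  kind <- match.arg(kind)
  check_uniform_axis(dose_axis)
  if (abs(dose_axis[1]) > 1e-12)
    kb_stop("contract_error", "DVH dose axis must start at 0 Gy")
  if (length(volume_fraction) != length(dose_axis))
    kb_stop("contract_error", "axis and volume fraction lengths differ")
  if (any(diff(volume_fraction) > 1e-9))
    kb_stop("contract_error", "DVH must be non-increasing")
  structure(list(structure = structure, kind = kind,
                 dose_axis = as.numeric(dose_axis),
                 volume_fraction = pmin(pmax(as.numeric(volume_fraction), 0), 1)),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("dvh_curve '%s' (%s), axis [0, %.1f] Gy, mean %.2f Gy\n",
              x$structure, x$kind, max(x$dose_axis), dvh_mean(x)))
  invisible(x)
}

#' Cumulative DVH from a predicted dose density
#'
#' `DVH(D) = 1 - integral_0^D p_D(x) dx` by cumulative trapezoid on the
#' density's own axis, clipped into `[0, 1]`.
#'
#' @param p a `predicted_density` (trapezoid-normalized; deviation of the
#'   integral beyond 1e-3 is a contract error).
#' @param structure structure label for the curve.
#' @return A [dvh_curve()] of kind `"predicted"`.
#' @export
density_to_dvh <- function(p, structure = NA_character_) {
  z <- trapz(p$dose_axis, p$density)
  if (abs(z - 1) > 1e-3)
    kb_stop("contract_error", "density integrates to %.6f, not 1", z)
  vf <- 1 - cumtrapz(p$dose_axis, p$density)
  vf <- pmin(pmax(vf, 0), 1)
  vf <- rev(cummax(rev(vf)))  # guard round-off monotonicity
  dvh_curve(p$dose_axis, vf, structure, kind = "predicted")
}

#' Achieved DVH from voxel dose samples
#'
#' `DVH(D)` is the fraction of samples strictly above `D` at every axis point
#' except 0, where the curve is 1 by definition (all volume receives >= 0 Gy).
#'
#' @param x nonempty voxel doses, Gy.
#' @param dx axis bin width, Gy.
#' @param x_max axis upper end, `>= max(x)`.
#' @param structure structure label.
#' @return A [dvh_curve()] of kind `"achieved"`.
#' @export
samples_to_dvh <- function(x, dx = 0.1, x_max = NULL, structure = NA_character_) {
  if (length(x) == 0) kb_stop("model_input_error", "samples_to_dvh: no samples")
  x_max <- x_max %||% (ceiling(max(x) / dx) * dx + dx)
  if (x_max < max(x))
    kb_stop("model_input_error", "x_max below the largest sample")
  axis <- seq(0, x_max, by = dx)
  # fraction strictly above each axis point, via the sorted-sample ecdf
  sx <- sort(x)
  vf <- 1 - findInterval(axis, sx, left.open = FALSE) / length(x)
  vf[1] <- 1
  curve <- dvh_curve(axis, vf, structure, kind = "achieved")
  curve$samples <- as.numeric(x)
  curve
}

#' Mean dose of a DVH curve, Gy
#'
#' For a nonnegative dose distribution the mean equals the area under the
#' cumulative DVH, `integral DVH(D) dD`; for an achieved curve carrying its
#' samples the exact sample mean is used.
#'
#' @param curve a [dvh_curve()].
#' @export
dvh_mean <- function(curve) {
  if (!is.null(curve$samples)) return(mean(curve$samples))
  trapz(curve$dose_axis, curve$volume_fraction)
}

#' DVH value at arbitrary doses
#'
#' Linear interpolation of the volume fraction on the curve's axis.
#'
#' @param curve a [dvh_curve()].
#' @param d doses, Gy, within the axis.
#' @export
dvh_at <- function(curve, d) {
  if (any(d < 0) || any(d > max(curve$dose_axis) + 1e-9))
    kb_stop("range_error", "cut-point %.1f Gy beyond the DVH axis", max(d))
  stats::approx(curve$dose_axis, curve$volume_fraction, xout = d, rule = 2)$y
}

#' Clinical DVH metrics: mean dose, Vd cut-points, near-maximum
#'
#' `Vd = 100 * DVH(d)` — percent volume receiving dose higher than `d` Gy.
#' The near-max is the smallest axis dose where the DVH falls to
#' `near_max_fraction` (default 0.001, i.e. D0.1%), a surrogate for the
#' maximum dose which a density model cannot bound; for achieved curves built
#' from samples the literal sample maximum is reported instead.
#'
#' @param curve a [dvh_curve()] (achieved curves may carry raw samples).
#' @param cutpoints numeric cut doses d, Gy, within the axis.
#' @param near_max_fraction volume fraction defining the near-max.
#' @return An object of class `dvh_metrics`: `mean_gy`, named `v_cutpoints`
#'   (percent), `near_max_gy`.
#' @export
dvh_metrics <- function(curve, cutpoints = numeric(0), near_max_fraction = 0.001) {
  v <- if (length(cutpoints)) 100 * dvh_at(curve, cutpoints) else numeric(0)
  names(v) <- if (length(cutpoints)) sprintf("V%g", cutpoints) else NULL
  if (!is.null(curve$samples)) {
    nm <- max(curve$samples)
  } else {
    below <- which(curve$volume_fraction <= near_max_fraction)
    nm <- if (length(below)) curve$dose_axis[below[1]] else max(curve$dose_axis)
  }
  structure(list(mean_gy = dvh_mean(curve), v_cutpoints = v, near_max_gy = nm),
            class = "dvh_metrics")
}

#' @export
print.dvh_metrics <- function(x, ...) {
  cat(sprintf("mean %.2f Gy; near-max %.2f Gy", x$mean_gy, x$near_max_gy))
  if (length(x$v_cutpoints))
    cat("; ", paste(sprintf("%s=%.1f%%", names(x$v_cutpoints), x$v_cutpoints),
                    collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}

#' Export DVH curves as a long data frame
#'
#' Columns `structure`, `kind`, `dose_gy`, `volume_pct`.
#'
#' @param curves one [dvh_curve()] or a list of them.
#' @export
dvh_as_data_frame <- function(curves) {
  if (inherits(curves, "dvh_curve")) curves <- list(curves)
  do.call(rbind, lapply(curves, function(cv)
    data.frame(structure = cv$structure, kind = cv$kind,
               dose_gy = cv$dose_axis, volume_pct = 100 * cv$volume_fraction)))
}
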