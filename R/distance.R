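# Signed distance to the PTV boundary and assembly of (t, x) training pairs.
#
# Convention: center-to-center. For a voxel outside the PTV, t is the Euclidean
# distance (mm, anisotropic spacing respected) from its center to the nearest
# PTV voxel center; inside, t is minus the distance to the nearest non-PTV
# center. |t| is therefore never 0 — every voxel is strictly inside or outside.

#' Signed distance field to a target mask
#'
#' Exact Euclidean distance transform (separable lower-envelope algorithm) of
#' the PTV occupancy and of its complement, combined into one signed field:
#' negative inside the PTV, positive outside. If the PTV fills the whole grid,
#' inside distances fall back to the distance to the nearest grid boundary
#' face.
#'
#' @param ptv a non-empty [structure_mask()] with role `"target"`.
#' @return An object of class `signed_distance_field`: `grid` plus array `t`
#'   (mm, `dim == grid$shape`).
#' @export
signed_distance_field <- function(ptv) {
  if (!inherits(ptv, "structure_mask") || ptv$role != "target")
    kb_stop("model_input_error", "signed_distance_field needs a target-role mask")
  if (ptv$empty)
    kb_stop("model_input_error", "signed_distance_field: PTV mask is empty")
  grid <- ptv$grid
  occ <- ptv$occupancy
  d_out <- sqrt(cpp_edt_sq(as.logical(occ), grid$shape, grid$spacing))
  if (all(occ)) {
    # distance from each center to the nearest outer face of the grid box
    ax <- grid_axes(grid)
    lo <- grid$origin - grid$spacing / 2
    hi <- grid$origin + (grid$shape - 0.5) * grid$spacing
    dx <- pmin(ax$x - lo[1], hi[1] - ax$x)
    dy <- pmin(ax$y - lo[2], hi[2] - ax$y)
    dz <- pmin(ax$z - lo[3], hi[3] - ax$z)
    d_in <- pmin(outer(outer(dx, dy, pmin), dz, pmin))
    d_in <- array(d_in, dim = grid$shape)
  } else {
    d_in <- sqrt(cpp_edt_sq(as.logical(!occ), grid$shape, grid$spacing))
  }
  t_arr <- array(ifelse(occ, -d_in, d_out), dim = grid$shape)
  structure(list(grid = grid, t = t_arr), class = "signed_distance_field")
}

#' Extract paired (distance, dose) samples for one structure
#'
#' One `(t, x)` pair per occupied OAR voxel, in voxel-index (column-major)
#' order. If the voxel count exceeds `max_samples`, a uniform random subsample
#' of exactly `max_samples` pairs is drawn under `seed` (deterministic,
#' logged); the cap keeps kernel-density training tractable at desk scale.
#'
#' @param oar a non-empty [structure_mask()].
#' @param sdf a [signed_distance_field()] on the same grid.
#' @param dose a [dose_grid()] on the same grid.
#' @param max_samples subsampling cap (default 20000 voxels per structure).
#' @param seed integer seed for the subsample draw.
#' @return An object of class `distance_dose_samples`: `structure`, `plan_id`,
#'   numeric vectors `t` (mm) and `x` (Gy), `voxel_volume` (mm^3).
#' @export
extract_samples <- function(oar, sdf, dose, max_samples = 20000L, seed = 1L) {
  if (!grid_equal(oar$grid, sdf$grid) || !grid_equal(oar$grid, dose$grid))
    kb_stop("geometry_error", "extract_samples: mask, distance field and dose share no grid")
  if (oar$empty)
    kb_stop("model_input_error", "extract_samples: OAR '%s' is empty", oar$name)
  idx <- which(oar$occupancy)
  tt <- sdf$t[idx]
  xx <- dose$dose[idx]
  if (length(idx) > max_samples) {
    keep <- with_seed(seed, sort(sample.int(length(idx), max_samples)))
    kb_log("extract_samples: '%s' subsampled %d -> %d voxels (seed %d)",
           oar$name, length(idx), max_samples, seed)
    tt <- tt[keep]; xx <- xx[keep]
  }
  distance_dose_samples(oar$name, tt, xx,
                        voxel_volume = voxel_volume(oar$grid))
}

#' Construct a (t, x) sample table
#'
#' @param structure structure label.
#' @param t signed distances, mm.
#' @param x doses, Gy (same length, >= 0).
#' @param plan_id plan identifier.
#' @param voxel_volume voxel volume, mm^3.
#' @export
distance_dose_samples <- function(structure, t, x, plan_id = NA_character_,
                                  voxel_volume = NA_real_) {
  if (length(t) != length(x) || length(t) < 1)
    kb_stop("model_input_error", "t and x must be nonempty and the same length")
  if (any(!is.finite(t)) || any(!is.finite(x)) || any(x < 0))
    kb_stop("model_input_error", "t must be finite, x finite and >= 0")
  structure(list(structure = structure, plan_id = plan_id,
                 t = as.numeric(t), x = as.numeric(x),
                 voxel_volume = voxel_volume),
            class = "distance_dose_samples")
}

#' Export sample tables as a data frame
#'
#' Long-format table with columns `plan_id`, `structure`, `t_mm`, `dose_gy`,
#' suitable for CSV export.
#'
#' @param samples one `distance_dose_samples` or a list of them.
#' @export
samples_as_data_frame <- function(samples) {
  if (inherits(samples, "distance_dose_samples")) samples <- list(samples)
  do.call(rbind, lapply(samples, function(s)
    data.frame(plan_id = s$plan_id, structure = s$structure,
               t_mm = s$t, dose_gy = s$x)))
}
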