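# Voxel-lattice geometry shared by every other module: axis-aligned grids in mm
# (patient-style world coordinates), binary structure masks, dose arrays in Gy,
# planar contour sets, and the three operations on them (contour rasterization,
# mask subtraction, trilinear dose resampling).

#' Axis-aligned voxel lattice
#'
#' The shared geometry frame of the package. World coordinates are in mm; the
#' `origin` is the world coordinate of the *center* of voxel index `(1,1,1)`
#' (R indexing; 0-based `(0,0,0)` in the storage convention). Arrays on a grid
#' are stored column-major with x fastest, i.e. `dim = shape`.
#'
#' @param shape integer triple `(nx, ny, nz)`, all >= 1.
#' @param spacing mm triple, all > 0.
#' @param origin mm triple, world coordinate of the first voxel center.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || any(shape < 1L))
    kb_stop("geometry_error", "shape must be 3 integers >= 1")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    kb_stop("geometry_error", "spacing must be 3 positive finite mm values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    kb_stop("geometry_error", "origin must be 3 finite mm values")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid %dx%dx%d, spacing %.3gx%.3gx%.3g mm, origin (%.3g, %.3g, %.3g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Voxel volume of a grid in mm^3
#' @param grid a [volume_grid()].
#' @export
voxel_volume <- function(grid) prod(grid$spacing)

#' Per-axis voxel-center coordinates of a grid
#' @param grid a [volume_grid()].
#' @return list with numeric vectors `x`, `y`, `z` (mm).
#' @export
grid_axes <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$shape[1]) - 1) * grid$spacing[1],
       y = grid$origin[2] + (seq_len(grid$shape[2]) - 1) * grid$spacing[2],
       z = grid$origin[3] + (seq_len(grid$shape[3]) - 1) * grid$spacing[3])
}

grid_equal <- function(a, b, tol = 1e-9) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Binary structure occupancy on a grid
#'
#' @param grid a [volume_grid()].
#' @param occupancy logical array with `dim == grid$shape` (or a logical vector
#'   of matching length).
#' @param name structure label.
#' @param role `"target"` (PTV) or `"oar"`.
#' @return An object of class `structure_mask`. An all-`FALSE` mask is
#'   constructible but carries `empty = TRUE`.
#' @export
structure_mask <- function(grid, occupancy, name, role = c("oar", "target")) {
  role <- match.arg(role)
  occupancy <- array(as.logical(occupancy), dim = grid$shape)
  if (anyNA(occupancy)) kb_stop("geometry_error", "occupancy contains NA")
  structure(list(grid = grid, occupancy = occupancy, name = name, role = role,
                 empty = !any(occupancy)),
            class = "structure_mask")
}

#' Number of occupied voxels of a mask
#' @param mask a [structure_mask()].
#' @export
mask_count <- function(mask) sum(mask$occupancy)

#' Structure volume in mm^3 (occupied voxels times voxel volume)
#' @param mask a [structure_mask()].
#' @export
mask_volume <- function(mask) mask_count(mask) * voxel_volume(mask$grid)

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("structure_mask '%s' (%s): %d voxels, %.1f cm^3%s\n",
              x$name, x$role, mask_count(x), mask_volume(x) / 1000,
              if (x$empty) " [EMPTY]" else ""))
  invisible(x)
}

#' Dose array (Gy) on a grid
#' @param grid a [volume_grid()].
#' @param dose numeric array of doses in Gy, `dim == grid$shape`, finite, >= 0.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(grid, dose) {
  dose <- array(as.numeric(dose), dim = grid$shape)
  if (any(!is.finite(dose)) || any(dose < 0))
    kb_stop("geometry_error", "dose values must be finite and >= 0 Gy")
  structure(list(grid = grid, dose = dose), class = "dose_grid")
}

#' Planar contour set for one structure
#'
#' Closed planar polygons, one or more per axial slice, as exchanged by
#' DICOM RT Structure Sets. Each contour is a list with `z` (slice
#' z-coordinate, mm) and `xy` (n x 2 matrix of vertices in mm; the polygon is
#' implicitly closed from the last vertex back to the first).
#'
#' @param name structure label.
#' @param contours list of `list(z =, xy =)` entries; each polygon needs >= 3
#'   vertices.
#' @return An object of class `contour_set`.
#' @export
contour_set <- function(name, contours) {
  for (ct in contours) {
    if (is.null(ct$xy) || !is.matrix(ct$xy) || ncol(ct$xy) != 2 || nrow(ct$xy) < 3)
      kb_stop("invalid_contour_error",
              "contour of '%s' has fewer than 3 vertices", name)
    if (is.null(ct$z) || !is.finite(ct$z))
      kb_stop("invalid_contour_error", "contour of '%s' lacks a slice z", name)
  }
  structure(list(name = name, contours = contours), class = "contour_set")
}

# Even-odd (crossing-count) point-in-polygon test, vectorized over points.
# Points lying exactly on a polygon edge are nudged toward the polygon
# centroid by a small fraction of `nudge` (half a voxel in practice) and
# retested: a deterministic tie-break.
point_in_polygon <- function(px, py, poly, nudge = 0) {
  vx <- poly[, 1]; vy <- poly[, 2]
  nv <- length(vx)
  jx <- c(vx[-1], vx[1]); jy <- c(vy[-1], vy[1])
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  eps <- 1e-9
  for (e in seq_len(nv)) {
    x1 <- vx[e]; y1 <- vy[e]; x2 <- jx[e]; y2 <- jy[e]
    crosses <- (y1 > py) != (y2 > py)
    if (any(crosses)) {
      xint <- x1 + (py[crosses] - y1) * (x2 - x1) / (y2 - y1)
      flip <- px[crosses] < xint
      inside[crosses] <- xor(inside[crosses], flip)
    }
    # on-segment detection for the tie-break
    ex <- x2 - x1; ey <- y2 - y1
    len2 <- ex * ex + ey * ey
    if (len2 > 0) {
      cross <- abs((px - x1) * ey - (py - y1) * ex)
      dot <- (px - x1) * ex + (py - y1) * ey
      on_edge <- on_edge | (cross <= eps * sqrt(len2) & dot >= -eps & dot <= len2 + eps)
    }
  }
  if (nudge > 0 && any(on_edge)) {
    cx <- mean(vx); cy <- mean(vy)
    dx <- cx - px[on_edge]; dy <- cy - py[on_edge]
    nrm <- sqrt(dx * dx + dy * dy)
    nrm[nrm == 0] <- 1
    inside[on_edge] <- point_in_polygon(px[on_edge] + nudge * dx / nrm,
                                        py[on_edge] + nudge * dy / nrm,
                                        poly, nudge = 0)
  }
  inside
}

#' Rasterize planar contours onto a grid
#'
#' A voxel is occupied iff its center lies inside an odd number of that
#' slice's polygons (even-odd rule, so ring-shaped structures with holes come
#' out right). Contours whose z matches no grid slice within half a slice
#' spacing are ignored with a warning.
#'
#' @param contours a [contour_set()].
#' @param grid a [volume_grid()].
#' @param role role for the resulting mask.
#' @return A [structure_mask()].
#' @export
rasterize_contours <- function(contours, grid, role = "oar") {
  occ <- array(FALSE, dim = grid$shape)
  ax <- grid_axes(grid)
  if (length(contours$contours) == 0) {
    kb_warn("empty_contour_warning", "contour set '%s' is empty", contours$name)
    return(structure_mask(grid, occ, contours$name, role))
  }
  ctr <- expand.grid(px = ax$x, py = ax$y)  # in-plane centers, x fastest
  half_dz <- grid$spacing[3] / 2
  nudge <- min(grid$spacing[1:2]) * 1e-3
  for (ct in contours$contours) {
    k <- which.min(abs(ax$z - ct$z))
    if (abs(ax$z[k] - ct$z) > half_dz + 1e-9) {
      kb_warn("contour_slice_warning",
              "contour of '%s' at z=%.3f mm matches no grid slice; ignored",
              contours$name, ct$z)
      next
    }
    inside <- point_in_polygon(ctr$px, ctr$py, ct$xy, nudge = nudge)
    occ[, , k] <- xor(occ[, , k], array(inside, dim = grid$shape[1:2]))
  }
  if (!any(occ))
    kb_warn("empty_mask_warning", "rasterization of '%s' produced an empty mask",
            contours$name)
  structure_mask(grid, occ, contours$name, role)
}

#' Boolean subtraction of structure masks
#'
#' Occupied where `a` is occupied and `b` is not; the standard construction of
#' derived structures such as lung minus PTV ("Lung-PTV").
#'
#' @param a,b [structure_mask()]s on the same grid.
#' @return A [structure_mask()] named `"<a>-<b>"` with `a`'s role.
#' @export
subtract_masks <- function(a, b) {
  if (!grid_equal(a$grid, b$grid))
    kb_stop("geometry_error", "subtract_masks: masks live on different grids")
  occ <- a$occupancy & !b$occupancy
  if (!any(occ))
    kb_warn("empty_mask_warning", "'%s' minus '%s' is empty", a$name, b$name)
  structure_mask(a$grid, occ, paste0(a$name, "-", b$name), a$role)
}

#' Resample a dose grid onto another lattice
#'
#' Trilinear interpolation at each target voxel center. Target centers outside
#' the source extent receive 0 Gy; their count is logged (a frequent artifact
#' of clinical dose exports, surfaced rather than silently zeroed).
#'
#' @param dose a [dose_grid()].
#' @param target a [volume_grid()] that spatially overlaps the dose extent.
#' @return A [dose_grid()] on `target`.
#' @export
resample_dose <- function(dose, target) {
  src <- dose$grid
  if (grid_equal(src, target)) return(dose_grid(target, dose$dose))
  # overlap of voxel-center extents
  lo_s <- src$origin; hi_s <- src$origin + (src$shape - 1) * src$spacing
  lo_t <- target$origin; hi_t <- target$origin + (target$shape - 1) * target$spacing
  if (any(lo_t > hi_s + 1e-9) || any(hi_t < lo_s - 1e-9))
    kb_stop("geometry_error", "resample_dose: target grid does not overlap dose extent")

  ax <- grid_axes(target)
  nt <- prod(target$shape)
  # continuous 0-based source index of every target center, per axis
  u1 <- (ax$x - src$origin[1]) / src$spacing[1]
  u2 <- (ax$y - src$origin[2]) / src$spacing[2]
  u3 <- (ax$z - src$origin[3]) / src$spacing[3]
  U1 <- rep(u1, times = target$shape[2] * target$shape[3])
  U2 <- rep(rep(u2, each = target$shape[1]), times = target$shape[3])
  U3 <- rep(u3, each = target$shape[1] * target$shape[2])
  tol <- 1e-9
  inext <- U1 >= -tol & U1 <= src$shape[1] - 1 + tol &
           U2 >= -tol & U2 <= src$shape[2] - 1 + tol &
           U3 >= -tol & U3 <= src$shape[3] - 1 + tol
  n_out <- sum(!inext)
  if (n_out > 0)
    kb_log("resample_dose: %d of %d target voxels outside dose extent set to 0 Gy",
           n_out, nt)

  interp_axis <- function(u, n) {
    u <- pmin(pmax(u, 0), n - 1)
    i0 <- pmin(floor(u), max(n - 2, 0))
    list(i0 = i0, f = u - i0)
  }
  a1 <- interp_axis(U1, src$shape[1])
  a2 <- interp_axis(U2, src$shape[2])
  a3 <- interp_axis(U3, src$shape[3])
  nx <- src$shape[1]; nxy <- nx * src$shape[2]
  d <- dose$dose
  s1 <- if (src$shape[1] > 1) 1 else 0
  s2 <- if (src$shape[2] > 1) nx else 0
  s3 <- if (src$shape[3] > 1) nxy else 0
  base <- 1 + a1$i0 + a2$i0 * nx + a3$i0 * nxy
  f1 <- a1$f; f2 <- a2$f; f3 <- a3$f
  val <- d[base]                    * (1 - f1) * (1 - f2) * (1 - f3) +
         d[base + s1]               * f1       * (1 - f2) * (1 - f3) +
         d[base + s2]               * (1 - f1) * f2       * (1 - f3) +
         d[base + s1 + s2]          * f1       * f2       * (1 - f3) +
         d[base + s3]               * (1 - f1) * (1 - f2) * f3 +
         d[base + s1 + s3]          * f1       * (1 - f2) * f3 +
         d[base + s2 + s3]          * (1 - f1) * f2       * f3 +
         d[base + s1 + s2 + s3]     * f1       * f2       * f3
  val[!inext] <- 0
  out <- dose_grid(target, array(val, dim = target$shape))
  attr(out, "n_out_of_extent") <- n_out
  out
}
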