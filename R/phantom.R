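# Synthetic esophageal-like plan cohorts with a known conditional dose law.
#
# Geometry: a central elongated target ellipsoid (jittered per plan), two
# large lateral lung-like ellipsoids, a heart-like ellipsoid overlapping the
# target (exercising the negative-distance branch), and a thin posterior
# cord-like cylinder in the sparse distal tail. Dose at a voxel with signed
# distance t to the target:
#
#   x = D_rx * S(t) + eta,   S(t) = 1 / (1 + exp((t - t0) / tau_plan)),
#
# eta drawn from a Normal(0, sigma_a^2) truncated so x >= 0; tau_plan is the
# cohort falloff scale times a log-normal per-plan multiplier. Because dose
# depends on geometry only through t, the conditional model the package fits
# holds exactly in this world, and the analytic DVH below is an oracle.

#' Specification of a synthetic phantom cohort
#'
#' Defaults describe a desk-scale esophageal-like cohort: 64^3 voxels at 4 mm,
#' 50 Gy prescription, sigmoid falloff with 10 mm offset and 4 mm scale, 1 Gy
#' voxel noise, and 10% log-normal inter-plan variability of the falloff
#' scale.
#'
#' @param shape,spacing grid shape and spacing (mm).
#' @param d_rx prescription dose, Gy.
#' @param target_radii target ellipsoid semi-axes, mm.
#' @param target_jitter max per-axis uniform jitter of the target center, mm.
#' @param t0 falloff offset, mm: dose is half the prescription at `t = t0`.
#' @param tau falloff scale, mm.
#' @param sigma_a voxel dose noise SD, Gy.
#' @param sigma_tau SD of the log-normal per-plan multiplier of `tau`.
#' @param oars per-OAR geometry list; see defaults in the source.
#' @param seed cohort seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), spacing = c(4, 4, 4),
                         d_rx = 50, target_radii = c(25, 20, 45),
                         target_jitter = 6, t0 = 10, tau = 4,
                         sigma_a = 1, sigma_tau = 0.1,
                         oars = NULL, seed = 42L) {
  if (d_rx <= 0 || tau <= 0 || sigma_a < 0 || any(target_radii <= 0))
    kb_stop("spec_error", "phantom_spec: d_rx, tau, radii must be > 0; sigma_a >= 0")
  oars <- oars %||% list(
    heart  = list(kind = "ellipsoid", center = c(0, 38, -30), radii = c(35, 30, 35)),
    lung_l = list(kind = "ellipsoid", center = c(-62, 0, 10), radii = c(40, 58, 85)),
    lung_r = list(kind = "ellipsoid", center = c(62, 0, 10), radii = c(40, 58, 85)),
    cord   = list(kind = "cylinder", center = c(0, -46, 0), radius = 6, half_length = 120)
  )
  grid <- volume_grid(shape, spacing,
                      origin = -(as.numeric(shape) - 1) / 2 * as.numeric(spacing))
  structure(list(grid = grid, d_rx = d_rx, target_radii = target_radii,
                 target_jitter = target_jitter, t0 = t0, tau = tau,
                 sigma_a = sigma_a, sigma_tau = sigma_tau,
                 oars = oars, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Occupancy of an axis-aligned ellipsoid / z-aligned cylinder on a grid.
shape_occupancy <- function(grid, geom) {
  ax <- grid_axes(grid)
  if (geom$kind == "ellipsoid") {
    qx <- ((ax$x - geom$center[1]) / geom$radii[1])^2
    qy <- ((ax$y - geom$center[2]) / geom$radii[2])^2
    qz <- ((ax$z - geom$center[3]) / geom$radii[3])^2
    arr <- outer(outer(qx, qy, "+"), qz, "+") <= 1
  } else if (geom$kind == "cylinder") {
    qx <- ((ax$x - geom$center[1]) / geom$radius)^2
    qy <- ((ax$y - geom$center[2]) / geom$radius)^2
    inplane <- outer(qx, qy, "+") <= 1
    inz <- abs(ax$z - geom$center[3]) <= geom$half_length
    arr <- outer(inplane, inz, "&")
  } else kb_stop("spec_error", "unknown phantom shape kind '%s'", geom$kind)
  array(arr, dim = grid$shape)
}

# Logistic falloff of relative dose with signed distance.
phantom_falloff <- function(t, t0, tau) 1 / (1 + exp((t - t0) / tau))

# Truncated-normal dose draw: x ~ N(mu, sigma^2) conditioned on x >= 0,
# via inverse-CDF sampling (exact, vectorized).
rnorm_trunc0 <- function(mu, sigma) {
  if (sigma == 0) return(mu)
  p0 <- pnorm(0, mean = mu, sd = sigma)
  u <- runif(length(mu), min = p0, max = 1)
  qnorm(u, mean = mu, sd = sigma)
}

#' Generate one synthetic plan
#'
#' Deterministic function of `(spec$seed, plan_index)`: the target center
#' jitter, the per-plan falloff multiplier and the voxel noise are drawn from
#' a plan-specific seeded stream.
#'
#' @param spec a [phantom_spec()].
#' @param plan_index nonnegative integer plan index.
#' @return An object of class `synthetic_plan`: `plan_id`, list `structures`
#'   of [structure_mask()]s (target first), `dose` ([dose_grid()]), and
#'   `ground_truth` (`tau_plan`, `t0`, `sigma_a`, `d_rx`, target center).
#' @export
generate_plan <- function(spec, plan_index = 0L) {
  grid <- spec$grid
  plan_seed <- (spec$seed + 131L * as.integer(plan_index)) %% .Machine$integer.max
  with_seed(plan_seed, {
    jitter <- runif(3, -spec$target_jitter, spec$target_jitter)
    tau_plan <- spec$tau * exp(rnorm(1, 0, spec$sigma_tau))
    target_geom <- list(kind = "ellipsoid", center = jitter,
                        radii = spec$target_radii)
    occ <- shape_occupancy(grid, target_geom)
    if (!any(occ))
      kb_stop("spec_error", "target ellipsoid rasterizes to zero voxels")
    target <- structure_mask(grid, occ, "PTV", role = "target")
    sdf <- signed_distance_field(target)
    mu <- spec$d_rx * phantom_falloff(sdf$t, spec$t0, tau_plan)
    dose_vals <- rnorm_trunc0(as.numeric(mu), spec$sigma_a)
    structures <- c(list(PTV = target),
                    lapply(spec$oars, function(g) NULL))
    for (nm in names(spec$oars))
      structures[[nm]] <- structure_mask(grid, shape_occupancy(grid, spec$oars[[nm]]),
                                         nm, role = "oar")
    structure(list(plan_id = sprintf("plan_%03d", as.integer(plan_index)),
                   structures = structures,
                   dose = dose_grid(grid, dose_vals),
                   prescription_gy = spec$d_rx,
                   ground_truth = list(tau_plan = tau_plan, t0 = spec$t0,
                                       sigma_a = spec$sigma_a, d_rx = spec$d_rx,
                                       target_center = jitter)),
              class = "synthetic_plan")
  })
}

#' Analytic ground-truth DVH of a synthetic plan structure
#'
#' With voxel doses drawn from a normal truncated at 0 around
#' `mu(t) = D_rx * S(t)`, the exact DVH at dose `D` is the average truncated
#' survival function over the structure's voxel distances:
#' `(1/M) sum_j P(X_j > D)` with
#' `P(X > D) = (1 - Phi((D - mu)/sigma)) / (1 - Phi(-mu/sigma))`.
#' The truncation denominator is numerically 1 when `mu/sigma > 5`. For
#' `sigma_a = 0` the exact step mixture (empirical DVH of the noiseless
#' doses) is returned.
#'
#' @param plan a [generate_plan()] result.
#' @param oar structure name in the plan.
#' @param dose_axis uniform ascending axis, Gy, starting at 0.
#' @return A [dvh_curve()] of kind `"achieved"` (it is the true curve).
#' @export
true_dvh <- function(plan, oar, dose_axis = seq(0, 60, by = 0.1)) {
  if (!oar %in% names(plan$structures))
    kb_stop("lookup_error", "no structure '%s' in plan %s", oar, plan$plan_id)
  gt <- plan$ground_truth
  mask <- plan$structures[[oar]]
  target <- plan$structures[[which(vapply(plan$structures, function(s)
    s$role == "target", TRUE))[1]]]
  sdf <- signed_distance_field(target)
  tt <- sdf$t[mask$occupancy]
  mu <- gt$d_rx * phantom_falloff(tt, gt$t0, gt$tau_plan)
  if (gt$sigma_a == 0) {
    vf <- vapply(dose_axis, function(D) mean(mu > D), 0.0)
    vf[1] <- 1
  } else {
    denom <- 1 - pnorm(-mu / gt$sigma_a)
    vf <- vapply(dose_axis, function(D)
      mean((1 - pnorm((D - mu) / gt$sigma_a)) / denom), 0.0)
    vf[1] <- 1  # truncated support is [0, Inf): all volume receives >= 0
    vf <- rev(cummax(rev(pmin(vf, 1))))
  }
  dvh_curve(dose_axis, vf, structure = oar, kind = "achieved")
}

#' Generate a cohort of synthetic plans
#'
#' @param spec a [phantom_spec()].
#' @param n_plans number of plans, >= 1.
#' @param first_index index of the first plan (use disjoint ranges for
#'   training and validation splits of one cohort world).
#' @param out_dir optional directory: each plan is written in the portable
#'   plan.json + NRRD format under `<out_dir>/<plan_id>/`.
#' @return list of `synthetic_plan`s.
#' @export
generate_cohort <- function(spec, n_plans, first_index = 0L, out_dir = NULL) {
  if (n_plans < 1) kb_stop("spec_error", "n_plans must be >= 1")
  plans <- lapply(seq_len(n_plans) - 1L + as.integer(first_index),
                  function(i) generate_plan(spec, i))
  if (!is.null(out_dir)) {
    for (p in plans) write_portable(p, file.path(out_dir, p$plan_id))
  }
  plans
}
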