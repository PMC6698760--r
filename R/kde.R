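# Conditional kernel density model of voxel dose given signed distance to the
# target boundary:
#
#   p(x|t) = sum_i K_hx(x - x_i) K_ht(t - t_i) / sum_i K_ht(t - t_i)
#
# with Gaussian kernels over pooled training pairs (t_i, x_i), and the new
# patient's dose density obtained by marginalizing over the empirical
# distribution of that patient's OAR voxel distances:
#
#   p_D(x) = (1/M) sum_j p(x | t_j).
#
# The dose kernel is boundary-corrected by reflection at x = 0 Gy, so each
# conditional density integrates to 1 over [0, Inf).

KDE_MODEL_VERSION <- "kbdvh-kde-1"

#' Kernel bandwidths by the Gaussian-reference MISE rule
#'
#' For a 2-D product Gaussian kernel the bandwidth minimizing the asymptotic
#' mean integrated squared error under a Gaussian reference is
#' `h_k = sigma_k * n^(-1/6)` per coordinate. `method = "lscv"` instead
#' minimizes the least-squares cross-validation score numerically (on a
#' subsample if n is large), for data far from Gaussian.
#'
#' @param t,x paired training coordinates (mm, Gy), length >= 2, each with
#'   nonzero variance.
#' @param method `"reference"` (default) or `"lscv"`.
#' @param lscv_max_n subsample cap for the O(n^2) LSCV score.
#' @param seed seed for the LSCV subsample.
#' @return list with bandwidths `h_t` (mm) and `h_x` (Gy).
#' @export
fit_bandwidths <- function(t, x, method = c("reference", "lscv"),
                           lscv_max_n = 1000L, seed = 1L) {
  method <- match.arg(method)
  n <- length(t)
  if (n < 2) kb_stop("degenerate_training_error", "need >= 2 samples, got %d", n)
  s_t <- sd(t); s_x <- sd(x)
  if (!is.finite(s_t) || s_t <= 0)
    kb_stop("degenerate_training_error", "zero variance in coordinate t")
  if (!is.finite(s_x) || s_x <= 0)
    kb_stop("degenerate_training_error", "zero variance in coordinate x")
  h <- c(h_t = s_t * n^(-1 / 6), h_x = s_x * n^(-1 / 6))
  if (method == "lscv") {
    if (n > lscv_max_n) {
      keep <- with_seed(seed, sample.int(n, lscv_max_n))
      t <- t[keep]; x <- x[keep]
    }
    h <- lscv_bandwidths(t, x, h)
  }
  list(h_t = unname(h[1]), h_x = unname(h[2]))
}

# Least-squares cross-validation for the 2-D product Gaussian kernel:
# LSCV(h) = int fhat^2 - (2/n) sum_i fhat_{-i}(X_i), both terms closed-form
# in the pairwise differences. Minimized over log-bandwidths from the
# reference-rule start.
lscv_bandwidths <- function(t, x, h0) {
  n <- length(t)
  dt <- outer(t, t, "-"); dx <- outer(x, x, "-")
  phi <- function(d, h) exp(-0.5 * (d / h)^2) / (h * sqrt(2 * pi))
  score <- function(lh) {
    ht <- exp(lh[1]); hx <- exp(lh[2])
    term1 <- sum(phi(dt, sqrt(2) * ht) * phi(dx, sqrt(2) * hx)) / n^2
    k <- phi(dt, ht) * phi(dx, hx)
    diag(k) <- 0
    term2 <- 2 * sum(k) / (n * (n - 1))
    term1 - term2
  }
  opt <- stats::optim(log(h0), score, method = "Nelder-Mead",
                      control = list(maxit = 200, reltol = 1e-6))
  exp(opt$par)
}

#' Construct a fitted conditional dose-distance KDE model
#'
#' Normally built via [train_model()]; exposed for deserialization and tests.
#'
#' @param oar_class organ class label the model applies to.
#' @param train_t,train_x pooled training pairs (mm, Gy).
#' @param h_t,h_x Gaussian kernel bandwidths (mm, Gy), > 0.
#' @param n_train_plans number of plans pooled.
#' @param x_max upper end of the dose domain `[0, x_max]`, >= max(train_x).
#' @export
kde_model <- function(oar_class, train_t, train_x, h_t, h_x,
                      n_train_plans = 1L, x_max = NULL) {
  if (length(train_t) != length(train_x) || length(train_t) < 2)
    kb_stop("model_input_error", "need >= 2 paired training samples")
  if (!is.finite(h_t) || h_t <= 0 || !is.finite(h_x) || h_x <= 0)
    kb_stop("model_input_error", "bandwidths must be positive and finite")
  x_max <- x_max %||% max(train_x)
  if (x_max < max(train_x))
    kb_stop("model_input_error", "x_max below the largest training dose")
  structure(list(version = KDE_MODEL_VERSION, oar_class = oar_class,
                 train_t = as.numeric(train_t), train_x = as.numeric(train_x),
                 h_t = h_t, h_x = h_x,
                 n_train_plans = as.integer(n_train_plans),
                 dose_domain = c(0, x_max)),
            class = "kde_model")
}

#' @export
print.kde_model <- function(x, ...) {
  cat(sprintf("kde_model '%s': %d pairs from %d plans, h_t=%.3f mm, h_x=%.3f Gy, dose domain [0, %.1f] Gy\n",
              x$oar_class, length(x$train_t), x$n_train_plans,
              x$h_t, x$h_x, x$dose_domain[2]))
  invisible(x)
}

#' Train a per-organ-class KDE model from pooled plan samples
#'
#' Samples are pooled across plans with equal weight per retained voxel
#' (`plan_weighting = "voxel"`); `"plan"` instead re-weights so every plan
#' contributes equally regardless of organ size. The dose domain upper bound
#' is `max(train_x) * 1.1` rounded up to the next `dx` multiple — 10% headroom
#' keeps reflected-kernel tail mass off the axis end.
#'
#' @param plans list of [distance_dose_samples()] for one organ class.
#' @param oar_class organ class label (defaults to the first sample's
#'   structure name).
#' @param dx dose bin width, Gy, used to round the domain bound.
#' @param bandwidth_method passed to [fit_bandwidths()].
#' @param plan_weighting `"voxel"` (default) or `"plan"`.
#' @return A [kde_model()].
#' @export
train_model <- function(plans, oar_class = NULL, dx = 0.1,
                        bandwidth_method = "reference",
                        plan_weighting = c("voxel", "plan")) {
  plan_weighting <- match.arg(plan_weighting)
  if (!inherits(plans, "list") || length(plans) == 0)
    kb_stop("model_input_error", "train_model: empty plan list")
  tt <- unlist(lapply(plans, `[[`, "t"), use.names = FALSE)
  xx <- unlist(lapply(plans, `[[`, "x"), use.names = FALSE)
  wts <- NULL
  if (plan_weighting == "plan") {
    counts <- vapply(plans, function(s) length(s$t), 0L)
    wts <- rep(1 / (counts * length(plans)), counts)
  }
  oar_class <- oar_class %||% plans[[1]]$structure
  h <- fit_bandwidths(tt, xx, method = bandwidth_method)
  x_max <- ceiling(max(xx) * 1.1 / dx) * dx
  m <- kde_model(oar_class, tt, xx, h$h_t, h$h_x,
                 n_train_plans = length(plans), x_max = x_max)
  m$weights <- wts
  m
}

# Gaussian distance-kernel weights for one query t, unnormalized (the
# normalization constant cancels in the conditional ratio). Underflow to an
# all-zero weight vector means the query sits far outside the training range;
# it is then clamped into [min(train_t), max(train_t)] per the model contract.
cond_weights <- function(model, t_query) {
  base <- model$weights %||% rep(1, length(model$train_t))
  w <- base * exp(-0.5 * ((t_query - model$train_t) / model$h_t)^2)
  clamped <- FALSE
  if (sum(w) == 0) {
    t_query <- min(max(t_query, min(model$train_t)), max(model$train_t))
    w <- base * exp(-0.5 * ((t_query - model$train_t) / model$h_t)^2)
    clamped <- TRUE
  }
  list(w = w / sum(w), clamped = clamped)
}

#' Conditional dose density p(x|t) at one query distance
#'
#' Direct Gaussian kernel ratio over all training pairs, with the dose kernel
#' reflected at 0 Gy. The result integrates to 1 over `[0, Inf)`; on an axis
#' with the model's 10% headroom the trapezoid integral is 1 within 1e-6.
#'
#' @param model a [kde_model()].
#' @param t_query signed distance, mm.
#' @param dose_axis uniform ascending dose axis (Gy) within the model's dose
#'   domain; defaults to the model domain at 0.1 Gy bins.
#' @return numeric densities (1/Gy) at each axis point.
#' @export
conditional_density <- function(model, t_query, dose_axis = kde_dose_axis(model)) {
  check_uniform_axis(dose_axis)
  cw <- cond_weights(model, t_query)
  if (cw$clamped)
    kb_log("conditional_density: query t outside training range, clamped")
  dx <- dose_axis[2] - dose_axis[1]
  as.numeric(cpp_gauss_mix_grid(model$train_x, cw$w, model$h_x,
                                dose_axis[1], dx, length(dose_axis), TRUE))
}

#' Default dose axis of a model
#' @param model a [kde_model()].
#' @param dx bin width, Gy.
#' @export
kde_dose_axis <- function(model, dx = 0.1) {
  seq(0, model$dose_domain[2], by = dx)
}

check_uniform_axis <- function(axis) {
  if (length(axis) < 2) kb_stop("model_input_error", "dose axis needs >= 2 points")
  d <- diff(axis)
  if (any(d <= 0) || max(d) - min(d) > 1e-9 * max(d))
    kb_stop("model_input_error", "dose axis must be uniform and ascending")
  invisible(axis)
}

#' Predicted dose density for a new patient organ
#'
#' Marginalizes the conditional density over the empirical distribution of
#' the patient's OAR voxel distances: `p_D(x) = (1/M) sum_j p(x | t_j)`.
#' Computed exactly by grouping duplicated distance values on both sides
#' (voxel-lattice distances are heavily tied, which makes the double kernel
#' sum cheap without any approximation) and renormalized on its axis.
#'
#' @param model a [kde_model()].
#' @param query_t nonempty numeric vector of the patient's signed distances, mm.
#' @param dx dose bin width, Gy (default 0.1).
#' @return An object of class `predicted_density`: `dose_axis`, `density`
#'   (1/Gy, trapezoid-normalized to 1), and the count of clamped queries.
#' @export
predict_dose_density <- function(model, query_t, dx = 0.1) {
  if (length(query_t) == 0)
    kb_stop("model_input_error", "predict_dose_density: empty query distances")
  axis <- kde_dose_axis(model, dx)
  M <- length(query_t)
  base <- model$weights %||% rep(1, length(model$train_t))

  uq <- sort(unique(query_t))
  mq <- as.numeric(tabulate(match(query_t, uq), nbins = length(uq)))
  ut <- sort(unique(model$train_t))
  iu <- match(model$train_t, ut)
  nt <- as.numeric(rowsum(base, iu))  # total base weight per unique t, ascending u

  # coefficient per training sample: c_i = (1/M) sum_j m_j K(uq_j - t_i) / D_j
  coef_u <- rep(0, length(ut))
  n_clamped <- 0L
  tmin <- min(ut); tmax <- max(ut)
  block <- max(1L, floor(2e7 / length(ut)))
  for (start in seq(1, length(uq), by = block)) {
    jj <- start:min(start + block - 1, length(uq))
    W <- exp(-0.5 * ((outer(uq[jj], ut, "-")) / model$h_t)^2)
    D <- as.numeric(W %*% nt)
    bad <- which(D == 0)
    if (length(bad) > 0) {
      n_clamped <- n_clamped + sum(mq[jj][bad])
      tq <- pmin(pmax(uq[jj][bad], tmin), tmax)
      W[bad, ] <- exp(-0.5 * ((outer(tq, ut, "-")) / model$h_t)^2)
      D[bad] <- as.numeric(W[bad, , drop = FALSE] %*% nt)
    }
    coef_u <- coef_u + as.numeric(crossprod(W, mq[jj] / D))
  }
  if (n_clamped > 0)
    kb_log("predict_dose_density: %d of %d query distances outside training range, clamped",
           n_clamped, M)
  coef_i <- base * coef_u[iu] / M
  dens <- as.numeric(cpp_gauss_mix_grid(model$train_x, coef_i, model$h_x,
                                        axis[1], dx, length(axis), TRUE))
  z <- trapz(axis, dens)
  if (z <= 0) kb_stop("model_input_error", "predicted density integrated to 0")
  structure(list(dose_axis = axis, density = dens / z, n_clamped = n_clamped),
            class = "predicted_density")
}

#' @export
print.predicted_density <- function(x, ...) {
  cat(sprintf("predicted_density on [0, %.1f] Gy (%d bins), mean %.2f Gy\n",
              max(x$dose_axis), length(x$dose_axis) - 1, density_mean(x)))
  invisible(x)
}

#' Mean of a predicted dose density, Gy
#' @param p a `predicted_density`.
#' @export
density_mean <- function(p) trapz(p$dose_axis, p$dose_axis * p$density)

#' Serialize a KDE model to versioned JSON
#'
#' Deterministic field order and full-precision numbers: identical training
#' inputs yield byte-identical files.
#'
#' @param model a [kde_model()].
#' @param path output file path.
#' @export
write_kde_model <- function(model, path) {
  doc <- list(version = model$version, oar_class = model$oar_class,
              n_train_plans = model$n_train_plans,
              h_t = model$h_t, h_x = model$h_x,
              dose_domain = model$dose_domain,
              train_t = model$train_t, train_x = model$train_x)
  if (!is.null(model$weights)) doc$weights <- model$weights
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  writeLines(json, path)
  invisible(path)
}

#' Read a serialized KDE model
#' @param path JSON file written by [write_kde_model()].
#' @export
read_kde_model <- function(path) {
  if (!file.exists(path)) kb_stop("io_error", "model file not found: %s", path)
  doc <- jsonlite::fromJSON(path)
  if (!identical(doc$version, KDE_MODEL_VERSION))
    kb_stop("version_error", "unsupported model version '%s' (expected '%s')",
            doc$version %||% "<missing>", KDE_MODEL_VERSION)
  m <- kde_model(doc$oar_class, doc$train_t, doc$train_x, doc$h_t, doc$h_x,
                 n_train_plans = doc$n_train_plans, x_max = doc$dose_domain[2])
  if (!is.null(doc$weights)) m$weights <- doc$weights
  m
}
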