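# Cohort-level comparison of predicted versus achieved DVHs: per-metric mean
# difference and RMSE across plans, and per-plan ordinary least squares of
# predicted on achieved volume fractions with R^2 as goodness of fit.

#' Per-metric mean difference and RMSE across a cohort
#'
#' Differences are `predicted - achieved` per plan;
#' `RMSE = sqrt(sum(diff^2) / N_plans)`.
#'
#' @param predicted,achieved named numeric vectors (one value per plan, names
#'   are plan ids) for a single metric, or equally-shaped data frames with a
#'   `plan_id` column and one column per metric.
#' @return list with `mean_difference`, `rmse`, `n_plans`.
#' @export
metric_differences <- function(predicted, achieved) {
  if (is.null(names(predicted)) || is.null(names(achieved)))
    kb_stop("pairing_error", "metric vectors must be named by plan id")
  unmatched <- c(setdiff(names(predicted), names(achieved)),
                 setdiff(names(achieved), names(predicted)))
  if (length(unmatched))
    kb_stop("pairing_error", "unmatched plan ids: %s",
            paste(unique(unmatched), collapse = ", "))
  achieved <- achieved[names(predicted)]
  d <- predicted - achieved
  list(mean_difference = mean(d), rmse = sqrt(sum(d^2) / length(d)),
       n_plans = length(d))
}

#' Linear fit of a predicted DVH against an achieved DVH
#'
#' Ordinary least squares of predicted volume fraction on achieved volume
#' fraction over all points of the common dose axis (the coarser curve is
#' linearly interpolated onto the finer axis first).
#'
#' @param predicted,achieved [dvh_curve()]s.
#' @return list with `slope`, `intercept`, `r_squared`.
#' @export
dvh_linear_fit <- function(predicted, achieved) {
  axes <- list(predicted$dose_axis, achieved$dose_axis)
  finer <- which.min(vapply(axes, function(a) a[2] - a[1], 0.0))
  axis <- axes[[finer]]
  axis <- axis[axis <= min(max(axes[[1]]), max(axes[[2]])) + 1e-9]
  yp <- stats::approx(predicted$dose_axis, predicted$volume_fraction,
                      xout = axis, rule = 2)$y
  ya <- stats::approx(achieved$dose_axis, achieved$volume_fraction,
                      xout = axis, rule = 2)$y
  if (var(ya) == 0)
    kb_stop("degenerate_fit_error",
            "achieved DVH is constant; linear fit undefined")
  slope <- stats::cov(ya, yp) / var(ya)
  intercept <- mean(yp) - slope * mean(ya)
  res <- yp - (intercept + slope * ya)
  ss_tot <- sum((yp - mean(yp))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(res^2) / ss_tot
  list(slope = slope, intercept = intercept, r_squared = max(0, min(1, r2)))
}

#' Aggregate cohort results into an evaluation report
#'
#' Takes per-plan predicted and achieved metrics plus per-plan curve pairs and
#' produces the two standard tables: per-metric mean difference and RMSE, and
#' per-plan-per-structure linear-fit statistics. Row ordering is deterministic
#' (organ class, then metric; plan id, then structure), so the report is a
#' pure, order-invariant function of its inputs.
#'
#' @param metric_rows data frame with columns `plan_id`, `oar_class`,
#'   `metric`, `predicted`, `achieved`.
#' @param curve_pairs optional list of `list(plan_id, structure, predicted,
#'   achieved)` with [dvh_curve()]s for the linear fits.
#' @return An object of class `evaluation_report`: `n_plans`, data frames
#'   `metrics` (oar_class, metric, mean_difference, rmse) and `fits`
#'   (plan_id, structure, slope, r_squared; `NA` for degenerate fits).
#' @export
build_report <- function(metric_rows, curve_pairs = list()) {
  need <- c("plan_id", "oar_class", "metric", "predicted", "achieved")
  if (!all(need %in% names(metric_rows)) || nrow(metric_rows) == 0)
    kb_stop("model_input_error", "metric_rows needs columns %s",
            paste(need, collapse = ", "))
  key <- interaction(metric_rows$oar_class, metric_rows$metric, drop = TRUE)
  parts <- split(metric_rows, key)
  metrics <- do.call(rbind, lapply(parts, function(p) {
    md <- metric_differences(stats::setNames(p$predicted, p$plan_id),
                             stats::setNames(p$achieved, p$plan_id))
    data.frame(oar_class = p$oar_class[1], metric = p$metric[1],
               mean_difference = md$mean_difference, rmse = md$rmse)
  }))
  metrics <- metrics[order(metrics$oar_class, metrics$metric), , drop = FALSE]
  rownames(metrics) <- NULL

  fits <- data.frame(plan_id = character(0), structure = character(0),
                     slope = numeric(0), r_squared = numeric(0))
  if (length(curve_pairs)) {
    fits <- do.call(rbind, lapply(curve_pairs, function(cp) {
      fit <- tryCatch(dvh_linear_fit(cp$predicted, cp$achieved),
                      kbdvh_degenerate_fit_error = function(e) {
                        kb_log("degenerate fit for %s/%s: %s",
                               cp$plan_id, cp$structure, conditionMessage(e))
                        list(slope = NA_real_, r_squared = NA_real_)
                      })
      data.frame(plan_id = cp$plan_id, structure = cp$structure,
                 slope = fit$slope, r_squared = fit$r_squared)
    }))
    fits <- fits[order(fits$plan_id, fits$structure), , drop = FALSE]
    rownames(fits) <- NULL
  }
  structure(list(n_plans = length(unique(metric_rows$plan_id)),
                 metrics = metrics, fits = fits),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

#' Plain-text rendering of an evaluation report
#'
#' Mirrors the standard predicted-to-achieved comparison table layout
#' (organ, metric, mean difference, RMSE) plus linear-fit summaries.
#'
#' @param report an `evaluation_report`.
#' @return character vector of lines.
#' @export
format_report <- function(report) {
  lines <- c(sprintf("Predicted-to-achieved value difference (N = %d plans)",
                     report$n_plans),
             sprintf("%-12s %-12s %10s %10s", "OAR", "Metric", "Mean", "RMSE"))
  for (i in seq_len(nrow(report$metrics))) {
    r <- report$metrics[i, ]
    lines <- c(lines, sprintf("%-12s %-12s %10.2f %10.2f",
                              r$oar_class, r$metric, r$mean_difference, r$rmse))
  }
  if (nrow(report$fits)) {
    lines <- c(lines, "", "Per-plan DVH linear fits (predicted on achieved)",
               sprintf("%-12s %-12s %10s %10s", "Plan", "Structure", "Slope", "R^2"))
    for (i in seq_len(nrow(report$fits))) {
      r <- report$fits[i, ]
      lines <- c(lines, sprintf("%-12s %-12s %10.3f %10.3f",
                                r$plan_id, r$structure, r$slope, r$r_squared))
    }
  }
  lines
}

#' Write an evaluation report to CSV and text files
#'
#' @param report an `evaluation_report`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(metrics = file.path(dir, "metrics.csv"),
             fits = file.path(dir, "linear_fits.csv"),
             text = file.path(dir, "report.txt"))
  write.csv(report$metrics, paths["metrics"], row.names = FALSE)
  write.csv(report$fits, paths["fits"], row.names = FALSE)
  writeLines(format_report(report), paths["text"])
  invisible(paths)
}
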