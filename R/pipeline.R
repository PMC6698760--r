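# End-to-end workflow: training-data extraction from a cohort of plans,
# per-organ-class model fitting, DVH prediction for new plans, and cohort
# evaluation. This is the programmatic surface the CLI wraps.

# Normalize a plan bundle for analysis: rasterize any contour-set structures
# onto the dose grid, resolve structure roles/classes via the match table,
# merge multi-structure classes (paired lungs) into one mask per class, and
# derive lung-PTV by Boolean subtraction when absent.
prepare_plan <- function(bundle, config = kbdvh_config()) {
  dose <- bundle$dose
  masks <- lapply(bundle$structures, function(s) {
    if (inherits(s, "contour_set")) rasterize_contours(s, dose$grid) else s
  })
  m <- match_structures(names(masks), config$match)
  target <- masks[[m$target]]
  target$role <- "target"
  target <- structure_mask(target$grid, target$occupancy, target$name, "target")
  by_class <- list()
  for (nm in names(m$classes)) {
    cl <- m$classes[[nm]]
    msk <- masks[[nm]]
    if (is.null(by_class[[cl]])) {
      by_class[[cl]] <- structure_mask(msk$grid, msk$occupancy, cl, "oar")
    } else {
      by_class[[cl]] <- structure_mask(msk$grid,
                                       by_class[[cl]]$occupancy | msk$occupancy,
                                       cl, "oar")
    }
  }
  if (!is.null(by_class[["lung"]]) && is.null(by_class[["lung-ptv"]])) {
    lp <- subtract_masks(by_class[["lung"]], target)
    by_class[["lung-ptv"]] <- structure_mask(lp$grid, lp$occupancy, "lung-ptv", "oar")
  }
  list(plan_id = bundle$plan_id, target = target, masks = by_class,
       sdf = signed_distance_field(target), dose = dose)
}

# Deterministic per-(plan, structure) subsampling seed derived from the
# config seed; kept well below 2^31.
plan_structure_seed <- function(seed, plan_id, class) {
  h <- sum(utf8ToInt(paste(plan_id, class, sep = "/")) *
             (seq_along(utf8ToInt(paste(plan_id, class, sep = "/")))))
  (as.integer(seed) + h) %% 2000000000L
}

#' Extract per-class training samples from one plan
#'
#' @param bundle a `plan_bundle` or `synthetic_plan`.
#' @param config a [kbdvh_config()].
#' @return named list (organ class) of [distance_dose_samples()].
#' @export
extract_plan_samples <- function(bundle, config = kbdvh_config()) {
  prep <- prepare_plan(bundle, config)
  out <- list()
  for (cl in names(prep$masks)) {
    s <- extract_samples(prep$masks[[cl]], prep$sdf, prep$dose,
                         max_samples = config$max_samples_per_structure,
                         seed = plan_structure_seed(config$seed, prep$plan_id, cl))
    s$plan_id <- prep$plan_id
    out[[cl]] <- s
  }
  out
}

#' Train one KDE model per organ class from a cohort of plans
#'
#' @param bundles list of plan bundles (training cohort).
#' @param config a [kbdvh_config()].
#' @return named list of [kde_model()]s.
#' @export
train_cohort <- function(bundles, config = kbdvh_config()) {
  if (length(bundles) == 0) kb_stop("model_input_error", "empty training cohort")
  per_plan <- lapply(bundles, extract_plan_samples, config = config)
  classes <- unique(unlist(lapply(per_plan, names)))
  models <- list()
  for (cl in classes) {
    plans <- Filter(Negate(is.null), lapply(per_plan, `[[`, cl))
    models[[cl]] <- train_model(plans, oar_class = cl,
                                dx = config$dose_bin_gy,
                                bandwidth_method = config$bandwidth_method,
                                plan_weighting = config$plan_weighting)
  }
  models
}

#' Predict and compare DVHs for one plan
#'
#' For every organ class with both a trained model and a structure in the
#' plan: marginalize the model over the plan's voxel distances, convert to a
#' predicted DVH, build the achieved DVH from the plan's own dose, and
#' compute the configured clinical metrics for both. Predicted mean dose is
#' the density mean `integral x p_D(x) dx`; the predicted near-max is D0.1%
#' while the achieved near-max is the literal voxel maximum.
#'
#' @param models named list of [kde_model()]s.
#' @param bundle a plan bundle.
#' @param config a [kbdvh_config()].
#' @return list with `plan_id`, `curves` (per class:
#'   `list(predicted, achieved)`), and data frame `metrics` with columns
#'   `plan_id`, `oar_class`, `metric`, `predicted`, `achieved`.
#' @export
predict_plan <- function(models, bundle, config = kbdvh_config()) {
  prep <- prepare_plan(bundle, config)
  dx <- config$dose_bin_gy
  curves <- list()
  rows <- list()
  for (cl in intersect(names(models), names(prep$masks))) {
    model <- models[[cl]]
    mask <- prep$masks[[cl]]
    if (mask$empty) next
    query_t <- prep$sdf$t[mask$occupancy]
    pd <- predict_dose_density(model, query_t, dx = dx)
    pred <- density_to_dvh(pd, structure = cl)
    xs <- prep$dose$dose[mask$occupancy]
    x_max <- max(model$dose_domain[2], ceiling(max(xs) / dx) * dx + dx)
    ach <- samples_to_dvh(xs, dx = dx, x_max = x_max, structure = cl)
    curves[[cl]] <- list(predicted = pred, achieved = ach)

    cuts <- config$cutpoints[[cl]] %||% numeric(0)
    mp <- dvh_metrics(pred, cuts, config$near_max_fraction)
    mp$mean_gy <- density_mean(pd)
    ma <- dvh_metrics(ach, cuts, config$near_max_fraction)
    metric_names <- c("mean_gy", names(mp$v_cutpoints),
                      if (cl %in% config$near_max_classes) "max_gy")
    pvals <- c(mp$mean_gy, unname(mp$v_cutpoints),
               if (cl %in% config$near_max_classes) mp$near_max_gy)
    avals <- c(ma$mean_gy, unname(ma$v_cutpoints),
               if (cl %in% config$near_max_classes) ma$near_max_gy)
    rows[[cl]] <- data.frame(plan_id = prep$plan_id, oar_class = cl,
                             metric = metric_names,
                             predicted = pvals, achieved = avals)
  }
  list(plan_id = prep$plan_id, curves = curves,
       metrics = do.call(rbind, unname(rows)))
}

#' Evaluate trained models against a cohort of plans
#'
#' Runs [predict_plan()] on every plan and aggregates per-metric mean
#' differences/RMSEs and per-plan linear fits into an `evaluation_report`.
#'
#' @param models named list of [kde_model()]s.
#' @param bundles list of plan bundles (validation cohort).
#' @param config a [kbdvh_config()].
#' @return list with `report` ([build_report()] result) and `predictions`
#'   (per-plan [predict_plan()] results).
#' @export
evaluate_cohort <- function(models, bundles, config = kbdvh_config()) {
  preds <- lapply(bundles, predict_plan, models = models, config = config)
  metric_rows <- do.call(rbind, lapply(preds, `[[`, "metrics"))
  curve_pairs <- list()
  for (p in preds)
    for (cl in names(p$curves))
      curve_pairs[[length(curve_pairs) + 1]] <-
        list(plan_id = p$plan_id, structure = cl,
             predicted = p$curves[[cl]]$predicted,
             achieved = p$curves[[cl]]$achieved)
  list(report = build_report(metric_rows, curve_pairs), predictions = preds)
}

#' Write predicted/achieved DVH overlay plots
#'
#' One PDF per plan; predicted curves dashed, achieved solid, per structure.
#'
#' @param predictions list of [predict_plan()] results.
#' @param dir output directory.
#' @export
write_overlays <- function(predictions, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in predictions) {
    path <- file.path(dir, paste0(p$plan_id, "_dvh.pdf"))
    grDevices::pdf(path, width = 7, height = 5)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::plot(NULL, xlim = c(0, max(vapply(p$curves, function(cv)
      max(cv$achieved$dose_axis), 0.0))), ylim = c(0, 100),
      xlab = "Dose (Gy)", ylab = "Volume (%)",
      main = paste("DVH:", p$plan_id))
    cols <- grDevices::rainbow(length(p$curves))
    i <- 0
    for (cl in names(p$curves)) {
      i <- i + 1
      cv <- p$curves[[cl]]
      graphics::lines(cv$achieved$dose_axis, 100 * cv$achieved$volume_fraction,
                      col = cols[i], lty = 1)
      graphics::lines(cv$predicted$dose_axis, 100 * cv$predicted$volume_fraction,
                      col = cols[i], lty = 2)
    }
    graphics::legend("topright", legend = names(p$curves), col = cols, lty = 1)
    grDevices::dev.off()
    on.exit(NULL)
  }
  invisible(dir)
}
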