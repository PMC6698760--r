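# Portable plan bundle: plan.json (metadata, schema-versioned) + one NRRD
# volume per structure mask and one for the dose grid. Lossless round trip:
# masks bit-exact, dose at full double precision.

PLAN_SCHEMA_VERSION <- "kbdvh-plan-1"

#' Write a plan bundle to a portable directory
#'
#' @param plan a `synthetic_plan` or `plan_bundle` (needs `structures`,
#'   `dose`, `plan_id`; optional `prescription_gy`, `ground_truth`).
#' @param dir output directory (created).
#' @export
write_portable <- function(plan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- plan$dose$grid
  st_meta <- list()
  for (nm in names(plan$structures)) {
    s <- plan$structures[[nm]]
    f <- paste0("mask_", gsub("[^A-Za-z0-9_.-]", "_", nm), ".nrrd")
    write_nrrd(s$occupancy, s$grid, file.path(dir, f))
    st_meta[[length(st_meta) + 1]] <-
      list(name = s$name, role = s$role, file = f)
  }
  write_nrrd(plan$dose$dose, grid, file.path(dir, "dose.nrrd"))
  doc <- list(schema_version = PLAN_SCHEMA_VERSION,
              plan_id = plan$plan_id,
              prescription_gy = plan$prescription_gy,
              grid = list(shape = grid$shape, spacing = grid$spacing,
                          origin = grid$origin),
              structures = st_meta,
              dose_file = "dose.nrrd",
              ground_truth = plan$ground_truth)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null"),
             file.path(dir, "plan.json"))
  invisible(dir)
}

#' Read a portable plan bundle directory
#'
#' @param dir directory holding `plan.json` plus the referenced NRRD volumes.
#' @return An object of class `plan_bundle` with `plan_id`, named `structures`
#'   list of [structure_mask()]s, `dose` ([dose_grid()]), optional
#'   `prescription_gy` and `ground_truth`.
#' @export
read_portable <- function(dir) {
  jf <- file.path(dir, "plan.json")
  if (!file.exists(jf)) kb_stop("io_error", "no plan.json in %s", dir)
  doc <- jsonlite::fromJSON(jf, simplifyDataFrame = FALSE)
  if (!identical(doc$schema_version, PLAN_SCHEMA_VERSION))
    kb_stop("version_error", "unsupported plan schema '%s' (expected '%s')",
            doc$schema_version %||% "<missing>", PLAN_SCHEMA_VERSION)
  structures <- list()
  for (st in doc$structures) {
    f <- file.path(dir, st$file)
    if (!file.exists(f)) kb_stop("io_error", "missing volume file: %s", f)
    vol <- read_nrrd(f)
    structures[[st$name]] <- structure_mask(vol$grid, vol$arr, st$name, st$role)
  }
  df <- file.path(dir, doc$dose_file)
  if (!file.exists(df)) kb_stop("io_error", "missing volume file: %s", df)
  dvol <- read_nrrd(df)
  structure(list(plan_id = doc$plan_id,
                 structures = structures,
                 dose = dose_grid(dvol$grid, dvol$arr),
                 prescription_gy = doc$prescription_gy,
                 ground_truth = doc$ground_truth),
            class = "plan_bundle")
}
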