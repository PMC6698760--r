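# Configuration and structure-name matching. Every tunable default (bin
# width, subsampling cap, bandwidth rule, near-max fraction, per-class
# cut-points, name aliases) is visible and overridable in one YAML file.

#' Default structure-name match table
#'
#' Case-insensitive glob patterns mapping clinical structure names to organ
#' classes. Classes are tried in list order, so more specific classes
#' (`lung-ptv`) precede general ones (`lung`). User tables extend or replace
#' these aliases.
#'
#' @return list with `target` (patterns) and ordered `classes` (named pattern
#'   lists).
#' @export
default_match_table <- function() {
  list(
    target = c("ptv*", "ctv*boost*"),
    classes = list(
      "lung-ptv" = c("lung*-ptv*", "lungs-ptv*"),
      heart = c("heart*", "cor"),
      lung = c("lung*", "*lung*"),
      cord = c("*cord*", "sc", "spinal*", "myelon*")
    )
  )
}

match_one <- function(name, patterns) {
  any(vapply(patterns, function(p)
    grepl(glob2rx(p), name, ignore.case = TRUE), TRUE))
}

#' Assign target/organ-class roles to a plan's structure names
#'
#' Each name is tested case-insensitively against the table's glob patterns.
#' Exactly one name must resolve to the target; organ structures take the
#' first matching class in table order; unmatched names are reported and
#' excluded.
#'
#' @param names character vector of structure names in a plan.
#' @param table a match table as from [default_match_table()].
#' @return list with `target` (one name), `classes` (named character: class
#'   per matched structure name), `unmatched` (character).
#' @export
match_structures <- function(names, table = default_match_table()) {
  if (length(table$target) == 0 || length(table$classes) == 0 ||
      any(!nzchar(unlist(table$classes))))
    kb_stop("matching_error", "invalid match table")
  is_target <- vapply(names, match_one, TRUE, patterns = table$target)
  if (sum(is_target) != 1)
    kb_stop("matching_error", "expected exactly 1 target match, got %d (%s)",
            sum(is_target),
            if (any(is_target)) paste(names[is_target], collapse = ", ") else "none")
  rest <- names[!is_target]
  cls <- vapply(rest, function(nm) {
    for (cl in names(table$classes))
      if (match_one(nm, table$classes[[cl]])) return(cl)
    NA_character_
  }, "a")
  unmatched <- rest[is.na(cls)]
  if (length(unmatched))
    kb_log("match_structures: unmatched structures excluded: %s",
           paste(unmatched, collapse = ", "))
  list(target = names[is_target], classes = cls[!is.na(cls)],
       unmatched = unmatched)
}

#' Pipeline configuration with defaults
#'
#' Defaults: 0.1 Gy dose bins, automatic dose-domain upper bound (10%
#' headroom over the training maximum), Gaussian-reference bandwidths, a
#' 20000-voxel per-structure subsampling cap, D0.1% near-max, and the
#' esophageal cut-point set (heart V30; lung and lung-PTV V20 + V5; cord
#' near-max only).
#'
#' @param path optional YAML file whose top-level keys override the defaults.
#' @param ... further overrides (take precedence over the file).
#' @return list of configuration values.
#' @export
kbdvh_config <- function(path = NULL, ...) {
  cfg <- list(
    dose_bin_gy = 0.1,
    max_dose_gy = NULL,  # auto: from training data
    bandwidth_method = "reference",
    max_samples_per_structure = 20000L,
    near_max_fraction = 0.001,
    cutpoints = list("lung-ptv" = c(20, 5), heart = 30, lung = c(20, 5),
                     cord = numeric(0)),
    near_max_classes = "cord",
    plan_weighting = "voxel",
    seed = 42L,
    match = default_match_table()
  )
  apply_over <- function(cfg, over) {
    for (k in names(over)) cfg[[k]] <- over[[k]]
    cfg
  }
  if (!is.null(path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      kb_stop("io_error", "the 'yaml' package is required to read config files")
    cfg <- apply_over(cfg, yaml::read_yaml(path))
  }
  apply_over(cfg, list(...))
}
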