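registry_columns <- c(
  "patient_id", "prior_mesh_present", "mesh_plane", "mesh_fracture",
  "mesh_migration", "concurrent_inguinal", "concurrent_parastomal_or_stomal",
  "wall_abnormality", "ongoing_sso", "defect_width_cm", "defect_length_cm",
  "n_prior_repairs"
)

registry_logical_columns <- c(
  "prior_mesh_present", "mesh_fracture", "mesh_migration",
  "concurrent_inguinal", "concurrent_parastomal_or_stomal",
  "wall_abnormality", "ongoing_sso"
)

mesh_planes <- c("onlay", "sublay", "underlay")

#' Assemble a cohort dataset
#'
#' Bundles per-patient registry ground truth and per-patient report
#' abstractions into a single dataset object, the unit every audit
#' operation consumes.
#'
#' @param registry Data frame of intraoperative/registry ground truth, one
#'   row per patient (see [generate_registry()] for the schema).
#' @param reports Data frame of report abstractions: `patient_id` plus one
#'   logical/0-1 column per catalog parameter id, `TRUE`/1 when the CT
#'   report explicitly addressed the parameter.
#' @param provenance Optional list echoed verbatim (seed, generator config).
#' @return A list of class `stampc_cohort` with elements `registry`,
#'   `reports`, `provenance`.
#' @export
cohort_dataset <- function(registry, reports, provenance = list()) {
  structure(
    list(registry = registry, reports = reports, provenance = provenance),
    class = "stampc_cohort"
  )
}

#' @export
print.stampc_cohort <- function(x, ...) {
  cat("AWR cohort dataset:", nrow(x$registry), "patients,",
      nrow(x$reports), "report abstractions\n")
  if (!is.null(x$provenance$seed))
    cat("  generator seed:", x$provenance$seed, "\n")
  invisible(x)
}

#' Validate a cohort dataset against its structural invariants
#'
#' Checks the invariants the audit relies on: registry and report patient
#' ids are identical, duplicate-free sets; a mesh plane is recorded iff
#' prior mesh is present; mesh fracture or migration implies prior mesh;
#' defect dimensions are positive; report columns are exactly the 16
#' catalog ids with 0/1 values; plane documentation never occurs without
#' mesh-presence documentation.
#'
#' @param dataset A `stampc_cohort` (see [cohort_dataset()]).
#' @return Data frame of class `stampc_validation` with columns `rule`,
#'   `patient_id`, `message`; zero rows iff the dataset is valid.
#' @export
validate_cohort <- function(dataset) {
  stopifnot(inherits(dataset, "stampc_cohort"))
  reg <- dataset$registry
  rep <- dataset$reports
  catalog <- load_parameter_catalog()
  v <- list()
  add <- function(rule, patient_id, message) {
    v[[length(v) + 1L]] <<- data.frame(
      rule = rule, patient_id = patient_id, message = message,
      stringsAsFactors = FALSE)
  }

  missing_cols <- setdiff(registry_columns, names(reg))
  if (length(missing_cols))
    add("registry_schema", NA_character_,
        paste("missing registry columns:", paste(missing_cols, collapse = ", ")))

  dup <- unique(reg$patient_id[duplicated(reg$patient_id)])
  for (id in dup) add("duplicate_patient", id, "duplicate patient_id in registry")
  dup_r <- unique(rep$patient_id[duplicated(rep$patient_id)])
  for (id in dup_r) add("duplicate_patient", id, "duplicate patient_id in reports")

  orphans <- setdiff(rep$patient_id, reg$patient_id)
  for (id in orphans) add("orphan_report", id, "report references unknown patient_id")
  unreported <- setdiff(reg$patient_id, rep$patient_id)
  for (id in unreported) add("missing_report", id, "registry patient has no report abstraction")

  expected <- c("patient_id", catalog$id)
  if (!setequal(names(rep), expected))
    add("report_schema", NA_character_, paste(
      "report columns must be patient_id plus the 16 catalog ids; got:",
      paste(setdiff(names(rep), expected), collapse = ", ")))

  if (!length(missing_cols)) {
    bad_plane <- !is.na(reg$mesh_plane) & !reg$prior_mesh_present
    for (id in reg$patient_id[bad_plane])
      add("plane_without_mesh", id, "mesh_plane recorded but prior_mesh_present is FALSE")
    no_plane <- is.na(reg$mesh_plane) & reg$prior_mesh_present
    for (id in reg$patient_id[no_plane])
      add("mesh_without_plane", id, "prior_mesh_present but mesh_plane missing")
    unknown_plane <- !is.na(reg$mesh_plane) & !(reg$mesh_plane %in% mesh_planes)
    for (id in reg$patient_id[unknown_plane])
      add("unknown_plane", id, paste("mesh_plane must be one of",
                                     paste(mesh_planes, collapse = "/")))
    impl <- (reg$mesh_fracture | reg$mesh_migration) & !reg$prior_mesh_present
    for (id in reg$patient_id[impl])
      add("mesh_complication_without_mesh", id,
          "mesh_fracture/mesh_migration implies prior_mesh_present")
    nonpos <- reg$defect_width_cm <= 0 | reg$defect_length_cm <= 0
    for (id in reg$patient_id[which(nonpos)])
      add("nonpositive_defect", id, "defect dimensions must be positive")
    negrep <- reg$n_prior_repairs < 0
    for (id in reg$patient_id[which(negrep)])
      add("negative_repairs", id, "n_prior_repairs must be non-negative")
  }

  if (all(c("old_mesh_plane", "prior_mesh") %in% names(rep))) {
    sub <- rep$old_mesh_plane & !rep$prior_mesh
    for (id in rep$patient_id[which(sub)])
      add("plane_doc_without_mesh_doc", id,
          "old_mesh_plane documented but mesh presence not documented")
  }

  out <- if (length(v)) do.call(rbind, v) else
    data.frame(rule = character(), patient_id = character(),
               message = character(), stringsAsFactors = FALSE)
  class(out) <- c("stampc_validation", "data.frame")
  out
}

#' @export
print.stampc_validation <- function(x, ...) {
  if (nrow(x) == 0) cat("Cohort valid: no invariant violations.\n")
  else {
    cat("Cohort invalid:", nrow(x), "violation(s)\n")
    print.data.frame(x, row.names = FALSE)
  }
  invisible(x)
}

# CSV dialect: UTF-8, comma-separated, header row, booleans as 0/1,
# doubles at full precision so round-trips are exact.
format_csv_value <- function(col) {
  if (is.logical(col)) as.integer(col)
  else if (is.double(col)) vapply(col, function(z)
    if (is.na(z)) "" else format(z, digits = 17, scientific = FALSE), "")
  else col
}

#' Write a cohort dataset to CSV files
#'
#' Serializes the registry and report tables with the package's CSV dialect
#' (UTF-8, header row, booleans as 0/1, full-precision reals) so that
#' [read_cohort()] round-trips field-for-field, and emits a reference copy
#' of the parameter catalog as JSON.
#'
#' @param dataset A `stampc_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`registry.csv`, `reports.csv`,
#'   `catalog.json`).
#' @export
write_cohort <- function(dataset, dir) {
  stopifnot(inherits(dataset, "stampc_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(registry = file.path(dir, "registry.csv"),
             reports  = file.path(dir, "reports.csv"),
             catalog  = file.path(dir, "catalog.json"))
  reg <- as.data.frame(lapply(dataset$registry, format_csv_value),
                       stringsAsFactors = FALSE)
  rep <- as.data.frame(lapply(dataset$reports, format_csv_value),
                       stringsAsFactors = FALSE)
  utils::write.csv(reg, paths[["registry"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(rep, paths[["reports"]], row.names = FALSE, quote = FALSE)
  jsonlite::write_json(load_parameter_catalog(), paths[["catalog"]],
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(paths)
}

#' Read a cohort dataset from CSV files
#'
#' Inverse of [write_cohort()]: parses `registry.csv` and `reports.csv`
#' from `dir`, restoring logical columns from their 0/1 encoding.
#'
#' @param dir Directory containing `registry.csv` and `reports.csv`.
#' @return A `stampc_cohort`.
#' @export
read_cohort <- function(dir) {
  reg_path <- file.path(dir, "registry.csv")
  rep_path <- file.path(dir, "reports.csv")
  for (p in c(reg_path, rep_path))
    if (!file.exists(p)) stop("cohort file not found: ", p)
  reg <- utils::read.csv(reg_path, stringsAsFactors = FALSE,
                         colClasses = c(patient_id = "character"))
  rep <- utils::read.csv(rep_path, stringsAsFactors = FALSE,
                         colClasses = c(patient_id = "character"))
  for (col in intersect(registry_logical_columns, names(reg)))
    reg[[col]] <- as.logical(reg[[col]])
  if ("mesh_plane" %in% names(reg)) {
    reg$mesh_plane <- as.character(reg$mesh_plane)
    reg$mesh_plane[reg$mesh_plane == ""] <- NA_character_
  }
  param_cols <- setdiff(names(rep), "patient_id")
  for (col in param_cols) rep[[col]] <- as.logical(rep[[col]])
  cohort_dataset(reg, rep)
}
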