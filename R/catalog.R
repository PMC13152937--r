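#' Canonical catalog of CT-based planning parameters
#'
#' Returns the fixed catalog of the 16 CT imaging parameters considered
#' essential for planning abdominal wall reconstruction (AWR): eight
#' *generalizable* parameters, assessable on any preoperative CT regardless
#' of surgical history (e.g. defect width, Tanaka index), and eight
#' *patient-specific* parameters conditional on prior interventions
#' (e.g. old mesh plane, mesh migration). The catalog carries the surgeon
#' consensus importance ratings (mean and SD on a 1-10 Likert scale, 61
#' raters) and, for the seven essential-panel parameters, their STAMP-C
#' mnemonic letter (Size, Tanaka, Anatomical location, Mesh, Plane,
#' Concurrent hernia; C maps to two parameters).
#'
#' The row order is the published consensus order (descending surgeon
#' rating) and is the canonical parameter axis for every downstream table:
#' audit rates, source scores and prioritization results all join on `id`.
#'
#' @return A data frame of class `stampc_catalog` with 16 rows and columns
#'   `id` (snake-case join key), `name`, `category`
#'   (`"generalizable"`/`"patient_specific"`), `stampc_letter`
#'   (`NA` for non-panel parameters), `survey_mean`, `survey_sd`, and
#'   `definition`.
#' @examples
#' cat16 <- load_parameter_catalog()
#' table(cat16$category)
#' cat16$id[!is.na(cat16$stampc_letter)]
#' @export
load_parameter_catalog <- function() {
  catalog <- data.frame(
    id = c(
      "defect_width", "concurrent_parastomal", "old_mesh_plane",
      "prior_mesh", "concurrent_inguinal", "tanaka_index",
      "ehs_location", "wall_abnormality", "n_defects",
      "rectus_measurements", "patient_habitus", "mesh_migration",
      "defect_length", "central_mesh_fracture", "hernia_content",
      "ongoing_sso"
    ),
    name = c(
      "Defect width",
      "Concurrent parastomal or old stomal site hernias",
      "Old mesh plane",
      "Presence of prior mesh",
      "Concurrent inguinal hernias",
      "Tanaka index",
      "Hernia location (EHS classification)",
      "Abdominal wall anatomical abnormalities",
      "Number of defects",
      "Rectus muscle measurements",
      "Patient habitus and fat distribution",
      "Mesh migration",
      "Defect length",
      "Central mesh fracture",
      "Hernia content",
      "Ongoing surgical site occurrences"
    ),
    category = c(
      "generalizable", "patient_specific", "patient_specific",
      "patient_specific", "patient_specific", "generalizable",
      "generalizable", "patient_specific", "generalizable",
      "generalizable", "generalizable", "patient_specific",
      "generalizable", "patient_specific", "generalizable",
      "patient_specific"
    ),
    stampc_letter = c(
      "S", "C", "P", "M", "C", "T", "A", NA, NA, NA, NA, NA, NA, NA, NA, NA
    ),
    survey_mean = c(
      9.16, 8.93, 8.80, 8.61, 8.54, 8.45, 8.36, 8.17,
      8.05, 7.98, 7.97, 7.95, 7.66, 7.64, 7.28, 7.28
    ),
    survey_sd = c(
      2.02, 1.91, 2.25, 2.25, 2.18, 2.32, 2.28, 2.31,
      2.53, 2.18, 2.54, 2.36, 2.73, 2.43, 2.98, 2.47
    ),
    definition = c(
      "Transverse distance between medial fascial edges at the widest point of the defect, axial view",
      "Hernia adjacent to a current stoma or at an old stomal site",
      "Anatomical layer of previously implanted mesh: onlay, sublay or underlay",
      "Visualization of previously placed prosthetic mesh in the abdominal wall or peritoneal cavity",
      "Ipsilateral or contralateral inguinal hernia",
      "Ratio of hernia-sac volume to total peritoneal volume (loss-of-domain predictor)",
      "Defect location per the European Hernia Society classification",
      "Loss or scarring of native fascial planes, especially the posterior rectus sheath",
      "Total count of discrete fascial defects on axial and coronal views",
      "Rectus abdominis width and depth at the widest part of the hernia, axial view",
      "Predominant adipose distribution, visceral versus subcutaneous",
      "Partial or complete displacement of mesh from its intended location",
      "Craniocaudal extent of the fascial defect, sagittal view",
      "Structural discontinuity, segmentation or tearing of a previously placed mesh",
      "Abdominal viscera within the hernia sac",
      "Wound complication: infection, seroma, hematoma, abscess or enterocutaneous fistula"
    ),
    stringsAsFactors = FALSE
  )
  class(catalog) <- c("stampc_catalog", "data.frame")
  catalog
}

#' @export
print.stampc_catalog <- function(x, ...) {
  cat("CT parameter catalog for AWR planning:", nrow(x), "parameters\n")
  cat("  generalizable:   ", sum(x$category == "generalizable"), "\n")
  cat("  patient-specific:", sum(x$category == "patient_specific"), "\n")
  cat("  STAMP-C panel:   ", sum(!is.na(x$stampc_letter)), "\n\n")
  print.data.frame(x[, c("id", "category", "stampc_letter",
                         "survey_mean", "survey_sd")], row.names = FALSE)
  invisible(x)
}

# Registry column holding the ground-truth flag for each patient-specific
# parameter. old_mesh_plane has no flag of its own: its occurrence is the
# prior-mesh-present count (a plane exists iff mesh exists).
registry_flag_column <- function(param_id) {
  map <- c(
    prior_mesh            = "prior_mesh_present",
    old_mesh_plane        = "prior_mesh_present",
    central_mesh_fracture = "mesh_fracture",
    mesh_migration        = "mesh_migration",
    concurrent_inguinal   = "concurrent_inguinal",
    concurrent_parastomal = "concurrent_parastomal_or_stomal",
    wall_abnormality      = "wall_abnormality",
    ongoing_sso           = "ongoing_sso"
  )
  unname(map[param_id])
}

#' Canonical STAMP-C letter map
#'
#' @return Named character vector: parameter id -> mnemonic letter for the
#'   seven essential-panel parameters.
#' @export
stampc_letters <- function() {
  catalog <- load_parameter_catalog()
  with_letter <- !is.na(catalog$stampc_letter)
  stats::setNames(catalog$stampc_letter[with_letter], catalog$id[with_letter])
}
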