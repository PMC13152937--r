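# Random positive reciprocal matrix with entries on the Saaty scale.
random_reciprocal_matrix <- function(n, seed) {
  set.seed(seed)
  saaty <- c(1 / (9:2), 1:9)
  M <- diag(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- sample(saaty, 1)
      M[i, j] <- v
      M[j, i] <- 1 / v
    }
  }
  M
}

# Perfectly consistent matrix generated by a positive weight vector.
consistent_matrix <- function(w) outer(w, w, "/")

# Tiny hand-built cohort: 4 patients with known ground truth and flags.
tiny_cohort <- function() {
  registry <- data.frame(
    patient_id = c("A", "B", "C", "D"),
    prior_mesh_present = c(TRUE, TRUE, FALSE, FALSE),
    mesh_plane = c("sublay", "onlay", NA, NA),
    mesh_fracture = c(TRUE, FALSE, FALSE, FALSE),
    mesh_migration = c(FALSE, FALSE, FALSE, FALSE),
    concurrent_inguinal = c(FALSE, TRUE, FALSE, FALSE),
    concurrent_parastomal_or_stomal = c(FALSE, FALSE, FALSE, FALSE),
    wall_abnormality = c(TRUE, FALSE, TRUE, FALSE),
    ongoing_sso = c(FALSE, FALSE, FALSE, TRUE),
    defect_width_cm = c(12, 20, 8, 15),
    defect_length_cm = c(18, 30, 10, 22),
    n_prior_repairs = c(1L, 3L, 1L, 2L),
    stringsAsFactors = FALSE)
  ids <- load_parameter_catalog()$id
  reports <- data.frame(patient_id = registry$patient_id,
                        stringsAsFactors = FALSE)
  for (pid in ids) reports[[pid]] <- c(FALSE, FALSE, FALSE, FALSE)
  reports$defect_width <- c(TRUE, TRUE, FALSE, FALSE)
  reports$prior_mesh <- c(TRUE, FALSE, FALSE, FALSE)
  reports$old_mesh_plane <- c(TRUE, FALSE, FALSE, FALSE)
  reports$concurrent_inguinal <- c(FALSE, TRUE, TRUE, FALSE)
  cohort_dataset(registry, reports)
}

# Well-separated synthetic source scores: large raw gaps in every column
# so small weight perturbations provably cannot reorder parameters.
separated_sources <- function() {
  ids <- load_parameter_catalog()$id
  structure(data.frame(
    id = ids,
    expert_audit_score = seq(16, 1),
    survey_mean = seq(10, 2.5, length.out = 16),
    literature_freq = seq(40, 4, length.out = 16),
    stringsAsFactors = FALSE), class = c("stampc_sources", "data.frame"))
}
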