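# One user-facing seed expands into fixed per-stage substreams so the
# registry, report and survey generators can be re-run independently while
# staying jointly reproducible.
substream_seed <- function(seed, stream) {
  offset <- c(registry = 11L, reports = 211L, survey = 3011L,
              sensitivity = 40009L)[[stream]]
  as.integer((as.numeric(seed) + offset) %% 2147483629)
}

#' Configuration for the synthetic AWR cohort generator
#'
#' Builds (and validates) the full parameterization of the synthetic
#' registry-and-reports generator. Defaults emulate the original audit
#' cohort: 834 elective TAR patients, all with recurrent incisional
#' hernias, with ground-truth prevalences, mesh-plane mix, defect-size
#' moments and per-parameter documentation behavior calibrated to the
#' published cohort tables.
#'
#' Documentation has two channels for patient-specific parameters:
#' `doc_prob_given_present` (sensitivity of the report to a true finding)
#' and `doc_prob_given_absent` (the over-calling channel), so expected
#' documented counts can exceed ground-truth occurrence — as observed for
#' concurrent inguinal hernias, documented at 2.4 times their
#' intraoperative occurrence. Default channel values assume true findings
#' among the four over-called parameters are always reported, with the
#' over-call probability solved so expected documented counts match the
#' published totals; under-documented parameters use the published rate as
#' sensitivity with no over-calling.
#'
#' @param n_patients Cohort size (default 834).
#' @param prevalence Named probabilities of ground-truth occurrence for the
#'   patient-specific parameters (marginal, over the whole cohort).
#' @param doc_prob Named unconditional documentation probabilities for the
#'   eight generalizable parameters.
#' @param doc_prob_given_present,doc_prob_given_absent Named documentation
#'   channels for the patient-specific parameters (excluding
#'   `old_mesh_plane`, which is driven by `plane_doc_given_mesh_doc`).
#' @param plane_doc_given_mesh_doc Probability the mesh plane is specified
#'   in a report that documents mesh presence (plane documentation is
#'   impossible otherwise).
#' @param plane_mix Mesh-plane distribution among mesh-present patients
#'   (onlay/sublay/underlay), must sum to 1.
#' @param defect_width_mean_sd_cm,defect_length_mean_sd_cm Mean and SD of
#'   the defect dimensions (cm); sampled from a normal truncated at 0.
#' @param n_prior_repairs_probs Distribution of the number of prior repairs
#'   (1..5); normalized to sum 1.
#' @param seed Integer master seed.
#' @return A list of class `stampc_generator_config`.
#' @export
generator_config <- function(
    n_patients = 834,
    prevalence = c(prior_mesh = 0.711, central_mesh_fracture = 0.101,
                   mesh_migration = 0.092, concurrent_inguinal = 0.041,
                   concurrent_parastomal = 0.041, wall_abnormality = 0.300,
                   ongoing_sso = 0.277),
    doc_prob = c(defect_width = 272 / 834, defect_length = 182 / 834,
                 n_defects = 262 / 834, ehs_location = 222 / 834,
                 tanaka_index = 108 / 834, hernia_content = 445 / 834,
                 rectus_measurements = 3 / 834, patient_habitus = 2 / 834),
    doc_prob_given_present = NULL,
    doc_prob_given_absent = NULL,
    plane_doc_given_mesh_doc = 10 / 215,
    plane_mix = c(onlay = 0.30, sublay = 0.56, underlay = 0.14),
    defect_width_mean_sd_cm = c(17.0, 6.8),
    defect_length_mean_sd_cm = c(24.0, 6.2),
    n_prior_repairs_probs = c(0.404, 0.288, 0.138, 0.065, 0.106),
    seed = 1L) {
  ps_ids <- c("prior_mesh", "central_mesh_fracture", "mesh_migration",
              "concurrent_inguinal", "concurrent_parastomal",
              "wall_abnormality", "ongoing_sso")
  gen_ids <- c("defect_width", "defect_length", "n_defects", "ehs_location",
               "tanaka_index", "hernia_content", "rectus_measurements",
               "patient_habitus")

  if (is.null(doc_prob_given_present)) {
    # Over-called parameters: every true finding reported. Under-documented
    # parameters: sensitivity equals the published rate-of-occurrence.
    doc_prob_given_present <- c(
      prior_mesh = 215 / 593, central_mesh_fracture = 1, mesh_migration = 1,
      concurrent_inguinal = 1, concurrent_parastomal = 1,
      wall_abnormality = 180 / 250, ongoing_sso = 51 / 231)
  }
  if (is.null(doc_prob_given_absent)) {
    target_ratio <- c(prior_mesh = 215 / 593, central_mesh_fracture = 87 / 84,
                      mesh_migration = 86 / 77, concurrent_inguinal = 82 / 34,
                      concurrent_parastomal = 80 / 34,
                      wall_abnormality = 180 / 250, ongoing_sso = 51 / 231)
    doc_prob_given_absent <- vapply(ps_ids, function(p) {
      calibrate_overcall(prevalence[[p]], doc_prob_given_present[[p]],
                         target_ratio[[p]])
    }, numeric(1))
  }

  cfg <- structure(list(
    n_patients = as.integer(n_patients), prevalence = prevalence,
    doc_prob = doc_prob, doc_prob_given_present = doc_prob_given_present,
    doc_prob_given_absent = doc_prob_given_absent,
    plane_doc_given_mesh_doc = plane_doc_given_mesh_doc,
    plane_mix = plane_mix,
    defect_width_mean_sd_cm = as.numeric(defect_width_mean_sd_cm),
    defect_length_mean_sd_cm = as.numeric(defect_length_mean_sd_cm),
    n_prior_repairs_probs = n_prior_repairs_probs / sum(n_prior_repairs_probs),
    seed = as.integer(seed)), class = "stampc_generator_config")

  if (cfg$n_patients < 1) stop("n_patients must be a positive integer")
  probs <- c(cfg$prevalence, cfg$doc_prob, cfg$doc_prob_given_present,
             cfg$doc_prob_given_absent, cfg$plane_doc_given_mesh_doc)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("all probabilities must lie in [0, 1]")
  if (!setequal(names(cfg$prevalence), ps_ids) ||
      !setequal(names(cfg$doc_prob_given_present), ps_ids) ||
      !setequal(names(cfg$doc_prob_given_absent), ps_ids))
    stop("patient-specific probability maps must cover exactly: ",
         paste(ps_ids, collapse = ", "))
  if (!setequal(names(cfg$doc_prob), gen_ids))
    stop("doc_prob must cover exactly the eight generalizable parameters")
  if (abs(sum(cfg$plane_mix) - 1) > 1e-9)
    stop("plane_mix must sum to 1")
  if (!setequal(names(cfg$plane_mix), mesh_planes))
    stop("plane_mix must be named onlay/sublay/underlay")
  for (p in c("central_mesh_fracture", "mesh_migration")) {
    if (cfg$prevalence[[p]] > cfg$prevalence[["prior_mesh"]] + 1e-12)
      stop(p, " marginal prevalence cannot exceed prior_mesh prevalence")
  }
  if (any(cfg$defect_width_mean_sd_cm <= 0) ||
      any(cfg$defect_length_mean_sd_cm <= 0))
    stop("defect dimension means and SDs must be positive")
  cfg
}

#' Solve the over-call channel for a target documentation ratio
#'
#' Given a ground-truth prevalence and a documentation sensitivity
#' P(documented | present), solves the over-call probability
#' P(documented | absent) such that the expected documented count is
#' `overcall_ratio` times the expected occurrence count:
#' `prevalence * p_present + (1 - prevalence) * p_absent =
#'  overcall_ratio * prevalence`.
#'
#' @param prevalence Ground-truth occurrence probability, in (0, 1).
#' @param p_present Documentation probability when the finding is present.
#' @param overcall_ratio Target documented/occurrence ratio (e.g. 2.412 for
#'   a rate of 241.2% of occurrence).
#' @return P(documented | absent), in \[0, 1\]; errors when the target is
#'   infeasible for the given sensitivity.
#' @export
calibrate_overcall <- function(prevalence, p_present, overcall_ratio) {
  stopifnot(prevalence > 0, prevalence < 1,
            p_present >= 0, p_present <= 1, overcall_ratio >= 0)
  p_absent <- (overcall_ratio * prevalence - prevalence * p_present) /
    (1 - prevalence)
  if (p_absent < -1e-12 || p_absent > 1 + 1e-12)
    stop(sprintf(
      "infeasible over-call target: ratio %.3f with p_present %.3f requires p_absent %.4f",
      overcall_ratio, p_present, p_absent))
  min(max(p_absent, 0), 1)
}

#' Generate a synthetic registry of intraoperative ground truth
#'
#' Simulates one row per patient of operative/registry findings under the
#' configured prevalences. Logical structure is enforced at sampling time:
#' mesh fracture and migration are drawn only among mesh-present patients,
#' with conditional rates `prevalence / prevalence[prior_mesh]` so the
#' configured marginal prevalences are recovered; a mesh plane is assigned
#' iff prior mesh is present; defect dimensions are drawn from normals
#' truncated at 0. Reproducible for a fixed `config$seed`.
#'
#' @param config A [generator_config()].
#' @return Data frame with one row per patient and the registry schema
#'   (`patient_id`, ground-truth flags, `mesh_plane`, defect dimensions,
#'   `n_prior_repairs`).
#' @export
generate_registry <- function(config) {
  stopifnot(inherits(config, "stampc_generator_config"))
  n <- config$n_patients
  prev <- config$prevalence
  set.seed(substream_seed(config$seed, "registry"))

  prior_mesh <- stats::runif(n) < prev[["prior_mesh"]]
  cond <- function(p) if (prev[["prior_mesh"]] > 0) p / prev[["prior_mesh"]] else 0
  fracture <- prior_mesh & stats::runif(n) < cond(prev[["central_mesh_fracture"]])
  migration <- prior_mesh & stats::runif(n) < cond(prev[["mesh_migration"]])
  plane <- rep(NA_character_, n)
  if (any(prior_mesh))
    plane[prior_mesh] <- sample(names(config$plane_mix), sum(prior_mesh),
                                replace = TRUE, prob = config$plane_mix)
  rtruncnorm0 <- function(n, mean, sd) {
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
    x
  }
  data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    prior_mesh_present = prior_mesh,
    mesh_plane = plane,
    mesh_fracture = fracture,
    mesh_migration = migration,
    concurrent_inguinal = stats::runif(n) < prev[["concurrent_inguinal"]],
    concurrent_parastomal_or_stomal =
      stats::runif(n) < prev[["concurrent_parastomal"]],
    wall_abnormality = stats::runif(n) < prev[["wall_abnormality"]],
    ongoing_sso = stats::runif(n) < prev[["ongoing_sso"]],
    defect_width_cm = rtruncnorm0(n, config$defect_width_mean_sd_cm[1],
                                  config$defect_width_mean_sd_cm[2]),
    defect_length_cm = rtruncnorm0(n, config$defect_length_mean_sd_cm[1],
                                   config$defect_length_mean_sd_cm[2]),
    n_prior_repairs = sample(seq_along(config$n_prior_repairs_probs), n,
                             replace = TRUE,
                             prob = config$n_prior_repairs_probs),
    stringsAsFactors = FALSE
  )
}

#' Generate synthetic CT-report abstractions for a registry
#'
#' Simulates the binary documented/not-documented flag for each of the 16
#' catalog parameters in each patient's CT report. Generalizable parameters
#' are documented with their unconditional probability. Patient-specific
#' parameters are documented through two channels — P(documented | finding
#' present) and P(documented | finding absent), the over-calling channel —
#' so documented counts can exceed ground-truth occurrence. The old mesh
#' plane can only be documented in reports that document mesh presence.
#'
#' @param registry Registry data frame from [generate_registry()] (or read
#'   from disk with the same schema).
#' @param config The [generator_config()] used (or to be used) with it.
#' @return Data frame: `patient_id` plus one logical column per catalog
#'   parameter id.
#' @export
generate_report_abstractions <- function(registry, config) {
  stopifnot(inherits(config, "stampc_generator_config"))
  if (nrow(registry) != config$n_patients)
    stop("registry has ", nrow(registry), " rows but config expects ",
         config$n_patients)
  n <- nrow(registry)
  set.seed(substream_seed(config$seed, "reports"))

  out <- data.frame(patient_id = registry$patient_id,
                    stringsAsFactors = FALSE)
  catalog <- load_parameter_catalog()
  two_channel <- function(present, p_pres, p_abs) {
    p <- ifelse(present, p_pres, p_abs)
    stats::runif(n) < p
  }
  for (pid in catalog$id) {
    if (pid == "old_mesh_plane") next
    if (catalog$category[catalog$id == pid] == "generalizable") {
      out[[pid]] <- stats::runif(n) < config$doc_prob[[pid]]
    } else {
      flag <- registry[[registry_flag_column(pid)]]
      out[[pid]] <- two_channel(flag, config$doc_prob_given_present[[pid]],
                                config$doc_prob_given_absent[[pid]])
    }
  }
  out$old_mesh_plane <- out$prior_mesh &
    stats::runif(n) < config$plane_doc_given_mesh_doc
  out[, c("patient_id", catalog$id)]
}

#' Generate a full synthetic cohort
#'
#' Convenience wrapper running [generate_registry()] and
#' [generate_report_abstractions()] under one config, returning a
#' [cohort_dataset()] with provenance (seed and config echo).
#'
#' @param config A [generator_config()].
#' @return A `stampc_cohort`.
#' @export
generate_cohort <- function(config = generator_config()) {
  registry <- generate_registry(config)
  reports <- generate_report_abstractions(registry, config)
  cohort_dataset(registry, reports,
                 provenance = list(seed = config$seed, config = unclass(config)))
}

#' Expected documentation rates implied by a generator configuration
#'
#' Closed-form expected audit rates (percent of the category-appropriate
#' denominator) implied by the configured documentation channels; the
#' values audit rates converge to as the cohort grows.
#'
#' @param config A [generator_config()].
#' @return Data frame with columns `id` and `expected_rate_pct`.
#' @export
expected_documentation_rates <- function(config) {
  stopifnot(inherits(config, "stampc_generator_config"))
  catalog <- load_parameter_catalog()
  prev <- config$prevalence
  rate <- vapply(catalog$id, function(pid) {
    if (catalog$category[catalog$id == pid] == "generalizable")
      return(100 * config$doc_prob[[pid]])
    if (pid == "old_mesh_plane") {
      pm <- prev[["prior_mesh"]]
      p_doc_mesh <- pm * config$doc_prob_given_present[["prior_mesh"]] +
        (1 - pm) * config$doc_prob_given_absent[["prior_mesh"]]
      return(100 * p_doc_mesh * config$plane_doc_given_mesh_doc / pm)
    }
    p <- prev[[pid]]
    100 * (p * config$doc_prob_given_present[[pid]] +
             (1 - p) * config$doc_prob_given_absent[[pid]]) / p
  }, numeric(1))
  data.frame(id = catalog$id, expected_rate_pct = unname(rate),
             stringsAsFactors = FALSE)
}

# Exact pmf of the latent-normal Likert model: Z ~ N(mu, sigma), clamped to
# [1, 10], rounded to the nearest integer. Support {1, ..., 10}.
likert_pmf <- function(mu, sigma) {
  k <- 1:10
  upper <- stats::pnorm((k + 0.5 - mu) / sigma)
  lower <- stats::pnorm((k - 0.5 - mu) / sigma)
  p <- upper - lower
  p[1] <- stats::pnorm((1.5 - mu) / sigma)
  p[10] <- 1 - stats::pnorm((9.5 - mu) / sigma)
  p
}

likert_moments <- function(mu, sigma) {
  p <- likert_pmf(mu, sigma)
  k <- 1:10
  m <- sum(k * p)
  v <- sum((k - m)^2 * p)
  c(mean = m, sd = sqrt(v))
}

#' Calibrate the truncated-Likert generator to target moments
#'
#' Solves for latent normal parameters (mu, sigma) such that the
#' clamped-and-rounded variable on the 1-10 support has the requested mean
#' and SD, by numerical root-finding against the exact moment sums over the
#' 10 support points. Used to make the synthetic surgeon survey reproduce
#' published per-parameter mean +/- SD pairs.
#'
#' Feasibility: no distribution on \[1, 10\] with mean m can have SD at or
#' above `sqrt((10 - m) * (m - 1))` (the two-point bound); targets at or
#' beyond it raise an error stating the feasible SD range.
#'
#' @param target_mean Target mean, strictly inside (1, 10).
#' @param target_sd Target SD, > 0 and below the two-point bound.
#' @param tol Required absolute accuracy on both achieved moments
#'   (default 1e-3).
#' @return Named numeric vector `c(mu, sigma)`.
#' @export
calibrate_truncated_likert <- function(target_mean, target_sd, tol = 1e-3) {
  if (!(target_mean > 1 && target_mean < 10))
    stop("target_mean must lie strictly inside (1, 10)")
  if (!(target_sd > 0)) stop("target_sd must be positive")
  sd_bound <- sqrt((10 - target_mean) * (target_mean - 1))
  if (target_sd >= sd_bound)
    stop(sprintf(
      "infeasible moment pair: with mean %.3f the SD must lie in (0, %.3f)",
      target_mean, sd_bound))
  obj <- function(par) {
    m <- likert_moments(par[1], exp(par[2]))
    (m[["mean"]] - target_mean)^2 + (m[["sd"]] - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 20000))
  mu <- fit$par[1]; sigma <- exp(fit$par[2])
  ach <- likert_moments(mu, sigma)
  if (abs(ach[["mean"]] - target_mean) > tol ||
      abs(ach[["sd"]] - target_sd) > tol)
    stop(sprintf(
      "calibration did not reach tolerance %g for target (%.3f, %.3f); achieved (%.4f, %.4f); the SD may be too close to the feasible bound %.3f",
      tol, target_mean, target_sd, ach[["mean"]], ach[["sd"]], sd_bound))
  c(mu = mu, sigma = sigma)
}

#' Generate a synthetic surgeon importance survey
#'
#' Simulates Likert ratings (integer 1-10) for each catalog parameter from
#' the calibrated latent-normal model, one row per rater. Defaults emulate
#' the published survey: 61 AWR surgeons, per-parameter target moments from
#' the consensus table. A target SD of 0 is handled as degenerate: every
#' rating equals the rounded target mean.
#'
#' @param n_raters Number of raters (default 61).
#' @param targets Data frame with columns `id`, `mean`, `sd` (defaults to
#'   the catalog's published moments).
#' @param seed Integer seed.
#' @return Integer matrix `n_raters x n_parameters` with parameter ids as
#'   column names and rater ids as row names.
#' @export
generate_survey <- function(n_raters = 61,
                            targets = NULL,
                            seed = 1L) {
  if (n_raters < 1) stop("n_raters must be >= 1")
  if (is.null(targets)) {
    catalog <- load_parameter_catalog()
    targets <- data.frame(id = catalog$id, mean = catalog$survey_mean,
                          sd = catalog$survey_sd, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "mean", "sd") %in% names(targets)))
  pars <- lapply(seq_len(nrow(targets)), function(i) {
    if (targets$sd[i] == 0) NULL
    else calibrate_truncated_likert(targets$mean[i], targets$sd[i])
  })
  set.seed(substream_seed(seed, "survey"))
  ratings <- vapply(seq_len(nrow(targets)), function(i) {
    if (is.null(pars[[i]])) rep(as.integer(round(targets$mean[i])), n_raters)
    else {
      z <- stats::rnorm(n_raters, pars[[i]][["mu"]], pars[[i]][["sigma"]])
      as.integer(round(pmin(pmax(z, 1), 10)))
    }
  }, integer(n_raters))
  ratings <- matrix(ratings, nrow = n_raters,
                    dimnames = list(sprintf("R%03d", seq_len(n_raters)),
                                    targets$id))
  ratings
}

#' Assemble the three-source score table for prioritization
#'
#' Joins the three evidence sources the multi-criteria analysis aggregates:
#' the expert-audit panel ranking (rank value 1-16, higher = more
#' important, used directly as the raw score), the surgeon-survey
#' per-parameter sample means, and literature citation frequencies from a
#' systematic review of `n_studies` studies.
#'
#' @param survey Ratings matrix from [generate_survey()] (columns =
#'   parameter ids).
#' @param audit_ranks Named integer vector (all catalog ids), each in
#'   1..16; a permutation-with-ties.
#' @param literature_freq Named non-negative counts (all catalog ids), each
#'   at most `n_studies`.
#' @param n_studies Size of the systematic review (default 40).
#' @return Data frame of class `stampc_sources` with columns `id`,
#'   `expert_audit_score`, `survey_mean`, `literature_freq`.
#' @export
generate_source_scores <- function(survey, audit_ranks, literature_freq,
                                   n_studies = 40) {
  catalog <- load_parameter_catalog()
  ids <- catalog$id
  if (!setequal(colnames(survey), ids))
    stop("survey columns must be exactly the 16 catalog ids")
  if (!setequal(names(audit_ranks), ids) ||
      !setequal(names(literature_freq), ids))
    stop("audit_ranks and literature_freq must be named by the 16 catalog ids")
  if (any(audit_ranks < 1 | audit_ranks > 16))
    stop("audit_ranks must lie in 1..16")
  if (any(literature_freq < 0 | literature_freq > n_studies))
    stop("literature_freq must lie in [0, n_studies]")
  out <- data.frame(
    id = ids,
    expert_audit_score = as.numeric(audit_ranks[ids]),
    survey_mean = colMeans(survey)[ids],
    literature_freq = as.numeric(literature_freq[ids]),
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("stampc_sources", "data.frame")
  out
}
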