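test_that("the generator is reproducible: same seed and config, identical output", {
  cfg <- generator_config(n_patients = 120, seed = 99)
  expect_identical(generate_registry(cfg), generate_registry(cfg))
  reg <- generate_registry(cfg)
  expect_identical(generate_report_abstractions(reg, cfg),
                   generate_report_abstractions(reg, cfg))
  expect_identical(generate_survey(61, seed = 5), generate_survey(61, seed = 5))
})

test_that("registry prevalences are recovered within binomial sampling error", {
  cfg <- generator_config(seed = 7)  # n = 834, prior mesh 0.711
  reg <- generate_registry(cfg)
  count <- sum(reg$prior_mesh_present)
  ci <- qbinom(c(0.005, 0.995), 834, 0.711)  # central 99% interval around 593
  expect_gte(count, ci[1])
  expect_lte(count, ci[2])
  expect_true(all(reg$defect_width_cm > 0))
  expect_true(all(is.na(reg$mesh_plane) == !reg$prior_mesh_present))
})

test_that("degenerate prevalences behave as configured", {
  zero_ps <- c(prior_mesh = 0, central_mesh_fracture = 0, mesh_migration = 0,
               concurrent_inguinal = 0, concurrent_parastomal = 0,
               wall_abnormality = 0, ongoing_sso = 0)
  cfg <- generator_config(n_patients = 80, prevalence = zero_ps,
                          doc_prob_given_present = zero_ps + 0.5,
                          doc_prob_given_absent = zero_ps, seed = 2)
  reg <- generate_registry(cfg)
  flags <- c("prior_mesh_present", "mesh_fracture", "mesh_migration",
             "concurrent_inguinal", "concurrent_parastomal_or_stomal",
             "wall_abnormality", "ongoing_sso")
  for (f in flags) expect_false(any(reg[[f]]), info = f)

  cfg1 <- generator_config(
    n_patients = 2000,
    prevalence = replace(zero_ps, "prior_mesh", 1),
    doc_prob_given_present = zero_ps + 0.5, doc_prob_given_absent = zero_ps,
    seed = 4)
  reg1 <- generate_registry(cfg1)
  expect_true(all(reg1$prior_mesh_present))
  expect_false(anyNA(reg1$mesh_plane))
  mix <- table(reg1$mesh_plane)[c("onlay", "sublay", "underlay")] / 2000
  expect_true(all(abs(mix - c(0.30, 0.56, 0.14)) < 0.04))
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(n_patients = 0), "positive")
  bad_prev <- c(prior_mesh = 1.2, central_mesh_fracture = 0.1,
                mesh_migration = 0.1, concurrent_inguinal = 0.04,
                concurrent_parastomal = 0.04, wall_abnormality = 0.3,
                ongoing_sso = 0.28)
  expect_error(
    generator_config(prevalence = bad_prev,
                     doc_prob_given_present = bad_prev * 0,
                     doc_prob_given_absent = bad_prev * 0),
    "\\[0, 1\\]")
  expect_error(
    generator_config(plane_mix = c(onlay = 0.5, sublay = 0.5, underlay = 0.5)),
    "sum to 1")
})

test_that("documented counts track the configured channels, over-calling included", {
  cfg <- generator_config(seed = 13)  # defect width doc prob 272/834
  cohort <- generate_cohort(cfg)
  documented <- sum(cohort$reports$defect_width)
  ci <- qbinom(c(0.005, 0.995), 834, 272 / 834)  # near 272
  expect_gte(documented, ci[1])
  expect_lte(documented, ci[2])
  # plane documentation is a subset of mesh-presence documentation
  expect_true(all(cohort$reports$prior_mesh[cohort$reports$old_mesh_plane]))

  zero <- cfg$doc_prob * 0
  cfg0 <- generator_config(
    n_patients = 100, doc_prob = zero,
    doc_prob_given_present = cfg$doc_prob_given_present * 0,
    doc_prob_given_absent = cfg$doc_prob_given_absent * 0,
    plane_doc_given_mesh_doc = 0, seed = 13)
  reports0 <- generate_report_abstractions(generate_registry(cfg0), cfg0)
  expect_false(any(as.matrix(reports0[, -1])))
})

test_that("the over-call channel solves for, then reproduces, a target ratio", {
  # expected documented = 2.412 x expected occurrence at prevalence 0.041
  p_absent <- calibrate_overcall(0.041, 0.5, 2.412)
  expect_equal(p_absent, (2.412 * 0.041 - 0.041 * 0.5) / (1 - 0.041),
               tolerance = 1e-12)
  expect_error(calibrate_overcall(0.5, 0.1, 3), "infeasible")

  prev <- c(prior_mesh = 0.711, central_mesh_fracture = 0.101,
            mesh_migration = 0.092, concurrent_inguinal = 0.041,
            concurrent_parastomal = 0.041, wall_abnormality = 0.300,
            ongoing_sso = 0.277)
  p_pres <- replace(prev * 0 + 1, "concurrent_inguinal", 0.5)
  p_abs <- prev * 0
  p_abs[["concurrent_inguinal"]] <- p_absent
  cfg <- generator_config(n_patients = 50000, prevalence = prev,
                          doc_prob_given_present = p_pres,
                          doc_prob_given_absent = p_abs, seed = 21)
  cohort <- generate_cohort(cfg)
  rate <- documentation_rate("concurrent_inguinal", cohort$reports,
                             cohort$registry)$rate_pct
  expect_lt(abs(rate - 241.2) / 241.2, 0.05)
})

test_that("Likert calibration hits target moments on the 1-10 support", {
  # symmetric target centers the latent mean
  par <- calibrate_truncated_likert(5.5, 2.5)
  expect_equal(unname(par[["mu"]]), 5.5, tolerance = 1e-6)

  par <- calibrate_truncated_likert(9.16, 2.02)
  # independent Monte Carlo oracle: simulate the clamp-and-round model
  set.seed(1)
  z <- rnorm(4e5, par[["mu"]], par[["sigma"]])
  x <- round(pmin(pmax(z, 1), 10))
  expect_equal(mean(x), 9.16, tolerance = 0.02)
  expect_equal(sd(x), 2.02, tolerance = 0.02)

  expect_error(calibrate_truncated_likert(9.99, 2.0), "infeasible")
  expect_error(calibrate_truncated_likert(10.5, 1), "inside")
  expect_error(calibrate_truncated_likert(5, 0), "positive")
})

test_that("survey generation respects support, degeneracy, and target moments", {
  s1 <- generate_survey(n_raters = 1, seed = 8)
  expect_equal(nrow(s1), 1L)
  expect_true(all(s1 >= 1 & s1 <= 10))

  deg <- generate_survey(5, targets = data.frame(id = "defect_width",
                                                 mean = 7.4, sd = 0), seed = 1)
  expect_true(all(deg == 7L))

  s <- generate_survey(61, seed = 42)
  expect_true(all(s == round(s) & s >= 1 & s <= 10))
  se <- 2.02 / sqrt(61)
  expect_lt(abs(mean(s[, "defect_width"]) - 9.16), 3 * se)
})

test_that("source-score assembly validates and orders its three columns", {
  survey <- generate_survey(10, seed = 3)
  ids <- load_parameter_catalog()$id
  ranks <- setNames(seq(16, 1), ids)
  freq <- setNames(rep(20, 16), ids)
  freq[["defect_width"]] <- 40
  src <- generate_source_scores(survey, ranks, freq)
  expect_equal(src$id, ids)
  expect_equal(src$expert_audit_score[src$id == "defect_width"], 16)
  expect_equal(which.max(src$literature_freq),
               which(src$id == "defect_width"))
  expect_error(generate_source_scores(survey, replace(ranks, 1, 17), freq),
               "1..16")
  expect_error(generate_source_scores(survey, ranks, replace(freq, 1, 41)),
               "n_studies")
  # all-equal inputs give constant columns
  flat <- generate_source_scores(
    matrix(5L, 4, 16, dimnames = list(NULL, ids)),
    setNames(rep(8L, 16), ids), setNames(rep(10, 16), ids))
  expect_equal(var(flat$expert_audit_score), 0)
  expect_equal(var(flat$survey_mean), 0)
})
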