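test_that("published per-parameter rates recompute from their counts", {
  rates <- rates_from_counts(reference_documentation_counts())
  pick <- function(id) rates$rate_pct[rates$id == id]
  expect_lt(abs(pick("defect_width") - 32.6), 0.1)   # 272/834
  expect_lt(abs(pick("prior_mesh") - 36.2), 0.1)     # 215/593
  expect_lt(abs(pick("old_mesh_plane") - 1.7), 0.1)  # 10/593
  expect_lt(abs(pick("central_mesh_fracture") - 103.6), 0.1)
  expect_lt(abs(pick("concurrent_inguinal") - 241.2), 0.1)
  # patient-specific rates may exceed 100; generalizable never do
  expect_true(all(rates$rate_pct[rates$category == "generalizable"] <= 100))
})

test_that("documentation_rate uses category-appropriate denominators", {
  cohort <- tiny_cohort()
  r <- documentation_rate("defect_width", cohort$reports, cohort$registry)
  expect_equal(r$denominator, 4L)      # whole cohort
  expect_equal(r$rate_pct, 50)
  r <- documentation_rate("prior_mesh", cohort$reports, cohort$registry)
  expect_equal(r$denominator, 2L)      # occurrence count
  expect_equal(r$rate_pct, 50)
  # over-calling: documented twice, present once
  r <- documentation_rate("concurrent_inguinal", cohort$reports,
                          cohort$registry)
  expect_equal(r$rate_pct, 200)
  # zero documented is 0%, zero occurrence is an error (suppressed, not 0)
  r <- documentation_rate("tanaka_index", cohort$reports, cohort$registry)
  expect_equal(r$rate_pct, 0)
  expect_error(
    documentation_rate("concurrent_parastomal", cohort$reports,
                       cohort$registry),
    "zero ground-truth occurrence")
})

test_that("occurrence counting follows ground truth, with the mesh-plane rule", {
  cohort <- tiny_cohort()
  expect_equal(occurrence_count("prior_mesh", cohort$registry), 2L)
  # old mesh plane occurrence equals the prior-mesh-present count
  expect_equal(occurrence_count("old_mesh_plane", cohort$registry), 2L)
  expect_equal(occurrence_count("ongoing_sso", cohort$registry[0, ]), 0L)
  expect_error(occurrence_count("defect_width", cohort$registry),
               "generalizable")
})

test_that("summaries use the midpoint median and carry the range", {
  rates <- rates_from_counts(reference_documentation_counts())
  gen <- category_summary(rates, "generalizable")
  expect_lt(abs(gen$median_pct - 24.2), 0.05)
  expect_lt(abs(gen$min_pct - 0.2), 0.05)
  expect_lt(abs(gen$max_pct - 53.4), 0.05)
  ps <- category_summary(rates, "patient_specific")
  expect_lt(abs(ps$median_pct - 87.8), 0.05)
  expect_lt(abs(ps$max_pct - 241.2), 0.05)

  one <- rates[rates$id == "defect_width", ]
  s <- category_summary(one, "generalizable")
  expect_equal(s$median_pct, s$min_pct)
  expect_equal(s$median_pct, s$max_pct)

  two <- rates[1:2, ]
  two$rate_pct <- c(10, 20)
  expect_equal(category_summary(two, "overall")$median_pct, 15)

  same <- rates
  same$rate_pct <- 33.3
  expect_equal(overall_summary(same)$median_pct, 33.3)
  expect_error(overall_summary(rates[-1, ]), "defect_width")
  expect_error(category_summary(rates[0, ], "overall"), "no rates")
})

test_that("summary medians are permutation-invariant and monotone", {
  rates <- rates_from_counts(reference_documentation_counts())
  shuffled <- rates[sample(nrow(rates)), ]
  expect_equal(overall_summary(shuffled)$median_pct,
               overall_summary(rates)$median_pct)
  base <- overall_summary(rates)$median_pct
  for (i in seq_len(nrow(rates))) {
    bumped <- rates
    bumped$rate_pct[i] <- bumped$rate_pct[i] + 7
    expect_gte(overall_summary(bumped)$median_pct, base)
  }
})

test_that("audit rates on a synthetic cohort converge to the configured channels", {
  cfg <- generator_config(n_patients = 20000, seed = 17)
  rates <- audit_cohort(generate_cohort(cfg))
  expected <- expected_documentation_rates(cfg)
  m <- merge(rates, expected, by = "id")
  low <- m$expected_rate_pct <= 100
  expect_true(all(abs(m$rate_pct - m$expected_rate_pct)[low] < 2.5))
  expect_true(all((abs(m$rate_pct - m$expected_rate_pct) /
                     m$expected_rate_pct)[!low] < 0.10))
})
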