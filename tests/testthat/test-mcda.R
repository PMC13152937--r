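test_that("normalization schemes behave as defined and reject degeneracy", {
  expect_equal(normalize_source(c(1, 1, 1, 1), "sum_to_100"), rep(25, 4))
  expect_equal(normalize_source(c(2, 4, 6), "min_max"), c(0, 0.5, 1))
  z <- normalize_source(c(2, 4, 9), "z_score")
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_error(normalize_source(c(3, 3, 3), "min_max"), "degenerate")
  expect_error(normalize_source(c(3, 3, 3), "z_score"), "degenerate")
  expect_error(normalize_source(5, "sum_to_100"), "at least 2")

  means <- load_parameter_catalog()$survey_mean
  n <- normalize_source(means, "sum_to_100")
  expect_equal(sum(n), 100, tolerance = 1e-12)
  expect_equal(which.max(n), 1L)  # defect width tops the survey column
})

test_that("aggregation is the weighted convex combination it claims to be", {
  cfg <- mcda_config()
  col <- c(5, 3, 1)
  same <- cbind(col, col, col)
  expect_equal(mcda_aggregate(same, cfg), col)  # convexity fixed point

  # hand computation oracle, three parameters
  normalized <- rbind(c(10, 20, 30), c(40, 50, 60), c(50, 30, 10))
  got <- mcda_aggregate(normalized, cfg)
  by_hand <- c(0.406 * 10 + 0.323 * 20 + 0.271 * 30,
               0.406 * 40 + 0.323 * 50 + 0.271 * 60,
               0.406 * 50 + 0.323 * 30 + 0.271 * 10)
  expect_equal(got, by_hand, tolerance = 1e-12)

  expect_equal(mcda_aggregate(normalized, mcda_config(scale_factor = 2)),
               2 * by_hand)
  expect_error(mcda_config(weights = c(0.5, 0.5, 0.5)), "sum to 1")
  expect_error(mcda_config(weights = c(1, 0, 0)), "positive")
  expect_error(mcda_config(tier_thresholds = c(5, 9)), "t1 > t2")
})

test_that("published final scores reproduce the published ranking and tiers", {
  ref <- reference_final_scores()
  res <- rank_and_tier(ref)
  expect_equal(res$id, ref$id)               # printed rank order
  expect_equal(res$rank, 1:16)
  expect_equal(unname(tabulate(res$tier)), c(7L, 3L, 6L))
  expect_equal(res$tier[res$final_score == 9.52], 1L)
  expect_equal(res$tier[res$final_score == 8.73], 2L)
  expect_equal(res$tier[res$final_score == 5.68], 3L)
  expect_equal(res$recommendation[1], "Essential")
  # every parameter sits in exactly one tier
  expect_true(all(res$tier %in% 1:3))
  expect_equal(nrow(res), 16L)
})

test_that("tier boundaries are closed at t1 and ties break by catalog order", {
  ids <- load_parameter_catalog()$id
  scores <- setNames(seq(16, 1) + 0.5, ids)
  scores[1:3] <- 9.0  # boundary and a three-way tie
  res <- rank_and_tier(scores)
  expect_equal(res$tier[match(ids[1:3], res$id)], rep(1L, 3))  # score >= 9 is Tier 1
  expect_equal(res$id[res$final_score == 9.0], ids[1:3])       # catalog order
  expect_equal(sort(res$rank[res$final_score == 9.0]),
               min(res$rank[res$final_score == 9.0]) + 0:2)    # consecutive
  expect_error(rank_and_tier(scores[-1]), "missing final score")
})

test_that("the STAMP-C panel is the Tier-1 set with its mnemonic letters", {
  res <- rank_and_tier(reference_final_scores())
  panel <- stampc_panel(res)
  expect_equal(nrow(panel), 7L)
  expect_setequal(panel$letter, c("S", "T", "A", "M", "P", "C"))
  expect_equal(sum(panel$letter == "C"), 2L)
  expect_equal(panel$id[1], "defect_width")

  ids <- load_parameter_catalog()$id
  low <- setNames(rep(5, 16), ids)
  expect_warning(empty <- stampc_panel(rank_and_tier(low)), "canonical")
  expect_equal(nrow(empty), 0L)

  solo <- replace(low, "defect_width", 9.5)
  expect_warning(p1 <- stampc_panel(rank_and_tier(solo)), "canonical")
  expect_equal(p1$letter, "S")
})

test_that("prioritization is monotone and permutation-equivariant", {
  src <- separated_sources()
  base <- mcda_prioritize(src)
  # permuting the parameter axis permutes ranks identically
  perm <- sample(16)
  res_p <- mcda_prioritize(src[perm, ], mcda_config())
  expect_equal(setNames(res_p$rank, res_p$id)[base$id],
               setNames(base$rank, base$id)[base$id])
  # boosting one parameter's raw score never drops it below a previously
  # lower-ranked competitor (rank-pair property under sum_to_100)
  base_rank <- setNames(base$rank, base$id)
  for (i in c(4, 9, 14)) {
    bumped <- src
    bumped$survey_mean[i] <- bumped$survey_mean[i] + 1
    new_rank <- with(mcda_prioritize(bumped), setNames(rank, id))
    below_before <- names(base_rank)[base_rank > base_rank[src$id[i]]]
    expect_true(all(new_rank[src$id[i]] < new_rank[below_before]))
  }
})

test_that("weight sensitivity is stable when perturbations vanish or cannot matter", {
  src <- separated_sources()
  s <- weight_sensitivity(src, n_draws = 50, concentration = 1e9, seed = 2)
  expect_equal(s$top_k_stability, 1)
  expect_equal(s$mean_rank_correlation, 1)

  flat <- src
  flat$expert_audit_score <- seq(16, 1)
  flat$survey_mean <- seq(16, 1)
  flat$literature_freq <- seq(16, 1)  # identical columns: weights irrelevant
  s2 <- weight_sensitivity(flat, n_draws = 50, concentration = 0.5, seed = 3)
  expect_equal(s2$top_k_stability, 1)
  expect_equal(s2$mean_rank_correlation, 1)

  expect_identical(
    weight_sensitivity(src, n_draws = 20, concentration = 10, seed = 7),
    weight_sensitivity(src, n_draws = 20, concentration = 10, seed = 7))
  expect_true(all(s$rank_summary$min_rank <= s$rank_summary$max_rank))
})
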