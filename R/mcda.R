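#' Configuration for the multi-criteria prioritization
#'
#' @param weights Length-3 positive weights for the three evidence sources,
#'   in the order (systematic review, expert audit, surgeon survey); must
#'   sum to 1 within 1e-9. Default: the published AHP-derived weights.
#' @param normalization Per-source normalization scheme: `"sum_to_100"`
#'   (default; each column rescaled to sum 100), `"min_max"` (affine onto
#'   \[0, 1\]) or `"z_score"` (mean 0, sample SD 1).
#' @param scale_factor Positive multiplier applied to aggregated scores
#'   (default 1).
#' @param tier_thresholds Tier cut-points `c(t1, t2)` with `t1 > t2`:
#'   Tier 1 (Essential) iff score >= t1; Tier 2 (Highly Recommended) iff
#'   t2 <= score < t1; Tier 3 (Recommended) otherwise. Default `c(9, 6)`.
#' @return List of class `stampc_mcda_config`.
#' @export
mcda_config <- function(weights = reference_ahp_weights(),
                        normalization = c("sum_to_100", "min_max", "z_score"),
                        scale_factor = 1,
                        tier_thresholds = c(t1 = 9.0, t2 = 6.0)) {
  normalization <- match.arg(normalization)
  weights <- as.numeric(weights)
  if (length(weights) != 3 || any(weights <= 0))
    stop("weights must be three strictly positive values")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  if (scale_factor <= 0) stop("scale_factor must be positive")
  tier_thresholds <- as.numeric(tier_thresholds)
  if (length(tier_thresholds) != 2 || tier_thresholds[1] <= tier_thresholds[2])
    stop("tier_thresholds must be c(t1, t2) with t1 > t2")
  structure(list(weights = stats::setNames(weights,
                                           c("systematic_review",
                                             "expert_audit",
                                             "surgeon_survey")),
                 normalization = normalization,
                 scale_factor = scale_factor,
                 tier_thresholds = stats::setNames(tier_thresholds,
                                                   c("t1", "t2"))),
            class = "stampc_mcda_config")
}

#' Normalize one source-score column
#'
#' @param raw Numeric vector of raw per-parameter scores (length >= 2).
#' @param scheme `"sum_to_100"`, `"min_max"`, or `"z_score"`.
#' @return Normalized vector: summing to 100, mapped onto \[0, 1\], or
#'   standardized to mean 0 / sample SD 1 respectively. A constant column
#'   is a degenerate-column error under `min_max` and `z_score`.
#' @export
normalize_source <- function(raw, scheme = c("sum_to_100", "min_max",
                                             "z_score")) {
  scheme <- match.arg(scheme)
  raw <- as.numeric(raw)
  if (length(raw) < 2) stop("need at least 2 parameters to normalize")
  if (any(!is.finite(raw))) stop("raw scores must be finite")
  switch(scheme,
    sum_to_100 = {
      if (sum(raw) == 0) stop("cannot rescale an all-zero column to sum 100")
      100 * raw / sum(raw)
    },
    min_max = {
      if (max(raw) == min(raw))
        stop("degenerate (constant) column under min_max normalization")
      (raw - min(raw)) / (max(raw) - min(raw))
    },
    z_score = {
      if (stats::sd(raw) == 0)
        stop("degenerate (constant) column under z_score normalization")
      (raw - mean(raw)) / stats::sd(raw)
    })
}

#' Aggregate normalized source scores into final scores
#'
#' `final(p) = scale_factor * sum_s weight_s * normalized_s(p)` over the
#' three evidence sources. Deterministic.
#'
#' @param normalized Numeric matrix or data frame, parameters x 3 sources,
#'   columns in the weight order (systematic review, expert audit, survey).
#' @param config A [mcda_config()].
#' @return Numeric vector of final scores (named if `normalized` has row
#'   names).
#' @export
mcda_aggregate <- function(normalized, config = mcda_config()) {
  stopifnot(inherits(config, "stampc_mcda_config"))
  normalized <- as.matrix(normalized)
  if (ncol(normalized) != 3)
    stop("expected three normalized source columns, got ", ncol(normalized))
  config$scale_factor * as.numeric(normalized %*% config$weights)
}

tier_of <- function(score, thresholds) {
  ifelse(score >= thresholds[["t1"]], 1L,
         ifelse(score >= thresholds[["t2"]], 2L, 3L))
}

tier_recommendation <- c("Essential", "Highly Recommended", "Recommended")

#' Rank parameters and assign evidence tiers
#'
#' Sorts final scores descending and assigns tiers by fixed thresholds:
#' Tier 1 (Essential) for scores at or above `t1`, Tier 2 (Highly
#' Recommended) for scores in `[t2, t1)`, Tier 3 (Recommended) below
#' `t2`. Ties are broken by catalog order, with equal scores receiving
#' consecutive ranks. STAMP-C membership is Tier-1 membership.
#'
#' @param final_scores Named numeric vector (names = catalog ids) covering
#'   all 16 parameters, or a data frame with columns `id`, `final_score`.
#' @param config A [mcda_config()] (only `tier_thresholds` is used here).
#' @return Data frame of class `stampc_mcda`, ordered by rank, with
#'   columns `rank`, `id`, `final_score`, `tier`, `recommendation`,
#'   `stampc_member`.
#' @export
rank_and_tier <- function(final_scores, config = mcda_config()) {
  stopifnot(inherits(config, "stampc_mcda_config"))
  if (is.data.frame(final_scores))
    final_scores <- stats::setNames(final_scores$final_score, final_scores$id)
  catalog <- load_parameter_catalog()
  missing <- setdiff(catalog$id, names(final_scores))
  if (length(missing))
    stop("missing final score for: ", paste(missing, collapse = ", "))
  scores <- final_scores[catalog$id]  # catalog order = deterministic tie-break
  ord <- order(-scores, seq_along(scores))
  out <- data.frame(
    rank = seq_along(scores),
    id = catalog$id[ord],
    final_score = as.numeric(scores[ord]),
    stringsAsFactors = FALSE)
  out$tier <- tier_of(out$final_score, config$tier_thresholds)
  out$recommendation <- tier_recommendation[out$tier]
  out$stampc_member <- out$tier == 1L
  class(out) <- c("stampc_mcda", "data.frame")
  out
}

#' @export
print.stampc_mcda <- function(x, ...) {
  y <- x
  y$final_score <- sprintf("%.2f", y$final_score)
  print.data.frame(y, row.names = FALSE)
  sizes <- tabulate(x$tier, nbins = 3)
  cat(sprintf("tiers: %d Essential / %d Highly Recommended / %d Recommended\n",
              sizes[1], sizes[2], sizes[3]))
  invisible(x)
}

#' Extract the STAMP-C essential panel from a prioritization
#'
#' Returns the Tier-1 (Essential) parameters with their mnemonic letters:
#' S = defect width (Size), T = Tanaka index, A = EHS location, M = prior
#' mesh, P = old mesh plane, C = concurrent inguinal and
#' parastomal/stomal hernias. If the Tier-1 set differs from the canonical
#' seven-parameter panel a warning is raised and the panel is emitted from
#' the tiers regardless.
#'
#' @param result A `stampc_mcda` from [rank_and_tier()].
#' @return Data frame with columns `letter`, `id`, `name`, `rank`,
#'   `final_score`, ordered by rank.
#' @export
stampc_panel <- function(result) {
  stopifnot(inherits(result, "stampc_mcda"))
  catalog <- load_parameter_catalog()
  letters_map <- stampc_letters()
  tier1 <- result[result$tier == 1L, ]
  if (!setequal(tier1$id, names(letters_map)))
    warning("Tier-1 set differs from the canonical 7-parameter STAMP-C panel")
  data.frame(
    letter = unname(letters_map[tier1$id]),
    id = tier1$id,
    name = catalog$name[match(tier1$id, catalog$id)],
    rank = tier1$rank,
    final_score = tier1$final_score,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Full prioritization from a raw source-score table
#'
#' Normalizes the three evidence columns (systematic-review citation
#' frequency, expert-audit score, survey mean) with the configured scheme,
#' aggregates them with the configured weights, and ranks/tiers the result.
#'
#' @param sources A `stampc_sources` table (see [generate_source_scores()]).
#' @param config A [mcda_config()].
#' @return A `stampc_mcda` data frame with the normalized columns attached
#'   (`norm_systematic_review`, `norm_expert_audit`, `norm_surgeon_survey`).
#' @export
mcda_prioritize <- function(sources, config = mcda_config()) {
  stopifnot(is.data.frame(sources))
  need <- c("id", "expert_audit_score", "survey_mean", "literature_freq")
  if (!all(need %in% names(sources)))
    stop("sources must have columns: ", paste(need, collapse = ", "))
  normalized <- cbind(
    systematic_review = normalize_source(sources$literature_freq,
                                         config$normalization),
    expert_audit = normalize_source(sources$expert_audit_score,
                                    config$normalization),
    surgeon_survey = normalize_source(sources$survey_mean,
                                      config$normalization))
  rownames(normalized) <- sources$id
  final <- stats::setNames(mcda_aggregate(normalized, config), sources$id)
  out <- rank_and_tier(final, config)
  i <- match(out$id, sources$id)
  out$norm_systematic_review <- normalized[i, "systematic_review"]
  out$norm_expert_audit <- normalized[i, "expert_audit"]
  out$norm_surgeon_survey <- normalized[i, "surgeon_survey"]
  out
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Weight-sensitivity analysis of the prioritization
#'
#' Perturbs the three source weights with Dirichlet draws centered on the
#' baseline (`alpha = concentration * baseline`), re-runs the
#' normalization/aggregation/ranking per draw, and summarizes ranking
#' stability: the fraction of draws whose top-k parameter identity set
#' (k = baseline Tier-1 size) equals the baseline's, and the mean Kendall
#' rank correlation between perturbed and baseline rankings. Seeded and
#' reproducible.
#'
#' @param sources A `stampc_sources` table.
#' @param config Baseline [mcda_config()].
#' @param n_draws Number of Dirichlet draws (default 500).
#' @param concentration Dirichlet concentration; larger means smaller
#'   perturbations (default 100).
#' @param seed Integer seed.
#' @return List of class `stampc_sensitivity`: `n_draws`, `concentration`,
#'   `seed`, `k`, `baseline_top_k`, `top_k_stability`,
#'   `mean_rank_correlation`, and `rank_summary` (per-parameter min /
#'   median / max rank over draws).
#' @export
weight_sensitivity <- function(sources, config = mcda_config(),
                               n_draws = 500, concentration = 100,
                               seed = 1L) {
  stopifnot(n_draws >= 1, concentration > 0)
  if (any(config$weights <= 0))
    stop("baseline weights must be strictly positive for Dirichlet perturbation")
  baseline <- mcda_prioritize(sources, config)
  k <- sum(baseline$tier == 1L)
  base_top <- baseline$id[baseline$rank <= k]
  base_rank <- stats::setNames(baseline$rank, baseline$id)

  set.seed(substream_seed(seed, "sensitivity"))
  alpha <- concentration * as.numeric(config$weights)
  ranks <- matrix(NA_integer_, nrow = n_draws, ncol = nrow(baseline),
                  dimnames = list(NULL, names(base_rank)))
  top_match <- logical(n_draws)
  taus <- numeric(n_draws)
  for (d in seq_len(n_draws)) {
    w <- rdirichlet1(alpha)
    cfg_d <- mcda_config(weights = w, normalization = config$normalization,
                         scale_factor = config$scale_factor,
                         tier_thresholds = config$tier_thresholds)
    res <- mcda_prioritize(sources, cfg_d)
    r <- stats::setNames(res$rank, res$id)[names(base_rank)]
    ranks[d, ] <- r
    top_match[d] <- setequal(res$id[res$rank <= k], base_top)
    taus[d] <- if (k == 0 || length(r) < 2) 1 else
      stats::cor(r, base_rank, method = "kendall")
  }
  rank_summary <- data.frame(
    id = names(base_rank),
    baseline_rank = as.integer(base_rank),
    min_rank = apply(ranks, 2, min),
    median_rank = apply(ranks, 2, stats::median),
    max_rank = apply(ranks, 2, max),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(n_draws = n_draws, concentration = concentration,
                 seed = seed, k = k, baseline_top_k = base_top,
                 top_k_stability = mean(top_match),
                 mean_rank_correlation = mean(taus),
                 rank_summary = rank_summary),
            class = "stampc_sensitivity")
}

#' @export
print.stampc_sensitivity <- function(x, ...) {
  cat(sprintf(
    "Weight sensitivity: %d Dirichlet draws, concentration %g, seed %d\n",
    x$n_draws, x$concentration, x$seed))
  cat(sprintf("  top-%d stability: %.3f\n", x$k, x$top_k_stability))
  cat(sprintf("  mean Kendall tau vs baseline: %.3f\n",
              x$mean_rank_correlation))
  invisible(x)
}
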