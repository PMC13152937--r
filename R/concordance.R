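#' Cohen's kappa for two binary raters
#'
#' Chance-corrected agreement between two raters' binary abstractions of
#' the same items: `kappa = (po - pe) / (1 - pe)` with `po` the fraction of
#' identical ratings and `pe` the expected agreement from the raters'
#' marginal label frequencies. When both raters are constant and identical
#' (`po = pe = 1`), kappa is 1 by convention.
#'
#' @param ratings_a,ratings_b Equal-length, non-empty logical/0-1 vectors.
#' @return List of class `stampc_kappa`: `observed_agreement`,
#'   `expected_agreement`, `kappa`, `n_items`.
#' @examples
#' a <- c(rep(1, 50), rep(0, 50))
#' b <- c(rep(1, 45), rep(0, 5), rep(1, 5), rep(0, 45))
#' cohens_kappa(a, b)$kappa  # 0.8
#' @export
cohens_kappa <- function(ratings_a, ratings_b) {
  if (length(ratings_a) == 0 || length(ratings_a) != length(ratings_b))
    stop("ratings must be equal-length non-empty vectors")
  a <- as.integer(as.logical(ratings_a))
  b <- as.integer(as.logical(ratings_b))
  if (anyNA(a) || anyNA(b)) stop("ratings must be binary with no missing values")
  n <- length(a)
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(1 - a) * mean(1 - b)
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 1
  structure(list(observed_agreement = po, expected_agreement = pe,
                 kappa = kappa, n_items = n),
            class = "stampc_kappa")
}

#' @export
print.stampc_kappa <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f (po = %.3f, pe = %.3f, n = %d)\n",
              x$kappa, x$observed_agreement, x$expected_agreement, x$n_items))
  invisible(x)
}

#' Chi-square test for a 2x2 contingency table
#'
#' Pearson chi-square for a 2x2 table of counts `rbind(c(a, b), c(c, d))`:
#' `X2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with 1 degree of freedom,
#' optionally with Yates' continuity correction. Used to compare
#' documentation proportions (e.g. intended versus actual documentation of
#' a parameter).
#'
#' @param table 2x2 numeric matrix of non-negative counts with strictly
#'   positive row and column margins.
#' @param correction Apply Yates' continuity correction (default `FALSE`).
#' @return List of class `stampc_chisq`: `statistic`, `df`, `p_value`,
#'   `correction`, `table`.
#' @export
chi_square_2x2 <- function(table, correction = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2")
  if (any(table < 0) || any(!is.finite(table)))
    stop("counts must be finite and non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row/column margin: statistic undefined")
  a <- table[1, 1]; b <- table[1, 2]; cc <- table[2, 1]; d <- table[2, 2]
  n <- sum(table)
  num <- abs(a * d - b * cc)
  if (correction) num <- max(0, num - n / 2)
  stat <- n * num^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
  structure(list(statistic = stat, df = 1L,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 correction = correction, table = table),
            class = "stampc_chisq")
}

#' @export
print.stampc_chisq <- function(x, ...) {
  cat(sprintf("Chi-square (df = 1%s): X2 = %.4f, p = %.4g\n",
              if (x$correction) ", Yates-corrected" else "",
              x$statistic, x$p_value))
  invisible(x)
}

#' Per-parameter summary of a Likert survey
#'
#' Sample mean and sample SD (n - 1 denominator) of each parameter's
#' ratings, sorted descending by mean — the survey summary table format.
#' With a single rater the SD is reported as `NA` (undefined), not 0.
#'
#' @param survey Ratings matrix (raters x parameters, parameter ids as
#'   column names), as from [generate_survey()].
#' @return Data frame with columns `id`, `mean`, `sd`, `n`, sorted by
#'   descending mean.
#' @export
likert_summary <- function(survey) {
  survey <- as.matrix(survey)
  if (nrow(survey) == 0 || ncol(survey) == 0) stop("empty survey")
  n <- nrow(survey)
  out <- data.frame(
    id = colnames(survey),
    mean = colMeans(survey),
    sd = if (n > 1) apply(survey, 2, stats::sd) else NA_real_,
    n = n,
    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$mean), , drop = FALSE]
}
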