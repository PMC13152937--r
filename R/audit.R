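#' Ground-truth occurrence count for a patient-specific parameter
#'
#' Counts registry records where the parameter's ground-truth flag is true.
#' For `old_mesh_plane` the occurrence is the prior-mesh-present count: a
#' mesh plane exists for exactly the patients with mesh. Defined only for
#' patient-specific parameters — generalizable parameters are audited
#' against the whole cohort, not an occurrence count.
#'
#' @param param_id A patient-specific catalog parameter id.
#' @param registry Registry data frame.
#' @return Integer count.
#' @export
occurrence_count <- function(param_id, registry) {
  catalog <- load_parameter_catalog()
  if (!param_id %in% catalog$id) stop("unknown parameter id: ", param_id)
  if (catalog$category[catalog$id == param_id] != "patient_specific")
    stop("occurrence_count is defined only for patient-specific parameters; ",
         param_id, " is generalizable")
  if (nrow(registry) == 0) return(0L)
  sum(registry[[registry_flag_column(param_id)]])
}

#' Documentation rate of one parameter with its category denominator
#'
#' The audit's core statistic. For a generalizable parameter, the rate is
#' the percent of all CT reports documenting it. For a patient-specific
#' parameter, the denominator is the ground-truth occurrence count, so the
#' rate is "percent of occurrence" and can exceed 100 when radiologists
#' over-call findings not confirmed intraoperatively. Rates are carried at
#' full precision; display rounds to one decimal.
#'
#' @param param_id A catalog parameter id.
#' @param reports Report-abstraction data frame.
#' @param registry Registry data frame.
#' @return One-row data frame: `id`, `category`, `numerator`,
#'   `denominator`, `rate_pct`.
#' @examples
#' cohort <- generate_cohort(generator_config(n_patients = 200, seed = 7))
#' documentation_rate("defect_width", cohort$reports, cohort$registry)
#' @export
documentation_rate <- function(param_id, reports, registry) {
  catalog <- load_parameter_catalog()
  if (!param_id %in% catalog$id) stop("unknown parameter id: ", param_id)
  category <- catalog$category[catalog$id == param_id]
  numerator <- sum(reports[[param_id]])
  if (category == "generalizable") {
    denominator <- nrow(reports)
    if (denominator == 0) stop("empty report set: rate undefined")
  } else {
    denominator <- occurrence_count(param_id, registry)
    if (denominator == 0)
      stop("parameter ", param_id,
           " has zero ground-truth occurrence: rate undefined (suppressed, not 0)")
  }
  data.frame(id = param_id, category = category,
             numerator = as.integer(numerator),
             denominator = as.integer(denominator),
             rate_pct = 100 * numerator / denominator,
             stringsAsFactors = FALSE)
}

#' Documentation rates for all 16 parameters of a cohort
#'
#' @param cohort A `stampc_cohort`.
#' @return Data frame of class `stampc_rates`, one row per catalog
#'   parameter in catalog order.
#' @export
audit_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "stampc_cohort"))
  catalog <- load_parameter_catalog()
  rows <- lapply(catalog$id, documentation_rate,
                 reports = cohort$reports, registry = cohort$registry)
  out <- do.call(rbind, rows)
  class(out) <- c("stampc_rates", "data.frame")
  out
}

#' Rates table from pre-tabulated numerator/denominator counts
#'
#' Builds the same rates table as [audit_cohort()] from already-counted
#' numerators and denominators (e.g. the published reference counts),
#' recomputing each percentage at full precision.
#'
#' @param counts Data frame with columns `id`, `numerator`, `denominator`
#'   covering all 16 catalog ids (e.g.
#'   [reference_documentation_counts()]).
#' @return Data frame of class `stampc_rates` in catalog order.
#' @export
rates_from_counts <- function(counts) {
  catalog <- load_parameter_catalog()
  missing <- setdiff(catalog$id, counts$id)
  if (length(missing))
    stop("counts table missing parameter(s): ", paste(missing, collapse = ", "))
  i <- match(catalog$id, counts$id)
  out <- data.frame(
    id = catalog$id,
    category = catalog$category,
    numerator = as.integer(counts$numerator[i]),
    denominator = as.integer(counts$denominator[i]),
    stringsAsFactors = FALSE)
  if (any(out$denominator <= 0)) stop("denominators must be positive")
  out$rate_pct <- 100 * out$numerator / out$denominator
  class(out) <- c("stampc_rates", "data.frame")
  out
}

#' @export
print.stampc_rates <- function(x, ...) {
  y <- x
  y$rate_pct <- sprintf("%.1f", y$rate_pct)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

# Median with the midpoint convention: mean of the two central order
# statistics for even counts (stats::median's default for numeric input).
rate_median <- function(x) stats::median(x)

#' Completeness summary over a set of documentation rates
#'
#' Median and range of documentation rates within one scope: the eight
#' generalizable parameters, the eight patient-specific parameters, or all
#' sixteen pooled (`overall`). The overall median pools both categories
#' despite their different denominators — the convention behind the
#' headline completeness figure.
#'
#' @param rates A `stampc_rates` table (or subset of one).
#' @param scope `"generalizable"`, `"patient_specific"`, or `"overall"`.
#' @return A list of class `stampc_summary`: `scope`, `median_pct`,
#'   `min_pct`, `max_pct`, `n`, `rates`.
#' @export
category_summary <- function(rates, scope = c("generalizable",
                                              "patient_specific", "overall")) {
  scope <- match.arg(scope)
  sub <- if (scope == "overall") rates else rates[rates$category == scope, ]
  if (nrow(sub) == 0) stop("no rates in scope ", scope)
  if (scope != "overall" && !all(sub$category == scope))
    stop("rates are not homogeneous in scope ", scope)
  structure(list(scope = scope,
                 median_pct = rate_median(sub$rate_pct),
                 min_pct = min(sub$rate_pct),
                 max_pct = max(sub$rate_pct),
                 n = nrow(sub),
                 rates = sub),
            class = "stampc_summary")
}

#' Overall completeness summary over all 16 parameters
#'
#' @param rates A full `stampc_rates` table (all 16 catalog parameters).
#' @return A `stampc_summary` with `scope = "overall"`.
#' @export
overall_summary <- function(rates) {
  catalog <- load_parameter_catalog()
  missing <- setdiff(catalog$id, rates$id)
  if (length(missing))
    stop("missing rate for parameter(s): ", paste(missing, collapse = ", "))
  category_summary(rates, "overall")
}

#' @export
print.stampc_summary <- function(x, ...) {
  cat(sprintf("%s documentation completeness (n = %d parameters)\n",
              x$scope, x$n))
  cat(sprintf("  median %.1f%%  range %.1f%%-%.1f%%\n",
              x$median_pct, x$min_pct, x$max_pct))
  invisible(x)
}
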