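# Saaty's classic random-consistency indices, orders 1..10.
saaty_ri_table <- c(0.00, 0.00, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)

#' Saaty random consistency index
#'
#' @param n Matrix order, 1..10.
#' @return The random index RI(n) used in the consistency ratio CR = CI/RI.
#' @export
saaty_ri <- function(n) {
  if (n < 1 || n > length(saaty_ri_table))
    stop("random-index table covers orders 1..10; got n = ", n)
  saaty_ri_table[n]
}

#' Validate a pairwise comparison matrix
#'
#' Checks the structural requirements of a Saaty judgment matrix: square,
#' strictly positive, unit diagonal, reciprocal (`a[j,i] = 1/a[i,j]` within
#' 1e-9), and — in strict Saaty mode — entries within \[1/9, 9\]. Scale
#' violations are reported as violations when `strict_saaty = TRUE` and as
#' warnings otherwise.
#'
#' @param M Numeric matrix of judgments.
#' @param strict_saaty Enforce the 1/9..9 scale bounds (default `TRUE`).
#' @return Data frame with columns `rule`, `i`, `j`, `message`; zero rows
#'   iff the matrix is valid.
#' @export
validate_pairwise_matrix <- function(M, strict_saaty = TRUE) {
  if (!is.matrix(M) || !is.numeric(M) || nrow(M) != ncol(M))
    stop("pairwise matrix must be a square numeric matrix")
  if (any(!is.finite(M)) || any(M <= 0))
    stop("pairwise matrix entries must be finite and strictly positive")
  n <- nrow(M)
  v <- list()
  add <- function(rule, i, j, message)
    v[[length(v) + 1L]] <<- data.frame(rule = rule, i = i, j = j,
                                       message = message,
                                       stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (abs(M[i, i] - 1) > 1e-9)
      add("diagonal", i, i, sprintf("diagonal entry %.6g != 1", M[i, i]))
    for (j in seq_len(n)) {
      if (j > i && abs(M[j, i] - 1 / M[i, j]) > 1e-9)
        add("reciprocity", i, j,
            sprintf("a[%d,%d] = %.6g but a[%d,%d] = %.6g (not reciprocal)",
                    i, j, M[i, j], j, i, M[j, i]))
      if (i != j && (M[i, j] < 1 / 9 - 1e-12 || M[i, j] > 9 + 1e-12)) {
        msg <- sprintf("a[%d,%d] = %.6g outside the Saaty 1/9..9 scale",
                       i, j, M[i, j])
        if (strict_saaty) add("saaty_scale", i, j, msg) else warning(msg)
      }
    }
  }
  if (length(v)) do.call(rbind, v) else
    data.frame(rule = character(), i = integer(), j = integer(),
               message = character(), stringsAsFactors = FALSE)
}

power_iteration_weights <- function(M, tol = 1e-12, max_iter = 10000L) {
  n <- nrow(M)
  w <- rep(1 / n, n)
  for (iter in seq_len(max_iter)) {
    w_new <- as.numeric(M %*% w)
    w_new <- w_new / sum(w_new)
    if (max(abs(w_new - w)) < tol) return(w_new)
    w <- w_new
  }
  stop("power iteration did not converge within ", max_iter, " iterations")
}

#' AHP priority weights and consistency diagnostics
#'
#' Derives the criterion priority vector of a positive reciprocal judgment
#' matrix and its consistency diagnostics. The default method is Saaty's
#' principal right eigenvector, computed by power iteration (successive
#' normalized iterates within 1e-12 in max norm); `geometric_mean` uses
#' normalized row geometric means — both coincide exactly for perfectly
#' consistent matrices. The maximum eigenvalue is estimated as the mean of
#' the component-wise Rayleigh ratios `(M w)_i / w_i` (exact at the true
#' eigenvector), giving `CI = (lambda_max - n) / (n - 1)` and
#' `CR = CI / RI(n)` against Saaty's random-index table; judgments are
#' conventionally acceptable when `CR < 0.10`. For `n <= 2`, CR is defined
#' as 0 (such matrices are always consistent).
#'
#' @param M Square positive reciprocal matrix (validated; structural
#'   violations are an error).
#' @param method `"eigenvector"` (default) or `"geometric_mean"`.
#' @param strict_saaty Enforce the 1/9..9 entry bounds (default `FALSE`
#'   here so derived/consistent matrices with larger ratios are accepted;
#'   entry-scale warnings still fire).
#' @return List of class `ahp_result`: `weights` (positive, summing to 1),
#'   `lambda_max`, `consistency_index`, `consistency_ratio`, `acceptable`
#'   (`CR < 0.10`), `method`, `n`.
#' @examples
#' M <- rbind(c(1, 2, 4), c(1/2, 1, 2), c(1/4, 1/2, 1))
#' ahp_weights(M)$weights  # (4/7, 2/7, 1/7)
#' @export
ahp_weights <- function(M, method = c("eigenvector", "geometric_mean"),
                        strict_saaty = FALSE) {
  method <- match.arg(method)
  viol <- validate_pairwise_matrix(M, strict_saaty = strict_saaty)
  if (nrow(viol))
    stop("invalid pairwise matrix: ", paste(viol$message, collapse = "; "))
  n <- nrow(M)
  if (n > 10)
    stop("consistency ratio is defined here only for n <= 10 (random-index table)")
  w <- if (method == "eigenvector" && n > 1) power_iteration_weights(M)
       else exp(rowMeans(log(M)))
  w <- w / sum(w)
  lambda_max <- if (n == 1) 1 else mean(as.numeric(M %*% w) / w)
  ci <- if (n <= 2) 0 else (lambda_max - n) / (n - 1)
  cr <- if (n <= 2) 0 else ci / saaty_ri(n)
  structure(list(weights = w, lambda_max = lambda_max,
                 consistency_index = ci, consistency_ratio = cr,
                 acceptable = cr < 0.10, method = method, n = n),
            class = "ahp_result")
}

#' Consistency ratio of a pairwise matrix
#'
#' Convenience accessor: runs [ahp_weights()] and returns the full result,
#' whose `consistency_ratio` and `acceptable` fields carry the diagnostic.
#'
#' @inheritParams ahp_weights
#' @return An `ahp_result`.
#' @export
consistency_ratio <- function(M, method = c("eigenvector", "geometric_mean")) {
  ahp_weights(M, method = match.arg(method))
}

#' @export
print.ahp_result <- function(x, ...) {
  cat(sprintf("AHP priorities (%s method, n = %d)\n", x$method, x$n))
  w <- if (is.null(names(x$weights))) {
    stats::setNames(x$weights, paste0("c", seq_along(x$weights)))
  } else x$weights
  for (i in seq_along(w))
    cat(sprintf("  %-20s %.4f\n", names(w)[i], w[i]))
  cat(sprintf("lambda_max = %.4f, CI = %.4f, CR = %.4f (%s)\n",
              x$lambda_max, x$consistency_index, x$consistency_ratio,
              if (x$acceptable) "acceptable, CR < 0.10" else "inconsistent"))
  invisible(x)
}
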