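#' Simon's optimal two-stage design by exhaustive enumeration
#'
#' Enumerates all two-stage designs `(r1/n1, r/n)` with `n <= n_max`:
#' enroll `n1` patients, stop for futility if at most `r1` respond, otherwise
#' enroll `n - n1` more and declare the treatment active if the total number
#' of responders exceeds `r`. Exact binomial two-stage error rates are
#' computed for every design; among designs with attained one-sided type I
#' error at most `alpha` (at the null response rate `p0`) and power at least
#' `1 - beta` (at the alternative `p1`), the optimal design minimizes the
#' expected sample size under the null, `EN0 = n1 + (1 - PET0) (n - n1)`.
#' Ties are broken by smallest `n`, then smallest `n1`, then largest `r1`,
#' then smallest `r`.
#'
#' @param p0 Null (uninteresting) response probability.
#' @param p1 Alternative response probability; must exceed `p0`.
#' @param alpha One-sided type I error bound (default 0.05).
#' @param beta Type II error bound; power bound is `1 - beta` (default 0.20).
#' @param n_max Largest total sample size searched (default 100).
#' @return A `simon_design` object: list with `p0, p1, alpha, beta, n1, r1,
#'   n, r, PET0, EN0, attained_alpha, attained_power`.
#' @examples
#' simon_optimal_design(0.05, 0.20, alpha = 0.05, beta = 0.20)
#' @export
simon_optimal_design <- function(p0, p1, alpha = 0.05, beta = 0.20,
                                 n_max = 100L) {
  if (!(p0 > 0 && p1 < 1 && p1 > p0))
    stop("parameter error: need 0 < p0 < p1 < 1")
  if (!(alpha > 0 && alpha < 1 && beta > 0 && beta < 1))
    stop("parameter error: need 0 < alpha, beta < 1")
  best <- NULL
  for (n in 2:n_max) {
    for (n1 in 1:(n - 1L)) {
      n2 <- n - n1
      # reject[r1+1, r+1] = P(X1 > r1 and X1 + X2 > r) for r1 in 0..n1-1,
      # r in 0..n; rows built by reverse cumulation over x1.
      rej0 <- two_stage_reject_matrix(n1, n2, p0)
      feas_a <- rej0 <= alpha
      if (!any(feas_a)) next
      rej1 <- two_stage_reject_matrix(n1, n2, p1)
      feas <- feas_a & rej1 >= 1 - beta
      # enforce r > r1
      r1v <- 0:(n1 - 1L)
      rv <- 0:n
      feas <- feas & outer(r1v, rv, `<`)
      if (!any(feas)) next
      PET0 <- pbinom(r1v, n1, p0)
      EN0 <- n1 + (1 - PET0) * n2
      cand_rows <- which(apply(feas, 1, any))
      i <- cand_rows[which.min(EN0[cand_rows])]
      # prefer largest feasible r1 at (numerically) equal EN0
      eq <- cand_rows[abs(EN0[cand_rows] - EN0[i]) < 1e-12]
      i <- max(eq)
      j <- which(feas[i, ])[1]              # smallest feasible r
      cand <- list(n1 = n1, r1 = r1v[i], n = n, r = rv[j],
                   PET0 = PET0[i], EN0 = EN0[i],
                   attained_alpha = rej0[i, j], attained_power = rej1[i, j])
      if (is.null(best) || cand$EN0 < best$EN0 - 1e-12) best <- cand
    }
  }
  if (is.null(best))
    stop("no feasible design with n <= ", n_max,
         "; increase n_max or relax the error bounds")
  structure(c(list(p0 = p0, p1 = p1, alpha = alpha, beta = beta), best),
            class = "simon_design")
}

# P(X1 > r1, X1 + X2 > r) for all r1 in 0..n1-1, r in 0..n1+n2.
two_stage_reject_matrix <- function(n1, n2, p) {
  x1 <- 0:n1
  b1 <- dbinom(x1, n1, p)
  # Q[k + n1 + 1] = P(X2 > k) for k in -n1..n1+n2
  kk <- -n1:(n1 + n2)
  Q <- 1 - pbinom(kk, n2, p)
  rv <- 0:(n1 + n2)
  # M[x1+1, r+1] = b1[x1] * P(X2 > r - x1)
  M <- b1 * matrix(Q[outer(rv, x1, `-`) + n1 + 1L],
                   nrow = n1 + 1L, ncol = n1 + n2 + 1L, byrow = TRUE)
  # reverse cumsum over rows: C[i, ] = sum_{x1 >= i-1} M[x1+1, ]
  C <- M
  for (i in n1:1) C[i, ] <- C[i + 1L, ] + M[i, ]
  # reject for r1 = i-1 uses rows x1 >= r1+1 = i, i.e. C[i+1, ]
  C[2:(n1 + 1L), , drop = FALSE]
}

#' @export
print.simon_design <- function(x, ...) {
  cat(sprintf("<simon_design> optimal two-stage design for p0=%.3g vs p1=%.3g (alpha=%.3g one-sided, power>=%.3g)\n",
              x$p0, x$p1, x$alpha, 1 - x$beta))
  cat(sprintf("  stage 1: %d patients, stop if <= %d responses\n", x$n1, x$r1))
  cat(sprintf("  total:   %d patients, active if >= %d responses\n", x$n, x$r + 1L))
  cat(sprintf("  PET0 = %.4f, EN0 = %.2f, attained alpha = %.4f, power = %.4f\n",
              x$PET0, x$EN0, x$attained_alpha, x$attained_power))
  invisible(x)
}

#' Operating characteristics of a two-stage design at a response rate
#'
#' @param design A `simon_design`.
#' @param p True response probability, in (0, 1).
#' @return List with `PET` (probability of early termination,
#'   `P(X1 <= r1)`), `reject_null_prob` (probability of declaring the
#'   treatment active, by exact two-stage binomial convolution) and `EN`
#'   (expected sample size).
#' @export
operating_characteristics <- function(design, p) {
  stopifnot(inherits(design, "simon_design"))
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1)
    stop("parameter error: p must lie in (0, 1)")
  n1 <- design$n1; n2 <- design$n - design$n1
  PET <- pbinom(design$r1, n1, p)
  x1 <- (design$r1 + 1L):n1
  reject <- sum(dbinom(x1, n1, p) * (1 - pbinom(design$r - x1, n2, p)))
  list(PET = PET, reject_null_prob = reject, EN = n1 + (1 - PET) * n2)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Tail-inversion exact interval via the beta-quantile characterization:
#' `lower = qbeta(a/2, k, n-k+1)` (0 when `k = 0`) and
#' `upper = qbeta(1-a/2, k+1, n-k)` (1 when `k = n`).
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param level Confidence level (default 0.95).
#' @return An `exact_ci` object: list with `k`, `n`, `level`, `estimate`,
#'   `lower`, `upper` (all proportions).
#' @examples
#' clopper_pearson_ci(4, 29)  # 95% CI 3.9% to 31.7%
#' @export
clopper_pearson_ci <- function(k, n, level = 0.95) {
  if (n < 1L || k < 0L || k > n) stop("parameter error: need 0 <= k <= n, n >= 1")
  if (level <= 0 || level >= 1) stop("parameter error: level in (0, 1)")
  a <- 1 - level
  lower <- if (k == 0) 0 else qbeta(a / 2, k, n - k + 1)
  upper <- if (k == n) 1 else qbeta(1 - a / 2, k + 1, n - k)
  structure(list(k = as.integer(k), n = as.integer(n), level = level,
                 estimate = k / n, lower = lower, upper = upper),
            class = "exact_ci")
}

#' @export
print.exact_ci <- function(x, ...) {
  cat(sprintf("%d/%d = %.1f%% (%.0f%% CI %.1f-%.1f)\n", x$k, x$n,
              100 * x$estimate, 100 * x$level, 100 * x$lower, 100 * x$upper))
  invisible(x)
}

#' Summarize best overall response against a two-stage design
#'
#' Computes the objective response rate (ORR = PR / n treated, reported as a
#' rounded percentage with an exact confidence interval), the clinical
#' benefit rate (PR or SD at the landmark week / n treated), and the
#' positivity call against the design's final boundary (positive when the
#' number of responders is at least `r + 1`). All treated patients form the
#' denominator.
#'
#' @param pr Number of confirmed partial (or better) responses.
#' @param clinical_benefit Number of patients with clinical benefit (PR or
#'   SD) at the landmark.
#' @param n_treated Number of treated patients.
#' @param design Optional `simon_design` for the positivity call.
#' @param level Confidence level for the exact CI (default 0.95).
#' @return A `response_summary` object: list with `orr`, `orr_percent`
#'   (rounded), `orr_ci` (exact, percent bounds to one decimal in `print`),
#'   `cbr`, `cbr_percent`, `positive` (or `NA` without a design).
#' @examples
#' d <- simon_optimal_design(0.05, 0.20)
#' response_summary(pr = 4, clinical_benefit = 8, n_treated = 29, design = d)
#' @export
response_summary <- function(pr, clinical_benefit, n_treated, design = NULL,
                             level = 0.95) {
  stopifnot(n_treated > 0, pr >= 0, pr <= n_treated,
            clinical_benefit >= 0, clinical_benefit <= n_treated)
  ci <- clopper_pearson_ci(pr, n_treated, level)
  positive <- if (is.null(design)) NA else pr >= design$r + 1L
  structure(list(
    pr = pr, clinical_benefit = clinical_benefit, n_treated = n_treated,
    orr = pr / n_treated, orr_percent = round(100 * pr / n_treated),
    orr_ci = ci,
    cbr = clinical_benefit / n_treated,
    cbr_percent = round(100 * clinical_benefit / n_treated),
    positive = positive
  ), class = "response_summary")
}

#' @export
print.response_summary <- function(x, ...) {
  cat(sprintf("ORR %d%% (%d/%d; %.0f%% CI %.1f-%.1f), CBR %d%% (%d/%d)\n",
              x$orr_percent, x$pr, x$n_treated, 100 * x$orr_ci$level,
              100 * x$orr_ci$lower, 100 * x$orr_ci$upper,
              x$cbr_percent, x$clinical_benefit, x$n_treated))
  if (!is.na(x$positive))
    cat(sprintf("Trial %s under the two-stage design boundary\n",
                if (x$positive) "POSITIVE" else "negative"))
  invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by direct hypergeometric enumeration: with margins
#' fixed, the p-value sums the probabilities of all tables whose
#' hypergeometric probability does not exceed that of the observed table.
#' A table with a zero margin has p = 1 by convention.
#'
#' @param table 2x2 matrix (or 4-vector, column-major) of nonnegative
#'   integer counts.
#' @return Two-sided p-value in (0, 1].
#' @examples
#' fisher_exact_2x2(matrix(c(3, 0, 1, 18), 2))
#' @export
fisher_exact_2x2 <- function(table) {
  m <- matrix(as.numeric(table), 2L, 2L)
  if (any(m < 0) || any(m != round(m))) stop("counts must be nonnegative integers")
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(m[, 2]) == 0) return(1)
  x <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(x, r1, r2, c1)
  p_obs <- dhyper(m[1, 1], r1, r2, c1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}
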