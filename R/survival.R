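#' Kaplan-Meier product-limit fit
#'
#' Product-limit estimate of the survival function (ties handled by
#' simultaneous decrement), with Greenwood standard errors and log-scale 95%
#' confidence intervals, computed through [survival::survfit()]. The median
#' is the smallest time at which the estimate drops to 0.5 or below, and is
#' `NA` when never reached.
#'
#' @param records Data frame with columns `time` (months, nonnegative) and
#'   `event` (1 = event observed, 0 = censored).
#' @param conf_level Confidence level (default 0.95).
#' @return A `km_curve` object: list with `time`, `surv`, `n_risk`,
#'   `n_event`, `lower`, `upper` (stepwise values at the distinct observed
#'   times), `median` and `n`.
#' @export
km_fit <- function(records, conf_level = 0.95) {
  stopifnot(is.data.frame(records), all(c("time", "event") %in% names(records)),
            nrow(records) >= 1L)
  if (any(!is.finite(records$time)) || any(records$time < 0))
    stop("input error: times must be finite and nonnegative")
  if (!all(records$event %in% c(0, 1)))
    stop("input error: event must be 0/1")
  fit <- survival::survfit(
    survival::Surv(time, event) ~ 1, data = records,
    conf.type = "log", conf.int = conf_level)
  med <- unname(summary(fit)$table["median"])
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, lower = fit$lower, upper = fit$upper,
                 median = med, n = nrow(records), conf_level = conf_level),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, %d events; median = %s months\n",
              x$n, sum(x$n_event),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Survival probability at landmark times
#'
#' Reads the right-continuous step function (and its confidence band) at the
#' requested times, e.g. 12 months for one-year survival.
#'
#' @param curve A `km_curve` from [km_fit()].
#' @param times Numeric vector of landmark times.
#' @return Data frame with columns `time`, `surv`, `lower`, `upper`.
#' @export
km_landmark <- function(curve, times) {
  stopifnot(inherits(curve, "km_curve"))
  idx <- findInterval(times, curve$time)
  get <- function(v) ifelse(idx == 0, 1, v[pmax(idx, 1)])
  data.frame(time = times, surv = get(curve$surv),
             lower = ifelse(idx == 0, 1, curve$lower[pmax(idx, 1)]),
             upper = ifelse(idx == 0, 1, curve$upper[pmax(idx, 1)]))
}

#' Two-group log-rank test
#'
#' Classical two-group log-rank test: at each distinct event time the
#' observed number of events per group is compared with its
#' hypergeometric expectation given the risk sets; the chi-square statistic
#' (1 df) and two-sided p-value are computed through
#' [survival::survdiff()]. With no events in either group the statistic is 0
#' and p = 1, with a warning.
#'
#' @param groupA,groupB Data frames with `time` and `event` columns.
#' @return A `logrank_result`: list with `chisq`, `df`, `p_value`,
#'   `observed` and `expected` (length-2 vectors, A then B).
#' @export
logrank_test <- function(groupA, groupB) {
  stopifnot(nrow(groupA) >= 1L, nrow(groupB) >= 1L)
  d <- rbind(
    data.frame(time = groupA$time, event = groupA$event, group = "A"),
    data.frame(time = groupB$time, event = groupB$event, group = "B"))
  if (any(!is.finite(d$time)) || any(d$time < 0))
    stop("input error: times must be finite and nonnegative")
  if (sum(d$event) == 0) {
    warning("no events in either group; log-rank statistic 0, p = 1")
    return(structure(list(chisq = 0, df = 1L, p_value = 1,
                          observed = c(A = 0, B = 0),
                          expected = c(A = 0, B = 0)),
                     class = "logrank_result"))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  structure(list(
    chisq = unname(sd$chisq), df = 1L,
    p_value = pchisq(sd$chisq, df = 1, lower.tail = FALSE),
    observed = setNames(as.numeric(sd$obs), c("A", "B")),
    expected = setNames(as.numeric(sd$exp), c("A", "B"))
  ), class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("<logrank> chisq = %.3f (df = %d), p = %.4g\n",
              x$chisq, x$df, x$p_value))
  cat(sprintf("  observed %s vs expected %s\n",
              paste(round(x$observed, 1), collapse = "/"),
              paste(round(x$expected, 2), collapse = "/")))
  invisible(x)
}

#' Stratify a clinical cohort into two biomarker groups
#'
#' Implements the stratifications used for survival comparisons:
#' * `median_split`: low group = values at or below the cohort median
#'   (ties go low, so group sizes differ by at most one), high group above;
#' * `threshold`: low group = values at or below `cut`, high above (e.g.
#'   LDH against the upper limit of normal);
#' * `bap1_or_uv`: favorable group = BAP1-wildtype OR UV-damaged genome;
#'   other group = BAP1-mutant without UV signature;
#' * `driver_gene`: GNAQ-mutant versus GNA11-mutant tumors.
#'
#' Records with missing/unknown values in the needed field(s) are excluded
#' and counted in the `excluded` attribute.
#'
#' @param records Clinical data frame (one row per patient); needs `field`
#'   for the numeric schemes, `bap1` ("mutant"/"wildtype"/NA) and `uv`
#'   (logical) for `bap1_or_uv`, `driver` ("GNAQ"/"GNA11"/other) for
#'   `driver_gene`.
#' @param scheme One of `"median_split"`, `"threshold"`, `"bap1_or_uv"`,
#'   `"driver_gene"`.
#' @param field Column name for the numeric schemes (e.g. `"ctdna_copies"`).
#' @param cut Threshold for `scheme = "threshold"`.
#' @return List with `groupA`, `groupB` (data frames; A = low / favorable /
#'   GNAQ), `labels`, and attribute `excluded` (count of dropped records).
#' @export
stratify <- function(records, scheme = c("median_split", "threshold",
                                         "bap1_or_uv", "driver_gene"),
                     field = NULL, cut = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(is.data.frame(records))
  if (scheme %in% c("median_split", "threshold")) {
    if (is.null(field) || !field %in% names(records))
      stop("`field` must name a column of `records`")
    v <- records[[field]]
    keep <- !is.na(v)
    r <- records[keep, , drop = FALSE]
    v <- v[keep]
    cutv <- if (scheme == "median_split") median(v) else {
      if (is.null(cut)) stop("`cut` required for threshold stratification")
      cut
    }
    sel <- v <= cutv
    labels <- paste0(field, c(" low", " high"))
  } else if (scheme == "bap1_or_uv") {
    ok <- !is.na(records$bap1) & records$bap1 %in% c("mutant", "wildtype") &
      !is.na(records$uv)
    r <- records[ok, , drop = FALSE]
    sel <- r$bap1 == "wildtype" | r$uv
    keep <- ok
    labels <- c("BAP1 wildtype or UV", "BAP1 mutant, no UV")
  } else {
    ok <- !is.na(records$driver) & records$driver %in% c("GNAQ", "GNA11")
    r <- records[ok, , drop = FALSE]
    sel <- r$driver == "GNAQ"
    keep <- ok
    labels <- c("GNAQ", "GNA11")
  }
  groupA <- r[sel, , drop = FALSE]
  groupB <- r[!sel, , drop = FALSE]
  if (nrow(groupA) == 0L || nrow(groupB) == 0L)
    stop("stratification error: empty group after split")
  structure(list(groupA = groupA, groupB = groupB, labels = labels),
            excluded = sum(!keep))
}

#' Read a per-patient clinical table
#'
#' Tab-separated, one row per patient, with at least `time` and `event`
#' columns plus the biomarker columns used by [stratify()].
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_clinical <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("time", "event") %in% names(d)))
    stop("clinical table needs `time` and `event` columns")
  if (!is.null(d$uv)) d$uv <- as.logical(d$uv)
  d
}

#' Compare survival between two biomarker strata
#'
#' Convenience wrapper: stratifies, fits a Kaplan-Meier curve per group and
#' runs the log-rank test.
#'
#' @inheritParams stratify
#' @param landmarks Landmark times (months) reported per group (default 12).
#' @return List with `stratification`, per-group `km` fits, `landmark`
#'   estimates and the `logrank` result.
#' @export
compare_survival <- function(records, scheme, field = NULL, cut = NULL,
                             landmarks = 12) {
  st <- stratify(records, scheme, field = field, cut = cut)
  kmA <- km_fit(st$groupA)
  kmB <- km_fit(st$groupB)
  list(stratification = st,
       km = setNames(list(kmA, kmB), st$labels),
       landmark = setNames(list(km_landmark(kmA, landmarks),
                                km_landmark(kmB, landmarks)), st$labels),
       logrank = logrank_test(st$groupA, st$groupB))
}
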