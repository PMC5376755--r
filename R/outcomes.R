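#' Kaplan-Meier product-limit curve for one group
#'
#' Wraps [survival::survfit()]. The reported median is the smallest event
#' time at which the survival function falls to 0.5 or below; if S never
#' reaches 0.5 the median is `NA`. Ties between events and censorings at
#' the same time follow the standard convention (events first).
#'
#' @param time positive follow-up times (months)
#' @param event 1 = event, 0 = censored
#' @return list of class `kmCurve`: `time` (ordered distinct times),
#'   `surv` (step values), `nRisk`, `nEvent`, `median`
#' @export
kmEstimate <- function(time, event) {
  if (length(time) == 0) stop("no survival records")
  if (any(!is.finite(time)) || any(time <= 0))
    stop("times must be finite and positive")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  med <- if (any(fit$surv <= 0.5 & fit$n.event > 0))
    min(fit$time[fit$surv <= 0.5 & fit$n.event > 0]) else NA_real_
  structure(list(time = fit$time, surv = fit$surv, nRisk = fit$n.risk,
                 nEvent = fit$n.event, median = med),
            class = "kmCurve")
}

#' @export
print.kmCurve <- function(x, ...) {
  cat("Kaplan-Meier curve:", sum(x$nEvent), "events over",
      length(x$time), "time points\n")
  cat("  median:", if (is.na(x$median)) "not reached"
      else paste(signif(x$median, 4), "months"), "\n")
  invisible(x)
}

#' Mantel-Haenszel log-rank test between two groups
#'
#' Accumulates observed-minus-expected events and the hypergeometric
#' variance at each distinct event time (via [survival::survdiff()]);
#' chi2 = (sum O - E)^2 / sum V on 1 df.
#'
#' @param time,event,group vectors over all records; `group` has two levels
#' @return list: chi2, p, obs (per group), exp (per group), groups
#' @export
logrankTest <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(group) != 2) stop("'group' must have exactly 2 levels")
  if (sum(event) < 1) stop("need at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  if (!is.finite(sd$chisq))
    stop("degenerate risk sets: log-rank variance is zero")
  list(chi2 = sd$chisq, p = stats::pchisq(sd$chisq, 1, lower.tail = FALSE),
       obs = stats::setNames(sd$obs, levels(group)),
       exp = stats::setNames(sd$exp, levels(group)),
       groups = levels(group))
}

#' Observed/expected hazard ratio with 95% CI
#'
#' `HR = (O_A / E_A) / (O_B / E_B)` from the log-rank table, with
#' `CI = exp(log HR +/- 1.96 * sqrt(1/E_A + 1/E_B))`. Group A is the first
#' factor level (reported relative to B).
#'
#' @inheritParams logrankTest
#' @return list: hr, ci (length 2), obs, exp, label (formatted as
#'   "HR = x.xx [a-b]")
#' @export
hazardRatioOE <- function(time, event, group) {
  lr <- logrankTest(time, event, group)
  if (any(lr$exp <= 0)) stop("zero expected events in a group")
  hr <- (lr$obs[1] / lr$exp[1]) / (lr$obs[2] / lr$exp[2])
  se <- sqrt(1 / lr$exp[1] + 1 / lr$exp[2])
  ci <- exp(log(hr) + c(-1.96, 1.96) * se)
  list(hr = unname(hr), ci = unname(ci), obs = lr$obs, exp = lr$exp,
       label = sprintf("HR = %.2f [%.1f-%.1f]", hr, ci[1], ci[2]))
}

#' Two-group comparison of a continuous measure
#'
#' `method = "welch"`: unequal-variance t test with Welch-Satterthwaite
#' degrees of freedom, two-sided. `method = "mannwhitney"`: Wilcoxon
#' rank-sum U, exact for small untied samples and normal-approximated with
#' tie correction otherwise, two-sided.
#'
#' @param a,b numeric vectors
#' @param method "welch" or "mannwhitney"
#' @return list: statistic, p, method
#' @export
groupCompare <- function(a, b, method = c("welch", "mannwhitney")) {
  method <- match.arg(method)
  if (method == "welch") {
    if (length(a) < 2 || length(b) < 2)
      stop("Welch comparison needs n >= 2 per group")
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      if (mean(a) == mean(b))
        return(list(statistic = 0, p = 1, method = method))
      stop("zero variance in both groups")
    }
    ht <- stats::t.test(a, b, var.equal = FALSE)
    list(statistic = unname(ht$statistic), p = ht$p.value, method = method)
  } else {
    if (length(a) < 1 || length(b) < 1)
      stop("need at least one value per group")
    ht <- suppressWarnings(stats::wilcox.test(a, b))
    list(statistic = unname(ht$statistic), p = ht$p.value, method = method)
  }
}

#' Survival summary of a labeled cohort
#'
#' Per-group KM medians, the log-rank test, and the O/E hazard ratio of
#' the first group relative to the second.
#'
#' @param surv data.frame with time_months, event, group (two levels;
#'   "high" ordered first when present)
#' @return list: medians (named), chi2, p, hr, ci, hrLabel
#' @export
survivalSummary <- function(surv) {
  lev <- unique(as.character(surv$group))
  if ("high" %in% lev) lev <- c("high", setdiff(lev, "high"))
  group <- factor(surv$group, levels = lev)
  med <- vapply(split(surv, group), function(d)
    kmEstimate(d$time_months, d$event)$median, numeric(1))
  lr <- logrankTest(surv$time_months, surv$event, group)
  hr <- hazardRatioOE(surv$time_months, surv$event, group)
  list(medians = med, chi2 = lr$chi2, p = lr$p,
       hr = hr$hr, ci = hr$ci, hrLabel = hr$label)
}
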