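#' Four-parameter logistic dose-response curve
#'
#' `v(d) = bottom + (top - bottom) / (1 + (d / ic50)^hill)`; viability
#' decreases with dose for positive Hill slopes, equals `top` at dose 0
#' and the midpoint `(top + bottom) / 2` at `d = ic50`.
#'
#' @param dose nonnegative doses (uM)
#' @param bottom,top lower/upper asymptotes (% viability)
#' @param hill Hill slope (> 0 for inhibition)
#' @param ic50 inflection dose (uM)
#' @return predicted viability
#' @export
fourPL <- function(dose, bottom, top, hill, ic50) {
  bottom + (top - bottom) / (1 + (dose / ic50)^hill)
}

#' Normalize raw viability signal to percent of vehicle control
#'
#' @param raw raw signal values
#' @param vehicle raw signal of the vehicle (untreated) replicates
#' @return `100 * raw / mean(vehicle)`
#' @export
normalizeViability <- function(raw, vehicle) {
  m <- mean(vehicle)
  if (!is.finite(m) || m <= 0) stop("vehicle mean must be > 0")
  100 * raw / m
}

#' Fit a 4PL model to a dose-response series
#'
#' Levenberg-Marquardt least squares (multi-start over an IC50 grid) of
#' [fourPL()] on the log10-dose axis. Dose-0 wells cannot enter the
#' log-dose fit; their mean anchors the starting value (and, if
#' `fixTop = TRUE`, the fixed value) of the top asymptote. Parameters are
#' bounded: 0 <= bottom <= top <= 120, ic50 > 0, hill in (0.1, 10].
#'
#' A series whose viability does not decrease with dose (nonnegative
#' dose-viability correlation or dynamic range under 5 points) is flagged
#' `no_inhibition` and returns no IC50.
#'
#' @param dose,viability replicate-level observations (uM, % control)
#' @param fixBottom,fixTop fix the asymptotes at `bottomValue` /
#'   `topValue` instead of fitting them
#' @param bottomValue,topValue the fixed asymptote values
#' @return list: ic50, hill, bottom, top, rss, converged, flag
#'   ("ok" or "no_inhibition"/"no_convergence")
#' @export
fitDoseResponse4PL <- function(dose, viability, fixBottom = FALSE,
                               fixTop = FALSE, bottomValue = 0,
                               topValue = 100) {
  ok <- is.finite(dose) & is.finite(viability)
  dose <- dose[ok]; viability <- viability[ok]
  posDose <- dose > 0
  if (length(unique(dose[posDose])) < 4)
    stop("need at least 4 distinct positive doses")

  top0 <- if (any(!posDose)) mean(viability[!posDose]) else max(viability)
  d <- dose[posDose]; v <- viability[posDose]

  agg <- tapply(v, d, mean)
  dynRange <- max(agg) - min(agg)
  if (dynRange < 5 || isTRUE(stats::cor(log10(d), v) >= 0))
    return(list(ic50 = NA_real_, hill = NA_real_, bottom = NA_real_,
                top = NA_real_, rss = NA_real_, converged = FALSE,
                flag = "no_inhibition"))

  df <- data.frame(ld = log10(d), v = v)
  model <- function(pars) {
    b <- if (fixBottom) bottomValue else pars[["bottom"]]
    t <- if (fixTop) topValue else pars[["top"]]
    fourPL(10^df$ld, b, t, pars[["hill"]], 10^pars[["lic50"]])
  }
  starts <- expand.grid(
    lic50 = log10(c(stats::median(d), min(d), max(d), 3 * max(d))),
    hill = c(0.5, 1, 2))
  lower <- c(lic50 = log10(min(d)) - 2, hill = 0.1)
  upper <- c(lic50 = log10(max(d)) + 2, hill = 10)
  startExtra <- c(bottom = max(0, min(v)), top = top0)
  if (!fixBottom) { lower["bottom"] <- 0; upper["bottom"] <- 120 }
  if (!fixTop)    { lower["top"] <- 0;    upper["top"] <- 120 }

  best <- NULL
  for (k in seq_len(nrow(starts))) {
    start <- c(lic50 = starts$lic50[k], hill = starts$hill[k])
    if (!fixBottom) start["bottom"] <- startExtra[["bottom"]]
    if (!fixTop) start["top"] <- startExtra[["top"]]
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = as.list(start),
        fn = function(p) df$v - model(unlist(p)),
        lower = lower[names(start)], upper = upper[names(start)],
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = unlist(fit$par), rss = rss,
                   converged = fit$info %in% 1:4)
  }
  if (is.null(best))
    return(list(ic50 = NA_real_, hill = NA_real_, bottom = NA_real_,
                top = NA_real_, rss = NA_real_, converged = FALSE,
                flag = "no_convergence"))
  b <- if (fixBottom) bottomValue else unname(best$par["bottom"])
  t <- if (fixTop) topValue else unname(best$par["top"])
  if (b > t) { tmp <- b; b <- t; t <- tmp }
  list(ic50 = unname(10^best$par["lic50"]),
       hill = unname(best$par["hill"]), bottom = b, top = t,
       rss = best$rss, converged = best$converged, flag = "ok")
}

#' Fit all chemograms in a long table
#'
#' @param chem data.frame with cell_id, dose_uM, viability_pct (and
#'   optionally group)
#' @param ... passed to [fitDoseResponse4PL()]
#' @return data.frame, one row per cell line: cell_id, group (if present),
#'   ic50, hill, bottom, top, rss, converged, flag
#' @export
fitChemograms <- function(chem, ...) {
  out <- lapply(split(chem, chem$cell_id), function(d) {
    f <- fitDoseResponse4PL(d$dose_uM, d$viability_pct, ...)
    cbind(data.frame(cell_id = d$cell_id[1],
                     group = if ("group" %in% names(d)) d$group[1] else NA,
                     stringsAsFactors = FALSE),
          as.data.frame(f[c("ic50", "hill", "bottom", "top", "rss",
                            "converged", "flag")]))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-group IC50 summary with Welch comparison
#'
#' @param fits a [fitChemograms()] table (or any data.frame with ic50,
#'   group, converged)
#' @return list: `table` (group, n, mean, sem; SEM is NA for n = 1) and
#'   `welch` ([groupCompare()] result, NULL with < 2 fits in a group)
#' @export
ic50GroupSummary <- function(fits) {
  fits <- fits[fits$converged & is.finite(fits$ic50), ]
  if (nrow(fits) == 0) stop("no converged fit")
  byGroup <- split(fits$ic50, fits$group)
  if (any(lengths(byGroup) == 0)) stop("a group has no converged fit")
  tab <- data.frame(
    group = names(byGroup), n = lengths(byGroup),
    mean = vapply(byGroup, mean, numeric(1)),
    sem = vapply(byGroup, function(v)
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
      numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  welch <- if (length(byGroup) == 2 && all(lengths(byGroup) >= 2))
    groupCompare(byGroup[[1]], byGroup[[2]], "welch") else NULL
  list(table = tab, welch = welch)
}

#' Spheroid volume from its radius
#'
#' `V = 4/3 * pi * r^3` (um^3 for r in um).
#'
#' @param r radius (nonnegative)
#' @return volume
#' @export
spheroidVolume <- function(r) {
  if (any(r < 0)) stop("radius must be nonnegative")
  4 / 3 * pi * r^3
}

#' Xenograft tumor volume from caliper length and width
#'
#' Standard ellipsoid approximation `V = length * width^2 / 2` (mm^3).
#' `asPrinted = TRUE` instead evaluates `(length / width^2) / 2`, the
#' dimensionally inconsistent form some reports print; it is provided only
#' to reproduce such numbers and is not a volume.
#'
#' @param length,width caliper measures (mm, nonnegative)
#' @param asPrinted use the literal printed form
#' @return volume (mm^3)
#' @export
tumorVolume <- function(length, width, asPrinted = FALSE) {
  if (any(length < 0) || any(width < 0))
    stop("dimensions must be nonnegative")
  if (asPrinted) (length / width^2) / 2 else length * width^2 / 2
}
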