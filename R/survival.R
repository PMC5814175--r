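## Quartile-stratified survival: split patients by the top and bottom
## 25 percentiles of a single gene's expression, estimate each group's
## survival with the product-limit (Kaplan-Meier) estimator and compare
## the groups with the two-group log-rank test. The estimator and test
## are delegated to the survival package; this module fixes the
## stratification convention and the result containers.

#' Stratify a survival table by covariate quartiles
#'
#' High group: covariate >= 75th percentile; low group: covariate <=
#' 25th percentile (type-7 quantiles); the middle half is discarded.
#' Samples exactly at a boundary are included in the respective extreme
#' group (inclusive cut). A degenerate covariate in which the two
#' boundaries coincide is a hard error.
#'
#' @param table a \code{\link{survival_table}} with a \code{covariate}
#'   column and at least 8 records.
#' @return list with \code{high} and \code{low} (both
#'   \code{survival_table}s) and \code{cut} (the two boundaries).
#' @export
#' @examples
#' st <- survival_table(letters[1:8], 1:8, rep(1, 8), covariate = 1:8)
#' stratify_quartiles(st)$low$sample_id  # "a" "b"
stratify_quartiles <- function(table) {
  stopifnot(inherits(table, "survival_table"))
  if (is.null(table$covariate)) stop("survival table has no covariate")
  if (nrow(table) < 8L) stop("need at least 8 records to stratify")
  q <- quantile(table$covariate, c(0.25, 0.75), type = 7, names = FALSE)
  if (q[1L] >= q[2L])
    stop("degenerate covariate: 25th and 75th percentiles coincide")
  low <- table[table$covariate <= q[1L], , drop = FALSE]
  high <- table[table$covariate >= q[2L], , drop = FALSE]
  if (nrow(low) == 0L || nrow(high) == 0L)
    stop("degenerate covariate: empty quartile group")
  class(low) <- class(high) <- c("survival_table", "data.frame")
  list(high = high, low = low, cut = c(q25 = q[1L], q75 = q[2L]))
}

#' Product-limit (Kaplan-Meier) survival estimate
#'
#' At each distinct time with at least one event, S is multiplied by
#' (1 - d/n) where d is the number of deaths and n the number at risk
#' just before that time; censored times shrink the risk set but add no
#' step, and events are processed before censorings at tied times.
#'
#' @param times follow-up times.
#' @param events logical/0-1 event indicators.
#' @return object of class \code{"km_curve"}: list with
#'   \code{event_times}, \code{survival}, \code{at_risk}, \code{events}
#'   (all aligned, event times only) and \code{n} (records used). With
#'   no events all fields are empty and S is identically 1.
#' @export
#' @examples
#' km <- km_estimate(c(5, 10, 15), c(1, 0, 1))
#' km$survival  # 2/3 after t = 5, 0 after t = 15
km_estimate <- function(times, events) {
  if (length(times) < 1L) stop("need at least one record")
  events <- as.logical(events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  keep <- fit$n.event >= 1
  structure(list(event_times = fit$time[keep],
                 survival = fit$surv[keep],
                 at_risk = fit$n.risk[keep],
                 events = fit$n.event[keep],
                 n = length(times)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", x$n, "records,", length(x$event_times),
      "event time(s)\n")
  if (length(x$event_times)) {
    print(data.frame(time = x$event_times, n_risk = x$at_risk,
                     events = x$events, S = round(x$survival, 4)),
          row.names = FALSE)
  } else cat("No events; S(t) = 1 throughout\n")
  invisible(x)
}

#' Survival function value of a KM curve at given times
#'
#' @param curve a \code{km_curve}.
#' @param t times at which to evaluate S(t).
#' @return numeric vector of survival probabilities (right-continuous
#'   step function, S = 1 before the first event).
#' @export
km_survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  vapply(t, function(ti) {
    i <- sum(curve$event_times <= ti)
    if (i == 0L) 1 else curve$survival[i]
  }, numeric(1L))
}

#' Two-group log-rank test
#'
#' Standard log-rank: at each distinct event time the expected number of
#' events per group is the hypergeometric mean and the variance the
#' hypergeometric variance; chi2 = (O - E)^2 / V on 1 degree of freedom,
#' two-sided p from the upper chi-square tail, no continuity correction.
#'
#' @param groupA,groupB \code{\link{survival_table}}s, both non-empty;
#'   at least one event overall.
#' @return object of class \code{"logrank_result"}: list with
#'   \code{chi2}, \code{df} (1), \code{p}, \code{observed} and
#'   \code{expected} (named per-group event totals), \code{n} (group
#'   sizes).
#' @export
logrank_test <- function(groupA, groupB) {
  stopifnot(inherits(groupA, "survival_table"),
            inherits(groupB, "survival_table"))
  if (nrow(groupA) == 0L || nrow(groupB) == 0L)
    stop("both groups must be non-empty")
  time <- c(groupA$time, groupB$time)
  event <- c(groupA$event, groupB$event)
  if (sum(event) == 0L) stop("no events in either group")
  grp <- factor(rep(c("A", "B"), c(nrow(groupA), nrow(groupB))))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ grp, rho = 0)
  chi2 <- unname(sd_$chisq)
  structure(list(chi2 = chi2, df = 1L,
                 p = pchisq(chi2, df = 1L, lower.tail = FALSE),
                 observed = setNames(as.numeric(sd_$obs), c("A", "B")),
                 expected = setNames(as.numeric(sd_$exp), c("A", "B")),
                 n = setNames(as.numeric(sd_$n), c("A", "B"))),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat("Log-rank test: chi2 =", format(x$chi2, digits = 4),
      "on 1 df, p =", format(x$p, digits = 4), "\n")
  print(data.frame(group = names(x$observed), n = x$n,
                   observed = x$observed, expected = round(x$expected, 2)),
        row.names = FALSE)
  invisible(x)
}

#' Quartile-stratified survival analysis for one gene
#'
#' Convenience wrapper: stratifies by the covariate quartiles, fits both
#' KM curves and runs the log-rank test.
#'
#' @param table a \code{survival_table} with covariate.
#' @return list with \code{high} and \code{low} (\code{km_curve}s),
#'   \code{logrank} (\code{logrank_result}) and \code{groups} (the
#'   stratification).
#' @export
survival_by_quartiles <- function(table) {
  st <- stratify_quartiles(table)
  list(high = km_estimate(st$high$time, st$high$event),
       low = km_estimate(st$low$time, st$low$event),
       logrank = logrank_test(st$high, st$low),
       groups = st)
}

#' Plot high/low quartile KM curves
#'
#' @param x output of \code{\link{survival_by_quartiles}} or a
#'   \code{km_curve}.
#' @param ... passed to \code{plot}.
#' @export
plot_km <- function(x, ...) {
  draw <- function(curve, col) {
    t <- c(0, rep(curve$event_times, each = 2))
    s <- c(1, 1, rep(curve$survival, each = 2))[seq_along(t)]
    lines(t, s, type = "l", col = col, lwd = 2)
  }
  if (inherits(x, "km_curve")) x <- list(high = x)
  xmax <- max(unlist(lapply(x[c("high", "low")], function(c.)
    if (!is.null(c.)) c.$event_times)), 1)
  plot(NA, xlim = c(0, xmax), ylim = c(0, 1), xlab = "time",
       ylab = "S(t)", ...)
  if (!is.null(x$high)) draw(x$high, "firebrick")
  if (!is.null(x$low)) draw(x$low, "steelblue")
  if (!is.null(x$low))
    legend("bottomleft", c("high", "low"), lwd = 2,
           col = c("firebrick", "steelblue"), bty = "n")
  invisible(x)
}
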