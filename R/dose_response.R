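## Four-parameter logistic (4PL) dose-response modelling:
##   response = bottom + (top - bottom) / (1 + (dose / ec50)^hill)
## the standard model for MTT viability curves, with derived inhibitory
## concentrations (IC-x) and case-resampling bootstrap confidence
## intervals. Fitting uses Levenberg-Marquardt least squares.

start_4pl <- function(dose, response) {
  bottom <- min(response); top <- max(response)
  mid <- (top + bottom) / 2
  ec50 <- dose[which.min(abs(response - mid))]
  if (ec50 <= 0) ec50 <- median(dose)
  c(bottom = bottom, top = top, hill = 1, ec50 = ec50)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of \code{response = bottom + (top - bottom) /
#' (1 + (dose/ec50)^hill)} by Levenberg-Marquardt, initialized at
#' bottom = min response, top = max response, ec50 = dose nearest
#' mid-response, hill = 1, with the bound ec50 > 0. Non-convergence
#' (including an essentially flat response, for which no IC is defined)
#' is flagged, never silently reported as a fit.
#'
#' @param doses positive concentrations (uM), at least 5 distinct.
#' @param responses viability as \% of control, finite.
#' @param ic_levels inhibition levels (\%) at which inhibitory
#'   concentrations are derived (default \code{c(20, 25, 50, 75)}).
#' @return object of class \code{"fit4pl"}: list with
#'   \code{coefficients} (bottom, top, hill, ec50), \code{converged},
#'   \code{residual_sse}, \code{ic_values} (named by level, NA where
#'   unattainable), \code{data}, and the usual accessor methods
#'   (\code{coef}, \code{predict}, \code{residuals}, \code{fitted},
#'   \code{summary}, \code{plot}, \code{simulate}).
#' @export
#' @examples
#' d <- c(5, 10, 20, 40, 80, 160)
#' r <- 100 / (1 + (d / 39)^1.5)
#' fit <- fit_4pl(d, r)
#' coef(fit)["ec50"]
fit_4pl <- function(doses, responses, ic_levels = c(20, 25, 50, 75)) {
  doses <- as.numeric(doses); responses <- as.numeric(responses)
  if (any(doses <= 0)) stop("doses must be positive")
  if (length(unique(doses)) < 5L) stop("need at least 5 distinct doses")
  if (any(!is.finite(responses))) stop("responses must be finite")
  dat <- data.frame(dose = doses, response = responses)
  out <- list(data = dat, ic_levels = ic_levels)
  class(out) <- "fit4pl"
  if (sd(responses) < 1e-8) {
    out$converged <- FALSE
    out$coefficients <- c(bottom = NA_real_, top = NA_real_,
                          hill = NA_real_, ec50 = NA_real_)
    out$residual_sse <- NA_real_
    out$ic_values <- setNames(rep(NA_real_, length(ic_levels)),
                              paste0("IC", ic_levels))
    return(out)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      response ~ bottom + (top - bottom) / (1 + (dose / ec50)^hill),
      data = dat, start = as.list(start_4pl(doses, responses)),
      lower = c(bottom = -Inf, top = -Inf, hill = -Inf, ec50 = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out$converged <- FALSE
    out$coefficients <- c(bottom = NA_real_, top = NA_real_,
                          hill = NA_real_, ec50 = NA_real_)
    out$residual_sse <- NA_real_
    out$ic_values <- setNames(rep(NA_real_, length(ic_levels)),
                              paste0("IC", ic_levels))
    return(out)
  }
  cf <- coef(fit)
  if (cf[["top"]] < cf[["bottom"]]) {
    # re-express with top > bottom by flipping the hill sign
    cf[c("bottom", "top")] <- cf[c("top", "bottom")]
    cf[["hill"]] <- -cf[["hill"]]
  }
  out$coefficients <- cf
  out$converged <- TRUE
  out$residual_sse <- sum(residuals(fit)^2)
  out$ic_values <- vapply(ic_levels, function(lv)
    tryCatch(inhibitory_concentration(out, lv), error = function(e) NA_real_),
    numeric(1L))
  names(out$ic_values) <- paste0("IC", ic_levels)
  out
}

#' @export
coef.fit4pl <- function(object, ...) object$coefficients

#' @export
predict.fit4pl <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("cannot predict from a non-converged fit")
  d <- if (is.null(newdata)) object$data$dose else
    if (is.data.frame(newdata)) newdata$dose else as.numeric(newdata)
  cf <- object$coefficients
  four_pl(d, cf[["bottom"]], cf[["top"]], cf[["hill"]], cf[["ec50"]])
}

#' @export
fitted.fit4pl <- function(object, ...) predict(object)

#' @export
residuals.fit4pl <- function(object, ...) {
  object$data$response - fitted(object)
}

#' @export
print.fit4pl <- function(x, ...) {
  if (!x$converged) {
    cat("4PL fit: NOT converged (", nrow(x$data), "points )\n")
    return(invisible(x))
  }
  cf <- x$coefficients
  cat("4PL dose-response fit (", nrow(x$data), "points )\n")
  cat(sprintf("  bottom %.3g  top %.3g  hill %.3g  ec50 %.4g uM\n",
              cf[["bottom"]], cf[["top"]], cf[["hill"]], cf[["ec50"]]))
  ic <- x$ic_values[!is.na(x$ic_values)]
  if (length(ic))
    cat("  ", paste(sprintf("%s = %.3g uM", names(ic), ic),
                    collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.fit4pl <- function(object, ...) {
  print(object)
  if (object$converged)
    cat("  residual SSE:", format(object$residual_sse, digits = 4), "\n")
  invisible(object)
}

#' @export
plot.fit4pl <- function(x, ...) {
  plot(x$data$dose, x$data$response, log = "x", xlab = "dose (uM)",
       ylab = "viability (% of control)", pch = 19, ...)
  if (x$converged) {
    d <- exp(seq(log(min(x$data$dose)), log(max(x$data$dose)),
                 length.out = 200))
    lines(d, predict(x, d), col = "firebrick", lwd = 2)
  }
  invisible(x)
}

#' @export
simulate.fit4pl <- function(object, nsim = 1, seed = NULL, ...) {
  if (!object$converged) stop("cannot simulate from a non-converged fit")
  s <- sd(residuals(object))
  gen <- function() object$data$response * 0 + fitted(object) +
    rnorm(nrow(object$data), 0, s)
  run <- function() as.data.frame(replicate(nsim, gen()))
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Inhibitory concentration at a given inhibition level
#'
#' Solves fitted response = (100 - level)\% of control on the fitted
#' curve by monotone root finding over the observed dose range extended
#' tenfold on both sides. By default the level is on the absolute
#' \%-of-control scale; \code{relative = TRUE} instead targets the
#' asymptote-relative response \code{top - level/100 * (top - bottom)}.
#' An unattainable level is an error that names the attainable range.
#'
#' @param fit a converged \code{fit4pl}.
#' @param level \% inhibition (e.g. 50 for the IC50).
#' @param relative use the asymptote-relative definition (default
#'   \code{FALSE}).
#' @return concentration in the dose units of the fit.
#' @export
inhibitory_concentration <- function(fit, level, relative = FALSE) {
  stopifnot(inherits(fit, "fit4pl"))
  if (!fit$converged) stop("fit did not converge; no IC defined")
  cf <- fit$coefficients
  target <- if (relative)
    cf[["top"]] - level / 100 * (cf[["top"]] - cf[["bottom"]])
  else 100 - level
  lo <- min(fit$data$dose) / 10
  hi <- max(fit$data$dose) * 10
  f <- function(d) four_pl(d, cf[["bottom"]], cf[["top"]], cf[["hill"]],
                           cf[["ec50"]]) - target
  flo <- f(lo); fhi <- f(hi)
  if (sign(flo) == sign(fhi)) {
    resp <- c(four_pl(lo, cf[["bottom"]], cf[["top"]], cf[["hill"]],
                      cf[["ec50"]]),
              four_pl(hi, cf[["bottom"]], cf[["top"]], cf[["hill"]],
                      cf[["ec50"]]))
    att <- sort(100 - resp)
    stop(sprintf(
      "inhibition level %g%% unattainable; attainable range %.3g%% to %.3g%%",
      level, att[1L], att[2L]))
  }
  stats::uniroot(f, lower = lo, upper = hi, tol = 1e-10)$root
}

#' Case-resampling bootstrap intervals for a 4PL fit
#'
#' Resamples (dose, response) pairs with replacement B times, refits,
#' and reports percentile 2.5/97.5 intervals for the parameters and the
#' requested inhibitory concentrations. If more than 20\% of resamples
#' fail to converge the intervals are withheld and the result flagged.
#'
#' @param doses,responses as for \code{\link{fit_4pl}}.
#' @param B resamples, at least 200 (default 1000).
#' @param seed integer seed.
#' @param ic_levels IC levels to bootstrap (default
#'   \code{c(20, 25, 50, 75)}).
#' @return list with \code{ci} (matrix: rows = quantities, columns
#'   lower/upper; \code{NULL} when withheld), \code{n_fail},
#'   \code{B}, \code{reliable} (logical).
#' @export
bootstrap_ci <- function(doses, responses, B = 1000, seed = 1,
                         ic_levels = c(20, 25, 50, 75)) {
  if (B < 200) stop("B must be at least 200")
  n <- length(doses)
  draws <- with_seed(child_seed(seed, "boot"), {
    replicate(B, {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(doses[idx])) < 5L) return(rep(NA_real_, 4L + length(ic_levels)))
      ft <- tryCatch(fit_4pl(doses[idx], responses[idx], ic_levels),
                     error = function(e) NULL)
      if (is.null(ft) || !ft$converged)
        rep(NA_real_, 4L + length(ic_levels))
      else c(ft$coefficients, ft$ic_values)
    })
  })
  rownames(draws) <- c("bottom", "top", "hill", "ec50",
                       paste0("IC", ic_levels))
  n_fail <- sum(is.na(draws["ec50", ]))
  reliable <- n_fail <= 0.2 * B
  ci <- NULL
  if (reliable) {
    ci <- t(apply(draws, 1L, quantile, probs = c(0.025, 0.975),
                  na.rm = TRUE, type = 7))
    colnames(ci) <- c("lower", "upper")
  }
  list(ci = ci, n_fail = n_fail, B = B, reliable = reliable)
}
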