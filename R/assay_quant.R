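## Bench-side quantification arithmetic: 2^-ddCt relative qPCR
## quantification, Western-blot densitometry ratios, clonogenic-assay
## percentages, cell-cycle phase-fraction folds, xenograft tumor
## volume/area, and the plain two-group Student t-test.

#' 2^-ddCt relative quantification
#'
#' Per replicate, dCT = CT(target) - CT(reference); ddCT = mean
#' dCT(treated) - mean dCT(control); fold change = 2^-ddCT. Per-replicate
#' folds (each treated replicate's dCT against the mean control dCT) are
#' returned for spread.
#'
#' @param control,treated \code{data.frame}s with columns
#'   \code{ct_target}, \code{ct_reference} and (if present) \code{gene};
#'   at least one replicate per arm and, when \code{gene} is present,
#'   one common gene label per arm.
#' @return list with \code{fold}, \code{ddct}, \code{dct_control},
#'   \code{dct_treated} (means), \code{replicate_folds}.
#' @export
#' @examples
#' ctl <- data.frame(ct_target = 25, ct_reference = 20)
#' trt <- data.frame(ct_target = 27, ct_reference = 20)
#' ddct_fold_change(ctl, trt)$fold  # 0.25
ddct_fold_change <- function(control, treated) {
  for (arm in list(control, treated))
    if (!all(c("ct_target", "ct_reference") %in% names(arm)) ||
        nrow(arm) < 1L)
      stop("each arm needs >= 1 replicate with ct_target and ct_reference")
  if (!is.null(control$gene) && !is.null(treated$gene)) {
    gc <- unique(control$gene); gt <- unique(treated$gene)
    if (length(gc) != 1L || length(gt) != 1L || gc != gt)
      stop("control and treated must measure the same single gene")
  }
  if (any(c(control$ct_target, control$ct_reference,
            treated$ct_target, treated$ct_reference) <= 0))
    stop("CT values must be positive")
  dct_c <- control$ct_target - control$ct_reference
  dct_t <- treated$ct_target - treated$ct_reference
  ddct <- mean(dct_t) - mean(dct_c)
  list(fold = 2^(-ddct), ddct = ddct,
       dct_control = mean(dct_c), dct_treated = mean(dct_t),
       replicate_folds = 2^(-(dct_t - mean(dct_c))))
}

#' Densitometry ratio relative to a loading control
#'
#' Relative protein level = (band / loading) / (control band / control
#' loading); the control lane is 1 by construction. Invariant to
#' rescaling all four intensities by a common factor.
#'
#' @param band,loading treated-lane band and loading-control (e.g.
#'   beta-actin) intensities.
#' @param control_band,control_loading same for the control lane.
#' @return relative protein level (control = 1).
#' @export
densitometry_ratio <- function(band, loading, control_band,
                               control_loading) {
  v <- c(band, loading, control_band, control_loading)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all intensities must be positive")
  (band / loading) / (control_band / control_loading)
}

#' Colony formation as percent of control
#'
#' Percent colony-forming units = 100 * mean(treated wells) /
#' mean(control wells), with a two-sided Student t-test across wells.
#'
#' @param treated_counts,control_counts colony counts per replicate
#'   well, at least 3 wells per arm.
#' @return list with \code{percent}, \code{p}, \code{mean_treated},
#'   \code{mean_control}.
#' @export
colony_percentage <- function(treated_counts, control_counts) {
  if (length(treated_counts) < 3L || length(control_counts) < 3L)
    stop("need at least 3 replicate wells per arm")
  if (mean(control_counts) == 0) stop("control mean is zero")
  tt <- group_ttest(treated_counts, control_counts)
  list(percent = 100 * mean(treated_counts) / mean(control_counts),
       p = tt$p, mean_treated = mean(treated_counts),
       mean_control = mean(control_counts))
}

#' Construct cell-cycle phase fractions
#'
#' @param g1,s,g2m percentages of cells in each phase, each in
#'   \code{[0, 100]}; the sum must lie in \code{[95, 105]} (tolerance
#'   for debris and gating loss).
#' @return list of class \code{"phase_fractions"}.
#' @export
phase_fractions <- function(g1, s, g2m) {
  v <- c(g1 = g1, s = s, g2m = g2m)
  if (any(v < 0 | v > 100)) stop("phase fractions must be in [0, 100]")
  if (sum(v) < 95 || sum(v) > 105)
    stop("phase fractions must sum to 95-105%; got ", sum(v))
  structure(as.list(v), class = "phase_fractions")
}

#' Fold change of one cell-cycle phase fraction
#'
#' fold = treated fraction / control fraction for the chosen phase.
#' Reported figures conventionally show one decimal (e.g. a 52\% vs
#' 14\% G2/M fraction is a 3.7-fold increase); the raw ratio is
#' returned so the reciprocal identity holds exactly, and rounding is
#' applied at report time.
#'
#' @param treated,control \code{\link{phase_fractions}}.
#' @param phase one of \code{"g1"}, \code{"s"}, \code{"g2m"}.
#' @return the fold change (raw ratio).
#' @export
#' @examples
#' trt <- phase_fractions(30, 18, 52)
#' ctl <- phase_fractions(60, 26, 14)
#' round(phase_fold_change(trt, ctl, "g2m"), 1)  # 3.7
phase_fold_change <- function(treated, control, phase = c("g2m", "g1", "s")) {
  stopifnot(inherits(treated, "phase_fractions"),
            inherits(control, "phase_fractions"))
  phase <- match.arg(phase)
  if (control[[phase]] <= 0) stop("control ", phase, " fraction is zero")
  treated[[phase]] / control[[phase]]
}

#' Xenograft tumor volume and area from caliper diameters
#'
#' volume = a * b^2 * 0.5 with a the longer and b the shorter diameter
#' (inputs are reordered so a >= b); area = a * b by default, or the
#' ellipse area pi/4 * a * b with \code{ellipse = TRUE}.
#'
#' @param a,b tumor diameters in mm, both positive.
#' @param ellipse use the ellipse area convention (default
#'   \code{FALSE}).
#' @return list of class \code{"tumor_measurement"} with \code{a},
#'   \code{b}, \code{volume} (mm^3), \code{area} (mm^2).
#' @export
#' @examples
#' tumor_metrics(4, 2)$volume  # 8
tumor_metrics <- function(a, b, ellipse = FALSE) {
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0)
    stop("tumor diameters must be positive")
  if (b > a) { tmp <- a; a <- b; b <- tmp }
  structure(list(a = a, b = b, volume = a * b^2 * 0.5,
                 area = if (ellipse) pi / 4 * a * b else a * b),
            class = "tumor_measurement")
}

#' @export
print.tumor_measurement <- function(x, ...) {
  cat(sprintf("Tumor %g x %g mm: volume %.4g mm^3, area %.4g mm^2\n",
              x$a, x$b, x$volume, x$area))
  invisible(x)
}

#' Two-group Student t-test (pooled variance)
#'
#' Two-sided pooled-variance Student t-test with group means and SDs.
#' With zero pooled variance the test is degenerate: p = 1 for equal
#' means, p = 0 otherwise (the groups are then trivially separated).
#'
#' @param groupA,groupB numeric vectors, at least 2 values each.
#' @return list with \code{p}, \code{t}, \code{mean_diff},
#'   \code{mean_a}, \code{mean_b}, \code{sd_a}, \code{sd_b}.
#' @export
group_ttest <- function(groupA, groupB) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least 2 values")
  ma <- mean(groupA); mb <- mean(groupB)
  va <- var(groupA); vb <- var(groupB)
  na <- length(groupA); nb <- length(groupB)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  if (sp2 == 0) {
    return(list(p = if (ma == mb) 1 else 0, t = if (ma == mb) 0 else Inf,
                mean_diff = ma - mb, mean_a = ma, mean_b = mb,
                sd_a = sqrt(va), sd_b = sqrt(vb)))
  }
  tt <- stats::t.test(groupA, groupB, var.equal = TRUE)
  list(p = tt$p.value, t = unname(tt$statistic), mean_diff = ma - mb,
       mean_a = ma, mean_b = mb, sd_a = sqrt(va), sd_b = sqrt(vb))
}
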