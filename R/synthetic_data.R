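## Synthetic-data generators. Every generator is a pure function of
## (config, seed): the same seed gives bit-identical output, and the
## ground truth used to generate is returned alongside the data so that
## recovery tests are self-contained.
##
## Expression is modelled as log2-normal: downstream statistics are
## median/rank-based and robust to the exact law, so a simple normal on
## the log2 scale is adequate and easy to reason about. No attempt is
## made to mimic batch structure, platform effects or gene-gene
## correlation.

#' Simulate a multi-cohort pan-cancer expression dataset
#'
#' Each cohort is an independent genes-by-samples block in which a
#' designated gene set is shifted up by a per-cohort log2 delta; all
#' other genes sit at the baseline. Defaults mirror the scale of a
#' pan-cancer screen with 24 tumor types whose set-level log2 fold
#' changes span roughly 0.55 to 1.34.
#'
#' @param n_cohorts number of cohorts (default 24).
#' @param genes_per_matrix total genes (default 2000).
#' @param samples_per_cohort samples per cohort, \eqn{\ge 2} (default 100).
#' @param set_size genes in the up-shifted set, \code{< genes_per_matrix}
#'   (default 200).
#' @param delta per-cohort log2 up-shift; scalar (recycled) or length
#'   \code{n_cohorts}. Default \code{seq(0.55, 1.34, length.out =
#'   n_cohorts)}.
#' @param baseline_mean,baseline_sd log2-scale normal parameters
#'   (defaults 8 and 2; \code{baseline_sd > 0}).
#' @param seed integer seed.
#' @return a list: \code{dataset} (an \code{ExpressionDataset} with
#'   cohort labels \code{"cohort01"}...), \code{truth} (named per-cohort
#'   delta) and \code{geneset} (the shifted \code{GeneSet}).
#' @export
#' @examples
#' sim <- simulate_pancancer(n_cohorts = 2, genes_per_matrix = 100,
#'                           samples_per_cohort = 5, set_size = 10,
#'                           delta = 1, seed = 1)
#' sim$truth
simulate_pancancer <- function(n_cohorts = 24, genes_per_matrix = 2000,
                               samples_per_cohort = 100, set_size = 200,
                               delta = seq(0.55, 1.34, length.out = n_cohorts),
                               baseline_mean = 8, baseline_sd = 2,
                               seed = 1) {
  if (set_size >= genes_per_matrix) stop("set_size must be < genes_per_matrix")
  if (samples_per_cohort < 2) stop("samples_per_cohort must be >= 2")
  if (baseline_sd <= 0) stop("baseline_sd must be > 0")
  if (n_cohorts < 1) stop("n_cohorts must be >= 1")
  delta <- rep_len(as.numeric(delta), n_cohorts)
  cohorts <- sprintf("cohort%02d", seq_len(n_cohorts))
  names(delta) <- cohorts
  genes <- sprintf("gene%05d", seq_len(genes_per_matrix))
  with_seed(seed, {
    members <- sort(sample(genes, set_size))
    in_set <- genes %in% members
    blocks <- lapply(seq_len(n_cohorts), function(ci) {
      m <- matrix(rnorm(genes_per_matrix * samples_per_cohort,
                        mean = baseline_mean, sd = baseline_sd),
                  nrow = genes_per_matrix)
      m[in_set, ] <- m[in_set, ] + delta[ci]
      colnames(m) <- sprintf("%s_s%03d", cohorts[ci],
                             seq_len(samples_per_cohort))
      m
    })
    values <- do.call(cbind, blocks)
    rownames(values) <- genes
    cohort <- setNames(rep(cohorts, each = samples_per_cohort),
                       colnames(values))
    list(dataset = expression_dataset(values, cohort),
         truth = delta,
         geneset = gene_set("sim_set", members,
                            description = "simulated up-shifted set"))
  })
}

#' Simulate survival times with expression-dependent hazard
#'
#' Event times are exponential with hazard
#' \code{baseline_hazard * exp(log_hazard_ratio * covariate)}
#' (proportional hazards). Censoring is independent of the event time:
#' each patient is, with probability \code{censor_rate}, subject to a
#' Uniform(0, \code{max_follow_up}) censoring time; with
#' \code{censor_rate = 0} every event is observed. All times are capped
#' by nothing else, so the time unit is whatever the hazard's unit is
#' (days by convention).
#'
#' @param covariate numeric per-patient covariate (e.g. log2 expression
#'   of one gene); names, if present, become sample ids.
#' @param baseline_hazard events per day, \code{> 0} (default 1/1000).
#' @param log_hazard_ratio per-unit-covariate log hazard ratio beta
#'   (default 0).
#' @param censor_rate fraction in \code{[0, 1)} (default 0.3).
#' @param max_follow_up days (default 3650).
#' @param seed integer seed.
#' @return a \code{\link{survival_table}} with the covariate attached.
#' @export
simulate_survival <- function(covariate, baseline_hazard = 1 / 1000,
                              log_hazard_ratio = 0, censor_rate = 0.3,
                              max_follow_up = 3650, seed = 1) {
  if (baseline_hazard <= 0) stop("baseline_hazard must be > 0")
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must be in [0, 1)")
  covariate <- as.numeric(covariate)
  n <- length(covariate)
  if (n == 0L) stop("need at least one patient")
  ids <- if (!is.null(names(covariate))) names(covariate) else
    sprintf("pt%04d", seq_len(n))
  with_seed(seed, {
    hz <- baseline_hazard * exp(log_hazard_ratio * covariate)
    t_event <- rexp(n, rate = hz)
    censored <- runif(n) < censor_rate
    t_cens <- ifelse(censored, runif(n, 0, max_follow_up), Inf)
    time <- pmin(t_event, t_cens)
    event <- t_event <= t_cens
    survival_table(ids, time, event, covariate = covariate)
  })
}

#' Simulate a treated-vs-control microarray experiment
#'
#' Generates replicate log2 expression columns for an ordered series of
#' conditions (control plus increasing doses); genes in \code{target_set}
#' are shifted down per condition by \code{shifts}, which must be
#' monotone non-increasing. Replicate noise is i.i.d. normal. The design
#' mirrors a triplicate microarray screen (3 controls plus 3 replicates
#' per treatment concentration).
#'
#' @param n_genes total genes (default 2000).
#' @param n_replicates replicates per condition, \eqn{\ge 2} (default 3).
#' @param conditions ordered condition labels (default
#'   \code{c("control", "IC25", "IC50", "IC75")}).
#' @param target_set a \code{GeneSet} of genes to shift; \code{NULL}
#'   picks 100 genes at random under the seed.
#' @param shifts per-condition log2 shift applied to the target set,
#'   same length as \code{conditions}, monotone non-increasing (default
#'   \code{c(0, -0.5, -1, -2)}).
#' @param baseline_mean,baseline_sd gene-level log2 normal parameters
#'   (defaults 8, 2).
#' @param noise_sd replicate noise SD (default 0.25).
#' @param seed integer seed.
#' @return a list: \code{dataset} (cohort label = condition),
#'   \code{truth} (named per-condition shift) and \code{geneset}.
#' @export
simulate_treatment_microarray <- function(n_genes = 2000, n_replicates = 3,
                                          conditions = c("control", "IC25",
                                                         "IC50", "IC75"),
                                          target_set = NULL,
                                          shifts = c(0, -0.5, -1, -2),
                                          baseline_mean = 8, baseline_sd = 2,
                                          noise_sd = 0.25, seed = 1) {
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  if (length(shifts) != length(conditions))
    stop("shifts must match conditions in length")
  if (any(diff(shifts) > 0))
    stop("shifts must be monotone non-increasing across conditions")
  if (baseline_sd <= 0 || noise_sd < 0) stop("invalid noise parameters")
  genes <- sprintf("gene%05d", seq_len(n_genes))
  with_seed(seed, {
    if (is.null(target_set)) {
      target_set <- gene_set("sim_target", sort(sample(genes, min(100, n_genes %/% 2))),
                             description = "simulated down-shifted set")
    }
    in_set <- genes %in% target_set$members
    if (!any(in_set)) stop("target_set has no genes in the matrix")
    base <- rnorm(n_genes, baseline_mean, baseline_sd)
    cols <- list(); labels <- character(0)
    for (ci in seq_along(conditions)) {
      for (r in seq_len(n_replicates)) {
        mu <- base + ifelse(in_set, shifts[ci], 0)
        cols[[length(cols) + 1L]] <- mu + rnorm(n_genes, 0, noise_sd)
        labels <- c(labels, conditions[ci])
      }
    }
    values <- do.call(cbind, cols)
    rownames(values) <- genes
    colnames(values) <- sprintf("%s_r%d", labels,
                                sequence(rep(n_replicates, length(conditions))))
    cohort <- setNames(labels, colnames(values))
    list(dataset = expression_dataset(values, cohort),
         truth = setNames(shifts, conditions),
         geneset = target_set)
  })
}

# 4PL response at dose d: bottom + (top - bottom) / (1 + (d / ec50)^hill)
four_pl <- function(dose, bottom, top, hill, ec50) {
  bottom + (top - bottom) / (1 + (dose / ec50)^hill)
}

#' Simulate a viability dose-response curve
#'
#' Viability (\% of control) follows a four-parameter logistic curve in
#' dose with additive normal noise, the standard MTT-assay model.
#'
#' @param doses positive concentrations (uM).
#' @param bottom,top lower/upper asymptote (\% of control; \code{top >
#'   bottom}).
#' @param hill Hill slope.
#' @param ec50 inflection concentration (uM), \code{> 0}. The default 39
#'   is a realistic OSCC-cell IC50 for an alkylphosphocholine.
#' @param noise_sd additive noise SD in viability \% (default 2).
#' @param seed integer seed.
#' @return a \code{data.frame} with columns \code{dose}, \code{viability}.
#' @export
simulate_dose_response <- function(doses, bottom = 0, top = 100, hill = 1.5,
                                   ec50 = 39, noise_sd = 2, seed = 1) {
  doses <- as.numeric(doses)
  if (any(doses <= 0)) stop("doses must be positive")
  if (top <= bottom) stop("top must exceed bottom")
  if (ec50 <= 0) stop("ec50 must be > 0")
  with_seed(seed, {
    v <- four_pl(doses, bottom, top, hill, ec50) +
      rnorm(length(doses), 0, noise_sd)
    data.frame(dose = doses, viability = v)
  })
}

#' Simulate a qPCR CT table
#'
#' For each target gene with true fold change f, the treated target CT is
#' the control target CT minus log2(f) (a down-regulated gene, f < 1,
#' needs more cycles), plus measurement noise; reference-gene CTs are
#' constant up to the same noise. Suitable for exercising
#' \code{\link{ddct_fold_change}}.
#'
#' @param true_folds named positive per-gene fold changes.
#' @param base_ct control-arm target CT (default 25).
#' @param ref_ct reference-gene CT (default 20).
#' @param n_replicates replicates per arm (default 3).
#' @param noise_sd CT noise SD in cycles (default 0.1).
#' @param seed integer seed.
#' @return a \code{data.frame} with columns \code{gene}, \code{group}
#'   (control/treated), \code{replicate}, \code{ct_target},
#'   \code{ct_reference}.
#' @export
simulate_qpcr <- function(true_folds, base_ct = 25, ref_ct = 20,
                          n_replicates = 3, noise_sd = 0.1, seed = 1) {
  if (any(true_folds <= 0)) stop("fold changes must be positive")
  if (is.null(names(true_folds)))
    names(true_folds) <- sprintf("gene%02d", seq_along(true_folds))
  with_seed(seed, {
    rows <- lapply(names(true_folds), function(g) {
      f <- true_folds[[g]]
      data.frame(
        gene = g,
        group = rep(c("control", "treated"), each = n_replicates),
        replicate = rep(seq_len(n_replicates), 2L),
        ct_target = c(base_ct + rnorm(n_replicates, 0, noise_sd),
                      base_ct - log2(f) + rnorm(n_replicates, 0, noise_sd)),
        ct_reference = ref_ct + rnorm(2L * n_replicates, 0, noise_sd))
    })
    do.call(rbind, rows)
  })
}
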