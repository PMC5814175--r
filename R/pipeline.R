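## End-to-end orchestration: one config drives simulation, the
## pan-cancer deregulation stage, quartile survival, differential
## expression with enrichment, and the assay quantification stage. Each
## stage draws its seed from the master seed through child_seed(), all
## outputs are plain TSV/JSON, and the run report lists exactly the
## files written. Identical (config, seed) give byte-identical result
## files; only the report's wall-clock differs between reruns.

#' Default pipeline configuration
#'
#' Thresholds default to the conventional analysis settings: BH-adjusted
#' p < 0.05 with |log2 FC| > 1 for differential expression, Bonferroni
#' 0.05 for enrichment, top/bottom 25 percentiles for survival
#' stratification, and 10^4 permutations for the set statistic (here
#' reduced per config for speed).
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @return nested configuration list; see \code{\link{validate_config}}
#'   for the schema.
#' @export
default_config <- function(out_dir = "cyclederg_out", seed = 1) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    stages = list(simulate = TRUE, pancancer = TRUE, survival = TRUE,
                  de = TRUE, assay = TRUE),
    inputs = list(expr = NULL, cohorts = NULL, geneset = NULL,
                  clinical = NULL, treatment_expr = NULL,
                  treatment_design = NULL, dose = NULL, qpcr = NULL),
    params = list(
      n_perm = 1000, alpha = 0.05, lfc = 1, bonferroni_alpha = 0.05,
      boot_B = 1000,
      sim = list(n_cohorts = 4, genes_per_matrix = 500,
                 samples_per_cohort = 20, set_size = 50,
                 n_patients = 200, log_hazard_ratio = 0.5,
                 doses = c(5, 10, 20, 40, 80, 160),
                 qpcr_folds = c(CDK1 = 0.05, CCNB1 = 0.2)))
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of
#' \code{\link{default_config}}; everything else keeps its default.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_cfg <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]))
        merge_cfg(base[[k]], over[[k]]) else over[[k]]
    }
    base
  }
  merge_cfg(default_config(), user)
}

#' Validate a pipeline configuration
#'
#' Never throws: returns a character vector of problems, each naming the
#' offending field and the remedy; an empty vector means the config is
#' runnable. Stages that read files (when simulation is disabled) must
#' have their input paths set.
#'
#' @param config configuration list.
#' @return character vector of problems (possibly empty), in stable
#'   field order.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  add <- function(msg) problems <<- c(problems, msg)
  if (is.null(config$out_dir) || !nzchar(config$out_dir))
    add("out_dir: set a writable output directory")
  sd_ <- suppressWarnings(as.integer(config$seed))
  if (is.null(config$seed) || is.na(sd_))
    add("seed: must be an integer")
  np <- config$params$n_perm
  if (is.null(np) || !is.numeric(np) || np < 1)
    add("params$n_perm: must be a count >= 1")
  for (fld in c("alpha", "bonferroni_alpha")) {
    v <- config$params[[fld]]
    if (is.null(v) || !is.numeric(v) || v <= 0 || v > 1)
      add(paste0("params$", fld, ": must be in (0, 1]"))
  }
  sim_on <- isTRUE(config$stages$simulate)
  need_input <- function(stage, fields) {
    if (!isTRUE(config$stages[[stage]]) || sim_on) return()
    for (f in fields)
      if (is.null(config$inputs[[f]]))
        add(paste0("inputs$", f, ": required when stage '", stage,
                   "' is enabled without simulation"))
  }
  need_input("pancancer", c("expr", "cohorts", "geneset"))
  need_input("survival", "clinical")
  need_input("de", c("treatment_expr", "treatment_design", "geneset"))
  need_input("assay", c("dose", "qpcr"))
  problems
}

write_tsv_with_header <- function(df, path, seed) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(version_header(seed), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages run in dependency order (simulate, then pan-cancer / survival
#' / differential expression, then assay quantification). A failing
#' stage aborts stages that depend on its outputs but not independent
#' ones, and the run report is always written. With simulation enabled
#' the downstream stages consume the simulated data (whose fixture files
#' and ground truth are also written); otherwise they read the
#' configured input files.
#'
#' @param config configuration list (see \code{\link{default_config}});
#'   a path to a YAML file is also accepted.
#' @return the run report (list of class \code{"run_report"}), with
#'   per-stage status, parameters used, the file manifest, wall-clock
#'   seconds and warnings. Also written as \code{report.json} in the
#'   output directory.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  t0 <- proc.time()[["elapsed"]]
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  manifest <- character(0)
  note <- function(path) manifest <<- c(manifest, path)
  status <- list()
  warnings_log <- character(0)
  sim <- NULL
  run_stage <- function(name, fn) {
    if (!isTRUE(config$stages[[name]])) {
      status[[name]] <<- "skipped"
      return(invisible(NULL))
    }
    res <- tryCatch(
      withCallingHandlers(fn(), warning = function(w) {
        warnings_log <<- c(warnings_log,
                           paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }),
      error = function(e) {
        status[[name]] <<- paste("error:", conditionMessage(e))
        NULL
      })
    if (is.null(status[[name]])) status[[name]] <<- "ok"
    res
  }

  sim <- run_stage("simulate", function() {
    p <- config$params$sim
    pc <- simulate_pancancer(
      n_cohorts = p$n_cohorts, genes_per_matrix = p$genes_per_matrix,
      samples_per_cohort = p$samples_per_cohort, set_size = p$set_size,
      seed = child_seed(seed, "pancancer"))
    cov <- with_seed(child_seed(seed, "survival"),
                     rnorm(p$n_patients, 8, 2))
    sv <- simulate_survival(cov, log_hazard_ratio = p$log_hazard_ratio,
                            seed = child_seed(seed, "survival"))
    tr <- simulate_treatment_microarray(
      n_genes = p$genes_per_matrix, seed = child_seed(seed, "treatment"))
    dr <- simulate_dose_response(p$doses, seed = child_seed(seed, "dose"))
    qp <- simulate_qpcr(p$qpcr_folds, seed = child_seed(seed, "qpcr"))
    fx <- file.path(out_dir, "fixtures")
    dir.create(fx, showWarnings = FALSE)
    note(write_expression_matrix(pc$dataset,
                                 file.path(fx, "pancancer_expr.tsv"),
                                 file.path(fx, "pancancer_cohorts.tsv"),
                                 seed = seed))
    note(file.path(fx, "pancancer_cohorts.tsv"))
    note(write_gmt(pc$geneset, file.path(fx, "geneset.gmt")))
    note(write_survival_table(sv, file.path(fx, "clinical.tsv"),
                              seed = seed))
    note(write_expression_matrix(tr$dataset,
                                 file.path(fx, "treatment_expr.tsv"),
                                 file.path(fx, "treatment_design.tsv"),
                                 seed = seed))
    note(file.path(fx, "treatment_design.tsv"))
    note(write_tsv_with_header(dr, file.path(fx, "dose_response.tsv"),
                               seed))
    note(write_tsv_with_header(qp, file.path(fx, "qpcr.tsv"), seed))
    truth <- list(pancancer_delta = as.list(pc$truth),
                  treatment_shift = as.list(tr$truth),
                  qpcr_folds = as.list(p$qpcr_folds),
                  log_hazard_ratio = p$log_hazard_ratio)
    jsonlite::write_json(truth, file.path(fx, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    note(file.path(fx, "truth.json"))
    list(pancancer = pc, survival = sv, treatment = tr, dose = dr,
         qpcr = qp)
  })

  run_stage("pancancer", function() {
    if (isTRUE(config$stages$simulate)) {
      if (is.null(sim)) stop("simulation failed; no expression input")
      ds <- sim$pancancer$dataset; gs <- sim$pancancer$geneset
    } else {
      ds <- read_expression_matrix(config$inputs$expr,
                                   config$inputs$cohorts)
      gs <- read_gmt(config$inputs$geneset)[[1L]]
    }
    res <- dereg_test(ds, gs, n_perm = config$params$n_perm, seed = seed)
    note(write_tsv_with_header(as.data.frame(res),
                               file.path(out_dir, "deregulation.tsv"),
                               seed))
    jsonlite::write_json(
      list(top_cohort = res$cohort[1L], top_log2_fc = res$log2_fc[1L],
           top_perm_p = res$perm_p[1L], n_perm = config$params$n_perm),
      file.path(out_dir, "deregulation_summary.json"),
      auto_unbox = TRUE, digits = NA)
    note(file.path(out_dir, "deregulation_summary.json"))
    res
  })

  run_stage("survival", function() {
    tab <- if (isTRUE(config$stages$simulate)) {
      if (is.null(sim)) stop("simulation failed; no clinical input")
      sim$survival
    } else read_survival_table(config$inputs$clinical)
    sq <- survival_by_quartiles(tab)
    for (g in c("high", "low")) {
      km <- sq[[g]]
      df <- data.frame(time = km$event_times, n_risk = km$at_risk,
                       events = km$events, survival = km$survival)
      note(write_tsv_with_header(df,
        file.path(out_dir, paste0("km_", g, ".tsv")), seed))
    }
    jsonlite::write_json(
      list(chi2 = sq$logrank$chi2, p = sq$logrank$p,
           n_high = unname(sq$logrank$n["A"]),
           n_low = unname(sq$logrank$n["B"])),
      file.path(out_dir, "logrank.json"), auto_unbox = TRUE, digits = NA)
    note(file.path(out_dir, "logrank.json"))
    sq
  })

  run_stage("de", function() {
    if (isTRUE(config$stages$simulate)) {
      if (is.null(sim)) stop("simulation failed; no treatment input")
      ds <- sim$treatment$dataset; gs <- sim$treatment$geneset
    } else {
      ds <- read_expression_matrix(config$inputs$treatment_expr,
                                   config$inputs$treatment_design)
      gs <- read_gmt(config$inputs$geneset)[[1L]]
    }
    de <- de_by_condition(ds, alpha = config$params$alpha,
                          lfc = config$params$lfc)
    for (cc in names(de$tests))
      note(write_tsv_with_header(de$tests[[cc]],
        file.path(out_dir, paste0("de_", cc, ".tsv")), seed))
    if (!is.null(de$overlap_down))
      note(write_tsv_with_header(de$overlap_down,
        file.path(out_dir, "venn_down.tsv"), seed))
    if (!is.null(de$overlap_up))
      note(write_tsv_with_header(de$overlap_up,
        file.path(out_dir, "venn_up.tsv"), seed))
    universe <- rownames(ds$values)
    enr <- lapply(de$tests, function(t.)
      hypergeom_enrichment(t.$gene[t.$status == "down"], universe,
                           list(gs)))
    for (cc in names(enr))
      if (nrow(enr[[cc]]))
        note(write_tsv_with_header(enr[[cc]],
          file.path(out_dir, paste0("enrichment_down_", cc, ".tsv")),
          seed))
    list(de = de, enrichment = enr)
  })

  run_stage("assay", function() {
    dr <- if (isTRUE(config$stages$simulate)) {
      if (is.null(sim)) stop("simulation failed; no assay input")
      sim$dose
    } else read.delim(config$inputs$dose, comment.char = "#")
    qp <- if (isTRUE(config$stages$simulate)) sim$qpcr else
      read.delim(config$inputs$qpcr, comment.char = "#")
    fit <- fit_4pl(dr$dose, dr$viability)
    folds <- lapply(split(qp, qp$gene), function(g)
      ddct_fold_change(g[g$group == "control", ],
                       g[g$group == "treated", ])$fold)
    jsonlite::write_json(
      list(dose_response = c(as.list(fit$coefficients),
                             list(converged = fit$converged,
                                  ic = as.list(fit$ic_values))),
           qpcr_folds = folds),
      file.path(out_dir, "assay.json"), auto_unbox = TRUE, digits = NA)
    note(file.path(out_dir, "assay.json"))
    list(fit = fit, folds = folds)
  })

  report <- list(stages = status,
                 parameters = config$params,
                 seed = seed,
                 manifest = manifest,
                 wall_clock_sec = proc.time()[["elapsed"]] - t0,
                 warnings = warnings_log)
  class(report) <- "run_report"
  jsonlite::write_json(unclass(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run (seed", x$seed, "):\n")
  for (s in names(x$stages)) cat("  ", s, ":", x$stages[[s]], "\n")
  cat("  files written:", length(x$manifest), "\n")
  cat(sprintf("  wall clock: %.2f s\n", x$wall_clock_sec))
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}
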