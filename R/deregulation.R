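## Gene-set deregulation: per-cohort comparison of the set's median log2
## expression against all other genes, with rank-sum significance, an
## empirical permutation null and a cross-cohort ranking.
##
## Aggregation order: per-gene medians across samples are computed
## first, then the set-vs-rest medians are taken over genes. Pooling all
## gene-by-sample values before the median is available via
## `pooled = TRUE` in dereg_test(); the per-gene-median reading is the
## default because it matches the quantile-reference convention (the
## reference quantiles are of per-gene medians).

#' Per-gene median log2 expression within a cohort
#'
#' Missing values are excluded from each gene's median; genes with no
#' non-missing observation are dropped and reported via the
#' \code{"dropped"} attribute.
#'
#' @param dataset an \code{ExpressionDataset}.
#' @param cohort cohort label present in the dataset.
#' @return named numeric vector of per-gene medians, with attribute
#'   \code{"dropped"} listing all-missing genes.
#' @export
gene_medians <- function(dataset, cohort) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  sel <- names(dataset$cohort)[dataset$cohort == cohort]
  if (length(sel) == 0L) stop("unknown cohort: ", cohort)
  if (length(sel) < 2L) stop("cohort ", cohort, " has fewer than 2 samples")
  m <- dataset$values[, sel, drop = FALSE]
  med <- apply(m, 1L, median, na.rm = TRUE)
  dropped <- names(med)[is.nan(med) | is.na(med)]
  med <- med[!names(med) %in% dropped]
  attr(med, "dropped") <- dropped
  med
}

#' Set-vs-rest median fold change
#'
#' On log2 data the difference of medians is the log2 fold change:
#' \code{log2_fc = median(set genes) - median(all other genes)}.
#'
#' @param medians named per-gene values (e.g. from
#'   \code{\link{gene_medians}}).
#' @param set a \code{GeneSet}.
#' @return list with \code{median_set}, \code{median_other},
#'   \code{log2_fc}, \code{n_set}, \code{n_other}.
#' @export
#' @examples
#' m <- c(a = 3, b = 4, c = 1, d = 2)
#' set_fold_change(m, gene_set("s", c("a", "b")))$log2_fc  # 2
set_fold_change <- function(medians, set) {
  stopifnot(inherits(set, "GeneSet"))
  in_set <- names(medians) %in% set$members
  if (!any(in_set))
    stop("gene set '", set$name, "' shares no genes with the measured genes")
  if (all(in_set))
    stop("gene set '", set$name, "' covers every measured gene; no background")
  ms <- median(medians[in_set]); mo <- median(medians[!in_set])
  list(median_set = ms, median_other = mo, log2_fc = ms - mo,
       n_set = sum(in_set), n_other = sum(!in_set))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration when both groups have fewer than 20 values and no
#' ties; otherwise the normal approximation with midranks and continuity
#' correction. If every value is tied across both groups the test is
#' uninformative and p = 1 is returned with a warning.
#'
#' @param set_values,other_values numeric vectors, both non-empty.
#' @return two-sided p-value.
#' @export
ranksum_test <- function(set_values, other_values) {
  if (length(set_values) == 0L || length(other_values) == 0L)
    stop("both groups must be non-empty")
  pooled <- c(set_values, other_values)
  if (length(unique(pooled)) == 1L) {
    warning("all values tied across both groups; p = 1")
    return(1)
  }
  exact <- max(length(set_values), length(other_values)) < 20
  suppressWarnings(
    wilcox.test(set_values, other_values, exact = exact,
                correct = TRUE)$p.value)
}

#' Permutation null for the set fold change
#'
#' Draws \code{M} random gene sets of the observed size (uniformly,
#' without replacement) from the measured genes, recomputes the
#' set-vs-rest log2 fold change for each, and reports the add-one
#' empirical p-value \code{(1 + #\{null >= observed\}) / (M + 1)}. Ties
#' count against significance (the tail uses \code{>=}), and p can never
#' be 0; its floor is \code{1 / (M + 1)}.
#'
#' @param medians named per-gene values.
#' @param set_size number of genes to relabel per draw, less than the
#'   number of genes.
#' @param observed observed log2 fold change.
#' @param M number of permutations, \eqn{\ge 1} (default 10000).
#' @param seed integer seed.
#' @return object of class \code{"permutation_null"}: list with
#'   \code{observed}, \code{null_values}, \code{p_emp}, \code{M},
#'   \code{seed}.
#' @export
permutation_null <- function(medians, set_size, observed, M = 10000,
                             seed = 1) {
  n <- length(medians)
  if (set_size >= n) stop("set_size must be < number of genes")
  if (set_size < 1 || M < 1) stop("set_size and M must be >= 1")
  null_values <- with_seed(seed, {
    vapply(seq_len(M), function(i) {
      idx <- sample.int(n, set_size)
      median(medians[idx]) - median(medians[-idx])
    }, numeric(1L))
  })
  p_emp <- (1 + sum(null_values >= observed)) / (M + 1)
  structure(list(observed = observed, null_values = null_values,
                 p_emp = p_emp, M = M, seed = seed),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat("Permutation null: M =", x$M, " observed log2 FC =",
      format(x$observed, digits = 4),
      " empirical p =", format(x$p_emp, digits = 4), "\n")
  invisible(x)
}

#' Rank cohorts by set fold change
#'
#' Rank 1 is the largest log2 fold change; ties are broken by smaller
#' rank-sum p, then lexicographically by cohort label, so the ranks are
#' always a permutation of 1..n.
#'
#' @param results \code{data.frame} with columns \code{cohort},
#'   \code{log2_fc} and (for tie-breaks) \code{ranksum_p}.
#' @return the same frame, ordered by rank, with a \code{rank} column.
#' @export
pancancer_rank <- function(results) {
  results <- as.data.frame(results)
  if (nrow(results) < 1L) stop("need at least one cohort result")
  if (anyDuplicated(results$cohort))
    stop("duplicate cohort label: ",
         results$cohort[duplicated(results$cohort)][1L])
  if (is.null(results$ranksum_p)) results$ranksum_p <- NA_real_
  ord <- order(-results$log2_fc, results$ranksum_p, results$cohort)
  results <- results[ord, , drop = FALSE]
  results$rank <- seq_len(nrow(results))
  rownames(results) <- NULL
  results
}

#' Quartile reference of per-gene medians
#'
#' The 25/50/75\% quantiles of the per-gene median expression of all
#' measured genes — the grey reference lines a set's genes are plotted
#' against. Uses the linear-interpolation (type 7) quantile definition;
#' quantile dialects differ, so the convention is fixed and documented.
#'
#' @param medians numeric vector with at least 4 values.
#' @return list with \code{q25}, \code{q50}, \code{q75}.
#' @export
quantile_reference <- function(medians) {
  medians <- medians[!is.na(medians)]
  if (length(medians) < 4L) stop("need at least 4 values")
  q <- quantile(medians, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(q25 = q[1L], q50 = q[2L], q75 = q[3L])
}

#' Paired tumor-vs-normal test per gene
#'
#' Two-sided Wilcoxon signed-rank test per gene across matched pairs,
#' with midranks and zero differences dropped; the direction is the sign
#' of the median paired difference. With 12 or fewer non-zero
#' differences the p-value is exact, from full enumeration of all 2^n
#' sign assignments of the midranked absolute differences (valid under
#' ties, where the textbook exact distribution is not); larger genes use
#' the normal approximation with continuity handled by midranks. Genes
#' whose differences are all zero get p = 1 and direction 0.
#'
#' @param tumor,normal numeric matrices (genes x pairs) with identical
#'   dimnames, columns aligned so column j of both is the same patient;
#'   at least 6 pairs.
#' @return \code{data.frame} with columns \code{gene}, \code{p},
#'   \code{direction}.
#' @export
matched_paired_test <- function(tumor, normal) {
  if (!all(dim(tumor) == dim(normal)))
    stop("tumor and normal must have identical dimensions")
  if (ncol(tumor) < 6L) stop("need at least 6 matched pairs")
  if (!identical(rownames(tumor), rownames(normal)))
    stop("tumor and normal must list the same genes in the same order")
  res <- t(vapply(seq_len(nrow(tumor)), function(i) {
    d <- tumor[i, ] - normal[i, ]
    d <- d[!is.na(d)]
    dn <- d[d != 0]
    if (length(dn) == 0L) return(c(p = 1, direction = 0))
    p <- if (length(dn) <= 12L) signrank_exact_p(dn) else
      suppressWarnings(wilcox.test(dn, correct = TRUE)$p.value)
    c(p = p, direction = sign(median(d)))
  }, numeric(2L)))
  data.frame(gene = rownames(tumor), p = res[, "p"],
             direction = res[, "direction"], row.names = NULL)
}

# Exact two-sided signed-rank p by enumerating all 2^n sign vectors of
# the midranked |differences|; correct in the presence of ties.
signrank_exact_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_null <- as.vector(signs %*% r)
  min(1, 2 * min(mean(v_null >= v_obs), mean(v_null <= v_obs)))
}

#' Gene-set deregulation test across cohorts
#'
#' The package's central analysis. For every cohort in the dataset it
#' computes per-gene medians, the set-vs-rest log2 fold change, a
#' two-sided rank-sum p (set-gene medians vs all other gene medians), an
#' empirical permutation p from \code{n_perm} random relabelings of the
#' set, and finally ranks the cohorts by fold change.
#'
#' @param dataset an \code{ExpressionDataset} with cohort labels.
#' @param set a \code{GeneSet}.
#' @param n_perm permutations per cohort (default 10000).
#' @param seed master seed; each cohort's permutation stream derives
#'   from it via \code{\link{child_seed}} plus the cohort index.
#' @param pooled if \code{TRUE}, medians pool all gene-by-sample values
#'   instead of aggregating per-gene medians first (alternative reading
#'   of "median gene expression"; default \code{FALSE}).
#' @return object of class \code{"dereg_result"}: a ranked
#'   \code{data.frame} (one row per cohort) with columns \code{cohort},
#'   \code{n_set}, \code{n_other}, \code{median_set},
#'   \code{median_other}, \code{log2_fc}, \code{ranksum_p},
#'   \code{perm_p}, \code{n_perm}, \code{rank}; the per-cohort
#'   \code{permutation_null} objects are kept in attribute
#'   \code{"nulls"}.
#' @export
#' @examples
#' sim <- simulate_pancancer(n_cohorts = 3, genes_per_matrix = 300,
#'                           samples_per_cohort = 10, set_size = 30,
#'                           delta = c(0.2, 0.6, 1.2), seed = 7)
#' res <- dereg_test(sim$dataset, sim$geneset, n_perm = 200, seed = 7)
#' res
dereg_test <- function(dataset, set, n_perm = 10000, seed = 1,
                       pooled = FALSE) {
  stopifnot(inherits(dataset, "ExpressionDataset"),
            inherits(set, "GeneSet"))
  cohorts <- unique(dataset$cohort)
  base_seed <- child_seed(seed, "perm")
  rows <- list(); nulls <- list()
  for (ci in seq_along(cohorts)) {
    co <- cohorts[ci]
    med <- gene_medians(dataset, co)
    if (pooled) {
      sel <- names(dataset$cohort)[dataset$cohort == co]
      m <- dataset$values[names(med), sel, drop = FALSE]
      fc <- set_fold_change_pooled(m, set)
      in_set <- rownames(m) %in% set$members
      p_rs <- ranksum_test(as.vector(m[in_set, ]), as.vector(m[!in_set, ]))
      pn <- permutation_null_pooled(m, fc$n_set, fc$log2_fc, M = n_perm,
                                    seed = (base_seed + ci) %% 2147483647)
    } else {
      fc <- set_fold_change(med, set)
      in_set <- names(med) %in% set$members
      p_rs <- ranksum_test(med[in_set], med[!in_set])
      pn <- permutation_null(med, fc$n_set, fc$log2_fc, M = n_perm,
                             seed = (base_seed + ci) %% 2147483647)
    }
    nulls[[co]] <- pn
    rows[[ci]] <- data.frame(
      cohort = co, n_set = fc$n_set, n_other = fc$n_other,
      median_set = fc$median_set, median_other = fc$median_other,
      log2_fc = fc$log2_fc, ranksum_p = p_rs, perm_p = pn$p_emp,
      n_perm = n_perm)
  }
  out <- pancancer_rank(do.call(rbind, rows))
  attr(out, "nulls") <- nulls
  attr(out, "geneset") <- set$name
  class(out) <- c("dereg_result", "data.frame")
  out
}

# Pooled reading of the statistic: medians are taken over all
# gene x sample values of each group jointly, not over per-gene medians.
set_fold_change_pooled <- function(m, set) {
  in_set <- rownames(m) %in% set$members
  if (!any(in_set))
    stop("gene set '", set$name, "' shares no genes with the measured genes")
  if (all(in_set))
    stop("gene set '", set$name, "' covers every measured gene; no background")
  ms <- median(m[in_set, ], na.rm = TRUE)
  mo <- median(m[!in_set, ], na.rm = TRUE)
  list(median_set = ms, median_other = mo, log2_fc = ms - mo,
       n_set = sum(in_set), n_other = sum(!in_set))
}

permutation_null_pooled <- function(m, set_size, observed, M, seed) {
  n <- nrow(m)
  if (set_size >= n) stop("set_size must be < number of genes")
  null_values <- with_seed(seed, {
    vapply(seq_len(M), function(i) {
      idx <- sample.int(n, set_size)
      median(m[idx, ], na.rm = TRUE) - median(m[-idx, ], na.rm = TRUE)
    }, numeric(1L))
  })
  p_emp <- (1 + sum(null_values >= observed)) / (M + 1)
  structure(list(observed = observed, null_values = null_values,
                 p_emp = p_emp, M = M, seed = seed),
            class = "permutation_null")
}

#' @export
print.dereg_result <- function(x, digits = 3, ...) {
  cat("Gene-set deregulation test (", attr(x, "geneset"), "), ",
      nrow(x), " cohort(s), ", x$n_perm[1L], " permutations\n\n", sep = "")
  df <- as.data.frame(x)
  df$median_set <- round(df$median_set, digits)
  df$median_other <- round(df$median_other, digits)
  df$log2_fc <- round(df$log2_fc, digits)
  df$ranksum_p <- signif(df$ranksum_p, digits)
  df$perm_p <- signif(df$perm_p, digits)
  print(df[, c("rank", "cohort", "n_set", "n_other", "log2_fc",
               "ranksum_p", "perm_p")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.dereg_result <- function(object, ...) {
  fc <- object$log2_fc
  cat("Cohorts:", nrow(object), "\n")
  cat("log2 fold change range:", format(min(fc), digits = 3), "to",
      format(max(fc), digits = 3), "\n")
  cat("Top cohort:", object$cohort[1L], "(log2 FC",
      format(fc[1L], digits = 3), ", permutation p",
      format(object$perm_p[1L], digits = 3), ")\n")
  invisible(object)
}
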