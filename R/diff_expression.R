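## Treated-vs-control differential expression and gene-set
## over-representation. The gene-wise test is a pooled-variance Student
## t-test on log2 values rather than a moderated (empirical-Bayes)
## statistic: the thresholds, overlap and enrichment logic are the
## point here, and a plain per-gene test keeps them transparent. At
## triplicate scale the pooled test retains usable power where a
## separate-variance (Welch) test does not, and it matches the
## equal-variance replicate noise such arrays exhibit. Exact gene lists
## from a moderated analysis will differ; the threshold semantics
## (BH-adjusted p < 0.05 and |log2 FC| > 1) are identical.

rowVars_ <- function(m) {
  nm <- rowMeans(m, na.rm = TRUE)
  rowSums((m - nm)^2, na.rm = TRUE) / (rowSums(!is.na(m)) - 1)
}

#' Gene-wise Student t-tests between two replicate groups
#'
#' For every gene: log2 fold change = mean(treated) - mean(control) and
#' a two-sided pooled-variance Student t-test across replicates. Genes
#' with zero variance in both arms and equal means are untestable and
#' get p = 1; zero pooled-variance genes with unequal means receive a
#' variance floor equal to the 10th percentile of all positive per-gene
#' pooled variances before testing (flagged in the \code{floored}
#' column), so degenerate fixtures never produce NaN statistics. Status
#' calls use the thresholds BH-adjusted p < \code{alpha} and |log2 FC| >
#' \code{lfc}.
#'
#' @param treated,control numeric matrices (genes x replicates), same
#'   genes in the same order, at least 2 replicates per arm.
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @param lfc absolute log2-fold-change threshold (default 1).
#' @return \code{data.frame} of class \code{"de_result"} with columns
#'   \code{gene}, \code{log2_fc}, \code{t_stat}, \code{p}, \code{adj_p},
#'   \code{status} (\code{"up"}, \code{"down"}, \code{"ns"}),
#'   \code{floored}.
#' @export
gene_tests <- function(treated, control, alpha = 0.05, lfc = 1) {
  if (!is.matrix(treated) || !is.matrix(control))
    stop("treated and control must be matrices")
  if (ncol(treated) < 2L || ncol(control) < 2L)
    stop("each arm needs at least 2 replicates")
  if (nrow(treated) != nrow(control) ||
      !identical(rownames(treated), rownames(control)))
    stop("arms must list the same genes in the same order")
  n1 <- rowSums(!is.na(treated)); n2 <- rowSums(!is.na(control))
  m1 <- rowMeans(treated, na.rm = TRUE); m2 <- rowMeans(control, na.rm = TRUE)
  v1 <- rowVars_(treated); v2 <- rowVars_(control)
  pooled <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  pos <- pooled[pooled > 0 & is.finite(pooled)]
  floor_v <- if (length(pos)) unname(quantile(pos, 0.10, type = 7)) else
    .Machine$double.eps
  degenerate <- pooled == 0 | !is.finite(pooled)
  floored <- degenerate & (m1 != m2)
  pooled[floored] <- floor_v
  se2 <- pooled * (1 / n1 + 1 / n2)
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- n1 + n2 - 2
  p <- 2 * pt(abs(t_stat), df, lower.tail = FALSE)
  untestable <- degenerate & (m1 == m2)
  t_stat[untestable] <- 0; p[untestable] <- 1
  adj_p <- bh_adjust(p)
  status <- rep("ns", length(p))
  status[adj_p < alpha & (m1 - m2) > lfc] <- "up"
  status[adj_p < alpha & (m1 - m2) < -lfc] <- "down"
  out <- data.frame(gene = rownames(treated), log2_fc = m1 - m2,
                    t_stat = t_stat, p = p, adj_p = adj_p,
                    status = status, floored = floored, row.names = NULL)
  class(out) <- c("de_result", "data.frame")
  out
}

#' @export
print.de_result <- function(x, ...) {
  cat("Differential expression:", nrow(x), "genes;",
      sum(x$status == "up"), "up,", sum(x$status == "down"), "down\n")
  NextMethod()
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR control: sort p ascending, adj_i = min over j >= i of
#' (p_j * m / j), capped at 1, returned in input order. Any p outside
#' [0, 1] is a hard error.
#'
#' @param pvals numeric p-values in \code{[0, 1]}.
#' @return adjusted p-values in input order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # all 0.03
bh_adjust <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Exclusive Venn-region counts across significant gene lists
#'
#' Partitions the union of the lists into every exclusive region of the
#' Venn diagram by exact set algebra. Region labels join the names of
#' the lists a region belongs to with \code{"&"}.
#'
#' @param de_lists named list (>= 2) of character gene vectors.
#' @return \code{data.frame} with columns \code{region}, \code{count};
#'   attribute \code{"genes"} holds the per-region gene vectors. Counts
#'   sum to |union|.
#' @export
#' @examples
#' overlap_sets(list(x = c("A", "B"), y = c("B", "C")))
overlap_sets <- function(de_lists) {
  if (length(de_lists) < 2L) stop("need at least 2 lists")
  if (is.null(names(de_lists)) || any(!nzchar(names(de_lists))))
    names(de_lists) <- paste0("set", seq_along(de_lists))
  universe <- unique(unlist(de_lists))
  member <- vapply(de_lists, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(de_lists)))
  sig <- apply(member, 1L, function(r)
    paste(names(de_lists)[r], collapse = "&"))
  k <- length(de_lists)
  combos <- unlist(lapply(seq_len(k), function(i)
    combn(names(de_lists), i, paste, collapse = "&")))
  counts <- vapply(combos, function(cc) sum(sig == cc), integer(1L))
  genes <- lapply(combos, function(cc) universe[sig == cc])
  names(genes) <- combos
  out <- data.frame(region = combos, count = unname(counts),
                    row.names = NULL)
  attr(out, "genes") <- genes
  out
}

#' Hypergeometric over-representation of gene sets
#'
#' For each term: K = term genes in the universe, k = DE genes in the
#' term, n = DE genes, N = universe size; p is the upper-tail
#' hypergeometric P(X >= k). Terms with no overlap with the universe are
#' excluded from testing and from the Bonferroni multiplier, which is
#' the number of terms actually tested. Results are sorted by p.
#'
#' @param de_genes character vector, must be a subset of
#'   \code{universe}.
#' @param universe character vector of all measured genes (non-empty).
#' @param terms list of \code{GeneSet}s.
#' @return \code{data.frame} with columns \code{term}, \code{k},
#'   \code{K}, \code{n}, \code{N}, \code{p_hyper}, \code{p_bonf}.
#' @export
hypergeom_enrichment <- function(de_genes, universe, terms) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("universe is empty")
  de_genes <- unique(as.character(de_genes))
  if (!all(de_genes %in% universe))
    stop("de_genes must be a subset of the universe")
  if (inherits(terms, "GeneSet")) terms <- list(terms)
  N <- length(universe); n <- length(de_genes)
  rows <- lapply(terms, function(tm) {
    tg <- intersect(tm$members, universe)
    K <- length(tg)
    if (K == 0L) return(NULL)
    k <- length(intersect(de_genes, tg))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm$name, k = k, K = K, n = n, N = N, p_hyper = p)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L)
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0),
                      p_hyper = numeric(0), p_bonf = numeric(0)))
  out <- do.call(rbind, rows)
  out$p_bonf <- pmin(1, out$p_hyper * nrow(out))
  out <- out[order(out$p_hyper, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Differential expression for every condition of a treatment dataset
#'
#' Runs \code{\link{gene_tests}} for each non-control condition against
#' the control columns of a condition-labelled expression dataset, then
#' computes the Venn overlap of the significant up and down lists.
#'
#' @param dataset an \code{ExpressionDataset} whose cohort labels are
#'   conditions.
#' @param control label of the control condition (default
#'   \code{"control"}).
#' @param alpha,lfc thresholds passed to \code{\link{gene_tests}}.
#' @return list with \code{tests} (named list of \code{de_result}),
#'   \code{overlap_up} and \code{overlap_down} (Venn-region frames, NULL
#'   with fewer than 2 treatment conditions).
#' @export
de_by_condition <- function(dataset, control = "control", alpha = 0.05,
                            lfc = 1) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  conds <- unique(dataset$cohort)
  if (!control %in% conds) stop("control condition not found: ", control)
  ctrl_cols <- names(dataset$cohort)[dataset$cohort == control]
  ctrl <- dataset$values[, ctrl_cols, drop = FALSE]
  treat_conds <- setdiff(conds, control)
  tests <- lapply(treat_conds, function(cc) {
    cols <- names(dataset$cohort)[dataset$cohort == cc]
    gene_tests(dataset$values[, cols, drop = FALSE], ctrl,
               alpha = alpha, lfc = lfc)
  })
  names(tests) <- treat_conds
  ov_up <- ov_dn <- NULL
  if (length(tests) >= 2L) {
    up <- lapply(tests, function(t.) t.$gene[t.$status == "up"])
    dn <- lapply(tests, function(t.) t.$gene[t.$status == "down"])
    ov_up <- overlap_sets(up)
    ov_dn <- overlap_sets(dn)
  }
  list(tests = tests, overlap_up = ov_up, overlap_down = ov_dn)
}
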