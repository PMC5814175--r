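test_that("gene medians match a naive sort-and-pick oracle", {
  m <- withr::with_seed(5, matrix(rnorm(50 * 20, 8, 2), 50, 20,
         dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:20))))
  m[1, 3] <- NA; m[7, ] <- NA  # one missing cell, one all-missing gene
  ds <- expression_dataset(m)
  med <- gene_medians(ds, "default")
  expect_identical(attr(med, "dropped"), "g07")
  expect_false("g07" %in% names(med))
  oracle <- apply(m[rownames(m) != "g07", ], 1L, naive_median)
  expect_equal(as.numeric(med), as.numeric(oracle), tolerance = 1e-12)
  expect_equal(as.numeric(med["g01"]), as.numeric(naive_median(m[1, ])))
  expect_error(gene_medians(ds, "nope"), "unknown cohort")
})

test_that("set fold change is exact arithmetic and shift-invariant", {
  med <- c(a = 3, b = 4, c = 1, d = 2)
  fc <- set_fold_change(med, gene_set("s", c("a", "b")))
  expect_equal(fc$log2_fc, 2)
  expect_equal(fc$median_set, 3.5)
  expect_equal(fc$median_other, 1.5)
  # identical distributions -> 0
  med2 <- c(a = 1, b = 2, c = 1, d = 2)
  expect_equal(set_fold_change(med2, gene_set("s", c("a", "b")))$log2_fc, 0)
  # invariance to adding a constant to every value
  for (k in c(-3, 0.5, 10)) {
    expect_equal(set_fold_change(med + k, gene_set("s", c("a", "b")))$log2_fc,
                 fc$log2_fc, tolerance = 1e-12)
  }
  expect_error(set_fold_change(med, gene_set("s", "zzz")), "no genes")
  expect_error(set_fold_change(med, gene_set("s", names(med))),
               "background")
})

test_that("rank-sum test: exact small-sample p, ties, and MC agreement", {
  expect_equal(ranksum_test(c(1, 2, 3), c(4, 5, 6)), 0.1, tolerance = 1e-12)
  expect_equal(ranksum_test(c(1, 2), c(1, 2)), 1)  # symmetric groups
  expect_warning(p <- ranksum_test(c(2, 2, 2), c(2, 2)), "tied")
  expect_equal(p, 1)
  # 30 vs 30: normal-approximation p within 3 SE of an MC permutation p
  x <- withr::with_seed(8, rnorm(30)); y <- withr::with_seed(9, rnorm(30, 0.5))
  p_pkg <- ranksum_test(x, y)
  pooled <- c(x, y); n <- length(pooled)
  w_obs <- sum(rank(pooled)[1:30])
  mu <- 30 * (n + 1) / 2
  B <- 2e4
  w_null <- withr::with_seed(1, vapply(seq_len(B), function(i)
    sum(rank(pooled)[sample.int(n, 30)]), numeric(1L)))
  p_mc <- mean(abs(w_null - mu) >= abs(w_obs - mu))
  se <- sqrt(p_mc * (1 - p_mc) / B)
  expect_lt(abs(p_pkg - p_mc), 3 * se + 1e-4)
})

test_that("permutation null: extremes, floor and exhaustive agreement", {
  # all medians equal: every null value is 0, ties count as >=
  pn <- permutation_null(rep(1, 6), 2, observed = 0, M = 100, seed = 1)
  expect_true(all(pn$null_values == 0))
  expect_equal(pn$p_emp, 1)
  # observed above every null value: p at its floor 1/(M+1)
  med <- c(a = 1, b = 1, c = 1, d = 1, e = 1)
  pn2 <- permutation_null(med, 2, observed = 99, M = 500, seed = 2)
  expect_equal(pn2$p_emp, 1 / 501)
  # 4-gene instance: MC p converges to the exhaustive 1/6
  med4 <- c(g1 = 1, g2 = 2, g3 = 3, g4 = 4)
  expect_equal(exhaustive_perm_p(med4, 2, 2.0), 1 / 6, tolerance = 1e-12)
  pn3 <- permutation_null(med4, 2, observed = 2.0, M = 30000, seed = 3)
  se <- sqrt((1 / 6) * (5 / 6) / 30000)
  expect_lt(abs(pn3$p_emp - 1 / 6), 3 * se + 1 / 30001)
  expect_identical(pn3$null_values,
                   permutation_null(med4, 2, 2.0, M = 30000,
                                    seed = 3)$null_values)
})

test_that("MC permutation p matches the exhaustive p on enumerable instances", {
  cases <- list(c(5, 2), c(6, 2), c(6, 3), c(7, 3), c(8, 2), c(8, 4))
  for (case in seq_along(cases)) {
    n_genes <- cases[[case]][1L]; k <- cases[[case]][2L]
    med <- withr::with_seed(100 + case, round(rnorm(n_genes, 8, 2), 2))
    names(med) <- paste0("g", seq_len(n_genes))
    obs <- median(med[1:k]) - median(med[-(1:k)])
    p_ex <- exhaustive_perm_p(med, k, obs)
    M <- 20000
    pn <- permutation_null(med, k, obs, M = M, seed = case)
    # the raw tail fraction is the unbiased MC estimate of p_ex; the
    # reported p_emp adds the conservative +1 in numerator and denominator
    b_over_m <- mean(pn$null_values >= obs)
    expect_equal(pn$p_emp, (b_over_m * M + 1) / (M + 1), tolerance = 1e-12)
    se <- sqrt(p_ex * (1 - p_ex) / M)
    expect_lt(abs(b_over_m - p_ex), 3 * se + 1e-9)
  }
})

test_that("cohort ranking orders by fold change with documented tie-breaks", {
  df <- data.frame(cohort = c("A", "B", "C"),
                   log2_fc = c(1.0, 0.5, 1.5),
                   ranksum_p = c(0.01, 0.2, 0.05))
  r <- pancancer_rank(df)
  expect_identical(r$cohort, c("C", "A", "B"))
  expect_identical(r$rank, 1:3)
  # tied fc: smaller p first
  df2 <- data.frame(cohort = c("A", "B"), log2_fc = c(1, 1),
                    ranksum_p = c(0.2, 0.01))
  expect_identical(pancancer_rank(df2)$cohort, c("B", "A"))
  # tied fc and p: lexicographic cohort
  df3 <- data.frame(cohort = c("B", "A"), log2_fc = c(1, 1),
                    ranksum_p = c(0.1, 0.1))
  expect_identical(pancancer_rank(df3)$cohort, c("A", "B"))
  expect_error(pancancer_rank(data.frame(cohort = c("A", "A"),
                                         log2_fc = c(1, 2))),
               "duplicate")
})

test_that("quantile reference uses type-7 quantiles of per-gene medians", {
  q <- quantile_reference(1:5)
  expect_equal(unlist(q), c(q25 = 2, q50 = 3, q75 = 4))
  expect_equal(unlist(quantile_reference(rep(7, 10))),
               c(q25 = 7, q50 = 7, q75 = 7))
  expect_error(quantile_reference(1:3), "at least 4")
  u <- withr::with_seed(4, runif(1e4))
  qq <- quantile_reference(u)
  expect_lt(max(abs(unlist(qq) - c(0.25, 0.5, 0.75))), 0.02)
})

test_that("matched paired test matches exhaustive sign enumeration", {
  norm <- withr::with_seed(6,
    matrix(rnorm(3 * 10, 8, 1), 3, 10,
           dimnames = list(c("gA", "gB", "gC"), paste0("p", 1:10))))
  tum <- norm; tum["gA", ] <- norm["gA", ] + 1     # uniform +1 shift
  tum["gB", ] <- norm["gB", ]                      # no change
  tum["gC", ] <- norm["gC", ] + withr::with_seed(7, rnorm(10, 0, 0.5))
  res <- matched_paired_test(tum, norm)
  expect_equal(res$p[res$gene == "gA"],
               exhaustive_signrank_p(rep(1, 10)), tolerance = 1e-12)
  expect_equal(res$p[res$gene == "gA"], 2 / 2^10, tolerance = 1e-12)
  expect_equal(res$direction[res$gene == "gA"], 1)
  expect_equal(res$p[res$gene == "gB"], 1)
  expect_equal(res$direction[res$gene == "gB"], 0)
  d <- tum["gC", ] - norm["gC", ]
  expect_equal(res$p[res$gene == "gC"], exhaustive_signrank_p(d),
               tolerance = 1e-9)
  # antisymmetric flip leaves p unchanged
  flip_tum <- norm; flip_tum["gC", ] <- norm["gC", ] - d
  res_flip <- matched_paired_test(flip_tum, norm)
  expect_equal(res_flip$p[res_flip$gene == "gC"],
               res$p[res$gene == "gC"], tolerance = 1e-9)
  expect_equal(res_flip$direction[res_flip$gene == "gC"],
               -res$direction[res$gene == "gC"])
})

test_that("dereg_test recovers injected effect order across cohorts", {
  deltas <- c(0.2, 0.7, 1.4)
  sim <- simulate_pancancer(n_cohorts = 3, genes_per_matrix = 600,
                            samples_per_cohort = 25, set_size = 60,
                            delta = deltas, seed = 21)
  res <- dereg_test(sim$dataset, sim$geneset, n_perm = 300, seed = 21)
  expect_setequal(res$rank, 1:3)
  expect_identical(res$cohort, c("cohort03", "cohort02", "cohort01"))
  expect_equal(res$log2_fc, sort(deltas, decreasing = TRUE),
               tolerance = 0.25)
  expect_true(all(res$perm_p >= 1 / 301 & res$perm_p <= 1))
  expect_true(all(res$log2_fc == res$median_set - res$median_other))
  # pooled reading gives comparable estimates on this clean design
  res_pooled <- dereg_test(sim$dataset, sim$geneset, n_perm = 100,
                           seed = 21, pooled = TRUE)
  expect_equal(res_pooled$log2_fc, res$log2_fc, tolerance = 0.3)
})
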