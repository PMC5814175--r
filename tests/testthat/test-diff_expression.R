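test_that("gene-wise Welch tests match stats::t.test and handle degeneracy", {
  m <- withr::with_seed(14, matrix(rnorm(20 * 6, 8, 1), 20, 6,
         dimnames = list(sprintf("g%02d", 1:20), paste0("r", 1:6))))
  trt <- m[, 1:3]; ctl <- m[, 4:6]
  res <- gene_tests(trt, ctl)
  for (i in c(1, 7, 20)) {
    tt <- t.test(trt[i, ], ctl[i, ], var.equal = TRUE)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-9)
    expect_equal(res$log2_fc[i],
                 unname(tt$estimate[1L] - tt$estimate[2L]),
                 tolerance = 1e-9)
  }
  # treated == control replicate-wise: all fc 0, nothing significant
  null <- gene_tests(trt, trt)
  expect_true(all(null$log2_fc == 0))
  expect_true(all(null$status == "ns"))
  # zero-variance gene with unequal means: floored, finite statistics
  trt2 <- trt; ctl2 <- ctl
  trt2[3, ] <- 2; ctl2[3, ] <- 5
  res2 <- gene_tests(trt2, ctl2)
  expect_equal(res2$log2_fc[3], -3)
  expect_true(res2$floored[3])
  expect_true(is.finite(res2$t_stat[3]) && is.finite(res2$p[3]))
  expect_error(gene_tests(trt[, 1, drop = FALSE], ctl), "2 replicates")
})

test_that("BH adjustment is the hand step-up, order-invariant", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03),
               tolerance = 1e-12)
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  p <- withr::with_seed(15, runif(40))
  perm <- withr::with_seed(16, sample.int(40))
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]), tolerance = 1e-12)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("Venn regions partition the union and match brute force", {
  ov <- overlap_sets(list(one = c("A", "B"), two = c("B", "C")))
  got <- setNames(ov$count, ov$region)
  expect_equal(got[["one"]], 1)
  expect_equal(got[["two"]], 1)
  expect_equal(got[["one&two"]], 1)
  # identical lists: everything in the full intersection
  same <- overlap_sets(list(x = c("A", "B"), y = c("A", "B")))
  expect_equal(setNames(same$count, same$region)[["x&y"]], 2)
  expect_equal(sum(same$count), 2)
  # 3 random lists vs a brute-force membership-tuple tally
  pool <- sprintf("g%04d", 1:1000)
  lists <- withr::with_seed(17, list(a = sample(pool, 100),
                                     b = sample(pool, 100),
                                     c = sample(pool, 100)))
  ov3 <- overlap_sets(lists)
  uni <- unique(unlist(lists))
  tup <- table(apply(vapply(lists, function(s) uni %in% s,
                            logical(length(uni))), 1L, paste,
                     collapse = ""))
  brute <- integer(0)
  for (reg in ov3$region) {
    key <- paste(ifelse(names(lists) %in% strsplit(reg, "&")[[1L]],
                        "TRUE", "FALSE"), collapse = "")
    brute <- c(brute, if (key %in% names(tup)) unname(tup[[key]]) else 0L)
  }
  expect_equal(ov3$count, brute)
  expect_equal(sum(ov3$count), length(uni))
})

test_that("hypergeometric upper tail equals exhaustive enumeration (N <= 12)", {
  # the canonical worked case: N=10, K=4, n=5, k=3 -> 66/252
  e <- hypergeom_enrichment(paste0("g", 1:5), paste0("g", 1:10),
                            list(gene_set("t", paste0("g", c(1:3, 7)))))
  expect_equal(e$p_hyper, 66 / 252, tolerance = 1e-12)
  expect_equal(e$k, 3); expect_equal(e$K, 4)
  # sweep every configuration with N <= 12
  for (N in c(5, 8, 12)) for (K in c(1, 3, N - 1)) for (n in c(2, N %/% 2)) {
    for (k in 0:min(K, n)) {
      expect_equal(phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                   exhaustive_hyper_p(N, K, n, k), tolerance = 1e-10,
                   label = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
    }
  }
  # k = 0 gives upper-tail p of 1
  e0 <- hypergeom_enrichment(paste0("g", 4:5), paste0("g", 1:10),
                             list(gene_set("t", paste0("g", 1:2))))
  expect_equal(e0$p_hyper, 1, tolerance = 1e-12)
})

test_that("terms disjoint from the universe are excluded from the multiplier", {
  uni <- paste0("g", 1:20)
  de <- paste0("g", 1:5)
  terms <- list(gene_set("hit", paste0("g", 1:4)),
                gene_set("cold", paste0("g", 10:14)),
                gene_set("alien", paste0("x", 1:5)))
  e <- hypergeom_enrichment(de, uni, terms)
  expect_equal(nrow(e), 2L)
  expect_false("alien" %in% e$term)
  expect_equal(e$p_bonf, pmin(1, e$p_hyper * 2), tolerance = 1e-12)
  expect_true(all(e$p_bonf >= e$p_hyper))
  expect_error(hypergeom_enrichment("g99", uni, terms), "subset")
  expect_error(hypergeom_enrichment(de, character(0), terms), "empty")
})

test_that("global null keeps the discovery fraction near zero", {
  hits <- vapply(1:20, function(s) {
    sim <- simulate_treatment_microarray(n_genes = 300,
                                         shifts = c(0, 0, 0, 0),
                                         noise_sd = 0.25, seed = s)
    de <- de_by_condition(sim$dataset)
    mean(vapply(de$tests, function(t.) sum(t.$status != "ns"),
                numeric(1L)))
  }, numeric(1L))
  expect_lt(mean(hits) / 300, 0.01)
})
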