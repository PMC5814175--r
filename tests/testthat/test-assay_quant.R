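test_that("noiseless 4PL fits recover the generating parameters", {
  d <- c(2.5, 5, 10, 20, 40, 80, 160)
  truth <- c(bottom = 0, top = 100, hill = 1.5, ec50 = 39)
  r <- four_pl_ref(d, truth)
  fit <- fit_4pl(d, r)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)["top"]), 100, tolerance = 1e-4)
  expect_equal(unname(coef(fit)["hill"]), 1.5, tolerance = 1e-4)
  expect_equal(unname(coef(fit)["ec50"]), 39, tolerance = 39 * 1e-4)
  expect_lt(abs(coef(fit)["bottom"]), 1e-3)
  # symmetric curve: IC50 equals ec50 exactly, ICs monotone in level
  expect_equal(unname(fit$ic_values["IC50"]), unname(coef(fit)["ec50"]),
               tolerance = 1e-6)
  expect_true(all(diff(fit$ic_values[c("IC20", "IC25", "IC50", "IC75")]) > 0))
  # residual/predict accessors are coherent
  expect_equal(fitted(fit) + residuals(fit), r, tolerance = 1e-9)
})

test_that("flat responses are flagged as non-converged, without IC values", {
  fit <- fit_4pl(c(1, 2, 4, 8, 16), rep(100, 5))
  expect_false(fit$converged)
  expect_true(all(is.na(fit$ic_values)))
  expect_error(predict(fit, 10), "non-converged")
  expect_error(fit_4pl(c(-1, 2, 4, 8, 16), 1:5), "positive")
  expect_error(fit_4pl(c(1, 1, 1, 2, 3), 1:5), "5 distinct")
})

test_that("inhibitory concentrations agree with the closed form", {
  cases <- list(c(0, 100, 1.2, 10), c(5, 95, 2.5, 50), c(0, 100, 0.8, 30))
  for (cs in cases) {
    names(cs) <- c("bottom", "top", "hill", "ec50")
    d <- exp(seq(log(cs["ec50"] / 10), log(cs["ec50"] * 10),
                 length.out = 9))
    fit <- fit_4pl(d, four_pl_ref(d, cs))
    for (lv in c(25, 50, 70)) {
      target <- 100 - lv
      closed <- cs[["ec50"]] *
        ((cs[["top"]] - cs[["bottom"]]) / (target - cs[["bottom"]]) - 1) ^
        (1 / cs[["hill"]])
      expect_equal(inhibitory_concentration(fit, lv), unname(closed),
                   tolerance = 1e-4)
    }
  }
  # unattainable level names the attainable range
  d <- c(2.5, 5, 10, 20, 40, 80, 160)
  fit <- fit_4pl(d, four_pl_ref(d, c(bottom = 60, top = 100, hill = 1.5,
                                     ec50 = 39)))
  expect_error(inhibitory_concentration(fit, 75), "attainable")
  # relative definition targets the asymptote midpoint at level 50
  expect_equal(inhibitory_concentration(fit, 50, relative = TRUE),
               unname(coef(fit)["ec50"]), tolerance = 1e-3)
})

test_that("bootstrap intervals are seed-deterministic and shrink without noise", {
  d <- rep(c(2.5, 5, 10, 20, 40, 80, 160), each = 2)
  r <- four_pl_ref(d, c(bottom = 0, top = 100, hill = 1.5, ec50 = 39))
  b1 <- bootstrap_ci(d, r, B = 200, seed = 4)
  b2 <- bootstrap_ci(d, r, B = 200, seed = 4)
  expect_identical(b1$ci, b2$ci)
  expect_true(b1$reliable)
  expect_lt(b1$ci["ec50", "upper"] - b1$ci["ec50", "lower"], 1e-4)
  expect_error(bootstrap_ci(d, r, B = 100), "200")
})

test_that("ddCt arithmetic is exact and shift-invariant", {
  ctl <- data.frame(ct_target = 25, ct_reference = 20)
  trt <- data.frame(ct_target = 27, ct_reference = 20)
  res <- ddct_fold_change(ctl, trt)
  expect_equal(res$ddct, 2)
  expect_equal(res$fold, 0.25)
  # treated dCT equal to control dCT: fold 1
  expect_equal(ddct_fold_change(ctl, ctl)$fold, 1)
  # invariance to adding a constant to both target and reference CTs
  shift <- function(df, k) data.frame(ct_target = df$ct_target + k,
                                      ct_reference = df$ct_reference + k)
  expect_equal(ddct_fold_change(shift(ctl, 3), shift(trt, 3))$fold,
               res$fold, tolerance = 1e-12)
  expect_error(ddct_fold_change(data.frame(ct_target = 25,
                                           ct_reference = 20, gene = "A"),
                                data.frame(ct_target = 27,
                                           ct_reference = 20, gene = "B")),
               "same single gene")
})

test_that("densitometry ratio is a double ratio, scale-invariant", {
  expect_equal(densitometry_ratio(10, 5, 10, 5), 1)
  expect_equal(densitometry_ratio(5, 5, 10, 5), 0.5)
  base <- densitometry_ratio(7, 3, 9, 4)
  for (c. in withr::with_seed(18, runif(5, 0.1, 50)))
    expect_equal(densitometry_ratio(7 * c., 3 * c., 9 * c., 4 * c.),
                 base, tolerance = 1e-12)
  expect_error(densitometry_ratio(0, 1, 1, 1), "positive")
})

test_that("colony percentages and the Student t behave as documented", {
  same <- colony_percentage(c(50, 52, 48), c(50, 52, 48))
  expect_equal(same$percent, 100)
  expect_equal(same$p, 1, tolerance = 1e-9)
  forty <- colony_percentage(c(40, 40, 40), c(100, 100, 100))
  expect_equal(forty$percent, 40)
  expect_error(colony_percentage(c(1, 2, 3), c(0, 0, 0)), "zero")
  # Student t vs exhaustive label permutation on 5 vs 5 wells
  a <- c(31, 45, 38, 41, 35); b <- c(52, 47, 58, 44, 56)
  p_t <- group_ttest(a, b)$p
  pool <- c(a, b)
  obs <- abs(mean(a) - mean(b))
  combos <- combn(10, 5)
  diffs <- apply(combos, 2L, function(idx)
    abs(mean(pool[idx]) - mean(pool[-idx])))
  p_perm <- mean(diffs >= obs - 1e-12)
  expect_lt(abs(p_t - p_perm), 0.1)
})

test_that("two-group Student t-test reports means, SDs, degenerate cases", {
  same <- group_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1, tolerance = 1e-12)
  shifted <- group_ttest(c(1, 2, 3), c(1, 2, 3) + 10)
  expect_lt(shifted$p, 0.01)
  expect_equal(shifted$mean_diff, -10)
  # the observed split is the most extreme of all label assignments
  pool <- c(1, 2, 3, 11, 12, 13)
  diffs <- apply(combn(6, 3), 2L, function(idx)
    abs(mean(pool[idx]) - mean(pool[-idx])))
  expect_equal(sum(diffs >= 10 - 1e-12), 2)  # the split and its mirror
  # shift invariance
  expect_equal(group_ttest(c(1, 2, 3) + 7, c(1, 2, 3) + 17)$p,
               shifted$p, tolerance = 1e-12)
  # zero pooled variance
  expect_equal(group_ttest(c(2, 2), c(2, 2))$p, 1)
  expect_equal(group_ttest(c(2, 2), c(5, 5))$p, 0)
})

test_that("phase fractions validate and fold changes mirror reports", {
  trt <- phase_fractions(30, 18, 52)
  ctl <- phase_fractions(60, 26, 14)
  fold <- phase_fold_change(trt, ctl, "g2m")
  expect_equal(round(fold, 1), 3.7)
  expect_equal(phase_fold_change(trt, trt, "g2m"), 1)
  expect_equal(phase_fold_change(ctl, trt, "g2m"), 1 / fold,
               tolerance = 1e-12)
  expect_error(phase_fractions(80, 50, 40), "95-105")
  expect_error(phase_fractions(-1, 50, 48), "0, 100")
  expect_error(phase_fold_change(trt, phase_fractions(70, 30, 0), "g2m"),
               "zero")
})

test_that("tumor metrics apply the caliper formula with reordering", {
  tm <- tumor_metrics(4, 2)
  expect_equal(tm$volume, 8)
  expect_equal(tm$area, 8)
  expect_equal(tumor_metrics(2, 2)$volume, 4)
  sw <- tumor_metrics(2, 4)
  expect_equal(sw$volume, tm$volume)
  expect_equal(sw$a, 4)
  expect_equal(tumor_metrics(4, 2, ellipse = TRUE)$area, pi / 4 * 8)
  expect_error(tumor_metrics(0, 1), "positive")
})
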