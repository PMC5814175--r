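# Independent oracles used across tests. These deliberately re-derive
# quantities by brute force (enumeration or naive arithmetic) and never
# call the package code paths they check.

# Exhaustive permutation p for the set-vs-rest median fold change:
# enumerate every size-k relabeling, tail counted with >= (ties against
# significance), add-one estimator over the full enumeration.
exhaustive_perm_p <- function(medians, set_size, observed) {
  combos <- combn(length(medians), set_size)
  nulls <- apply(combos, 2L, function(idx)
    median(medians[idx]) - median(medians[-idx]))
  sum(nulls >= observed) / ncol(combos)
}

# Exhaustive two-sided signed-rank p: enumerate all 2^n sign
# assignments of the ranked absolute differences.
exhaustive_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_null <- as.matrix(signs) %*% r
  p_ge <- mean(v_null >= v_obs)
  p_le <- mean(v_null <= v_obs)
  min(1, 2 * min(p_ge, p_le))
}

# Exhaustive upper-tail hypergeometric P(X >= k): enumerate all
# C(N, n) draws of n from a universe with K marked elements.
exhaustive_hyper_p <- function(N, K, n, k) {
  draws <- combn(N, n)
  marked <- seq_len(K)
  hits <- apply(draws, 2L, function(cc) sum(cc %in% marked))
  mean(hits >= k)
}

# Naive sort-and-pick median (independent of stats::median).
naive_median <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0L) return(NA_real_)
  if (n %% 2L == 1L) x[(n + 1L) / 2L] else (x[n / 2L] + x[n / 2L + 1L]) / 2
}

# Hand log-rank computation from the hypergeometric moments at each
# distinct event time (group A observed vs expected).
hand_logrank_chi2 <- function(timeA, eventA, timeB, eventB) {
  times <- sort(unique(c(timeA[eventA == 1], timeB[eventB == 1])))
  o_minus_e <- 0; v <- 0
  for (t in times) {
    nA <- sum(timeA >= t); nB <- sum(timeB >= t); n <- nA + nB
    dA <- sum(timeA == t & eventA == 1)
    dB <- sum(timeB == t & eventB == 1)
    d <- dA + dB
    e <- d * nA / n
    o_minus_e <- o_minus_e + (dA - e)
    if (n > 1)
      v <- v + d * (nA / n) * (nB / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Reference 4PL evaluation, written out independently of the package.
four_pl_ref <- function(dose, p) {
  p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
    (1 + (dose / p[["ec50"]])^p[["hill"]])
}

tmpfile <- function(ext = ".tsv") tempfile(fileext = ext)
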