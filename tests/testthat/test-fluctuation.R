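# Luria-Delbruck machinery: clone-size law under plating, compound-Poisson
# count pmf, MLE, profile intervals, rate conversion.

test_that("clone_pmf matches closed forms", {
  # epsilon = 1: q_k = 1/(k(k+1)), q_0 = 0
  q <- clone_pmf(1, 5)$q
  expect_equal(q, c(0, 1/2, 1/6, 1/12, 1/20, 1/30))
  # epsilon = 0.5: q_0 = 1 + ln(1/2) = 0.30685
  expect_equal(clone_pmf(0.5, 0)$q[1], 1 + log(0.5), tolerance = 1e-12)
  # q_0 = sum_j (1-eps)^j / (j(j+1)) for any eps (series evaluated directly)
  for (eps in c(0.1, 0.25, 0.49, 0.6, 0.9)) {
    j <- 1:20000
    q0_direct <- sum((1 - eps)^j / (j * (j + 1)))
    expect_equal(clone_pmf(eps, 0)$q[1], q0_direct, tolerance = 1e-10)
  }
})

test_that("clone_pmf recurrence agrees with direct binomial-thinning sums", {
  for (eps in c(0.025, 0.1, 0.3, 0.7)) {
    q <- clone_pmf(eps, 12)$q
    q_direct <- vapply(0:12, function(k) {
      j <- max(k, 1):50000
      sum(stats::dbinom(k, j, eps) / (j * (j + 1)))
    }, numeric(1))
    expect_equal(q, q_direct, tolerance = 1e-9)
  }
})

test_that("clone_pmf matches Monte-Carlo clone thinning (chi-square)", {
  set.seed(42)
  n <- 2e5
  eps <- 0.4
  j <- floor(1 / runif(n))
  obs <- rbinom(n, j, eps)
  kmax <- 8
  q <- clone_pmf(eps, kmax)$q
  tab <- tabulate(pmin(obs, kmax + 1) + 1, nbins = kmax + 2)
  p_theory <- c(q, 1 - sum(q))
  chi <- suppressWarnings(chisq.test(tab, p = p_theory))
  expect_gt(chi$p.value, 0.01)
})

test_that("clone_pmf probabilities are a valid sub-distribution", {
  for (eps in c(0.025, 0.5, 1)) {
    q <- clone_pmf(eps, 200)$q
    expect_true(all(q >= 0))
    expect_lte(sum(q), 1 + 1e-12)
  }
  expect_error(clone_pmf(0, 5), "epsilon")
  expect_error(clone_pmf(1.2, 5), "epsilon")
})

test_that("count_pmf reproduces hand-evaluated recursion values", {
  p <- count_pmf(1, 1, 2)
  expect_equal(p[1], exp(-1), tolerance = 1e-12)
  expect_equal(p[2], exp(-1) / 2, tolerance = 1e-12)
  expect_equal(p[3], 0.5 * (p[1] / 3 + p[2] / 2), tolerance = 1e-12)
})

test_that("count_pmf at epsilon 1 equals the classic recursion", {
  m <- 1.7; nmax <- 60
  p_classic <- numeric(nmax + 1)
  p_classic[1] <- exp(-m)
  for (n in 1:nmax) {
    i <- 0:(n - 1)
    p_classic[n + 1] <- (m / n) * sum(p_classic[i + 1] / (n - i + 1))
  }
  expect_equal(count_pmf(m, 1, nmax), p_classic, tolerance = 1e-12)
})

test_that("count_pmf is a sub-distribution and m = 0 is degenerate", {
  p <- count_pmf(2.5, 0.3, 400)
  expect_true(all(p >= 0))
  expect_lte(sum(p), 1 + 1e-12)
  p0 <- count_pmf(0, 0.5, 5)
  expect_equal(p0, c(1, rep(0, 5)))
  expect_error(count_pmf(-1, 1, 5), "m")
})

test_that("count_pmf matches simulate_fluctuation empirically (chi-square)", {
  cfg <- fluctuation_sim_config(mu = 1.2 / (1e8 - 730), N0 = 730, Nt = 1e8,
                                epsilon = 1, n_cultures = 1e5, seed = 99)
  counts <- simulate_fluctuation(cfg)
  kmax <- 10
  p_theory <- count_pmf(attr(counts, "m"), 1, kmax)
  tab <- tabulate(pmin(counts, kmax + 1) + 1, nbins = kmax + 2)
  chi <- suppressWarnings(
    chisq.test(tab, p = c(p_theory, 1 - sum(p_theory))))
  expect_gt(chi$p.value, 0.01)
})

test_that("mle_m solves analytic cases", {
  # all-zero counts: boundary at 0
  expect_equal(mle_m(rep(0, 6), 1)$m, 0)
  # {0,0,0,1}: logL = -4m + ln m - ln 2, stationary at m = 1/4
  expect_equal(mle_m(c(0, 0, 0, 1), 1)$m, 0.25, tolerance = 1e-7)
})

test_that("mle_m equals a dense grid-search oracle", {
  datasets <- list(
    list(counts = c(0, 1, 0, 3, 12, 0, 2, 0, 0, 5), eps = 0.25),
    list(counts = c(0, 0, 1, 1, 2, 7), eps = 1),
    list(counts = c(3, 0, 0, 0, 25, 1, 0, 2), eps = 0.1)
  )
  for (d in datasets) {
    fit <- mle_m(d$counts, d$eps)
    grid <- seq(1e-3, 12, by = 1e-4)
    nmax <- max(d$counts)
    ll <- vapply(grid, function(m) {
      sum(log(count_pmf(m, d$eps, nmax)[d$counts + 1]))
    }, numeric(1))
    expect_lt(abs(fit$m - grid[which.max(ll)]), 1e-3)
    expect_true(fit$converged)
  }
})

test_that("profile_ci has the closed-form upper bound for all-zero counts", {
  # logL = -C m at eps 1; 2 C m* = qchisq(.95, 1) => m* = 1.92073/C
  for (C in c(5, 10)) {
    fit <- profile_ci(mle_m(rep(0, C), 1))
    expect_equal(fit$ci[["lower"]], 0)
    expect_equal(fit$ci[["upper"]], qchisq(0.95, 1) / (2 * C),
                 tolerance = 1e-5)
  }
})

test_that("profile_ci brackets the MLE", {
  fit <- profile_ci(mle_m(c(0, 2, 0, 1, 9, 0, 0, 3, 1, 0), 0.5))
  expect_lte(fit$ci[["lower"]], fit$m)
  expect_gte(fit$ci[["upper"]], fit$m)
  expect_gt(fit$ci[["upper"]], fit$ci[["lower"]])
})

test_that("mutation_rate converts m to per-division and per-kb rates", {
  fit <- structure(list(m = 0.25, ci = NULL), class = "fluctuation_fit")
  r <- mutation_rate(fit, list(N0 = 1e-9, Nt = 1e7, gene_length = 1000))
  expect_equal(r$mu_per_kb, 2.5e-8, tolerance = 1e-6)
  # halving gene length doubles the per-kb rate
  r2 <- mutation_rate(fit, list(N0 = 1e-9, Nt = 1e7, gene_length = 500))
  expect_equal(r2$mu_per_kb, 2 * r$mu_per_kb)
  # zero m gives zero rate
  fit0 <- structure(list(m = 0, ci = NULL), class = "fluctuation_fit")
  expect_equal(mutation_rate(fit0, list(N0 = 1, Nt = 1e7,
                                        gene_length = 1000))$mu, 0)
  # nt divisor convention
  rn <- mutation_rate(fit, list(N0 = 5e6, Nt = 1e7, gene_length = 1000),
                      divisor = "nt")
  expect_equal(rn$mu, 0.25 / 1e7)
})

test_that("rate_ratio handles identity, recovery and zero denominators", {
  cfgA <- fluctuation_sim_config(mu = 5e-8, Nt = 1e8, epsilon = 0.5,
                                 n_cultures = 200, seed = 3)
  cfgB <- fluctuation_sim_config(mu = 1e-8, Nt = 1e8, epsilon = 0.5,
                                 n_cultures = 200, seed = 4)
  fa <- profile_ci(mle_m(simulate_fluctuation(cfgA), 0.5))
  fb <- profile_ci(mle_m(simulate_fluctuation(cfgB), 0.5))
  des <- list(N0 = 730, Nt = 1e8, gene_length = 1000)
  expect_equal(rate_ratio(fa, fa, des, des)$ratio, 1)
  rr <- rate_ratio(fa, fb, des, des)
  expect_gt(rr$ratio, 3); expect_lt(rr$ratio, 8)
  # zero-rate denominator yields the Inf sentinel, not an error
  f0 <- profile_ci(mle_m(rep(0, 10), 0.5))
  expect_equal(rate_ratio(fa, f0, des, des)$ratio, Inf)
})

test_that("censoring cap keeps jackpot datasets tractable and stable", {
  counts <- c(0, 1, 0, 2, 150000, 1, 0, 0, 3, 1)
  fit <- mle_m(counts, 0.25, cap = 500)
  expect_true(fit$converged)
  # the capped fit should be close to a fit with a larger cap
  fit2 <- mle_m(counts, 0.25, cap = 2000)
  expect_equal(fit$m, fit2$m, tolerance = 0.05)
})
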