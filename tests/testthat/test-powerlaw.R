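# Reference values of zeta(alpha) = hurwitz_zeta(alpha, 1), 16 significant
# digits (standard constants).
RIEMANN_ZETA <- c(`1.5` = 2.612375348685488, `2` = 1.644934066848226,
                  `2.5` = 1.341487257250917, `3` = 1.202056903159594,
                  `4` = 1.082323233711138)

test_that("hurwitz zeta matches reference constants and the summation oracle", {
  expect_equal(hurwitz_zeta(2, 1), pi^2 / 6, tolerance = 1e-12)
  for (a in names(RIEMANN_ZETA)) {
    expect_equal(hurwitz_zeta(as.numeric(a), 1), unname(RIEMANN_ZETA[a]),
                 tolerance = 1e-12)
    expect_equal(hurwitz_zeta(as.numeric(a), 1),
                 oracle_zeta(as.numeric(a)), tolerance = 1e-8)
  }
  # generic kmin against the same oracle
  expect_equal(hurwitz_zeta(2.2, 5), oracle_zeta(2.2, kmin = 5),
               tolerance = 1e-8)
  expect_error(hurwitz_zeta(1, 1), class = "grnsparse_divergence")
  expect_error(hurwitz_zeta(0.7, 1), class = "grnsparse_divergence")
})

test_that("power-law pmf is normalised and sampling respects the support", {
  p <- dpowerlaw(1:10000, 2.5)
  expect_lt(abs(sum(p) - 1), 1e-4)   # truncation tail only
  set.seed(1)
  x <- rpowerlaw(5000, 2.5)
  expect_true(all(x >= 1))
  expect_equal(mean(x == 1), dpowerlaw(1, 2.5), tolerance = 0.05)
})

test_that("exponent estimator reproduces its closed forms", {
  ones <- degree_distribution_from_degrees(rep(1L, 7))
  expect_equal(fit_alpha_ml(ones)$alpha, 1 + 1 / log(2), tolerance = 1e-12)

  dd <- degree_distribution_from_degrees(c(1, 1, 2, 3, 5))
  hand <- 1 + 5 / (2 * log(2) + log(4) + log(6) + log(10))
  expect_equal(fit_alpha_ml(dd)$alpha, hand, tolerance = 1e-12)
  expect_equal(fit_alpha_ml(dd)$zeta_value,
               oracle_zeta(hand), tolerance = 1e-8)
})

test_that("exponent fit is undefined when some gene has no out-link", {
  # a zero out-degree contributes ln(0): the estimate degenerates to 1 where
  # the zeta normalisation diverges
  with_zero <- degree_distribution_from_degrees(c(0, 1, 2, 4))
  expect_error(fit_alpha_ml(with_zero), class = "grnsparse_undefined_fit")
  expect_false(gof_metric(with_zero)$defined)
  empty <- degree_distribution_from_degrees(rep(0L, 5))
  expect_error(fit_alpha_ml(empty), class = "grnsparse_undefined_fit")
  expect_false(gof_metric(empty)$defined)
})

test_that("exponent fit depends only on the degree sequence", {
  # full-support network: every gene keeps at least one out-link
  set.seed(5)
  m <- matrix(rnorm(625) * rbinom(625, 1, 0.15), 25, 25)
  diag(m) <- 0
  for (i in 1:25) if (all(m[i, -i] == 0)) m[i, (i %% 25) + 1] <- 1
  f1 <- fit_alpha_ml(grn(m))
  f2 <- fit_alpha_ml(grn(m * -7.3))
  expect_equal(f1$alpha, f2$alpha, tolerance = 1e-15)
})

test_that("Q matches a brute-force two-loop implementation on random tables", {
  for (seed in 1:20) {
    degrees <- random_degree_table(seed)
    got <- gof_metric(degree_distribution_from_degrees(degrees))
    expect_true(got$defined)
    expect_equal(got$q, oracle_q(degrees), tolerance = 1e-10)
  }
})

test_that("Q is invariant under permutation of gene order", {
  degrees <- random_degree_table(99)
  q1 <- gof_metric(degree_distribution_from_degrees(degrees))$q
  set.seed(1)
  q2 <- gof_metric(degree_distribution_from_degrees(sample(degrees)))$q
  expect_equal(q1, q2, tolerance = 1e-12)
})

test_that("Q separates power-law from geometric degree sequences", {
  # degree tables drawn from the assumed model score systematically smaller
  # Q than equally sized geometric-tailed controls
  q_pl <- q_geo <- numeric(30)
  for (s in 1:30) {
    set.seed(s)
    pl <- pmin(rpowerlaw(300, 2.3), 300L)
    geo <- pmin(1L + stats::rgeom(300, 1 / 3), 300L)
    q_pl[s] <- gof_metric(degree_distribution_from_degrees(pl))$q
    q_geo[s] <- gof_metric(degree_distribution_from_degrees(geo))$q
  }
  expect_lt(median(q_pl), median(q_geo))
})

test_that("log-log correlation and p-value match the textbook computation", {
  # exactly log-linear table: x_d = 64 d^-2 over d in {1,2,4,8}
  loglinear <- degree_distribution_from_table(
    c(`1` = 64, `2` = 16, `4` = 4, `8` = 1))
  res <- loglin_metric(loglinear)
  expect_true(res$defined)
  expect_equal(res$r, -1)
  expect_equal(res$p_value, 0)

  # fixed frequency table against the oracle
  fixed <- rep(c(1L, 2L, 3L, 5L, 9L), c(30, 10, 8, 2, 1))
  got <- loglin_metric(degree_distribution_from_degrees(fixed))
  want <- oracle_loglin(fixed)
  expect_equal(got$r, want$r, tolerance = 1e-10)
  expect_equal(got$p_value, want$p, tolerance = 1e-10)

  # random tables
  for (seed in 21:40) {
    degrees <- random_degree_table(seed)
    got <- loglin_metric(degree_distribution_from_degrees(degrees))
    if (!got$defined) next
    want <- oracle_loglin(degrees)
    expect_equal(got$r, want$r, tolerance = 1e-10)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
  }
})

test_that("correlation metric is undefined below 3 support points", {
  two <- degree_distribution_from_table(c(`1` = 5, `2` = 3))
  expect_false(loglin_metric(two)$defined)
  flat <- degree_distribution_from_table(c(`1` = 4, `2` = 4, `3` = 4))
  expect_false(loglin_metric(flat)$defined)  # constant log-frequencies
})

test_that("r stays in [-1, 1] and hits -1 exactly on any pure power table", {
  for (gamma in c(0.5, 1, 2.7)) {
    d <- c(1, 2, 3, 5, 8)
    counts <- round(1000 * d^(-gamma))
    names(counts) <- d
    res <- loglin_metric(degree_distribution_from_table(counts))
    expect_gte(res$r, -1)
    # rounding keeps these tables only near-exact; sanity-check the trend
    expect_lt(res$r, -0.99)
  }
  exact <- degree_distribution_from_table(c(`1` = 81, `3` = 9, `9` = 1))
  expect_equal(loglin_metric(exact)$r, -1)
})

test_that("scale-freeness R^2 equals r^2 and matches an OLS oracle", {
  loglinear <- degree_distribution_from_table(
    c(`1` = 64, `2` = 16, `4` = 4, `8` = 1))
  expect_equal(scale_freeness_r2(loglinear), 1.0, tolerance = 1e-12)

  fixed <- rep(c(1L, 2L, 3L, 5L, 9L), c(30, 10, 8, 2, 1))
  dd <- degree_distribution_from_degrees(fixed)
  expect_equal(scale_freeness_r2(dd), oracle_r2(fixed), tolerance = 1e-10)
  expect_equal(scale_freeness_r2(dd), loglin_metric(dd)$r^2,
               tolerance = 1e-12)

  for (seed in 41:50) {
    degrees <- random_degree_table(seed)
    dd <- degree_distribution_from_degrees(degrees)
    if (!loglin_metric(dd)$defined) next
    expect_equal(scale_freeness_r2(dd), loglin_metric(dd)$r^2,
                 tolerance = 1e-12)
  }
  expect_error(scale_freeness_r2(degree_distribution_from_table(c(`1` = 3))),
               class = "grnsparse_undefined_metric")
})
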