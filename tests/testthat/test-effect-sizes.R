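test_that("Hedges' g matches the closed formulas", {
  # identical arms: zero effect, variance (nx+ny)/(nx ny)
  a <- list(n = 50, mean = 1.3, sd = 0.8)
  g0 <- hedges_g(a, a)
  expect_equal(g0$effect, 0)
  expect_equal(g0$variance, 100 / 2500)

  # hand-computed: d = -0.5, J = 1 - 3/791
  g <- hedges_g(list(n = 100, mean = 1, sd = 2),
                list(n = 100, mean = 2, sd = 2))
  expect_equal(g$effect, (1 - 3 / 791) * -0.5, tolerance = 1e-12)
  expect_equal(g$effect, -0.49810367, tolerance = 1e-7)
  expect_equal(g$variance, 200 / 1e4 + g$effect^2 / 400, tolerance = 1e-12)
  expect_equal(g$variance, 0.02062027, tolerance = 1e-6)
})

test_that("Hedges' g properties: antisymmetry, shrinkage, monotone variance", {
  set.seed(42)
  for (i in 1:25) {
    ax <- list(n = sample(20:300, 1), mean = rnorm(1), sd = runif(1, .5, 3))
    ay <- list(n = sample(20:300, 1), mean = rnorm(1), sd = runif(1, .5, 3))
    gxy <- hedges_g(ax, ay); gyx <- hedges_g(ay, ax)
    expect_equal(gxy$effect, -gyx$effect)
    expect_equal(gxy$variance, gyx$variance)
    # |g| <= |d| since J < 1
    sp <- sqrt(((ax$n - 1) * ax$sd^2 + (ay$n - 1) * ay$sd^2) /
                 (ax$n + ay$n - 2))
    expect_lte(abs(gxy$effect), abs((ax$mean - ay$mean) / sp))
    # variance decreases in both sample sizes
    bigger <- hedges_g(modifyList(ax, list(n = ax$n * 2)), ay)
    expect_lt(bigger$variance, gxy$variance)
  }
})

test_that("Hedges' g agrees with metafor's standardized mean difference", {
  skip_if_not_installed("metafor")
  set.seed(7)
  for (i in 1:10) {
    n1 <- sample(50:300, 1); n2 <- sample(50:300, 1)
    m1 <- rnorm(1); m2 <- rnorm(1); s1 <- runif(1, .5, 2); s2 <- runif(1, .5, 2)
    es <- metafor::escalc(measure = "SMD", m1i = m1, m2i = m2, sd1i = s1,
                          sd2i = s2, n1i = n1, n2i = n2)
    g <- hedges_g(list(n = n1, mean = m1, sd = s1),
                  list(n = n2, mean = m2, sd = s2))
    # metafor uses the exact gamma-function bias correction; ours is the
    # standard 1 - 3/(4m - 1) approximation
    expect_equal(g$effect, as.numeric(es$yi), tolerance = 1e-4)
    expect_equal(g$variance, as.numeric(es$vi), tolerance = 1e-3)
  }
})

test_that("log odds ratio matches the 2x2-table formulas", {
  lo0 <- log_odds_ratio(list(n = 100, events = 10),
                        list(n = 100, events = 10))
  expect_equal(lo0$effect, 0)
  expect_equal(lo0$variance, 2 * (1 / 10 + 1 / 90))

  lo <- log_odds_ratio(list(n = 100, events = 20),
                       list(n = 100, events = 10))
  expect_equal(lo$effect, log(2.25), tolerance = 1e-12)
  expect_equal(lo$variance, 1 / 20 + 1 / 80 + 1 / 10 + 1 / 90,
               tolerance = 1e-12)

  # zero cell: 0.5 added to all four cells
  loz <- log_odds_ratio(list(n = 50, events = 0), list(n = 50, events = 5))
  expect_equal(loz$effect, log((0.5 * 45.5) / (50.5 * 5.5)), tolerance = 1e-12)
  expect_equal(loz$variance, 1 / 0.5 + 1 / 50.5 + 1 / 5.5 + 1 / 45.5,
               tolerance = 1e-12)
  expect_false(loz$double_zero)

  # double-zero trials stay finite but are flagged
  lodz <- log_odds_ratio(list(n = 50, events = 0), list(n = 60, events = 0))
  expect_true(is.finite(lodz$effect) && is.finite(lodz$variance))
  expect_true(lodz$double_zero)

  # antisymmetry
  set.seed(3)
  for (i in 1:20) {
    ax <- list(n = 100, events = sample(0:100, 1))
    ay <- list(n = 120, events = sample(0:120, 1))
    expect_equal(log_odds_ratio(ax, ay)$effect,
                 -log_odds_ratio(ay, ax)$effect)
    expect_equal(log_odds_ratio(ax, ay)$variance,
                 log_odds_ratio(ay, ax)$variance)
  }
})

test_that("log odds ratio agrees with metafor's escalc", {
  skip_if_not_installed("metafor")
  set.seed(11)
  for (i in 1:10) {
    n1 <- sample(50:300, 1); n2 <- sample(50:300, 1)
    a <- sample(0:20, 1); b <- sample(1:20, 1)
    es <- metafor::escalc(measure = "OR", ai = a, n1i = n1, ci = b, n2i = n2)
    lo <- log_odds_ratio(list(n = n1, events = a), list(n = n2, events = b))
    expect_equal(lo$effect, as.numeric(es$yi), tolerance = 1e-10)
    expect_equal(lo$variance, as.numeric(es$vi), tolerance = 1e-10)
  }
})

test_that("outcome selection follows the hierarchy", {
  cand <- list(WOMAC_total = "t", WOMAC_function = "f")
  expect_equal(select_outcome(cand, function_hierarchy()), "f",
               ignore_attr = TRUE)
  expect_equal(select_outcome(list(Lequesne = "l", WOMAC_total = "t"),
                              function_hierarchy()), "t", ignore_attr = TRUE)
  expect_equal(attr(select_outcome(cand, function_hierarchy()), "scale"),
               "WOMAC_function")
  expect_equal(select_outcome(list(OddScale = "o"), function_hierarchy()),
               "o", ignore_attr = TRUE)
  expect_equal(select_outcome(list(single = 5), c("a", "other")), 5,
               ignore_attr = TRUE)
  expect_error(select_outcome(list(OddScale = "o"), c("VAS_walking")),
               "no candidate matches")
})
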