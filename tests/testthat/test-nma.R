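test_that("model construction counts parameters and data points", {
  sim <- simulate_network(table1_sim_config(seed = 21), "binary")
  m <- nma_model(sim$arms, reference = "PBO")
  expect_equal(m$n_datapoints, 50) # one point per arm
  expect_equal(m$n_mu, 24)
  expect_equal(m$n_basic, 2)
  expect_equal(m$n_re, 50 - 24)
  expect_equal(m$treatments[1], "PBO")

  simc <- simulate_network(table1_sim_config(seed = 21), "continuous")
  mc <- nma_model(simc$arms, reference = "PBO")
  expect_equal(mc$n_datapoints, 26) # one point per contrast
  expect_equal(mc$n_mu, 0)

  single <- two_arm_continuous()
  ms <- nma_model(single, reference = "PBO")
  expect_equal(ms$n_basic, 1)
  expect_equal(ms$n_re, 1)

  expect_error(nma_model(single, reference = "Z"), "absent")
})

test_that("identical configuration reproduces draws bit-identically", {
  sim <- simulate_network(table1_sim_config(seed = 2), "binary")
  f1 <- nma(sim$arms, n_iter = 800, n_burnin = 300, seed = 5)
  f2 <- nma(sim$arms, n_iter = 800, n_burnin = 300, seed = 5)
  expect_identical(f1$chains, f2$chains)
  f3 <- nma(sim$arms, n_iter = 800, n_burnin = 300, seed = 6)
  expect_false(identical(f1$chains[[1]]$d, f3$chains[[1]]$d))
})

test_that("symmetric single binary trial centres the contrast at zero", {
  arms <- as_arm_data(data.frame(study = "S1", treatment = c("PBO", "X"),
                                 n = 100, events = 10), "binary")
  fit <- nma(arms, n_iter = 6000, n_burnin = 2000, seed = 4)
  expect_lt(abs(median(attr(relative_effect(fit, "X", exponentiate = FALSE),
                            "draws"))), 0.05)
})

test_that("reference draws are zero and the league table is skew-symmetric", {
  sim <- simulate_network(table1_sim_config(seed = 13))
  fit <- fast_fit(sim$arms)
  re_ref <- relative_effect(fit, "PBO", "PBO", exponentiate = FALSE)
  expect_equal(unname(re_ref["median"]), 0)
  expect_equal(unname(re_ref["upper"] - re_ref["lower"]), 0)
  lt <- league_table(fit)
  for (i in seq_len(nrow(lt))) {
    rev <- lt[lt$t1 == lt$t2[i] & lt$t2 == lt$t1[i], ]
    expect_equal(lt$median[i], -rev$median, tolerance = 1e-10)
    expect_equal(lt$lower[i], -rev$upper, tolerance = 1e-10)
    expect_equal(lt$significant[i], rev$significant)
  }
  # constant-shift identity: contrast draws are differences by construction
  D <- do.call(rbind, lapply(fit$chains, function(cc) cc$d))
  dr <- attr(relative_effect(fit, "C200QD", "C100BID", exponentiate = FALSE),
             "draws")
  expect_equal(unname(dr), unname(D[, "C200QD"] - D[, "C100BID"]))
})

test_that("binary league tables are multiplicatively inverse under reversal", {
  sim <- simulate_network(table1_sim_config(seed = 17), "binary")
  fit <- fast_fit(sim$arms)
  lt <- league_table(fit) # exponentiated
  for (i in seq_len(nrow(lt))) {
    rev <- lt[lt$t1 == lt$t2[i] & lt$t2 == lt$t1[i], ]
    expect_equal(lt$median[i], 1 / rev$median, tolerance = 1e-10)
    expect_equal(lt$lower[i], 1 / rev$upper, tolerance = 1e-10)
  }
})

test_that("sampled posterior matches the analytic normal posterior", {
  arms <- as_arm_data(data.frame(study = "S1", treatment = c("PBO", "X"),
                                 n = 80, mean = c(2.0, 1.7), sd = 1),
                      "continuous")
  m <- nma_model(arms, reference = "PBO")
  y <- m$y; v <- m$v
  fit <- nma(arms, n_iter = 8000, n_burnin = 2000, seed = 9, tau_fixed = 0)
  D <- do.call(rbind, lapply(fit$chains, function(cc) cc$d))[, 1]
  ess <- unname(effective_size(fit)[1])
  sdev <- sd(D)
  se_med <- sqrt(pi / 2) * sdev / sqrt(ess)
  expect_lt(abs(median(D) - y), 3 * se_med)
  for (p in c(0.025, 0.975)) {
    se_q <- sqrt(p * (1 - p)) / (sqrt(ess) * dnorm(qnorm(p))) * sdev
    expect_lt(abs(quantile(D, p) - (y + qnorm(p) * sqrt(v))), 3 * se_q)
  }
})

test_that("indirect-only networks still identify the head-to-head contrast", {
  cfg <- sim_config(
    d = c(C200QD = -0.38, C100BID = -0.42), tau = 0.15,
    designs = list(list(treatments = c("PBO", "C100BID"), n_trials = 6),
                   list(treatments = c("PBO", "C200QD"), n_trials = 6)),
    n_range = c(117, 481), seed = 31)
  sim <- simulate_network(cfg)
  fit <- fast_fit(sim$arms)
  D <- do.call(rbind, lapply(fit$chains, function(cc) cc$d))
  dr <- attr(relative_effect(fit, "C200QD", "C100BID", exponentiate = FALSE),
             "draws")
  expect_equal(unname(dr), unname(D[, "C200QD"] - D[, "C100BID"]))
  expect_true(is.finite(median(dr)))
})

test_that("posterior recovers simulated truth on one network", {
  sim <- simulate_network(table1_sim_config(seed = 3))
  fit <- nma(sim$arms, n_iter = 6000, n_burnin = 2000, seed = 11)
  co <- coef(fit)
  expect_lt(abs(co[["d[C200QD]"]] - (-0.38)), 0.15)
  expect_lt(abs(co[["d[C100BID]"]] - (-0.42)), 0.2)
  expect_true(all(gelman_rubin(fit) < 1.05))
})

test_that("the sampler agrees with an independent MCMC engine", {
  skip_if_not_installed("rjags")
  arms <- small_binary_network()
  fit <- nma(arms, reference = "PBO", n_iter = 12000, n_burnin = 3000,
             seed = 14)
  mine <- coef(fit)

  studies <- unique(arms$study)
  treatments <- c("PBO", "A", "B")
  na <- vapply(studies, function(s) sum(arms$study == s), integer(1))
  mk <- function(col) {
    m <- matrix(NA_real_, length(studies), max(na))
    for (i in seq_along(studies)) {
      rows <- arms[arms$study == studies[i], ]
      rows <- rows[order(match(rows$treatment, treatments)), ]
      m[i, seq_len(nrow(rows))] <- rows[[col]]
    }
    m
  }
  tmat <- matrix(NA_integer_, length(studies), max(na))
  for (i in seq_along(studies)) {
    rows <- arms[arms$study == studies[i], ]
    tmat[i, seq_len(nrow(rows))] <-
      sort(match(rows$treatment, treatments))
  }
  model <- "model {
    for (i in 1:ns) {
      w[i,1] <- 0
      delta[i,1] <- 0
      mu[i] ~ dnorm(0, 1.0E-4)
      for (k in 1:na[i]) {
        r[i,k] ~ dbin(p[i,k], n[i,k])
        logit(p[i,k]) <- mu[i] + delta[i,k]
      }
      for (k in 2:na[i]) {
        delta[i,k] ~ dnorm(md[i,k], taud[i,k])
        md[i,k] <- d[t[i,k]] - d[t[i,1]] + sw[i,k]
        taud[i,k] <- prec * 2 * (k-1) / k
        w[i,k] <- delta[i,k] - d[t[i,k]] + d[t[i,1]]
        sw[i,k] <- sum(w[i,1:(k-1)]) / (k-1)
      }
    }
    d[1] <- 0
    for (k in 2:nt) { d[k] ~ dnorm(0, 1.0E-4) }
    tau ~ dunif(0, 5)
    prec <- pow(tau, -2)
  }"
  jm <- rjags::jags.model(
    textConnection(model),
    data = list(ns = length(studies), nt = 3, na = na, t = tmat,
                r = mk("events"), n = mk("n")),
    inits = list(.RNG.name = "base::Wichmann-Hill", .RNG.seed = 2024),
    n.chains = 1, quiet = TRUE)
  update(jm, 3000, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("d", "tau"), n.iter = 20000,
                              progress.bar = "none")
  jd <- as.matrix(samp)
  expect_equal(mine[["d[A]"]], median(jd[, "d[2]"]), tolerance = 0.05)
  expect_equal(mine[["d[B]"]], median(jd[, "d[3]"]), tolerance = 0.05)
  expect_equal(mine[["tau"]], median(jd[, "tau"]), tolerance = 0.12)
})

test_that("posterior draw export is long-format and complete", {
  sim <- simulate_network(table1_sim_config(seed = 23))
  fit <- nma(sim$arms, n_iter = 500, n_burnin = 200, seed = 1)
  pd <- posterior_draws(fit, pars = c("d", "tau"))
  expect_equal(sort(unique(pd$parameter)),
               sort(c("d[C100BID]", "d[C200QD]", "tau")))
  expect_equal(nrow(pd), 3 * 300 * 3) # chains x kept x parameters
  expect_equal(pd$value[pd$chain == 2 & pd$parameter == "tau"],
               fit$chains[[2]]$tau)
})

test_that("consistency contrasts combine summary effects", {
  expect_equal(consistency_contrast(-0.38, -0.42), 0.04)
  expect_equal(consistency_contrast(-0.40, -0.43), 0.03)
  expect_equal(consistency_contrast(0.2, 0.2), 0)
  expect_equal(consistency_contrast(2, 4, scale = "or"), 0.5)
  expect_equal(consistency_contrast(log(2), log(4), scale = "log_or"),
               log(0.5))
})
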