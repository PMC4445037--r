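# builds a minimal nma-like object from explicit draws so ranking can be
# exercised against known posteriors
fake_fit <- function(d_draws_list, treatments, seed = 1) {
  chains <- lapply(d_draws_list, function(m) {
    colnames(m) <- treatments[-1]
    list(d = m, mu = matrix(numeric(0), nrow(m), 0),
         delta = matrix(numeric(0), nrow(m), 0), tau = rep(0.1, nrow(m)))
  })
  structure(list(model = list(), chains = chains, treatments = treatments,
                 reference = treatments[1], outcome_kind = "continuous",
                 config = list(n_chains = length(chains), seed = seed)),
            class = "nma")
}

test_that("dominant draws give a degenerate rank matrix", {
  m <- cbind(A = rep(-0.5, 1000), B = rep(-0.2, 1000))
  fit <- fake_fit(list(m), c("PBO", "A", "B"))
  rk <- rank_probabilities(fit, "lower_is_better")
  expect_equal(unname(rk$p_best["A"]), 1)
  expect_equal(unname(rk$rank_matrix["A", ]), c(1, 0, 0))
  expect_equal(unname(rk$rank_matrix["B", ]), c(0, 1, 0))
  expect_equal(unname(rk$rank_matrix["PBO", ]), c(0, 0, 1))
  expect_equal(unname(rk$sucra["A"]), 100)
  expect_equal(unname(rk$sucra["PBO"]), 0)
})

test_that("exchangeable draws split the probability of being best", {
  set.seed(9)
  m <- cbind(A = rnorm(20000, -0.3, 0.1), B = rnorm(20000, -0.3, 0.1))
  fit <- fake_fit(list(m), c("PBO", "A", "B"))
  rk <- rank_probabilities(fit, "lower_is_better")
  expect_equal(unname(rk$p_best["A"]), 0.5, tolerance = 0.03)
  expect_equal(unname(rk$p_best["B"]), 0.5, tolerance = 0.03)
  expect_equal(unname(rk$p_best["PBO"]), 0, tolerance = 0.01)
})

test_that("SUCRA identities: best 100, worst 0, uniform 50, mean always 50", {
  P_best <- rbind(A = c(1, 0, 0), B = c(0, 1, 0), C = c(0, 0, 1))
  s <- sucra(P_best)
  expect_equal(unname(s["A"]), 100)
  expect_equal(unname(s["C"]), 0)
  P_unif <- matrix(1 / 3, 3, 3, dimnames = list(c("A", "B", "C"), NULL))
  expect_equal(unname(sucra(P_unif)), rep(50, 3))
  # mean SUCRA over treatments is exactly 50 for any valid rank matrix
  set.seed(12)
  for (i in 1:20) {
    Tn <- sample(2:6, 1)
    # random doubly-stochastic-ish matrix: normalized permutation mixtures
    P <- Reduce(`+`, lapply(1:8, function(j) {
      perm <- sample(Tn)
      w <- runif(1)
      w * diag(Tn)[perm, , drop = FALSE]
    }))
    P <- P / rowSums(P)
    # rows sum to 1 but columns may not; project columns too
    for (it in 1:50) {
      P <- P / rowSums(P)
      P <- t(t(P) / colSums(P))
    }
    P <- P / rowSums(P)
    expect_equal(mean(sucra(P)), 50, tolerance = 1e-6)
  }
})

test_that("reversing the direction reverses the SUCRA ordering", {
  set.seed(4)
  m <- cbind(A = rnorm(5000, -0.5, 0.1), B = rnorm(5000, -0.2, 0.1))
  fit <- fake_fit(list(m), c("PBO", "A", "B"))
  lo <- rank_probabilities(fit, "lower_is_better")
  hi <- rank_probabilities(fit, "higher_is_better")
  expect_equal(order(lo$sucra), rev(order(hi$sucra)))
})

test_that("rank probabilities are proper distributions and ties break fairly", {
  # all-tied draws: every rank equally likely for everyone
  m <- cbind(A = rep(0, 4000), B = rep(0, 4000))
  fit <- fake_fit(list(m), c("PBO", "A", "B"))
  rk <- rank_probabilities(fit, "lower_is_better", seed = 7)
  expect_equal(rowSums(rk$rank_matrix), c(PBO = 1, A = 1, B = 1))
  expect_equal(colSums(rk$rank_matrix), c("1" = 1, "2" = 1, "3" = 1))
  expect_true(all(abs(rk$rank_matrix - 1 / 3) < 0.05))
  # deterministic under the same tie-break seed
  rk2 <- rank_probabilities(fit, "lower_is_better", seed = 7)
  expect_identical(rk$rank_matrix, rk2$rank_matrix)
})

test_that("recovery-run posterior ranks BID over QD over placebo", {
  sim <- simulate_network(table1_sim_config(seed = 3))
  fit <- nma(sim$arms, n_iter = 4000, n_burnin = 1500, seed = 11)
  rk <- rank_probabilities(fit, "lower_is_better")
  expect_gt(rk$sucra["C100BID"], rk$sucra["C200QD"])
  expect_gt(rk$sucra["C200QD"], rk$sucra["PBO"])
  expect_equal(mean(rk$sucra), 50, tolerance = 1e-9)
  expect_equal(sum(rk$p_best), 1)
})
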