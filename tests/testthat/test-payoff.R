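test_that("unconditional self-play matches the Bernoulli closed form", {
  for (e in c(1e-2, 1e-4)) {
    b <- 3
    pp <- pair_payoff("AllC", "AllC", b, e)
    expect_equal(pp$gamma_pq, 1 - e, tolerance = 1e-12)
    expect_equal(pp$pi_pq, (b - 1) * (1 - e), tolerance = 1e-12)
    # v_CC = (1-e)^2: both players' most recent action C
    m <- 1
    idx_cc <- 1 * 2^m + 1 + 1
    expect_equal(pp$v[idx_cc], (1 - e)^2, tolerance = 1e-12)
    expect_equal(pair_payoff("AllD", "AllD", b, e)$gamma_pq, e,
                 tolerance = 1e-12)
  }
})

test_that("effective strategies mix the table with its complement", {
  expect_equal(effective_strategy("AllC", 0.1), rep(0.9, 1))
  expect_equal(effective_strategy("AllD", 1e-6), rep(1e-6, 1))
  s <- ipd_strategy("WSLS")
  expect_equal(effective_strategy(s, 0), as.numeric(s$table))
})

test_that("transition matrices are row-stochastic with the shift structure", {
  set.seed(41)
  for (k in 1:5) {
    p <- random_strategy(sample(1:3, 1))
    q <- random_strategy(sample(1:3, 1))
    T_ <- transition_matrix(p, q, runif(1, 0, 0.4))
    expect_equal(rowSums(T_), rep(1, nrow(T_)), tolerance = 1e-12)
    expect_true(all(T_ >= 0))
    # at most 4 successors per state
    expect_true(all(rowSums(T_ > 0) <= 4))
  }
  # TFT vs TFT at e = 0 from CD goes to DC with probability 1
  T0 <- transition_matrix("TFT", "TFT", 0)
  i_cd <- 1 * 2 + 0 + 1  # (a1, b1) = (C, D)
  i_dc <- 0 * 2 + 1 + 1
  expect_equal(T0[i_cd, i_dc], 1)
  expect_equal(sum(T0[i_cd, ]), 1)
})

test_that("stationary distributions are proper and satisfy the payoff identity", {
  set.seed(42)
  for (k in 1:10) {
    p <- random_strategy(sample(1:3, 1))
    q <- random_strategy(sample(1:3, 1))
    b <- runif(1, 1.5, 6)
    e <- 10^runif(1, -6, -2)
    pp <- pair_payoff(p, q, b, e)
    expect_true(all(pp$v >= 0))
    expect_equal(sum(pp$v), 1, tolerance = 1e-12)
    expect_equal(pp$pi_pq, b * pp$gamma_qp - pp$gamma_pq)
    expect_equal(pp$pi_qp, b * pp$gamma_pq - pp$gamma_qp)
  }
})

test_that("payoffs are invariant under lifting to a larger capacity", {
  set.seed(43)
  for (k in 1:8) {
    p <- random_strategy(sample(1:2, 1))
    q <- random_strategy(sample(1:2, 1))
    a <- pair_payoff(p, q, b = 3, e = 1e-4)
    b_ <- pair_payoff(strategy_lift(p, 3), strategy_lift(q, 3),
                      b = 3, e = 1e-4)
    expect_equal(a$gamma_pq, b_$gamma_pq, tolerance = 1e-10)
    expect_equal(a$gamma_qp, b_$gamma_qp, tolerance = 1e-10)
    expect_equal(a$pi_pq, b_$pi_pq, tolerance = 1e-10)
  }
})

test_that("classic pairings reproduce their known limits", {
  b <- 3
  # AllC is exploited by AllD: unilateral donation every round
  pp <- pair_payoff("AllC", "AllD", b, 1e-6)
  expect_equal(pp$pi_pq, -1, tolerance = 1e-4)
  expect_equal(pp$pi_qp, b, tolerance = 1e-4)
  # TFT never falls behind AllD by more than O(e)
  pp <- pair_payoff("TFT", "AllD", b, 1e-6)
  expect_lt(abs(pp$pi_pq - pp$pi_qp), 10 * 1e-6 * (b + 1))
  # WSLS recovers cooperation with itself
  expect_gt(pair_payoff("WSLS", "WSLS", b, 1e-4)$gamma_pq, 0.99)
  # payoff_entries bundles the four values consistently
  pe <- payoff_entries("WSLS", "AllD", b, 1e-4)
  expect_equal(pe[["pi_pp"]],
               pair_payoff("WSLS", "WSLS", b, 1e-4)$pi_pq)
  pe_same <- payoff_entries("TFT", "TFT", b, 1e-4)
  expect_equal(unname(pe_same), rep(pe_same[["pi_pp"]], 4))
})

test_that("stationary payoffs agree with direct game simulation", {
  set.seed(44)
  rounds <- 2e5
  for (k in 1:4) {
    p <- random_strategy(sample(1:2, 1))
    q <- random_strategy(sample(1:2, 1))
    b <- 3; e <- 0.02
    sim <- simulate_game(p, q, b, e, rounds)
    exact <- pair_payoff(p, q, b, e)
    expect_lt(abs(sim$pi_pq - exact$pi_pq), 4 * sim$se_pq)
    expect_lt(abs(sim$pi_qp - exact$pi_qp), 4 * sim$se_qp)
  }
})
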