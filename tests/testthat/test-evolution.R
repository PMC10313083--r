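test_that("the Fermi function has its defining properties", {
  expect_equal(fermi_prob(1, 1, 3), 0.5)
  set.seed(71)
  for (k in 1:10) {
    a <- rnorm(1); b_ <- rnorm(1); s <- runif(1, 0, 50)
    expect_equal(fermi_prob(a, b_, s) + fermi_prob(b_, a, s), 1)
  }
  # strong selection limits
  expect_gt(fermi_prob(0, 1, 1e4), 1 - 1e-10)
  expect_lt(fermi_prob(1, 0, 1e4), 1e-10)
  # no overflow at extreme selection strengths
  expect_true(is.finite(fermi_prob(-1e6, 1e6, 1e6)))
})

test_that("fixation probability reduces to the known closed forms", {
  # neutral: all payoffs equal -> rho = 1/N for any sigma
  for (N in c(2, 5, 8, 64))
    expect_equal(fixation_rho_cpp(1.2, 1.2, 1.2, 1.2, N, 7), 1 / N)
  # sigma = 0 is neutral regardless of payoffs
  expect_equal(fixation_rho_cpp(0, 3, -1, 2, 8, 0), 1 / 8)
  # N = 2: rho = 1 / (1 + exp(sigma * (pi_XY - pi_YX)))
  set.seed(72)
  for (k in 1:10) {
    pis <- rnorm(4); s <- runif(1, 0, 5)
    expect_equal(fixation_rho_cpp(pis[1], pis[2], pis[3], pis[4], 2, s),
                 1 / (1 + exp(s * (pis[2] - pis[3]))),
                 tolerance = 1e-12)
  }
  # extreme selection cannot overflow
  expect_gte(fixation_rho_cpp(100, 100, -100, -100, 8, 1e5), 0)
})

test_that("fixation formula matches the stochastic within-group process", {
  set.seed(73)
  N <- 4; b <- 3; e <- 0.01; sigma <- 1
  cases <- list(c("AllD", "WSLS"), c("WSLS", "AllD"), c("TFT", "AllC"))
  for (cs in cases) {
    rho <- fixation_probability(cs[1], cs[2], N, sigma, b, e)
    trials <- 4000
    est <- simulate_fixation(cs[1], cs[2], N, sigma, b, e, trials)
    se <- sqrt(rho * (1 - rho) / trials)
    expect_lt(abs(est - rho), 4 * se + 1e-3)
  }
})

test_that("group transition probability composes Fermi and fixation", {
  b <- 3; e <- 1e-6; s_in <- 15; s_out <- 15; N <- 2
  # identical strategies: fermi tie (1/2) times neutral fixation (1/N)
  expect_equal(group_transition_probability("TFT", "TFT", N, s_in, s_out,
                                            b, e), 0.5 / N)
  # an efficient strategy is imitated by defectors across groups but
  # cannot fix against them within the group
  pe <- payoff_entries("AllD", "WSLS", b, e)
  f_out <- fermi_prob(pe[["pi_pp"]], pe[["pi_qq"]], s_out)
  T_ <- group_transition_probability("AllD", "WSLS", N, s_in, s_out, b, e)
  expect_gt(f_out, 0.99)          # WSLS group looks much better off
  expect_lt(T_, f_out * (1 / N))  # but fixation suppresses the switch
})

test_that("runs are reproducible and observables are well-formed", {
  cfg <- well_mixed_config(N = 4, b = 3, m = 1, steps = 2e4, burn_in = 2e3,
                           seed = 99, thin = 100)
  r1 <- run_well_mixed(cfg)
  r2 <- run_well_mixed(cfg)
  expect_identical(r1$observables, r2$observables)
  expect_identical(r1$series, r2$series)
  expect_equal(names(r1$series),
               c("t", "cooperation", "frac_fr", "frac_eff", "frac_rival",
                 "mean_m1", "mean_m2"))
  o <- r1$observables
  expect_true(o$mean_cooperation >= 0 && o$mean_cooperation <= 1)
  expect_lte(o$frac_fr + o$frac_eff + o$frac_rival, 1 + 1e-12)
  expect_true(o$mean_m1 >= 0 && o$mean_m1 <= 1)

  gcfg <- group_config(M = 10, N = 2, b = 3, m = 2, r = 0.05, steps = 2e4,
                       burn_in = 2e3, seed = 100, thin = 100)
  g1 <- run_group_structured(gcfg)
  g2 <- run_group_structured(gcfg)
  expect_identical(g1$observables, g2$observables)
  expect_true(g1$observables$mean_m2 <= 2)
})

test_that("neutral selection recovers the sampler's base rates", {
  # with sigma_in = 0 every mutant fixes with probability 1/N, so the
  # resident chain is a time-rescaled copy of the sampler
  set.seed(74)
  base <- table(factor(vapply(sample_mutant(1, 4000), function(s)
    classify_strategy(s)$label, character(1)),
    levels = c("FR", "non-FR efficient", "non-FR rival", "other"))) / 4000
  cfg <- well_mixed_config(N = 2, b = 3, m = 1, sigma_in = 0, steps = 5e4,
                           burn_in = 5e3, seed = 75, thin = 0)
  o <- run_well_mixed(cfg)$observables
  expect_lt(abs(o$frac_eff - base[["non-FR efficient"]]), 0.05)
  expect_lt(abs(o$frac_rival - base[["non-FR rival"]]), 0.05)
  expect_equal(o$frac_fr, 0)  # no FR exists in the memory-one space
})

test_that("friendly rivals are evolutionarily robust against mutants", {
  # robustness (no mutant fixes at a rate above neutral) is a
  # vanishing-error statement: at finite e the payoffs carry O(e)
  # perturbations that leak into rho linearly, so evaluate at an error
  # rate small enough for the O(e) term to sit below the tolerance
  set.seed(76)
  frs <- enumerate_friendly_rivals(2, 2)
  expect_length(frs, 8L)
  mutants <- sample_mutant(3, 200)
  for (fr_ in frs[c(1, 5)]) {
    x <- strategy_lift(fr_, 3)
    for (N in c(2, 8)) {
      rho <- vapply(mutants, function(y)
        fixation_probability(x, y, N, 30 / 2, b = 3, e = 1e-12), numeric(1))
      expect_true(all(rho <= 1 / N + 1e-9))
    }
  }
  # at the study's e = 1e-6 the excess over 1/N stays O(e)
  x <- strategy_lift(frs[[1]], 3)
  rho6 <- vapply(mutants[1:50], function(y)
    fixation_probability(x, y, 2, 15, b = 3, e = 1e-6), numeric(1))
  expect_true(all(rho6 <= 1 / 2 + 1e-4))
})
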