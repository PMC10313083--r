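test_that("canonical strategies fall into their known classes", {
  expect_true(is_efficient("WSLS"))
  expect_false(is_efficient("TFT"))
  expect_false(is_efficient("AllD"))
  expect_true(is_efficient("AllC"))

  expect_true(is_rival("TFT"))
  expect_true(is_rival("AllD"))
  expect_true(is_rival("GRIM"))
  expect_false(is_rival("WSLS"))
  expect_false(is_rival("AllC"))

  expect_false(is_friendly_rival("WSLS"))
  expect_false(is_friendly_rival("TFT"))

  expect_equal(classify_strategy("WSLS")$label, "non-FR efficient")
  expect_equal(classify_strategy("AllC")$label, "non-FR efficient")
  expect_equal(classify_strategy("GRIM")$label, "non-FR rival")
  expect_equal(classify_strategy("TFT")$label, "non-FR rival")
})

test_that("label buckets are consistent with the two binary tests", {
  set.seed(51)
  for (k in 1:25) {
    s <- random_strategy(sample(1:2, 1))
    cl <- classify_strategy(s)
    expect_equal(cl$label == "FR", cl$efficient && cl$rival)
    expect_equal(cl$label == "non-FR efficient", cl$efficient && !cl$rival)
    expect_equal(cl$label == "non-FR rival", cl$rival && !cl$efficient)
    expect_equal(cl$label == "other", !cl$efficient && !cl$rival)
  }
})

test_that("memory-one rivals are never beaten by any memory-one opponent", {
  # necessary condition for rivalry, checked exhaustively on the 16 x 16
  # memory-one payoff table at near-zero error
  tol <- 1e-4
  e <- 1e-6
  b <- 2.5
  strategies <- lapply(0:15, function(k)
    ipd_strategy(as.integer(intToBits(k)[1:4])))
  rival_flags <- vapply(strategies, is_rival, logical(1))
  beaten <- vapply(strategies, function(p) {
    any(vapply(strategies, function(q) {
      pp <- pair_payoff(p, q, b, e)
      pp$pi_qp > pp$pi_pq + tol
    }, logical(1)))
  }, logical(1))
  expect_true(all(!beaten[rival_flags]))
  # 4 rivals and 3 efficient strategies among the 16 memory-one tables
  expect_equal(sum(rival_flags), 4L)
  expect_equal(sum(vapply(strategies, is_efficient, logical(1))), 3L)
  # the well-known exploitables are indeed beaten within memory one
  idx_wsls <- which(vapply(strategies, strategy_equal, logical(1),
                           b = "WSLS"))
  expect_true(beaten[idx_wsls])
})

test_that("Floyd-Warshall agrees with Bellman-Ford on random strategies", {
  set.seed(52)
  for (k in 1:40) {
    s <- random_strategy(2)
    expect_equal(is_rival(s), oracle_is_rival_bf(s))
  }
  for (nm in strategy_names())
    expect_equal(is_rival(nm), oracle_is_rival_bf(nm))
})

test_that("rivalry is invariant under lifting the representation", {
  set.seed(53)
  for (k in 1:10) {
    s <- random_strategy(sample(1:2, 1))
    expect_equal(is_rival(s), is_rival(strategy_lift(s, 3)))
  }
})

test_that("the efficiency decision is stable under the judgement parameters", {
  # the numerical judgement (self-cooperation above a threshold at small
  # e) targets the vanishing-error limit: the decision must not change
  # when e is pushed further down, with either threshold.  At e = 1e-4 a
  # strategy whose error recovery takes k rounds has gamma ~ 1 - k e, so
  # a threshold as strict as 0.999 misreads slow recoverers (k > 10);
  # at e = 1e-5 the two thresholds coincide with the standard setting.
  for (cls in list(c(1, 1), c(1, 2), c(2, 1), c(2, 2))) {
    ref <- census_exhaustive_cpp(cls[1], cls[2], 1e-4, 0.99)
    for (par in list(c(1e-5, 0.99), c(1e-5, 0.999))) {
      alt <- census_exhaustive_cpp(cls[1], cls[2], par[1], par[2])
      expect_equal(alt$n_efficient, ref$n_efficient)
      expect_equal(alt$n_fr, ref$n_fr)
    }
    # the FR census itself is threshold-insensitive even at e = 1e-4
    expect_equal(census_exhaustive_cpp(cls[1], cls[2], 1e-4, 0.999)$n_fr,
                 ref$n_fr)
  }
})
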