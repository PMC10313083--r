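# Independent oracles used across the suite.  These deliberately avoid the
# package's compiled code paths: memory lengths by definition-level
# dependence checks, rivalry by Bellman-Ford, payoffs by round-by-round
# simulation of the repeated game.

# uniform random strategy at capacity m
random_strategy <- function(m) {
  ipd_strategy(sample(0:1, 2^(2 * m), replace = TRUE))
}

# profile index -> (A, B) at capacity m
profile_split <- function(i, m) {
  c(A = i %/% 2^m, B = i %% 2^m)
}

# Brute-force memory lengths: the smallest k such that the prescription is
# unchanged when the own (resp. co-player) history bits beyond depth k are
# zeroed, checked over every profile.
oracle_memory_lengths <- function(s) {
  s <- ipd_strategy(s)
  m <- s$m_cap
  tab <- s$table
  act_at <- function(A, B) tab[A * 2^m + B + 1]
  depends_only <- function(k, own) {
    keep <- 2^k - 1  # low-bit mask: the k most recent rounds
    for (i in 0:(2^(2 * m) - 1)) {
      A <- i %/% 2^m; B <- i %% 2^m
      A2 <- if (own) bitwAnd(A, keep) else A
      B2 <- if (own) B else bitwAnd(B, keep)
      if (act_at(A, B) != act_at(A2, B2)) return(FALSE)
    }
    TRUE
  }
  m1 <- 0
  for (k in 0:m) if (depends_only(k, own = TRUE)) { m1 <- k; break }
  m2 <- 0
  for (k in 0:m) if (depends_only(k, own = FALSE)) { m2 <- k; break }
  c(m1 = m1, m2 = m2)
}

# Rivalry graph of a strategy at its capacity (lifted to >= 1):
# nodes 0..(2^(2m)-1), two out-edges per node, weights in {-1, 0, +1}.
rivalry_edges <- function(s) {
  s <- strategy_lift(ipd_strategy(s), max(1L, ipd_strategy(s)$m_cap))
  m <- s$m_cap
  n <- 2^(2 * m)
  mask <- 2^m - 1
  edges <- NULL
  for (i in 0:(n - 1)) {
    A <- i %/% 2^m; B <- i %% 2^m
    ap <- s$table[i + 1]
    A2 <- bitwAnd(A * 2 + ap, mask)
    for (bp in 0:1) {
      B2 <- bitwAnd(B * 2 + bp, mask)
      w <- if (ap == bp) 0 else if (ap == 1) -1 else 1
      edges <- rbind(edges, c(from = i, to = A2 * 2^m + B2, w = w))
    }
  }
  list(n = n, edges = edges)
}

# Bellman-Ford negative-cycle detection over the whole graph (virtual
# source connected to every node with weight 0).
oracle_is_rival_bf <- function(s) {
  g <- rivalry_edges(s)
  dist <- rep(0, g$n)
  for (iter in seq_len(g$n)) {
    changed <- FALSE
    for (k in seq_len(nrow(g$edges))) {
      e <- g$edges[k, ]
      cand <- dist[e[["from"]] + 1] + e[["w"]]
      if (cand < dist[e[["to"]] + 1]) {
        dist[e[["to"]] + 1] <- cand
        changed <- TRUE
      }
    }
    if (!changed) return(TRUE)  # relaxed to a fixed point: no negative cycle
  }
  FALSE  # still relaxing after n passes => negative cycle
}

# Round-by-round simulation of the repeated donation game with
# implementation errors; returns empirical payoffs/cooperation rates and
# their standard errors.
simulate_game <- function(p, q, b, e, rounds) {
  p <- ipd_strategy(p); q <- ipd_strategy(q)
  m <- max(1L, p$m_cap, q$m_cap)
  p <- strategy_lift(p, m); q <- strategy_lift(q, m)
  mask <- 2^m - 1
  A <- mask; B <- mask  # start from mutual cooperation over the window
  a_coop <- logical(rounds); b_coop <- logical(rounds)
  for (t in seq_len(rounds)) {
    ap <- p$table[A * 2^m + B + 1]
    bp <- q$table[B * 2^m + A + 1]
    if (runif(1) < e) ap <- 1 - ap
    if (runif(1) < e) bp <- 1 - bp
    a_coop[t] <- ap == 1
    b_coop[t] <- bp == 1
    A <- bitwAnd(A * 2 + ap, mask)
    B <- bitwAnd(B * 2 + bp, mask)
  }
  pay_a <- b * b_coop - a_coop
  pay_b <- b * a_coop - b_coop
  # standard errors from block means (the round-level series is
  # autocorrelated through the Markov chain)
  nblk <- 500
  blk <- rep(seq_len(nblk), each = rounds %/% nblk)[seq_len(rounds)]
  se_blk <- function(x) sd(tapply(x, blk, mean)) / sqrt(nblk)
  list(pi_pq = mean(pay_a), pi_qp = mean(pay_b),
       se_pq = se_blk(pay_a), se_qp = se_blk(pay_b),
       gamma_pq = mean(a_coop), gamma_qp = mean(b_coop))
}

# Stochastic within-group fixation oracle: a single Y-mutant in a group of
# N X-players, pairwise Fermi imitation with fitnesses recomputed from the
# current group composition (mean payoff against the other members).
simulate_fixation <- function(x, y, N, sigma, b, e, trials) {
  pp <- pair_payoff(x, y, b, e)
  pi_xx <- pair_payoff(x, x, b, e)$pi_pq
  pi_yy <- pair_payoff(y, y, b, e)$pi_pq
  pi_xy <- pp$pi_pq; pi_yx <- pp$pi_qp
  fixed <- 0L
  for (tr in seq_len(trials)) {
    k <- 1L  # number of Y players
    repeat {
      if (k == 0L) break
      if (k == N) { fixed <- fixed + 1L; break }
      # fitnesses by composition (self excluded)
      fit_y <- ((k - 1) * pi_yy + (N - k) * pi_yx) / (N - 1)
      fit_x <- (k * pi_xy + (N - k - 1) * pi_xx) / (N - 1)
      ij <- sample.int(N, 2)  # focal, role model
      focal_y <- ij[1] <= k; role_y <- ij[2] <= k
      if (focal_y == role_y) next
      f_focal <- if (focal_y) fit_y else fit_x
      f_role <- if (role_y) fit_y else fit_x
      if (runif(1) < 1 / (1 + exp(sigma * (f_focal - f_role))))
        k <- k + (if (role_y) 1L else -1L)
    }
  }
  fixed / trials
}
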