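# Strategy-space combinatorics: exact-memory class sizes, enumeration,
# the two-step mutant sampler, and the class census.

#' Number of strategies with exact memory (m1, m2)
#'
#' Counted by inclusion-exclusion over the at-most-memory table counts
#' N(i, j) = 2^(2^(i+j)):
#' \deqn{|S(m_1,m_2)| = N(m_1,m_2) - N(m_1-1,m_2) - N(m_1,m_2-1) +
#'   N(m_1-1,m_2-1),}
#' dropping the terms whose index would go negative.  For example
#' |S(1,1)| = 16 - 4 - 4 + 2 = 10 and |S(0,0)| = 2 (AllC and AllD).
#'
#' @param m1,m2 non-negative integers.
#' @return a double; exact as long as the value stays below 2^53
#'   (i.e. m1 + m2 <= 5).
#' @export
count_exact_memory <- function(m1, m2) {
  stopifnot(m1 >= 0, m2 >= 0)
  N <- function(i, j) if (i < 0 || j < 0) 0 else 2^(2^(i + j))
  N(m1, m2) - N(m1 - 1, m2) - N(m1, m2 - 1) + N(m1 - 1, m2 - 1)
}

#' Enumerate all strategies with exact memory (m1, m2)
#'
#' Iterates over all 2^(2^(m1+m2)) prescription tables on the short
#' histories, keeps those whose exact memory is (m1, m2), and embeds
#' them at capacity max(m1, m2, 1).  Refuses classes with m1 + m2 > 4
#' (more than 2^16 candidate tables); use [sample_mutant()] or
#' [memory_census()] with sampling there.
#'
#' @param m1,m2 integers in 0..3 with m1 + m2 <= 4.
#' @return a list of [ipd_strategy()] objects of length
#'   \code{count_exact_memory(m1, m2)}.
#' @export
enumerate_exact_memory <- function(m1, m2) {
  res <- enumerate_class_cpp(as.integer(m1), as.integer(m2))
  tables <- res$tables
  m_min <- max(m1, m2)
  lapply(seq_len(nrow(tables)), function(k) {
    s <- new_strategy(res$m_cap, tables[k, ])
    if (res$m_cap == m_min) s else strategy_lift(s, m_min)
  })
}

#' Sample mutant strategies by the two-step scheme
#'
#' Step 1 draws the exact memory lengths m1 and m2 independently and
#' uniformly from {0, ..., m}; step 2 draws a strategy uniformly from
#' the exact class S(m1, m2) (by rejection from uniform tables).  Under
#' neutral selection the mean memory lengths are therefore (m/2, m/2),
#' and short-memory strategies such as AllD or TFT appear with
#' non-negligible probability even for m = 3.
#'
#' @param m memory cap, 1..3.
#' @param n number of draws.
#' @return an [ipd_strategy()] if \code{n == 1}, else a list of them.
#'   Uses R's RNG; seed with [set.seed()] for reproducibility.
#' @export
sample_mutant <- function(m, n = 1) {
  stopifnot(m %in% 1:3, n >= 1)
  tabs <- sample_mutants_cpp(as.integer(m), as.integer(n))
  out <- lapply(seq_len(nrow(tabs)), function(k) new_strategy(m, tabs[k, ]))
  if (n == 1) out[[1]] else out
}

#' List the friendly rivals of an exact-memory class
#'
#' Exhaustively classifies the class (requires m1 + m2 <= 4) and returns
#' the strategies that are both efficient and rival.  The memory-2
#' strategy space holds its 8 FRs in the (2, 2) class.
#'
#' @inheritParams memory_census
#' @return a list of [ipd_strategy()] objects (possibly empty).
#' @export
enumerate_friendly_rivals <- function(m1, m2, e = 1e-4, threshold = 0.99) {
  m1 <- as.integer(m1); m2 <- as.integer(m2)
  res <- census_exhaustive_cpp(m1, m2, e, threshold)
  lapply(res$fr_class_tables, function(ct)
    ipd_strategy(embed_class_table_cpp(ct, m1, m2)))
}

wilson_interval <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lo = max(0, ctr - hw), hi = min(1, ctr + hw))
}

#' Census of one exact-memory class
#'
#' Classifies every strategy of the class exhaustively when
#' m1 + m2 <= 4; larger classes are estimated from \code{n_samples}
#' uniform draws within the class, in which case the FR fraction is a
#' Monte Carlo estimate (reported with a Wilson interval and a warning,
#' since FRs are extremely rare).
#'
#' @param m1,m2 integers in 0..3.
#' @param n_samples Monte Carlo sample size for classes with
#'   m1 + m2 > 4.
#' @param e,threshold efficiency-judgement parameters, see
#'   [is_efficient()].
#' @return a one-row data.frame with columns \code{m1}, \code{m2},
#'   \code{n_total}, \code{frac_efficient}, \code{frac_rival},
#'   \code{frac_fr}, \code{fr_lo}, \code{fr_hi}, \code{method},
#'   \code{n_samples}.
#' @examples
#' memory_census(1, 1)  # 10 strategies: 20% efficient, 20% rival, no FR
#' @export
memory_census <- function(m1, m2, n_samples = 1e4, e = 1e-4,
                          threshold = 0.99) {
  m1 <- as.integer(m1); m2 <- as.integer(m2)
  stopifnot(m1 >= 0, m2 >= 0, m1 <= 3, m2 <= 3)
  n_total <- count_exact_memory(m1, m2)
  if (m1 + m2 <= 4) {
    res <- census_exhaustive_cpp(m1, m2, e, threshold)
    stopifnot(res$n_total == n_total)
    data.frame(m1 = m1, m2 = m2, n_total = n_total,
               frac_efficient = res$n_efficient / n_total,
               frac_rival = res$n_rival / n_total,
               frac_fr = res$n_fr / n_total,
               fr_lo = res$n_fr / n_total, fr_hi = res$n_fr / n_total,
               method = "exhaustive", n_samples = n_total)
  } else {
    n_samples <- as.integer(n_samples)
    res <- census_sample_cpp(m1, m2, n_samples, e, threshold)
    wi <- wilson_interval(res$n_fr, n_samples)
    warning("class (", m1, ",", m2, ") censused by sampling; the FR ",
            "fraction is a Monte Carlo estimate and FRs are rare ",
            "(Wilson interval [", signif(wi[1], 3), ", ", signif(wi[2], 3),
            "])")
    data.frame(m1 = m1, m2 = m2, n_total = n_total,
               frac_efficient = res$n_efficient / n_samples,
               frac_rival = res$n_rival / n_samples,
               frac_fr = res$n_fr / n_samples,
               fr_lo = wi[["lo"]], fr_hi = wi[["hi"]],
               method = "sampled", n_samples = n_samples)
  }
}
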