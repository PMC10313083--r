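# Small-mutation-limit evolutionary Monte Carlo for well-mixed and
# group-structured populations.

#' Fermi imitation probability
#'
#' Probability that a focal player with payoff \code{pi_x} adopts a role
#' model's strategy with payoff \code{pi_y}:
#' \code{1 / (1 + exp(sigma * (pi_x - pi_y)))}.  Equals 1/2 on a payoff
#' tie and decreases in \code{pi_x - pi_y}; the exponent is clamped to
#' avoid overflow at large selection strength.
#'
#' @param pi_x,pi_y payoffs of the focal and the role model.
#' @param sigma selection strength (>= 0).
#' @export
fermi_prob <- function(pi_x, pi_y, sigma) {
  stopifnot(is.finite(pi_x), is.finite(pi_y), sigma >= 0)
  fermi_cpp(pi_x, pi_y, sigma)
}

#' Fixation probability of a mutant under pairwise comparison
#'
#' Probability that a single Y-mutant takes over a homogeneous group of
#' N X-players when strategies spread by pairwise Fermi imitation with
#' selection strength \code{sigma_in} and fitnesses are averages of
#' long-term payoffs against the other group members:
#' \deqn{\rho_{X \to Y} = \left\{ \sum_{j=0}^{N-1} \exp\!\Big[\sigma_{in}
#'   j \frac{(2N-j-3)\pi_{XX} + (j+1)\pi_{XY} - (2N-j-1)\pi_{YX} -
#'   (j-1)\pi_{YY}}{2(N-1)}\Big] \right\}^{-1}.}
#' The j = 0 term is 1, and when all four payoffs coincide every term is
#' 1, giving the neutral value 1/N.  Computed in log-sum-exp form, so it
#' is overflow-proof for any selection strength.
#'
#' @param x resident strategy X; @param y mutant strategy Y.
#' @param N group (or population) size, >= 2.
#' @param sigma_in intra-group selection strength.
#' @param b,e game parameters, see [pair_payoff()].
#' @return fixation probability in (0, 1].
#' @export
fixation_probability <- function(x, y, N, sigma_in, b, e) {
  pe <- payoff_entries(x, y, b, e)
  fixation_rho_cpp(pe[["pi_pp"]], pe[["pi_pq"]], pe[["pi_qp"]],
                   pe[["pi_qq"]], as.integer(N), sigma_in)
}

#' Probability that a group switches strategy via out-group imitation
#'
#' The focal group (resident X) imitates a role-model group (resident Y)
#' with the Fermi probability computed from the homogeneous-group
#' self-payoffs pi_XX and pi_YY (members of different groups do not play
#' each other), after which the single convert must fix within the
#' group: \code{T_XY = fermi(pi_XX, pi_YY, sigma_out) * rho_XY}.
#'
#' @inheritParams fixation_probability
#' @param sigma_out out-group selection strength.
#' @export
group_transition_probability <- function(x, y, N, sigma_in, sigma_out, b, e) {
  pe <- payoff_entries(x, y, b, e)
  fermi_cpp(pe[["pi_pp"]], pe[["pi_qq"]], sigma_out) *
    fixation_rho_cpp(pe[["pi_pp"]], pe[["pi_pq"]], pe[["pi_qp"]],
                     pe[["pi_qq"]], as.integer(N), sigma_in)
}

#' Configuration for a well-mixed-population run
#'
#' Defaults follow the standard study conditions: error rate 1e-6,
#' intra-group selection strength 30/(b-1), 1e6 time steps with the
#' first 1e5 discarded.
#'
#' @param N population size (>= 2).
#' @param b benefit of cooperation (> 1).
#' @param e implementation-error rate.
#' @param m memory cap of the strategy space, 1..3.
#' @param sigma_in selection strength.
#' @param steps,burn_in total and discarded time steps.
#' @param seed integer seed; drawn at random (and recorded) when NULL.
#' @param thin record a time-series row every \code{thin} steps
#'   (0 disables the series).
#' @export
well_mixed_config <- function(N, b, e = 1e-6, m = 1,
                              sigma_in = 30 / (b - 1),
                              steps = 1e6, burn_in = 1e5,
                              seed = NULL, thin = 1000) {
  check_game_params(b, e)
  stopifnot(N >= 2, m %in% 1:3, steps > burn_in, burn_in >= 0, sigma_in >= 0)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  structure(list(N = as.integer(N), b = b, e = e, m = as.integer(m),
                 sigma_in = sigma_in, steps = steps, burn_in = burn_in,
                 seed = as.integer(seed), thin = thin),
            class = c("well_mixed_config", "fr_config"))
}

#' Configuration for a group-structured-population run
#'
#' Defaults are the scaled-down desk conditions: M = 100 groups of
#' N = 2, b = 3, e = 1e-6, both selection strengths 30/(b-1) = 15, 1e7
#' steps with the first tenth discarded.
#'
#' @param M number of groups (>= 2).
#' @param N group size (>= 2).
#' @param r relative mutation probability in [0, 1] (frequency of
#'   mutation relative to out-group imitation).
#' @param sigma_out out-group selection strength.
#' @inheritParams well_mixed_config
#' @export
group_config <- function(M = 100, N = 2, b = 3, e = 1e-6, m = 3,
                         sigma_in = 30 / (b - 1),
                         sigma_out = 30 / (b - 1), r = 1e-2,
                         steps = 1e7, burn_in = steps / 10,
                         seed = NULL, thin = 1000) {
  check_game_params(b, e)
  stopifnot(M >= 2, N >= 2, m %in% 1:3, r >= 0, r <= 1,
            steps > burn_in, burn_in >= 0, sigma_in >= 0, sigma_out >= 0)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  structure(list(M = as.integer(M), N = as.integer(N), b = b, e = e,
                 m = as.integer(m), sigma_in = sigma_in,
                 sigma_out = sigma_out, r = r, steps = steps,
                 burn_in = burn_in, seed = as.integer(seed), thin = thin),
            class = c("group_config", "fr_config"))
}

finish_run <- function(raw, config, mode) {
  obs <- raw[c("mean_cooperation", "frac_fr", "frac_eff", "frac_rival",
               "mean_m1", "mean_m2")]
  structure(list(observables = obs, series = raw$series, config = config,
                 mode = mode, seed = config$seed),
            class = "fr_run")
}

#' Evolve a well-mixed population in the small-mutation limit
#'
#' A single resident strategy X is challenged once per time step by a
#' mutant Y drawn by the two-step sampler ([sample_mutant()]); the
#' mutant replaces the resident with the fixation probability
#' \code{rho_XY} and vanishes otherwise.  Observables are streaming time
#' averages of the resident's self-cooperation level, reporting-class
#' fractions and exact memory lengths after burn-in.
#'
#' @param config a [well_mixed_config()].
#' @return an object of class \code{"fr_run"}: a list with
#'   \code{observables}, a thinned \code{series} data.frame
#'   (t, cooperation, frac_fr, frac_eff, frac_rival, mean_m1, mean_m2),
#'   the \code{config} and the \code{seed}.  Identical configs and seeds
#'   reproduce results bit-identically.
#' @export
run_well_mixed <- function(config) {
  stopifnot(inherits(config, "well_mixed_config"))
  set.seed(config$seed)
  raw <- run_well_mixed_cpp(config$N, config$b, config$e, config$m,
                            config$sigma_in, config$steps, config$burn_in,
                            config$thin)
  finish_run(raw, config, "well-mixed")
}

#' Evolve a group-structured population in the small-mutation limit
#'
#' Each of M groups is occupied by one resident strategy.  Per time
#' step a focal group (resident X) is picked uniformly; with probability
#' r a mutant Y from the two-step sampler fixes there with probability
#' \code{rho_XY}, otherwise a random other group's resident Y replaces X
#' with the out-group transition probability
#' \code{T_XY = fermi(pi_XX, pi_YY, sigma_out) * rho_XY}.  Initial
#' residents are independent draws of the mutant sampler.  Observables
#' are time averages (after burn-in) of group-mean resident properties.
#'
#' @param config a [group_config()].
#' @return an \code{"fr_run"} object, see [run_well_mixed()].
#' @export
run_group_structured <- function(config) {
  stopifnot(inherits(config, "group_config"))
  set.seed(config$seed)
  raw <- run_group_structured_cpp(config$M, config$N, config$b, config$e,
                                  config$m, config$sigma_in,
                                  config$sigma_out, config$r, config$steps,
                                  config$burn_in, config$thin)
  finish_run(raw, config, "group-structured")
}

#' @export
print.fr_run <- function(x, ...) {
  o <- x$observables
  cat(sprintf("<fr_run> %s, seed %d\n", x$mode, x$seed))
  cat(sprintf("  mean cooperation: %.4f\n", o$mean_cooperation))
  cat(sprintf("  class fractions:  FR %.4f | non-FR efficient %.4f | non-FR rival %.4f\n",
              o$frac_fr, o$frac_eff, o$frac_rival))
  cat(sprintf("  mean memory:      (m1, m2) = (%.3f, %.3f)\n",
              o$mean_m1, o$mean_m2))
  invisible(x)
}
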