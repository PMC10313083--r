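# Efficiency, rivalry and friendly-rival classification.

#' Is a strategy efficient (a self-cooperator)?
#'
#' A strategy is efficient when its self-play cooperation level tends to
#' 1 in the vanishing-error limit.  Numerically the judgement uses the
#' stationary self-cooperation at a small error rate against a
#' threshold; the decision is insensitive to the threshold choice.
#'
#' @param s a strategy (any form accepted by [ipd_strategy()]).
#' @param e error rate used for the numerical judgement (default 1e-4).
#' @param threshold efficiency threshold on gamma_pp (default 0.99).
#' @return logical.
#' @examples
#' is_efficient("WSLS")  # TRUE: WSLS recovers cooperation after an error
#' is_efficient("TFT")   # FALSE: TFT locks into retaliation
#' @export
is_efficient <- function(s, e = 1e-4, threshold = 0.99) {
  s <- ipd_strategy(s)
  is_efficient_cpp(s$table, e, threshold)
}

#' Is a strategy a rival (unbeatable)?
#'
#' A rival never allows any co-player a strictly higher long-term payoff,
#' for any co-player strategy and any initial state, at zero error.  The
#' test builds the rivalry graph on the strategy's full-memory state
#' space -- two outgoing edges per state (the co-player's action is
#' free), weighted by the sign of the per-round payoff difference -- and
#' declares rivalry iff no cycle has negative total weight
#' (Floyd-Warshall negative-cycle detection).
#'
#' @param s a strategy.
#' @return logical.
#' @examples
#' is_rival("TFT")   # TRUE
#' is_rival("WSLS")  # FALSE: AllD exploits WSLS
#' @export
is_rival <- function(s) {
  s <- ipd_strategy(s)
  is_rival_cpp(s$table)
}

#' Is a strategy a friendly rival?
#'
#' Friendly rivals are simultaneously efficient and rival: they fully
#' cooperate with themselves yet never fall behind any co-player.  They
#' exist only when the total memory m1 + m2 is at least 4.
#'
#' @inheritParams is_efficient
#' @export
is_friendly_rival <- function(s, e = 1e-4, threshold = 0.99) {
  is_efficient(s, e, threshold) && is_rival(s)
}

#' Classify a strategy into the four reporting categories
#'
#' @inheritParams is_efficient
#' @return a list with logical \code{efficient} and \code{rival}, the
#'   reporting \code{label} (one of \code{"FR"}, \code{"non-FR
#'   efficient"}, \code{"non-FR rival"}, \code{"other"}), and the exact
#'   memory lengths \code{m1}, \code{m2}.
#' @export
classify_strategy <- function(s, e = 1e-4, threshold = 0.99) {
  s <- ipd_strategy(s)
  eff <- is_efficient(s, e, threshold)
  riv <- is_rival(s)
  ml <- memory_lengths(s)
  label <- if (eff && riv) "FR"
           else if (eff) "non-FR efficient"
           else if (riv) "non-FR rival"
           else "other"
  list(efficient = eff, rival = riv, label = label,
       m1 = ml[["m1"]], m2 = ml[["m2"]])
}

class_labels <- c("other", "non-FR efficient", "non-FR rival", "FR")
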