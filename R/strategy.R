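# Deterministic memory-(m1, m2) strategies: construction, memory-length
# determination, lifting/canonicalization, text serialization.

#' Construct a deterministic iterated-game strategy
#'
#' A strategy of memory capacity \code{m_cap} prescribes C (1) or D (0)
#' for each of the 2^(2 m_cap) joint history profiles.  Profiles are
#' indexed by \code{i = A * 2^m_cap + B}, where \code{A} encodes the
#' focal player's own last moves and \code{B} the co-player's, with the
#' most recent move in the lowest bit and C encoded as 1.
#'
#' @param x one of: a preset name (see [strategy_names()]), a serialized
#'   strategy string of the form \code{"m:<hex>"} as produced by
#'   [strategy_encode()], or a 0/1 vector of length 2^(2 m_cap) giving
#'   the prescription table in profile-index order.
#' @param m_cap memory capacity (0--3); required only when \code{x} is a
#'   table whose length is ambiguous (it never is, so this is normally
#'   omitted and validated against the table length when given).
#' @return an object of class \code{"ipd_strategy"} with fields
#'   \code{m_cap} and \code{table}.
#' @examples
#' wsls <- ipd_strategy("WSLS")
#' memory_lengths(wsls)
#' ipd_strategy(c(1, 0, 0, 1))  # the same table, index order (DD, DC, CD, CC)
#' @export
ipd_strategy <- function(x, m_cap = NULL) {
  if (inherits(x, "ipd_strategy")) return(x)
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    if (grepl("^[0-3]:", x)) return(strategy_decode(x))
    return(make_named(x))
  }
  if (!is.numeric(x)) stop("`x` must be a name, an \"m:<hex>\" string or a 0/1 table")
  if (anyNA(x) || !all(x %in% c(0, 1)))
    stop("strategy tables must be deterministic: entries 0 (D) or 1 (C) only")
  table <- as.integer(x)
  m <- match(length(table), 2^(2 * (0:3))) - 1L
  if (is.na(m))
    stop("strategy table length must be 2^(2*m_cap) for m_cap in 0..3, got ",
         length(table))
  if (!is.null(m_cap) && as.integer(m_cap) != m)
    stop("table length ", length(table), " does not match m_cap = ", m_cap)
  new_strategy(m, table)
}

new_strategy <- function(m_cap, table) {
  structure(list(m_cap = as.integer(m_cap), table = as.integer(table)),
            class = "ipd_strategy")
}

# canonical memory-one 4-tuples (p_CC, p_CD, p_DC, p_DD)
.presets_m1 <- list(
  TFT  = c(1, 0, 1, 0),
  WSLS = c(1, 0, 0, 1),
  GRIM = c(1, 0, 0, 0)
)

#' Named preset strategies
#'
#' Available presets: \code{AllC}, \code{AllD} (memory capacity 0) and
#' \code{TFT}, \code{WSLS}, \code{GRIM} (memory capacity 1, defined by
#' their \code{(p_CC, p_CD, p_DC, p_DD)} tuples: TFT = (1,0,1,0),
#' WSLS = (1,0,0,1), GRIM = (1,0,0,0)).
#'
#' @param name preset name (case-insensitive).
#' @return an \code{ipd_strategy}.
#' @export
make_named <- function(name) {
  key <- toupper(name)
  if (key == "ALLC") return(new_strategy(0L, 1L))
  if (key == "ALLD") return(new_strategy(0L, 0L))
  p <- .presets_m1[[key]]
  if (is.null(p))
    stop("unknown strategy name: ", name, " (known: ",
         paste(strategy_names(), collapse = ", "), ")")
  # map (p_CC, p_CD, p_DC, p_DD) onto profile indices i = a1*2 + b1
  table <- integer(4)
  table[0 + 1] <- p[4]  # (a1, b1) = (D, D)
  table[1 + 1] <- p[3]  # (D, C)
  table[2 + 1] <- p[2]  # (C, D)
  table[3 + 1] <- p[1]  # (C, C)
  new_strategy(1L, table)
}

#' @rdname make_named
#' @export
strategy_names <- function() c("AllC", "AllD", "TFT", "WSLS", "GRIM")

#' Exact memory lengths of a strategy
#'
#' Determines the minimal pair (m1, m2) such that the prescription
#' depends only on the focal player's last m1 moves and the co-player's
#' last m2 moves, by testing dependence on each history depth from the
#' capacity downward (the deeper rounds act as wildcards once shown to
#' be irrelevant).
#'
#' @param s an [ipd_strategy()].
#' @return named integer vector \code{c(m1 = , m2 = )}.
#' @examples
#' memory_lengths(ipd_strategy("TFT"))   # (0, 1)
#' memory_lengths(ipd_strategy("AllD"))  # (0, 0)
#' @export
memory_lengths <- function(s) {
  s <- ipd_strategy(s)
  memory_lengths_cpp(s$table)
}

#' Represent a strategy at a different memory capacity
#'
#' Lifting to a larger capacity pads the table so the added history depth
#' is ignored; the behavior and the exact memory lengths are unchanged.
#' Shrinking is allowed down to the minimal capacity max(m1, m2).
#'
#' @param s an [ipd_strategy()].
#' @param m_target target capacity in 0..3; must be at least
#'   \code{max(memory_lengths(s))}.
#' @export
strategy_lift <- function(s, m_target) {
  s <- ipd_strategy(s)
  m_target <- as.integer(m_target)
  if (m_target < 0L || m_target > 3L) stop("m_target must be in 0..3")
  new_strategy(m_target, reindex_cpp(s$table, m_target))
}

#' Canonicalize a strategy to its minimal memory capacity
#'
#' Two behaviorally identical strategies held at different capacities
#' have identical canonical forms (and hence identical encodings).
#'
#' @param s an [ipd_strategy()].
#' @export
strategy_canonicalize <- function(s) {
  s <- ipd_strategy(s)
  ml <- memory_lengths(s)
  strategy_lift(s, max(ml))
}

#' Serialize / deserialize a strategy
#'
#' The text form is \code{"m:<hex>"}: the memory capacity, a colon, and
#' the table bits as a hexadecimal number (profile index 0 in the lowest
#' bit).  For example WSLS is \code{"1:9"} and TFT is \code{"1:a"}.
#'
#' @param s an [ipd_strategy()].
#' @return \code{strategy_encode}: a string; \code{strategy_decode}: an
#'   \code{ipd_strategy}.
#' @export
strategy_encode <- function(s) {
  s <- ipd_strategy(s)
  nyb <- max(1L, length(s$table) %/% 4L)
  hex <- vapply(seq_len(nyb), function(k) {
    lo <- (k - 1L) * 4L
    bits <- s$table[(lo + 1L):min(lo + 4L, length(s$table))]
    sprintf("%x", sum(bits * 2L^(seq_along(bits) - 1L)))
  }, character(1))
  paste0(s$m_cap, ":", paste(rev(hex), collapse = ""))
}

#' @rdname strategy_encode
#' @param code a string of the form \code{"m:<hex>"}.
#' @export
strategy_decode <- function(code) {
  stopifnot(is.character(code), length(code) == 1L)
  parts <- strsplit(code, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !grepl("^[0-3]$", parts[1]) ||
      !grepl("^[0-9a-fA-F]+$", parts[2]))
    stop("malformed strategy code: ", code)
  m <- as.integer(parts[1])
  n <- 2L^(2L * m)
  nyb <- strtoi(rev(strsplit(tolower(parts[2]), "")[[1]]), base = 16L)
  bits <- integer(max(n, 4L * length(nyb)))
  for (k in seq_along(nyb))
    bits[(k - 1L) * 4L + 1:4] <- bitwAnd(nyb[k] %/% c(1L, 2L, 4L, 8L), 1L)
  if (any(bits[-seq_len(n)] != 0L))
    stop("strategy code has more bits than 2^(2*", m, "): ", code)
  new_strategy(m, bits[seq_len(n)])
}

#' Test behavioral equality of two strategies
#'
#' Strategies are compared after canonicalization to minimal memory, so
#' representations at different capacities compare equal when they
#' prescribe the same behavior.
#'
#' @param a,b strategies (any form accepted by [ipd_strategy()]).
#' @export
strategy_equal <- function(a, b) {
  identical(strategy_canonicalize(a)$table, strategy_canonicalize(b)$table) &&
    strategy_canonicalize(a)$m_cap == strategy_canonicalize(b)$m_cap
}

#' @export
print.ipd_strategy <- function(x, ...) {
  ml <- memory_lengths(x)
  cat(sprintf("<ipd_strategy> %s  m_cap=%d  memory=(%d,%d)\n",
              strategy_encode(x), x$m_cap, ml[["m1"]], ml[["m2"]]))
  invisible(x)
}

#' @export
format.ipd_strategy <- function(x, ...) strategy_encode(x)
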