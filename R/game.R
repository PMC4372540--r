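#' Moves and outcomes
#'
#' The two moves of the Prisoner's Dilemma, cooperate (`"C"`) and defect
#' (`"D"`), and the four joint outcomes of a round in canonical order
#' `(CC, CD, DC, DD)`, always read from the focal player's perspective
#' (own move first). All strategy vectors, stationary distributions and
#' transition matrices in the package use this outcome order.
#'
#' @format Character vectors of length 2 (`MOVES`) and 4 (`OUTCOMES`).
#' @export
MOVES <- c("C", "D")

#' @rdname MOVES
#' @export
OUTCOMES <- c("CC", "CD", "DC", "DD")

#' Swap the perspective of an outcome
#'
#' Maps each outcome to what the other player sees in the same round:
#' `CD` and `DC` exchange, `CC` and `DD` are fixed.
#'
#' @param outcome Character vector of outcomes (`"CC"`, `"CD"`, `"DC"`, `"DD"`).
#' @return Character vector of the same length.
#' @export
#' @examples
#' swap_outcome(c("CC", "CD", "DC", "DD"))
swap_outcome <- function(outcome) {
  idx <- outcome_index(outcome)
  OUTCOMES[c(1L, 3L, 2L, 4L)][idx]
}

#' @rdname swap_outcome
#' @return `outcome_index()` returns the 1-based position of each outcome in
#'   the canonical `(CC, CD, DC, DD)` order.
#' @export
outcome_index <- function(outcome) {
  idx <- match(outcome, OUTCOMES)
  if (anyNA(idx)) {
    abort(paste0("invalid outcome(s): ",
                 paste(unique(outcome[is.na(idx)]), collapse = ", ")))
  }
  idx
}

#' Prisoner's Dilemma payoff matrices
#'
#' `game_matrix()` builds a 2x2 symmetric game from its four payoffs in the
#' conventional `(R, S, T, P)` notation: `R` for mutual cooperation, `S` to a
#' cooperator meeting a defector, `T` to that defector, and `P` for mutual
#' defection. `donation_matrix()` builds the donation-game special case in
#' which cooperation means paying a cost `c` to confer a benefit `b` on the
#' partner, so `(R, S, T, P) = (b - c, -c, b, 0)`; it requires `0 < c < b`.
#' The package default throughout is `donation_matrix(3, 1)`, i.e.
#' `(2, -1, 3, 0)`.
#'
#' @param R,S,T,P Numeric payoffs.
#' @param check_pd If `TRUE` (default), require the Prisoner's Dilemma
#'   ordering `T > R > P > S`.
#' @return An object of class `game_matrix`: a list with elements `R`, `S`,
#'   `T`, `P`.
#' @export
#' @examples
#' donation_matrix(3, 1)
#' game_matrix(3, 0, 5, 1)
game_matrix <- function(R, S, T, P, check_pd = TRUE) {
  vals <- c(R = R, S = S, T = T, P = P)
  if (!all(is.finite(vals))) abort("payoffs must be finite numbers")
  if (check_pd && !(T > R && R > P && P > S)) {
    abort("not a Prisoner's Dilemma: need T > R > P > S")
  }
  structure(list(R = R, S = S, T = T, P = P), class = "game_matrix")
}

#' @param b,c Benefit and cost of cooperation, `0 < c < b`.
#' @rdname game_matrix
#' @export
donation_matrix <- function(b = 3, c = 1) {
  if (!(c > 0 && c < b)) abort("donation game requires 0 < c < b")
  game_matrix(R = b - c, S = -c, T = b, P = 0)
}

#' @export
print.game_matrix <- function(x, ...) {
  cat(sprintf("<game_matrix> (R, S, T, P) = (%g, %g, %g, %g)\n",
              x$R, x$S, x$T, x$P))
  invisible(x)
}

# payoff vectors over outcomes (CC, CD, DC, DD)
payoffs_focal <- function(matrix) c(matrix$R, matrix$S, matrix$T, matrix$P)
payoffs_opponent <- function(matrix) c(matrix$R, matrix$T, matrix$S, matrix$P)

#' Payoffs of a single round
#'
#' Returns the pair of payoffs earned in one round, focal player first:
#' `CC -> (R, R)`, `CD -> (S, T)`, `DC -> (T, S)`, `DD -> (P, P)`.
#'
#' @param outcome A single outcome (`"CC"`, `"CD"`, `"DC"`, `"DD"`).
#' @param matrix A [game_matrix()].
#' @return Numeric vector of length two, `c(focal, opponent)`.
#' @export
#' @examples
#' payoff_pair("CD", donation_matrix(3, 1))
payoff_pair <- function(outcome, matrix) {
  i <- outcome_index(outcome)
  stopifnot(length(i) == 1L)
  c(focal = payoffs_focal(matrix)[i], opponent = payoffs_opponent(matrix)[i])
}

#' Apply move noise
#'
#' Flips each move independently with probability `epsilon`, the ambient
#' execution-error model of the simulations: a player intends a move and the
#' realized (observed) move differs with probability `epsilon`. Exactly one
#' uniform random draw is consumed per move.
#'
#' @param move Character vector of intended moves (`"C"` / `"D"`).
#' @param epsilon Flip probability, in `[0, 1/2]`.
#' @return Character vector of realized moves.
#' @export
#' @examples
#' set.seed(1)
#' table(apply_noise(rep("C", 1000), 0.05))
apply_noise <- function(move, epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L ||
      epsilon < 0 || epsilon > 0.5) {
    abort("epsilon must be a single probability in [0, 1/2]")
  }
  bad <- !move %in% MOVES
  if (any(bad)) abort("moves must be \"C\" or \"D\"")
  flip <- runif(length(move)) < epsilon
  out <- move
  out[flip] <- ifelse(move[flip] == "C", "D", "C")
  out
}
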