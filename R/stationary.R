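#' Noise-adjusted strategy vector
#'
#' Under move noise `epsilon`, a player intending to cooperate with
#' probability `p` is observed to cooperate with probability
#' `(1 - 2 epsilon) p + epsilon`. Stationary quantities "under noise" are
#' computed on these effective vectors, which for memory-one play is
#' exactly equivalent in distribution to modelling the noise as a separate
#' channel.
#'
#' @param p Strategy vector.
#' @param epsilon Move-flip probability in `[0, 1/2]`.
#' @return The effective strategy vector.
#' @export
#' @examples
#' effective_vector(ALLC, 0.05)
effective_vector <- function(p, epsilon) {
  p <- as_strategy(p)
  if (epsilon < 0 || epsilon > 0.5) abort("epsilon must lie in [0, 1/2]")
  (1 - 2 * epsilon) * p + epsilon
}

#' One-round transition matrix of a strategy pair
#'
#' The repeated game between memory-one strategies `p` (focal) and `q`
#' (opponent) is a Markov chain on the four outcomes `(CC, CD, DC, DD)`
#' seen from the focal perspective. Row `o` gives the distribution of the
#' next outcome: the focal player cooperates with probability `p[o]` while
#' the opponent, who sees the perspective-swapped outcome, cooperates with
#' probability `q[swap(o)]` (`q` conditions on `CD` where the focal player
#' sees `DC`, and vice versa).
#'
#' @param p,q Strategy vectors (focal, opponent).
#' @return A 4x4 row-stochastic matrix with outcome dimnames.
#' @export
transition_matrix <- function(p, q) {
  p <- as_strategy(p, "p")
  q <- as_strategy(q, "q")
  qs <- q[c(1L, 3L, 2L, 4L)]
  M <- cbind(p * qs, p * (1 - qs), (1 - p) * qs, (1 - p) * (1 - qs))
  dimnames(M) <- list(OUTCOMES, OUTCOMES)
  M
}

# Press-Dyson matrix D(p, q, f); columns as printed in the determinant form
pd_matrix <- function(p, q, f) {
  rbind(c(-1 + p[1] * q[1], -1 + p[1], -1 + q[1], f[1]),
        c(p[2] * q[3],      -1 + p[2], q[3],      f[2]),
        c(p[3] * q[2],      p[3],      -1 + q[2], f[3]),
        c(p[4] * q[4],      p[4],      q[4],      f[4]))
}

#' Stationary mean via the Press-Dyson determinant
#'
#' For an ergodic chain between memory-one strategies `p` and `q`, the
#' stationary mean of any per-outcome vector `f` equals the ratio of two
#' 4x4 determinants, `D(p, q, f) / D(p, q, 1)`, where `D` is the
#' Press-Dyson determinant built from the strategy entries (the opponent's
#' entries appear perspective-swapped). This gives exact long-run scores
#' without simulating the chain.
#'
#' @param p,q Strategy vectors (focal, opponent).
#' @param f Numeric vector of length 4 over `(CC, CD, DC, DD)`.
#' @return The stationary mean of `f`.
#' @section Degenerate chains: when `|D(p, q, 1)| < 1e-12` the chain is not
#'   ergodic (possible only when some entries are exactly 0 or 1 at zero
#'   noise) and an error of class `ipdpop_degenerate` is signalled; use
#'   [stationary_scores()], which falls back to power iteration.
#' @export
#' @examples
#' p <- effective_vector(TFT, 0.05)
#' press_dyson_score(p, p, payoffs_focal(donation_matrix(3, 1)))
press_dyson_score <- function(p, q, f) {
  p <- as_strategy(p, "p")
  q <- as_strategy(q, "q")
  stopifnot(is.numeric(f), length(f) == 4L)
  den <- det(pd_matrix(p, q, rep(1, 4)))
  if (abs(den) < 1e-12) {
    abort("degenerate (non-ergodic) chain: |D(p, q, 1)| < 1e-12",
          class = "ipdpop_degenerate")
  }
  det(pd_matrix(p, q, f)) / den
}

# lazy power iteration; init is an outcome index (1..4) or NULL for uniform
power_stationary <- function(p, q, init = NULL, max_iter = 10000, tol = 1e-13) {
  M <- transition_matrix(p, q)
  s <- if (is.null(init)) rep(0.25, 4) else replace(rep(0, 4), init, 1)
  for (i in seq_len(max_iter)) {
    ns <- 0.5 * (as.vector(s %*% M) + s)
    ns <- ns / sum(ns)
    if (sum(abs(ns - s)) < tol) {
      s <- ns
      break
    }
    s <- ns
  }
  stats::setNames(s, OUTCOMES)
}

#' Stationary distribution and long-term scores of a strategy pair
#'
#' Computes the stationary outcome distribution of the repeated game
#' between memory-one strategies `p` and `q` under move noise `epsilon`,
#' and both players' long-term mean payoffs, using the Press-Dyson
#' determinant on the noise-adjusted ([effective_vector()]) strategies.
#' For any `epsilon > 0` the chain is ergodic and the determinant applies;
#' at `epsilon = 0` degenerate (absorbing or periodic) chains fall back to
#' power iteration started from mutual cooperation, i.e. both players
#' opening with `C`, which makes the reported result the
#' initial-condition-dependent long-run average from that standard start.
#'
#' @param p,q Strategy vectors (focal, opponent).
#' @param matrix A [game_matrix()].
#' @param epsilon Move noise in `[0, 1/2]`.
#' @return An object of class `stationary_result`: list with `dist` (named
#'   4-vector over outcomes from the focal perspective), `score_focal` and
#'   `score_opp`.
#' @export
#' @examples
#' stationary_scores(ALLD, ALLC, donation_matrix(3, 1))   # (3, -1)
#' stationary_scores(TFT, TFT, donation_matrix(3, 1), epsilon = 0.05)
stationary_scores <- function(p, q, matrix = donation_matrix(3, 1), epsilon = 0) {
  pe <- effective_vector(p, epsilon)
  qe <- effective_vector(q, epsilon)
  Sx <- payoffs_focal(matrix)
  Sy <- payoffs_opponent(matrix)
  den <- det(pd_matrix(pe, qe, rep(1, 4)))
  if (abs(den) >= 1e-12) {
    dist <- vapply(1:4, function(i) {
      det(pd_matrix(pe, qe, replace(rep(0, 4), i, 1))) / den
    }, numeric(1))
  } else {
    dist <- power_stationary(pe, qe, init = 1L)
  }
  dist <- pmax(dist, 0)
  dist <- dist / sum(dist)
  names(dist) <- OUTCOMES
  structure(list(dist = dist,
                 score_focal = sum(dist * Sx),
                 score_opp = sum(dist * Sy),
                 epsilon = epsilon),
            class = "stationary_result")
}

#' @export
print.stationary_result <- function(x, ...) {
  cat(sprintf("<stationary_result> eps = %g\n", x$epsilon))
  cat("  dist:", paste(sprintf("%s %.4f", OUTCOMES, x$dist), collapse = ", "), "\n")
  cat(sprintf("  scores: focal %.4f, opponent %.4f\n", x$score_focal, x$score_opp))
  invisible(x)
}

#' @export
#' @method tidy stationary_result
tidy.stationary_result <- function(x, ...) {
  tibble(outcome = OUTCOMES, probability = unname(x$dist))
}

#' @export
#' @method glance stationary_result
glance.stationary_result <- function(x, ...) {
  tibble(score_focal = x$score_focal, score_opp = x$score_opp,
         epsilon = x$epsilon)
}
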