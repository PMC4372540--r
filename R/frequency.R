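#' Frequency-dependent mean score difference
#'
#' With `m` players of an invading type I among `N` total (the remaining
#' `N - m` of resident type G), and pairwise stationary scores `S_II`,
#' `S_IG`, `S_GI`, `S_GG` (first index: the scorer), the difference in mean
#' stationary payoff between a type-I and a type-G player is
#' \deqn{\bar S_I - \bar S_G = \frac{m-1}{N-1} S_{II} + \frac{N-m}{N-1} S_{IG}
#'   - \frac{m}{N-1} S_{GI} - \frac{N-m-1}{N-1} S_{GG}.}
#' At `N = 2` this reduces exactly to `S_IG - S_GI` (the head-to-head
#' case), and as `N` grows it approaches
#' `f (S_II - S_GI) + (1 - f)(S_IG - S_GG)` with `f = m/N`.
#'
#' @param s_ii,s_ig,s_gi,s_gg Pairwise stationary scores.
#' @param N Population size (>= 2).
#' @param m Invader count(s), each in `1..N-1`; vectorized.
#' @return Numeric vector of score differences, one per `m`.
#' @export
#' @examples
#' mean_score_difference(2, 3, -1, 2, N = 100, m = 1:99)
mean_score_difference <- function(s_ii, s_ig, s_gi, s_gg, N, m) {
  if (N < 2) abort("N must be at least 2")
  if (any(m < 1 | m > N - 1)) abort("m must lie in 1..N-1")
  ((m - 1) * s_ii + (N - m) * s_ig - m * s_gi - (N - m - 1) * s_gg) / (N - 1)
}

# resolve the four pairwise stationary scores for an invader spec
# (vector or tag_pair) against a resident vector
pairwise_scores <- function(invader, resident, matrix, epsilon) {
  resident <- as_strategy(resident, "resident")
  if (inherits(invader, "tag_pair")) {
    ii <- stationary_scores(invader$vs_self, invader$vs_self, matrix, epsilon)
    ig <- stationary_scores(invader$vs_other, resident, matrix, epsilon)
  } else {
    invader <- as_strategy(invader, "invader")
    ii <- stationary_scores(invader, invader, matrix, epsilon)
    ig <- stationary_scores(invader, resident, matrix, epsilon)
  }
  gg <- stationary_scores(resident, resident, matrix, epsilon)
  list(s_ii = ii$score_focal, s_ig = ig$score_focal,
       s_gi = ig$score_opp, s_gg = gg$score_focal)
}

#' Score-difference curve across invader fractions
#'
#' Evaluates the mean stationary score difference between invader and
#' resident at every invader count `m` in `1..N-1`, using exact stationary
#' pairwise scores under noise `epsilon`. The invader may be a plain
#' memory-one vector or a [tag_pair()] (which plays `vs_self` in
#' invader-invader games and `vs_other` against the resident); the
#' resident plays a single vector in all games.
#'
#' @param invader Strategy vector or [tag_pair()].
#' @param resident Strategy vector.
#' @param matrix A [game_matrix()].
#' @param epsilon Move noise.
#' @param N Population size.
#' @return A tibble of class `ipd_curve` with columns `m`, `f` (= m/N) and
#'   `difference`.
#' @export
#' @examples
#' score_difference_curve(con_def(), ALLC, N = 20)
score_difference_curve <- function(invader, resident,
                                   matrix = donation_matrix(3, 1),
                                   epsilon = 0.05, N = 100) {
  sc <- pairwise_scores(invader, resident, matrix, epsilon)
  m <- seq_len(N - 1)
  out <- tibble(m = m, f = m / N,
                difference = mean_score_difference(sc$s_ii, sc$s_ig,
                                                   sc$s_gi, sc$s_gg, N, m))
  class(out) <- c("ipd_curve", class(out))
  attr(out, "epsilon") <- epsilon
  attr(out, "N") <- N
  out
}

#' Best response at a given population mixture
#'
#' Among a finite list of candidate invader strategies, returns the one
#' maximizing the mean stationary score difference against the resident at
#' invader count `m` out of `N`. Which candidate wins typically depends on
#' `m`: cooperation tends to win in the minority and defection in the
#' majority, so no memory-one strategy is optimal at every mixture.
#'
#' @param candidates Named list of strategy vectors or [tag_pair()]s.
#' @param resident Resident strategy vector.
#' @param matrix A [game_matrix()].
#' @param epsilon Move noise.
#' @param N Population size.
#' @param m Invader count.
#' @return The winning candidate, with attribute `"name"`; ties are broken
#'   by list order.
#' @export
#' @examples
#' best_response_at_fraction(list(ALLC = ALLC, ALLD = ALLD), TFT,
#'                           epsilon = 0.05, N = 100, m = 1)
best_response_at_fraction <- function(candidates, resident,
                                      matrix = donation_matrix(3, 1),
                                      epsilon = 0.05, N = 100, m = 1) {
  if (length(candidates) == 0L) abort("need at least one candidate")
  vals <- vapply(candidates, function(cand) {
    sc <- pairwise_scores(cand, resident, matrix, epsilon)
    mean_score_difference(sc$s_ii, sc$s_ig, sc$s_gi, sc$s_gg, N, m)
  }, numeric(1))
  best <- which.max(vals)  # which.max takes the first maximum: list order
  out <- candidates[[best]]
  attr(out, "name") <- names(candidates)[best] %||% as.character(best)
  out
}
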