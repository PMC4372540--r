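#' Beta posterior mean of a cooperation probability
#'
#' The information player models each conditional cooperation probability
#' of an opponent as a binomial parameter with a uniform prior; after
#' observing `m` cooperations in `n` conditioning rounds the posterior
#' expectation is `(m + 1) / (n + 2)`.
#'
#' @param n Number of observations (vectorized).
#' @param m Number of those where the next move was C.
#' @return Posterior mean probabilities.
#' @export
#' @examples
#' posterior_mean(0, 0)  # 0.5
#' posterior_mean(8, 6)  # 0.7
posterior_mean <- function(n, m) {
  if (any(m > n) || any(m < 0) || any(n < 0)) abort("need 0 <= m <= n")
  (m + 1) / (n + 2)
}

#' Per-opponent outcome counts
#'
#' The sufficient statistics an information player keeps about one
#' opponent: for each joint outcome `AB` (own move `A`, opponent move `B`),
#' `n` counts rounds with that outcome that have an observed successor and
#' `m` counts how many of those were followed by opponent cooperation.
#'
#' @param n,m Numeric vectors of length 4 over `(CC, CD, DC, DD)`.
#' @return A list of class `outcome_counts`.
#' @export
outcome_counts <- function(n = rep(0, 4), m = rep(0, 4)) {
  stopifnot(length(n) == 4L, length(m) == 4L, all(m <= n), all(m >= 0))
  structure(list(n = stats::setNames(as.numeric(n), OUTCOMES),
                 m = stats::setNames(as.numeric(m), OUTCOMES)),
            class = "outcome_counts")
}

#' Deterministic tie-break by MD5 hash
#'
#' When the infogain move expectations tie exactly, the information player
#' breaks the tie deterministically from the shared history of play: it
#' takes the MD5 digest of the chronological outcome string (two characters
#' per round: own move then opponent move, e.g. `"CCDC"` for rounds CC then
#' DC; empty for round one) and plays C if the least-significant bit of the
#' final digest byte is 0, else D. Because the history is common knowledge
#' within a pair, each player can also evaluate the rule on the opponent's
#' perspective string and so predict the other's tie-break.
#'
#' @param history The perspective history string.
#' @return `"C"` or `"D"`.
#' @export
#' @examples
#' md5_tiebreak("")  # digest d41d8...427e, last byte 0x7e, LSB 0 -> "C"
md5_tiebreak <- function(history) {
  stopifnot(is.character(history), length(history) == 1L)
  if (cpp_md5_lsb(history) == 0L) "C" else "D"
}

#' Infogain move selection
#'
#' During its information-gain phase the player steers the game toward the
#' outcomes it knows least about. Given the current outcome `ab` it picks
#' the own-move `A` minimizing the expected count of the next outcome,
#' `E(n_AB | ab) = sum_B p(B | ab) n_AB`, where `p(C | ab)` is the
#' [posterior_mean()] of the opponent's cooperation after `ab`. With no
#' previous outcome both opponent responses are weighted 1/2. Exact ties
#' go to [md5_tiebreak()] on the history string.
#'
#' @param counts An [outcome_counts()].
#' @param last_outcome Previous outcome (`"CC"`...`"DD"`) or `NULL`.
#' @param history History string for the tie-break.
#' @return `"C"` or `"D"`.
#' @export
#' @examples
#' infogain_move(outcome_counts())  # round 1: tie -> md5_tiebreak("") -> "C"
infogain_move <- function(counts, last_outcome = NULL, history = "") {
  stopifnot(inherits(counts, "outcome_counts"))
  last <- if (is.null(last_outcome)) -1L else outcome_index(last_outcome) - 1L
  mv <- cpp_infogain_move(unname(counts$n), unname(counts$m), last, history)
  MOVES[mv + 1L]
}

#' Self-recognition by binomial test (infogain phase)
#'
#' Under the null hypothesis that an opponent is another information player
#' executing the (predictable) infogain rule, each of its `n` observed
#' moves deviates from the predicted move only through noise, independently
#' with probability `epsilon`. The upper binomial tail of the observed
#' mismatch count `e` is the p-value; at or below `alpha` the opponent is
#' confidently classified as a group player (GP).
#'
#' @param n Rounds observed.
#' @param e Mismatches between observed and predicted infogain moves.
#' @param epsilon Assumed move-error rate.
#' @param alpha Significance level.
#' @return List with `p_value` and `confident_gp`.
#' @export
#' @examples
#' classify_infogain(10, 3, 0.05)  # p ~ 0.0115, not confident at 0.01
classify_infogain <- function(n, e, epsilon, alpha = 0.01) {
  if (e > n || e < 0) abort("need 0 <= e <= n")
  p <- if (e == 0) 1 else pbinom(e - 1, n, epsilon, lower.tail = FALSE)
  list(p_value = p, confident_gp = p <= alpha)
}

#' Log-odds update for self/non-self classification
#'
#' Adds the log likelihood ratio of one observed move to the running
#' log-odds that an opponent is an information player rather than a group
#' player: `L' = L + log(p_if_ip / p_if_gp)`. Probabilities are clamped to
#' `[1e-12, 1 - 1e-12]` so a zero likelihood cannot produce an infinite
#' jump.
#'
#' @param L Current log-odds.
#' @param p_if_ip Probability of the observed move if the opponent is an
#'   information player (infogain prediction with error `epsilon`, or the
#'   HMM marginal likelihood in the groupmax phase).
#' @param p_if_gp Probability of the observed move under the inferred
#'   group-player vector.
#' @return Updated log-odds.
#' @export
update_log_odds <- function(L, p_if_ip, p_if_gp) {
  clamp <- function(x) pmin(pmax(x, 1e-12), 1 - 1e-12)
  L + log(clamp(p_if_ip)) - log(clamp(p_if_gp))
}

#' Two-state HMM forward step (groupmax phase)
#'
#' In the groupmax phase another information player either recognizes me
#' (state ALLC: it cooperates) or does not (state GP-max: it plays its
#' groupmax vector against me). The two hidden states switch with
#' probability `switch_prob` per round. One forward-algorithm step mixes
#' the prior with the switch, scores the observed move under each state's
#' emission (with noise `epsilon`), and renormalizes; the observation's
#' marginal likelihood is returned for use as `p_if_ip` in
#' [update_log_odds()].
#'
#' @param allc_prob Prior probability of the ALLC state.
#' @param observed Observed opponent move (`"C"` / `"D"`).
#' @param p_groupmax_c Cooperation probability of the groupmax state for
#'   the current conditioning outcome (already noise-adjusted).
#' @param epsilon Assumed error rate (emission noise of the ALLC state).
#' @param switch_prob Per-round state-switch probability.
#' @return List with `allc_prob` (posterior) and `likelihood` (marginal).
#' @export
hmm_update <- function(allc_prob, observed, p_groupmax_c, epsilon,
                       switch_prob = 0.01) {
  stopifnot(observed %in% MOVES, allc_prob >= 0, allc_prob <= 1)
  prior <- allc_prob * (1 - switch_prob) + (1 - allc_prob) * switch_prob
  e_allc <- if (observed == "C") 1 - epsilon else epsilon
  e_gp <- if (observed == "C") p_groupmax_c else 1 - p_groupmax_c
  marg <- prior * e_allc + (1 - prior) * e_gp
  post <- if (marg > 0) prior * e_allc / marg else prior
  list(allc_prob = post, likelihood = marg)
}

#' Estimated number of information players in the population
#'
#' The posterior expectation of the count of information players given one
#' log-odds `L_i` per other player: `1 + sum_i 1/(exp(-L_i) + 1)` (the
#' extra count is the player itself).
#'
#' @param log_odds Numeric vector of per-opponent log-odds.
#' @return The expected count `m_bar`.
#' @export
#' @examples
#' estimate_m_bar(rep(0, 99))  # 50.5
estimate_m_bar <- function(log_odds) 1 + sum(plogis(log_odds))

#' Prior log-odds for a newborn player
#'
#' When a birth is detected, the newcomer's prior log-odds of being an
#' information player is `log(m_bar / N)`, the log prior odds implied by
#' the current population-composition estimate.
#'
#' @param m_bar Estimated information-player count, in `[1, N]`.
#' @param N Population size.
#' @return The prior log-odds.
#' @export
new_player_prior <- function(m_bar, N) {
  if (m_bar <= 0) abort("m_bar must be positive")
  log(m_bar / N)
}

#' Groupmax strategy optimization
#'
#' Finds the memory-one vector `q` maximizing the interaction terms of the
#' relative score against the inferred group strategy `p_bar`,
#' \deqn{\frac{N - \bar m}{N - 1} S(q, \bar p) - \frac{\bar m}{N - 1} S(\bar p, q),}
#' where `S(p, q)` is the stationary score of `p` against `q` under noise
#' `epsilon` and `m_bar` the estimated count of information players.
#' Optimization is projected gradient ascent on `[1e-3, 1 - 1e-3]^4`
#' (initial step 0.05 with backtracking, tolerance 1e-6, at most 500
#' iterations) from six starts: ALLC, ALLD, TFT, WSLS, `p_bar` and the
#' previous optimum when supplied.
#'
#' @param p_bar Inferred opponent-group strategy vector.
#' @param m_bar Estimated information-player count.
#' @param N Population size.
#' @param matrix A [game_matrix()].
#' @param epsilon Move noise.
#' @param previous Previous optimum used as a warm start, or `NULL`.
#' @return The optimizing strategy vector, with attribute `"objective"`.
#' @export
#' @examples
#' groupmax_optimize(ALLC, 1, 100, epsilon = 0.05)  # ~ ALLD: exploit pure cooperators
groupmax_optimize <- function(p_bar, m_bar, N, matrix = donation_matrix(3, 1),
                              epsilon = 0, previous = NULL) {
  p_bar <- as_strategy(p_bar, "p_bar")
  stopifnot(m_bar >= 0, m_bar <= N, N >= 2)
  res <- cpp_groupmax_optimize(unname(p_bar), m_bar, as.integer(N),
                               payoffs_focal(matrix), epsilon,
                               if (is.null(previous)) NULL else unname(as_strategy(previous)))
  out <- stats::setNames(res$par, OUTCOMES)
  attr(out, "objective") <- res$value
  out
}

# ---------------------------------------------------------------------------
# A functional, R-level opponent model. This mirrors, step for step, the
# model the compiled population engine keeps per opponent; it exists so the
# inference machinery can be driven and inspected round by round (and
# cross-checked against the engine in the tests).

#' Information player opponent model
#'
#' The per-opponent state of an information player: outcome counts about
#' the opponent's behaviour, mirror counts (what the opponent has seen of
#' me, used to predict its moves and its opinion of me), round and
#' mismatch tallies, the running log-odds of the opponent being an
#' information player, the HMM state probability, and the two perspective
#' history strings. `ip0_choose_move()` and `ip0_observe()` advance the
#' model functionally (they return the updated model).
#'
#' @param prior Initial log-odds (e.g. [new_player_prior()]).
#' @return A list of class `ip0_model`.
#' @export
ip0_model <- function(prior = 0) {
  z <- stats::setNames(numeric(4), OUTCOMES)
  structure(list(n = z, m = z, n2 = z, m2 = z,
                 rounds = 0L, mismatches = 0L,
                 log_odds = prior, log_odds_other = prior,
                 hmm_allc_prob = 0.5, confident_gp = FALSE,
                 history = "", history_opp = "",
                 last_outcome = NULL,
                 pending_pred = NULL, pending_intent = NULL),
            class = "ip0_model")
}

#' @export
print.ip0_model <- function(x, ...) {
  cat(sprintf("<ip0_model> rounds %d, mismatches %d, L %.3f, phase %s\n",
              x$rounds, x$mismatches, x$log_odds,
              if (x$rounds < 10) "infogain" else "groupmax"))
  invisible(x)
}

# phase test against a config
ip0_phase <- function(model, config) {
  if (model$rounds < config$infogain_length) "infogain" else "groupmax"
}

#' Choose the information player's move against one opponent
#'
#' In the infogain phase (first `config$infogain_length` rounds with this
#' opponent) the move is the deterministic [infogain_move()]; the model
#' also records the move an information-player opponent would be predicted
#' to make (the infogain rule evaluated from the opponent's perspective,
#' which is shared knowledge). In the groupmax phase the player cooperates
#' with opponents it believes are information players (`L > 0`) and
#' otherwise samples its current groupmax vector conditioned on the last
#' outcome.
#'
#' @param model An [ip0_model()].
#' @param config An [ip_config()].
#' @param p_groupmax Current groupmax vector (required in groupmax phase).
#' @return List with `move` (intended move) and the updated `model`
#'   (pending prediction bookkeeping).
#' @export
ip0_choose_move <- function(model, config, p_groupmax = NULL) {
  lo <- model$last_outcome
  if (ip0_phase(model, config) == "infogain") {
    mv <- infogain_move(outcome_counts(model$n, model$m), lo, model$history)
    pred <- infogain_move(outcome_counts(model$n2, model$m2),
                          if (is.null(lo)) NULL else swap_outcome(lo),
                          model$history_opp)
    model$pending_pred <- pred
  } else {
    model$pending_pred <- NULL
    if (model$log_odds > 0 || is.null(lo)) {
      mv <- "C"
    } else {
      if (is.null(p_groupmax)) abort("groupmax phase needs p_groupmax")
      pc <- p_groupmax[outcome_index(lo)]
      mv <- if (runif(1) < pc) "C" else "D"
    }
  }
  model$pending_intent <- mv
  list(move = mv, model = model)
}

#' Record one observed round against an opponent
#'
#' Advances the opponent model after a round resolves with realized
#' (post-noise) moves `my_move` and `opp_move`: updates the mismatch count
#' and binomial classification and the opponent's imputed opinion of me
#' (infogain phase) or runs the HMM forward step (groupmax phase), updates
#' the log-odds with the likelihood of the observed move, increments the
#' previous outcome's count pairs, extends the history strings, and at the
#' phase transition seeds the HMM prior with the opponent's imputed
#' posterior that I am an information player.
#'
#' @param model An [ip0_model()].
#' @param my_move,opp_move Realized moves of this round.
#' @param config An [ip_config()]; `epsilon_assumed` must be set.
#' @param pooled_theta Pooled per-outcome cooperation estimates for the
#'   group (length 4), or `NULL` to use this opponent's own counts.
#' @param p_groupmax Current groupmax vector (groupmax phase emissions).
#' @return The updated model.
#' @export
ip0_observe <- function(model, my_move, opp_move, config,
                        pooled_theta = NULL, p_groupmax = NULL) {
  stopifnot(my_move %in% MOVES, opp_move %in% MOVES)
  eps <- config$epsilon_assumed
  if (is.null(eps)) abort("set epsilon_assumed in ip_config() for model stepping")
  lo <- model$last_outcome
  loi <- if (is.null(lo)) NULL else outcome_index(lo)
  theta <- if (is.null(loi)) 0.5
           else if (!is.null(pooled_theta)) pooled_theta[loi]
           else posterior_mean(model$n[loi], model$m[loi])
  p_gp <- if (opp_move == "C") theta else 1 - theta

  if (ip0_phase(model, config) == "infogain") {
    mism <- opp_move != model$pending_pred
    if (mism) model$mismatches <- model$mismatches + 1L
    p_ip <- if (mism) eps else 1 - eps
    # the opponent's imputed view of me
    mism2 <- my_move != model$pending_intent
    p_ip2 <- if (mism2) eps else 1 - eps
    th2 <- if (is.null(loi)) 0.5 else {
      si <- outcome_index(swap_outcome(lo))
      posterior_mean(model$n2[si], model$m2[si])
    }
    p_gp2 <- if (my_move == "C") th2 else 1 - th2
    model$log_odds_other <- update_log_odds(model$log_odds_other, p_ip2, p_gp2)
    cls <- classify_infogain(model$rounds + 1L, model$mismatches, eps, config$alpha)
    if (cls$confident_gp) model$confident_gp <- TRUE
  } else {
    si <- outcome_index(swap_outcome(lo))
    gc <- if (is.null(p_groupmax)) 0.5 else (1 - 2 * eps) * p_groupmax[si] + eps
    h <- hmm_update(model$hmm_allc_prob, opp_move, gc, eps,
                    config$hmm_switch_prob)
    model$hmm_allc_prob <- h$allc_prob
    p_ip <- h$likelihood
  }
  model$log_odds <- update_log_odds(model$log_odds, p_ip, p_gp)

  if (!is.null(loi)) {
    model$n[loi] <- model$n[loi] + 1
    model$m[loi] <- model$m[loi] + (opp_move == "C")
    si <- outcome_index(swap_outcome(lo))
    model$n2[si] <- model$n2[si] + 1
    model$m2[si] <- model$m2[si] + (my_move == "C")
  }
  if (ip0_phase(model, config) == "infogain") {
    model$history <- paste0(model$history, my_move, opp_move)
    model$history_opp <- paste0(model$history_opp, opp_move, my_move)
  }
  model$rounds <- model$rounds + 1L
  if (model$rounds == config$infogain_length) {
    model$hmm_allc_prob <- plogis(model$log_odds_other)
  }
  model$last_outcome <- paste0(my_move, opp_move)
  model
}

#' Simulate one infogain identification duel
#'
#' Plays one information player head-to-head against either a memory-one
#' opponent or a second information player for a fixed number of rounds
#' under move noise, tracking the mismatches between the opponent's
#' observed moves and the moves an information-player twin would have been
#' predicted to make. This is the primitive behind the identification ROC
#' analysis; it is driven entirely by the R-level [ip0_model()] machinery.
#'
#' @param opponent Memory-one vector, or `NULL` for an information-player
#'   opponent.
#' @param rounds Number of rounds.
#' @param epsilon Move noise.
#' @param first_move Opponent's first move (memory-one opponents).
#' @return A tibble with one row per round (`round`, `predicted`,
#'   `my_move`, `opp_move`, `mismatch`) plus attributes `mismatches` and
#'   `p_value`.
#' @export
#' @examples
#' set.seed(1)
#' infogain_duel(zdr_strategy(), rounds = 10, epsilon = 0.05)
infogain_duel <- function(opponent = NULL, rounds = 10, epsilon = 0.05,
                          first_move = "C") {
  config <- ip_config(epsilon_assumed = epsilon)
  model <- ip0_model()
  opp_is_ip <- is.null(opponent)
  if (!opp_is_ip) opponent <- as_strategy(opponent, "opponent")
  rows <- vector("list", rounds)
  for (t in seq_len(rounds)) {
    cm <- ip0_choose_move(model, config)
    model <- cm$model
    pred <- model$pending_pred
    a <- apply_noise(cm$move, epsilon)
    if (opp_is_ip) {
      b <- apply_noise(pred, epsilon)
    } else {
      lo <- model$last_outcome
      pc <- if (is.null(lo)) (if (first_move == "C") 1 else 0)
            else opponent[outcome_index(swap_outcome(lo))]
      pc <- (1 - 2 * epsilon) * pc + epsilon
      b <- if (runif(1) < pc) "C" else "D"
    }
    rows[[t]] <- tibble(round = t, predicted = pred, my_move = a,
                        opp_move = b, mismatch = b != pred)
    model <- ip0_observe(model, a, b, config)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "mismatches") <- model$mismatches
  attr(out, "p_value") <-
    classify_infogain(rounds, model$mismatches, epsilon)$p_value
  out
}
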