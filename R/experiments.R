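#' Identification ROC for the infogain phase
#'
#' Measures how well the information player's self-recognition separates a
#' given opponent strategy from other information players after a fixed
#' number of infogain rounds under move noise. `n_replicates` independent
#' duels are simulated against the opponent (positives: truly non-IP) and
#' against a second information player (negatives), each scored by the
#' binomial-tail p-value of its observed mismatch count; the classification
#' threshold on that p-value is swept to build the empirical ROC.
#'
#' @param opponent Memory-one strategy vector (the positive class).
#' @param rounds Infogain rounds per duel.
#' @param epsilon Move noise.
#' @param n_replicates Duels per class.
#' @param seed Integer seed (positive and negative batches use derived
#'   streams).
#' @param first_move Opponent's first move.
#' @return An object of class `ipd_roc`: list with `points` (tibble
#'   `threshold`, `fpr`, `tpr`), `auc` (trapezoid), and the run settings.
#' @export
#' @examples
#' roc <- roc_identification(zdr_strategy(), rounds = 10, epsilon = 0.05,
#'                           n_replicates = 200, seed = 1)
#' glance(roc)
roc_identification <- function(opponent, rounds = 10, epsilon = 0.05,
                               n_replicates = 2000, seed = 1,
                               first_move = "C") {
  if (rounds < 1) {
    # no observations: the classifier is uninformative by construction
    pts <- tibble(threshold = c(-Inf, Inf), fpr = c(0, 1), tpr = c(0, 1))
    return(structure(list(points = pts, auc = 0.5, rounds = rounds,
                          epsilon = epsilon, n_pos = 0L, n_neg = 0L),
                     class = "ipd_roc"))
  }
  opponent <- as_strategy(opponent, "opponent")
  e_pos <- cpp_infogain_batch(unname(opponent), first_move, FALSE,
                              as.integer(rounds), epsilon,
                              as.integer(n_replicates), as.numeric(seed))
  e_neg <- cpp_infogain_batch(numeric(0), "C", TRUE, as.integer(rounds),
                              epsilon, as.integer(n_replicates),
                              as.numeric(seed) + 1e6)
  tail_p <- function(e) ifelse(e == 0, 1,
                               pbinom(e - 1, rounds, epsilon,
                                      lower.tail = FALSE))
  p_pos <- tail_p(e_pos)
  p_neg <- tail_p(e_neg)
  # flag "group player" when p <= threshold; sweep over observed p-values
  th <- sort(unique(c(p_pos, p_neg)))
  pts <- tibble(
    threshold = c(-Inf, th, Inf),
    fpr = c(0, vapply(th, function(t) mean(p_neg <= t), numeric(1)), 1),
    tpr = c(0, vapply(th, function(t) mean(p_pos <= t), numeric(1)), 1))
  pts <- dplyr::arrange(pts, .data$fpr, .data$tpr)
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, rounds = rounds, epsilon = epsilon,
                 n_pos = length(e_pos), n_neg = length(e_neg)),
            class = "ipd_roc")
}

#' @export
print.ipd_roc <- function(x, ...) {
  cat(sprintf("<ipd_roc> %d rounds, eps = %g, AUC = %.4f (%d + %d duels)\n",
              x$rounds, x$epsilon, x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
#' @method tidy ipd_roc
tidy.ipd_roc <- function(x, ...) x$points

#' @export
#' @method glance ipd_roc
glance.ipd_roc <- function(x, ...) {
  tibble(auc = x$auc, rounds = x$rounds, epsilon = x$epsilon,
         n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Operating point of a ROC curve
#'
#' Linearly interpolates the empirical ROC at a target false-positive
#' rate and returns the corresponding true-positive rate.
#'
#' @param roc An [roc_identification()] result.
#' @param fpr Target false-positive rate.
#' @return The interpolated true-positive rate.
#' @export
roc_tpr_at_fpr <- function(roc, fpr = 0.1) {
  stopifnot(inherits(roc, "ipd_roc"), fpr >= 0, fpr <= 1)
  pts <- dplyr::summarise(dplyr::group_by(roc$points, .data$fpr),
                          tpr = max(.data$tpr), .groups = "drop")
  stats::approx(pts$fpr, pts$tpr, xout = fpr, ties = max, rule = 2)$y
}

#' Fixation odds-ratio table
#'
#' Runs [fixation_experiment()] for each (invader, resident) pair and
#' stacks the records, with deterministic per-pair seeds derived from
#' `seed`. `pairs` is a list of two-element lists (`invader`, `resident`),
#' or use `crossing = TRUE` with a roster to run all ordered pairs.
#'
#' @param pairs List of `list(invader =, resident =)` pairs, or (with
#'   `crossing = TRUE`) a named roster list.
#' @param crossing Build all ordered pairs of distinct roster entries.
#' @inheritParams run_to_fixation
#' @param n_sims Simulations per pair.
#' @return A tibble with one `fixation_record` row per pair.
#' @export
fixation_table <- function(pairs, crossing = FALSE, m0 = 1, N = 100,
                           matrix = donation_matrix(3, 1), epsilon = 0.05,
                           sigma = 1, rule = "imitation", n_sims = 1000,
                           seed = 1, max_generations = 1e6) {
  if (crossing) {
    roster <- lapply(names(pairs), function(nm) as_player_spec(pairs[[nm]], nm))
    idx <- which(outer(seq_along(roster), seq_along(roster), "!="), arr.ind = TRUE)
    pairs <- lapply(seq_len(nrow(idx)), function(r) {
      list(invader = roster[[idx[r, 1]]], resident = roster[[idx[r, 2]]])
    })
  }
  recs <- lapply(seq_along(pairs), function(i) {
    fixation_experiment(pairs[[i]]$invader, pairs[[i]]$resident, m0 = m0,
                        N = N, matrix = matrix, epsilon = epsilon,
                        sigma = sigma, rule = rule, n_sims = n_sims,
                        seed = seed + (i - 1) * 10000,
                        max_generations = max_generations)
  })
  dplyr::bind_rows(recs)
}

#' Invasion success across noise levels
#'
#' One fixation experiment per noise level, reporting odds ratios
#' normalized so 1.0 is neutral fixation.
#'
#' @param invader,resident Player specifications.
#' @param epsilon_grid Noise levels to sweep.
#' @inheritParams run_to_fixation
#' @return A tibble of class `ipd_noise_sweep` (one record row per
#'   `epsilon`); empty grid gives an empty tibble.
#' @export
invasion_vs_noise <- function(invader, resident, epsilon_grid, m0 = 1,
                              N = 100, matrix = donation_matrix(3, 1),
                              sigma = 1, rule = "imitation", n_sims = 1000,
                              seed = 1, max_generations = 1e6) {
  recs <- lapply(seq_along(epsilon_grid), function(i) {
    dplyr::mutate(
      fixation_experiment(invader, resident, m0 = m0, N = N, matrix = matrix,
                          epsilon = epsilon_grid[i], sigma = sigma,
                          rule = rule, n_sims = n_sims,
                          seed = seed + (i - 1) * 10000,
                          max_generations = max_generations),
      epsilon = epsilon_grid[i], .before = 1)
  })
  out <- dplyr::bind_rows(recs)
  if (length(recs) == 0L) {
    out <- tibble(epsilon = numeric(0), invader = character(0),
                  resident = character(0), n_sims = integer(0), k = integer(0),
                  n_unresolved = integer(0), rho = numeric(0),
                  rho_neutral = numeric(0), odds_ratio = numeric(0),
                  p_value = numeric(0))
  }
  class(out) <- c("ipd_noise_sweep", class(out))
  out
}

#' Stationary self-score across noise levels
#'
#' The long-term score a memory-one strategy earns against a copy of
#' itself, as a function of move noise. Noise is what degrades
#' conditionally cooperative strategies (TFT, ZD) in self-play: error
#' cascades push the pair away from mutual cooperation.
#'
#' @param strategy Memory-one vector.
#' @param epsilon_grid Noise levels.
#' @param matrix A [game_matrix()].
#' @return A tibble of class `ipd_self_score` with columns `epsilon`,
#'   `self_score`.
#' @export
#' @examples
#' self_score_vs_noise(zdr_strategy(), c(0, 0.01, 0.05, 0.1))
self_score_vs_noise <- function(strategy, epsilon_grid,
                                matrix = donation_matrix(3, 1)) {
  strategy <- as_strategy(strategy)
  out <- tibble(
    epsilon = as.numeric(epsilon_grid),
    self_score = vapply(epsilon_grid, function(e) {
      stationary_scores(strategy, strategy, matrix, e)$score_focal
    }, numeric(1)))
  class(out) <- c("ipd_self_score", class(out))
  out
}
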