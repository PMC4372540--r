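#' Binomial p-value for observed fixations
#'
#' Under the null hypothesis of neutral drift an invader starting from a
#' single copy fixes with probability `theta = 1/N`; the p-value of
#' observing `k` or more fixations in `n_sims` independent runs is the
#' upper binomial tail at that rate.
#'
#' @param k Observed fixations.
#' @param n_sims Number of simulations.
#' @param N Population size (neutral rate `1/N`).
#' @return The tail probability.
#' @export
#' @examples
#' fixation_pvalue(2, 10, 100)  # ~ 0.0043
fixation_pvalue <- function(k, n_sims, N) {
  if (k > n_sims || k < 0) abort("need 0 <= k <= n_sims")
  if (k == 0) return(1)
  pbinom(k - 1, n_sims, 1 / N, lower.tail = FALSE)
}

# normalize the update-rule argument
match_rule <- function(rule) {
  rlang::arg_match0(rule, c("imitation", "moran", "fermi"))
}

# strip a player_spec to what the engine parses
engine_spec <- function(spec) {
  spec <- as_player_spec(spec)
  unclass(spec)
}

#' Run invasion simulations to fixation
#'
#' Simulates a well-mixed population of `N` players, `m0` of the invading
#' type and `N - m0` of the resident type, under the generation protocol:
#' every generation each player plays one move against every other player
#' (memory-one players conditioning on the pair's last outcome, or their
#' first move for new pairings), moves are flipped with probability
#' `epsilon`, fitness is the mean payoff over the `N - 1` games, and one
#' player dies and is born per generation according to the chosen update
#' rule. Runs continue until one type is extinct (or `max_generations` is
#' hit, reported as `NA`).
#'
#' Update rules: `"imitation"` (default) replaces a uniformly chosen player
#' by a copy of a model drawn from the whole population with probability
#' proportional to `exp(sigma * fitness)`; `"moran"` draws the reproducer
#' by the same exponential weights and replaces a uniform victim;
#' `"fermi"` is the pairwise comparison process (uniform focal and model,
#' adoption with probability `1/(1 + exp(-sigma * (f_model - f_focal)))`).
#' Exponential weights are used instead of raw fitness because donation-
#' game payoffs can be negative. New players get a fresh identity: empty
#' histories with every opponent, and information players inherit nothing.
#'
#' @param invader,resident Player specifications ([memory_one_player()],
#'   [tag_player()], [ip0_player()], [conswitch_player()]), or anything
#'   coercible (a strategy vector, a [tag_pair()]).
#' @param m0 Initial invader count.
#' @param N Population size.
#' @param matrix A [game_matrix()].
#' @param epsilon Move noise.
#' @param sigma Selection strength.
#' @param rule Update rule.
#' @param n_sims Number of independent simulations.
#' @param seed Integer seed; replicate `i` uses a stream derived from
#'   `(seed, i)`, so results are reproducible bit for bit.
#' @param max_generations Safety cap per run.
#' @return `run_to_fixation()`: logical vector of length `n_sims` (invader
#'   fixed?), with the generation counts as attribute `"generations"`.
#' @export
#' @examples
#' run_to_fixation(memory_one_player(ALLD, name = "ALLD"),
#'                 memory_one_player(ALLC, name = "ALLC"),
#'                 N = 20, n_sims = 5, seed = 1)
run_to_fixation <- function(invader, resident, m0 = 1, N = 100,
                            matrix = donation_matrix(3, 1), epsilon = 0.05,
                            sigma = 1, rule = "imitation", n_sims = 1,
                            seed = 1, max_generations = 1e6) {
  stopifnot(m0 >= 1, m0 <= N - 1)
  rule <- match_rule(rule)
  inv <- engine_spec(invader)
  res <- engine_spec(resident)
  if (identical(inv$name, res$name)) res$name <- paste0(res$name, ".resident")
  out <- cpp_run_fixation_batch(list(inv, res), as.integer(m0), as.integer(N),
                                payoffs_focal(matrix), epsilon, sigma, rule,
                                as.integer(n_sims), as.numeric(seed),
                                as.integer(max_generations))
  fixed <- as.logical(out$fixed)
  attr(fixed, "generations") <- out$generations
  fixed
}

#' @rdname run_to_fixation
#' @return `fixation_experiment()`: a one-row tibble of class
#'   `fixation_record` with columns `invader`, `resident`, `n_sims`, `k`
#'   (successful invasions), `n_unresolved`, `rho` (fixation probability),
#'   `rho_neutral` (`m0/N`), `odds_ratio` and `p_value`.
#' @export
fixation_experiment <- function(invader, resident, m0 = 1, N = 100,
                                matrix = donation_matrix(3, 1), epsilon = 0.05,
                                sigma = 1, rule = "imitation", n_sims = 1000,
                                seed = 1, max_generations = 1e6) {
  inv <- as_player_spec(invader)
  res <- as_player_spec(resident)
  fixed <- run_to_fixation(inv, res, m0 = m0, N = N, matrix = matrix,
                           epsilon = epsilon, sigma = sigma, rule = rule,
                           n_sims = n_sims, seed = seed,
                           max_generations = max_generations)
  k <- sum(fixed, na.rm = TRUE)
  unresolved <- sum(is.na(fixed))
  rho <- k / n_sims
  rho_neutral <- m0 / N
  out <- tibble(invader = inv$name, resident = res$name,
                n_sims = n_sims, k = k, n_unresolved = unresolved,
                rho = rho, rho_neutral = rho_neutral,
                odds_ratio = rho / rho_neutral,
                p_value = fixation_pvalue(k, n_sims, N / m0))
  class(out) <- c("fixation_record", class(out))
  out
}

#' Simulate a population trajectory
#'
#' Runs the generation protocol for a fixed number of generations over an
#' arbitrary mixture of player types, recording per-generation type
#' counts, mean fitness per type and the aggregate outcome distribution.
#' Useful for inspecting the dynamics rather than racing to fixation.
#'
#' @param players List of player specifications (one per type).
#' @param counts Integer vector of initial copies per type.
#' @param generations Number of generations to simulate.
#' @param update Apply the death-birth update each generation? With
#'   `FALSE` the composition stays fixed (pure repeated play).
#' @inheritParams run_to_fixation
#' @return A list of class `pop_trajectory` with tibbles `types`
#'   (generation, type, count, mean_fitness) and `outcomes` (generation,
#'   outcome, frequency), plus `last_fitness` (per-slot fitness of the
#'   final generation).
#' @export
#' @examples
#' tr <- simulate_population(list(memory_one_player(ALLC, name = "ALLC")),
#'                           counts = 10, generations = 3, epsilon = 0)
#' tr$types
simulate_population <- function(players, counts, generations = 100,
                                matrix = donation_matrix(3, 1), epsilon = 0.05,
                                sigma = 1, rule = "imitation", update = TRUE,
                                seed = 1) {
  rule <- match_rule(rule)
  specs <- lapply(players, engine_spec)
  nms <- vapply(specs, `[[`, "", "name")
  res <- cpp_simulate_population(specs, as.integer(counts),
                                 as.integer(generations),
                                 payoffs_focal(matrix), epsilon, sigma, rule,
                                 isTRUE(update), as.numeric(seed))
  types <- as_tibble(res$type_counts, .name_repair = ~nms) |>
    dplyr::mutate(generation = dplyr::row_number()) |>
    tidyr::pivot_longer(-"generation", names_to = "type", values_to = "count")
  fitness <- as_tibble(res$mean_fitness, .name_repair = ~nms) |>
    dplyr::mutate(generation = dplyr::row_number()) |>
    tidyr::pivot_longer(-"generation", names_to = "type",
                        values_to = "mean_fitness")
  types <- dplyr::left_join(types, fitness, by = c("generation", "type"))
  outcomes <- as_tibble(res$outcome_freq, .name_repair = ~OUTCOMES) |>
    dplyr::mutate(generation = dplyr::row_number()) |>
    tidyr::pivot_longer(-"generation", names_to = "outcome",
                        values_to = "frequency")
  structure(list(types = types, outcomes = outcomes,
                 last_fitness = as.numeric(res$last_fitness)),
            class = "pop_trajectory")
}

#' @export
print.pop_trajectory <- function(x, ...) {
  g <- max(x$types$generation)
  cat(sprintf("<pop_trajectory> %d generations\n", g))
  print(dplyr::filter(x$types, .data$generation == g))
  invisible(x)
}
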