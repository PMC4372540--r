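gm <- donation_matrix(3, 1)

test_that("fixation_pvalue is the binomial tail at the neutral rate", {
  expect_equal(fixation_pvalue(0, 50, 100), 1)
  # explicit sum oracle for k = 2, n = 10, N = 100
  oracle <- sum(vapply(2:10, function(K) {
    choose(10, K) * 0.01^K * 0.99^(10 - K)
  }, numeric(1)))
  expect_equal(fixation_pvalue(2, 10, 100), oracle, tolerance = 1e-12)
  expect_equal(round(fixation_pvalue(2, 10, 100), 4), 0.0043)
  expect_equal(fixation_pvalue(5, 5, 100), 1e-10, tolerance = 1e-12)
  expect_error(fixation_pvalue(6, 5, 100))
})

test_that("identical seeds reproduce identical trajectories", {
  a <- run_to_fixation(memory_one_player(ALLD, name = "A"),
                       memory_one_player(TFT, name = "B"),
                       N = 30, n_sims = 20, seed = 99)
  b <- run_to_fixation(memory_one_player(ALLD, name = "A"),
                       memory_one_player(TFT, name = "B"),
                       N = 30, n_sims = 20, seed = 99)
  expect_identical(a, b)
  expect_identical(attr(a, "generations"), attr(b, "generations"))
  d <- run_to_fixation(memory_one_player(ALLD, name = "A"),
                       memory_one_player(TFT, name = "B"),
                       N = 30, n_sims = 20, seed = 100)
  expect_false(identical(attr(a, "generations"), attr(d, "generations")))
})

test_that("per-generation fitness counts every one of the N-1 games", {
  # all-ALLC population at zero noise: everyone earns R
  tr <- simulate_population(list(memory_one_player(ALLC, name = "ALLC")),
                            counts = 20, generations = 2, epsilon = 0,
                            update = FALSE, seed = 1)
  expect_equal(tr$last_fitness, rep(2, 20))
  # one ALLD among 99 ALLC: T for the defector, (98 R + S)/99 for the rest
  tr <- simulate_population(list(memory_one_player(ALLD, name = "ALLD"),
                                 memory_one_player(ALLC, name = "ALLC")),
                            counts = c(1, 99), generations = 1, epsilon = 0,
                            update = FALSE, seed = 1)
  expect_equal(sort(unique(tr$last_fitness)), sort(c(3, (98 * 2 - 1) / 99)))
  expect_equal(sum(tr$last_fitness == 3), 1)
})

test_that("total move randomization gives uniform outcome frequencies", {
  tr <- simulate_population(list(memory_one_player(TFT, name = "TFT"),
                                 memory_one_player(WSLS, name = "WSLS")),
                            counts = c(15, 15), generations = 12,
                            epsilon = 0.5, update = FALSE, seed = 5)
  freq <- dplyr::summarise(dplyr::group_by(tr$outcomes, .data$outcome),
                           f = mean(.data$frequency))
  expect_lt(max(abs(freq$f - 0.25)), 0.02)
})

test_that("tag-based conditional defectors cooperate among themselves at zero noise", {
  tr <- simulate_population(list(tag_player(con_def(), name = "ConDef"),
                                 memory_one_player(ALLD, name = "ALLD")),
                            counts = c(10, 2), generations = 5, epsilon = 0,
                            update = FALSE, seed = 3)
  # 45 of 66 unordered pairs are ConDef-ConDef (all CC); the rest all DD
  last <- dplyr::filter(tr$outcomes, .data$generation == 5)
  expect_equal(last$frequency[last$outcome == "CC"], 45 / 66, tolerance = 1e-12)
  expect_equal(last$frequency[last$outcome == "DD"], 21 / 66, tolerance = 1e-12)
})

test_that("label-only invaders drift neutrally under all update rules", {
  for (rl in c("imitation", "moran", "fermi")) {
    f <- run_to_fixation(memory_one_player(TFT, name = "inv"),
                         memory_one_player(TFT, name = "res"),
                         m0 = 1, N = 20, epsilon = 0.05, rule = rl,
                         n_sims = 1200, seed = 77)
    rho <- mean(f)
    expect_lt(abs(rho - 0.05), 3 * sqrt(0.05 * 0.95 / 1200))
  }
})

test_that("selection favors the pairwise-dominant type", {
  f <- run_to_fixation(memory_one_player(ALLD, name = "ALLD"),
                       memory_one_player(ALLC, name = "ALLC"),
                       m0 = 1, N = 50, epsilon = 0.05, n_sims = 300, seed = 7)
  rho <- mean(f)
  expect_gt(rho, 1 / 50 + 3 * sqrt(rho * (1 - rho) / 300))
  # and the converse invader never fixes
  f2 <- run_to_fixation(memory_one_player(ALLC, name = "ALLC"),
                        memory_one_player(ALLD, name = "ALLD"),
                        m0 = 1, N = 50, epsilon = 0.05, n_sims = 200, seed = 7)
  expect_equal(sum(f2), 0)
})

test_that("a population of information players settles into full cooperation", {
  tr <- simulate_population(list(ip0_player()), counts = 12, generations = 25,
                            epsilon = 0, update = FALSE, seed = 2)
  late <- dplyr::filter(tr$outcomes, .data$generation > 15,
                        .data$outcome == "CC")
  expect_equal(late$frequency, rep(1, nrow(late)))
  expect_equal(unique(round(tr$last_fitness, 10)), 2)
})

test_that("population size is conserved through updates", {
  tr <- simulate_population(list(memory_one_player(ALLD, name = "A"),
                                 memory_one_player(ALLC, name = "B")),
                            counts = c(5, 15), generations = 50,
                            epsilon = 0.05, update = TRUE, seed = 9)
  totals <- dplyr::summarise(dplyr::group_by(tr$types, .data$generation),
                             n = sum(.data$count))
  expect_equal(totals$n, rep(20, 50))
})

test_that("fixation_experiment summarizes runs into a coherent record", {
  rec <- fixation_experiment(memory_one_player(ALLD, name = "ALLD"),
                             memory_one_player(ALLC, name = "ALLC"),
                             N = 30, n_sims = 50, seed = 3)
  expect_s3_class(rec, "fixation_record")
  expect_equal(rec$k, sum(run_to_fixation(
    memory_one_player(ALLD, name = "ALLD"),
    memory_one_player(ALLC, name = "ALLC"), N = 30, n_sims = 50, seed = 3)))
  expect_equal(rec$rho, rec$k / 50)
  expect_equal(rec$odds_ratio, rec$rho / (1 / 30))
  expect_equal(rec$p_value, fixation_pvalue(rec$k, 50, 30))
})
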