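gm <- donation_matrix(3, 1)

test_that("posterior_mean is the Beta posterior expectation", {
  expect_equal(posterior_mean(0, 0), 0.5)
  expect_equal(posterior_mean(8, 6), 0.7)
  expect_equal(posterior_mean(10, 10), 11 / 12)
  expect_error(posterior_mean(3, 4))
})

test_that("md5_tiebreak follows the last-byte LSB rule on frozen digests", {
  # digests computed with an independent MD5 implementation (Python hashlib):
  # ""     -> d41d8cd98f00b204e9800998ecf8427e  last byte 0x7e -> C
  # "CC"   -> aa53ca0b650dfd85c4f59fa156f7a2cc  last byte 0xcc -> C
  # "CCDC" -> b7ebdbe3127036305cea6053057d6181  last byte 0x81 -> D
  # "CD"   -> 4170acd6af571e8d0d59fdad999cc605  last byte 0x05 -> D
  expect_equal(ipdpop:::cpp_md5_hex(""), "d41d8cd98f00b204e9800998ecf8427e")
  expect_equal(ipdpop:::cpp_md5_hex("CC"), "aa53ca0b650dfd85c4f59fa156f7a2cc")
  expect_equal(md5_tiebreak(""), "C")
  expect_equal(md5_tiebreak("CC"), "C")
  expect_equal(md5_tiebreak("CCDC"), "D")
  expect_equal(md5_tiebreak("CD"), "D")
  expect_equal(md5_tiebreak("CCDC"), md5_tiebreak("CCDC"))
})

test_that("the compiled MD5 agrees with an independent implementation", {
  set.seed(4)
  for (i in 1:25) {
    s <- paste(sample(c("C", "D"), sample(0:120, 1), replace = TRUE),
               collapse = "")
    expect_equal(ipdpop:::cpp_md5_hex(s), unname(cli::hash_md5(s)))
  }
})

test_that("infogain_move minimizes the expected count of the next outcome", {
  # round one: everything ties, so the empty-history tie-break gives C
  expect_equal(infogain_move(outcome_counts()), "C")
  # counts concentrated on CC steer toward defection outcomes
  cnt <- outcome_counts(n = c(5, 0, 0, 0), m = c(5, 0, 0, 0))
  expect_equal(infogain_move(cnt, "CC"), "D")
  # brute-force the expectation over random count tables
  set.seed(8)
  for (i in 1:50) {
    n <- sample(0:12, 4, replace = TRUE)
    m <- vapply(n, function(k) sample(0:k, 1), integer(1))
    last <- sample(OUTCOMES, 1)
    hist <- paste(sample(c("C", "D"), 8, replace = TRUE), collapse = "")
    pc <- (m[outcome_index(last)] + 1) / (n[outcome_index(last)] + 2)
    eC <- pc * n[1] + (1 - pc) * n[2]
    eD <- pc * n[3] + (1 - pc) * n[4]
    expected <- if (eC < eD) "C" else if (eD < eC) "D" else md5_tiebreak(hist)
    expect_equal(infogain_move(outcome_counts(n, m), last, hist), expected)
  }
})

test_that("compiled and R infogain rules agree", {
  set.seed(12)
  for (i in 1:40) {
    n <- sample(0:9, 4, replace = TRUE)
    m <- vapply(n, function(k) sample(0:k, 1), integer(1))
    last <- sample(c(NA, OUTCOMES), 1)
    hist <- paste(sample(c("C", "D"), 6, replace = TRUE), collapse = "")
    li <- if (is.na(last)) -1L else outcome_index(last) - 1L
    cpp <- MOVES[ipdpop:::cpp_infogain_move(n, m, li, hist) + 1L]
    r <- infogain_move(outcome_counts(n, m),
                       if (is.na(last)) NULL else last, hist)
    expect_equal(cpp, r)
  }
})

test_that("classify_infogain computes the binomial tail and threshold", {
  expect_equal(classify_infogain(10, 0, 0.05)$p_value, 1)
  r <- classify_infogain(10, 3, 0.05)
  # explicit tail sum as oracle
  tail_sum <- sum(vapply(3:10, function(E) {
    choose(10, E) * 0.05^E * 0.95^(10 - E)
  }, numeric(1)))
  expect_equal(r$p_value, tail_sum, tolerance = 1e-12)
  expect_equal(round(r$p_value, 4), 0.0115)
  expect_false(r$confident_gp)
  r0 <- classify_infogain(5, 1, 0)
  expect_equal(r0$p_value, 0)
  expect_true(r0$confident_gp)
  expect_error(classify_infogain(5, 6, 0.05))
})

test_that("update_log_odds adds clamped log likelihood ratios", {
  expect_equal(update_log_odds(0, 0.3, 0.3), 0)
  expect_equal(update_log_odds(0, 0.95, 0.5), log(0.95 / 0.5))
  expect_true(is.finite(update_log_odds(0, 0, 1)))
  L <- 1.7
  for (i in 1:5) L <- update_log_odds(L, 0.4, 0.4)
  expect_equal(L, 1.7)
})

test_that("hmm_update performs a correct two-state forward step", {
  # absorbing consistent state
  expect_equal(hmm_update(1, "C", 0.2, 0, switch_prob = 0)$allc_prob, 1)
  # identical emissions are uninformative
  r <- hmm_update(0.5, "C", 1 - 0.05, 0.05)
  expect_equal(r$allc_prob, 0.5)
  # defection with a defecting groupmax state pulls the posterior down
  r <- hmm_update(0.5, "D", 0.1, 0.05)
  expect_lt(r$allc_prob, 0.2)
  # generic forward-algorithm oracle over a random sequence
  set.seed(20)
  a <- 0.5
  fwd <- c(0.5, 0.5)  # explicit two-state forward variables
  for (t in 1:15) {
    obs <- sample(MOVES, 1)
    gc <- runif(1)
    eps <- 0.05
    sw <- 0.01
    r <- hmm_update(a, obs, gc, eps, sw)
    a <- r$allc_prob
    Tm <- matrix(c(1 - sw, sw, sw, 1 - sw), 2, 2, byrow = TRUE)
    em <- if (obs == "C") c(1 - eps, gc) else c(eps, 1 - gc)
    fwd <- as.vector(fwd %*% Tm) * em
    marg <- sum(fwd)
    expect_equal(r$likelihood, marg, tolerance = 1e-12)
    fwd <- fwd / marg
    expect_equal(a, fwd[1], tolerance = 1e-12)
  }
})

test_that("estimate_m_bar pools the per-opponent posteriors monotonically", {
  expect_equal(estimate_m_bar(rep(-1e6, 99)), 1)
  expect_equal(estimate_m_bar(rep(1e6, 99)), 100)
  expect_equal(estimate_m_bar(rep(0, 99)), 50.5)
  base <- rnorm(10)
  bumped <- base
  bumped[4] <- bumped[4] + 1
  expect_gt(estimate_m_bar(bumped), estimate_m_bar(base))
})

test_that("new_player_prior is the log prior odds", {
  expect_equal(new_player_prior(100, 100), 0)
  expect_equal(new_player_prior(1, 100), log(0.01))
  expect_equal(new_player_prior(50, 100), log(0.5))
  expect_error(new_player_prior(0, 100))
})

test_that("groupmax_optimize matches the exhaustive grid oracle", {
  # exploiting unconditional cooperators: optimum at the ALLD corner
  g <- groupmax_optimize(ALLC, 1, 100, gm, epsilon = 0.05)
  expect_lt(max(abs(unname(g) - c(0, 0, 0, 0))), 0.05)
  oracle <- oracle_groupmax_grid(ALLC, 1, 100, gm, 0.05,
                                 grid = c(0.001, 0.25, 0.5, 0.75, 0.999))
  expect_gte(attr(g, "objective"), oracle$value - 1e-3)
  # the returned vector always beats playing the estimate back at itself
  set.seed(14)
  for (i in 1:5) {
    pb <- rand_strategy()
    mb <- runif(1, 1, 99)
    g <- groupmax_optimize(pb, mb, 100, gm, epsilon = 0.05)
    obj <- function(q) {
      (100 - mb) / 99 * stationary_scores(q, pb, gm, 0.05)$score_focal -
        mb / 99 * stationary_scores(pb, q, gm, 0.05)$score_focal
    }
    expect_gte(attr(g, "objective"), obj(pmin(pmax(pb, 1e-3), 1 - 1e-3)) - 1e-9)
    # never below the best corner strategy
    corners <- list(ALLC, ALLD, TFT, WSLS)
    corner_best <- max(vapply(corners, function(q) {
      obj(pmin(pmax(q, 1e-3), 1 - 1e-3))
    }, numeric(1)))
    expect_gte(attr(g, "objective"), corner_best - 1e-6)
  }
})

test_that("groupmax_optimize attacks an incumbent majority (grid-refined oracle)", {
  pb <- c(0.95, 0.05, 0.95, 0.05)  # a TFT-like estimate
  g <- groupmax_optimize(pb, 99, 100, gm, epsilon = 0.05)
  oracle <- oracle_groupmax_grid(pb, 99, 100, gm, 0.05,
                                 grid = c(0.001, 0.05, 0.25, 0.5, 0.75, 0.95, 0.999))
  expect_gte(attr(g, "objective"), oracle$value - 1e-3)
})

test_that("two information players make identical infogain predictions of each other", {
  cfg <- ip_config(epsilon_assumed = 0)
  A <- ip0_model()
  B <- ip0_model()
  for (t in 1:20) {
    ca <- ip0_choose_move(A, cfg)
    cb <- ip0_choose_move(B, cfg)
    A <- ca$model
    B <- cb$model
    if (t <= cfg$infogain_length) {
      # each predicts the other's move exactly (shared-information closure)
      expect_equal(A$pending_pred, cb$move)
      expect_equal(B$pending_pred, ca$move)
    } else {
      # mutual recognition: both cooperate in the groupmax phase
      expect_equal(ca$move, "C")
      expect_equal(cb$move, "C")
    }
    A <- ip0_observe(A, ca$move, cb$move, cfg)
    B <- ip0_observe(B, cb$move, ca$move, cfg)
  }
  expect_equal(A$mismatches, 0L)
  expect_equal(B$mismatches, 0L)
  expect_gt(A$log_odds, 0)
  expect_false(A$confident_gp)
})

test_that("at zero noise a single deviation exposes a group player immediately", {
  cfg <- ip_config(epsilon_assumed = 0)
  M <- ip0_model()
  cm <- ip0_choose_move(M, cfg)
  M <- cm$model
  deviant <- ifelse(M$pending_pred == "C", "D", "C")
  M <- ip0_observe(M, cm$move, deviant, cfg)
  expect_true(M$confident_gp)
  expect_equal(M$mismatches, 1L)
})

test_that("the first observed round records moves but increments no counts", {
  cfg <- ip_config(epsilon_assumed = 0.05)
  M <- ip0_model()
  cm <- ip0_choose_move(M, cfg)
  M <- ip0_observe(cm$model, cm$move, "C", cfg)
  expect_equal(sum(M$n), 0)
  expect_equal(sum(M$n2), 0)
  expect_equal(M$rounds, 1L)
  expect_equal(M$last_outcome, paste0(cm$move, "C"))
  # the second round increments exactly one count pair
  cm2 <- ip0_choose_move(M, cfg)
  M2 <- ip0_observe(cm2$model, cm2$move, "D", cfg)
  expect_equal(sum(M2$n), 1)
  expect_equal(sum(M2$n2), 1)
})

test_that("R model stepping reproduces the compiled infogain duel exactly at zero noise", {
  for (opp in list(list(v = ALLC, fm = "C"), list(v = ALLD, fm = "D"),
                   list(v = TFT, fm = "C"), list(v = WSLS, fm = "C"))) {
    cpp <- ipdpop:::cpp_infogain_trace(unname(opp$v), opp$fm, FALSE, 10, 0, 7)
    set.seed(1)
    rduel <- infogain_duel(opp$v, rounds = 10, epsilon = 0, first_move = opp$fm)
    expect_equal(MOVES[cpp$predicted + 1L], rduel$predicted)
    expect_equal(MOVES[cpp$my_move + 1L], rduel$my_move)
    expect_equal(MOVES[cpp$opp_move + 1L], rduel$opp_move)
  }
  # against a true information player at zero noise there are no mismatches
  cpp <- ipdpop:::cpp_infogain_trace(numeric(0), "C", TRUE, 10, 0, 7)
  expect_equal(sum(cpp$predicted != cpp$opp_move), 0L)
  set.seed(2)
  rduel <- infogain_duel(NULL, rounds = 10, epsilon = 0)
  expect_equal(attr(rduel, "mismatches"), 0L)
})
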