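gm <- donation_matrix(3, 1)

test_that("a zero-round classifier is uninformative and a noiseless one perfect", {
  r0 <- roc_identification(zdr_strategy(), rounds = 0, epsilon = 0.05,
                           n_replicates = 10, seed = 1)
  expect_equal(r0$auc, 0.5)
  r1 <- roc_identification(zdr_strategy(), rounds = 3, epsilon = 0,
                           n_replicates = 300, seed = 1)
  expect_equal(r1$auc, 1)
})

test_that("corner strategies are identified essentially perfectly under noise", {
  r <- roc_identification(ALLD, rounds = 10, epsilon = 0.05,
                          n_replicates = 500, seed = 2, first_move = "D")
  expect_gt(r$auc, 0.999)
  expect_gte(roc_tpr_at_fpr(r, 0.1), 0.995)
  r2 <- roc_identification(ALLC, rounds = 10, epsilon = 0.05,
                           n_replicates = 500, seed = 2)
  expect_gt(r2$auc, 0.995)
  expect_gte(roc_tpr_at_fpr(r2, 0.1), 0.99)
})

test_that("ROC points are monotone with proper endpoints and a consistent AUC", {
  r <- roc_identification(zdr_strategy(), rounds = 10, epsilon = 0.05,
                          n_replicates = 400, seed = 3)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[1], 0)
  expect_equal(r$points$fpr[nrow(r$points)], 1)
  expect_equal(r$points$tpr[nrow(r$points)], 1)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  expect_gte(r$auc, 0)
  expect_lte(r$auc, 1)
  expect_equal(glance(r)$auc, r$auc)
  expect_equal(nrow(tidy(r)), nrow(r$points))
})

test_that("discrimination improves with rounds and degrades with noise", {
  aucs <- sapply(c(0, 0.01, 0.05, 0.1), function(eps) {
    sapply(c(3, 10), function(rd) {
      roc_identification(zdr_strategy(), rounds = rd, epsilon = eps,
                         n_replicates = 600, seed = 11)$auc
    })
  })
  # more rounds never hurt (up to sampling error)
  expect_true(all(aucs[2, ] >= aucs[1, ] - 0.015))
  # more noise never helps at fixed rounds
  expect_true(all(diff(aucs[1, ]) <= 0.015))
  expect_true(all(diff(aucs[2, ]) <= 0.015))
})

test_that("roc_tpr_at_fpr interpolates the empirical curve", {
  r <- structure(list(points = tibble::tibble(
    threshold = c(-Inf, 1, 2, Inf),
    fpr = c(0, 0.2, 0.6, 1), tpr = c(0, 0.5, 0.9, 1)),
    auc = NA, rounds = 1, epsilon = 0, n_pos = 1L, n_neg = 1L),
    class = "ipd_roc")
  expect_equal(roc_tpr_at_fpr(r, 0.2), 0.5)
  expect_equal(roc_tpr_at_fpr(r, 0.4), 0.7)
  expect_equal(roc_tpr_at_fpr(r, 0), 0)
})

test_that("self-score versus noise reproduces the analytic endpoints", {
  s <- self_score_vs_noise(ALLC, c(0, 0.5), gm)
  expect_equal(s$self_score, c(2, 1))
  set.seed(5)
  s2 <- self_score_vs_noise(rand_strategy(), 0.5, gm)
  expect_equal(s2$self_score, 1)  # uniform outcomes average the matrix
  zdr_curve <- self_score_vs_noise(zdr_strategy(), c(0, 0.01, 0.05, 0.1), gm)
  expect_true(all(diff(zdr_curve$self_score) < 0))
  expect_equal(zdr_curve$self_score[1], 2)
})

test_that("an empty noise grid yields an empty sweep", {
  out <- invasion_vs_noise(memory_one_player(ALLD, name = "A"),
                           memory_one_player(ALLC, name = "B"),
                           epsilon_grid = numeric(0))
  expect_equal(nrow(out), 0)
  expect_s3_class(out, "ipd_noise_sweep")
})

test_that("fixation_table runs pairs with reproducible per-pair seeds", {
  tab <- fixation_table(list(
    list(invader = memory_one_player(TFT, name = "inv"),
         resident = memory_one_player(TFT, name = "res")),
    list(invader = memory_one_player(ALLD, name = "ALLD"),
         resident = memory_one_player(ALLC, name = "ALLC"))),
    N = 20, n_sims = 300, seed = 13)
  expect_equal(nrow(tab), 2)
  # label-only pair is neutral; the dominant invader is far above
  expect_lt(abs(tab$rho[1] - 1 / 20), 3 * sqrt(0.05 * 0.95 / 300))
  expect_gt(tab$odds_ratio[2], 3)
  tab2 <- fixation_table(list(
    list(invader = memory_one_player(TFT, name = "inv"),
         resident = memory_one_player(TFT, name = "res")),
    list(invader = memory_one_player(ALLD, name = "ALLD"),
         resident = memory_one_player(ALLC, name = "ALLC"))),
    N = 20, n_sims = 300, seed = 13)
  expect_identical(tab$k, tab2$k)
})

test_that("rosters read back from configuration files", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "TFT: [1, 0, 1, 0]",
    "ZDR: {kappa: 2, chi: 0.5, phi: 0.1}",
    "IP0: ip0",
    "ConSwitch: conswitch"), path)
  roster <- read_roster(path, gm)
  expect_named(roster, c("TFT", "ZDR", "IP0", "ConSwitch"))
  expect_equal(roster$TFT$vector, c(1, 0, 1, 0))
  expect_equal(roster$ZDR$vector, c(1, 0.75, 0.35, 0.1))
  expect_equal(roster$IP0$kind, "ip0")
  expect_equal(roster$ConSwitch$kind, "conswitch")
})

test_that("autoplot methods return ggplot objects", {
  r <- roc_identification(zdr_strategy(), rounds = 5, epsilon = 0.05,
                          n_replicates = 50, seed = 1)
  expect_s3_class(autoplot(r), "ggplot")
  cv <- score_difference_curve(ALLD, TFT, gm, 0.05, N = 20)
  expect_s3_class(autoplot(cv), "ggplot")
  ss <- self_score_vs_noise(zdr_strategy(), c(0, 0.1), gm)
  expect_s3_class(autoplot(ss), "ggplot")
})
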