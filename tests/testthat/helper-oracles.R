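# Independent oracles, written from first principles and deliberately not
# sharing code paths with the package internals.

# transition matrix built with explicit role logic
oracle_transition <- function(p, q) {
  swp <- c(1, 3, 2, 4)
  M <- matrix(0, 4, 4)
  for (o in 1:4) {
    pc <- p[o]
    qc <- q[swp[o]]
    M[o, ] <- c(pc * qc, pc * (1 - qc), (1 - pc) * qc, (1 - pc) * (1 - qc))
  }
  M
}

# stationary distribution by plain power iteration (with a lazy step so
# periodic chains settle)
oracle_stationary <- function(p, q, iters = 20000, tol = 1e-15) {
  M <- oracle_transition(p, q)
  s <- rep(0.25, 4)
  for (i in seq_len(iters)) {
    ns <- 0.5 * (as.vector(s %*% M) + s)
    ns <- ns / sum(ns)
    if (sum(abs(ns - s)) < tol) return(ns)
    s <- ns
  }
  s
}

# explicit noisy match simulation; roles fully spelled out
oracle_match <- function(pA, pB, eps, rounds, fmA = "C", fmB = "C") {
  idx <- function(me, you) 1 + 2 * (me == "D") + (you == "D")
  Sx <- c(2, -1, 3, 0)
  flip <- function(mv) if (runif(1) < eps) ifelse(mv == "C", "D", "C") else mv
  a <- flip(fmA)
  b <- flip(fmB)
  accA <- accB <- 0
  for (t in seq_len(rounds)) {
    accA <- accA + Sx[idx(a, b)]
    accB <- accB + Sx[idx(b, a)]
    # draw intended moves, then apply noise
    na <- ifelse(runif(1) < pA[idx(a, b)], "C", "D")
    nb <- ifelse(runif(1) < pB[idx(b, a)], "C", "D")
    a <- flip(na)
    b <- flip(nb)
  }
  c(accA / rounds, accB / rounds)
}

rand_strategy <- function(lo = 0.05, hi = 0.95) runif(4, lo, hi)

# grid search oracle for the groupmax objective, computed with the package's
# analytic scores but an exhaustive search independent of the optimizer
oracle_groupmax_grid <- function(p_bar, m_bar, N, matrix, epsilon,
                                 grid = seq(0.001, 0.999, length.out = 11)) {
  objective <- function(q) {
    s1 <- stationary_scores(q, p_bar, matrix, epsilon)$score_focal
    s2 <- stationary_scores(p_bar, q, matrix, epsilon)$score_focal
    (N - m_bar) / (N - 1) * s1 - m_bar / (N - 1) * s2
  }
  best <- -Inf
  best_q <- NULL
  for (a in grid) for (b in grid) for (cc in grid) for (d in grid) {
    v <- objective(c(a, b, cc, d))
    if (v > best) {
      best <- v
      best_q <- c(a, b, cc, d)
    }
  }
  list(par = best_q, value = best, objective = objective)
}
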