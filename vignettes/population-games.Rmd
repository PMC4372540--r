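---
title: "Population games, zero-determinant strategies and information players"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population games, zero-determinant strategies and information players}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipdpop)
```

## The model

`ipdpop` studies the evolution of cooperation in a well-mixed population of
`N` agents playing the iterated Prisoner's Dilemma. Payoffs come from a
`(R, S, T, P)` game matrix; the default is the donation game with benefit
`b = 3` and cost `c = 1`, i.e. `(2, -1, 3, 0)`. Strategies are, at the base
level, *memory-one*: a vector
`p = (Pr(C|CC), Pr(C|CD), Pr(C|DC), Pr(C|DD))` of cooperation probabilities
conditioned on the previous round's joint outcome, read from the focal
player's perspective (own move first; the partner sees the
perspective-swapped outcome, so `CD` and `DC` exchange).

The repeated game between two memory-one strategies `p` and `q` is a Markov
chain on the four outcomes. For an ergodic chain the long-run mean of any
per-outcome quantity `f` is a ratio of two 4x4 determinants,
`D(p, q, f) / D(p, q, 1)` (`press_dyson_score()`), which gives exact
long-term scores without simulation. Move noise — each executed move flips
independently with probability `epsilon` — is folded into the *effective
vector* `(1 - 2 eps) p + eps`; for memory-one play this is exactly
equivalent in distribution to modelling noise as a separate channel, and it
makes every chain ergodic for `eps > 0`. At `eps = 0` absorbing or periodic
chains are possible; `stationary_scores()` then falls back to lazy power
iteration started from mutual cooperation (both players opening with `C`),
and reports the long-run average from that standard start. The degeneracy
test is `|D(p, q, 1)| < 1e-12`; the fallback iterates to `1e-13` with a cap
of 10^4 steps.

Zero-determinant (ZD) strategies are built from `(kappa, chi, phi)` as

```
p = (1,1,0,0) + phi * [ chi * (Sx - kappa) - (Sy - kappa) ]
```

with `Sx = (R,S,T,P)`, `Sy = (R,T,S,P)`. Against any ergodic opponent the
construction pins the line `s_opp - kappa = chi * (s_zd - kappa)`. Of the
two possible sign conventions for which player's score is amplified, this is
the only one for which the two standard parameter sets — generous
`(kappa = R, chi = 1/2, phi = 0.1)` and extortionate
`(kappa = P, chi = 1/2, phi = 0.1)` on the donation game — land inside
`[0,1]^4`; the enforced relation is pinned by a property test rather than
assumed. Note the slope convention: `chi = 1/2` here means the ZD player's
surplus is *twice* the opponent's, which corresponds to an extortion factor
of 2 in the alternative parameterization that writes the relation the other
way around.

## Frequency-dependent fitness

With `m` invaders of type I among `N` players, pairwise stationary scores
`S_II, S_IG, S_GI, S_GG` determine the mean payoff difference

```
(m-1)/(N-1) S_II + (N-m)/(N-1) S_IG - m/(N-1) S_GI - (N-m-1)/(N-1) S_GG
```

(`mean_score_difference()`). Because the weights change with `m`, the best
invader strategy is frequency dependent: against a tit-for-tat resident at
5% noise, unconditional cooperation wins in the minority and unconditional
defection in the majority (`best_response_at_fraction()`). One consequence
worth flagging: against an *extortionate* ZD resident the difference is
positive at small `m` and negative at large `m`, so there is an interior
stable mixture (around `m ~ 56` of 100 at `eps = 0.05`). Invasion
experiments for that pairing therefore stall in long coexistence rather
than sweeping to fixation; the fixation odds the simulator reports for
unconditional cooperators against extortionate residents are accordingly
small, whatever generation cap is used. This follows from the score
analysis itself, not from a simulation artifact: any update rule that is
monotone in per-generation mean payoff faces the same barrier.

## The information player

`ip0_player()` implements a strategy that is not memory-one: it exploits
the full per-opponent history three ways — *identification* (is this
opponent another information player?), *opponent-strategy estimation*, and
*population-fraction estimation* — and turns them into frequency-dependent
play.

**Inference.** For each opponent it keeps, per joint outcome `AB`, the pair
`(n_AB, m_AB)`: conditioning rounds observed, and how many were followed by
opponent cooperation. Each conditional cooperation probability gets a
uniform prior, so the point estimate is the Beta posterior mean
`(m+1)/(n+2)` (`posterior_mean()`).

**Infogain phase** (first 10 rounds with each opponent, a fixed length even
if classification is confident earlier): the player picks the own-move `A`
minimizing the expected count of the next conditioning outcome,
`sum_B p(B|ab) n_AB`, steering play toward the outcomes it knows least
about. Exact ties — always in round one — are broken deterministically by
the MD5 digest of the chronological history string (two characters per
round, own move then opponent's, post-noise): cooperate if the
least-significant bit of the *last* digest byte is 0. Which byte carries
the tie-break is a free choice; the last byte is fixed here and tested
against frozen digests. Each player hashes its own perspective string, and
because the history is common knowledge within a pair, each can evaluate
the rule on the partner's perspective string too — which is what makes the
infogain move sequence *predictable*: an information player knows exactly
what another information player would play.

**Self-recognition.** During infogain, the observed mismatches `e` between
the opponent's moves and its predicted infogain moves are binomially
distributed (rate `epsilon`) if the opponent is a true information player;
`classify_infogain()` computes the upper-tail p-value and flags a confident
group player (GP) at `alpha = 0.01`. In parallel a running log-odds `L` is
updated each round with the likelihood ratio of the observed move under
"information player" versus "GP with the inferred vector"
(`update_log_odds()`; probabilities clamped at `1e-12`). The inferred GP
probability used in the denominator is taken directly from the posterior
means of the observed (post-noise) counts — it is *not* pushed through the
noise map a second time, since the estimate already reflects noisy play.
After the infogain phase, the expected move of a fellow information player
is ambiguous — it depends on whether *they* believe *me* to be one — so a
two-state hidden Markov model takes over (`hmm_update()`): state ALLC
("they recognize me") versus state groupmax ("they exploit me"), 1%
state-switch probability per round, with the forward-step marginal serving
as the likelihood in the log-odds update. The HMM prior at the phase
transition is the posterior that the opponent would assign to me, computed
by running the same likelihood-ratio bookkeeping on my own realized moves
(realized, not intended: both sides can observe only post-noise moves).

**Frequency-dependent optimization.** The estimated number of information
players is `m_bar = 1 + sum_i sigmoid(L_i)` (`estimate_m_bar()`). Against
the opposing group the player uses the vector maximizing

```
(N - m_bar)/(N - 1) * S(q, p_bar)  -  m_bar/(N - 1) * S(p_bar, q)
```

(`groupmax_optimize()`), where `p_bar` is the pooled GP estimate. Pooling:
once at least one opponent is confidently GP (binomial flag, or
`L < log(alpha)`), counts of all confident GPs — plus saved counts of
confidently-GP players that have died — are pooled; before that,
per-opponent estimates are used for the likelihood ratios, and the
optimizer pools over opponents currently classified GP (`L <= 0`), falling
back to all opponents. One subtlety: the counts condition on outcomes from
the *observer's* perspective, so the opponent's strategy vector in its own
perspective is the estimate with `CD` and `DC` swapped; the optimizer
receives the swapped vector. In play, the player cooperates with any
opponent whose `L > 0` and samples the groupmax vector against the rest.

The optimizer is projected gradient ascent on `[1e-3, 1 - 1e-3]^4`
(central differences, initial step 0.05 with backtracking, objective
tolerance `1e-6`, at most 500 iterations) from six starts: ALLC, ALLD,
TFT, WSLS, `p_bar` and the previous optimum. Because the objective's inputs
move only slightly between generations, the per-generation re-optimization
inside the simulator uses a tracking schedule: ascend from the previous
optimum and from the best raw canonical candidate (which is what detects
the defend-to-attack basin switch as `m_bar` grows), with a full
multi-start every 50th call and whenever no previous optimum exists. A
grid-search oracle in the test suite checks that the returned objective is
within `1e-3` of the exhaustive optimum.

**Births and deaths.** A dead opponent's counts are saved into the pooled
GP data iff it was confidently GP (`L < log alpha`); everything else about
it is forgotten. A newcomer's prior log-odds is `log(m_bar / N)`
(`new_player_prior()`). A newborn information player itself starts from
zero knowledge: its own prior for everyone is `log(1/N)` (at birth its
`m_bar` is 1), and `L_other` — the imputed opinion the opponent holds about
me — starts at the same value. The player assumes the ambient error rate;
no attempt is made to estimate `epsilon` from data.

## The evolutionary protocol

`run_to_fixation()` and `simulate_population()` implement: every
generation each player plays **one** move against every other player
(memory-one players condition on the pair's last outcome — carried across
generations — or play their first move for a fresh pairing; the default
first move is `C`, except `D` for unconditional defectors), moves flip
with probability `epsilon`, fitness is the mean payoff over the `N - 1`
games, and one player dies and one is born per generation. The default
update is exponential imitation: a uniformly chosen player is replaced by
a copy of a model drawn from the whole population (self included, so a
no-op is possible) with probability proportional to
`exp(sigma * fitness)`. Exponential weights rather than raw fitness are
used because donation-game payoffs can be negative. A Moran variant
(reproducer by the same exponential weights, uniform victim) and the Fermi
pairwise-comparison rule are provided as alternatives. Replacement clears
the slot's pairwise histories, and information players are notified of the
death and birth as above; imitation copies only the strategy — never any
internal state.

Tag-based idealized players short-circuit the inference: `con_def()`
cooperates with its own type and defects against the rest; `zd_t()` plays
a ZD vector against the rest; `conswitch_player()` keeps the groupmax
machinery (opponent-vector estimation, objective optimization, with
`m_bar` equal to the true own-type count) but reads true type tags instead
of running the infogain phase.

## What the simulations emulate — and what they do not

The engine generates exactly the synthetic study conditions used
throughout: `N = 100`, donation matrix `(2, -1, 3, 0)`, `epsilon = 0.05`
unless stated, `sigma = 1`, a single invader (or ten where stated), runs
to fixation. All randomness passes through one counter-seeded generator
per replicate, so every experiment is reproducible bit-for-bit from
`(configuration, seed)`. These are idealized conditions: a well-mixed
population, no spatial or network structure, no mutation during runs,
exactly two types per run, symmetric 2x2 payoffs, and noise that is
independent per move with a rate known to the information player. Passing
tests therefore validate the algorithms under the stated model, not
behaviour on empirical interaction data.

## Numerical and scale choices

The test suite runs identification ROCs at 2,000 duels per class
(20,000 for one assertion whose true value sits close to its bound),
neutral-drift controls at 2,000 runs with `N = 20`, and scaled-down
invasion experiments of 30-400 runs per claim; the bundled
`scripts/acceptance.R` uses 2,000 duels per class for the ROC targets,
1,000 runs for the tag-based invasion count and 2,000 runs (generation cap
5,000, unresolved counted as non-fixation) for the cooperator-invades-
extortioner odds ratio. Statistical assertions use three-standard-error
bands (with small-sample t quantiles and a family correction where many
comparisons are tested jointly). Monte-Carlo cross-checks of the
determinant scores use twenty independent 10^5-round match segments per
strategy pair.

## Known limitations

* The interior-equilibrium effect described above means fixation odds for
  unconditional cooperators invading extortionate (and, more weakly,
  generous) ZD residents are far below what a takeoff-only analysis would
  suggest; the package reports the honest, trapped values.
* Invasion odds for the information player against tit-for-tat depend only
  weakly on noise here, because resident TFT pairs drift toward their
  noisy stationary play over tens of generations regardless of the rate.
* The groupmax optimizer is a local ascent with canonical restarts; the
  tests bound its objective gap at `1e-3` against a grid oracle, not a
  certificate of global optimality.
* Higher-order Markov opponents are not modelled: the information player's
  inference assumes memory-one group players, and the engine's memory-one
  machinery is the only opponent class provided.
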