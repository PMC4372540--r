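# ipdpop

Evolution of cooperation in population games: exact stationary-score
analysis of memory-one and zero-determinant strategies for the iterated
Prisoner's Dilemma, an inference-driven "information player", and a fast
evolutionary simulation engine producing fixation probabilities and
identification ROC curves.

## What problem this addresses

In a well-mixed population of `N` agents playing the repeated Prisoner's
Dilemma (one move per pair per generation, payoffs from an `(R, S, T, P)`
matrix, moves flipped with probability `ε`), whether a strategy can invade
depends not only on head-to-head play but on the *population mixture*. With
`m` invaders among `N`, the mean payoff difference between invader I and
resident G is

    ΔS = (m−1)/(N−1)·S_II + (N−m)/(N−1)·S_IG − m/(N−1)·S_GI − (N−m−1)/(N−1)·S_GG

where `S_XY` are pairwise long-run scores. These are computed exactly from
the Press–Dyson determinant: for memory-one vectors
`p = (Pr(C|CC), Pr(C|CD), Pr(C|DC), Pr(C|DD))` the repeated game is a
four-state Markov chain whose stationary mean of any `f` is
`D(p,q,f)/D(p,q,1)`, a ratio of 4×4 determinants. Because ΔS changes sign
with `m` for many pairings, no memory-one strategy is optimal at every
mixture — which is the opening for a strategy that *infers* who is who.

The package's centerpiece is such an information player (`ip0_player()`):
it probes each new opponent for 10 rounds with information-maximizing
moves (deterministic, with an MD5-hash tie-break, hence predictable to its
own kind), recognizes fellow information players by a binomial test on
move mismatches (and a two-state HMM later on), estimates the opponent
group's strategy vector with Beta posterior means, estimates its own
type's population share from per-opponent log-odds, and plays the vector
maximizing `(N−m̄)/(N−1)·S(q,p̄) − m̄/(N−1)·S(p̄,q)` against the rest while
cooperating with its own kind. Tag-based idealizations (`con_def()`,
`zd_t()`, `conswitch_player()`) and zero-determinant strategies
(`zd_strategy()`, generous `zdr_strategy()` and extortionate
`zd_chi_strategy()`) round out the roster. The evolutionary engine
(imitation, Moran, and Fermi updates) is compiled code driven through
tidyverse-style wrappers returning tibbles, with `autoplot()` methods for
every result type.

## Worked example

```r
library(ipdpop)
gm <- donation_matrix(3, 1)      # (R, S, T, P) = (2, -1, 3, 0)

# an extortionate zero-determinant strategy, and what it does to ALLC
zd_chi_strategy(gm)
#>   CC   CD   DC   DD
#> 0.90 0.65 0.25 0.00
stationary_scores(ALLC, zd_chi_strategy(gm), gm, epsilon = 0.05)
#> <stationary_result> eps = 0.05
#>   dist: CC 0.6038, CD 0.3462, DC 0.0318, DD 0.0182
#>   scores: focal 0.9566, opponent 2.2145
```

The extortioner pins the cooperator to 0.96 per round while collecting
2.21 — about twice the surplus, as its `(κ = 0, χ = 1/2)` parameters
dictate. Optimal play against a resident depends on your population share:

```r
attr(best_response_at_fraction(list(ALLC = ALLC, ALLD = ALLD), TFT,
                               gm, epsilon = 0.05, N = 100, m = 1), "name")
#> [1] "ALLC"   # minority: cooperate with resident TFT
attr(best_response_at_fraction(list(ALLC = ALLC, ALLD = ALLD), TFT,
                               gm, epsilon = 0.05, N = 100, m = 99), "name")
#> [1] "ALLD"   # majority: defect against the remnant
```

How fast can an information player tell a ZD opponent from its own kind?

```r
roc <- roc_identification(zdr_strategy(gm), rounds = 10, epsilon = 0.05,
                          n_replicates = 2000, seed = 1)
roc
#> <ipd_roc> 10 rounds, eps = 0.05, AUC = 0.9896 (2000 + 2000 duels)
roc_tpr_at_fpr(roc, 0.1)
#> [1] 0.978    # ~98% of ZD opponents flagged at a 10% false-positive rate
autoplot(roc)
```

And a scaled invasion experiment (defectors sweep a cooperator population):

```r
fixation_experiment(memory_one_player(ALLD, name = "ALLD"),
                    memory_one_player(ALLC, name = "ALLC"),
                    N = 100, epsilon = 0.05, n_sims = 200, seed = 1)
#>   invader resident   k  rho odds_ratio  p_value
#>      ALLD     ALLC 128 0.64         64  1.6e-201
```

`rho` is the empirical fixation probability, `odds_ratio` its ratio to the
neutral baseline `m0/N = 0.01`, and `p_value` the binomial tail under
neutral drift.

A thin command-line front end is installed at `exec/ipdpop`
(`Rscript $(Rscript -e 'cat(system.file("exec/ipdpop", package="ipdpop"))') roc --opponent ZDR`)
with subcommands `curves`, `self-score`, `roc`, `fixation`, `noise-sweep`,
writing CSV plus a JSON manifest.

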