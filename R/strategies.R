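#' Classic memory-one strategies
#'
#' Memory-one strategies are encoded as a vector of four cooperation
#' probabilities conditioned on the previous round's outcome, in the order
#' `(Pr(C|CC), Pr(C|CD), Pr(C|DC), Pr(C|DD))` from the focal player's
#' perspective. These constants are the standard named strategies:
#' always-cooperate, always-defect, tit-for-tat and win-stay-lose-shift.
#'
#' @format Named numeric vectors of length 4.
#' @seealso [zd_strategy()] for zero-determinant strategies.
#' @export
ALLC <- c(CC = 1, CD = 1, DC = 1, DD = 1)

#' @rdname ALLC
#' @export
ALLD <- c(CC = 0, CD = 0, DC = 0, DD = 0)

#' @rdname ALLC
#' @export
TFT <- c(CC = 1, CD = 0, DC = 1, DD = 0)

#' @rdname ALLC
#' @export
WSLS <- c(CC = 1, CD = 0, DC = 0, DD = 1)

# validate and name a strategy vector
as_strategy <- function(p, arg = "strategy") {
  p <- as.numeric(p)
  if (length(p) != 4L || anyNA(p) || any(p < 0) || any(p > 1)) {
    abort(sprintf("%s must be 4 cooperation probabilities in [0, 1]", arg))
  }
  names(p) <- OUTCOMES
  p
}

#' Zero-determinant strategies
#'
#' Constructs the memory-one vector of a zero-determinant (ZD) strategy from
#' its `(kappa, chi, phi)` parameterization on a given payoff matrix:
#' \deqn{p = (1,1,0,0) + \phi [\chi (S_x - \kappa 1) - (S_y - \kappa 1)]}
#' where \eqn{S_x = (R,S,T,P)} and \eqn{S_y = (R,T,S,P)} are the focal and
#' opponent payoff vectors. Against any ergodic opponent (at zero noise) the
#' resulting strategy enforces the linear score relation
#' \eqn{s_{opp} - \kappa = \chi (s_{zd} - \kappa)}: `kappa` is the baseline
#' score it pins, and `chi` the slope of the enforced line. `kappa = R`
#' gives a generous ("robust") ZD strategy, `kappa = P` an extortionate one.
#'
#' The sign convention above is the unique one under which both standard
#' parameter sets (`kappa = R` and `kappa = P`, with `chi = 1/2`,
#' `phi = 0.1` on the default donation game) produce valid probability
#' vectors; the enforced relation is pinned by tests rather than assumed.
#'
#' @param kappa Baseline score of the enforced relation.
#' @param chi Slope, in `(0, 1]` for the strategies used here.
#' @param phi Scale parameter; the construction must land in `[0,1]^4`.
#' @param matrix A [game_matrix()].
#' @return A named strategy vector.
#' @export
#' @examples
#' zd_strategy(kappa = 2, chi = 0.5, phi = 0.1, donation_matrix(3, 1))
#' zdr_strategy()   # generous:     (1, 0.75, 0.35, 0.1)
#' zd_chi_strategy()  # extortionate: (0.9, 0.65, 0.25, 0)
zd_strategy <- function(kappa, chi, phi, matrix = donation_matrix(3, 1)) {
  Sx <- payoffs_focal(matrix)
  Sy <- payoffs_opponent(matrix)
  p <- c(1, 1, 0, 0) + phi * (chi * (Sx - kappa) - (Sy - kappa))
  tol <- 1e-9
  if (any(p < -tol) || any(p > 1 + tol)) {
    abort(sprintf(
      "ZD parameters (kappa=%g, chi=%g, phi=%g) give probabilities outside [0,1]: (%s)",
      kappa, chi, phi, paste(signif(p, 4), collapse = ", ")))
  }
  as_strategy(pmin(pmax(p, 0), 1), "ZD strategy")
}

#' @rdname zd_strategy
#' @details `zdr_strategy()` and `zd_chi_strategy()` give the two standard
#'   parameterizations used throughout: the robust/generous `ZDR`
#'   (`kappa = R`, `chi = 1/2`, `phi = 0.1`) and the extortionate `ZD_chi`
#'   (`kappa = P`, `chi = 1/2`, `phi = 0.1`).
#' @export
zdr_strategy <- function(matrix = donation_matrix(3, 1), chi = 0.5, phi = 0.1) {
  zd_strategy(kappa = matrix$R, chi = chi, phi = phi, matrix = matrix)
}

#' @rdname zd_strategy
#' @export
zd_chi_strategy <- function(matrix = donation_matrix(3, 1), chi = 0.5, phi = 0.1) {
  zd_strategy(kappa = matrix$P, chi = chi, phi = phi, matrix = matrix)
}

#' Tag-based strategy pairs
#'
#' An idealized player that is told the true type of each opponent and plays
#' one memory-one vector against players of its own type (`vs_self`) and
#' another against the opposing type (`vs_other`). `con_def()` is the
#' conditional defector (cooperate with own type, defect against others);
#' `zd_t()` cooperates with its own type and plays a ZD vector against
#' others.
#'
#' @param vs_self,vs_other Memory-one vectors.
#' @param first_move_self,first_move_other First moves when no previous
#'   outcome with a partner exists.
#' @return An object of class `tag_pair`.
#' @export
#' @examples
#' con_def()
#' zd_t()
tag_pair <- function(vs_self, vs_other,
                     first_move_self = "C", first_move_other = "C") {
  stopifnot(first_move_self %in% MOVES, first_move_other %in% MOVES)
  structure(
    list(vs_self = as_strategy(vs_self, "vs_self"),
         vs_other = as_strategy(vs_other, "vs_other"),
         first_move_self = first_move_self,
         first_move_other = first_move_other),
    class = "tag_pair")
}

#' @rdname tag_pair
#' @export
con_def <- function() tag_pair(ALLC, ALLD, first_move_other = "D")

#' @param matrix A [game_matrix()] used to build the ZD vector.
#' @param vector The ZD vector played against the opposing type; defaults to
#'   [zdr_strategy()].
#' @rdname tag_pair
#' @export
zd_t <- function(matrix = donation_matrix(3, 1), vector = zdr_strategy(matrix)) {
  tag_pair(ALLC, vector)
}

#' @export
print.tag_pair <- function(x, ...) {
  cat("<tag_pair>\n  vs self:  (", paste(x$vs_self, collapse = ", "),
      ") first move ", x$first_move_self, "\n  vs other: (",
      paste(x$vs_other, collapse = ", "), ") first move ",
      x$first_move_other, "\n", sep = "")
  invisible(x)
}

#' Information player configuration
#'
#' Tunable parameters of the information player `IP0`: the length of the
#' information-gain phase per opponent (rounds), the significance level of
#' the binomial self-recognition test, the per-round state-switch
#' probability of the two-state HMM used for self-recognition in the
#' groupmax phase, and the error rate the player assumes when evaluating
#' move likelihoods (`NULL` means: use the ambient simulation noise).
#'
#' @param infogain_length Rounds of infogain play per opponent (default 10).
#' @param alpha Significance level of the binomial test (default 0.01).
#' @param hmm_switch_prob HMM state-switch probability per round (default 0.01).
#' @param epsilon_assumed Assumed move-error rate, or `NULL` for the ambient rate.
#' @return A list of class `ip_config`.
#' @export
ip_config <- function(infogain_length = 10, alpha = 0.01,
                      hmm_switch_prob = 0.01, epsilon_assumed = NULL) {
  stopifnot(infogain_length >= 1, alpha > 0, alpha <= 1,
            hmm_switch_prob >= 0, hmm_switch_prob <= 1,
            is.null(epsilon_assumed) ||
              (epsilon_assumed >= 0 && epsilon_assumed <= 0.5))
  structure(list(infogain_length = as.integer(infogain_length), alpha = alpha,
                 hmm_switch_prob = hmm_switch_prob,
                 epsilon_assumed = epsilon_assumed),
            class = "ip_config")
}

#' Player specifications for the population engine
#'
#' A `player_spec` bundles everything the evolutionary engine needs to
#' instantiate a player: its kind (`memory_one`, `tag_based`, `ip0` or
#' `conswitch`), its payload (strategy vector, tag pair, or information
#' player configuration), its first move, and a type label used for
#' fixation bookkeeping.
#'
#' * `memory_one_player()`: plays a fixed strategy vector. The default first
#'   move is `"C"` except for the all-defect vector.
#' * `tag_player()`: a tag-based idealized player (see [tag_pair()]).
#' * `ip0_player()`: the full information player, inferring opponent
#'   strategies, recognizing other IP0s, and optimizing its group strategy.
#' * `conswitch_player()`: the tag-based information player; true type tags
#'   replace the infogain/recognition machinery but opponent-vector
#'   estimation and groupmax optimization are retained.
#'
#' @param vector Memory-one strategy vector.
#' @param first_move First move when no previous outcome exists.
#' @param name Type label (defaults to something descriptive).
#' @param pair A [tag_pair()].
#' @param config An [ip_config()].
#' @return A list of class `player_spec`.
#' @export
#' @examples
#' memory_one_player(TFT, name = "TFT")
#' ip0_player()
memory_one_player <- function(vector, first_move = NULL, name = NULL) {
  vector <- as_strategy(vector)
  if (is.null(first_move)) first_move <- if (all(vector == 0)) "D" else "C"
  stopifnot(first_move %in% MOVES)
  structure(list(kind = "memory_one", vector = unname(vector),
                 first_move = first_move,
                 name = name %||% paste0("mem1(", paste(signif(vector, 3), collapse = ","), ")")),
            class = "player_spec")
}

#' @rdname memory_one_player
#' @export
tag_player <- function(pair, name = NULL) {
  stopifnot(inherits(pair, "tag_pair"))
  structure(list(kind = "tag_based",
                 vs_self = unname(pair$vs_self), vs_other = unname(pair$vs_other),
                 first_move_self = pair$first_move_self,
                 first_move_other = pair$first_move_other,
                 name = name %||% "tag"),
            class = "player_spec")
}

#' @rdname memory_one_player
#' @export
ip0_player <- function(config = ip_config(), name = "IP0") {
  stopifnot(inherits(config, "ip_config"))
  structure(c(list(kind = "ip0", name = name), unclass(config)),
            class = "player_spec")
}

#' @rdname memory_one_player
#' @export
conswitch_player <- function(config = ip_config(), name = "ConSwitch") {
  stopifnot(inherits(config, "ip_config"))
  structure(c(list(kind = "conswitch", name = name), unclass(config)),
            class = "player_spec")
}

#' @export
print.player_spec <- function(x, ...) {
  cat(sprintf("<player_spec> %s [%s]\n", x$name, x$kind))
  invisible(x)
}

# Coerce a strategy vector / tag pair / spec to a player_spec.
as_player_spec <- function(x, name = NULL) {
  if (inherits(x, "player_spec")) {
    if (!is.null(name)) x$name <- name
    return(x)
  }
  if (inherits(x, "tag_pair")) return(tag_player(x, name = name))
  if (is.numeric(x)) return(memory_one_player(x, name = name))
  abort("cannot interpret object as a player specification")
}

#' Read a strategy roster from a configuration file
#'
#' Reads a YAML (or JSON) roster mapping strategy names to either a vector
#' of four cooperation probabilities, a ZD parameter triple
#' (`kappa`, `chi`, `phi`), or a player kind (`"ip0"`, `"conswitch"`).
#'
#' @param path Path to the roster file.
#' @param matrix Payoff matrix used to resolve ZD parameter triples.
#' @return A named list of [player_spec][memory_one_player] objects.
#' @export
read_roster <- function(path, matrix = donation_matrix(3, 1)) {
  spec <- yaml::read_yaml(path)
  out <- lapply(names(spec), function(nm) {
    entry <- spec[[nm]]
    if (is.character(entry) && length(entry) == 1L) {
      return(switch(entry,
                    ip0 = ip0_player(name = nm),
                    conswitch = conswitch_player(name = nm),
                    abort(sprintf("unknown player kind '%s' for '%s'", entry, nm))))
    }
    if (is.list(entry) && all(c("kappa", "chi", "phi") %in% names(entry))) {
      return(memory_one_player(
        zd_strategy(entry$kappa, entry$chi, entry$phi, matrix), name = nm))
    }
    vec <- unlist(entry, use.names = FALSE)
    if (is.numeric(vec) && length(vec) == 4L) {
      return(memory_one_player(vec, name = nm))
    }
    abort(sprintf("cannot interpret roster entry '%s'", nm))
  })
  names(out) <- names(spec)
  out
}
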