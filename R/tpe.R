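#' TPE sampler configuration
#'
#' Hyperparameters of the categorical tree-structured Parzen estimator. The
#' defaults mirror the common framework defaults for categorical TPE:
#' 10 random startup trials, 24 acquisition candidates per position, prior
#' weight 1, and a good-set size of `min(ceil(0.1 n), 25)` observations.
#'
#' @param gamma_fraction Fraction in (0, 1) defining the good-set size as
#'   `ceil(gamma_fraction * n)`, or `NULL` (default) for the adaptive rule
#'   `min(ceil(0.1 n), 25)`.
#' @param n_startup_trials Number of uniform-random trials before TPE
#'   proposals start (warm-start records count toward the history).
#' @param n_ei_candidates Number of candidate residues drawn per position when
#'   maximizing the density ratio.
#' @param prior_weight Weight of the uniform pseudo-observation smoothing the
#'   categorical Parzen densities (> 0).
#' @return A classed list (`tpe_config`).
#' @export
tpe_config <- function(gamma_fraction = NULL, n_startup_trials = 10L,
                       n_ei_candidates = 24L, prior_weight = 1.0) {
  if (!is.null(gamma_fraction))
    stopifnot(is.numeric(gamma_fraction), gamma_fraction > 0,
              gamma_fraction < 1)
  stopifnot(n_startup_trials >= 0, n_ei_candidates >= 1, prior_weight > 0)
  structure(list(gamma_fraction = gamma_fraction,
                 n_startup_trials = as.integer(n_startup_trials),
                 n_ei_candidates = as.integer(n_ei_candidates),
                 prior_weight = as.numeric(prior_weight)),
            class = "tpe_config")
}

n_good_rule <- function(n, config) {
  ng <- if (is.null(config$gamma_fraction)) {
    min(ceiling(0.1 * n), 25L)
  } else {
    ceiling(config$gamma_fraction * n)
  }
  as.integer(max(1L, min(ng, n)))
}

#' Split the trial history into good and bad sets
#'
#' TPE works in a minimization convention: internally the objective is
#' negated, and the good set is the `ceil(gamma * n)` trials with the lowest
#' internal value (i.e. the highest objective). Ties are broken stably by
#' trial index. The two sets partition the history.
#'
#' @param history Data frame of trial records with columns `trial` (0-based
#'   index) and `objective`.
#' @param config A [tpe_config()].
#' @return A list with integer row-index vectors `good` and `bad`, and the
#'   good-set size `n_good`.
#' @export
split_observations <- function(history, config = tpe_config()) {
  if (nrow(history) < 1L) stop("history is empty")
  split_core(history$objective, history$trial, config)
}

# Plain-vector split used by the hot loop.
split_core <- function(objective, trial, config) {
  n <- length(objective)
  ord <- order(-objective, trial)   # minimize -objective; ties by trial index
  ng <- n_good_rule(n, config)
  list(good = sort(ord[seq_len(ng)]),
       bad = sort(ord[setdiff(seq_len(n), seq_len(ng))]),
       n_good = ng)
}

#' Smoothed categorical Parzen density at one position
#'
#' The empirical residue distribution smoothed with a uniform
#' pseudo-observation: `p(c) = (count(c) + w/K) / (N + w)` with `K` candidate
#' residues, `N` observations and prior weight `w`. With no observations this
#' is the uniform prior; every probability is strictly positive.
#'
#' @param observations Character vector of observed residues (multiset), in
#'   trial order.
#' @param candidates Ordered character vector of allowed residues.
#' @param prior_weight Positive smoothing weight.
#' @param weights Optional non-negative per-observation weights (defaults to
#'   unit weights). The sampler passes the framework-default recency ramp via
#'   [tpe_weights()], which keeps old observations from permanently
#'   suppressing a residue's density ratio.
#' @return Named probability vector over `candidates`, summing to 1.
#' @export
categorical_parzen <- function(observations, candidates, prior_weight = 1.0,
                               weights = NULL) {
  stopifnot(prior_weight > 0, length(candidates) >= 1L)
  outside <- setdiff(unique(observations), candidates)
  if (length(outside))
    stop("observed residue(s) outside the candidate set: ",
         paste(outside, collapse = ", "))
  K <- length(candidates)
  if (is.null(weights)) weights <- rep(1, length(observations))
  stopifnot(length(weights) == length(observations), all(weights >= 0))
  idx <- match(observations, candidates)
  counts <- vapply(seq_len(K), function(k) sum(weights[idx == k]),
                   numeric(1L))
  p <- (counts + prior_weight / K) / (sum(weights) + prior_weight)
  stats::setNames(p, candidates)
}

#' Recency weights for a set of n observations
#'
#' The framework-default observation weighting: sets of up to 25 observations
#' are unweighted; in larger sets the oldest `n - 25` observations ramp
#' linearly from `1/n` up to 1 while the newest 25 keep weight 1.
#'
#' @param n Number of observations (trial order).
#' @return Numeric weight vector of length `n`.
#' @export
tpe_weights <- function(n) {
  if (n <= 25L) return(rep(1, n))
  c(seq(1 / n, 1, length.out = n - 25L), rep(1, 25L))
}

#' Propose the next variant by density-ratio maximization
#'
#' Before `n_startup_trials` observations exist, returns a uniform-random
#' valid variant. Afterwards the history is split into good and bad sets; at
#' each position a smoothed categorical density is built from each set,
#' `n_ei_candidates` residues are drawn from the good density, each draw is
#' scored by `log p_good(c) - log p_bad(c)` (the log density ratio, the
#' categorical-TPE acquisition), and the best-scoring draw wins — ties go to
#' the earliest draw, which keeps proposals uniform when the two densities
#' coincide. Positions are treated independently (univariate TPE). The result
#' is deterministic given the history and the RNG state (or `seed`).
#'
#' @param history Trial-record data frame (columns `trial`, `objective`, and
#'   assignment columns `pos_*`), or `NULL`/empty for a startup draw.
#' @param space A [search_space()].
#' @param config A [tpe_config()].
#' @param seed Optional integer; when given, the draw is made under this seed
#'   without disturbing the caller's RNG state.
#' @return Character vector: the proposed variant assignment.
#' @export
propose <- function(history, space, config = tpe_config(), seed = NULL) {
  if (!is.null(seed))
    return(withr::with_seed(seed, propose(history, space, config)))
  n <- if (is.null(history)) 0L else nrow(history)
  if (n == 0L)
    return(propose_core(NULL, numeric(0), integer(0), space, config))
  A <- history_assignments(history, length(space$positions))
  propose_core(A, history$objective, history$trial, space, config)
}

# Hot-loop proposal on plain structures: A is the assignment character
# matrix (rows = trials), parallel to `objective` and `trial`.
propose_core <- function(A, objective, trial, space, config) {
  L <- length(space$positions)
  n <- length(objective)
  if (n < config$n_startup_trials || n < 2L) {
    return(vapply(space$candidates, function(cand)
      cand[sample.int(length(cand), 1L)], character(1L)))
  }
  sp <- split_core(objective, trial, config)
  wg <- tpe_weights(length(sp$good))
  wb <- tpe_weights(length(sp$bad))
  v <- character(L)
  for (j in seq_len(L)) {
    cand <- space$candidates[[j]]
    pg <- categorical_parzen(A[sp$good, j], cand, config$prior_weight, wg)
    pb <- categorical_parzen(A[sp$bad, j], cand, config$prior_weight, wb)
    draws_i <- sample.int(length(cand), config$n_ei_candidates,
                          replace = TRUE, prob = pg)
    score <- log(pg[draws_i]) - log(pb[draws_i])
    v[j] <- cand[draws_i[which.max(score)]]  # first max = earliest draw
  }
  v
}

# Extract the assignment matrix (rows = trials, cols = positions) from a
# history data frame with pos_1..pos_L columns.
history_assignments <- function(history, L) {
  if (L == 0L) return(matrix(character(0), nrow = nrow(history), ncol = 0L))
  cols <- paste0("pos_", seq_len(L))
  as.matrix(history[cols])
}

#' Seed the history with the top measured training sequences
#'
#' Projects the top-`k` training rows (by measured value, descending, stable)
#' onto the search space and scores each with the run's objective function —
#' not the lab measurement — so the history stays on a single scale. Rows not
#' realizable in the space (a mutation outside it) are skipped and counted.
#'
#' @param data A [labeled_dataset()].
#' @param space A [search_space()].
#' @param k Number of top rows to use (>= 0).
#' @param objective_fn Function `(variant) -> list(value, mu, sigma)`, e.g. a
#'   partially applied [objective_value()].
#' @return A data frame of warm-start trial records (0-based `trial`,
#'   assignment columns, `sequence`, `mu`, `sigma`, `objective`, `distance`,
#'   `provenance`), with attribute `skipped` counting unrealizable rows.
#' @export
warm_start <- function(data, space, k, objective_fn) {
  stopifnot(k >= 0)
  if (k == 0L || nrow(data) == 0L)
    return(structure(empty_history(length(space$positions)), skipped = 0L))
  ord <- order(-data$value)
  take <- ord[seq_len(min(k, nrow(data)))]
  if (k > nrow(data))
    warning("warm_start: k = ", k, " exceeds dataset size ", nrow(data))
  records <- list()
  skipped <- 0L
  for (i in take) {
    v <- project_variant(space, data$sequence[i])
    if (is.null(v)) { skipped <- skipped + 1L; next }
    records[[length(records) + 1L]] <- v
  }
  if (skipped > 0L)
    warning("warm_start: ", skipped,
            " top sequence(s) not realizable in the space; skipped")
  h <- empty_history(length(space$positions))
  for (idx in seq_along(records)) {
    v <- records[[idx]]
    sc <- objective_fn(v)
    h <- rbind(h, history_row(idx - 1L, v, space, sc, "warm_start"))
  }
  structure(h, skipped = skipped)
}

empty_history <- function(L) {
  base <- data.frame(trial = integer(0), sequence = character(0),
                     mu = numeric(0), sigma = numeric(0),
                     objective = numeric(0), distance = integer(0),
                     provenance = character(0), stringsAsFactors = FALSE)
  for (j in seq_len(L)) base[[paste0("pos_", j)]] <- character(0)
  base
}

history_row <- function(trial, v, space, score, provenance) {
  seqn <- realize_variant(space, v)
  row <- data.frame(trial = as.integer(trial), sequence = seqn,
                    mu = if (is.null(score$mu)) NA_real_ else score$mu,
                    sigma = if (is.null(score$sigma)) NA_real_ else score$sigma,
                    objective = score$value,
                    distance = hamming_distance(seqn, space$parent$residues),
                    provenance = provenance, stringsAsFactors = FALSE)
  for (j in seq_along(v)) row[[paste0("pos_", j)]] <- v[j]
  row
}
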