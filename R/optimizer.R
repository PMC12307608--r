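#' Run offline model-based optimization with (MD-)TPE
#'
#' The main fitting-style entry point: seeds the trial history with the top
#' measured training sequences (optional warm start), then runs `n_trials` of
#' propose-evaluate-append with the categorical TPE sampler. The objective is
#' either an [md_objective()] (GP proxy scored as `rho*mu - sigma` or plain
#' `mu`) or any function mapping a full-length sequence to a numeric score
#' (used, e.g., to optimize a synthetic oracle directly). Everything is
#' deterministic given the seed; duplicate proposals are evaluated and
#' recorded (deduplication happens only in [top_k()]).
#'
#' @param space A [search_space()].
#' @param objective An [md_objective()] or a function `(sequence) -> numeric`.
#' @param featurizer Featurizer closure; defaults to
#'   [onehot_featurizer()] over `space`. Ignored for function objectives.
#' @param n_trials Number of sampled trials (>= 1).
#' @param warm_start_data Optional [labeled_dataset()] supplying the warm
#'   start.
#' @param warm_start_k Number of top training sequences to seed with.
#' @param tpe A [tpe_config()].
#' @param seed Integer RNG seed.
#' @return An object of class `mdtpe_run`: list with `history` (one row per
#'   trial: 0-based `trial`, assignment columns, `sequence`, `mu`, `sigma`,
#'   `objective`, `distance`, `provenance`), `best` (the best-objective row),
#'   `config`, `space`, and `n_warm`.
#' @examples
#' parent <- parent_sequence("toy", "AAAA")
#' space <- search_space(parent, 1:4, rep(list(c("A", "V")), 4))
#' fit <- mdtpe(space, function(s) -hamming_distance(s, parent$residues),
#'              n_trials = 50, seed = 1)
#' fit$best$sequence # the parent: objective favours zero mutations
#' @export
mdtpe <- function(space, objective, featurizer = NULL, n_trials = 1000L,
                  warm_start_data = NULL, warm_start_k = 0L,
                  tpe = tpe_config(), seed = 1L) {
  stopifnot(inherits(space, "search_space"), n_trials >= 1)
  is_md <- inherits(objective, "md_objective")
  if (!is_md && !is.function(objective))
    stop("objective must be an md_objective or a function(sequence)")
  if (is.null(featurizer) && is_md) featurizer <- onehot_featurizer(space)
  L <- length(space$positions)

  score_fn <- if (is_md) {
    function(v) objective_value(objective, space, v, featurizer)
  } else {
    function(v) {
      val <- objective(realize_variant(space, v))
      if (!is.numeric(val) || length(val) != 1L || !is.finite(val))
        stop("objective function must return one finite number")
      list(value = as.numeric(val), mu = NA_real_, sigma = NA_real_)
    }
  }

  withr::local_seed(seed)

  warm <- if (!is.null(warm_start_data) && warm_start_k > 0L) {
    warm_start(warm_start_data, space, warm_start_k, score_fn)
  } else {
    empty_history(L)
  }
  n_warm <- nrow(warm)

  n_tot <- n_warm + n_trials
  A <- matrix(NA_character_, nrow = n_tot, ncol = L)
  objective_v <- numeric(n_tot)
  mu_v <- sigma_v <- numeric(n_tot)
  seq_v <- prov_v <- character(n_tot)
  dist_v <- integer(n_tot)
  if (n_warm > 0L) {
    A[seq_len(n_warm), ] <- history_assignments(warm, L)
    objective_v[seq_len(n_warm)] <- warm$objective
    mu_v[seq_len(n_warm)] <- warm$mu
    sigma_v[seq_len(n_warm)] <- warm$sigma
    seq_v[seq_len(n_warm)] <- warm$sequence
    dist_v[seq_len(n_warm)] <- warm$distance
    prov_v[seq_len(n_warm)] <- warm$provenance
  }
  trial_v <- seq_len(n_tot) - 1L

  for (t in seq_len(n_trials)) {
    i <- n_warm + t
    nhist <- i - 1L
    v <- propose_core(A[seq_len(nhist), , drop = FALSE],
                      objective_v[seq_len(nhist)],
                      trial_v[seq_len(nhist)], space, tpe)
    prov_v[i] <- if (nhist < tpe$n_startup_trials || nhist < 2L)
      "random_startup" else "sampled"
    sc <- tryCatch(score_fn(v), error = function(e)
      stop("objective evaluation failed at trial ", i - 1L, ": ",
           conditionMessage(e)))
    A[i, ] <- v
    objective_v[i] <- sc$value
    mu_v[i] <- sc$mu
    sigma_v[i] <- sc$sigma
    seq_v[i] <- realize_variant(space, v)
    dist_v[i] <- hamming_distance(seq_v[i], space$parent$residues)
  }

  history <- data.frame(trial = trial_v, sequence = seq_v, mu = mu_v,
                        sigma = sigma_v, objective = objective_v,
                        distance = dist_v, provenance = prov_v,
                        stringsAsFactors = FALSE)
  for (j in seq_len(L)) history[[paste0("pos_", j)]] <- A[, j]

  cfg <- run_config(
    rho = if (is_md) objective$rho else 1,
    n_trials = n_trials, warm_start_k = warm_start_k, seed = seed,
    objective_mode = if (is_md) objective$mode else "mean_only",
    tpe = unclass(tpe))
  structure(list(history = history,
                 best = history[which.max(history$objective), , drop = FALSE],
                 config = cfg, space = space, n_warm = n_warm),
            class = "mdtpe_run")
}

#' @export
print.mdtpe_run <- function(x, ...) {
  cat("MD-TPE run:", x$config$n_trials, "trials (+", x$n_warm,
      "warm-start) on", length(x$space$positions), "mutable positions\n")
  cat("  objective:", x$config$objective_mode,
      if (x$config$objective_mode == "mean_deviation")
        sprintf("(rho = %.3g)", x$config$rho) else "", "\n")
  b <- x$best
  cat(sprintf("  best objective %.4g at trial %d (distance %d from parent)\n",
              b$objective, b$trial, b$distance))
  invisible(x)
}

#' @export
summary.mdtpe_run <- function(object, k = 48L, landscape = NULL, ...) {
  summarize_run(object, object$space, k = k, landscape = landscape)
}

#' Scatter of GP mean against GP deviation over a run
#'
#' The standard diagnostic view of safe exploration: a mean-only run drifts
#' to the high-deviation region, a mean-deviation run stays below the
#' training deviation envelope.
#'
#' @param x An `mdtpe_run`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mdtpe_run <- function(x, ...) {
  h <- x$history
  if (all(is.na(h$sigma)))
    stop("run has no GP predictions to plot (function objective)")
  graphics::plot(h$mu, h$sigma, xlab = "GP mean", ylab = "GP deviation",
                 pch = 16, cex = 0.6,
                 col = ifelse(h$provenance == "warm_start", "grey50", "#2166ac"),
                 main = paste0("Sampled sequences (", x$config$objective_mode,
                               ")"), ...)
  invisible(x)
}

#' Extract the top-k proposals of a run
#'
#' Rows sorted by objective value descending, ties broken by trial index;
#' optional deduplication collapses identical sequences keeping the earliest.
#'
#' @param result An `mdtpe_run`.
#' @param k Number of rows wanted (>= 1; fewer are returned if the history is
#'   smaller).
#' @param dedupe Collapse duplicate sequences first occurrence wins.
#' @return Data frame with columns `sequence`, `mu`, `sigma`, `objective`,
#'   `distance`, `trial`.
#' @export
top_k <- function(result, k, dedupe = TRUE) {
  stopifnot(inherits(result, "mdtpe_run"), k >= 1)
  h <- result$history
  ord <- order(-h$objective, h$trial)
  h <- h[ord, , drop = FALSE]
  if (dedupe) h <- h[!duplicated(h$sequence), , drop = FALSE]
  out <- h[seq_len(min(k, nrow(h))),
           c("sequence", "mu", "sigma", "objective", "distance", "trial")]
  rownames(out) <- NULL
  out
}
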