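#' Mean-deviation acquisition value
#'
#' The risk-averse objective `rho * mu - sigma`: the predicted value weighted
#' by the risk tolerance rho, penalized by the predictive deviation. Large rho
#' recovers unpenalized model-based optimization; small rho keeps candidates
#' inside the low-uncertainty neighbourhood of the training data. At rho = 1
#' the ranking coincides with the lower confidence bound mu - sigma.
#'
#' @param mu Predictive mean (vectorized).
#' @param sigma Predictive deviation, `>= 0` (vectorized).
#' @param rho Risk tolerance, `> 0`.
#' @return `rho * mu - sigma`.
#' @examples
#' mean_deviation(2, 0.3, rho = 0.15) # exactly 0
#' @export
mean_deviation <- function(mu, sigma, rho) {
  stopifnot(is.numeric(mu), is.numeric(sigma), is.numeric(rho),
            length(rho) == 1L, rho > 0)
  if (any(sigma < 0)) stop("sigma must be non-negative")
  rho * mu - sigma
}

#' Objective wrapping a GP proxy
#'
#' Bundles a fitted proxy, the risk tolerance, and the mode:
#' `"mean_deviation"` scores a candidate as `rho*mu(x) - sigma(x)`;
#' `"mean_only"` scores it as `mu(x)` (the conventional-TPE objective, no
#' uncertainty penalty).
#'
#' @param proxy A [gp_fit()] proxy.
#' @param rho Risk tolerance (> 0).
#' @param mode `"mean_deviation"` or `"mean_only"`.
#' @return A classed list (`md_objective`).
#' @export
md_objective <- function(proxy, rho = 0.15,
                         mode = c("mean_deviation", "mean_only")) {
  mode <- match.arg(mode)
  stopifnot(inherits(proxy, "gp_proxy"), is.numeric(rho), rho > 0)
  structure(list(proxy = proxy, rho = as.numeric(rho), mode = mode),
            class = "md_objective")
}

#' Score one variant under an objective
#'
#' Realizes the variant, featurizes it, queries the proxy, and applies the
#' objective mode. Deterministic for a fixed variant.
#'
#' @param obj An [md_objective()].
#' @param space A [search_space()].
#' @param v Variant: character vector of residues parallel to
#'   `space$positions`.
#' @param featurizer A featurizer closure ([onehot_featurizer()] or
#'   [table_featurizer()]).
#' @return A list with `value`, `mu`, `sigma`.
#' @export
objective_value <- function(obj, space, v, featurizer) {
  stopifnot(inherits(obj, "md_objective"))
  x <- featurizer(realize_variant(space, v))
  p <- predict(obj$proxy, x)
  value <- if (obj$mode == "mean_deviation") {
    mean_deviation(p$mu, p$sigma, obj$rho)
  } else {
    p$mu
  }
  list(value = as.numeric(value), mu = p$mu, sigma = p$sigma)
}

#' Calibrate the risk tolerance rho on the training deviation envelope
#'
#' Runs a brief seeded MD-TPE optimization for each candidate rho and checks
#' whether the sampled sequences keep their GP deviation comparable to the
#' training data's: the criterion is that the median sampled sigma does not
#' exceed the 90th percentile of sigma over the training sequences. Among the
#' candidates that pass, the largest (most exploratory safe value) is chosen;
#' if none passes, the smallest grid value is returned with a warning flag in
#' the diagnostics.
#'
#' @param grid Numeric vector of candidate rho values (the published grid is
#'   `c(0.05, 0.10, 0.15, 0.20, 0.30, 0.40)`).
#' @param space A [search_space()].
#' @param proxy A [gp_fit()] proxy.
#' @param data The training [labeled_dataset()] (defines the sigma envelope
#'   and the warm start).
#' @param featurizer Featurizer closure.
#' @param budget Trials per candidate rho (default 300, a brief run of
#'   roughly a tenth of a production budget).
#' @param warm_start_k Warm-start size for the brief runs.
#' @param seed Integer seed.
#' @return A list: `rho` (chosen value), `diagnostics` (one row per grid
#'   value: rho, median_sigma, training_sigma_p90, pass, warning).
#' @export
calibrate_rho <- function(grid = c(0.05, 0.10, 0.15, 0.20, 0.30, 0.40),
                          space, proxy, data, featurizer = NULL,
                          budget = 300L, warm_start_k = 10L, seed = 1L) {
  stopifnot(length(grid) >= 1L, all(grid > 0), budget >= 10L)
  if (is.null(featurizer)) featurizer <- onehot_featurizer(space)
  train_sigma <- vapply(data$sequence, function(s)
    predict(proxy, featurizer(s))$sigma, numeric(1L), USE.NAMES = FALSE)
  p90 <- as.numeric(stats::quantile(train_sigma, 0.9, type = 7))

  grid <- sort(unique(grid))
  med <- numeric(length(grid))
  for (i in seq_along(grid)) {
    run <- mdtpe(space, md_objective(proxy, rho = grid[i],
                                     mode = "mean_deviation"),
                 featurizer = featurizer, n_trials = budget,
                 warm_start_data = data, warm_start_k = warm_start_k,
                 seed = seed)
    h <- run$history
    med[i] <- stats::median(h$sigma[h$provenance != "warm_start"])
  }
  pass <- med <= p90
  no_pass <- !any(pass)
  chosen <- if (no_pass) grid[1L] else max(grid[pass])
  diagnostics <- data.frame(rho = grid, median_sigma = med,
                            training_sigma_p90 = p90, pass = pass,
                            warning = no_pass, stringsAsFactors = FALSE)
  list(rho = chosen, diagnostics = diagnostics)
}

#' Write rho-calibration diagnostics as TSV
#'
#' @param calib A [calibrate_rho()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rho_diagnostics <- function(calib, path) {
  df <- calib$diagnostics
  df$median_sigma <- signif(df$median_sigma, 6L)
  df$training_sigma_p90 <- signif(df$training_sigma_p90, 6L)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
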