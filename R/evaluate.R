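#' Summarize a run's sampled and top-k distributions
#'
#' Collects the per-trial and top-k distributions of GP mean, GP deviation,
#' objective value and Hamming distance to the parent, with medians and IQRs,
#' plus the functional (non-collapsed) fraction when a ground-truth landscape
#' is available.
#'
#' @param result An [mdtpe()] run.
#' @param space The run's [search_space()] (defaults to the one stored in the
#'   run).
#' @param k Top-k size (48 is the usual selection size for experimental
#'   follow-up; 128 for in-silico re-scoring).
#' @param landscape Optional [generate_landscape()] oracle for functional
#'   fractions.
#' @return A list of class `run_summary` with elements `trials` (data frame),
#'   `top` (data frame), `k`, `k_truncated` (TRUE when the history is smaller
#'   than `k`), `medians`, `iqrs`, and optionally `functional_fraction`.
#' @export
summarize_run <- function(result, space = result$space, k = 48L,
                          landscape = NULL) {
  stopifnot(inherits(result, "mdtpe_run"), k >= 1)
  h <- result$history
  top <- top_k(result, k = k, dedupe = TRUE)
  metrics <- c("mu", "sigma", "objective", "distance")
  safe <- function(f, x) if (all(is.na(x))) NA_real_ else f(x, na.rm = TRUE)
  med <- lapply(metrics, function(m)
    list(trials = safe(stats::median, h[[m]]),
         top = safe(stats::median, top[[m]])))
  names(med) <- metrics
  iqr <- lapply(metrics, function(m)
    list(trials = safe(stats::IQR, h[[m]]),
         top = safe(stats::IQR, top[[m]])))
  names(iqr) <- metrics
  out <- list(trials = h[c("trial", "sequence", metrics, "provenance")],
              top = top, k = as.integer(k),
              k_truncated = nrow(top) < k,
              medians = med, iqrs = iqr)
  if (!is.null(landscape)) {
    out$functional_fraction <- list(
      trials = functional_fraction(h$sequence, landscape),
      top = functional_fraction(top$sequence, landscape))
  }
  class(out) <- "run_summary"
  out
}

#' @export
print.run_summary <- function(x, ...) {
  cat("Run summary over", nrow(x$trials), "trials; top", nrow(x$top),
      if (x$k_truncated) "(history smaller than k)" else "", "\n")
  for (m in names(x$medians))
    cat(sprintf("  median %-9s trials %8.4g | top-k %8.4g\n",
                m, x$medians[[m]]$trials, x$medians[[m]]$top))
  if (!is.null(x$functional_fraction))
    cat(sprintf("  functional fraction: trials %.3f | top-k %.3f\n",
                x$functional_fraction$trials, x$functional_fraction$top))
  invisible(x)
}

#' Rank-sum comparison of a metric between two runs
#'
#' Two-sided Mann-Whitney U test on the top-k distributions of the metric in
#' two run summaries, as used to compare mean-only against mean-deviation
#' runs. The direction is the sign of the median difference (a - b).
#'
#' @param a,b [summarize_run()] results.
#' @param metric One of `"mu"`, `"sigma"`, `"objective"`, `"distance"`.
#' @return A list with `statistic` (U), `p_value`, `direction` (-1, 0, 1),
#'   and the two medians.
#' @export
compare_runs <- function(a, b, metric = c("sigma", "mu", "objective",
                                          "distance")) {
  metric <- match.arg(metric)
  stopifnot(inherits(a, "run_summary"), inherits(b, "run_summary"))
  xa <- a$top[[metric]]
  xb <- b$top[[metric]]
  if (is.null(xa) || is.null(xb) || all(is.na(xa)) || all(is.na(xb)))
    stop("metric '", metric, "' absent from one of the summaries")
  wt <- suppressWarnings(stats::wilcox.test(xa, xb, alternative = "two.sided",
                                            exact = FALSE, correct = TRUE))
  md <- stats::median(xa) - stats::median(xb)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       direction = sign(md),
       median_a = stats::median(xa), median_b = stats::median(xb))
}

#' Fraction of sequences inside the functional region
#'
#' The simulation analogue of expression success: the fraction of sequences
#' whose Hamming distance to the parent does not exceed the landscape's
#' collapse radius.
#'
#' @param sequences Character vector of full-length sequences.
#' @param landscape A [generate_landscape()] result.
#' @return Real in `[0, 1]`.
#' @export
functional_fraction <- function(sequences, landscape) {
  stopifnot(inherits(landscape, "synthetic_landscape"))
  if (length(sequences) == 0L) return(NaN)
  parent <- landscape$space$parent$residues
  d <- vapply(sequences, hamming_distance, integer(1L), b = parent,
              USE.NAMES = FALSE)
  mean(d <= landscape$collapse_distance)
}
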