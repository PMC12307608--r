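#' Generate a synthetic fitness landscape over a search space
#'
#' A ground-truth oracle with the structure offline sequence-design campaigns
#' face: additive per-mutation effects (i.i.d. normal, parent residues at 0),
#' a set of random pairwise epistatic interactions, Gaussian observation
#' noise, and a hard loss-of-function collapse — any sequence more than
#' `collapse_distance` mutations from the parent scores `collapse_value`,
#' emulating variants that are no longer expressed. The collapse region is
#' exactly the high-mean/high-uncertainty trap a proxy trained on
#' near-parent data extrapolates into.
#'
#' @param space A [search_space()] with at least one position.
#' @param n_epistasis Number of pairwise interaction terms.
#' @param effect_sd Standard deviation of additive and epistatic effects.
#' @param collapse_distance Hamming radius of the functional region (>= 1).
#' @param collapse_value Value assigned outside the functional region;
#'   `NULL` (default) uses a lower bound on in-radius values minus
#'   `3 * effect_sd`, guaranteeing collapsed sequences score below every
#'   functional one.
#' @param noise_sd Observation noise standard deviation (>= 0).
#' @param seed Integer seed; the same seed reproduces the landscape exactly.
#' @return An object of class `synthetic_landscape`.
#' @export
generate_landscape <- function(space, n_epistasis = 10L, effect_sd = 0.5,
                               collapse_distance = 4L, collapse_value = NULL,
                               noise_sd = 0.1, seed = 1L) {
  stopifnot(inherits(space, "search_space"),
            length(space$positions) >= 1L,
            collapse_distance >= 1L, noise_sd >= 0, effect_sd >= 0)
  L <- length(space$positions)
  pv <- parent_variant(space)

  pairs_avail <- if (L >= 2L) utils::combn(L, 2L) else
    matrix(integer(0), nrow = 2L)
  # one epistasis term per position pair at most, on non-parent residues
  if (n_epistasis > ncol(pairs_avail))
    stop("n_epistasis = ", n_epistasis, " exceeds available position pairs (",
         ncol(pairs_avail), ")")

  withr::local_seed(seed)
  additive <- lapply(seq_len(L), function(j) {
    cand <- space$candidates[[j]]
    eff <- stats::rnorm(length(cand), 0, effect_sd)
    eff[cand == pv[j]] <- 0
    stats::setNames(eff, cand)
  })
  epistasis <- list()
  if (n_epistasis > 0L) {
    chosen <- pairs_avail[, sample.int(ncol(pairs_avail), n_epistasis),
                          drop = FALSE]
    for (k in seq_len(n_epistasis)) {
      i <- chosen[1L, k]; j <- chosen[2L, k]
      ri <- non_parent_residue(space, i, pv)
      rj <- non_parent_residue(space, j, pv)
      epistasis[[k]] <- list(pos_i = i, res_i = ri, pos_j = j, res_j = rj,
                             effect = stats::rnorm(1L, 0, effect_sd))
    }
  }

  if (is.null(collapse_value)) {
    # lower bound on any in-radius value: the collapse_distance most negative
    # per-position minima plus every negative epistasis term
    mins <- vapply(additive, min, numeric(1L))
    neg <- sort(pmin(mins, 0))
    lb <- sum(neg[seq_len(min(collapse_distance, L))]) +
      sum(pmin(vapply(epistasis, `[[`, numeric(1L), "effect"), 0))
    collapse_value <- lb - 3 * effect_sd
  }

  structure(list(space = space, additive = additive, epistasis = epistasis,
                 collapse_distance = as.integer(collapse_distance),
                 collapse_value = as.numeric(collapse_value),
                 noise_sd = as.numeric(noise_sd), seed = as.integer(seed)),
            class = "synthetic_landscape")
}

non_parent_residue <- function(space, j, pv) {
  cand <- setdiff(space$candidates[[j]], pv[j])
  if (length(cand) == 0L) pv[j] else cand[sample.int(length(cand), 1L)]
}

#' @export
print.synthetic_landscape <- function(x, ...) {
  cat("Synthetic fitness landscape:", length(x$space$positions),
      "positions,", length(x$epistasis), "epistatic pairs\n")
  cat(sprintf("  collapse beyond distance %d -> %.3g; noise sd %.3g\n",
              x$collapse_distance, x$collapse_value, x$noise_sd))
  invisible(x)
}

#' Evaluate the ground-truth oracle
#'
#' The parent scores 0; a functional sequence scores the sum of the additive
#' effects of its non-parent residues plus every matched epistasis term; a
#' sequence beyond the collapse radius scores `collapse_value`. Optional
#' Gaussian observation noise is seeded.
#'
#' @param landscape A [generate_landscape()] result.
#' @param sequence Full-length residue string realizable in the landscape's
#'   space.
#' @param with_noise Add `N(0, noise_sd^2)` observation noise.
#' @param seed Seed for the noise draw (required when `with_noise`).
#' @return Numeric oracle value.
#' @export
oracle_value <- function(landscape, sequence, with_noise = FALSE,
                         seed = NULL) {
  space <- landscape$space
  v <- project_variant(space, sequence)
  if (is.null(v))
    stop("sequence not realizable in the landscape's search space")
  d <- hamming_distance(sequence, space$parent$residues)
  val <- if (d > landscape$collapse_distance) {
    landscape$collapse_value
  } else {
    pv <- parent_variant(space)
    s <- 0
    for (j in seq_along(v))
      if (v[j] != pv[j]) s <- s + landscape$additive[[j]][[v[j]]]
    for (ep in landscape$epistasis)
      if (v[ep$pos_i] == ep$res_i && v[ep$pos_j] == ep$res_j &&
          ep$res_i != pv[ep$pos_i] && ep$res_j != pv[ep$pos_j])
        s <- s + ep$effect
    s
  }
  if (with_noise) {
    noise <- if (is.null(seed)) stats::rnorm(1L, 0, landscape$noise_sd)
    else withr::with_seed(seed, stats::rnorm(1L, 0, landscape$noise_sd))
    val <- val + noise
  }
  as.numeric(val)
}

#' Sample a training set from the parent's neighbourhood
#'
#' Draws `n` distinct variants uniformly from the Hamming ball of radius
#' `max_d` around the parent (the parent itself always included) and labels
#' them with noisy oracle values — the offline dataset of a mutational scan
#' concentrated near the template.
#'
#' @param landscape A [generate_landscape()] result.
#' @param n Number of rows (must not exceed the ball size).
#' @param max_d Maximum Hamming distance of sampled variants.
#' @param seed Integer seed.
#' @return A [labeled_dataset()].
#' @export
generate_training_set <- function(landscape, n, max_d = 2L, seed = 1L) {
  space <- landscape$space
  ball <- enumerate_ball(space, max_d)
  if (n > nrow(ball))
    stop("n = ", n, " exceeds the ", nrow(ball),
         " distinct variants within distance ", max_d)
  withr::local_seed(seed)
  pick <- c(1L, sample(seq_len(nrow(ball))[-1L], n - 1L))  # row 1 = parent
  seqs <- apply(ball[pick, , drop = FALSE], 1L, function(v)
    realize_variant(space, v))
  vals <- vapply(seqs, function(s)
    oracle_value(landscape, s, with_noise = landscape$noise_sd > 0),
    numeric(1L), USE.NAMES = FALSE)
  labeled_dataset(seqs, vals)
}

# Enumerate all variants within Hamming distance max_d of the parent
# (parent first). Rows are assignment vectors.
enumerate_ball <- function(space, max_d, max_variants = 2e5) {
  L <- length(space$positions)
  pv <- parent_variant(space)
  rows <- list(pv)
  if (max_d >= 1L && L >= 1L) {
    for (d in seq_len(min(max_d, L))) {
      subsets <- utils::combn(L, d, simplify = FALSE)
      for (sub in subsets) {
        alts <- lapply(sub, function(j)
          setdiff(space$candidates[[j]], pv[j]))
        if (any(vapply(alts, length, integer(1L)) == 0L)) next
        grid <- expand.grid(alts, stringsAsFactors = FALSE,
                            KEEP.OUT.ATTRS = FALSE)
        for (g in seq_len(nrow(grid))) {
          v <- pv
          v[sub] <- as.character(grid[g, ])
          rows[[length(rows) + 1L]] <- v
          if (length(rows) > max_variants)
            stop("Hamming ball exceeds ", max_variants, " variants")
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Serialize / restore a landscape as JSON
#'
#' @param landscape A [generate_landscape()] result.
#' @param path Output JSON path.
#' @return `path` invisibly ([write_landscape()]); the landscape
#'   ([read_landscape()]).
#' @export
write_landscape <- function(landscape, path) {
  space <- landscape$space
  obj <- list(
    parent = list(id = space$parent$id, residues = space$parent$residues),
    positions = space$positions,
    candidates = space$candidates,
    additive = lapply(landscape$additive, as.list),
    epistasis = landscape$epistasis,
    collapse_distance = landscape$collapse_distance,
    collapse_value = landscape$collapse_value,
    noise_sd = landscape$noise_sd,
    seed = landscape$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  parent <- parent_sequence(obj$parent$id, obj$parent$residues)
  cand <- lapply(obj$candidates, function(x) unlist(x, use.names = FALSE))
  space <- search_space(parent, unlist(obj$positions), cand)
  additive <- lapply(obj$additive, function(a)
    stats::setNames(as.numeric(unlist(a)), names(a)))
  epistasis <- lapply(obj$epistasis, function(ep)
    list(pos_i = as.integer(ep$pos_i), res_i = ep$res_i,
         pos_j = as.integer(ep$pos_j), res_j = ep$res_j,
         effect = as.numeric(ep$effect)))
  structure(list(space = space, additive = additive, epistasis = epistasis,
                 collapse_distance = as.integer(obj$collapse_distance),
                 collapse_value = as.numeric(obj$collapse_value),
                 noise_sd = as.numeric(obj$noise_sd),
                 seed = as.integer(obj$seed)),
            class = "synthetic_landscape")
}
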