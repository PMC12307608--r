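#' Read parent/proposed sequences from a FASTA file
#'
#' Sequences are uppercased; headers become ids; wrapped and unwrapped records
#' are both accepted. Residues outside the alphabet are rejected.
#'
#' @param path FASTA file path.
#' @param alphabet Allowed residue characters.
#' @return A list of [parent_sequence()] objects.
#' @export
read_fasta <- function(path, alphabet = AA_ALPHABET) {
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("cannot parse FASTA '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0L)
    stop("FASTA file '", path, "' contains no records")
  lapply(seq_along(set), function(i) {
    parent_sequence(names(set)[i], as.character(set[[i]]),
                    alphabet = alphabet)
  })
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector (names become headers) or a list of
#'   [parent_sequence()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (is.list(sequences) && all(vapply(sequences, inherits, logical(1L),
                                       "parent_sequence"))) {
    nm <- vapply(sequences, `[[`, character(1L), "id")
    sequences <- stats::setNames(
      vapply(sequences, `[[`, character(1L), "residues"), nm)
  }
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a labeled variant dataset from a delimited file
#'
#' Rows are kept in file order; duplicated sequences are retained. Values must
#' parse as finite reals; malformed rows raise row-identified errors rather
#' than being coerced.
#'
#' @param path CSV (or TSV via `sep`) file with a header row.
#' @param seq_col,value_col Column names holding the sequence and the measured
#'   value.
#' @param sep Field separator, `","` by default.
#' @return A [labeled_dataset()].
#' @export
read_labeled_csv <- function(path, seq_col = "sequence", value_col = "value",
                             sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = "character",
                          check.names = FALSE)
  for (col in c(seq_col, value_col))
    if (!col %in% names(df))
      stop("column '", col, "' not found in '", path, "' (columns: ",
           paste(names(df), collapse = ", "), ")")
  vals <- suppressWarnings(as.numeric(df[[value_col]]))
  bad <- which(is.na(vals) | !is.finite(vals))
  if (length(bad))
    stop("non-finite or non-numeric value '", df[[value_col]][bad[1L]],
         "' at data row ", bad[1L])
  labeled_dataset(df[[seq_col]], vals)
}

#' Run configuration
#'
#' Bundles the knobs of one optimization run: the risk tolerance rho, the
#' trial budget, the warm-start size, the seed, the objective mode, sampler
#' overrides, and the featurization scheme.
#'
#' @param rho Risk tolerance (> 0). Values below 1 weight the uncertainty
#'   penalty over the predicted mean and keep the search near the training
#'   data; the default 0.15 is the published working point.
#' @param n_trials Number of sampler trials (>= 1).
#' @param warm_start_k Number of top training sequences used to seed the
#'   history (>= 0).
#' @param seed Integer RNG seed.
#' @param objective_mode `"mean_deviation"` (rho*mu - sigma) or `"mean_only"`
#'   (plain mu, the conventional-TPE objective).
#' @param featurization Name of the featurization scheme (`"onehot"` or
#'   `"table"`).
#' @param tpe Optional list of [tpe_config()] overrides
#'   (`gamma_fraction`, `n_startup_trials`, `n_ei_candidates`, `prior_weight`).
#' @return A classed list (`run_config`).
#' @export
run_config <- function(rho = 0.15, n_trials = 1000L, warm_start_k = 10L,
                       seed = 1L,
                       objective_mode = c("mean_deviation", "mean_only"),
                       featurization = "onehot", tpe = list()) {
  objective_mode <- match.arg(objective_mode)
  stopifnot(is.numeric(rho), length(rho) == 1L, rho > 0,
            n_trials >= 1, warm_start_k >= 0)
  structure(list(rho = as.numeric(rho),
                 n_trials = as.integer(n_trials),
                 warm_start_k = as.integer(warm_start_k),
                 seed = as.integer(seed),
                 objective_mode = objective_mode,
                 featurization = featurization,
                 tpe = tpe),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path File ending in `.yaml`/`.yml` or `.json`.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(run_config))
  do.call(run_config, lst[intersect(names(lst), known)])
}

#' Write a run configuration
#'
#' @param config A [run_config()].
#' @param path Destination ending in `.yaml`/`.yml` or `.json`.
#' @return `path`, invisibly. Round-trips through [read_run_config()]
#'   unchanged.
#' @export
write_run_config <- function(config, path) {
  lst <- unclass(config)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(lst, path)
  } else {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Write the per-trial report of a run
#'
#' Emits a TSV of per-trial records (trial index, sequence, GP mean and
#' deviation, objective value, Hamming distance to the parent) and a JSON
#' sidecar holding the run configuration. Numeric columns use 6 significant
#' digits; output is byte-identical across reruns with the same seed.
#'
#' @param result An [mdtpe()] run result.
#' @param path Output TSV path; the sidecar is written to
#'   `paste0(path, ".config.json")`.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(result, path) {
  stopifnot(inherits(result, "mdtpe_run"))
  h <- result$history
  df <- data.frame(
    trial = h$trial,
    sequence = h$sequence,
    mu = signif(h$mu, 6L),
    sigma = signif(h$sigma, 6L),
    objective = signif(h$objective, 6L),
    hamming_to_parent = h$distance,
    provenance = h$provenance,
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_run_config(result$config, paste0(path, ".config.json"))
  invisible(path)
}
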