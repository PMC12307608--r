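# Canonical 20-letter amino-acid alphabet. An extended alphabet (e.g. with X)
# can be passed explicitly where a function takes `alphabet`.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Parent (template) protein sequence
#'
#' Constructs the template sequence that a mutation search space and all
#' variant distances are measured against, e.g. avGFP for a GFP brightness
#' campaign or a lead antibody clone for affinity maturation.
#'
#' @param id Character scalar identifier (FASTA header).
#' @param residues Character scalar: the amino-acid sequence, one-letter code.
#'   Uppercased on input.
#' @param alphabet Allowed residue characters; defaults to the canonical
#'   20-letter alphabet.
#' @return An object of class `parent_sequence` with elements `id` and
#'   `residues`.
#' @examples
#' parent_sequence("toy", "ACDEFGHIKL")
#' @export
parent_sequence <- function(id, residues, alphabet = AA_ALPHABET) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (nchar(residues) == 0L)
    stop("parent sequence '", id, "' is empty")
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), alphabet)
  if (length(bad))
    stop("parent sequence '", id, "' contains residues outside the alphabet: ",
         paste(bad, collapse = ", "))
  structure(list(id = id, residues = residues),
            class = "parent_sequence")
}

#' @export
print.parent_sequence <- function(x, ...) {
  cat("Parent sequence '", x$id, "' (", nchar(x$residues), " aa)\n", sep = "")
  invisible(x)
}

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

#' Mutation search space over a parent sequence
#'
#' A search space is a set of mutable positions of the parent together with
#' the candidate residues allowed at each; the discrete optimization domain is
#' the Cartesian product of the candidate sets. The parent residue is always a
#' member of its position's candidate set, so the unmutated parent is in-space.
#'
#' @param parent A [parent_sequence()].
#' @param positions Integer vector of 1-based positions into the parent,
#'   strictly increasing.
#' @param candidates List of character vectors, parallel to `positions`: the
#'   allowed residues at each position. The parent residue is added if absent.
#' @return An object of class `search_space`.
#' @seealso [build_search_space()] to construct one from labeled data.
#' @export
search_space <- function(parent, positions, candidates) {
  stopifnot(inherits(parent, "parent_sequence"))
  positions <- as.integer(positions)
  L <- nchar(parent$residues)
  if (length(positions)) {
    if (any(positions < 1L | positions > L))
      stop("positions must lie in 1..", L)
    if (is.unsorted(positions, strictly = TRUE))
      stop("positions must be strictly increasing and unique")
  }
  if (length(candidates) != length(positions))
    stop("candidates list length (", length(candidates),
         ") must equal number of positions (", length(positions), ")")
  pchars <- seq_chars(parent$residues)
  candidates <- lapply(seq_along(positions), function(i) {
    cand <- unique(toupper(candidates[[i]]))
    par_res <- pchars[positions[i]]
    if (!par_res %in% cand) cand <- c(par_res, cand)
    if (length(cand) > 20L)
      stop("candidate set at position ", positions[i], " exceeds 20 residues")
    cand
  })
  structure(list(parent = parent,
                 positions = positions,
                 candidates = candidates),
            class = "search_space")
}

#' @export
print.search_space <- function(x, ...) {
  cat("Mutation search space on '", x$parent$id, "': ",
      length(x$positions), " mutable positions, ",
      count_combinations(x), " variant combinations\n", sep = "")
  invisible(x)
}

#' Hamming distance between equal-length residue strings
#'
#' The number of positions at which two fixed-length substitution variants
#' differ. For indel-free variant libraries this coincides with edit distance.
#'
#' @param a,b Character scalars of equal length.
#' @return Non-negative integer count of differing positions.
#' @examples
#' hamming_distance("ACDE", "ACDF") # 1
#' @export
hamming_distance <- function(a, b) {
  stopifnot(is.character(a), length(a) == 1L,
            is.character(b), length(b) == 1L)
  na <- nchar(a); nb <- nchar(b)
  if (na != nb)
    stop("sequences have unequal lengths: ", na, " vs ", nb)
  sum(seq_chars(a) != seq_chars(b))
}

#' Labeled variant dataset
#'
#' The static offline dataset D = {(sequence, value)}: full-length variant
#' sequences with one measured value each (brightness, binding affinity, ...).
#'
#' @param sequence Character vector of residue strings.
#' @param value Numeric vector of finite measured values.
#' @return A `data.frame` with columns `sequence` and `value`, classed
#'   `labeled_dataset`.
#' @export
labeled_dataset <- function(sequence, value) {
  stopifnot(is.character(sequence), is.numeric(value),
            length(sequence) == length(value))
  if (length(value) && any(!is.finite(value)))
    stop("non-finite value at row(s): ",
         paste(utils::head(which(!is.finite(value)), 5L), collapse = ", "))
  out <- data.frame(sequence = toupper(sequence), value = as.numeric(value),
                    stringsAsFactors = FALSE)
  class(out) <- c("labeled_dataset", "data.frame")
  out
}

check_lengths <- function(data, parent) {
  lens <- nchar(data$sequence)
  L <- nchar(parent$residues)
  bad <- which(lens != L)
  if (length(bad))
    stop("row ", bad[1L], ": sequence length ", lens[bad[1L]],
         " differs from parent length ", L)
  invisible(TRUE)
}

#' Restrict a dataset to the parent's mutational neighbourhood
#'
#' Keeps rows whose Hamming distance to the parent is at most `max_d`,
#' emulating the practical situation where measured variants carry only a few
#' substitutions from the template (e.g. a training set of single and double
#' mutants). Row order is preserved.
#'
#' @param data A [labeled_dataset()].
#' @param parent A [parent_sequence()].
#' @param max_d Maximum allowed Hamming distance (>= 0).
#' @return The filtered `labeled_dataset`.
#' @export
filter_by_distance <- function(data, parent, max_d) {
  stopifnot(inherits(parent, "parent_sequence"), max_d >= 0)
  check_lengths(data, parent)
  d <- vapply(data$sequence, hamming_distance, integer(1L),
              b = parent$residues, USE.NAMES = FALSE)
  out <- data[d <= max_d, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("labeled_dataset", "data.frame")
  out
}

#' Build a search space from the best measured variants
#'
#' Takes the `top_n` rows by measured value (descending; ties broken by input
#' order) and records every (position, residue) at which such a row differs
#' from the parent. The union over rows gives per-position candidate sets; the
#' parent residue is added to each set, so the parent is always in-space. This
#' is the standard construction of the mutated-positions-and-residues table
#' from a directed-evolution dataset (top-30 for the GFP task, top-100 for
#' antibody affinity maturation).
#'
#' @param data A [labeled_dataset()].
#' @param parent A [parent_sequence()].
#' @param top_n Number of top rows to use (>= 1).
#' @return A [search_space()].
#' @export
build_search_space <- function(data, parent, top_n) {
  stopifnot(inherits(parent, "parent_sequence"), top_n >= 1)
  if (nrow(data) == 0L) stop("empty dataset")
  check_lengths(data, parent)
  ord <- order(-data$value)          # stable: ties keep input order
  top <- data$sequence[ord[seq_len(min(top_n, nrow(data)))]]
  pchars <- seq_chars(parent$residues)
  cand <- list()
  for (s in top) {
    sc <- seq_chars(s)
    diffp <- which(sc != pchars)
    for (p in diffp) {
      key <- as.character(p)
      cand[[key]] <- union(cand[[key]], sc[p])
    }
  }
  positions <- sort(as.integer(names(cand)))
  search_space(parent, positions,
               lapply(as.character(positions), function(k) cand[[k]]))
}

#' Exact number of variant combinations in a search space
#'
#' The product over positions of the candidate-set sizes, computed exactly in
#' arbitrary precision (published search spaces reach beyond 1e18, past the
#' exact range of doubles).
#'
#' @param space A [search_space()].
#' @return Character scalar: the exact decimal count. `as.numeric()` gives an
#'   approximation for display.
#' @export
count_combinations <- function(space) {
  stopifnot(inherits(space, "search_space"))
  big_product(vapply(space$candidates, length, integer(1L)))
}

# Exact product of small positive integers as a decimal string.
# Digits little-endian base 10; schoolbook multiply by a small integer.
big_product <- function(ks) {
  stopifnot(all(ks >= 1L))
  digits <- 1L
  for (k in ks) {
    prod <- digits * as.integer(k)
    carry <- 0L
    for (i in seq_along(prod)) {
      v <- prod[i] + carry
      prod[i] <- v %% 10L
      carry <- v %/% 10L
    }
    while (carry > 0L) {
      prod <- c(prod, carry %% 10L)
      carry <- carry %/% 10L
    }
    digits <- prod
  }
  paste(rev(digits), collapse = "")
}

#' Realize a variant assignment as a full sequence
#'
#' Substitutes the variant's residue choices into the parent at the space's
#' mutable positions.
#'
#' @param space A [search_space()].
#' @param v Character vector of residues, parallel to `space$positions`.
#' @return Character scalar: the full-length sequence.
#' @export
realize_variant <- function(space, v) {
  stopifnot(inherits(space, "search_space"))
  if (length(v) != length(space$positions))
    stop("variant length ", length(v), " != number of positions ",
         length(space$positions))
  for (i in seq_along(v)) {
    if (!v[i] %in% space$candidates[[i]])
      stop("residue '", v[i], "' not in the candidate set at position ",
           space$positions[i])
  }
  chars <- seq_chars(space$parent$residues)
  chars[space$positions] <- v
  paste(chars, collapse = "")
}

# Parent's own assignment within a space.
parent_variant <- function(space) {
  pchars <- seq_chars(space$parent$residues)
  pchars[space$positions]
}

# Project a full sequence onto the space's assignment, or NULL when the
# sequence is not realizable (mutation outside the space, or residue not in
# the candidate set).
project_variant <- function(space, sequence) {
  pchars <- seq_chars(space$parent$residues)
  sc <- seq_chars(sequence)
  if (length(sc) != length(pchars)) return(NULL)
  diffp <- which(sc != pchars)
  if (length(setdiff(diffp, space$positions))) return(NULL)
  v <- sc[space$positions]
  for (i in seq_along(v))
    if (!v[i] %in% space$candidates[[i]]) return(NULL)
  v
}

# Enumerate every variant of a space as a character matrix (rows = variants).
# Guarded by max_variants since spaces are combinatorial.
enumerate_variants <- function(space, max_variants = 1e6) {
  n <- as.numeric(count_combinations(space))
  if (n > max_variants)
    stop("space has ", n, " variants; enumeration capped at ", max_variants)
  if (length(space$positions) == 0L)
    return(matrix(character(0), nrow = 1L, ncol = 0L))
  grid <- expand.grid(space$candidates, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  as.matrix(grid)
}

#' Write a search space as a tab-separated table
#'
#' One row per mutable position with 1-based coordinates, mirroring the usual
#' supplementary-table layout of mutated positions and residues.
#'
#' @param space A [search_space()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_search_space <- function(space, path) {
  df <- data.frame(
    position_1based = space$positions,
    parent_residue = parent_variant(space),
    candidate_residues = vapply(space$candidates, paste,
                                character(1L), collapse = ","),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
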