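#' One-hot embedding over mutable positions
#'
#' Concatenates one 20-dimensional indicator block per mutable position of the
#' space (dimension = 20 * number of positions). Positions outside the space
#' are constant across all in-space variants and carry no information, so they
#' are omitted, keeping the GP input dimension small.
#'
#' @param seq Full-length residue string (same length as the parent).
#' @param space A [search_space()].
#' @param alphabet Residue alphabet defining the block layout.
#' @return Numeric vector with exactly one 1 per block.
#' @export
embed_onehot <- function(seq, space, alphabet = AA_ALPHABET) {
  stopifnot(inherits(space, "search_space"))
  sc <- seq_chars(seq)
  if (length(sc) != nchar(space$parent$residues))
    stop("sequence length ", length(sc), " != parent length ",
         nchar(space$parent$residues))
  K <- length(alphabet)
  res <- sc[space$positions]
  idx <- match(res, alphabet)
  if (anyNA(idx))
    stop("unknown residue '", res[which(is.na(idx))[1L]],
         "' at mutable position ",
         space$positions[which(is.na(idx))[1L]])
  v <- numeric(K * length(idx))
  if (length(idx))
    v[(seq_along(idx) - 1L) * K + idx] <- 1
  v
}

#' Featurizer closures
#'
#' A featurizer maps a full-length sequence to the fixed-length numeric vector
#' the GP proxy consumes. `onehot_featurizer()` uses [embed_onehot()] over a
#' space's mutable positions; `table_featurizer()` looks sequences up in a
#' precomputed embedding table (e.g. protein-language-model embeddings
#' computed externally) and errors on absent sequences rather than falling
#' back to a neighbour.
#'
#' @param space A [search_space()].
#' @param alphabet Residue alphabet for the one-hot layout.
#' @return A function `function(sequence) -> numeric vector`.
#' @export
onehot_featurizer <- function(space, alphabet = AA_ALPHABET) {
  force(space); force(alphabet)
  function(sequence) embed_onehot(sequence, space, alphabet)
}

#' @rdname onehot_featurizer
#' @param table An [load_embedding_table()] result.
#' @export
table_featurizer <- function(table) {
  stopifnot(inherits(table, "embedding_table"))
  function(sequence) {
    i <- match(sequence, table$sequence)
    if (is.na(i))
      stop("sequence absent from the embedding table: ",
           substr(sequence, 1L, 30L), "...")
    table$vectors[i, ]
  }
}

#' Load an externally computed per-sequence embedding table
#'
#' Adapter for embeddings computed outside this package (e.g. by a pretrained
#' protein language model): a CSV with a `sequence` key column and numbered
#' feature columns. Any consistent dimension is accepted. Duplicate keys with
#' identical vectors collapse to one entry; duplicate keys with differing
#' vectors are an error.
#'
#' @param path CSV file path.
#' @param seq_col Name of the key column.
#' @return An `embedding_table` with elements `sequence` (character) and
#'   `vectors` (numeric matrix, one row per sequence).
#' @export
load_embedding_table <- function(path, seq_col = "sequence") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!seq_col %in% names(df))
    stop("column '", seq_col, "' not found in '", path, "'")
  keys <- toupper(as.character(df[[seq_col]]))
  feat <- df[setdiff(names(df), seq_col)]
  mat <- as.matrix(as.data.frame(lapply(feat, as.numeric)))
  if (ncol(mat) == 0L) stop("no feature columns in '", path, "'")
  if (any(!is.finite(mat)))
    stop("non-finite embedding entries at data row ",
         which(rowSums(!is.finite(mat)) > 0)[1L])
  keep <- !logical(length(keys))
  dup <- duplicated(keys)
  for (i in which(dup)) {
    first <- match(keys[i], keys)
    if (!isTRUE(all.equal(mat[i, ], mat[first, ], check.attributes = FALSE)))
      stop("duplicate sequence key with differing vectors at data row ", i)
    keep[i] <- FALSE
  }
  structure(list(sequence = keys[keep],
                 vectors = mat[keep, , drop = FALSE],
                 dim = ncol(mat)),
            class = "embedding_table")
}
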