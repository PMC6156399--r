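#' @keywords internal
#' @useDynLib snmda, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Entity ordering contract: names are unique and sorted with radix (C-locale)
# sort so in-memory order never depends on the platform locale.
sort_names <- function(x) sort(unique(as.character(x)), method = "radix")

stop_snmda <- function(...) stop(..., call. = FALSE)

#' Construct a binary disease x miRNA association matrix
#'
#' The association matrix `A` encodes the known bipartite network:
#' `A[i, j] = 1` when disease `i` has an experimentally supported association
#' with miRNA `j`, and 0 otherwise. Rows are diseases, columns are miRNAs;
#' both dimensions carry unique entity names.
#'
#' @param values Numeric or integer matrix with entries in \{0, 1\} and full
#'   dimnames (row names = disease identifiers, column names = miRNA
#'   identifiers).
#' @return An `association_matrix` object (an integer matrix with class
#'   attribute).
#' @export
association_matrix <- function(values) {
  if (!is.matrix(values)) stop_snmda("association matrix must be a matrix")
  dn <- dimnames(values)
  if (is.null(dn) || is.null(dn[[1]]) || is.null(dn[[2]]))
    stop_snmda("association matrix needs disease row names and miRNA column names")
  if (anyDuplicated(dn[[1]])) stop_snmda("duplicated disease names")
  if (anyDuplicated(dn[[2]])) stop_snmda("duplicated miRNA names")
  if (anyNA(values) || !all(values %in% c(0, 1)))
    stop_snmda("association matrix entries must all be 0 or 1")
  out <- matrix(as.integer(values), nrow(values), ncol(values), dimnames = dn)
  class(out) <- c("association_matrix", class(matrix()))
  out
}

#' Construct a similarity matrix over one entity set
#'
#' A square, nonnegative, symmetric matrix of pairwise similarities. The
#' `kind` tag records provenance: `"precomputed"` (functional or semantic
#' similarity supplied as input), `"reconstructed"` (learned from interaction
#' profiles), `"fused"` (average of the two), or `"normalized"` (degree
#' normalized for propagation; exempt from the symmetry check only as a
#' formality -- symmetric input stays symmetric).
#'
#' @param values Square numeric matrix with matching row/column names.
#' @param kind One of `"precomputed"`, `"reconstructed"`, `"fused"`,
#'   `"normalized"`.
#' @param check_symmetry Set `FALSE` to skip the symmetry validation (used for
#'   unsymmetrized reconstruction weight output).
#' @return A `similarity_matrix` object.
#' @export
similarity_matrix <- function(values,
                              kind = c("precomputed", "reconstructed",
                                       "fused", "normalized"),
                              check_symmetry = TRUE) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || nrow(values) != ncol(values))
    stop_snmda("similarity matrix must be square")
  dn <- dimnames(values)
  if (is.null(dn) || is.null(dn[[1]]) || is.null(dn[[2]]))
    stop_snmda("similarity matrix needs row and column names")
  if (!identical(dn[[1]], dn[[2]]))
    stop_snmda("similarity row and column names must agree")
  if (anyDuplicated(dn[[1]])) stop_snmda("duplicated entity names")
  if (anyNA(values) || any(!is.finite(values)))
    stop_snmda("similarity entries must be finite")
  if (any(values < 0)) stop_snmda("similarity entries must be nonnegative")
  if (check_symmetry && kind != "normalized" &&
      max(abs(values - t(values))) > 1e-10)
    stop_snmda("similarity matrix is not symmetric (tolerance 1e-10)")
  out <- matrix(as.numeric(values), nrow(values), dimnames = dn)
  attr(out, "kind") <- kind
  class(out) <- c("similarity_matrix", class(matrix()))
  out
}

#' @export
print.association_matrix <- function(x, ...) {
  cat(sprintf("<association_matrix> %d diseases x %d miRNAs, %d known associations\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d x %d (kind: %s)\n",
              nrow(x), ncol(x), attr(x, "kind")))
  invisible(x)
}

# Strip snmda classes/attributes down to a base matrix for arithmetic.
as_base_matrix <- function(x) {
  out <- matrix(as.numeric(x), nrow(x), ncol(x), dimnames = dimnames(x))
  out
}

#' Construct a miRNA x disease score matrix
#'
#' Holds the final relevance scores `F` (and the intermediates from each
#' propagation side). Orientation is miRNA x disease throughout: the
#' miRNA-side propagation produces scores of that shape and the disease-side
#' result is transposed into it before combination.
#'
#' @param values Numeric matrix, miRNAs in rows, diseases in columns, with
#'   full dimnames; all entries finite.
#' @return A `score_matrix` object.
#' @export
score_matrix <- function(values) {
  if (!is.matrix(values)) stop_snmda("score matrix must be a matrix")
  dn <- dimnames(values)
  if (is.null(dn) || is.null(dn[[1]]) || is.null(dn[[2]]))
    stop_snmda("score matrix needs miRNA row names and disease column names")
  if (anyNA(values) || any(!is.finite(values)))
    stop_snmda("score matrix entries must be finite")
  out <- matrix(as.numeric(values), nrow(values), dimnames = dn)
  class(out) <- c("score_matrix", class(matrix()))
  out
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> %d miRNAs x %d diseases\n", nrow(x), ncol(x)))
  invisible(x)
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
# The data generators use the default Mersenne-Twister stream; evaluation
# code (fold partitions, null scorers) uses L'Ecuyer-CMRG so that passing
# one seed to both a generator and an evaluator never reuses a stream.
with_seed <- function(seed, expr, kind = NULL) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  old_kind <- RNGkind()
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else {
      RNGkind(old_kind[1], old_kind[2], old_kind[3])
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = kind)
  expr
}
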