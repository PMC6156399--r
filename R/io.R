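#' Read a disease-miRNA association matrix from disk
#'
#' Two on-disk forms are supported. The edge-list form is a 2-column TSV of
#' `disease<TAB>miRNA` rows (`#` comment lines ignored, duplicate edges
#' collapsed); entity indices are built from the distinct names, sorted
#' lexicographically so the in-memory matrix is independent of file row
#' order. The matrix form is a labeled TSV: header row carries miRNA names,
#' first column carries disease names, cells are 0/1.
#'
#' @param path Path to the TSV file.
#' @param format `"edge_list"` or `"matrix"`.
#' @return An [association_matrix()].
#' @export
read_associations <- function(path, format = c("edge_list", "matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_snmda("file not found: ", path)
  if (format == "edge_list") {
    lines <- readLines(path, warn = FALSE)
    keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
    if (length(keep) == 0L) stop_snmda("no association rows in ", path)
    parts <- strsplit(lines[keep], "\t", fixed = TRUE)
    ok <- vapply(parts, function(p) {
      length(p) >= 2L && nzchar(trimws(p[[1]])) && nzchar(trimws(p[[2]]))
    }, logical(1))
    if (!all(ok))
      stop_snmda(sprintf("malformed association row at line %d of %s",
                         keep[which(!ok)[1]], path))
    d <- trimws(vapply(parts, `[[`, character(1), 1L))
    m <- trimws(vapply(parts, `[[`, character(1), 2L))
    diseases <- sort_names(d)
    mirnas <- sort_names(m)
    A <- matrix(0L, length(diseases), length(mirnas),
                dimnames = list(diseases, mirnas))
    A[cbind(match(d, diseases), match(m, mirnas))] <- 1L
    association_matrix(A)
  } else {
    tab <- utils::read.delim(path, check.names = FALSE, row.names = 1L,
                             stringsAsFactors = FALSE)
    if (nrow(tab) == 0L || ncol(tab) == 0L) stop_snmda("empty matrix in ", path)
    A <- as.matrix(tab)
    if (!is.numeric(A)) stop_snmda("non-numeric cell in association matrix ", path)
    association_matrix(A)
  }
}

#' Write an association matrix in labeled matrix form
#'
#' Inverse of `read_associations(format = "matrix")`; the round trip is
#' bit-exact.
#'
#' @param A An [association_matrix()].
#' @param path Output TSV path.
#' @export
write_associations <- function(A, path) {
  write_labeled_tsv(A, path)
}

write_labeled_tsv <- function(x, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("", colnames(x)), collapse = "\t"), con)
  body <- apply(x, 1L, function(r) paste(format(r, trim = TRUE, digits = 15),
                                         collapse = "\t"))
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

#' Read a labeled similarity matrix
#'
#' Expects a TSV whose header row and first column both carry entity names.
#' Asymmetry up to 1e-8 (absolute) is silently repaired as `(S + t(S))/2`;
#' anything larger is an error. When `expected_index` is given the table must
#' cover those names and is reordered to match them, so files with permuted
#' rows load identically.
#'
#' @param path Path to the TSV file.
#' @param expected_index Optional character vector of entity names the matrix
#'   must be aligned to.
#' @param kind Provenance tag for the result, default `"precomputed"`.
#' @return A [similarity_matrix()].
#' @export
read_similarity <- function(path, expected_index = NULL, kind = "precomputed") {
  if (!file.exists(path)) stop_snmda("file not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE, row.names = 1L,
                           stringsAsFactors = FALSE)
  S <- as.matrix(tab)
  if (!is.numeric(S)) stop_snmda("non-numeric cell in similarity table ", path)
  if (nrow(S) != ncol(S)) stop_snmda("similarity table is not square: ", path)
  if (!setequal(rownames(S), colnames(S)))
    stop_snmda("row and column labels differ in ", path)
  S <- S[, rownames(S), drop = FALSE]
  if (!is.null(expected_index)) {
    missing <- setdiff(expected_index, rownames(S))
    if (length(missing))
      stop_snmda("similarity table ", path, " is missing label(s): ",
                 paste(utils::head(missing, 5L), collapse = ", "))
    S <- S[expected_index, expected_index, drop = FALSE]
  }
  asym <- max(abs(S - t(S)))
  if (asym > 1e-8)
    stop_snmda(sprintf("similarity table %s is asymmetric (max |S - t(S)| = %.3g)",
                       path, asym))
  if (asym > 0) S <- (S + t(S)) / 2
  similarity_matrix(S, kind = kind)
}

#' Write a similarity matrix as a labeled TSV
#'
#' @param S A [similarity_matrix()] (or labeled square matrix).
#' @param path Output TSV path.
#' @export
write_similarity <- function(S, path) {
  write_labeled_tsv(S, path)
}

#' Write ranked candidate predictions per disease
#'
#' Serialises the score matrix as a ranked candidate list: for each disease
#' the *unknown* pairs (entries with `A = 0`; known associations are excluded
#' from ranking, matching the usual candidate definition for case studies)
#' are sorted by descending score and assigned per-disease ranks with the
#' average-tie convention. Output columns: `disease`, `mirna`, `score`,
#' `rank`.
#'
#' @param F A [score_matrix()] (miRNA x disease).
#' @param known The [association_matrix()] of known pairs; indices must match
#'   `F` (diseases = columns of `F`, miRNAs = rows of `F`).
#' @param path Output TSV path.
#' @param top_k Optional cap on rows written per disease (best `top_k`
#'   candidates).
#' @export
write_predictions <- function(F, known, path, top_k = NULL) {
  if (!identical(rownames(F), colnames(known)) ||
      !identical(colnames(F), rownames(known)))
    stop_snmda("score matrix and association matrix indices do not match")
  if (!is.null(top_k) && (length(top_k) != 1L || top_k < 1))
    stop_snmda("top_k must be a positive integer")
  rows <- lapply(colnames(F), function(d) {
    unknown <- which(known[d, ] == 0L)
    if (length(unknown) == 0L) return(NULL)
    sc <- F[unknown, d]
    rk <- rank(-sc, ties.method = "average")
    ord <- order(rk, names(sc), method = "radix")
    out <- data.frame(disease = d, mirna = names(sc)[ord],
                      score = unname(sc[ord]), rank = unname(rk[ord]),
                      stringsAsFactors = FALSE)
    if (!is.null(top_k)) out <- utils::head(out, top_k)
    out
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(disease = character(), mirna = character(),
                      score = numeric(), rank = numeric())
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(res)
}
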