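#' Disease DAG for semantic similarity
#'
#' Diseases in a MeSH-style classification form a directed acyclic graph in
#' which each disease points to its (possibly multiple) parent categories.
#' Semantic similarity between two diseases is derived from the ancestor
#' sets of this DAG.
#'
#' @param nodes Character vector of disease identifiers.
#' @param parents Named list mapping each node to a character vector of its
#'   parent nodes (possibly empty). Every parent must itself be a node.
#' @return A `disease_dag` object.
#' @export
disease_dag <- function(nodes, parents) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop_snmda("duplicated node in DAG")
  parents <- parents[nodes[nodes %in% names(parents)]]
  full <- stats::setNames(vector("list", length(nodes)), nodes)
  for (n in nodes) full[[n]] <- unique(as.character(parents[[n]]))
  dangling <- setdiff(unlist(full, use.names = FALSE), nodes)
  if (length(dangling))
    stop_snmda("dangling parent(s) not declared as nodes: ",
               paste(utils::head(dangling, 5L), collapse = ", "))
  assert_acyclic(nodes, full)
  structure(list(nodes = nodes, parents = full), class = "disease_dag")
}

# Kahn's algorithm on child -> parent edges; on failure walk the parent map
# inside the unresolved set to name one concrete cycle.
assert_acyclic <- function(nodes, parents) {
  outdeg <- vapply(parents, length, integer(1))  # edges child -> parent
  children <- stats::setNames(vector("list", length(nodes)), nodes)
  for (n in nodes) for (p in parents[[n]]) children[[p]] <- c(children[[p]], n)
  queue <- nodes[outdeg == 0L]
  seen <- 0L
  while (length(queue)) {
    n <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    for (ch in children[[n]]) {
      outdeg[[ch]] <- outdeg[[ch]] - 1L
      if (outdeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(nodes)) {
    left <- nodes[outdeg > 0L]
    # walk parents restricted to the unresolved set until a node repeats
    path <- left[[1]]
    repeat {
      nxt <- intersect(parents[[path[length(path)]]], left)[1]
      if (nxt %in% path) {
        cyc <- c(path[which(path == nxt)[1]:length(path)], nxt)
        stop_snmda("cycle in disease DAG: ", paste(cyc, collapse = " -> "))
      }
      path <- c(path, nxt)
    }
  }
  invisible(TRUE)
}

#' @export
print.disease_dag <- function(x, ...) {
  n_edges <- sum(vapply(x$parents, length, integer(1)))
  cat(sprintf("<disease_dag> %d nodes, %d child->parent edges\n",
              length(x$nodes), n_edges))
  invisible(x)
}

#' Load a disease DAG from a child/parent TSV
#'
#' Each row is `child<TAB>parent`; a node with no parent is listed as
#' `node<TAB>-`. A node may appear on several rows (multiple parents).
#' The graph is validated to be acyclic at load time.
#'
#' @param path Path to the TSV file.
#' @return A [disease_dag()].
#' @export
load_dag <- function(path) {
  if (!file.exists(path)) stop_snmda("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(keep) == 0L) stop_snmda("no DAG rows in ", path)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  ok <- vapply(parts, function(p) length(p) >= 2L && nzchar(trimws(p[[1]])),
               logical(1))
  if (!all(ok))
    stop_snmda(sprintf("malformed DAG row at line %d of %s",
                       keep[which(!ok)[1]], path))
  child <- trimws(vapply(parts, `[[`, character(1), 1L))
  parent <- trimws(vapply(parts, `[[`, character(1), 2L))
  root <- parent == "-"
  nodes <- sort_names(c(child, parent[!root]))
  parents <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in which(!root))
    parents[[child[i]]] <- c(parents[[child[i]]], parent[i])
  disease_dag(nodes, parents)
}

#' Ancestor contributions of a disease
#'
#' For a disease `d`, every node `t` in its ancestor closure `T(d)` (the
#' ancestors of `d` plus `d` itself) contributes a semantic weight: `d`
#' contributes 1 to itself, and each step up the DAG multiplies the
#' contribution by the decay factor (0.5 by default), taking the maximum
#' over descending paths. With a uniform decay this equals
#' `decay^(shortest ascending path length from d to t)`.
#'
#' @param dag A [disease_dag()].
#' @param d A node of `dag`.
#' @param decay Semantic decay factor in (0, 1]; default 0.5.
#' @return Named numeric vector over `T(d)`; `[d] == 1`, values in (0, 1].
#' @export
dag_contributions <- function(dag, d, decay = 0.5) {
  if (!(d %in% dag$nodes)) stop_snmda("disease not in DAG: ", d)
  if (decay <= 0 || decay > 1) stop_snmda("decay must be in (0, 1]")
  dist <- stats::setNames(0L, d)
  frontier <- d
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(dag$parents[frontier], use.names = FALSE)),
                   names(dist))
    if (length(nxt) == 0L) break
    dist[nxt] <- dist[[frontier[1]]] + 1L   # BFS level
    frontier <- nxt
  }
  decay^dist
}

#' Semantic value of a disease
#'
#' The total semantic content of a disease: the sum of the contributions of
#' every node in its ancestor closure. Always at least 1 (the disease's own
#' contribution).
#'
#' @param cm Contribution vector from [dag_contributions()].
#' @return A scalar `>= 1`.
#' @export
semantic_value <- function(cm) {
  if (length(cm) == 0L || anyNA(cm)) stop_snmda("invalid contribution map")
  sum(cm)
}

#' Semantic similarity between two diseases
#'
#' Diseases sharing a larger portion of their ancestor DAGs are more
#' semantically similar. The similarity is the summed contribution of the
#' shared ancestors (counted from both sides) over the two semantic values:
#' `S(a, b) = sum_{t in T(a) ^ T(b)} (D_a(t) + D_b(t)) / (DV(a) + DV(b))`.
#' Symmetric, in \[0, 1\], with `S(a, a) = 1`.
#'
#' @inheritParams dag_contributions
#' @param a,b Nodes of `dag`.
#' @return Similarity score in \[0, 1\].
#' @export
semantic_similarity <- function(dag, a, b, decay = 0.5) {
  ca <- dag_contributions(dag, a, decay)
  cb <- dag_contributions(dag, b, decay)
  shared <- intersect(names(ca), names(cb))
  sum(ca[shared] + cb[shared]) / (sum(ca) + sum(cb))
}

#' Disease semantic similarity matrix from a DAG
#'
#' Computes all pairwise semantic similarities, memoising one ancestor
#' traversal per disease. When a precomputed disease similarity matrix is
#' available this step can be skipped entirely and the matrix supplied
#' directly to the pipeline.
#'
#' @inheritParams dag_contributions
#' @param diseases Character vector of diseases to include (default: all DAG
#'   nodes, lexicographic order).
#' @return A [similarity_matrix()] with unit diagonal, `kind = "precomputed"`.
#' @export
build_dss <- function(dag, diseases = NULL, decay = 0.5) {
  if (is.null(diseases)) diseases <- sort_names(dag$nodes)
  missing <- setdiff(diseases, dag$nodes)
  if (length(missing))
    stop_snmda("disease(s) not in DAG: ",
               paste(utils::head(missing, 5L), collapse = ", "))
  cms <- lapply(diseases, dag_contributions, dag = dag, decay = decay)
  dvs <- vapply(cms, sum, numeric(1))
  n <- length(diseases)
  S <- diag(1, n)
  dimnames(S) <- list(diseases, diseases)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
      shared <- intersect(names(cms[[i]]), names(cms[[j]]))
      s <- if (length(shared))
        sum(cms[[i]][shared] + cms[[j]][shared]) / (dvs[i] + dvs[j]) else 0
      S[i, j] <- S[j, i] <- s
    }
  }
  similarity_matrix(S, kind = "precomputed")
}
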