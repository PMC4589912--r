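# Directed acyclic graphs over named variables.

#' Construct a DAG
#'
#' @param nodes Character vector of node names (unique).
#' @param edges `NULL`, or a 2-column matrix/data frame of (parent, child)
#'   pairs.  Self-loops and cycles are rejected.
#' @return A `bn_dag`: list with `nodes` (character) and `edges` (2-column
#'   character matrix with columns `parent`, `child`).
#' @examples
#' g <- dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
#' is_acyclic(g)
#' @export
dag <- function(nodes, edges = NULL) {
  stopifnot(is.character(nodes), length(nodes) >= 1, !anyDuplicated(nodes))
  if (is.null(edges) || NROW(edges) == 0) {
    em <- matrix(character(0), ncol = 2)
  } else {
    em <- as.matrix(edges)
    stopifnot(ncol(em) == 2)
    storage.mode(em) <- "character"
    if (!all(em %in% nodes)) stop("edge endpoints must be nodes")
    if (any(em[, 1] == em[, 2])) stop("self-loops are not allowed")
    if (anyDuplicated(paste(em[, 1], em[, 2]))) stop("duplicate edges")
  }
  colnames(em) <- c("parent", "child")
  g <- structure(list(nodes = nodes, edges = em), class = "bn_dag")
  if (!is_acyclic(g)) stop("graph contains a directed cycle")
  g
}

#' Test a directed graph for acyclicity
#'
#' Kahn's algorithm (repeated removal of in-degree-zero nodes), O(V + E).
#'
#' @param g A `bn_dag` (the constructor enforces acyclicity, so this is
#'   mainly useful on graphs assembled by hand or from files).
#' @return `TRUE` iff a topological order exists.
#' @export
is_acyclic <- function(g) {
  stopifnot(inherits(g, "bn_dag"))
  n <- length(g$nodes)
  if (nrow(g$edges) == 0) return(TRUE)
  pi <- match(g$edges[, 1], g$nodes)
  ci <- match(g$edges[, 2], g$nodes)
  indeg <- tabulate(ci, nbins = n)
  queue <- which(indeg == 0)
  removed <- 0L
  while (length(queue) > 0) {
    u <- queue[[1]]
    queue <- queue[-1]
    removed <- removed + 1L
    for (e in which(pi == u)) {
      indeg[ci[e]] <- indeg[ci[e]] - 1L
      if (indeg[ci[e]] == 0) queue <- c(queue, ci[e])
    }
  }
  removed == n
}

#' Parent sets of a DAG
#'
#' @param g A `bn_dag`.
#' @return Named list: for each node, the character vector of its parents.
#' @export
dag_parents <- function(g) {
  stopifnot(inherits(g, "bn_dag"))
  out <- setNames(vector("list", length(g$nodes)), g$nodes)
  for (n in g$nodes) out[[n]] <- character(0)
  if (nrow(g$edges) > 0)
    for (i in seq_len(nrow(g$edges)))
      out[[g$edges[i, 2]]] <- c(out[[g$edges[i, 2]]], g$edges[i, 1])
  out
}

# sorted "u|v" keys of the undirected skeleton
dag_skeleton <- function(g) {
  if (nrow(g$edges) == 0) return(character(0))
  unique(apply(g$edges, 1, function(e) paste(sort(e), collapse = "|")))
}

#' @export
print.bn_dag <- function(x, ...) {
  cat(sprintf("DAG with %d nodes, %d edges\n", length(x$nodes),
              nrow(x$edges)))
  if (nrow(x$edges) > 0)
    cat(paste0("  ", x$edges[, 1], " -> ", x$edges[, 2], collapse = "\n"),
        "\n")
  invisible(x)
}

#' Markov equivalence of two DAGs
#'
#' Two DAGs are Markov equivalent iff they share the same skeleton and the
#' same set of v-structures (colliders with non-adjacent parents); such
#' pairs receive identical scores under any score-equivalent metric (BDeu
#' included).
#'
#' @param d1,d2 `bn_dag` objects over the same node set.
#' @return Logical.
#' @export
markov_equivalent <- function(d1, d2) {
  stopifnot(inherits(d1, "bn_dag"), inherits(d2, "bn_dag"))
  if (!setequal(d1$nodes, d2$nodes)) stop("node sets differ")
  if (!setequal(dag_skeleton(d1), dag_skeleton(d2))) return(FALSE)
  vkey <- function(g) {
    v <- detect_v_structures(g)$colliders
    if (nrow(v) == 0) return(character(0))
    paste(v$parent_a, v$parent_b, v$child, sep = "|")
  }
  setequal(vkey(d1), vkey(d2))
}
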