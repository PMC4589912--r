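# Bayesian-Dirichlet (BDeu) scoring of discrete networks.

#' BDeu family score
#'
#' Log marginal likelihood of one child column given a parent set, under
#' uniform Dirichlet hyperparameters `alpha_ijk = ess / (q_i * r_i)` where
#' `r_i` is the child arity and `q_i` the number of parent configurations:
#' `sum_j [lnG(a_ij) - lnG(a_ij + N_ij)] + sum_jk [lnG(a_ijk + N_ijk) -
#' lnG(a_ijk)]`.  Depends on the data only through the contingency counts,
#' so it is invariant to row order; an empty table scores 0.
#'
#' @param data A `discrete_table` (see [apply_bins()], [as_discrete_table()]).
#' @param child Child column name.
#' @param parents Character vector of parent column names (default none).
#' @param ess Equivalent sample size, the Dirichlet prior's total
#'   pseudo-count (default 1).
#' @return The log marginal likelihood (finite for finite counts).
#' @examples
#' d <- as_discrete_table(data.frame(A = c(0L, 1L)), arity = c(A = 2))
#' family_score(d, "A")  # -3 * log(2)
#' @export
family_score <- function(data, child, parents = character(0), ess = 1) {
  stopifnot(inherits(data, "discrete_table"), ess > 0)
  vars <- names(data)
  if (!child %in% vars) stop("unknown child variable: ", child)
  if (!all(parents %in% vars))
    stop("unknown parent variable(s): ",
         paste(setdiff(parents, vars), collapse = ", "))
  if (child %in% parents) stop("child cannot be its own parent")
  bdeu_family_score_cpp(dt_matrix(data), unname(dt_arity(data)),
                        match(child, vars) - 1L,
                        match(parents, vars) - 1L, ess)
}

#' Score a DAG
#'
#' The BDeu score decomposes over families: the network's log posterior
#' (uniform structure prior, so equal to the log marginal likelihood up to
#' an additive constant) is the sum over nodes of [family_score()] of the
#' node given its parents.  Family scores are cached by (child, parent set)
#' so repeated queries cost one lookup.
#'
#' @param data A `discrete_table` whose columns include every node.
#' @param g A `bn_dag`.
#' @param ess Equivalent sample size (default 1).
#' @param cache Optional environment reused across calls as a family-score
#'   cache.
#' @return A `scored_network`: list with `dag`, `log_posterior` and `ess`.
#' @export
score_dag <- function(data, g, ess = 1, cache = NULL) {
  stopifnot(inherits(g, "bn_dag"))
  if (!all(g$nodes %in% names(data)))
    stop("DAG nodes must be columns of the data")
  if (!is_acyclic(g)) stop("graph contains a directed cycle")
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  total <- 0
  for (nd in g$nodes) {
    par <- sort(dag_parents(g)[[nd]])
    key <- paste(nd, paste(par, collapse = ","), sep = "|")
    s <- cache[[key]]
    if (is.null(s)) {
      s <- family_score(data, nd, par, ess)
      cache[[key]] <- s
    }
    total <- total + s
  }
  scored_network(g, total, ess)
}

scored_network <- function(g, log_posterior, ess) {
  structure(list(dag = g, log_posterior = log_posterior, ess = ess),
            class = "scored_network")
}

#' @export
print.scored_network <- function(x, ...) {
  cat(sprintf("Scored network: log posterior %.6f (ess = %g)\n",
              x$log_posterior, x$ess))
  print(x$dag)
  invisible(x)
}
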