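# Structure search: exhaustive enumeration (small-problem oracle) and
# simulated annealing over DAG space.

#' Search configuration
#'
#' Desk-scale defaults (20 restarts x 1e5 proposals) keep runs interactive;
#' the original study-scale effort (100 restarts x 5e7 proposals per
#' compartment) remains reachable by setting the fields explicitly.
#'
#' @param ess Equivalent sample size for the BDeu score.
#' @param max_parents Maximum parents per node (bounds the parent
#'   configuration blow-up on small samples).
#' @param n_restarts Independent annealing restarts.
#' @param proposals_per_restart Edge-move proposals per restart.
#' @param initial_temperature Starting temperature, reset at each restart.
#' @param cooling_factor Geometric cooling multiplier in (0, 1), applied
#'   every `max(1, proposals_per_restart / 1000)` proposals.
#' @param seed Integer seed; the whole search is reproducible from it.
#' @param top_k_retained Maximum co-best structures kept per restart (all
#'   structures within `1e-9` of the restart best, up to this cap).
#' @return A `search_config` list.
#' @export
search_config <- function(ess = 1, max_parents = 5L, n_restarts = 20L,
                          proposals_per_restart = 1e5,
                          initial_temperature = 1000,
                          cooling_factor = 0.9, seed = 1L,
                          top_k_retained = 50L) {
  stopifnot(ess > 0, max_parents >= 1, n_restarts >= 1,
            proposals_per_restart >= 1, initial_temperature > 0,
            cooling_factor > 0, cooling_factor < 1, top_k_retained >= 1)
  structure(list(ess = ess, max_parents = as.integer(max_parents),
                 n_restarts = as.integer(n_restarts),
                 proposals_per_restart = as.integer(proposals_per_restart),
                 initial_temperature = initial_temperature,
                 cooling_factor = cooling_factor, seed = as.integer(seed),
                 top_k_retained = as.integer(top_k_retained)),
            class = "search_config")
}

#' Exhaustive structure search (enumeration oracle)
#'
#' Enumerates every labeled DAG over the data columns (each unordered pair
#' is absent, forward or backward; cyclic assignments are discarded), scores
#' each with the BDeu metric, and returns all global maximizers.  Intended
#' as the correctness oracle for [anneal_search()]; limited to 5 variables
#' (29,281 DAGs).
#'
#' @param data A `discrete_table` with at most 5 columns.
#' @param ess Equivalent sample size.
#' @param tol Score tolerance within which DAGs count as co-maximal.
#' @return List of `scored_network` maximizers (ties kept), with attribute
#'   `n_enumerated`, the number of DAGs scored.
#' @export
exhaustive_search <- function(data, ess = 1, tol = 1e-9) {
  vars <- names(data)
  p <- length(vars)
  if (p > 5) stop("exhaustive search supports at most 5 variables")
  # family scores for every (child, parent subset)
  fam <- lapply(seq_len(p), function(ci) {
    others <- setdiff(seq_len(p), ci)
    masks <- 0:(2^length(others) - 1)
    vapply(masks, function(m) {
      par <- others[bitwAnd(bitwShiftR(m, seq_along(others) - 1), 1) == 1]
      family_score(data, vars[ci], vars[par], ess)
    }, numeric(1))
  })
  pair_idx <- if (p >= 2) combn(p, 2) else matrix(integer(0), nrow = 2)
  m <- ncol(pair_idx)
  n_dags <- 0L
  best <- -Inf
  winners <- list()
  states <- integer(m) # 0 none, 1 lo->hi, 2 hi->lo
  repeat {
    parents <- integer(p) # bitmask of parents per node
    for (k in seq_len(m)) {
      if (states[k] == 1)
        parents[pair_idx[2, k]] <- bitwOr(parents[pair_idx[2, k]],
                                          bitwShiftL(1L, pair_idx[1, k] - 1L))
      else if (states[k] == 2)
        parents[pair_idx[1, k]] <- bitwOr(parents[pair_idx[1, k]],
                                          bitwShiftL(1L, pair_idx[2, k] - 1L))
    }
    # acyclicity by repeated removal of parent-free nodes
    remaining <- seq_len(p)
    rem_mask <- 2^p - 1L
    repeat {
      free <- remaining[bitwAnd(parents[remaining], rem_mask) == 0]
      if (length(free) == 0) break
      remaining <- setdiff(remaining, free)
      for (f in free) rem_mask <- bitwAnd(rem_mask,
                                          bitwNot(bitwShiftL(1L, f - 1L)))
      if (length(remaining) == 0) break
    }
    if (length(remaining) == 0) {
      n_dags <- n_dags + 1L
      # parent mask relative to "others" ordering used in fam
      s <- 0
      for (ci in seq_len(p)) {
        others <- setdiff(seq_len(p), ci)
        sub <- sum(bitwShiftL(
          1L, which(bitwAnd(parents[ci], bitwShiftL(1L, others - 1L)) > 0) -
            1L))
        s <- s + fam[[ci]][sub + 1]
      }
      if (s > best + tol) {
        best <- s
        winners <- list(parents)
      } else if (s >= best - tol) {
        winners <- c(winners, list(parents))
      }
    }
    # next assignment in base 3
    k <- 1L
    while (k <= m && states[k] == 2L) { states[k] <- 0L; k <- k + 1L }
    if (k > m) break
    states[k] <- states[k] + 1L
    if (m == 0) break
  }
  out <- lapply(winners, function(parents) {
    edges <- NULL
    for (ci in seq_len(p)) {
      par <- which(bitwAnd(parents[ci], bitwShiftL(1L, seq_len(p) - 1L)) > 0)
      if (length(par) > 0)
        edges <- rbind(edges, cbind(vars[par], vars[ci]))
    }
    scored_network(dag(vars, edges), best, ess)
  })
  attr(out, "n_enumerated") <- n_dags
  out
}

#' Simulated-annealing structure search
#'
#' Each restart starts from the empty DAG and proposes single-edge moves
#' (add, delete, reverse) drawn uniformly from the current move multiset;
#' cycle-creating or parent-limit-violating proposals are rejected.  A move
#' with score change `d >= 0` is always accepted, otherwise with
#' probability `exp(d / T)`; the temperature cools geometrically on a fixed
#' step schedule and resets at each restart.  All structures within `1e-9`
#' of a restart's best score are retained as co-bests.
#'
#' @param data A non-empty `discrete_table`.
#' @param config A [search_config()].
#' @return List of `scored_network`, the retained best structures of every
#'   restart pooled and sorted by non-increasing `log_posterior`, with
#'   attribute `effort` (proposals, acceptances, distinct family scores
#'   evaluated).
#' @examples
#' d <- as_discrete_table(data.frame(A = rep(0:1, 10), B = rep(0:1, 10)))
#' res <- anneal_search(d, search_config(n_restarts = 2,
#'                                       proposals_per_restart = 500))
#' res[[1]]$log_posterior
#' @export
anneal_search <- function(data, config = search_config()) {
  stopifnot(inherits(data, "discrete_table"), inherits(config, "search_config"),
            nrow(data) >= 1)
  vars <- names(data)
  set.seed(config$seed)
  cool_every <- max(1L, as.integer(config$proposals_per_restart / 1000))
  raw <- anneal_search_cpp(dt_matrix(data), unname(dt_arity(data)),
                           config$ess, config$max_parents,
                           config$n_restarts,
                           config$proposals_per_restart,
                           config$initial_temperature,
                           config$cooling_factor, cool_every,
                           1e-9, config$top_k_retained)
  nets <- list()
  for (rs in raw$restarts) {
    for (em in rs$edges) {
      g <- if (nrow(em) == 0) dag(vars) else
        dag(vars, cbind(vars[em[, 1]], vars[em[, 2]]))
      nets[[length(nets) + 1]] <- scored_network(g, rs$score, config$ess)
    }
  }
  ord <- order(vapply(nets, `[[`, numeric(1), "log_posterior"),
               decreasing = TRUE)
  out <- nets[ord]
  attr(out, "effort") <- list(
    proposals = config$n_restarts * config$proposals_per_restart,
    accepted = raw$accepted, score_evals = raw$score_evals)
  out
}
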