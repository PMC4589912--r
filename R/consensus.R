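# Consensus networks from top-scoring structures, and the V / Y motifs used
# for causal interpretation.

#' Build a consensus network from top-scoring structures
#'
#' Networks within `score_tolerance` of the best log posterior are kept
#' (numeric tolerance stands in for "sharing the top score": floating-point
#' equality is unreliable).  An adjacency enters the consensus iff it is
#' present, in some orientation, in every kept network; it is drawn as a
#' directed edge iff the orientation is the same in all of them, and as an
#' undirected edge when it appears at least once in the opposing direction.
#' Adjacencies supported by only some kept networks are excluded from the
#' graph but reported with support counts.
#'
#' @param networks Non-empty list of `scored_network` over one node set.
#' @param score_tolerance Width of the top-score band (default `1e-9`).
#' @return A `consensus_network`: `nodes`, `directed` and `undirected`
#'   2-column edge matrices, `support` (data frame of all observed
#'   adjacencies with `n_support` out of `n_networks`), and `n_networks`,
#'   the number of kept networks.
#' @export
build_consensus <- function(networks, score_tolerance = 1e-9) {
  if (length(networks) == 0) stop("no networks supplied")
  stopifnot(all(vapply(networks, inherits, logical(1), "scored_network")))
  nodes <- networks[[1]]$dag$nodes
  for (nw in networks)
    if (!setequal(nw$dag$nodes, nodes)) stop("networks have mismatched node sets")
  scores <- vapply(networks, `[[`, numeric(1), "log_posterior")
  kept <- networks[scores >= max(scores) - score_tolerance]
  nk <- length(kept)

  # per kept network: adjacency keys and orientation sets
  adj_count <- new.env(parent = emptyenv())
  fwd <- new.env(parent = emptyenv()) # orientations seen, keyed by adjacency
  for (nw in kept) {
    em <- nw$dag$edges
    keys <- if (nrow(em) == 0) character(0) else
      apply(em, 1, function(e) paste(sort(e), collapse = "|"))
    for (i in seq_along(keys)) {
      k <- keys[[i]]
      adj_count[[k]] <- (adj_count[[k]] %||% 0L) + 1L
      fwd[[k]] <- union(fwd[[k]], paste(em[i, 1], em[i, 2], sep = "|"))
    }
  }
  directed <- undirected <- NULL
  support <- data.frame(node_a = character(0), node_b = character(0),
                        n_support = integer(0))
  for (k in ls(adj_count)) {
    uv <- strsplit(k, "|", fixed = TRUE)[[1]]
    cnt <- adj_count[[k]]
    support <- rbind(support, data.frame(node_a = uv[1], node_b = uv[2],
                                         n_support = cnt))
    if (cnt < nk) next # not consensual
    ors <- fwd[[k]]
    if (length(ors) == 1) {
      e <- strsplit(ors, "|", fixed = TRUE)[[1]]
      directed <- rbind(directed, e)
    } else {
      undirected <- rbind(undirected, uv)
    }
  }
  shape <- function(m) {
    if (is.null(m)) m <- matrix(character(0), ncol = 2)
    dimnames(m) <- list(NULL, c("from", "to"))
    m
  }
  rownames(support) <- NULL
  structure(list(nodes = nodes, directed = shape(directed),
                 undirected = shape(undirected), support = support,
                 n_networks = nk,
                 top_score = max(scores)),
            class = "consensus_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.consensus_network <- function(x, ...) {
  cat(sprintf(
    "Consensus of %d top-scoring network(s): %d directed, %d undirected edge(s)\n",
    x$n_networks, nrow(x$directed), nrow(x$undirected)))
  if (nrow(x$directed) > 0)
    cat(paste0("  ", x$directed[, 1], " -> ", x$directed[, 2],
               collapse = "\n"), "\n")
  if (nrow(x$undirected) > 0)
    cat(paste0("  ", x$undirected[, 1], " -- ", x$undirected[, 2],
               collapse = "\n"), "\n")
  invisible(x)
}

# directed edges + full adjacency (directed and undirected) of a graph
graph_parts <- function(graph) {
  if (inherits(graph, "scored_network")) graph <- graph$dag
  if (inherits(graph, "bn_dag")) {
    list(nodes = graph$nodes, directed = graph$edges, extra_adj = NULL)
  } else if (inherits(graph, "consensus_network")) {
    list(nodes = graph$nodes, directed = graph$directed,
         extra_adj = graph$undirected)
  } else stop("expected a bn_dag, scored_network or consensus_network")
}

adjacent_pairs <- function(parts) {
  m <- rbind(parts$directed, parts$extra_adj)
  if (is.null(m) || nrow(m) == 0) return(character(0))
  unique(apply(m, 1, function(e) paste(sort(e), collapse = "|")))
}

#' Detect collider ("V") structures
#'
#' A collider is an ordered-normalized triple `(a, b, c)` with directed
#' edges `a -> c` and `b -> c` and `a`, `b` non-adjacent (the fork-like "V"
#' the network analysis reads as co-regulation of `c` by two factors).  On
#' a consensus network only directed edges provide arrows, but undirected
#' edges count towards adjacency.
#'
#' @param graph A `bn_dag`, `scored_network` or `consensus_network`.
#' @return A `motif_report` with element `colliders`: data frame
#'   `parent_a`, `parent_b` (sorted), `child`.
#' @export
detect_v_structures <- function(graph) {
  parts <- graph_parts(graph)
  adj <- adjacent_pairs(parts)
  em <- parts$directed
  colliders <- data.frame(parent_a = character(0), parent_b = character(0),
                          child = character(0))
  if (nrow(em) > 0) {
    for (child in unique(em[, 2])) {
      pars <- sort(em[em[, 2] == child, 1])
      if (length(pars) < 2) next
      for (i in seq_len(length(pars) - 1)) {
        for (j in seq(i + 1, length(pars))) {
          if (!paste(pars[i], pars[j], sep = "|") %in% adj &&
              !paste(pars[j], pars[i], sep = "|") %in% adj)
            colliders <- rbind(colliders, data.frame(
              parent_a = pars[i], parent_b = pars[j], child = child))
        }
      }
    }
  }
  rownames(colliders) <- NULL
  structure(list(colliders = colliders), class = "motif_report")
}

#' Detect "Y" structures
#'
#' A Y structure extends a collider `(a, b, c)` by one directed edge
#' `c -> d`; its presence is read as support for a causal direction from
#' `c` to `d`.
#'
#' @inheritParams detect_v_structures
#' @return A `motif_report` with elements `colliders` and `y_structures`
#'   (data frame `parent_a`, `parent_b`, `child`, `grandchild`).
#' @export
detect_y_structures <- function(graph) {
  parts <- graph_parts(graph)
  rep_v <- detect_v_structures(graph)
  v <- rep_v$colliders
  em <- parts$directed
  ys <- data.frame(parent_a = character(0), parent_b = character(0),
                   child = character(0), grandchild = character(0))
  if (nrow(v) > 0 && nrow(em) > 0) {
    for (i in seq_len(nrow(v))) {
      kids <- em[em[, 1] == v$child[i], 2]
      kids <- setdiff(kids, c(v$parent_a[i], v$parent_b[i]))
      for (d in kids)
        ys <- rbind(ys, data.frame(parent_a = v$parent_a[i],
                                   parent_b = v$parent_b[i],
                                   child = v$child[i], grandchild = d))
    }
  }
  rownames(ys) <- NULL
  structure(list(colliders = v, y_structures = ys), class = "motif_report")
}

#' @export
print.motif_report <- function(x, ...) {
  cat(sprintf("Motif report: %d collider(s)", nrow(x$colliders)))
  if (!is.null(x$y_structures))
    cat(sprintf(", %d Y structure(s)", nrow(x$y_structures)))
  cat("\n")
  if (nrow(x$colliders) > 0)
    cat(paste0("  ", x$colliders$parent_a, " -> ", x$colliders$child,
               " <- ", x$colliders$parent_b, collapse = "\n"), "\n")
  invisible(x)
}
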