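# Graph serialization: edge-list text, GraphML (via igraph) and DOT.

#' Write / read a DAG as an edge-list file
#'
#' One `parent<TAB>child` line per edge; isolated nodes are preserved in a
#' leading `# nodes:` comment so the round trip is exact.
#'
#' @param g A `bn_dag`.
#' @param path Output file.
#' @return `write_edge_list` returns `path` invisibly; `read_edge_list`
#'   returns the `bn_dag`.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "bn_dag"))
  lines <- c(paste0("# nodes: ", paste(g$nodes, collapse = ",")),
             if (nrow(g$edges) > 0)
               paste(g$edges[, 1], g$edges[, 2], sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  nodes <- strsplit(sub("^# nodes: ", "", lines[1]), ",")[[1]]
  body <- lines[-1]
  body <- body[nzchar(body)]
  edges <- if (length(body) > 0)
    do.call(rbind, strsplit(body, "\t", fixed = TRUE)) else NULL
  dag(nodes, edges)
}

consensus_igraph <- function(cn) {
  em <- rbind(cn$directed, cn$undirected)
  directed_flag <- c(rep(TRUE, nrow(cn$directed)),
                     rep(FALSE, nrow(cn$undirected)))
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(g, length(cn$nodes), name = cn$nodes)
  if (nrow(em) > 0) {
    g <- igraph::add_edges(g, as.vector(t(em)))
    sup <- cn$support
    key <- paste(pmin(em[, 1], em[, 2]), pmax(em[, 1], em[, 2]))
    skey <- paste(pmin(sup$node_a, sup$node_b), pmax(sup$node_a, sup$node_b))
    igraph::E(g)$directed <- directed_flag
    igraph::E(g)$support <- sup$n_support[match(key, skey)] / cn$n_networks
  }
  g
}

#' Export a consensus network as GraphML
#'
#' Edges carry a boolean `directed` attribute (undirected consensus edges
#' are stored with an arbitrary orientation and `directed = false`) and a
#' `support` attribute (fraction of kept networks containing the
#' adjacency).
#'
#' @param cn A `consensus_network`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(cn, path) {
  stopifnot(inherits(cn, "consensus_network"))
  igraph::write_graph(consensus_igraph(cn), path, format = "graphml")
  invisible(path)
}

#' Read a consensus network back from GraphML
#'
#' Inverse of [write_graphml()] up to edge order and the `support` /
#' `n_networks` bookkeeping (support fractions are restored; the
#' contributing networks themselves are not stored in the file).
#'
#' @param path GraphML file written by [write_graphml()].
#' @return A `consensus_network`.
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::V(g)$name
  em <- igraph::as_edgelist(g)
  dirflag <- if (igraph::ecount(g) > 0) igraph::E(g)$directed else logical(0)
  shape <- function(m) {
    if (is.null(m) || length(m) == 0) m <- matrix(character(0), ncol = 2)
    dimnames(m) <- list(NULL, c("from", "to"))
    m
  }
  support <- if (igraph::ecount(g) > 0)
    data.frame(node_a = pmin(em[, 1], em[, 2]),
               node_b = pmax(em[, 1], em[, 2]),
               n_support = NA_integer_)
  else data.frame(node_a = character(0), node_b = character(0),
                  n_support = integer(0))
  structure(list(nodes = nodes,
                 directed = shape(em[dirflag, , drop = FALSE]),
                 undirected = shape(em[!dirflag, , drop = FALSE]),
                 support = support, n_networks = NA_integer_,
                 top_score = NA_real_),
            class = "consensus_network")
}

#' Export a consensus network as DOT
#'
#' Directed consensus edges get arrowheads; undirected edges are written
#' with `dir=none`.
#'
#' @param cn A `consensus_network`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dot <- function(cn, path) {
  stopifnot(inherits(cn, "consensus_network"))
  q <- function(x) paste0("\"", x, "\"")
  lines <- c("digraph consensus {",
             paste0("  ", q(cn$nodes), ";"),
             if (nrow(cn$directed) > 0)
               paste0("  ", q(cn$directed[, 1]), " -> ",
                      q(cn$directed[, 2]), ";"),
             if (nrow(cn$undirected) > 0)
               paste0("  ", q(cn$undirected[, 1]), " -> ",
                      q(cn$undirected[, 2]), " [dir=none];"),
             "}")
  writeLines(lines, path)
  invisible(path)
}

#' Write a motif report as JSON
#'
#' @param report A `motif_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_motifs <- function(report, path) {
  jsonlite::write_json(
    list(colliders = report$colliders,
         y_structures = report$y_structures),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
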