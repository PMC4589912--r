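# Independent oracles used to check the package implementations.

cond_vars <- c("CLP", "LungInsult", "InjuryInterval")

# Dirichlet-multinomial marginal likelihood by the sequential chain rule:
# within each parent configuration, multiply the predictive probabilities
# (alpha_k + n_k) / (alpha + n) observation by observation.  No lgamma, no
# shared code with the package's scoring path.
oracle_family_score <- function(df, arity, child, parents, ess) {
  r <- arity[[child]]
  q <- if (length(parents) > 0) prod(unlist(arity[parents])) else 1
  aijk <- ess / (q * r)
  key <- if (length(parents) > 0) {
    do.call(paste, c(df[parents], sep = "."))
  } else rep("all", nrow(df))
  total <- 0
  for (lev in unique(key)) {
    x <- df[[child]][key == lev]
    counts <- rep(0, r)
    seen <- 0
    for (v in x) {
      total <- total + log((aijk + counts[v + 1]) / (aijk * r + seen))
      counts[v + 1] <- counts[v + 1] + 1
      seen <- seen + 1
    }
  }
  total
}

# number of labeled DAGs on n nodes, by the standard inclusion-exclusion
# recurrence over the set of sink-free node subsets
oracle_count_dags <- function(n) {
  a <- numeric(n + 1)
  a[1] <- 1 # a(0)
  for (m in seq_len(n)) {
    s <- 0
    for (k in seq_len(m)) {
      s <- s + (-1)^(k + 1) * choose(m, k) * 2^(k * (m - k)) * a[m - k + 1]
    }
    a[m + 1] <- s
  }
  a[n + 1]
}

# brute-force collider scan over every ordered triple of a directed graph
# given as a 2-column edge matrix (+ optional undirected adjacencies)
oracle_colliders <- function(nodes, directed, undirected = NULL) {
  has_dir <- function(a, b) {
    nrow(directed) > 0 && any(directed[, 1] == a & directed[, 2] == b)
  }
  adj <- function(a, b) {
    m <- rbind(directed, undirected)
    nrow(m) > 0 && any((m[, 1] == a & m[, 2] == b) |
                         (m[, 1] == b & m[, 2] == a))
  }
  out <- NULL
  for (a in nodes) for (b in nodes) for (ch in nodes) {
    if (a >= b || a == ch || b == ch) next
    if (has_dir(a, ch) && has_dir(b, ch) && !adj(a, b))
      out <- rbind(out, data.frame(parent_a = a, parent_b = b, child = ch))
  }
  if (is.null(out))
    out <- data.frame(parent_a = character(0), parent_b = character(0),
                      child = character(0))
  out
}

# all DAGs on a (small) node set, enumerated independently of the package:
# every unordered pair is absent / forward / backward, cyclic results
# dropped via igraph
oracle_all_dags <- function(nodes) {
  p <- length(nodes)
  pairs <- t(combn(p, 2))
  m <- nrow(pairs)
  out <- list()
  for (code in 0:(3^m - 1)) {
    states <- (code %/% 3^(seq_len(m) - 1)) %% 3
    edges <- NULL
    for (k in seq_len(m)) {
      if (states[k] == 1) edges <- rbind(edges, nodes[pairs[k, ]])
      if (states[k] == 2) edges <- rbind(edges, rev(nodes[pairs[k, ]]))
    }
    g <- igraph::graph_from_data_frame(
      if (is.null(edges)) data.frame(from = character(0), to = character(0))
      else data.frame(from = edges[, 1], to = edges[, 2]),
      directed = TRUE, vertices = nodes)
    if (igraph::is_dag(g)) out <- c(out, list(edges))
  }
  out
}

# random discrete data frame with named arities
random_discrete_df <- function(n, arity) {
  as.data.frame(lapply(arity, function(r) sample(0:(r - 1), n, replace = TRUE)))
}

# adjacency key set ("a|b", sorted) of a consensus network
consensus_adjacencies <- function(cn) {
  m <- rbind(cn$directed, cn$undirected)
  if (nrow(m) == 0) return(character(0))
  apply(m, 1, function(e) paste(sort(e), collapse = "|"))
}
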