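two_col <- function(...) {
  m <- rbind(...)
  dimnames(m) <- list(NULL, c("from", "to"))
  m
}

snet <- function(nodes, edges, score) {
  sn <- score_dag(
    as_discrete_table(setNames(as.data.frame(matrix(0L, 2, length(nodes))),
                               nodes),
                      setNames(rep(1, length(nodes)), nodes)),
    dag(nodes, edges))
  sn$log_posterior <- score
  sn
}

test_that("opposing orientations yield an undirected consensus edge", {
  n1 <- snet(c("A", "B"), rbind(c("A", "B")), -10)
  n2 <- snet(c("A", "B"), rbind(c("B", "A")), -10)
  cn <- build_consensus(list(n1, n2))
  expect_equal(nrow(cn$directed), 0L)
  expect_equal(unname(cn$undirected[1, ]), c("A", "B"))
  expect_equal(cn$n_networks, 2L)
})

test_that("a single kept network keeps all its edges directed", {
  n1 <- snet(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")), -5)
  cn <- build_consensus(list(n1))
  expect_equal(nrow(cn$undirected), 0L)
  expect_setequal(paste(cn$directed[, 1], cn$directed[, 2]),
                  c("A B", "B C"))
})

test_that("non-unanimous adjacencies are excluded but reported with support", {
  n1 <- snet(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")), -7)
  n2 <- snet(c("A", "B", "C"), rbind(c("A", "B")), -7)
  cn <- build_consensus(list(n1, n2))
  expect_equal(paste(cn$directed[, 1], cn$directed[, 2]), "A B")
  expect_equal(nrow(cn$undirected), 0L)
  bc <- cn$support[cn$support$node_a == "B" & cn$support$node_b == "C", ]
  expect_equal(bc$n_support, 1L)
  expect_equal(cn$n_networks, 2L)
})

test_that("the score tolerance filters out sub-top networks", {
  n1 <- snet(c("A", "B"), rbind(c("A", "B")), -10)
  n2 <- snet(c("A", "B"), rbind(c("B", "A")), -10 - 1e-12) # within tol
  n3 <- snet(c("A", "B"), NULL, -11)                        # outside
  cn <- build_consensus(list(n1, n2, n3), score_tolerance = 1e-9)
  expect_equal(cn$n_networks, 2L)
  expect_equal(nrow(cn$undirected), 1L)
})

test_that("mismatched node sets and empty input are rejected", {
  n1 <- snet(c("A", "B"), NULL, -1)
  n2 <- snet(c("A", "C"), NULL, -1)
  expect_error(build_consensus(list(n1, n2)), "mismatched")
  expect_error(build_consensus(list()), "no networks")
})

test_that("collider detection matches a brute-force scan on all 3-node DAGs", {
  nodes <- c("A", "B", "C")
  dags <- oracle_all_dags(nodes)
  expect_equal(length(dags), 25L)
  for (edges in dags) {
    g <- dag(nodes, edges)
    got <- detect_v_structures(g)$colliders
    want <- oracle_colliders(nodes,
                             if (is.null(edges))
                               matrix(character(0), ncol = 2) else edges)
    expect_equal(got[order(got$parent_a, got$child), ],
                 want[order(want$parent_a, want$child), ],
                 ignore_attr = TRUE)
  }
})

test_that("chains have no colliders; the V and Y of the lung analysis are found", {
  chain <- dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  expect_equal(nrow(detect_v_structures(chain)$colliders), 0L)
  g <- dag(c("CLP", "LungInsult", "NE", "EO"),
           rbind(c("CLP", "NE"), c("LungInsult", "NE"), c("NE", "EO")))
  v <- detect_v_structures(g)$colliders
  expect_equal(v$parent_a, "CLP")
  expect_equal(v$parent_b, "LungInsult")
  expect_equal(v$child, "NE")
  y <- detect_y_structures(g)$y_structures
  expect_equal(nrow(y), 1L)
  expect_equal(y$grandchild, "EO")
  # collider whose child has no children -> no Y
  g2 <- dag(c("A", "B", "C"), rbind(c("A", "C"), c("B", "C")))
  expect_equal(nrow(detect_y_structures(g2)$y_structures), 0L)
})

test_that("Y counts equal collider count times child out-degree on random DAGs", {
  set.seed(30)
  nodes <- LETTERS[1:6]
  for (i in 1:25) {
    ord <- sample(nodes)
    edges <- NULL
    for (a in 1:5) for (b in (a + 1):6)
      if (runif(1) < 0.3) edges <- rbind(edges, c(ord[a], ord[b]))
    if (is.null(edges)) next
    g <- dag(nodes, edges)
    v <- detect_v_structures(g)$colliders
    y <- detect_y_structures(g)$y_structures
    expected <- 0L
    if (nrow(v) > 0) for (k in seq_len(nrow(v)))
      expected <- expected + sum(edges[, 1] == v$child[k])
    expect_equal(nrow(y), expected)
  }
})

test_that("undirected consensus edges block the non-adjacency condition", {
  cn <- structure(list(
    nodes = c("A", "B", "C"),
    directed = two_col(c("A", "C"), c("B", "C")),
    undirected = two_col(c("A", "B")),
    support = data.frame(node_a = c("A", "A", "B"),
                         node_b = c("B", "C", "C"),
                         n_support = c(2L, 2L, 2L)),
    n_networks = 2L, top_score = -1), class = "consensus_network")
  expect_equal(nrow(detect_v_structures(cn)$colliders), 0L)
})

test_that("Markov equivalence separates chains/forks from colliders", {
  nodes <- c("A", "B", "C")
  c1 <- dag(nodes, rbind(c("A", "B"), c("B", "C")))
  c2 <- dag(nodes, rbind(c("C", "B"), c("B", "A")))
  fork <- dag(nodes, rbind(c("B", "A"), c("B", "C")))
  coll <- dag(nodes, rbind(c("A", "B"), c("C", "B")))
  expect_true(markov_equivalent(c1, c2))
  expect_true(markov_equivalent(c1, fork))
  expect_false(markov_equivalent(c1, coll))
  expect_error(markov_equivalent(c1, dag(c("A", "B", "D"))), "node sets")
})

test_that("the 25 three-node DAGs partition into 11 equivalence classes", {
  nodes <- c("A", "B", "C")
  dags <- lapply(oracle_all_dags(nodes), function(e) dag(nodes, e))
  reps <- list()
  for (g in dags) {
    matched <- FALSE
    for (r in reps) if (markov_equivalent(g, r)) { matched <- TRUE; break }
    if (!matched) reps[[length(reps) + 1]] <- g
  }
  expect_equal(length(reps), 11L)
})
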