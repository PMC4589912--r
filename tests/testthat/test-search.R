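test_that("exhaustive enumeration counts match the DAG-count recurrence", {
  set.seed(20)
  expect_equal(oracle_count_dags(3), 25)
  expect_equal(oracle_count_dags(4), 543)
  d1 <- as_discrete_table(random_discrete_df(10, c(A = 2)))
  expect_equal(attr(exhaustive_search(d1), "n_enumerated"), 1L)
  d3 <- as_discrete_table(random_discrete_df(15, c(A = 2, B = 2, C = 3)))
  expect_equal(attr(exhaustive_search(d3), "n_enumerated"), 25L)
  d4 <- as_discrete_table(random_discrete_df(15, c(A = 2, B = 2, C = 3,
                                                   D = 2)))
  expect_equal(attr(exhaustive_search(d4), "n_enumerated"), 543L)
  expect_error(exhaustive_search(
    as_discrete_table(random_discrete_df(5, setNames(rep(2, 6),
                                                     LETTERS[1:6])))),
    "at most 5")
})

test_that("exhaustive maximizers on strongly dependent pairs form the equivalence class", {
  set.seed(21)
  A <- sample(0:2, 100, replace = TRUE)
  B <- (A + rbinom(100, 1, 0.05)) %% 3
  dt <- as_discrete_table(data.frame(A = A, B = B))
  res <- exhaustive_search(dt)
  expect_equal(length(res), 2L)
  keys <- vapply(res, function(r)
    paste(r$dag$edges[, 1], r$dag$edges[, 2], collapse = ";"), character(1))
  expect_setequal(keys, c("A B", "B A"))
})

test_that("annealing on single-variable data returns the empty DAG", {
  dt <- as_discrete_table(data.frame(A = rep(0:1, 10)))
  res <- anneal_search(dt, search_config(n_restarts = 2,
                                         proposals_per_restart = 100,
                                         seed = 1))
  expect_equal(nrow(res[[1]]$dag$edges), 0L)
  expect_equal(res[[1]]$log_posterior, family_score(dt, "A"),
               tolerance = 1e-12)
})

test_that("annealing is reproducible and returns score-sorted acyclic DAGs", {
  set.seed(22)
  arity <- c(A = 2, B = 3, C = 2, D = 2)
  dt <- as_discrete_table(random_discrete_df(80, arity), arity)
  cfg <- search_config(n_restarts = 5, proposals_per_restart = 3000,
                       seed = 77)
  r1 <- anneal_search(dt, cfg)
  r2 <- anneal_search(dt, cfg)
  edges_of <- function(res) lapply(res, function(x) x$dag$edges)
  expect_identical(edges_of(r1), edges_of(r2))
  expect_identical(vapply(r1, `[[`, numeric(1), "log_posterior"),
                   vapply(r2, `[[`, numeric(1), "log_posterior"))
  scores <- vapply(r1, `[[`, numeric(1), "log_posterior")
  expect_true(all(diff(scores) <= 0))
  expect_true(all(vapply(r1, function(x) is_acyclic(x$dag), logical(1))))
  # per-restart best never drops below the empty-graph score
  empty <- score_dag(dt, dag(names(arity)))$log_posterior
  expect_true(all(scores >= empty - 1e-9))
})

test_that("accepted states stay acyclic across many random trajectories", {
  set.seed(23)
  for (i in 1:20) {
    arity <- setNames(sample(2:3, 5, replace = TRUE), LETTERS[1:5])
    dt <- as_discrete_table(random_discrete_df(25, arity), arity)
    res <- anneal_search(dt, search_config(n_restarts = 5,
                                           proposals_per_restart = 400,
                                           seed = i))
    expect_true(all(vapply(res, function(x) is_acyclic(x$dag), logical(1))))
  }
})

test_that("parent limit is honoured", {
  set.seed(24)
  arity <- setNames(rep(2, 5), LETTERS[1:5])
  dt <- as_discrete_table(random_discrete_df(60, arity), arity)
  res <- anneal_search(dt, search_config(max_parents = 1, n_restarts = 3,
                                         proposals_per_restart = 2000,
                                         seed = 5))
  for (x in res) {
    npar <- table(factor(x$dag$edges[, 2], levels = LETTERS[1:5]))
    expect_true(all(npar <= 1))
  }
})

test_that("annealing attains the exhaustive maximum on 4-variable data", {
  tr <- default_truth("strong")
  hits <- 0L
  for (s in 1:10) {
    t <- generate_cohort(tr, n_per_group = 17, seed = 300 + s,
                         compartment = "blood")$blood
    t <- t[c("CLP", "InjuryInterval", "NE", "IL6")]
    disc <- apply_bins(t, fit_bins(t))
    ex <- exhaustive_search(disc)
    an <- anneal_search(disc, search_config(n_restarts = 20,
                                            proposals_per_restart = 1e4,
                                            seed = s))
    if (abs(an[[1]]$log_posterior - ex[[1]]$log_posterior) < 1e-9)
      hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("search_config validates its fields", {
  expect_error(search_config(ess = 0))
  expect_error(search_config(cooling_factor = 1))
  expect_error(search_config(n_restarts = 0))
})
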