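# Three-state discretization of continuous mediator columns.  Condition
# variables (CLP, LungInsult, InjuryInterval, type) are never rebinned: they
# pass through with their declared arities.

tertile_edges <- function(x) {
  sx <- sort(x)
  n <- length(sx)
  ux <- unique(sx)
  if (length(ux) == 1)
    return(list(edges = numeric(0), n_states = 1L, degenerate = TRUE))
  if (length(ux) == 2) {
    return(list(edges = mean(ux), n_states = 2L, degenerate = TRUE))
  }
  # order-statistic tertiles; each cut point is the midpoint between the
  # quantile order statistic and the next distinct value above it, so no
  # observation ever sits exactly on a cut
  cut_at <- function(q) {
    above <- ux[ux > q]
    if (length(above) == 0) return(NA_real_)
    (q + min(above)) / 2
  }
  e1 <- cut_at(sx[ceiling(n / 3)])
  e2 <- cut_at(sx[ceiling(2 * n / 3)])
  edges <- unique(c(e1, e2))
  edges <- edges[!is.na(edges)]
  if (length(edges) < 2)
    return(list(edges = edges, n_states = length(edges) + 1L,
                degenerate = TRUE))
  list(edges = edges, n_states = 3L, degenerate = FALSE)
}

#' Fit a 3-state discretization scheme
#'
#' The default `"tertiles"` policy places the two cut points at the
#' empirical 1/3 and 2/3 quantiles of each continuous column (midpoints
#' between adjacent distinct order statistics, so intervals are unambiguous).
#' Columns with fewer than 3 distinct values collapse to fewer states and
#' are marked degenerate rather than erroring.  The `"manual"` policy takes
#' user-supplied edges, emulating expert binning.
#'
#' @param table A `sample_table` data frame.
#' @param policy `"tertiles"` or `"manual"`.
#' @param edges For `"manual"`: named list, variable -> strictly increasing
#'   numeric vector of interior cut points (usually length 2).
#' @return A `discretization_scheme`: per continuous variable, its `edges`,
#'   `n_states`, `degenerate` flag and the policy tag.
#' @examples
#' s <- fit_bins(data.frame(x = 1:9))
#' s$variables$x$edges  # 3.5, 6.5
#' @export
fit_bins <- function(table, policy = c("tertiles", "manual"), edges = NULL) {
  policy <- match.arg(policy)
  cont <- setdiff(names(table), c(condition_vars(), "type"))
  vars <- list()
  if (policy == "tertiles") {
    for (v in cont) {
      x <- table[[v]]
      if (anyNA(x)) stop(sprintf("column %s contains missing values", v))
      vars[[v]] <- c(tertile_edges(x), list(policy = "tertiles"))
    }
  } else {
    if (is.null(edges) || is.null(names(edges)))
      stop("manual policy requires a named list of edges")
    missing <- setdiff(cont, names(edges))
    if (length(missing) > 0)
      stop("manual edges missing for: ", paste(missing, collapse = ", "))
    for (v in cont) {
      e <- as.numeric(edges[[v]])
      if (length(e) < 1 || any(diff(e) <= 0))
        stop(sprintf("edges for %s must be strictly increasing", v))
      vars[[v]] <- list(edges = e, n_states = length(e) + 1L,
                        degenerate = length(e) + 1L < 3L,
                        policy = "manual")
    }
  }
  structure(list(policy = policy, variables = vars),
            class = "discretization_scheme")
}

#' Apply a discretization scheme
#'
#' Maps each continuous value to a state by the right-closed convention:
#' values `<=` the first cut point go to state 0, `<=` the second to state
#' 1, and the rest to state 2.  Condition columns are copied verbatim and
#' keep their declared arities (CLP 2, LungInsult 4, InjuryInterval 4,
#' type 3) even when some states are unobserved.
#'
#' @param table A `sample_table` data frame.
#' @param scheme A [fit_bins()] scheme covering every continuous column.
#' @return A `discrete_table`: integer data frame of 0-based states with an
#'   `arity` attribute (named integer vector).
#' @export
apply_bins <- function(table, scheme) {
  stopifnot(inherits(scheme, "discretization_scheme"))
  out <- list()
  arity <- integer(0)
  for (v in names(table)) {
    x <- table[[v]]
    if (is_condition_var(v)) {
      out[[v]] <- as.integer(x)
      arity[v] <- condition_arity()[[v]]
      if (any(out[[v]] < 0 | out[[v]] >= arity[v]))
        stop(sprintf("condition column %s has out-of-range states", v))
    } else {
      sch <- scheme$variables[[v]]
      if (is.null(sch)) stop(sprintf("column %s missing from scheme", v))
      if (anyNA(x)) stop(sprintf("column %s contains missing values", v))
      out[[v]] <- as.integer(findInterval(x, sch$edges, left.open = TRUE))
      arity[v] <- as.integer(sch$n_states)
    }
  }
  as_discrete_table(as.data.frame(out), arity)
}

#' Construct a discrete table directly
#'
#' Wraps an integer data frame of 0-based state indices for use with the
#' scoring and search functions.  Arities default to the per-column observed
#' maximum plus one.
#'
#' @param data Data frame (or matrix) of integer states, 0-based.
#' @param arity Optional named integer vector of state counts per column.
#' @return A `discrete_table`.
#' @export
as_discrete_table <- function(data, arity = NULL) {
  data <- as.data.frame(data)
  for (v in names(data)) data[[v]] <- as.integer(data[[v]])
  if (is.null(arity)) {
    arity <- vapply(data, function(x)
      max(1L, if (nrow(data) > 0) max(x) + 1L else 1L), integer(1))
  }
  arity <- setNames(as.integer(arity[names(data)]), names(data))
  stopifnot(all(arity >= 1))
  for (v in names(data))
    if (nrow(data) > 0 && any(data[[v]] < 0 | data[[v]] >= arity[v]))
      stop(sprintf("column %s has states outside [0, arity)", v))
  structure(data, arity = arity, class = c("discrete_table", "data.frame"))
}

dt_arity <- function(data) attr(data, "arity")

dt_matrix <- function(data) {
  m <- as.matrix(as.data.frame(data))
  storage.mode(m) <- "integer"
  m
}

#' Read or write a discretization scheme as JSON
#'
#' The file form round-trips losslessly: `read_scheme(write_scheme(s, f))`
#' reconstructs `s` exactly.
#'
#' @param scheme A `discretization_scheme`.
#' @param path JSON file path.
#' @return `write_scheme` returns `path` invisibly; `read_scheme` returns
#'   the scheme.
#' @export
write_scheme <- function(scheme, path) {
  jsonlite::write_json(
    list(policy = scheme$policy,
         variables = lapply(scheme$variables, function(v)
           list(edges = as.numeric(v$edges), n_states = v$n_states,
                degenerate = v$degenerate, policy = v$policy))),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  vars <- lapply(raw$variables, function(v)
    list(edges = as.numeric(v$edges), n_states = as.integer(v$n_states),
         degenerate = as.logical(v$degenerate), policy = v$policy))
  structure(list(policy = raw$policy, variables = vars),
            class = "discretization_scheme")
}
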