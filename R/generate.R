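# Ancestral sampling of synthetic cohorts from a causal_truth model.

# per-row expected value for a node, given condition columns and any
# already-sampled mediator parents
node_mean <- function(nd, cond, med) {
  n <- nrow(cond)
  if (length(nd$cparents) == 0) {
    mu <- rep(unname(nd$base), n)
  } else {
    key <- do.call(cfg_key, unname(cond[nd$cparents]))
    idx <- match(key, names(nd$base))
    if (anyNA(idx))
      stop(sprintf("no base mean for %s configuration(s): %s", nd$name,
                   paste(unique(key[is.na(idx)]), collapse = ", ")))
    mu <- unname(nd$base[idx])
  }
  for (pn in names(nd$effects)) {
    e <- nd$effects[[pn]]
    state <- findInterval(med[[pn]], e$breaks) + 1L
    mu <- mu * e$mult[state]
  }
  mu
}

node_cv <- function(nd, cond) {
  if (length(nd$cv) == 1) return(rep(unname(nd$cv), nrow(cond)))
  key <- do.call(cfg_key, unname(cond[nd$cparents]))
  cv <- unname(nd$cv[match(key, names(nd$cv))])
  if (anyNA(cv)) stop(sprintf("no CV for a %s configuration", nd$name))
  cv
}

sample_node <- function(nd, cond, med) {
  mu <- node_mean(nd, cond, med)
  cv <- node_cv(nd, cond)
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mu) - sdlog^2 / 2
  x <- rlnorm(nrow(cond), meanlog = meanlog, sdlog = sdlog)
  if (nd$counts) x <- round(x * nd$scale) / nd$scale
  x
}

#' Generate a synthetic multi-compartment cohort
#'
#' Draws one animal table per compartment by ancestral sampling of the truth
#' DAG: condition columns are fixed by the design, then each mediator is
#' drawn from its log-normal conditional model in topological order.  The
#' output is fully reproducible: identical `(truth, design, n_per_group,
#' seed)` give identical tables.
#'
#' @param truth A [default_truth()] object.
#' @param design A [enumerate_design()] data frame (or a subset of its
#'   rows).
#' @param n_per_group Animals per group; overrides the design's `n_animals`.
#' @param seed Integer seed for the whole cohort.
#' @param compartment Compartments to generate (default all three).
#' @return Named list of `sample_table` data frames (condition columns as
#'   integers, mediators as non-negative doubles), with attributes
#'   `compartment`, `seed` and `preset`.
#' @examples
#' tabs <- generate_cohort(default_truth("paper-like"), seed = 1)
#' dim(tabs$bal)
#' @export
generate_cohort <- function(truth, design = enumerate_design(),
                            n_per_group = 10L, seed = 1L,
                            compartment = compartments()) {
  validate_truth(truth)
  stopifnot(n_per_group >= 1, all(compartment %in% compartments()),
            nrow(design) >= 1)
  set.seed(as.integer(seed))
  idx <- rep(seq_len(nrow(design)), each = n_per_group)
  cond <- design[idx, condition_vars(), drop = FALSE]
  rownames(cond) <- NULL

  out <- list()
  for (comp in compartments()) { # canonical order, fixed draw sequence
    if (!comp %in% compartment) next
    nodes <- truth$compartments[[comp]]
    med <- list()
    for (nm in topo_order_nodes(nodes))
      med[[nm]] <- sample_node(nodes[[nm]], cond, med)
    tab <- cbind(cond, as.data.frame(med)[names(nodes)])
    attr(tab, "compartment") <- comp
    attr(tab, "seed") <- as.integer(seed)
    attr(tab, "preset") <- truth$preset
    class(tab) <- c("sample_table", "data.frame")
    out[[comp]] <- tab
  }
  out
}

#' Write a cohort to CSV files with a JSON sidecar
#'
#' One CSV per compartment (`<dir>/<compartment>.csv`) plus
#' `<dir>/cohort.json` recording the seed, preset and per-compartment truth
#' DAG edge lists.
#'
#' @param tables Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param truth The truth model the tables were drawn from.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(tables, dir, truth) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (comp in names(tables))
    write.csv(tables[[comp]], file.path(dir, paste0(comp, ".csv")),
              row.names = FALSE)
  meta <- list(
    seed = attr(tables[[1]], "seed"),
    preset = truth$preset,
    truth_dag = lapply(setNames(nm = names(tables)), function(comp)
      truth_dag(truth, comp))
  )
  jsonlite::write_json(meta, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a compartment table written by [write_cohort()]
#'
#' @param path CSV file path.
#' @param compartment Compartment tag to attach.
#' @return A `sample_table` data frame.
#' @export
read_sample_table <- function(path, compartment) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  for (v in intersect(condition_vars(), names(tab)))
    tab[[v]] <- as.integer(tab[[v]])
  attr(tab, "compartment") <- compartment
  class(tab) <- c("sample_table", "data.frame")
  tab
}
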