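# End-to-end orchestration: (simulate | read CSV) -> discretize -> anneal
# -> consensus -> motifs, per compartment and for the combined stacked
# dataset with the 3-state "type" variable.

#' Pipeline configuration
#'
#' @param input `"simulate"`, or a named list of CSV paths (one per
#'   compartment, names from [compartments()]) written by [write_cohort()].
#' @param preset Generator preset for simulated input ([default_truth()]).
#' @param n_per_group Animals per group for simulated input.
#' @param seed Master seed; generation and each compartment's search derive
#'   their seeds from it, so a run is reproducible end-to-end.
#' @param policy Discretization policy ([fit_bins()]).
#' @param manual_edges Named list of edges for the manual policy.
#' @param search A [search_config()]; its `seed` field is overridden by the
#'   derived per-stage seed.
#' @param score_tolerance Top-score band for [build_consensus()].
#' @param variables Optional character vector restricting the analysis to a
#'   subset of mediators (condition variables are always kept).
#' @param out_dir Optional directory; when set, every stage artifact is
#'   persisted there.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = "simulate", preset = "paper-like",
                            n_per_group = 10L, seed = 1L,
                            policy = "tertiles", manual_edges = NULL,
                            search = search_config(),
                            score_tolerance = 1e-9, variables = NULL,
                            out_dir = NULL) {
  simulate <- identical(input, "simulate")
  if (!simulate) {
    stopifnot(is.list(input), all(names(input) %in% compartments()))
    for (p in unlist(input)) if (!file.exists(p)) stop("missing input: ", p)
  }
  structure(list(input = input, simulate = simulate, preset = preset,
                 n_per_group = as.integer(n_per_group),
                 seed = as.integer(seed), policy = policy,
                 manual_edges = manual_edges, search = search,
                 score_tolerance = score_tolerance, variables = variables,
                 out_dir = out_dir),
            class = "pipeline_config")
}

# small deterministic seed derivation, kept below 2^31
derive_seed <- function(seed, stage) {
  (seed * 7L + stage * 1009L) %% 2147480009L
}

pipeline_table <- function(config, compartment) {
  if (config$simulate) {
    truth <- default_truth(config$preset)
    generate_cohort(truth, enumerate_design(config$n_per_group),
                    n_per_group = config$n_per_group,
                    seed = derive_seed(config$seed, 0L),
                    compartment = compartment)[[compartment]]
  } else {
    read_sample_table(config$input[[compartment]], compartment)
  }
}

restrict_vars <- function(table, variables) {
  if (is.null(variables)) return(table)
  keep <- c(intersect(c(condition_vars(), "type"), names(table)),
            intersect(variables, names(table)))
  out <- table[, unique(keep), drop = FALSE]
  attributes(out)[c("compartment", "seed", "preset")] <-
    attributes(table)[c("compartment", "seed", "preset")]
  class(out) <- class(table)
  out
}

run_stage_chain <- function(table, config, tag, stage_seed) {
  scheme <- fit_bins(table, policy = config$policy,
                     edges = config$manual_edges)
  disc <- apply_bins(table, scheme)
  sc <- config$search
  sc$seed <- stage_seed
  nets <- anneal_search(disc, sc)
  cons <- build_consensus(nets, config$score_tolerance)
  motifs <- detect_y_structures(cons)
  log <- list(stage = tag, seed = stage_seed,
              n_rows = nrow(table), n_vars = ncol(table),
              effort = attr(nets, "effort"),
              best_score = nets[[1]]$log_posterior,
              n_top = cons$n_networks)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    pre <- file.path(config$out_dir, tag)
    write.csv(table, paste0(pre, "_data.csv"), row.names = FALSE)
    write_scheme(scheme, paste0(pre, "_scheme.json"))
    write_edge_list(nets[[1]]$dag, paste0(pre, "_best.edges"))
    write_graphml(cons, paste0(pre, "_consensus.graphml"))
    write_dot(cons, paste0(pre, "_consensus.dot"))
    write_motifs(motifs, paste0(pre, "_motifs.json"))
    cat(jsonlite::toJSON(log, auto_unbox = TRUE, digits = NA), "\n",
        sep = "", file = file.path(config$out_dir, "run_log.jsonl"),
        append = TRUE)
  }
  list(consensus = cons, motifs = motifs, networks = nets,
       scheme = scheme, table = table, log = log)
}

#' Run the full analysis for one compartment
#'
#' Simulates (or loads) the compartment table, discretizes it, runs the
#' annealing search, builds the consensus of the top-scoring networks and
#' detects V / Y motifs.  Deterministic given the configuration.
#'
#' @param config A [pipeline_config()].
#' @param compartment One of [compartments()].
#' @return List with `consensus`, `motifs`, `networks`, `scheme`, `table`
#'   and `log` (stage, seed, effort counters, best score).
#' @export
run_compartment_analysis <- function(config,
                                     compartment = c("peritoneum", "blood",
                                                     "bal")) {
  compartment <- match.arg(compartment)
  stopifnot(inherits(config, "pipeline_config"))
  table <- restrict_vars(pipeline_table(config, compartment),
                         config$variables)
  stage <- match(compartment, compartments())
  run_stage_chain(table, config, compartment,
                  derive_seed(config$seed, stage))
}

#' Run the combined three-compartment analysis
#'
#' Stacks the three compartment tables on their shared mediator panel
#' (albumin, measured only in BAL, is dropped), adds the 3-state `type`
#' column encoding the fluid source (0 peritoneum, 1 blood, 2 BAL), and
#' runs the same discretize/search/consensus/motif chain on the stacked
#' table.
#'
#' @param config A [pipeline_config()].
#' @return As [run_compartment_analysis()], for the combined table.
#' @export
run_combined_analysis <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  tabs <- lapply(setNames(nm = compartments()), function(comp)
    restrict_vars(pipeline_table(config, comp), config$variables))
  shared <- Reduce(intersect, lapply(tabs, names))
  extra <- lapply(tabs, function(t)
    setdiff(setdiff(names(t), shared), "ALB"))
  if (any(lengths(extra) > 0))
    stop("compartment panels differ beyond the albumin exception: ",
         paste(unlist(extra), collapse = ", "))
  stacked <- do.call(rbind, c(lapply(seq_along(tabs), function(i) {
    t <- as.data.frame(tabs[[i]])[shared]
    t$type <- i - 1L
    t
  }), make.row.names = FALSE))
  class(stacked) <- c("sample_table", "data.frame")
  attr(stacked, "compartment") <- "combined"
  run_stage_chain(stacked, config, "combined", derive_seed(config$seed, 4L))
}
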