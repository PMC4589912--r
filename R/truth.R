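# Ground-truth causal models for the synthetic cohort generator.
#
# Each compartment carries a DAG over {condition variables} U {mediators}.
# Condition variables are roots fixed by the design; every mediator node has
# a log-normal conditional model:
#   * `base`: expected value (original units) per configuration of its
#     condition parents (a named vector keyed by "v1.v2" state strings, or a
#     scalar when it has no condition parents);
#   * `cv`: coefficient of variation, scalar or per-configuration;
#   * `effects`: for each mediator parent, two breakpoints splitting the
#     parent's value into 3 ranges and a multiplicative effect per range —
#     "effect sizes per parent state" on the mean;
#   * `counts`: cell-count nodes are rounded to whole cells (`scale` converts
#     the stored unit to cells, e.g. 1000 for blood counts in 10^3 cells/ul).
# The log-normal is parameterised so that its mean equals the configured
# mean exactly: sdlog^2 = log(1 + cv^2), meanlog = log(mean) - sdlog^2/2.

med_node <- function(name, cparents = character(0), mparents = character(0),
                     base = 1, cv = 0.5, effects = NULL, counts = FALSE,
                     scale = 1) {
  stopifnot(is.numeric(base), all(base > 0), all(cv > 0), scale > 0)
  if (length(cparents) == 0 && length(base) != 1)
    stop("scalar base required when there are no condition parents")
  if (!is.null(effects)) {
    stopifnot(setequal(names(effects), mparents))
    for (e in effects) {
      stopifnot(length(e$breaks) == 2, diff(e$breaks) > 0,
                length(e$mult) == 3, all(e$mult > 0))
    }
  }
  list(name = name, cparents = cparents, mparents = mparents,
       base = base, cv = cv, effects = effects, counts = counts,
       scale = scale)
}

cfg_key <- function(...) do.call(paste, c(list(...), sep = "."))

# base means keyed over CLP x InjuryInterval for the in-design configurations
clp_interval_base <- function(none, h0, h12, h48) {
  c("0.0" = none, "1.1" = h0, "1.2" = h12, "1.3" = h48)
}

# base means keyed over CLP x LungInsult (all 8 encodable configurations)
clp_insult_base <- function(saline, acid, particles, clp_mult) {
  b <- c(saline, acid, particles)
  out <- c(min(b) / 2, b, clp_mult * min(b) / 2, clp_mult * b)
  names(out) <- cfg_key(rep(0:1, each = 4), rep(0:3, 2))
  out
}

insult_base <- function(none, saline, acid, particles) {
  setNames(c(none, saline, acid, particles), cfg_key(0:3))
}

noise_cytokines <- function(names, mean = 40, cv = 0.6) {
  lapply(names, med_node, base = mean, cv = cv)
}

paper_like_compartment <- function(compartment, cv = 0.5) {
  panel <- mediator_panel(compartment)
  nodes <- list()
  add <- function(n) nodes[[n$name]] <<- n

  if (compartment == "bal") {
    # neutrophils: the collider child of CLP and LungInsult; recruitment
    # rises with aspirate severity and is suppressed by concurrent sepsis
    add(med_node("NE", cparents = c("CLP", "LungInsult"),
                 base = clp_insult_base(20, 150, 500, clp_mult = 0.35),
                 cv = cv, counts = TRUE))
    # eosinophils downstream of NE (completes the "Y")
    add(med_node("EO", mparents = "NE", base = 4, cv = cv, counts = TRUE,
                 effects = list(NE = list(breaks = c(40, 200),
                                          mult = c(1, 3, 8)))))
    # albumin leak follows the neutrophil burden
    add(med_node("ALB", mparents = "NE", base = 25, cv = 0.4,
                 effects = list(NE = list(breaks = c(40, 200),
                                          mult = c(1, 2.5, 6)))))
    # chemokines depend on the aspirate type only, not on CLP
    add(med_node("KC",    cparents = "LungInsult",
                 base = insult_base(30, 80, 500, 1600), cv = cv))
    add(med_node("MIP2a", cparents = "LungInsult",
                 base = insult_base(25, 60, 400, 1400), cv = cv))
    add(med_node("LIX",   cparents = "LungInsult",
                 base = insult_base(20, 50, 250, 800), cv = cv))
    add(med_node("MCP1",  cparents = "LungInsult",
                 base = insult_base(40, 100, 450, 1200), cv = cv))
    # local pro-inflammatory cytokines track the lung insult
    add(med_node("IL6",  cparents = "LungInsult",
                 base = insult_base(25, 60, 350, 900), cv = cv))
    add(med_node("TNFa", cparents = "LungInsult",
                 base = insult_base(15, 30, 150, 450), cv = cv))
    add(med_node("IL1b", cparents = "LungInsult",
                 base = insult_base(18, 40, 200, 600), cv = cv))
    add(med_node("WBC", base = 350, cv = cv, counts = TRUE))
    add(med_node("MO",  base = 120, cv = cv, counts = TRUE))
    add(med_node("LY",  base = 40, cv = cv, counts = TRUE))
  } else if (compartment == "peritoneum") {
    # CLP drives peritoneal neutrophil recruitment; the lung insult does not
    add(med_node("NE", cparents = "CLP", base = c("0" = 50, "1" = 2500),
                 cv = cv, counts = TRUE))
    # systemic-compartment cytokines peak 12 h post CLP and resolve by 48 h
    add(med_node("IL6",  cparents = c("CLP", "InjuryInterval"),
                 base = clp_interval_base(40, 200, 2000, 300), cv = cv))
    add(med_node("TNFa", cparents = c("CLP", "InjuryInterval"),
                 base = clp_interval_base(25, 150, 900, 200), cv = cv))
    add(med_node("IL1b", cparents = c("CLP", "InjuryInterval"),
                 base = clp_interval_base(30, 120, 700, 150), cv = cv))
    add(med_node("KC", cparents = "CLP", base = c("0" = 80, "1" = 600),
                 cv = cv))
    add(med_node("MIP2a", cparents = "CLP", base = c("0" = 60, "1" = 450),
                 cv = cv))
    add(med_node("WBC", base = 800, cv = cv, counts = TRUE))
    add(med_node("MO",  base = 400, cv = cv, counts = TRUE))
    add(med_node("LY",  base = 150, cv = cv, counts = TRUE))
    add(med_node("EO",  base = 15, cv = cv, counts = TRUE))
  } else { # blood
    # circulating neutrophils (10^3 cells/ul): 1.9 at the time of CLP and in
    # uninjured animals, a nadir of 0.8 at 12 h, partial rebound by 48 h.
    # CVs per state reproduce a group SD of ~0.63 (SEM 0.2 at n = 10).
    add(med_node("NE", cparents = c("CLP", "InjuryInterval"),
                 base = clp_interval_base(1.9, 1.9, 0.8, 1.4),
                 cv = c("0.0" = 0.33, "1.1" = 0.33, "1.2" = 0.75,
                        "1.3" = 0.45),
                 counts = TRUE, scale = 1000))
    add(med_node("IL6",  cparents = c("CLP", "InjuryInterval"),
                 base = clp_interval_base(20, 120, 900, 150), cv = cv))
    add(med_node("TNFa", cparents = c("CLP", "InjuryInterval"),
                 base = clp_interval_base(12, 80, 400, 90), cv = cv))
    add(med_node("IL1b", cparents = c("CLP", "InjuryInterval"),
                 base = clp_interval_base(15, 60, 300, 80), cv = cv))
    add(med_node("WBC", base = 6, cv = 0.35, counts = TRUE, scale = 1000))
    add(med_node("MO",  base = 0.4, cv = 0.5, counts = TRUE, scale = 1000))
    add(med_node("LY",  base = 3.5, cv = 0.35, counts = TRUE, scale = 1000))
    add(med_node("EO",  base = 0.15, cv = 0.6, counts = TRUE, scale = 1000))
  }

  # remaining panel members carry no condition dependence (background noise)
  all_vars <- panel_vars(compartment)
  missing <- setdiff(all_vars, names(nodes))
  is_cell <- missing %in% panel$cells
  for (nm in missing[!is_cell]) add(med_node(nm, base = 40, cv = 0.6))
  for (nm in missing[is_cell]) add(med_node(nm, base = 20, cv = 0.6,
                                            counts = TRUE))
  nodes[all_vars]
}

null_compartment <- function(compartment) {
  nodes <- paper_like_compartment(compartment)
  lapply(nodes, function(nd) {
    med_node(nd$name, base = mean(nd$base),
             cv = if (length(nd$cv) > 1) mean(nd$cv) else nd$cv,
             counts = nd$counts, scale = nd$scale)
  })
}

#' Ground-truth causal model presets for the cohort generator
#'
#' Builds the per-compartment causal structure the generator samples from.
#' The `"paper-like"` preset encodes the qualitative dependency structure of
#' the two-hit study: BAL neutrophils as a collider child of CLP and
#' LungInsult, BAL eosinophils and albumin downstream of NE, BAL chemokines
#' and pro-inflammatory cytokines driven by the lung insult only, peritoneal
#' and blood IL-6/TNF-a/IL-1b driven by CLP and the injury interval, and
#' peritoneal NE driven by CLP.  Blood neutrophil means are anchored at
#' 1.9 x 10^3 cells/ul (0 h interval / no CLP) and 0.8 x 10^3 cells/ul
#' (12 h).  `"strong"` keeps the same structure with tighter dispersion
#' (CV 0.25); `"null"` removes every dependency on the condition variables
#' and on other mediators.
#'
#' @param effect_profile `"paper-like"`, `"null"` or `"strong"`.
#' @return A `causal_truth` object: per-compartment node models plus the
#'   implied DAG (see [truth_dag()]).
#' @examples
#' tr <- default_truth("paper-like")
#' truth_dag(tr, "bal")
#' @export
default_truth <- function(effect_profile = c("paper-like", "null", "strong")) {
  effect_profile <- match.arg(effect_profile)
  comps <- compartments()
  nodes <- switch(effect_profile,
    "paper-like" = lapply(comps, paper_like_compartment),
    "strong" = lapply(comps, paper_like_compartment, cv = 0.25),
    "null" = lapply(comps, null_compartment))
  names(nodes) <- comps
  out <- structure(list(preset = effect_profile, compartments = nodes),
                   class = "causal_truth")
  validate_truth(out)
  out
}

validate_truth <- function(truth) {
  stopifnot(inherits(truth, "causal_truth"))
  for (comp in names(truth$compartments)) {
    nodes <- truth$compartments[[comp]]
    nms <- vapply(nodes, `[[`, character(1), "name")
    stopifnot(identical(unname(nms), names(nodes)))
    for (nd in nodes) {
      stopifnot(all(nd$cparents %in% condition_vars()),
                all(nd$mparents %in% nms), all(nd$base > 0), all(nd$cv > 0))
    }
    topo_order_nodes(nodes) # errors on a cyclic mediator graph
  }
  invisible(truth)
}

# topological order of mediator nodes by their mediator parents
topo_order_nodes <- function(nodes) {
  nms <- names(nodes)
  placed <- character(0)
  remaining <- nms
  while (length(remaining) > 0) {
    ready <- remaining[vapply(remaining, function(n)
      all(nodes[[n]]$mparents %in% placed), logical(1))]
    if (length(ready) == 0) stop("cyclic mediator dependency in truth model")
    placed <- c(placed, ready)
    remaining <- setdiff(remaining, ready)
  }
  placed
}

#' Edge list of a compartment's ground-truth DAG
#'
#' @param truth A [default_truth()] object.
#' @param compartment One of [compartments()].
#' @return Data frame with columns `parent`, `child`.
#' @export
truth_dag <- function(truth, compartment = c("peritoneum", "blood", "bal")) {
  compartment <- match.arg(compartment)
  nodes <- truth$compartments[[compartment]]
  edges <- do.call(rbind, lapply(nodes, function(nd) {
    par <- c(nd$cparents, nd$mparents)
    if (length(par) == 0) return(NULL)
    data.frame(parent = par, child = nd$name, stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(parent = character(0), child = character(0))
  rownames(edges) <- NULL
  edges
}
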