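# Encodings of the experimental condition variables.
#
# CLP: 0/1, absence/presence of cecal ligation and puncture (sepsis).
# LungInsult: 0 no injury, 1 saline, 2 acid, 3 acid + particles.  State 0 is
#   part of the encoding but does not occur in the study design (every group
#   received an aspirate).
# InjuryInterval: 0 none, 1 = 0 h, 2 = 12 h, 3 = 48 h between CLP and the
#   lung insult.  "none" encodes the groups without CLP: no CLP means there
#   is no CLP-to-insult interval.  (The interval is still a 4-state variable.)
# type: fluid source in the combined analysis, 0 peritoneum, 1 blood, 2 BAL.

#' Condition-variable encodings
#'
#' State labels for the discrete condition variables of the two-hit design.
#' The order of each vector is the integer encoding (first label = state 0).
#'
#' @return A named list of character vectors: `CLP`, `LungInsult`,
#'   `InjuryInterval` and `type`.
#' @examples
#' condition_levels()$LungInsult
#' @export
condition_levels <- function() {
  list(
    CLP = c("none", "clp"),
    LungInsult = c("none", "saline", "acid", "particles"),
    InjuryInterval = c("none", "0h", "12h", "48h"),
    type = c("peritoneum", "blood", "bal")
  )
}

#' @rdname condition_levels
#' @export
condition_arity <- function() {
  vapply(condition_levels(), length, integer(1))
}

condition_vars <- function() c("CLP", "LungInsult", "InjuryInterval")

is_condition_var <- function(x) x %in% c(condition_vars(), "type")

#' Compartments sampled in the study
#'
#' @return Character vector `c("peritoneum", "blood", "bal")` in canonical
#'   order (peritoneal lavage, plasma/blood, bronchoalveolar lavage).
#' @export
compartments <- function() c("peritoneum", "blood", "bal")

#' Enumerate the 12-group experimental design
#'
#' The two-hit design crosses sepsis (CLP) with an aspiration lung insult:
#' three aspirates (saline, acid, acid + particles) given without CLP, plus
#' the same three aspirates given 0, 12 or 48 h after CLP — 3 + 3 x 3 = 12
#' groups.  Groups without CLP carry `InjuryInterval = 0` ("none"): with no
#' CLP there is no CLP-to-insult interval.
#'
#' @param n_per_group Animals per group (design default 10).
#' @return A `group_design` data frame with integer columns `CLP`,
#'   `LungInsult`, `InjuryInterval` (see [condition_levels()]) and
#'   `n_animals`, ordered lexicographically by (CLP, LungInsult,
#'   InjuryInterval).
#' @examples
#' d <- enumerate_design()
#' nrow(d)  # 12
#' @export
enumerate_design <- function(n_per_group = 10L) {
  stopifnot(length(n_per_group) == 1, n_per_group >= 1)
  no_clp <- expand.grid(CLP = 0L, LungInsult = 1:3, InjuryInterval = 0L)
  with_clp <- expand.grid(CLP = 1L, LungInsult = 1:3, InjuryInterval = 1:3)
  d <- rbind(no_clp, with_clp)
  d <- d[order(d$CLP, d$LungInsult, d$InjuryInterval), , drop = FALSE]
  rownames(d) <- NULL
  d$n_animals <- as.integer(n_per_group)
  class(d) <- c("group_design", "data.frame")
  d
}

#' Mediator panel measured in a compartment
#'
#' The cytokine, chemokine and leukocyte variables carried into the network
#' analysis.  Albumin (`ALB`), the vascular-leak indicator, is measured in
#' BAL fluid only.
#'
#' @param compartment One of [compartments()].
#' @return Named list with elements `pro_inflammatory`, `anti_inflammatory`,
#'   `chemokines`, `cells` and `extras` (character vectors of variable
#'   names).
#' @examples
#' mediator_panel("bal")$cells
#' @export
mediator_panel <- function(compartment = c("peritoneum", "blood", "bal")) {
  compartment <- match.arg(compartment)
  panel <- list(
    pro_inflammatory = c("TNFa", "IL6", "IL1b", "IL12", "IFNg",
                         "IL13", "IL4", "IL5", "IL18", "IL2"),
    anti_inflammatory = c("IL10", "TNFsr1", "TNFsr2", "IL1ra"),
    chemokines = c("MIP2a", "KC", "LIX", "MCP1", "MIP1a", "RANTES",
                   "Eotaxin"),
    cells = c("WBC", "NE", "MO", "LY", "EO"),
    extras = if (compartment == "bal") "ALB" else character(0)
  )
  stopifnot(!anyDuplicated(unlist(panel)))
  panel
}

panel_vars <- function(compartment) {
  unlist(mediator_panel(compartment), use.names = FALSE)
}
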