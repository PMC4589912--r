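# Conventional analysis surface: group summaries (mean +/- SEM) and
# significance tests (Student's t, one-way ANOVA with Tukey HSD), for
# contrast with the network results.

#' Per-group mean and SEM of a mediator
#'
#' @param table A `sample_table`.
#' @param variable Continuous mediator column name.
#' @return Data frame with one row per design group present in the table:
#'   condition columns, `n`, `mean`, `sem`.  Groups with a single animal get
#'   `sem = NA` with a warning.
#' @export
group_summary <- function(table, variable) {
  if (!variable %in% names(table)) stop("unknown variable: ", variable)
  cond <- intersect(condition_vars(), names(table))
  key <- interaction(table[cond], drop = TRUE, lex.order = TRUE)
  out <- do.call(rbind, lapply(levels(key), function(k) {
    rows <- table[key == k, , drop = FALSE]
    x <- rows[[variable]]
    cbind(rows[1, cond, drop = FALSE],
          data.frame(n = length(x), mean = mean(x),
                     sem = if (length(x) > 1) sd(x) / sqrt(length(x))
                           else NA_real_))
  }))
  if (any(out$n == 1))
    warning("SEM undefined for group(s) with a single animal")
  rownames(out) <- NULL
  out
}

#' Compare groups on one mediator
#'
#' Two factor levels: Student's two-sample t test (pooled variance, as in
#' the original analysis; set `welch = TRUE` for the unequal-variance
#' form).  More than two levels: one-way ANOVA with Tukey HSD pairwise
#' comparisons flagged at `alpha`.
#'
#' @param table A `sample_table`.
#' @param variable Continuous mediator column name.
#' @param factor_var Condition column to compare across (levels with fewer
#'   than 2 observations are rejected).
#' @param alpha Pairwise significance level (default 0.05).
#' @param welch Use the Welch t test instead of pooled variance.
#' @return A `comparison_result`: `variable`, `factor`, `test` ("t" or
#'   "anova+tukey"), `statistic`, `p_value`, and for ANOVA a `pairwise`
#'   data frame (`level_a`, `level_b`, `diff`, `p_adj`, `significant`).
#' @export
compare_groups <- function(table, variable, factor_var, alpha = 0.05,
                           welch = FALSE) {
  if (!variable %in% names(table)) stop("unknown variable: ", variable)
  if (!factor_var %in% names(table)) stop("unknown factor: ", factor_var)
  f <- factor(table[[factor_var]])
  x <- table[[variable]]
  sizes <- table(f)
  if (length(sizes) < 2 || any(sizes < 2))
    stop("need >= 2 levels with >= 2 observations each")
  if (length(sizes) == 2) {
    lv <- levels(f)
    tt <- t.test(x[f == lv[1]], x[f == lv[2]], var.equal = !welch)
    res <- list(variable = variable, factor = factor_var, test = "t",
                statistic = unname(tt$statistic), p_value = tt$p.value,
                pairwise = NULL)
  } else {
    fit <- aov(x ~ f)
    tab <- summary(fit)[[1]]
    tk <- TukeyHSD(fit, conf.level = 1 - alpha)$f
    pw <- data.frame(
      level_a = sub("-.*$", "", rownames(tk)),
      level_b = sub("^[^-]*-", "", rownames(tk)),
      diff = unname(tk[, "diff"]),
      p_adj = unname(tk[, "p adj"]))
    pw$significant <- pw$p_adj < alpha
    rownames(pw) <- NULL
    res <- list(variable = variable, factor = factor_var,
                test = "anova+tukey",
                statistic = tab[["F value"]][1],
                p_value = tab[["Pr(>F)"]][1],
                pairwise = pw)
  }
  structure(res, class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s across %s: %s, statistic = %.4f, p = %.4g\n",
              x$variable, x$factor, x$test, x$statistic, x$p_value))
  if (!is.null(x$pairwise)) print(x$pairwise)
  invisible(x)
}

#' Write group summaries and comparisons as TSV
#'
#' @param x A [group_summary()] data frame or `comparison_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_stats <- function(x, path) {
  if (inherits(x, "comparison_result")) {
    hdr <- data.frame(variable = x$variable, factor = x$factor,
                      test = x$test, statistic = x$statistic,
                      p_value = x$p_value)
    write.table(hdr, path, sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(x$pairwise)) {
      cat("\n", file = path, append = TRUE)
      suppressWarnings(
        write.table(x$pairwise, path, sep = "\t", row.names = FALSE,
                    quote = FALSE, append = TRUE, col.names = TRUE))
    }
  } else {
    write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
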