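# The measurement table is a tidy data.frame with one value per
# (subject, region, measure): columns subject_id, group, region, measure,
# value; measures are SUV, AUC, AUCr and VT; groups are DIPG and sham.

validateMeasurementTable <- function(table, measure = NULL) {
  need <- c("subject_id", "group", "region", "measure", "value")
  if (!all(need %in% names(table)))
    petStop("table", "measurement table needs columns: %s",
            paste(need, collapse = ", "))
  if (!all(table$group %in% c("DIPG", "sham")))
    petStop("table", "groups must be 'DIPG' or 'sham'")
  if (anyDuplicated(table[c("subject_id", "region", "measure")]))
    petStop("table", "more than one value per (subject, region, measure)")
  if (!is.null(measure)) {
    table <- table[table$measure == measure, , drop = FALSE]
    if (!nrow(table))
      petStop("table", "no rows for measure '%s'", measure)
  }
  table
}

#' Per-region, per-group summary of a measure
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator); the
#' SD of a single observation is reported as missing, not zero.
#'
#' @param table measurement table (see [structureGroupAnova()]).
#' @param measure one of the measure names in the table.
#' @return data.frame: region, group, n, mean, sd.
#' @export
summarizeMeasures <- function(table, measure) {
  tab <- validateMeasurementTable(table, measure)
  out <- do.call(rbind, lapply(split(tab, tab[c("region", "group")], drop = TRUE),
    function(d) data.frame(region = d$region[1], group = d$group[1],
                           n = nrow(d), mean = mean(d$value),
                           sd = if (nrow(d) > 1) stats::sd(d$value)
                                else NA_real_,
                           stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$region, out$group), ]
}

#' Two-group comparison of a measure within one region
#'
#' Two-sided t-test of DIPG against sham values. The Welch
#' (unequal-variance) form is the default, appropriate for the unequal
#' group sizes of the emulated design; Student's pooled-variance test is
#' available via `welch = FALSE`.
#'
#' @param table measurement table.
#' @param region region name.
#' @param measure measure name.
#' @param welch logical; Welch test if `TRUE` (default).
#' @return One-row data.frame: region, measure, per-group n/mean/sd,
#'   statistic, df, p_value, method.
#' @export
twoGroupTest <- function(table, region, measure, welch = TRUE) {
  tab <- validateMeasurementTable(table, measure)
  tab <- tab[tab$region == region, , drop = FALSE]
  if (!nrow(tab)) petStop("table", "no rows for region '%s'", region)
  a <- tab$value[tab$group == "DIPG"]
  b <- tab$value[tab$group == "sham"]
  if (length(a) < 2L || length(b) < 2L)
    petStop("table", "need >= 2 subjects per group in region '%s'", region)
  if (stats::sd(c(a, b)) < 1e-12 * max(1, abs(mean(c(a, b))))) {
    stat <- 0; df <- length(a) + length(b) - 2; p <- 1
    method <- if (welch) "Welch t-test" else "Student t-test"
  } else {
    ht <- stats::t.test(a, b, var.equal = !welch)
    stat <- unname(ht$statistic); df <- unname(ht$parameter); p <- ht$p.value
    method <- if (welch) "Welch t-test" else "Student t-test"
  }
  data.frame(region = region, measure = measure,
             n_dipg = length(a), mean_dipg = mean(a), sd_dipg = stats::sd(a),
             n_sham = length(b), mean_sham = mean(b), sd_sham = stats::sd(b),
             statistic = stat, df = df, p_value = p, method = method,
             stringsAsFactors = FALSE)
}

#' Structure-by-group ANOVA with Bonferroni pairwise comparisons
#'
#' Two-way fixed-effects ANOVA of a measure on the two qualitative
#' variables brain structure and animal group (main effects plus
#' interaction), followed by per-structure two-group comparisons with
#' Bonferroni adjustment across structures (`p_adj = min(1, m * p)` for m
#' structures). Type-II sums of squares are used so the main effects are
#' unambiguous under the unbalanced 6-versus-4 design; on balanced data
#' they coincide with the textbook decomposition.
#'
#' @param table measurement table with columns subject_id, group, region,
#'   measure, value.
#' @param measure measure to analyse.
#' @param alpha significance level for the `significant` flag (default
#'   0.05).
#' @param welch logical; pairwise tests use the Welch form if `TRUE`.
#' @return list with `anova` (term, sum_sq, df, statistic, p_value) and
#'   `pairwise` (per-structure comparison rows plus `p_adjusted`,
#'   `adjustment`, `significant`).
#' @export
structureGroupAnova <- function(table, measure, alpha = 0.05, welch = TRUE) {
  tab <- validateMeasurementTable(table, measure)
  tab$region <- factor(tab$region)
  tab$group <- factor(tab$group, levels = c("sham", "DIPG"))
  if (nlevels(tab$region) < 2L)
    petStop("table", "structure-by-group ANOVA needs >= 2 regions")
  fit <- stats::lm(value ~ region * group, data = tab)
  a2 <- tryCatch(car::Anova(fit, type = 2),
                 error = function(e) {
                   # degenerate zero-residual fits (e.g. all values equal):
                   # fall back to the sequential decomposition, which is
                   # well defined and reports the same (zero) sums of squares
                   suppressWarnings(stats::anova(fit))
                 })
  anova <- data.frame(
    term = c("structure", "group", "structure:group", "residual"),
    sum_sq = a2[["Sum Sq"]],
    df = a2[["Df"]],
    statistic = a2[["F value"]],
    p_value = a2[["Pr(>F)"]],
    stringsAsFactors = FALSE)

  regions <- levels(tab$region)
  m <- length(regions)
  pairwise <- do.call(rbind, lapply(regions, function(rn)
    twoGroupTest(tab, rn, measure, welch = welch)))
  pairwise$p_adjusted <- pmin(1, pairwise$p_value * m)
  pairwise$adjustment <- "bonferroni"
  pairwise$significant <- pairwise$p_adjusted < alpha
  list(anova = anova, pairwise = pairwise)
}
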