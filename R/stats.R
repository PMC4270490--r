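#' Descriptive statistics of a group
#'
#' Mean and sample standard deviation (n - 1 denominator; undefined and
#' reported as `NA` at n = 1).
#'
#' @param values numeric vector (nonempty).
#' @return List `mean`, `sd`, `n`.
#' @export
describe_group <- function(values) {
  if (!length(values)) stop("empty group", call. = FALSE)
  list(mean = mean(values),
       sd = if (length(values) > 1) stats::sd(values) else NA_real_,
       n = length(values))
}

#' Two-sample Student's t-test (pooled variance)
#'
#' Classical two-sided pooled-variance t-test, the traditional pairwise
#' comparison of an experimental group against its control. Welch's
#' correction is available by flag. Degenerate inputs (zero pooled
#' variance) return p = 1 when the means agree and p = 0 (with a warning)
#' when they do not.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @param welch use Welch's unequal-variance form instead.
#' @return List `statistic`, `df`, `p_value`.
#' @export
students_t <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    stop("both samples need n >= 2", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(statistic = 0,
                                        df = length(a) + length(b) - 2,
                                        p_value = 1))
    warning("zero variance with unequal means: p = 0", call. = FALSE)
    return(list(statistic = Inf, df = length(a) + length(b) - 2, p_value = 0))
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' One-way ANOVA
#'
#' Omnibus F-test across all groups of an experiment (between-group mean
#' square over within-group mean square). For two groups, F equals the
#' square of the pooled t statistic exactly.
#'
#' @param groups named or unnamed list of numeric vectors (>= 2 groups,
#'   each n >= 2).
#' @return List `statistic` (F), `df` (c(between, within)), `p_value`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("every group needs n >= 2", call. = FALSE)
  vals <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  within_var <- vapply(groups, stats::var, numeric(1))
  df1 <- length(groups) - 1
  df2 <- length(vals) - length(groups)
  if (all(within_var == 0)) {
    means <- vapply(groups, mean, numeric(1))
    if (max(means) == min(means))
      return(list(statistic = 0, df = c(df1, df2), p_value = 1))
    warning("zero within-group variance with unequal means: p = 0", call. = FALSE)
    return(list(statistic = Inf, df = c(df1, df2), p_value = 0))
  }
  ht <- stats::oneway.test(vals ~ fac, var.equal = TRUE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Dual-significance rule
#'
#' A comparison counts as significant only if both the pairwise Student's
#' t-test and the omnibus one-way ANOVA pass the threshold; the ANOVA acts
#' as the more stringent, experiment-wide gate. Stars follow the
#' convention: `"*"` for p < 0.05 (both tests), `"**"` for p < 0.01 (both
#' tests).
#'
#' @param p_t pairwise t-test p-value.
#' @param p_anova omnibus ANOVA p-value.
#' @param alpha_levels thresholds, c(star, double-star).
#' @return List `p_t`, `p_anova`, `significant_05`, `significant_01`,
#'   `stars`.
#' @export
dual_significance <- function(p_t, p_anova, alpha_levels = c(0.05, 0.01)) {
  if (any(!is.finite(c(p_t, p_anova))) || any(c(p_t, p_anova) < 0) ||
      any(c(p_t, p_anova) > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  sig05 <- p_t < alpha_levels[1] && p_anova < alpha_levels[1]
  sig01 <- p_t < alpha_levels[2] && p_anova < alpha_levels[2]
  list(p_t = p_t, p_anova = p_anova,
       significant_05 = sig05, significant_01 = sig01,
       stars = if (sig01) "**" else if (sig05) "*" else "")
}

#' Figure-style statistical report
#'
#' Per-genotype descriptives plus all control comparisons under the
#' dual-significance rule, one metric at a time. No multiple-testing
#' correction is applied; the number of comparisons is reported so users
#' can apply their own.
#'
#' @param measurements data.frame with columns `genotype`, `metric`,
#'   `value` (and optionally `unit_id`); each muscle measurement is one
#'   observation.
#' @param control control genotype label (default: first level present).
#' @param min_n warn when a cohort is smaller than this configured design
#'   size.
#' @return List with `descriptives` and `comparisons` data.frames and
#'   `n_comparisons`.
#' @export
build_report <- function(measurements, control = NULL, min_n = 2) {
  need <- c("genotype", "metric", "value")
  missing_cols <- setdiff(need, names(measurements))
  if (length(missing_cols))
    stop("measurements lack required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  control <- control %||% unique(measurements$genotype)[1]
  desc <- do.call(rbind, lapply(split(measurements,
                                      measurements[c("metric", "genotype")],
                                      drop = TRUE), function(d) {
    s <- describe_group(d$value)
    data.frame(metric = d$metric[1], genotype = d$genotype[1],
               mean = s$mean, sd = s$sd, n = s$n)
  }))
  rownames(desc) <- NULL
  small <- desc[desc$n < min_n, , drop = FALSE]
  if (nrow(small))
    warning("cohort(s) smaller than the configured design size: ",
            paste(sprintf("%s/%s (n=%d)", small$genotype, small$metric, small$n),
                  collapse = "; "), call. = FALSE)
  comps <- NULL
  for (m in unique(measurements$metric)) {
    dm <- measurements[measurements$metric == m, ]
    groups <- split(dm$value, dm$genotype)
    if (!(control %in% names(groups)) || length(groups) < 2) next
    if (any(vapply(groups, length, integer(1)) < 2)) next
    pa <- one_way_anova(groups)$p_value
    for (g in setdiff(names(groups), control)) {
      tt <- students_t(groups[[g]], groups[[control]])
      dual <- dual_significance(tt$p_value, pa)
      comps <- rbind(comps, data.frame(
        metric = m, genotype = g, control = control,
        p_t = tt$p_value, p_anova = pa,
        significant_05 = dual$significant_05,
        significant_01 = dual$significant_01,
        stars = dual$stars))
    }
  }
  list(descriptives = desc[order(desc$metric, desc$genotype), ],
       comparisons = comps,
       n_comparisons = if (is.null(comps)) 0L else nrow(comps))
}
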