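#' Aggregate per-cell values to per-animal means
#'
#' Guards against pseudoreplication: the animal, not the cell, is the
#' statistical unit, so per-cell (or per-event) values are averaged within
#' each animal before any group test, and every animal contributes exactly
#' one value regardless of how many cells it provided.
#'
#' @param cell_rows `data.frame` with columns `animal_id`, `genotype_group`
#'   and the value column.
#' @param value_col name of the value column (default `"value"`).
#' @param metric_name label carried into the output.
#' @return `data.frame` with one row per (animal, metric): `animal_id`,
#'   `genotype_group`, `metric_name`, `value` (the animal mean), `n_units`.
#' @export
per_animal_aggregate <- function(cell_rows, value_col = "value",
                                 metric_name = value_col) {
  stopifnot(all(c("animal_id", "genotype_group", value_col) %in% names(cell_rows)))
  if (anyNA(cell_rows$animal_id)) stop("rows without animal_id")
  v <- cell_rows[[value_col]]
  by <- list(animal_id = cell_rows$animal_id,
             genotype_group = cell_rows$genotype_group)
  means <- aggregate(list(value = v), by, mean, na.rm = TRUE)
  ns <- aggregate(list(n = v), by, function(x) sum(!is.na(x)))
  if (any(ns$n == 0)) stop("animal with zero usable values")
  out <- data.frame(animal_id = means$animal_id,
                    genotype_group = means$genotype_group,
                    metric_name = metric_name, value = means$value,
                    n_units = ns$n[match(paste(means$animal_id, means$genotype_group),
                                         paste(ns$animal_id, ns$genotype_group))],
                    stringsAsFactors = FALSE)
  out[order(out$genotype_group, out$animal_id), , drop = FALSE]
}

# classic pooled-s.d. Cohen's d (optionally Hedges-corrected)
cohens_d <- function(x, y, hedges = FALSE) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  if (sp2 == 0) return(if (mean(x) == mean(y)) 0 else Inf * sign(mean(y) - mean(x)))
  d <- (mean(y) - mean(x)) / sqrt(sp2)
  if (hedges) d <- d * (1 - 3 / (4 * (nx + ny) - 9))
  d
}

#' Assumption-gated two-group t-test
#'
#' Reproduces the two-group testing policy used for the imaging metrics:
#' equality of variances is assessed first (F-ratio test at `alpha_gate`);
#' if not rejected a two-sided Student's t-test (pooled variance) is used,
#' otherwise Welch's t-test. Normality (Shapiro-Wilk per group, where
#' computable) is reported but does not alter the test choice, since only
#' parametric tests are in scope. Effect size is Cohen's d with pooled
#' standard deviation (Hedges' correction optional).
#'
#' @param group1,group2 numeric vectors (each n >= 2), e.g. per-animal means.
#' @param alpha_gate significance level of the variance-equality gate.
#' @param labels length-2 character vector of group names.
#' @param hedges apply Hedges' small-sample correction to d.
#' @return An object of class `group_comparison`: test used, t statistic,
#'   two-sided p, Cohen's d (sign of group2 - group1), group sizes and an
#'   assumption report. Degenerate inputs (zero variance in both groups with
#'   equal means) are flagged, with t = 0, p = 1, d = 0.
#' @examples
#' gated_t_test(c(1, 2, 3), c(4, 5, 6))
#' @export
gated_t_test <- function(group1, group2, alpha_gate = 0.05,
                         labels = c("group1", "group2"), hedges = FALSE) {
  stopifnot(length(group1) >= 2, length(group2) >= 2)
  v1 <- var(group1); v2 <- var(group2)
  degenerate <- v1 == 0 && v2 == 0
  if (degenerate && mean(group1) == mean(group2)) {
    out <- list(metric_name = NA, groups = labels,
                n_per_group = c(length(group1), length(group2)),
                test_used = "student_t", t_stat = 0, p_value = 1, cohens_d = 0,
                direction = 0,
                assumption_report = list(variance_p = NA, normality_p = c(NA, NA)),
                degenerate = TRUE)
    return(structure(out, class = "group_comparison"))
  }
  var_p <- if (degenerate) NA_real_ else var.test(group1, group2)$p.value
  equal_var <- degenerate || var_p >= alpha_gate
  # t carries the sign of (group1 - group2); d the sign of (group2 - group1)
  tt <- t.test(group1, group2, var.equal = equal_var)
  sw <- function(x) {
    if (length(x) < 3 || length(x) > 5000 || var(x) == 0) return(NA_real_)
    shapiro.test(x)$p.value
  }
  d <- cohens_d(group1, group2, hedges = hedges)
  structure(list(metric_name = NA, groups = labels,
                 n_per_group = c(length(group1), length(group2)),
                 test_used = if (equal_var) "student_t" else "welch_t",
                 t_stat = unname(tt$statistic), p_value = tt$p.value,
                 cohens_d = d, direction = sign(mean(group2) - mean(group1)),
                 assumption_report = list(variance_p = var_p,
                                          normality_p = c(sw(group1), sw(group2))),
                 degenerate = degenerate),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (n=%d) vs %s (n=%d)\n", x$groups[1],
              x$n_per_group[1], x$groups[2], x$n_per_group[2]))
  cat(sprintf("  %s: t = %.4f, p = %.4g, Cohen's d = %.3f\n",
              x$test_used, x$t_stat, x$p_value, x$cohens_d))
  if (!is.na(x$assumption_report$variance_p))
    cat(sprintf("  variance-equality F test p = %.3g; normality p = %s\n",
                x$assumption_report$variance_p,
                paste(signif(x$assumption_report$normality_p, 3), collapse = ", ")))
  if (isTRUE(x$degenerate)) cat("  [degenerate: zero variance in both groups]\n")
  invisible(x)
}

#' Compare two groups of per-animal values for one metric
#'
#' Convenience wrapper: aggregates per animal with [per_animal_aggregate()],
#' then runs [gated_t_test()] on the per-animal means of the two groups.
#'
#' @param cell_rows `data.frame` with `animal_id`, `genotype_group`, value.
#' @param value_col value column name.
#' @param group_order optional length-2 vector fixing which group is first
#'   (the reference) in the comparison.
#' @param ... passed to [gated_t_test()].
#' @return A `group_comparison`; its `n_per_group` equals the number of
#'   animals, never the number of cells.
#' @export
compare_groups <- function(cell_rows, value_col = "value",
                           group_order = NULL, ...) {
  an <- per_animal_aggregate(cell_rows, value_col)
  gr <- unique(an$genotype_group)
  if (!is.null(group_order)) gr <- group_order
  if (length(gr) != 2) stop("exactly two groups required, got: ",
                            paste(gr, collapse = ", "))
  g1 <- an$value[an$genotype_group == gr[1]]
  g2 <- an$value[an$genotype_group == gr[2]]
  out <- gated_t_test(g1, g2, labels = gr, ...)
  out$metric_name <- value_col
  out
}

#' Two-way ANOVA with Bonferroni-adjusted pairwise comparisons
#'
#' Thin plumbing over `aov()` for multi-factor comparisons (e.g. genotype by
#' age or brain region): the standard two-way ANOVA table with interaction,
#' plus all pairwise t-tests between design cells with Bonferroni adjustment
#' (`p_adj = min(1, m * p)`).
#'
#' @param values numeric response.
#' @param factor_a,factor_b factors (coerced) of the same length as `values`.
#' @return List with `anova_table` and `pairwise` (`data.frame` of cell
#'   pairs, raw and adjusted p). An empty design cell is an error.
#' @export
two_way_anova_bonferroni <- function(values, factor_a, factor_b) {
  fa <- factor(factor_a); fb <- factor(factor_b)
  if (any(table(fa, fb) == 0)) stop("empty cell in the two-factor design")
  if (nlevels(fa) < 2 && nlevels(fb) < 2)
    stop("need at least two design cells")
  fit <- if (nlevels(fa) < 2) aov(values ~ fb)
         else if (nlevels(fb) < 2) aov(values ~ fa)
         else aov(values ~ fa * fb)
  tab <- summary(fit)[[1]]
  cell <- interaction(fa, fb, sep = ":")
  lv <- levels(cell)
  pairs <- utils::combn(lv, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(i) {
    x <- values[cell == pairs[1, i]]
    y <- values[cell == pairs[2, i]]
    p <- if (length(x) >= 2 && length(y) >= 2 && (var(x) > 0 || var(y) > 0))
      t.test(x, y, var.equal = TRUE)$p.value else NA_real_
    data.frame(cell_1 = pairs[1, i], cell_2 = pairs[2, i], p_raw = p,
               p_bonferroni = pmin(1, m * p))
  })
  list(anova_table = tab, pairwise = do.call(rbind, rows),
       n_comparisons = m)
}
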