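#' Lilliefors test for composite normality
#'
#' Kolmogorov-Smirnov distance against a normal distribution with estimated
#' mean and SD, with the Dallal-Wilkinson p-value approximation (via
#' \pkg{nortest}).  The statistic is location-scale free, so p-values are
#' exactly invariant under affine transforms `a*x + b`, `a > 0`.
#'
#' @param x numeric sample, `n >= 5`, non-constant.
#' @return List with the KS distance `D` and `p`.
#' @export
lilliefors <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 5) stop("need at least 5 observations")
  if (stats::sd(x) == 0) stop("sample is constant")
  lt <- nortest::lillie.test(x)
  list(D = unname(lt$statistic), p = unname(lt$p.value))
}

#' Log-transform policy for the battery outcomes
#'
#' Screens every task outcome for deviation from normality separately in
#' controls and in patients; a task whose outcome deviates in either group
#' is log-transformed for both groups, so that parametric group-level
#' analyses can be used.  The decision and both p-values are recorded per
#' task; re-running the policy on an already transformed table performs no
#' second transform.
#'
#' @param cohort cohort table with a `group` column.
#' @param tasks outcome columns to screen.
#' @param alpha screening significance level.  The default 0.01 keeps the
#'   rate of spurious transforms low across the 24 screening tests while
#'   retaining power against genuinely log-normal thresholds (see the
#'   methods vignette).
#' @return List with `cohort` (transformed table, transformed columns
#'   renamed in place), `transformed` (character vector of logged tasks)
#'   and `decisions` (per-task data.frame).
#' @export
apply_transform_policy <- function(cohort, tasks = battery_task_ids(),
                                   alpha = 0.01) {
  if (isTRUE(attr(cohort, "transform_applied")))
    return(list(cohort = cohort,
                transformed = attr(cohort, "transformed_tasks"),
                decisions = attr(cohort, "transform_decisions")))
  is_ctrl <- cohort$group == "control"
  dec <- lapply(tasks, function(task) {
    pc <- lilliefors(cohort[[task]][is_ctrl])$p
    pp <- lilliefors(cohort[[task]][!is_ctrl])$p
    data.frame(task = task, p_controls = pc, p_patients = pp,
               log_applied = pc < alpha || pp < alpha)
  })
  dec <- do.call(rbind, dec)
  logged <- dec$task[dec$log_applied]
  for (task in logged) {
    if (any(cohort[[task]] <= 0, na.rm = TRUE))
      stop("task ", task, " selected for log transform has non-positive ",
           "values")
    cohort[[task]] <- log(cohort[[task]])
  }
  attr(cohort, "transform_applied") <- TRUE
  attr(cohort, "transformed_tasks") <- logged
  attr(cohort, "transform_decisions") <- dec
  list(cohort = cohort, transformed = logged, decisions = dec)
}

#' Patients-versus-controls group comparison
#'
#' Per task, a one-sided independent-samples t-test (pooled variance by
#' default; set `var_equal = FALSE` for Welch) with the alternative that
#' patients are worse -- larger thresholds, or smaller scores for the two
#' fixed-level tasks.  Significance flags are Bonferroni-corrected by the
#' number of tasks.
#'
#' @inheritParams apply_transform_policy
#' @param alpha family significance level.
#' @param var_equal pool the group variances?
#' @return data.frame: task, t, df, p (one-sided), significant flags.
#' @export
group_compare <- function(cohort, tasks = battery_task_ids(), alpha = 0.05,
                          var_equal = TRUE) {
  miss <- setdiff(tasks, names(cohort))
  if (length(miss)) stop("missing task columns: ",
                         paste(miss, collapse = ", "))
  dir <- task_directions()[tasks]
  is_ctrl <- cohort$group == "control"
  if (sum(is_ctrl) < 2 || sum(!is_ctrl) < 2)
    stop("need at least 2 subjects per group")
  n_tests <- length(tasks)
  out <- lapply(tasks, function(task) {
    tt <- stats::t.test(cohort[[task]][!is_ctrl], cohort[[task]][is_ctrl],
                        alternative = if (dir[[task]]) "greater" else "less",
                        var.equal = var_equal)
    data.frame(task = task, transform_applied =
                 task %in% attr(cohort, "transformed_tasks"),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value,
               significant_uncorrected = tt$p.value < alpha,
               significant_bonferroni = tt$p.value < alpha / n_tests)
  })
  do.call(rbind, out)
}

#' Kruskal-Wallis rank ANOVA
#'
#' Tie-corrected H with a chi-square upper-tail p on `k - 1` df (wraps
#' [stats::kruskal.test()]).  `kw_pvalue()` exposes the tail arithmetic for
#' a given H and df; for df = 2 it equals `exp(-H/2)`.
#'
#' @param values numeric outcomes.
#' @param groups group labels (>= 2 groups, total n >= 5).
#' @return List with `H`, `df`, `p`.
#' @examples
#' kw_pvalue(9.36, 2)  # 0.0093
#' @export
kruskal_wallis <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (length(values) < 5) stop("need total n >= 5")
  if (length(unique(values)) == 1) stop("all values tied")
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' @rdname kruskal_wallis
#' @param H Kruskal-Wallis statistic.
#' @param df degrees of freedom (groups - 1).
#' @export
kw_pvalue <- function(H, df) {
  stopifnot(H >= 0, df >= 1)
  stats::pchisq(H, df, lower.tail = FALSE)
}

#' Tukey-Kramer pairwise comparison on rank means
#'
#' Post-hoc follow-up to [kruskal_wallis()]: pooled midranks, group mean
#' ranks, tie-corrected variance, and the studentized-range criterion with
#' the Kramer unequal-n adjustment (the conventional "multcompare after
#' kruskalwallis" procedure).
#'
#' @inheritParams kruskal_wallis
#' @param conf_level family confidence level (default 0.95).
#' @return data.frame of pairs with rank-mean difference, critical value
#'   and significance flag.
#' @export
tukey_kramer_ranks <- function(values, groups, conf_level = 0.95) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  k <- nlevels(groups)
  if (k < 2) stop("need at least 2 groups")
  N <- length(values)
  r <- rank(values)
  mr <- tapply(r, groups, mean)
  ns <- tabulate(groups)
  ties <- table(values)
  tie_adj <- sum(ties^3 - ties) / (12 * (N - 1))
  v <- N * (N + 1) / 12 - tie_adj
  qc <- stats::qtukey(conf_level, k, Inf) / sqrt(2)
  pairs <- utils::combn(levels(groups), 2)
  out <- apply(pairs, 2, function(pr) {
    i <- match(pr[1], levels(groups)); j <- match(pr[2], levels(groups))
    se <- sqrt(v * (1 / ns[i] + 1 / ns[j]))
    d <- abs(mr[i] - mr[j])
    data.frame(group1 = pr[1], group2 = pr[2], rank_diff = unname(d),
               critical = qc * se, significant = unname(d > qc * se))
  })
  do.call(rbind, out)
}

#' Per-task subtype comparison
#'
#' Kruskal-Wallis across the patient subtypes for every task, with
#' Tukey-Kramer post hocs run where the omnibus test is significant.
#'
#' @inheritParams group_compare
#' @param alpha omnibus significance level (uncorrected, following the
#'   original procedure).
#' @return List with `omnibus` (data.frame) and `posthoc` (named list of
#'   pairwise tables for significant tasks).
#' @export
subtype_compare <- function(cohort, tasks = battery_task_ids(),
                            alpha = 0.05) {
  pat <- cohort[cohort$group != "control", , drop = FALSE]
  omnibus <- lapply(tasks, function(task) {
    kw <- kruskal_wallis(pat[[task]], pat$group)
    data.frame(task = task, H = kw$H, df = kw$df, p = kw$p,
               significant = kw$p < alpha)
  })
  omnibus <- do.call(rbind, omnibus)
  posthoc <- lapply(tasks[omnibus$significant], function(task)
    tukey_kramer_ranks(pat[[task]], pat$group))
  names(posthoc) <- tasks[omnibus$significant]
  list(omnibus = omnibus, posthoc = posthoc)
}

#' Correlations of battery outcomes with an external variable
#'
#' Pearson or Spearman correlation of each column in `y_set` with `x`,
#' with multiplied-p Bonferroni correction capped at 1.  One-tailed
#' alternatives are available where an analysis specifies a direction.
#'
#' @param data data.frame holding the columns.
#' @param x name of the independent variable.
#' @param y_set names of the outcome columns.
#' @param method `"pearson"` or `"spearman"`.
#' @param alternative `"two.sided"`, `"less"` or `"greater"`; may be a
#'   vector, one per outcome.
#' @param n_tests Bonferroni family size (default: number of outcomes).
#' @return data.frame: y, n, r, p, p_corrected.
#' @export
corr_tests <- function(data, x, y_set, method = c("pearson", "spearman"),
                       alternative = "two.sided", n_tests = length(y_set)) {
  method <- match.arg(method)
  alternative <- rep_len(alternative, length(y_set))
  out <- lapply(seq_along(y_set), function(i) {
    yv <- data[[y_set[i]]]
    xv <- data[[x]]
    ok <- !is.na(yv) & !is.na(xv)
    if (sum(ok) < 4) stop("fewer than 4 paired observations for ", y_set[i])
    if (stats::sd(yv[ok]) == 0 || stats::sd(xv[ok]) == 0)
      stop("zero variance in ", y_set[i], " or ", x)
    ct <- suppressWarnings(
      stats::cor.test(xv[ok], yv[ok], method = method,
                      alternative = alternative[i]))
    data.frame(y = y_set[i], n = sum(ok), r = unname(ct$estimate),
               p = ct$p.value, p_corrected = min(1, n_tests * ct$p.value))
  })
  do.call(rbind, out)
}
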