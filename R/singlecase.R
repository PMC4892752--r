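#' Crawford-Howell modified t-test for a single case
#'
#' Compares one patient's score against a small control sample, treating the
#' control mean and SD as sample estimates rather than population values:
#'
#' \deqn{t = \frac{x^* - \bar{x}}{s\sqrt{(n+1)/n}}, \qquad df = n - 1.}
#'
#' The reported p is one-tailed in the task's deficit direction
#' (`higher_worse = TRUE` for thresholds, `FALSE` for score-correct
#' outcomes), and the normalized Z is the standard-normal quantile of
#' `1 - p`, so that deficits are always positive.
#'
#' @param x_star the patient's score.
#' @param control_mean,control_sd,n control sample statistics (`n >= 2`,
#'   `sd > 0`); alternatively pass the raw control scores as `controls`.
#' @param controls optional numeric vector of control scores.
#' @param higher_worse deficit direction: is a larger score worse?
#' @param alpha,n_tests significance level and Bonferroni family size for
#'   the impairment flags.
#' @return An object of class `single_case` with fields `t`, `df`,
#'   `p_one_tailed`, `z`, `impaired_uncorrected`, `impaired_bonferroni`,
#'   `adjusted = FALSE`.
#' @examples
#' crawford_t(60, control_mean = 50, control_sd = 5, n = 28)
#' @references Crawford & Howell (1998), Clin Neuropsychol 12:482-486.
#' @export
crawford_t <- function(x_star, control_mean = NULL, control_sd = NULL,
                       n = NULL, controls = NULL, higher_worse = TRUE,
                       alpha = 0.05, n_tests = 12) {
  if (!is.null(controls)) {
    control_mean <- mean(controls)
    control_sd <- stats::sd(controls)
    n <- length(controls)
  }
  if (n < 2) stop("need at least 2 controls")
  if (!control_sd > 0) stop("control SD must be positive")
  t <- (x_star - control_mean) / (control_sd * sqrt((n + 1) / n))
  df <- n - 1
  p <- stats::pt(t, df, lower.tail = !higher_worse)
  finish_single_case(t, df, p, adjusted = FALSE, alpha = alpha,
                     n_tests = n_tests)
}

finish_single_case <- function(t, df, p, adjusted, alpha, n_tests) {
  z <- p_to_z(p)
  structure(list(t = t, df = df, p_one_tailed = p, z = z,
                 impaired_uncorrected = p < alpha,
                 impaired_bonferroni = p < alpha / n_tests,
                 adjusted = adjusted, alpha = alpha, n_tests = n_tests),
            class = "single_case")
}

#' @export
print.single_case <- function(x, ...) {
  cat(sprintf(
    "single-case %st(%d) = %.3f, one-tailed p = %.4g, Z = %.3f%s\n",
    if (x$adjusted) "(covariate-adjusted) " else "", x$df, x$t,
    x$p_one_tailed, x$z,
    if (x$impaired_bonferroni) "  [impaired, corrected]"
    else if (x$impaired_uncorrected) "  [impaired, uncorrected]" else ""))
  invisible(x)
}

#' Convert a one-tailed deficit p-value to a normalized Z
#'
#' `z = qnorm(1 - p)`: the estimated percentile of the patient in the
#' control population, expressed in standard-normal units with deficits
#' positive.
#'
#' @param p_one_tailed one-tailed p in (0, 1), already oriented so that
#'   small values mean deficit.
#' @export
p_to_z <- function(p_one_tailed) {
  if (any(p_one_tailed <= 0 | p_one_tailed >= 1))
    stop("p must lie strictly in (0, 1)")
  stats::qnorm(1 - p_one_tailed)
}

#' Bonferroni-corrected Z criterion
#'
#' The Z threshold equalling a one-tailed significance level of
#' `alpha`, Bonferroni-corrected for `n_tests` tests:
#' `qnorm(1 - alpha/n_tests)`.  For `alpha = 0.05` and 12 tasks this is
#' 2.64.
#'
#' @param alpha family significance level in (0, 1).
#' @param n_tests number of tests in the family.
#' @export
z_threshold <- function(alpha = 0.05, n_tests = 12) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  stats::qnorm(1 - alpha / n_tests)
}

#' Select covariates from control regressions
#'
#' Fits, per task, `outcome ~ candidates` in the controls by multiple
#' linear regression.  A candidate is selected if its coefficient is
#' significant (two-tailed p < `alpha`) for at least one of the tasks; the
#' selected covariates are then used for every task in the adjusted
#' single-case comparisons, mirroring the all-or-none rule of the original
#' analysis.
#'
#' @param controls data.frame of control subjects.
#' @param tasks character vector of outcome columns (default: the 12 task
#'   ids).
#' @param candidates character vector of candidate covariate columns.
#' @param alpha per-coefficient significance level.
#' @return Character vector of selected covariates (possibly empty), with a
#'   `details` attribute holding the per-task p-values.
#' @export
select_covariates <- function(controls, tasks = battery_task_ids(),
                              candidates = c("age", "cpm"), alpha = 0.05) {
  stopifnot(all(tasks %in% names(controls)))
  missing_cand <- setdiff(candidates, names(controls))
  if (length(missing_cand))
    stop("candidate covariates not in table: ",
         paste(missing_cand, collapse = ", "))
  keep <- vapply(candidates,
                 function(v) stats::var(controls[[v]], na.rm = TRUE) > 0, NA)
  if (any(!keep)) {
    warning("dropping constant candidate(s): ",
            paste(candidates[!keep], collapse = ", "))
    candidates <- candidates[keep]
  }
  if (length(candidates) > 1) {
    cc <- stats::cor(controls[candidates], use = "complete.obs")
    if (any(abs(cc[upper.tri(cc)]) > 0.999))
      stop("candidate covariates are collinear (|r| > 0.999): ",
           paste(candidates, collapse = ", "))
  }
  if (!length(candidates))
    return(structure(character(0), details = NULL))
  pmat <- sapply(tasks, function(task) {
    fml <- stats::reformulate(candidates, response = task)
    fit <- stats::lm(fml, data = controls)
    stats::coef(summary(fit))[candidates, "Pr(>|t|)"]
  })
  pmat <- matrix(pmat, nrow = length(candidates),
                 dimnames = list(candidates, tasks))
  selected <- candidates[apply(pmat < alpha, 1, any)]
  structure(selected, details = pmat)
}

#' Covariate-adjusted single-case comparison
#'
#' Regression-based single-case test (Crawford & Garthwaite): the control
#' scores are regressed on the covariates, the patient's predicted score is
#' formed from their own covariate values, and the discrepancy is tested
#' with
#'
#' \deqn{t = \frac{y^* - \hat{y}^*}{s_e \sqrt{1 + h^*}}, \qquad
#'   h^* = x_0^{*\prime} (X_0'X_0)^{-1} x_0^*,}
#'
#' where \eqn{X_0} is the intercept-augmented control design matrix,
#' \eqn{s_e} the residual SD and `df = n - k - 1` for `k` covariates.
#'
#' @param y_star patient outcome.
#' @param x_star named numeric vector of the patient's covariate values.
#' @param controls_y control outcomes.
#' @param controls_X data.frame or matrix of control covariates (columns
#'   matching `names(x_star)`).
#' @inheritParams crawford_t
#' @return A `single_case` object with `adjusted = TRUE`.
#' @export
adjusted_singlecase <- function(y_star, x_star, controls_y, controls_X,
                                higher_worse = TRUE, alpha = 0.05,
                                n_tests = 12) {
  X <- as.matrix(controls_X)
  if (is.null(colnames(X))) colnames(X) <- names(x_star)
  x_star <- x_star[colnames(X)]
  if (anyNA(x_star)) stop("patient covariate values missing")
  ok <- stats::complete.cases(X, controls_y)
  X <- X[ok, , drop = FALSE]
  y <- controls_y[ok]
  n <- length(y)
  k <- ncol(X)
  if (n <= k + 2) stop("too few controls (", n, ") for ", k, " covariates")
  X0 <- cbind(1, X)
  if (qr(X0)$rank < ncol(X0)) stop("control design matrix is rank deficient")
  XtXi <- solve(crossprod(X0))
  beta <- XtXi %*% crossprod(X0, y)
  res <- y - X0 %*% beta
  df <- n - k - 1
  s_e <- sqrt(sum(res^2) / df)
  x0 <- c(1, as.numeric(x_star))
  h <- drop(t(x0) %*% XtXi %*% x0)
  t <- (y_star - drop(x0 %*% beta)) / (s_e * sqrt(1 + h))
  p <- stats::pt(t, df, lower.tail = !higher_worse)
  finish_single_case(t, df, p, adjusted = TRUE, alpha = alpha,
                     n_tests = n_tests)
}

#' Single-case results for every patient and task of a cohort
#'
#' Runs [crawford_t()] (and, when covariates are supplied or selectable,
#' [adjusted_singlecase()]) for each patient on each task, against the
#' control sample of the same cohort.  Missing patient scores propagate as
#' missing rows; the Bonferroni family size stays at `n_tests`.
#'
#' @param cohort a cohort table (see [generate_cohort()] /
#'   [read_cohort()]), already on the analysis (possibly log) scale.
#' @param tasks outcome columns to test.
#' @param covariates character vector of covariate columns for the adjusted
#'   variant; `NULL` skips adjustment, `"auto"` runs [select_covariates()].
#' @inheritParams crawford_t
#' @return A long data.frame: patient, task, t, df, p, z, impairment flags
#'   and adjusted-variant columns (heatmap-ready).
#' @export
single_case_table <- function(cohort, tasks = battery_task_ids(),
                              covariates = "auto", alpha = 0.05,
                              n_tests = 12) {
  dir <- task_directions()[tasks]
  ctrl <- cohort[cohort$group == "control", , drop = FALSE]
  pat <- cohort[cohort$group != "control", , drop = FALSE]
  if (identical(covariates, "auto"))
    covariates <- as.character(select_covariates(ctrl, tasks))
  adjust <- length(covariates) > 0
  rows <- list()
  for (task in tasks) {
    cy <- ctrl[[task]]
    for (i in seq_len(nrow(pat))) {
      y <- pat[[task]][i]
      if (is.na(y)) {
        res <- list(t = NA_real_, df = NA_integer_, p_one_tailed = NA_real_,
                    z = NA_real_, impaired_uncorrected = NA,
                    impaired_bonferroni = NA)
      } else {
        res <- crawford_t(y, controls = cy[!is.na(cy)],
                          higher_worse = dir[[task]], alpha = alpha,
                          n_tests = n_tests)
      }
      arow <- list(t_adj = NA_real_, p_adj = NA_real_, z_adj = NA_real_,
                   impaired_bonferroni_adj = NA)
      if (adjust && !is.na(y)) {
        xs <- unlist(pat[i, covariates, drop = FALSE])
        if (!anyNA(xs)) {
          a <- adjusted_singlecase(y, xs, cy, ctrl[covariates],
                                   higher_worse = dir[[task]],
                                   alpha = alpha, n_tests = n_tests)
          arow <- list(t_adj = a$t, p_adj = a$p_one_tailed, z_adj = a$z,
                       impaired_bonferroni_adj = a$impaired_bonferroni)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        patient = pat$subject_id[i], group = pat$group[i], task = task,
        t = res$t, df = res$df, p = res$p_one_tailed, z = res$z,
        impaired_uncorrected = res$impaired_uncorrected,
        impaired_bonferroni = res$impaired_bonferroni,
        adjusted = adjust, arow)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "covariates") <- covariates
  out
}
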