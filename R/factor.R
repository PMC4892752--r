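#' Factor analysis of the neuropsychological battery
#'
#' Principal-component extraction on the correlation matrix of the
#' (internally standardized) variables, eigenvalue-greater-than-one
#' retention when `n_factors = "auto"`, varimax rotation by default, and
#' regression-method factor scores.  With correlation-matrix extraction the
#' eigenvalues sum to the number of variables and each factor explains
#' `100 * eigenvalue / n_variables` per cent of the variance.
#'
#' @param table data.frame or matrix, subjects x variables (complete cases
#'   are used; at least `n_variables / 2` required).
#' @param n_factors `"auto"` (eigenvalue > 1) or an integer.
#' @param rotation `"varimax"` or `"none"`.
#' @return A `factor_solution`: `eigenvalues` (all), `variance_explained`
#'   (\% per retained factor, from the unrotated eigenvalues), `loadings`
#'   (variables x factors, rotated), `factor_scores` (subjects x factors,
#'   zero mean over the fitting sample), `n_variables`, `n_factors`,
#'   `rotation`, `complete_rows` (row index used), and a
#'   `retention_stable` flag (`FALSE` when eigenvalues near 1 make the
#'   retention count unstable).
#' @export
fit_factors <- function(table, n_factors = "auto",
                        rotation = c("varimax", "none")) {
  rotation <- match.arg(rotation)
  X <- as.matrix(table)
  if (is.null(colnames(X))) colnames(X) <- paste0("v", seq_len(ncol(X)))
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]
  p <- ncol(X)
  if (nrow(X) < p / 2)
    stop("too few complete-case subjects (", nrow(X), ") for ", p,
         " variables")
  Z <- scale(X)
  R <- stats::cor(X)
  kap <- kappa(R, exact = TRUE)
  if (!all(is.finite(R)) || kap > 1e12)
    stop("correlation matrix is (near-)singular; condition number ",
         format(kap, digits = 3))
  eig <- eigen(R, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  k <- if (identical(n_factors, "auto")) max(1L, sum(vals > 1))
       else as.integer(n_factors)
  # retention is unstable when eigenvalues hug the retention cut at 1
  stable <- !(vals[k] - 1 < 0.05 || (k < p && 1 - vals[k + 1] < 0.05))
  if (!stable)
    warning("eigenvalues close to 1: factor retention is unstable")
  L <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(vals[seq_len(k)]), k)
  rownames(L) <- colnames(X)
  if (rotation == "varimax" && k >= 2) {
    rot <- stats::varimax(L, normalize = TRUE)
    L <- L %*% rot$rotmat
  }
  # canonical orientation: each factor's mean loading positive
  flip <- ifelse(colSums(L) < 0, -1, 1)
  L <- sweep(L, 2, flip, `*`)
  colnames(L) <- paste0("F", seq_len(k))
  scores <- Z %*% solve(R) %*% L
  colnames(scores) <- colnames(L)
  structure(list(
    eigenvalues = vals,
    variance_explained = variance_explained(vals[seq_len(k)], p),
    loadings = L, factor_scores = scores, n_variables = p, n_factors = k,
    rotation = rotation, complete_rows = which(keep),
    retention_stable = stable), class = "factor_solution")
}

#' @export
print.factor_solution <- function(x, digits = 3, ...) {
  cat(sprintf("factor solution: %d variables, %d factor(s), %s rotation\n",
              x$n_variables, x$n_factors, x$rotation))
  cat("  eigenvalues:",
      paste(round(x$eigenvalues[seq_len(x$n_factors)], digits),
            collapse = ", "),
      "\n  variance explained (%):",
      paste(round(x$variance_explained, 2), collapse = ", "), "\n")
  print(round(x$loadings, digits))
  invisible(x)
}

#' Percentage of variance explained by an eigenvalue
#'
#' For correlation-matrix extraction: `100 * eigenvalue / n_variables`.
#'
#' @param eigenvalue eigenvalue(s), >= 0.
#' @param n_variables number of variables (>= 1).
#' @examples
#' variance_explained(7.938, 14)  # 56.7
#' @export
variance_explained <- function(eigenvalue, n_variables) {
  stopifnot(all(eigenvalue >= 0), n_variables >= 1)
  100 * eigenvalue / n_variables
}

#' Correlate patient factor scores with the psychoacoustic outcomes
#'
#' Pearson correlation of each retained factor's patient scores with each
#' battery outcome, one-tailed in the deficit-consistent direction (higher
#' factor score, i.e. better cognition, should go with lower thresholds and
#' higher scores-correct), Bonferroni-corrected by
#' `length(tasks) * n_factors`.
#'
#' @param solution a [fit_factors()] result fitted on the whole cohort.
#' @param cohort the cohort table the solution was fitted on (same row
#'   order).
#' @param tasks battery outcome columns.
#' @param alpha family significance level.
#' @return data.frame: factor, task, n, r, p (one-tailed), p_corrected,
#'   significant flag.
#' @export
factor_psychoacoustic_corr <- function(solution, cohort,
                                       tasks = battery_task_ids(),
                                       alpha = 0.05) {
  stopifnot(inherits(solution, "factor_solution"))
  rows_used <- solution$complete_rows
  sub <- cohort[rows_used, , drop = FALSE]
  pat <- sub$group != "control"
  if (!any(pat)) stop("no patients with factor scores")
  scores <- solution$factor_scores[pat, , drop = FALSE]
  if (anyNA(scores)) stop("missing factor scores")
  dir <- task_directions()[tasks]
  n_tests <- length(tasks) * solution$n_factors
  out <- list()
  for (f in colnames(scores)) for (task in tasks) {
    yv <- sub[[task]][pat]
    ok <- !is.na(yv)
    alt <- if (dir[[task]]) "less" else "greater"
    ct <- stats::cor.test(scores[ok, f], yv[ok], alternative = alt)
    out[[length(out) + 1L]] <- data.frame(
      factor = f, task = task, n = sum(ok), r = unname(ct$estimate),
      p = ct$p.value, p_corrected = min(1, n_tests * ct$p.value),
      significant = n_tests * ct$p.value < alpha)
  }
  do.call(rbind, out)
}
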