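#' Run the full behavioural analysis pipeline on a cohort
#'
#' Applies, in order: the normality screen and log-transform policy;
#' covariate selection from control regressions; the one-sided
#' patients-versus-controls group contrast (Bonferroni-corrected across the
#' 12 tasks); the Kruskal-Wallis subtype comparison with Tukey-Kramer post
#' hocs; single-case Crawford tests (raw and covariate-adjusted) for every
#' patient and task; pairwise linear-SVM subtype classification with a
#' permutation test; factor analysis of the neuropsychological battery
#' (fitted on controls plus patients, scores read off for patients) with
#' factor--psychoacoustic correlations; and the symptom-duration, hearing
#' and digit-span correlation screens.
#'
#' @param cohort a cohort table ([generate_cohort()] / [read_cohort()]).
#' @param tasks battery outcome columns.
#' @param alpha family significance level.
#' @param norm_alpha normality-screening level for the transform policy.
#' @param adjust run the covariate-adjusted single-case variant?
#' @param svm_n_perm permutations for the SVM test (0 skips it).
#' @param svm_pairs optional character vector restricting the subtype pairs
#'   classified, e.g. `c("NFV-LV")`; order within a pair is ignored.
#' @param n_factors passed to [fit_factors()].
#' @param seed root seed for the stochastic stages (SVM permutations).
#' @param stages character vector naming stages to run (any of
#'   `"group"`, `"subtype"`, `"singlecase"`, `"svm"`, `"factors"`,
#'   `"correlations"`); stages whose inputs are absent are skipped with a
#'   warning.
#' @return An `audbat_analysis` object; see the individual stage functions
#'   for the component formats.
#' @export
analyze_cohort <- function(cohort, tasks = battery_task_ids(),
                           alpha = 0.05, norm_alpha = 0.01, adjust = TRUE,
                           svm_n_perm = 1000, svm_pairs = NULL,
                           n_factors = "auto", seed = 1,
                           stages = c("group", "subtype", "singlecase",
                                      "svm", "factors", "correlations")) {
  res <- list(seed = seed, alpha = alpha, n_tasks = length(tasks))
  have_tasks <- all(tasks %in% names(cohort))
  pat <- cohort[cohort$group != "control", , drop = FALSE]

  if (have_tasks) {
    tp <- apply_transform_policy(cohort, tasks, alpha = norm_alpha)
    cohort_t <- tp$cohort
    res$transform <- tp$decisions
    res$transformed_tasks <- tp$transformed
  } else {
    warning("battery outcome columns absent: psychoacoustic stages skipped")
    cohort_t <- cohort
    stages <- intersect(stages, "factors")
  }

  if ("group" %in% stages)
    res$group <- group_compare(cohort_t, tasks, alpha = alpha)

  if ("subtype" %in% stages) {
    if (length(unique(pat$group)) >= 2)
      res$subtype <- subtype_compare(cohort_t, tasks, alpha = alpha)
    else warning("fewer than 2 patient subtypes: subtype stage skipped")
  }

  if ("singlecase" %in% stages) {
    covs <- if (adjust) "auto" else NULL
    res$singlecase <- single_case_table(cohort_t, tasks, covariates = covs,
                                        alpha = alpha,
                                        n_tests = length(tasks))
    res$covariates <- attr(res$singlecase, "covariates")
  }

  if ("svm" %in% stages) {
    subtypes <- sort(unique(pat$group))
    prs <- if (length(subtypes) >= 2) utils::combn(subtypes, 2,
                                                   simplify = FALSE)
           else list()
    if (!is.null(svm_pairs)) {
      canon <- function(x) paste(sort(x), collapse = "-")
      want <- vapply(strsplit(svm_pairs, "-", fixed = TRUE), canon, "")
      prs <- Filter(function(pr) canon(pr) %in% want, prs)
    }
    res$svm <- list()
    for (pr in prs) {
      sel <- pat$group %in% pr
      if (min(table(pat$group[sel])) < 2) {
        warning("subtype pair ", paste(pr, collapse = "-"),
                " has a class with < 2 members: skipped")
        next
      }
      feats <- as.matrix(as.data.frame(cohort_t)[cohort_t$group != "control",
                                                 tasks])[sel, , drop = FALSE]
      r <- pairwise_svm(feats, pat$group[sel], seed = seed,
                        n_perm = svm_n_perm)
      res$svm[[r$pair]] <- r
    }
  }

  if ("factors" %in% stages) {
    np <- intersect(neuropsych_vars(), names(cohort))
    if (length(np) >= 4) {
      res$factors <- fit_factors(as.data.frame(cohort)[np],
                                 n_factors = n_factors)
      if (have_tasks && "correlations" %in% stages)
        res$factor_corr <- factor_psychoacoustic_corr(res$factors, cohort_t,
                                                      tasks, alpha = alpha)
    } else warning("neuropsychological columns absent: factor stage skipped")
  }

  if ("correlations" %in% stages && have_tasks) {
    pat_t <- cohort_t[cohort_t$group != "control", , drop = FALSE]
    res$duration_corr <- corr_tests(pat_t, "symptom_duration", tasks,
                                    method = "pearson", n_tests = 12)
    res$hearing_corr <- corr_tests(pat_t, "hearing_level", tasks,
                                   method = "pearson", n_tests = 12)
    if ("digit_span" %in% names(pat_t) &&
        sum(!is.na(pat_t$digit_span)) >= 4)
      res$digitspan_corr <- corr_tests(pat_t, "digit_span", tasks,
                                       method = "spearman", n_tests = 12)
  }

  structure(res, class = "audbat_analysis")
}

#' @export
print.audbat_analysis <- function(x, ...) {
  cat("Psychoacoustic battery analysis\n")
  if (!is.null(x$transformed_tasks))
    cat("  log-transformed tasks:",
        if (length(x$transformed_tasks))
          paste(x$transformed_tasks, collapse = ", ") else "none", "\n")
  if (!is.null(x$group))
    cat("  group contrast, corrected-significant tasks:",
        if (any(x$group$significant_bonferroni))
          paste(x$group$task[x$group$significant_bonferroni],
                collapse = ", ") else "none", "\n")
  if (!is.null(x$subtype))
    cat("  subtype Kruskal-Wallis significant:",
        if (any(x$subtype$omnibus$significant))
          paste(x$subtype$omnibus$task[x$subtype$omnibus$significant],
                collapse = ", ") else "none", "\n")
  if (!is.null(x$singlecase)) {
    nimp <- sum(x$singlecase$impaired_bonferroni, na.rm = TRUE)
    cat("  single-case corrected impairments:", nimp, "\n")
  }
  if (!is.null(x$svm))
    for (r in x$svm)
      cat(sprintf("  SVM %s: %.1f%%%s\n", r$pair, r$accuracy,
                  if (is.na(r$p_perm)) "" else
                    sprintf(" (perm p = %.3g)", r$p_perm)))
  if (!is.null(x$factors))
    cat(sprintf("  factors: %d retained, %.1f%% variance\n",
                x$factors$n_factors, sum(x$factors$variance_explained)))
  invisible(x)
}

#' @export
summary.audbat_analysis <- function(object, ...) {
  print(object)
  if (!is.null(object$group)) {
    cat("\nGroup comparison:\n")
    print(object$group, row.names = FALSE)
  }
  if (!is.null(object$factors)) {
    cat("\n")
    print(object$factors)
  }
  invisible(object)
}

#' Corrected-significant headline findings of an analysis
#'
#' The study-level headline is the patients-versus-controls group contrast;
#' this helper returns the tasks flagged at the Bonferroni-corrected level,
#' the quantity whose family-wise false-positive rate the null-cohort
#' calibration controls.
#'
#' @param analysis an `audbat_analysis`.
#' @export
headline_findings <- function(analysis) {
  if (is.null(analysis$group)) return(character(0))
  analysis$group$task[analysis$group$significant_bonferroni]
}

#' Generate a cohort and analyze it end to end
#'
#' Pipeline driver: [generate_cohort()], optionally [generate_trial_level()]
#' (so the analysed outcomes are staircase estimates rather than the
#' generated values), then [analyze_cohort()].
#'
#' @inheritParams analyze_cohort
#' @param config a [cohort_config()].
#' @param seed root seed for all stages.
#' @param trial_level simulate trial-by-trial staircases?
#' @param ... passed to [analyze_cohort()].
#' @return An `audbat_report`: list with `cohort`, `tracks` (or `NULL`),
#'   `analysis`, `config`, `seed`.
#' @export
end_to_end <- function(config = cohort_config(), seed = 1,
                       trial_level = FALSE, ...) {
  cohort <- generate_cohort(config, seed)
  tracks <- NULL
  if (trial_level) {
    tl <- tryCatch(generate_trial_level(cohort, seed = seed),
                   error = function(e) stop("trial simulation stage: ",
                                            conditionMessage(e)))
    cohort_a <- tl$cohort_estimated
    tracks <- tl$tracks
  } else cohort_a <- cohort
  analysis <- tryCatch(analyze_cohort(cohort_a, seed = seed, ...),
                       error = function(e) stop("analysis stage: ",
                                                conditionMessage(e)))
  structure(list(cohort = cohort_a, tracks = tracks, analysis = analysis,
                 config = config, seed = seed), class = "audbat_report")
}

#' @export
print.audbat_report <- function(x, ...) {
  cat(sprintf("audbat report (seed %s): %d subjects%s\n", x$seed,
              nrow(x$cohort),
              if (is.null(x$tracks)) "" else ", trial-level"))
  print(x$analysis)
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' @param report an `audbat_report`.
#' @param path optional output file.
#' @export
report_json <- function(report, path = NULL) {
  a <- report$analysis
  js <- list(
    seed = report$seed,
    n_subjects = nrow(report$cohort),
    groups = as.list(table(report$cohort$group)),
    transformed_tasks = as.list(a$transformed_tasks),
    group = a$group, subtype_omnibus = a$subtype$omnibus,
    singlecase = a$singlecase, covariates = as.list(a$covariates),
    svm = lapply(a$svm, function(r)
      list(pair = r$pair, accuracy = r$accuracy, p_perm = r$p_perm,
           feature_weights = as.list(r$feature_weights))),
    factors = if (!is.null(a$factors)) list(
      eigenvalues = a$factors$eigenvalues,
      variance_explained = a$factors$variance_explained,
      loadings = as.data.frame(a$factors$loadings)),
    factor_corr = a$factor_corr,
    duration_corr = a$duration_corr,
    hearing_corr = a$hearing_corr,
    digitspan_corr = a$digitspan_corr)
  out <- jsonlite::toJSON(js, auto_unbox = TRUE, digits = NA,
                          dataframe = "rows", na = "null", pretty = TRUE)
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(path)
}

#' Validate the structure of a serialized report
#'
#' Checks a report (or its JSON) against the shipped section contract
#' (`inst/schema/report-schema.json`): required sections present and of the
#' right type.
#'
#' @param x an `audbat_report`, a JSON string, or a path to a JSON file.
#' @return `TRUE` invisibly; errors describe the first violated field.
#' @export
validate_report <- function(x) {
  if (inherits(x, "audbat_report")) x <- report_json(x)
  js <- jsonlite::fromJSON(x)
  req <- c("seed", "n_subjects", "groups", "transformed_tasks", "group",
           "singlecase")
  miss <- setdiff(req, names(js))
  if (length(miss)) stop("report missing section(s): ",
                         paste(miss, collapse = ", "))
  if (!is.numeric(js$n_subjects)) stop("n_subjects must be numeric")
  if (!all(c("task", "p") %in% names(js$group)))
    stop("group section must contain task and p columns")
  invisible(TRUE)
}
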