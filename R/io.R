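#' Read and write cohort tables
#'
#' Cohort tables are delimited text (CSV canonical, TSV accepted) with one
#' row per subject and the column dictionary documented in
#' [generate_cohort()]: `subject_id`, `group` (control/SV/NFV/LV), the 12
#' battery outcomes, and optional neuropsychological/demographic columns.
#' Missing values may be empty, `-`, `--` or `NA` (as in clinical tables
#' where a dash marks a test not performed).  Unknown columns are
#' preserved.
#'
#' @param path file path.
#' @param dec decimal separator; use `","` for decimal-comma dialects.
#' @return A `cohort` data.frame.
#' @export
read_cohort <- function(path, dec = ".") {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else if (dec == ",") ";" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, dec = dec,
                          na.strings = c("", "-", "--", "–", "NA"),
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  req <- c("subject_id", "group")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("cohort file lacks column(s): ",
                         paste(miss, collapse = ", "))
  bad_groups <- setdiff(unique(df$group), c("control", "SV", "NFV", "LV"))
  if (length(bad_groups)) stop("unknown group label(s): ",
                               paste(bad_groups, collapse = ", "))
  for (task in intersect(battery_task_ids(), names(df))) {
    v <- df[[task]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(coerced))
      if (length(bad)) stop("non-numeric value in column ", task,
                            " at row(s) ", paste(bad, collapse = ", "))
      df[[task]] <- coerced
    }
  }
  class(df) <- c("cohort", "data.frame")
  df
}

#' @rdname read_cohort
#' @param cohort a cohort table.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  attr(df, "truth") <- NULL
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read/write a run configuration as JSON
#'
#' @param path JSON file.
#' @return `read_config()`: a validated [cohort_config()].
#' @export
read_config <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  validate_config(js)
  defaults <- cohort_config()
  for (nm in names(js)) {
    if (nm %in% c("deficit_profiles", "latent_shifts"))
      js[[nm]] <- lapply(js[[nm]], unlist)
    if (nm == "subgroups") js[[nm]] <- unlist(js[[nm]])
    if (nm == "outcome_model")
      js[[nm]] <- lapply(js[[nm]], as.list)
    defaults[[nm]] <- js[[nm]]
  }
  do.call(cohort_config, defaults[setdiff(names(defaults), NULL)])
}

#' @rdname read_config
#' @param config a config list (parsed JSON or [cohort_config()]).
#' @export
write_config <- function(config, path) {
  # named atomic vectors must serialize as JSON objects, not bare arrays
  as_named <- function(x) {
    if (is.list(x)) lapply(x, as_named)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  jsonlite::write_json(as_named(unclass(config)), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname read_config
#' @details `validate_config()` checks the parsed JSON against the shipped
#'   schema contract (`inst/schema/config-schema.json`): known field names
#'   and basic types.  Violations raise an error naming the offending
#'   field ("schema path").
#' @export
validate_config <- function(config) {
  allowed <- names(formals(cohort_config))
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop("config schema violation at /", unknown[1],
         ": unknown field (allowed: ", paste(allowed, collapse = ", "), ")")
  num1 <- function(field) {
    if (!is.null(config[[field]]) &&
        (!is.numeric(unlist(config[[field]])) ||
         any(!is.finite(unlist(config[[field]])))))
      stop("config schema violation at /", field, ": must be numeric")
  }
  for (f in c("n_controls", "subgroups", "cpm_p2_r", "age_mean", "age_sd",
              "observer_beta", "observer_lapse"))
    num1(f)
  if (!is.null(config$cpm_p2_r) && abs(config$cpm_p2_r) >= 1)
    stop("config schema violation at /cpm_p2_r: must lie in (-1, 1)")
  invisible(TRUE)
}

fnv_hash <- function(txt) {
  h <- 2166136261
  for (ch in utf8ToInt(txt))
    h <- ((h %% 65536) * 16777619 + (h %/% 65536) * 41845 + ch) %% 4294967291
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run manifest
#'
#' Self-describing record of a pipeline run: config hash (stable across
#' reruns of an identical config), seed, package version, stage list with
#' timestamps and every output file written.
#'
#' @param config the run configuration.
#' @param seed root seed.
#' @param stages character vector of executed stages.
#' @param files character vector of output paths.
#' @export
run_manifest <- function(config, seed, stages, files) {
  cfg_json <- as.character(jsonlite::toJSON(unclass(config),
                                            auto_unbox = TRUE, digits = NA))
  list(config_hash = fnv_hash(cfg_json), seed = seed,
       package_version = as.character(utils::packageVersion("audbat")),
       stages = data.frame(stage = stages,
                           timestamp = format(Sys.time(), tz = "UTC")),
       files = basename(files))
}

#' Command-line style entry points
#'
#' `cli_simulate()` generates a cohort (optionally with trial-level
#' staircase logs) and writes `cohort.csv`, `tracks.csv`, `truth.json` and
#' `manifest.json` to `outdir`.  `cli_analyze()` reads a cohort file, runs
#' [analyze_cohort()] and writes tidy result CSVs plus `report.json`.
#' A thin wrapper script exposing these as `simulate` / `analyze`
#' subcommands ships in `inst/cli/audbat`.
#'
#' @param config_path JSON config file (`NULL` for defaults).
#' @param seed root seed.
#' @param outdir output directory (created if needed).
#' @param trial_level simulate staircases?
#' @return Invisibly, the vector of files written.
#' @export
cli_simulate <- function(config_path = NULL, seed = 1, outdir = ".",
                         trial_level = TRUE) {
  config <- if (is.null(config_path)) cohort_config()
            else read_config(config_path)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(config, seed)
  truth <- cohort_truth(cohort)
  files <- file.path(outdir, c("cohort.csv", "tracks.csv", "truth.json",
                               "manifest.json"))
  if (trial_level) {
    tl <- generate_trial_level(cohort, seed = seed)
    write_cohort(tl$cohort_estimated, files[1])
    utils::write.csv(tl$tracks, files[2], row.names = FALSE)
  } else {
    write_cohort(cohort, files[1])
    utils::write.csv(data.frame(), files[2], row.names = FALSE)
  }
  jsonlite::write_json(
    list(seed = seed, latents = as.data.frame(truth$latents),
         shifts = as.data.frame(truth$shifts),
         true_outcomes = truth$true_outcomes),
    files[3], digits = NA, pretty = TRUE)
  man <- run_manifest(config, seed,
                      c("generate", if (trial_level) "trial_level"),
                      files)
  jsonlite::write_json(man, files[4], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(files)
}

#' @rdname cli_simulate
#' @param cohort_path cohort CSV/TSV.
#' @param adjust,svm_n_perm,svm_pairs,alpha passed to [analyze_cohort()].
#' @export
cli_analyze <- function(cohort_path, outdir = ".", seed = 1, adjust = TRUE,
                        svm_n_perm = 1000, svm_pairs = NULL, alpha = 0.05) {
  cohort <- read_cohort(cohort_path)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  analysis <- analyze_cohort(cohort, seed = seed, adjust = adjust,
                             svm_n_perm = svm_n_perm, svm_pairs = svm_pairs,
                             alpha = alpha)
  report <- structure(list(cohort = cohort, tracks = NULL,
                           analysis = analysis, config = NULL, seed = seed),
                      class = "audbat_report")
  files <- character(0)
  wr <- function(obj, name) {
    f <- file.path(outdir, name)
    utils::write.csv(obj, f, row.names = FALSE)
    files <<- c(files, f)
  }
  if (!is.null(analysis$group)) wr(analysis$group, "group.csv")
  if (!is.null(analysis$subtype)) wr(analysis$subtype$omnibus,
                                     "subtype.csv")
  if (!is.null(analysis$singlecase)) wr(analysis$singlecase,
                                        "singlecase.csv")
  if (!is.null(analysis$svm) && length(analysis$svm)) {
    w <- do.call(rbind, lapply(analysis$svm, function(r)
      data.frame(pair = r$pair, feature = names(r$feature_weights),
                 weight = unname(r$feature_weights))))
    wr(w, "svm_weights.csv")
  }
  if (!is.null(analysis$factors))
    wr(data.frame(variable = rownames(analysis$factors$loadings),
                  analysis$factors$loadings), "factor_loadings.csv")
  f <- file.path(outdir, "report.json")
  report_json(report, f)
  files <- c(files, f)
  man <- run_manifest(list(alpha = alpha, adjust = adjust,
                           svm_n_perm = svm_n_perm), seed,
                      "analyze", files)
  mf <- file.path(outdir, "manifest.json")
  jsonlite::write_json(man, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(files, mf))
}
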