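#' The 12-task psychoacoustic battery
#'
#' Builds the parametric definition of the full battery: four tasks in each
#' of three domains (pitch, rhythm/timing, timbre/modulation).  Ten tasks are
#' adaptive forced-choice tasks run with a two-down one-up staircase and a
#' threshold outcome; the two pitch-sequence tasks (`p3`, `p4`) use a fixed
#' difficulty same--different paradigm with a score-correct outcome.
#'
#' Tasks:
#' \describe{
#'   \item{p1}{basic change-in-pitch detection (AB, 2AFC, semitones)}
#'   \item{p2}{pitch change-direction discrimination (AB, 2AFC, semitones)}
#'   \item{p3}{local change in a 4-tone pitch sequence, contour preserved
#'     (same--different, 40 trials, score /40)}
#'   \item{p4}{global change in a 4-tone pitch sequence, contour violated
#'     (same--different, 40 trials, score /40)}
#'   \item{r1}{single time-interval duration discrimination (\% IOI)}
#'   \item{r2}{isochrony deviation detection in a 5-tone sequence (\% IOI)}
#'   \item{r3}{strongly metrical 7-tone pattern discrimination (XAB, 3AFC)}
#'   \item{r4}{weakly metrical 7-tone pattern discrimination (XAB, 3AFC)}
#'   \item{m1}{2 Hz frequency-modulation detection (depth, fraction of carrier)}
#'   \item{m2}{40 Hz frequency-modulation detection (depth)}
#'   \item{m3}{dynamic (spectro-temporal) modulation detection (ripple depth)}
#'   \item{m4}{dynamic modulation discrimination (\% spectral density
#'     difference, AXB, 3AFC)}
#' }
#'
#' `higher_worse` records the deficit direction of the outcome (thresholds:
#' higher is worse; scores: lower is worse) and `log_transform_outcome` the
#' tasks whose thresholds are expected to be log-normally distributed.
#' Staircase step sizes, floors, ceilings and starting levels are
#' reconstructions (the original stimulus inventories are unpublished) and
#' can be overridden per task.
#'
#' @return An object of class `task_battery`: a list of 12 `task_definition`
#'   lists, named by task id.
#' @examples
#' bat <- build_battery()
#' names(bat)
#' bat$p3$paradigm
#' @export
build_battery <- function() {
  def <- function(task_id, domain, name, paradigm, difficulty_dimension,
                  units, log_transform_outcome, higher_worse = TRUE,
                  start_level = NA, floor = NA, ceiling = NA,
                  fixed_delta = NA) {
    n_trials <- if (paradigm == "fixed_same_different") 40L else 50L
    guess <- if (paradigm == "adaptive_3AFC") 1 / 3 else 0.5
    structure(list(
      task_id = task_id, domain = domain, name = name, paradigm = paradigm,
      n_trials = n_trials, difficulty_dimension = difficulty_dimension,
      units = units, log_transform_outcome = log_transform_outcome,
      higher_worse = higher_worse, guess_rate = guess,
      start_level = start_level, floor = floor, ceiling = ceiling,
      fixed_delta = fixed_delta), class = "task_definition")
  }
  tasks <- list(
    def("p1", "pitch", "change in pitch detection", "adaptive_2AFC",
        "frequency change", "semitones", TRUE,
        start_level = 4, floor = 0.01, ceiling = 12),
    def("p2", "pitch", "pitch change direction discrimination",
        "adaptive_2AFC", "frequency change", "semitones", FALSE,
        start_level = 4, floor = 0.01, ceiling = 12),
    def("p3", "pitch", "local change in pitch sequence",
        "fixed_same_different", "frequency change in one tone", "semitones",
        FALSE, higher_worse = FALSE, fixed_delta = 1),
    def("p4", "pitch", "global change in pitch sequence",
        "fixed_same_different", "frequency change in one tone", "semitones",
        FALSE, higher_worse = FALSE, fixed_delta = 1),
    def("r1", "rhythm", "single time-interval duration discrimination",
        "adaptive_2AFC", "interval lengthening", "% of reference IOI", TRUE,
        start_level = 60, floor = 0.5, ceiling = 200),
    def("r2", "rhythm", "isochrony deviation detection", "adaptive_2AFC",
        "IOI lengthening between tones 3 and 4", "% of reference IOI", TRUE,
        start_level = 60, floor = 0.5, ceiling = 200),
    def("r3", "rhythm", "metrical pattern discrimination (strong)",
        "adaptive_3AFC", "onset displacement", "% of beat", FALSE,
        start_level = 60, floor = 0.5, ceiling = 100),
    def("r4", "rhythm", "metrical pattern discrimination (weak)",
        "adaptive_3AFC", "onset displacement", "% of beat", FALSE,
        start_level = 60, floor = 0.5, ceiling = 100),
    def("m1", "timbre", "2 Hz FM detection", "adaptive_2AFC",
        "FM depth", "fraction of carrier", FALSE,
        start_level = 0.2, floor = 1e-4, ceiling = 0.5),
    def("m2", "timbre", "40 Hz FM detection", "adaptive_2AFC",
        "FM depth", "fraction of carrier", TRUE,
        start_level = 0.2, floor = 1e-4, ceiling = 0.5),
    def("m3", "timbre", "dynamic modulation detection", "adaptive_2AFC",
        "ripple modulation depth", "fraction", TRUE,
        start_level = 0.8, floor = 1e-3, ceiling = 1),
    def("m4", "timbre", "dynamic modulation discrimination", "adaptive_3AFC",
        "spectral density difference", "% of reference density", FALSE,
        start_level = 80, floor = 1, ceiling = 300)
  )
  names(tasks) <- vapply(tasks, `[[`, "", "task_id")
  structure(tasks, class = "task_battery")
}

#' @export
print.task_battery <- function(x, ...) {
  cat("Psychoacoustic battery:", length(x), "tasks\n")
  for (t in x)
    cat(sprintf("  %-3s %-7s %-22s %2d trials  [%s, %s]\n", t$task_id,
                t$domain, t$paradigm, t$n_trials, t$difficulty_dimension,
                t$units))
  invisible(x)
}

#' Task ids of the battery, optionally filtered
#'
#' @param battery a `task_battery`, defaults to [build_battery()].
#' @param paradigm optional paradigm filter.
#' @return Character vector of task ids.
#' @export
battery_task_ids <- function(battery = build_battery(), paradigm = NULL) {
  ids <- names(battery)
  if (!is.null(paradigm))
    ids <- ids[vapply(battery, function(t) t$paradigm %in% paradigm, NA)]
  ids
}

#' Deficit direction of each task outcome
#'
#' Thresholds (10 adaptive tasks) are "higher = worse"; the two fixed-level
#' score outcomes (`p3`, `p4`) are "lower = worse".
#'
#' @return Named logical vector, `TRUE` where a larger outcome means worse
#'   performance.
#' @export
task_directions <- function() {
  b <- build_battery()
  vapply(b, `[[`, NA, "higher_worse")
}

#' Tasks whose thresholds are treated as log-normal a priori
#' @return Character vector of task ids.
#' @export
log_tasks <- function() {
  b <- build_battery()
  names(b)[vapply(b, `[[`, NA, "log_transform_outcome")]
}

#' Serialize a battery to JSON
#'
#' @param battery a `task_battery`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @export
battery_json <- function(battery = build_battery(), path = NULL) {
  js <- jsonlite::toJSON(lapply(unclass(battery), unclass),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
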