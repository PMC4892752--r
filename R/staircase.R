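#' Two-down one-up adaptive staircase
#'
#' The staircase makes the task harder (level divided by the current step
#' factor) after two consecutive correct responses and easier (level
#' multiplied by the step factor) after every error, converging on the
#' 70.7\%-correct point of the psychometric function.  Steps are
#' multiplicative: factor 2 until the second reversal, then `sqrt(2)`.
#' Levels are clipped to `[floor, ceiling]`.
#'
#' @param start_level starting difficulty level.
#' @param floor,ceiling hard bounds on the level.
#' @param step_initial,step_final multiplicative step factors before/after
#'   the second reversal.
#' @return `staircase_new()`: a `staircase_state` list.
#' @export
staircase_new <- function(start_level, floor = start_level / 1024,
                          ceiling = start_level * 4,
                          step_initial = 2, step_final = sqrt(2)) {
  stopifnot(start_level > 0, floor > 0, ceiling >= start_level,
            floor <= start_level, step_initial > 1, step_final > 1)
  structure(list(
    level = start_level, floor = floor, ceiling = ceiling,
    step_initial = step_initial, step_final = step_final,
    consecutive_correct = 0L, direction = "none",
    reversal_levels = numeric(0), trial_index = 0L,
    levels = numeric(0), responses = logical(0)), class = "staircase_state")
}

#' @rdname staircase_new
#' @param state a `staircase_state`.
#' @param correct logical, was the response correct?
#' @return `staircase_update()`: the updated state.  A reversal is recorded
#'   (at the pre-move level) whenever the direction of movement flips.
#' @export
staircase_update <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"), is.logical(correct))
  state$trial_index <- state$trial_index + 1L
  state$levels <- c(state$levels, state$level)
  state$responses <- c(state$responses, correct)
  move <- NULL
  if (correct) {
    state$consecutive_correct <- state$consecutive_correct + 1L
    if (state$consecutive_correct >= 2L) {
      move <- "down"
      state$consecutive_correct <- 0L
    }
  } else {
    move <- "up"
    state$consecutive_correct <- 0L
  }
  if (!is.null(move)) {
    if (state$direction != "none" && state$direction != move)
      state$reversal_levels <- c(state$reversal_levels, state$level)
    step <- if (length(state$reversal_levels) < 2L) state$step_initial
            else state$step_final
    state$level <- if (move == "down") state$level / step
                   else state$level * step
    state$level <- min(max(state$level, state$floor), state$ceiling)
    state$direction <- move
  }
  state
}

#' Threshold from a finished staircase track
#'
#' The threshold is the geometric mean of the last six reversal levels, the
#' standard summary for a multiplicative (log-spaced) staircase.  Tracks
#' with fewer than six reversals are flagged as not converged and get an
#' `NA` threshold.
#'
#' @param track a `staircase_track` (from [run_adaptive()]) or a
#'   `staircase_state`.
#' @param n_reversals how many final reversals to average.
#' @return List with `threshold` and `converged`.
#' @examples
#' st <- staircase_new(8, floor = 1, ceiling = 64)
#' estimate_threshold(list(reversal_levels = c(8, 4, 8, 4, 8, 4)))
#' @export
estimate_threshold <- function(track, n_reversals = 6) {
  rev <- track$reversal_levels
  if (is.null(rev) && !is.null(track$levels))
    stop("track has no reversal record")
  if (length(track) == 0 || (is.null(rev) && is.null(track$levels)))
    stop("empty track")
  if (length(rev) < n_reversals)
    return(list(threshold = NA_real_, converged = FALSE))
  last <- utils::tail(rev, n_reversals)
  list(threshold = exp(mean(log(last))), converged = TRUE)
}

#' Run an adaptive task against a virtual observer
#'
#' Simulates the practice phase (repeated at the starting level until five
#' consecutive correct responses; every ten unsuccessful practice trials the
#' level is eased by one initial step, mirroring the individual easing
#' allowed for patients) followed by exactly `task$n_trials` (50) test
#' trials under the two-down one-up rule.  Fully reproducible given `seed`.
#'
#' @param task a `task_definition` with an adaptive paradigm.
#' @param observer a [virtual_observer()]; its guess rate must match the
#'   paradigm (0.5 for 2AFC, 1/3 for 3AFC).
#' @param seed integer seed.
#' @return A `staircase_track`: per-trial levels and responses, reversal
#'   levels, threshold estimate, convergence flag and practice-trial count.
#' @export
run_adaptive <- function(task, observer, seed) {
  stopifnot(inherits(task, "task_definition"))
  if (!task$paradigm %in% c("adaptive_2AFC", "adaptive_3AFC"))
    stop("task ", task$task_id, " is not adaptive")
  if (abs(observer$guess - task$guess_rate) > 1e-8)
    stop("observer guess rate ", observer$guess,
         " incompatible with paradigm ", task$paradigm)
  with_seed(seed, {
    start <- task$start_level
    practice <- 0L
    streak <- 0L
    while (streak < 5L && practice < 100L) {
      practice <- practice + 1L
      streak <- if (observer_respond(observer, start)) streak + 1L else 0L
      if (streak == 0L && practice %% 10L == 0L)
        start <- min(start * 2, task$ceiling)
    }
    st <- staircase_new(start, floor = task$floor, ceiling = task$ceiling)
    for (i in seq_len(task$n_trials))
      st <- staircase_update(st, observer_respond(observer, st$level))
    est <- estimate_threshold(st)
    structure(list(
      task_id = task$task_id, levels = st$levels, responses = st$responses,
      reversal_levels = st$reversal_levels, threshold = est$threshold,
      converged = est$converged, practice_trials = practice,
      start_level = start, seed = seed), class = "staircase_track")
  })
}

#' @export
print.staircase_track <- function(x, ...) {
  cat(sprintf(
    "staircase track [%s]: %d trials, %d reversals, threshold %s%s\n",
    x$task_id, length(x$levels), length(x$reversal_levels),
    format(x$threshold, digits = 4),
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
plot.staircase_track <- function(x, ...) {
  graphics::plot(seq_along(x$levels), x$levels, type = "b", log = "y",
                 xlab = "trial", ylab = "level",
                 main = paste("staircase", x$task_id), ...)
  if (x$converged) graphics::abline(h = x$threshold, lty = 2)
  invisible(x)
}

#' Run a fixed-difficulty same--different task
#'
#' The two pitch-sequence tasks present 40 trials at a fixed difficulty: 20
#' "same" and 20 "different", with each of 20 reference sequences occurring
#' once in each condition.  The virtual observer answers each trial
#' correctly with probability `psi(fixed_delta)` (an unbiased responder;
#' undecidable zero-difference stimuli are answered at chance).
#'
#' @inheritParams run_adaptive
#' @return A `fixed_track` list with the integer `score` (0--40), the trial
#'   table and the balanced design.
#' @export
run_fixed <- function(task, observer, seed) {
  stopifnot(inherits(task, "task_definition"))
  if (task$paradigm != "fixed_same_different")
    stop("task ", task$task_id, " is not a fixed same-different task")
  with_seed(seed, {
    conds <- sample(rep(c(TRUE, FALSE), each = 20L))   # TRUE = "same"
    refs <- sample(rep(seq_len(20L), 2L))
    p_diff <- psychometric(observer, task$fixed_delta)
    correct <- logical(40L)
    for (i in seq_len(40L)) {
      trial <- make_pitch_sequence_trial(task$task_id, same = conds[i],
                                         delta = task$fixed_delta)
      p <- if (trial$undecidable) observer$guess else p_diff
      correct[i] <- stats::runif(1) < p
    }
    structure(list(task_id = task$task_id, score = sum(correct),
                   n_trials = 40L, same = conds, reference_id = refs,
                   responses = correct, seed = seed), class = "fixed_track")
  })
}

#' Long-format trial log of one or more tracks
#'
#' @param tracks a single track or list of tracks; names are used as
#'   subject ids if present.
#' @return A data.frame with columns subject, task, trial, level, correct,
#'   reversal_flag (tidy CSV-ready).
#' @export
tracks_to_df <- function(tracks) {
  if (inherits(tracks, "staircase_track")) tracks <- list(tracks)
  out <- lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    sid <- if (!is.null(names(tracks)) && nzchar(names(tracks)[i]))
      names(tracks)[i] else paste0("run", i)
    if (inherits(tr, "fixed_track"))
      return(data.frame(subject = sid, task = tr$task_id,
                        trial = seq_len(tr$n_trials), level = NA_real_,
                        correct = tr$responses, reversal_flag = FALSE))
    flag <- logical(length(tr$levels))
    # flag trials whose level coincides with a recorded reversal level
    seen <- tr$reversal_levels
    for (j in seq_along(tr$levels)) {
      hit <- which(abs(seen - tr$levels[j]) < 1e-12)
      if (length(hit)) { flag[j] <- TRUE; seen <- seen[-hit[1]] }
    }
    data.frame(subject = sid, task = tr$task_id,
               trial = seq_along(tr$levels), level = tr$levels,
               correct = tr$responses, reversal_flag = flag)
  })
  do.call(rbind, out)
}
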