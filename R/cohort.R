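#' Configuration of the synthetic cohort generator
#'
#' The defaults emulate the study conditions the analyses assume: 28
#' healthy controls and 18 patients in subgroups of 8 SV / 6 NFV / 4 LV;
#' log-normally distributed thresholds for the five tasks whose outcomes
#' are treated as log-normal (`p1, r1, r2, m2, m3`; log-SD 1.1, i.e. an
#' order-of-magnitude spread between poor and good listeners) and normal
#' thresholds or scores elsewhere; a control-side correlation of 0.45
#' between fluid intelligence (CPM) and the pitch-direction task `p2`; a
#' two-latent (semantic / repetition) structure in the 14-variable
#' neuropsychological battery; and subtype deficit profiles with the
#' non-fluent variant worst on the sequence and rhythm tasks.
#'
#' Deficit shifts are expressed in control-SD units on the analysis scale
#' (log scale for the log-normal tasks) and are positive for impairment in
#' the task's deficit direction.
#'
#' @param n_controls number of controls.
#' @param subgroups named patient subgroup sizes.
#' @param deficit_profiles named list (per subtype) of named shift vectors.
#' @param latent_shifts named list (per subtype) of length-2 shifts of the
#'   semantic (`F1`) and repetition (`F2`) latents.
#' @param cpm_p2_r target control-side CPM--p2 correlation.
#' @param outcome_model per-task outcome distributions; see
#'   [default_outcome_model()].
#' @param age_mean,age_sd age distribution (years), no true effect on any
#'   outcome by default.
#' @param observer_beta,observer_lapse psychometric slope and lapse rate
#'   used when simulating trial-level data.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_controls = 28,
                          subgroups = c(SV = 8, NFV = 6, LV = 4),
                          deficit_profiles = default_deficit_profiles(),
                          latent_shifts = list(SV = c(-2.5, 0),
                                               NFV = c(0, -2.5),
                                               LV = c(0, -1)),
                          cpm_p2_r = 0.45,
                          outcome_model = default_outcome_model(),
                          age_mean = 62, age_sd = 8,
                          observer_beta = 8, observer_lapse = 0.02) {
  stopifnot(n_controls >= 0, all(subgroups >= 0),
            abs(cpm_p2_r) < 1)
  for (prof in deficit_profiles)
    stopifnot(all(is.finite(prof)))
  structure(list(
    n_controls = n_controls, subgroups = subgroups,
    deficit_profiles = deficit_profiles, latent_shifts = latent_shifts,
    cpm_p2_r = cpm_p2_r, outcome_model = outcome_model,
    age_mean = age_mean, age_sd = age_sd,
    observer_beta = observer_beta, observer_lapse = observer_lapse),
    class = "cohort_config")
}

#' @rdname cohort_config
#' @details
#' `default_deficit_profiles()` encodes the qualitative deficit pattern the
#' analyses are designed to detect: the non-fluent variant most affected,
#' with severe (near chance-level) deficits on the local pitch-sequence
#' task `p3` and the weakly metrical rhythm task `r4` -- the two tasks that
#' dominate the NFV-versus-LV discrimination -- plus milder deficits on
#' `p4`, `r2`, `r3` and `m4`; the semantic variant mildly affected on the
#' sequence tasks and the strongly metrical task `r3`; and the logopenic
#' variant spared.
#' @export
default_deficit_profiles <- function() {
  list(
    SV = c(p3 = 1.5, p4 = 1, r3 = 1.5, r4 = 1),
    NFV = c(p3 = 4, p4 = 1, r2 = 1, r3 = 1.5, r4 = 4, m4 = 1),
    LV = c()
  )
}

#' @rdname cohort_config
#' @details
#' `default_outcome_model()` gives each task's control-population
#' distribution: `lognormal` (geometric mean `gm`, log-SD `sdlog`) for the
#' five log tasks, truncated-`normal` thresholds elsewhere, and integer
#' `score` outcomes (mean, SD, max 40) for the two fixed-level tasks.
#' @export
default_outcome_model <- function() {
  list(
    p1 = list(dist = "lognormal", gm = 0.8, sdlog = 1.1),
    p2 = list(dist = "normal", mean = 1.5, sd = 0.5),
    p3 = list(dist = "score", mean = 33, sd = 3.5, max = 40),
    p4 = list(dist = "score", mean = 32, sd = 3.5, max = 40),
    r1 = list(dist = "lognormal", gm = 12, sdlog = 1.1),
    r2 = list(dist = "lognormal", gm = 10, sdlog = 1.1),
    r3 = list(dist = "normal", mean = 25, sd = 6),
    r4 = list(dist = "normal", mean = 30, sd = 7),
    m1 = list(dist = "normal", mean = 0.05, sd = 0.012),
    m2 = list(dist = "lognormal", gm = 0.04, sdlog = 1.1),
    m3 = list(dist = "lognormal", gm = 0.1, sdlog = 1.1),
    m4 = list(dist = "normal", mean = 35, sd = 8)
  )
}

# 14-variable neuropsychological battery: loadings on the semantic (F1) and
# repetition (F2) latents, plus the score scale used for realistic units.
neuropsych_model <- function() {
  m <- function(l1, l2, mean, sd, max)
    list(l1 = l1, l2 = l2, mean = mean, sd = sd, max = max)
  list(
    aat_wr_wp_match  = m(0.90, 0.15, 27, 2.0, 30),
    bnt              = m(0.92, 0.10, 52, 4.0, 60),
    aat_aud_wp_match = m(0.89, 0.13, 27, 2.0, 30),
    ppt              = m(0.87, 0.16, 49, 2.0, 52),
    palpa_wp_match   = m(0.86, 0.05, 38, 1.5, 40),
    objdec_hard      = m(0.79, 0.16, 26, 2.5, 32),
    palpa_assoc_sem  = m(0.74, 0.37, 26, 2.0, 30),
    objdec_easy      = m(0.73, 0.29, 29, 2.0, 32),
    aat_wr_sp_match  = m(0.57, 0.57, 27, 2.5, 30),
    aat_aud_sp_match = m(0.59, 0.40, 27, 2.5, 30),
    palpa_pseudo_rep = m(0.13, 0.91, 74, 5.0, 80),
    aat_rep          = m(0.05, 0.86, 145, 5.0, 150),
    cpm              = m(0.17, 0.80, 32, 3.0, 36),
    palpa_word_rep   = m(0.25, 0.77, 78, 2.0, 80)
  )
}

#' Names of the neuropsychological battery columns
#' @export
neuropsych_vars <- function() names(neuropsych_model())

#' Generate a synthetic cohort table
#'
#' Draws a complete subjects-by-outcomes table with the statistical
#' structure described in [cohort_config()]: battery outcomes (with subtype
#' deficits implanted as shifts in control-SD units on the analysis scale),
#' the 14 neuropsychological scores from the two-latent model (the semantic
#' latent impaired in SV, the repetition latent in NFV), digit span forward
#' driven by the repetition latent (missing for two random patients,
#' mirroring incomplete clinical records), age, symptom duration and
#' audiometric hearing level (no true effect on any outcome).
#'
#' @param config a [cohort_config()].
#' @param seed integer root seed; the same seed reproduces the table
#'   byte-identically.
#' @return A data.frame of class `cohort` with a `truth` attribute (the
#'   generating parameters and latent values, for recovery tests only --
#'   the analysis stages never read it).
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(child_seed(seed, "cohort"), {
    groups <- c(rep("control", config$n_controls),
                rep(names(config$subgroups), config$subgroups))
    n <- length(groups)
    ids <- sprintf("S%02d", seq_len(n))
    is_ctrl <- groups == "control"

    # latent cognitive factors
    F1 <- stats::rnorm(n)
    F2 <- stats::rnorm(n)
    for (g in names(config$latent_shifts)) {
      sel <- groups == g
      F1[sel] <- F1[sel] + config$latent_shifts[[g]][1]
      F2[sel] <- F2[sel] + config$latent_shifts[[g]][2]
    }

    np <- neuropsych_model()
    neuro <- lapply(np, function(v) {
      raw <- v$l1 * F1 + v$l2 * F2 +
        stats::rnorm(n, sd = sqrt(max(1e-6, 1 - v$l1^2 - v$l2^2)))
      pmin(v$max, pmax(0, round(v$mean + v$sd * raw)))
    })

    # per-task deficit shift matrix (subjects x tasks)
    tasks <- battery_task_ids()
    shift <- matrix(0, n, length(tasks), dimnames = list(NULL, tasks))
    for (g in names(config$deficit_profiles)) {
      prof <- config$deficit_profiles[[g]]
      for (task in names(prof))
        shift[groups == g, task] <- prof[[task]]
    }

    cpm <- neuro$cpm
    z <- matrix(stats::rnorm(n * length(tasks)), n,
                dimnames = list(NULL, tasks))
    # control-side coupling of p2 with fluid intelligence
    r <- config$cpm_p2_r
    zc <- scale(cpm[is_ctrl])[, 1]
    z[is_ctrl, "p2"] <- r * zc + sqrt(1 - r^2) * z[is_ctrl, "p2"]

    out <- list()
    for (task in tasks) {
      om <- config$outcome_model[[task]]
      zi <- z[, task] + shift[, task]
      out[[task]] <- switch(om$dist,
        lognormal = om$gm * exp(om$sdlog * zi),
        normal = pmax(om$mean / 100, om$mean + om$sd * zi),
        score = pmin(om$max, pmax(0, round(om$mean + om$sd *
                                             (z[, task] - shift[, task])))),
        stop("unknown outcome distribution ", om$dist))
    }

    ds_raw <- 0.8 * F2 + 0.6 * stats::rnorm(n)
    digit_span <- pmin(8, pmax(2, round(5.5 + 1.5 * ds_raw)))
    pat_idx <- which(!is_ctrl)
    if (length(pat_idx) > 2)
      digit_span[sample(pat_idx, 2)] <- NA

    cohort <- data.frame(
      subject_id = ids, group = groups,
      age = round(pmin(85, pmax(45, stats::rnorm(n, config$age_mean,
                                                 config$age_sd)))),
      symptom_duration = ifelse(is_ctrl, NA,
                                round(stats::runif(n, 0.5, 6) * 2) / 2),
      hearing_level = round(pmin(29, pmax(5, stats::rnorm(n, 17, 5)))),
      digit_span = digit_span)
    cohort <- cbind(cohort, as.data.frame(out), as.data.frame(neuro))
    class(cohort) <- c("cohort", "data.frame")
    attr(cohort, "truth") <- list(
      seed = seed, config = config, latents = cbind(F1 = F1, F2 = F2),
      shifts = shift, true_outcomes = as.data.frame(out))
    cohort
  })
}

#' Ground-truth record of a synthetic cohort
#'
#' Accessor for the generating parameters stored by [generate_cohort()];
#' intended for parameter-recovery tests only.
#' @param cohort a synthetic `cohort`.
#' @export
cohort_truth <- function(cohort) attr(cohort, "truth")

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d subjects (%s)\n", nrow(x),
              paste(names(table(x$group)), table(x$group), sep = " = ",
                    collapse = ", ")))
  NextMethod()
}

#' Simulate trial-level data for every subject and task
#'
#' Turns each subject into a [virtual_observer()] whose true threshold is
#' the subject's generated outcome and runs the full battery: adaptive
#' two-down one-up staircases for the ten threshold tasks and the 40-trial
#' fixed design for `p3`/`p4` (where the observer is calibrated so its
#' expected score matches the generated score).  Estimated thresholds and
#' scores are written back next to the true values.
#'
#' @param cohort a synthetic `cohort` from [generate_cohort()].
#' @param battery a `task_battery`.
#' @param seed root seed; per-subject-per-task substreams are derived
#'   deterministically.
#' @return List with `cohort_estimated` (cohort with outcomes replaced by
#'   the staircase/score estimates), `tracks` (long trial log data.frame)
#'   and `true_outcomes`.
#' @export
generate_trial_level <- function(cohort, battery = build_battery(),
                                 seed = 1) {
  stopifnot(inherits(cohort, "cohort"))
  cfg <- cohort_truth(cohort)$config
  beta <- cfg$observer_beta
  lapse <- cfg$observer_lapse
  est <- cohort
  all_tracks <- list()
  for (task in names(battery)) {
    tdef <- battery[[task]]
    for (i in seq_len(nrow(cohort))) {
      sid <- cohort$subject_id[i]
      s <- child_seed(seed, "trials", sid, task)
      if (tdef$paradigm == "fixed_same_different") {
        p_target <- max(tdef$guess_rate + 0.02, cohort[[task]][i] / 40)
        Fo <- min(0.995, max(0.005, (p_target - tdef$guess_rate) /
                               (1 - tdef$guess_rate - lapse)))
        alpha <- tdef$fixed_delta * exp(-stats::qlogis(Fo) / beta)
        obs <- virtual_observer(alpha, beta, lapse, tdef$guess_rate)
        tr <- run_fixed(tdef, obs, s)
        est[[task]][i] <- tr$score
      } else {
        alpha <- min(max(cohort[[task]][i], tdef$floor * 1.5),
                     tdef$ceiling)
        obs <- virtual_observer(alpha, beta, lapse, tdef$guess_rate)
        tr <- run_adaptive(tdef, obs, s)
        est[[task]][i] <- tr$threshold
      }
      all_tracks[[paste(sid, task)]] <- tr
    }
  }
  names(all_tracks) <- sub(" .*", "", names(all_tracks))
  tracks <- tracks_to_df(all_tracks)
  list(cohort_estimated = est, tracks = tracks,
       true_outcomes = cohort_truth(cohort)$true_outcomes)
}
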