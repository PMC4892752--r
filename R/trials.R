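#' Construct single trials of the battery tasks
#'
#' These functions build parametric trial descriptors (frequencies in Hz,
#' onsets in ms) from the task's difficulty value.  They use the current RNG
#' stream; callers that need reproducibility should seed it (the run
#' functions do this via [child_seed()]).
#'
#' `make_pitch_trial()` builds a two-interval trial for the basic pitch
#' tasks: for `p1` one pair is flat and the other contains an up-or-down
#' frequency change of `delta_semitones`; for `p2` both pairs change by
#' `delta_semitones`, rising or falling, and the answer is whether the two
#' directions agree.  Reference frequencies are drawn near 500 Hz
#' (+/- 2 semitones).
#'
#' @param task task id (`"p1"` or `"p2"`).
#' @param delta_semitones frequency change in semitones (>= 0).
#' @param ref_low,ref_high range (semitones re 500 Hz) of the reference draw.
#' @return A list describing the trial; `undecidable` is `TRUE` when
#'   `delta = 0` (the intervals are then identical).
#' @examples
#' set.seed(1)
#' tr <- make_pitch_trial("p1", 1)
#' tr$pairs[[tr$target]]
#' @export
make_pitch_trial <- function(task, delta_semitones, ref_low = -2,
                             ref_high = 2) {
  task <- match.arg(task, c("p1", "p2"))
  if (delta_semitones < 0) stop("delta_semitones must be >= 0")
  st <- function(f, s) f * 2^(s / 12)
  ref <- function() st(500, stats::runif(1, ref_low, ref_high))
  if (task == "p1") {
    f <- ref()
    dir <- sample(c(-1, 1), 1)
    target <- sample(1:2, 1)
    pairs <- list(c(f, f), c(f, f))
    pairs[[target]][2] <- st(f, dir * delta_semitones)
    list(task = "p1", pairs = pairs, target = target, direction = dir,
         delta = delta_semitones, undecidable = delta_semitones == 0)
  } else {
    f1 <- ref(); f2 <- ref()
    s <- sample(c(-1, 1), 2, replace = TRUE)
    pairs <- list(c(f1, st(f1, s[1] * delta_semitones)),
                  c(f2, st(f2, s[2] * delta_semitones)))
    list(task = "p2", pairs = pairs, directions = s,
         answer = if (s[1] == s[2]) "same" else "different",
         delta = delta_semitones, undecidable = delta_semitones == 0)
  }
}

contour_of <- function(freqs) {
  paste(ifelse(diff(freqs) > 0, "+", "-"), collapse = "")
}

#' @rdname make_pitch_trial
#'
#' @details
#' `make_pitch_sequence_trial()` builds the 4-tone sequence pairs of `p3`
#' (local change: the third or fourth tone moves but the contour of ups and
#' downs is preserved) and `p4` (global change: the altered transition flips
#' sign).  Reference sequences have random contours with inter-tone steps of
#' 1.5--3 semitones, so a 1-semitone local change can never flip a step.
#'
#' @param same logical: build a "same" (identical sequences) trial?
#' @param delta alteration size in semitones for "different" trials.
#' @export
make_pitch_sequence_trial <- function(task, same, delta = 1) {
  task <- match.arg(task, c("p3", "p4"))
  step_lo <- max(1.5, delta * 1.5)
  steps <- sample(c(-1, 1), 3, replace = TRUE) *
    stats::runif(3, min = step_lo, max = step_lo + 1.5)
  f0 <- 500 * 2^(stats::runif(1, -2, 2) / 12)
  semis <- cumsum(c(0, steps))
  reference <- f0 * 2^(semis / 12)
  comparison <- reference
  altered_pos <- NA_integer_
  if (!same && delta > 0) {
    altered_pos <- sample(3:4, 1)
    if (task == "p3") {
      # move the tone without flipping any adjacent step
      d <- sample(c(-1, 1), 1)
      comparison[altered_pos] <- reference[altered_pos] * 2^(d * delta / 12)
    } else {
      # re-place the tone on the far side of its predecessor: the step into
      # it flips sign, changing the global contour at that transition
      s_in <- sign(steps[altered_pos - 1])
      comparison[altered_pos] <- reference[altered_pos - 1] *
        2^(-s_in * delta / 12)
    }
  }
  list(task = task, reference = reference, comparison = comparison,
       same = same, altered_pos = altered_pos, delta = delta,
       contour_reference = contour_of(reference),
       contour_comparison = contour_of(comparison),
       undecidable = !same && delta == 0)
}

#' @rdname make_pitch_trial
#'
#' @details
#' `make_rhythm_trial()` builds the timing trials.  `r1`: two tone pairs,
#' one with interonset interval (IOI) `ref_ioi`, the other lengthened by
#' `delta_pct` per cent.  `r2`: a 5-tone isochronous sequence versus one
#' whose IOI between tones 3 and 4 is lengthened by `delta_pct` per cent.
#' `r3`/`r4`: three 7-tone sequences (XAB), the reference strongly (`r3`) or
#' weakly (`r4`) metrical in beats of 4, with one of A/B distorted by
#' displacing one onset by `delta_pct` per cent of the beat.
#'
#' @param ref_ioi reference interonset interval in ms (drawn in 300--600 ms
#'   per trial in the original design; enforced for r1/r2).
#' @param delta_pct difficulty as a percentage (>= 0).
#' @export
make_rhythm_trial <- function(task, ref_ioi, delta_pct) {
  task <- match.arg(task, c("r1", "r2", "r3", "r4"))
  if (delta_pct < 0) stop("delta_pct must be >= 0")
  if (task %in% c("r1", "r2") && (ref_ioi < 300 || ref_ioi > 600))
    stop("ref_ioi must lie in [300, 600] ms for ", task)
  if (task == "r1") {
    target_ioi <- ref_ioi * (1 + delta_pct / 100)
    order <- sample(1:2)
    pairs <- list(c(0, ref_ioi), c(0, target_ioi))[order]
    list(task = "r1", onsets = pairs, target = which(order == 2),
         ref_ioi = ref_ioi, delta = delta_pct,
         undecidable = delta_pct == 0)
  } else if (task == "r2") {
    ref <- ref_ioi * (0:4)
    ext <- ref_ioi * delta_pct / 100
    target <- ref + c(0, 0, 0, ext, ext)     # gap 3->4 lengthened
    order <- sample(1:2)
    seqs <- list(ref, target)[order]
    list(task = "r2", onsets = seqs, target = which(order == 2),
         ref_ioi = ref_ioi, delta = delta_pct,
         undecidable = delta_pct == 0)
  } else {
    beat <- if (ref_ioi >= 300 && ref_ioi <= 600) ref_ioi else 500
    unit <- beat / 4                              # sixteenth grid, 4 beats
    slots <- if (task == "r3") c(0, 2, 4, 8, 10, 12, 14)
             else c(0, 2, 5, 7, 9, 11, 14)        # syncopated: beats absent
    ref <- slots * unit
    j <- sample(2:6, 1)
    gap_lo <- ref[j] - ref[j - 1]
    gap_hi <- ref[j + 1] - ref[j]
    shift <- beat * delta_pct / 100
    dir <- sample(c(-1, 1), 1)
    # keep onsets strictly increasing: flip or shrink if needed
    if (dir > 0 && shift >= gap_hi) dir <- -1
    if (dir < 0 && shift >= gap_lo) shift <- min(shift, 0.9 * gap_lo)
    distorted <- ref
    distorted[j] <- ref[j] + dir * shift
    odd <- sample(2:3, 1)                         # X is position 1
    seqs <- list(ref, ref, ref)
    seqs[[odd]] <- distorted
    list(task = task, onsets = seqs, odd = odd, displaced = j,
         ref_ioi = beat, delta = delta_pct, undecidable = delta_pct == 0)
  }
}
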