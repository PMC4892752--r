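#' Tone, sequence and modulation specifications
#'
#' Lightweight parametric descriptions of the stimuli used by the battery.
#' All analysis in the package operates on these descriptors; waveform
#' synthesis ([synth_pure_tone()], [synth_modulated()]) is provided for
#' inspection and WAV export only.
#'
#' @param frequency tone frequency in Hz (> 0).
#' @param duration duration in ms (> 0).
#' @param level level in dB re full scale (<= 0).
#' @param ramp raised-cosine onset/offset ramp in ms; `2 * ramp` must not
#'   exceed `duration`.
#' @return A `tone_spec` list.
#' @examples
#' tone_spec(500, 100)
#' @export
tone_spec <- function(frequency, duration, level = -6, ramp = 10) {
  stopifnot(frequency > 0, duration > 0, level <= 0, ramp >= 0)
  if (2 * ramp > duration)
    stop("ramps (2 x ", ramp, " ms) exceed tone duration (", duration, " ms)")
  structure(list(frequency = frequency, duration = duration, level = level,
                 ramp = ramp), class = "tone_spec")
}

#' @rdname tone_spec
#' @param tones list of `tone_spec` objects.
#' @param onsets onset times in ms from sequence start, strictly increasing.
#' @export
sequence_spec <- function(tones, onsets) {
  stopifnot(length(tones) == length(onsets))
  if (any(diff(onsets) <= 0)) stop("onsets must be strictly increasing")
  durs <- vapply(tones, `[[`, 0, "duration")
  overlap <- any(diff(onsets) < durs[-length(durs)])
  structure(list(tones = tones, onsets = onsets, overlapping = overlap),
            class = "sequence_spec")
}

#' @rdname tone_spec
#' @param carrier carrier frequency, Hz.
#' @param fm_rate FM rate in Hz (2 or 40 for the FM tasks).
#' @param fm_depth FM depth as a fraction of the carrier, in `[0, 1]`.
#' @param ripple_density spectral ripple density, cycles/octave.
#' @param ripple_rate ripple drift rate, Hz.
#' @export
modulation_spec <- function(carrier = 500, fm_rate = 2, fm_depth = 0,
                            ripple_density = 1, ripple_rate = 4,
                            duration = 1000) {
  stopifnot(carrier > 0, fm_depth >= 0, fm_depth <= 1, duration > 0,
            ripple_density >= 0, ripple_rate >= 0)
  structure(list(carrier = carrier, fm_rate = fm_rate, fm_depth = fm_depth,
                 ripple_density = ripple_density, ripple_rate = ripple_rate,
                 duration = duration), class = "modulation_spec")
}

raised_cosine_envelope <- function(n, ramp_samples) {
  env <- rep(1, n)
  if (ramp_samples > 0) {
    r <- 0.5 * (1 - cos(pi * seq_len(ramp_samples) / ramp_samples))
    env[seq_len(ramp_samples)] <- r
    env[n + 1 - seq_len(ramp_samples)] <- r
  }
  env
}

#' Synthesize a pure tone
#'
#' @param spec a [tone_spec()].
#' @param sample_rate sampling rate in Hz; must be at least four times the
#'   tone frequency (comfortably above Nyquist).
#' @return Numeric waveform with `round(duration/1000 * sample_rate)`
#'   samples, peak amplitude `10^(level/20) <= 1`.
#' @examples
#' w <- synth_pure_tone(tone_spec(500, 100), 44100)
#' length(w)  # 4410
#' @export
synth_pure_tone <- function(spec, sample_rate = 44100) {
  stopifnot(inherits(spec, "tone_spec"))
  if (sample_rate < 4 * spec$frequency)
    stop("sample_rate ", sample_rate, " Hz too low for a ", spec$frequency,
         " Hz tone (aliasing); need >= 4 x frequency")
  n <- round(spec$duration / 1000 * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  amp <- 10^(spec$level / 20)
  y <- amp * sin(2 * pi * spec$frequency * t)
  y * raised_cosine_envelope(n, round(spec$ramp / 1000 * sample_rate))
}

#' Render a tone sequence to a waveform
#'
#' Mixes the tones of a [sequence_spec()] at their onsets.  The result is
#' renormalized only if overlapping tones push the peak above 1.
#'
#' @param seq a `sequence_spec`.
#' @inheritParams synth_pure_tone
#' @export
synth_sequence <- function(seq, sample_rate = 44100) {
  stopifnot(inherits(seq, "sequence_spec"))
  durs <- vapply(seq$tones, `[[`, 0, "duration")
  total_ms <- max(seq$onsets + durs)
  out <- numeric(ceiling(total_ms / 1000 * sample_rate))
  for (i in seq_along(seq$tones)) {
    w <- synth_pure_tone(seq$tones[[i]], sample_rate)
    at <- round(seq$onsets[i] / 1000 * sample_rate)
    idx <- at + seq_along(w)
    out[idx] <- out[idx] + w
  }
  pk <- max(abs(out))
  if (pk > 1) out <- out / pk
  out
}

#' Synthesize modulated (timbre-task) stimuli
#'
#' For the FM detection tasks (`m1`, `m2`) the instantaneous frequency is
#' `carrier * (1 + depth * sin(2 pi rate t))`, i.e. sinusoidal FM about a
#' 500 Hz carrier at 2 or 40 Hz; zero depth reproduces the unmodulated
#' carrier exactly.  For the dynamic-modulation tasks (`m3`, `m4`) the
#' stimulus is a ripple: a sum of log-spaced carriers (250--4000 Hz, fixed
#' deterministic phases) whose spectral envelope drifts over log-frequency
#' with the requested density (cycles/octave) and rate (Hz); depth 0 again
#' reproduces the flat-envelope reference.
#'
#' @param task one of `"m1"`, `"m2"`, `"m3"`, `"m4"`.
#' @param spec a [modulation_spec()].
#' @inheritParams synth_pure_tone
#' @param n_carriers number of ripple carriers (m3/m4).
#' @return Numeric waveform, peak-bounded in `[-1, 1]`.
#' @export
synth_modulated <- function(task, spec, sample_rate = 16000,
                            n_carriers = 40) {
  stopifnot(inherits(spec, "modulation_spec"))
  task <- match.arg(task, c("m1", "m2", "m3", "m4"))
  n <- round(spec$duration / 1000 * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  if (task %in% c("m1", "m2")) {
    want <- if (task == "m1") 2 else 40
    if (!isTRUE(all.equal(spec$fm_rate, want)))
      stop("task ", task, " requires fm_rate = ", want, " Hz")
    if (sample_rate < 4 * spec$carrier * (1 + spec$fm_depth))
      stop("sample_rate too low for modulated carrier (aliasing)")
    f <- spec$carrier
    phase <- 2 * pi * f * t +
      2 * pi * f * spec$fm_depth * (1 - cos(2 * pi * spec$fm_rate * t)) /
        (2 * pi * spec$fm_rate)
    y <- 0.9 * sin(phase)
  } else {
    f_lo <- 250
    f_hi <- 4000
    if (sample_rate < 4 * f_hi)
      stop("sample_rate too low for ripple carriers (aliasing)")
    oct <- seq(0, log2(f_hi / f_lo), length.out = n_carriers)
    freqs <- f_lo * 2^oct
    # fixed quasi-random phases keep the zero-depth reference deterministic
    phases <- 2 * pi * ((seq_len(n_carriers) * 0.6180339887) %% 1)
    y <- numeric(n)
    for (k in seq_len(n_carriers)) {
      env <- 1 + spec$fm_depth *
        sin(2 * pi * (spec$ripple_rate * t + spec$ripple_density * oct[k]))
      y <- y + env * sin(2 * pi * freqs[k] * t + phases[k])
    }
    y <- 0.9 * y / (n_carriers * (1 + spec$fm_depth)) * sqrt(n_carriers)
    pk <- max(abs(y))
    if (pk > 1) y <- y / pk
  }
  y * raised_cosine_envelope(n, round(10 / 1000 * sample_rate))
}

#' Write a waveform as a 16-bit PCM RIFF/WAVE file
#'
#' Minimal mono WAV export for inspecting battery stimuli.
#'
#' @param waveform numeric vector in `[-1, 1]`.
#' @param path output file.
#' @param sample_rate sampling rate in Hz.
#' @export
write_wav <- function(waveform, path, sample_rate = 44100) {
  stopifnot(max(abs(waveform)) <= 1 + 1e-9)
  pcm <- as.integer(round(pmax(-1, pmin(1, waveform)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, 1L), con, size = 2, endian = "little")         # PCM, mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(c(2L, 16L), con, size = 2, endian = "little")        # align, bits
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
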