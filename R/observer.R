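#' Virtual psychometric-function observer
#'
#' A simulated responder standing in for a human subject.  The probability
#' of a correct response at stimulus difference `delta` (in the task's
#' difficulty units) is the standard high-threshold psychometric function
#'
#' \deqn{\psi(\delta) = \gamma + (1 - \gamma - \lambda)\,
#'   F(\log\delta;\ \log\alpha,\ \beta)}
#'
#' with `F` the logistic CDF on the log-difficulty axis, `alpha` the true
#' threshold (the level where `F = 0.5`), `beta` the (dimensionless) slope,
#' `gamma` the guess rate (0.5 for 2AFC, 1/3 for 3AFC) and `lambda` the
#' lapse rate.
#'
#' @param alpha true threshold, in task difficulty units (> 0).
#' @param beta logistic slope on the log-difficulty axis.
#' @param lapse lapse rate in `[0, 0.1]`.
#' @param guess guess rate (chance level of the paradigm).
#' @return A `virtual_observer` object.
#' @examples
#' obs <- virtual_observer(alpha = 10, beta = 8)
#' psychometric(obs, 10)  # 0.75 for 2AFC with no lapses
#' @export
virtual_observer <- function(alpha, beta = 8, lapse = 0.02, guess = 0.5) {
  stopifnot(alpha > 0, beta > 0, lapse >= 0, lapse <= 0.1,
            guess > 0, guess < 1)
  structure(list(alpha = alpha, beta = beta, lapse = lapse, guess = guess),
            class = "virtual_observer")
}

#' @rdname virtual_observer
#' @param observer a `virtual_observer`.
#' @param delta stimulus difference(s), >= 0.  At `delta = 0` the trial is
#'   undecidable and the response probability is the guess rate.
#' @return `psychometric()`: probability of a correct response.
#' @export
psychometric <- function(observer, delta) {
  stopifnot(inherits(observer, "virtual_observer"), all(delta >= 0))
  F <- stats::plogis(observer$beta * (log(delta) - log(observer$alpha)))
  F[delta == 0] <- 0
  observer$guess + (1 - observer$guess - observer$lapse) * F
}

#' @rdname virtual_observer
#' @param p_correct target overall proportion correct.
#' @return `psychometric_target_level()`: the stimulus level at which
#'   `psi(delta) = p_correct` (e.g. the 70.7\%-correct point tracked by a
#'   two-down one-up staircase).
#' @export
psychometric_target_level <- function(observer, p_correct = sqrt(0.5)) {
  Fo <- (p_correct - observer$guess) / (1 - observer$guess - observer$lapse)
  if (Fo <= 0 || Fo >= 1)
    stop("target proportion correct unreachable for this observer")
  observer$alpha * exp(stats::qlogis(Fo) / observer$beta)
}

#' @rdname virtual_observer
#' @return `observer_respond()`: logical, whether the simulated response was
#'   correct.  Uses the current RNG stream.
#' @export
observer_respond <- function(observer, delta) {
  stopifnot(length(delta) == 1L, delta >= 0)
  stats::runif(1) < psychometric(observer, delta)
}

#' @export
print.virtual_observer <- function(x, ...) {
  cat(sprintf(
    "virtual observer: alpha = %g, beta = %g, lapse = %g, guess = %g\n",
    x$alpha, x$beta, x$lapse, x$guess))
  invisible(x)
}
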