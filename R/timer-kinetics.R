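# Two-state maturation model per channel:
#   du/dt = beta - (m + kDeg) u        (unmatured, dark)
#   df/dt = m u - kDeg f               (matured, fluorescent)
# Steady state: f* = beta/kDeg * m/(m + kDeg).

.ssFraction <- function(m, kDeg) m / (m + kDeg)

# mCherry/sfGFP steady-state ratio as a function of the degradation rate;
# vectorised over kDeg.
.ratioFromKdeg <- function(kDeg, mG, mC) {
  .ssFraction(mC, kDeg) / .ssFraction(mG, kDeg)
}

#' Steady-state channel intensities of a timer fusion
#'
#' Closed-form steady state of the two-state maturation model: per channel
#' \code{I = bg + beta/kDeg * m/(m + kDeg)}. Requires \code{kDeg > 0};
#' with no degradation the protein pool grows without bound and no steady
#' state exists.
#'
#' @param p a [TimerParams-class] object with \code{kDeg > 0}
#' @return named numeric vector \code{c(sfGFP = , mCherry = )} (a.u.)
#' @examples
#' steadyStateIntensities(TimerParams(beta = 100, kDeg = log(2) / 60))
#' @export
steadyStateIntensities <- function(p) {
  stopifnot(is(p, "TimerParams"))
  validObject(p)
  if (p@kDeg <= 0)
    stop("no steady state: kDeg must be > 0")
  total <- p@beta / p@kDeg
  c(sfGFP  = p@bgG + total * .ssFraction(p@mG, p@kDeg),
    mCherry = p@bgC + total * .ssFraction(p@mC, p@kDeg))
}

#' Steady-state mCherry/sfGFP intensity ratio
#'
#' Ratio of the background-free steady-state intensities,
#' \code{[mC/(mC + kDeg)] / [mG/(mG + kDeg)]}. In the timer regime
#' (\code{mC < mG}) it is strictly decreasing in the degradation rate and
#' bounded in \code{(mC/mG, 1]}: a lower ratio means faster turnover.
#' Synthesis rate and backgrounds cancel.
#'
#' @param p a [TimerParams-class] object (\code{kDeg >= 0} allowed;
#'   \code{kDeg = 0} gives ratio 1, both fluorophores fully matured)
#' @return dimensionless ratio in \code{(mC/mG, 1]}
#' @export
steadyStateRatio <- function(p) {
  stopifnot(is(p, "TimerParams"))
  validObject(p)
  unname(.ratioFromKdeg(p@kDeg, p@mG, p@mC))
}

#' Invert the steady-state ratio to a degradation rate
#'
#' The ratio-vs-kDeg relation is a Moebius function with the analytic
#' inverse \code{kDeg = mC mG (1 - r) / (r mG - mC)}, unique on the
#' attainable open band \code{(mC/mG, 1)}.
#'
#' @param ratio observed mCherry/sfGFP ratio, strictly inside
#'   \code{(mC/mG, 1)}
#' @param mG,mC maturation rates (1/min) with \code{mC < mG}
#' @return the unique degradation rate (1/min) reproducing \code{ratio}
#' @examples
#' p <- TimerParams(kDeg = 0.02)
#' inferKdegFromRatio(steadyStateRatio(p), p@mG, p@mC)  # 0.02
#' @export
inferKdegFromRatio <- function(ratio, mG = log(2) / 6, mC = log(2) / 40) {
  if (!(mC < mG)) stop("timer regime requires mC < mG")
  lo <- mC / mG
  bad <- !is.finite(ratio) | ratio <= lo | ratio >= 1
  if (any(bad))
    stop(sprintf(
      "ratio outside attainable open interval (%.6g, 1); got %s",
      lo, paste(format(ratio[bad]), collapse = ", ")))
  mC * mG * (1 - ratio) / (ratio * mG - mC)
}

#' Numerically integrate the timer's maturation kinetics
#'
#' Solves the four-dimensional linear ODE (unmatured and matured pools per
#' channel, both degraded at \code{kDeg}) from an empty cell and reports
#' the fluorescent-pool intensities plus background on a time grid. This is
#' the validation oracle for [steadyStateIntensities()]: for
#' \code{kDeg > 0} the trajectory converges to the closed form.
#'
#' @param p a [TimerParams-class] object
#' @param times nonnegative, strictly increasing time grid (minutes)
#' @return data.frame with columns \code{time}, \code{sfGFP},
#'   \code{mCherry} (intensities, a.u.)
#' @export
simulateTrajectory <- function(p, times) {
  stopifnot(is(p, "TimerParams"))
  validObject(p)
  if (any(!is.finite(times)) || any(times < 0) || any(diff(times) <= 0))
    stop("times must be finite, nonnegative and strictly increasing")
  tgrid <- if (times[1] > 0) c(0, times) else times
  deriv <- function(t, y, parms) {
    with(as.list(parms), list(c(
      uG = beta - (mG + kDeg) * y[1],
      fG = mG * y[1] - kDeg * y[2],
      uC = beta - (mC + kDeg) * y[3],
      fC = mC * y[3] - kDeg * y[4])))
  }
  out <- deSolve::ode(
    y = c(uG = 0, fG = 0, uC = 0, fC = 0), times = tgrid, func = deriv,
    parms = c(beta = p@beta, mG = p@mG, mC = p@mC, kDeg = p@kDeg),
    rtol = 1e-10, atol = 1e-10)
  out <- as.data.frame(out)
  out <- out[out$time %in% times, , drop = FALSE]
  data.frame(time = out$time,
             sfGFP = out$fG + p@bgG,
             mCherry = out$fC + p@bgC,
             row.names = NULL)
}
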