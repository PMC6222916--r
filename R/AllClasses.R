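#' @import methods
NULL

#' Kinetic parameters of a tandem fluorescent timer fusion
#'
#' A tFT fusion carries a fast-maturing sfGFP and a slow-maturing mCherry.
#' Each channel is modelled as a two-state birth-death process: unmatured
#' protein is synthesised at rate \code{beta}, matures at the channel's
#' maturation rate, and both forms are degraded at \code{kDeg}. At steady
#' state the mCherry/sfGFP intensity ratio is a monotone readout of the
#' degradation rate: faster turnover leaves less time for mCherry to mature.
#'
#' @slot beta synthesis rate (molecules per min), >= 0
#' @slot kDeg first-order degradation rate (1/min), >= 0
#' @slot mG sfGFP (fast) maturation rate (1/min), > 0
#' @slot mC mCherry (slow) maturation rate (1/min), > 0
#' @slot bgG,bgC additive background fluorescence per channel (a.u.), >= 0
#'
#' @section Timer regime:
#' The timer only reports turnover when mCherry matures more slowly than
#' sfGFP (\code{mC < mG}, the default regime). Equal rates are admitted
#' (the ratio then degenerates to 1 for every degradation rate) but the
#' generator and the ratio inversion require the timer ordering.
#'
#' @seealso [TimerParams()], [steadyStateIntensities()], [steadyStateRatio()]
#' @name TimerParams-class
#' @aliases TimerParams-class
#' @exportClass TimerParams
setClass("TimerParams",
  representation(beta = "numeric", kDeg = "numeric", mG = "numeric",
                 mC = "numeric", bgG = "numeric", bgC = "numeric"),
  prototype(beta = 100, kDeg = log(2) / 30, mG = log(2) / 6,
            mC = log(2) / 40, bgG = 0, bgC = 0))

setValidity("TimerParams", function(object) {
  v <- c(beta = object@beta, kDeg = object@kDeg, mG = object@mG,
         mC = object@mC, bgG = object@bgG, bgC = object@bgC)
  if (any(lengths(list(object@beta, object@kDeg, object@mG, object@mC,
                       object@bgG, object@bgC)) != 1L))
    return("all slots must be scalar")
  if (any(!is.finite(v))) return("all parameters must be finite")
  if (object@beta < 0) return("beta must be >= 0")
  if (object@kDeg < 0) return("kDeg must be >= 0")
  if (object@mG <= 0 || object@mC <= 0)
    return("maturation rates must be > 0")
  if (object@bgG < 0 || object@bgC < 0)
    return("backgrounds must be >= 0")
  TRUE
})

#' Construct timer kinetic parameters
#'
#' Defaults encode maturation half-times of 6 min (sfGFP) and 40 min
#' (mCherry) and a tagged-protein half-life of 30 min; intensity units are
#' arbitrary and only ratios and log-differences are interpreted
#' downstream.
#'
#' @param beta synthesis rate (molecules/min)
#' @param kDeg degradation rate (1/min)
#' @param mG sfGFP maturation rate (1/min)
#' @param mC mCherry maturation rate (1/min)
#' @param bgG,bgC additive per-channel background fluorescence (a.u.)
#' @return a [TimerParams-class] object
#' @examples
#' p <- TimerParams(beta = 100, kDeg = log(2) / 60)
#' steadyStateRatio(p)
#' @export
TimerParams <- function(beta = 100, kDeg = log(2) / 30, mG = log(2) / 6,
                        mC = log(2) / 40, bgG = 0, bgC = 0) {
  new("TimerParams", beta = beta, kDeg = kDeg, mG = mG, mC = mC,
      bgG = bgG, bgC = bgC)
}

setMethod("show", "TimerParams", function(object) {
  cat("TimerParams\n")
  cat(sprintf("  synthesis beta: %.4g /min\n", object@beta))
  cat(sprintf("  degradation kDeg: %.4g /min (half-life %.3g min)\n",
              object@kDeg,
              if (object@kDeg > 0) log(2) / object@kDeg else Inf))
  cat(sprintf("  maturation mG (sfGFP): %.4g /min, mC (mCherry): %.4g /min\n",
              object@mG, object@mC))
  cat(sprintf("  background (G, C): %.4g, %.4g a.u.\n",
              object@bgG, object@bgC))
  invisible(NULL)
})

#' Measurement-noise model for the synthetic plate-reader screen
#'
#' Colony intensities are generated as
#' \code{size * steadyState * exp(eps) + autofluorescence} with
#' \code{eps ~ N(0, sigmaChannel^2)} independent per colony and channel.
#' The colony-size factor is lognormal with sdlog \code{sigmaSize} and is
#' shared by both channels of a colony, so it cancels from the
#' mCherry/sfGFP ratio. A fraction \code{failFraction} of sample colonies
#' are failed crosses: they carry autofluorescence only and a colony size
#' below the exclusion threshold.
#'
#' @slot sigmaChannel sdlog of the multiplicative per-channel noise
#' @slot sigmaSize sdlog of the shared colony-size factor
#' @slot autofluorG,autofluorC additive autofluorescence per channel (a.u.)
#' @slot failFraction fraction of sample colonies that are failed crosses
#' @name NoiseModel-class
#' @exportClass NoiseModel
setClass("NoiseModel",
  representation(sigmaChannel = "numeric", sigmaSize = "numeric",
                 autofluorG = "numeric", autofluorC = "numeric",
                 failFraction = "numeric"),
  prototype(sigmaChannel = 0.1, sigmaSize = 0.15, autofluorG = 40,
            autofluorC = 20, failFraction = 0.02))

setValidity("NoiseModel", function(object) {
  if (object@sigmaChannel < 0 || object@sigmaSize < 0)
    return("noise sigmas must be >= 0")
  if (object@autofluorG < 0 || object@autofluorC < 0)
    return("autofluorescence must be >= 0")
  if (object@failFraction < 0 || object@failFraction > 1)
    return("failFraction must be in [0, 1]")
  TRUE
})

#' @param sigmaChannel,sigmaSize,autofluorG,autofluorC,failFraction see slots
#' @return a [NoiseModel-class] object
#' @rdname NoiseModel-class
#' @export
NoiseModel <- function(sigmaChannel = 0.1, sigmaSize = 0.15,
                       autofluorG = 40, autofluorC = 20,
                       failFraction = 0.02) {
  new("NoiseModel", sigmaChannel = sigmaChannel, sigmaSize = sigmaSize,
      autofluorG = autofluorG, autofluorC = autofluorC,
      failFraction = failFraction)
}

setMethod("show", "NoiseModel", function(object) {
  cat("NoiseModel\n")
  cat(sprintf("  sigmaChannel %.3g, sigmaSize %.3g\n",
              object@sigmaChannel, object@sigmaSize))
  cat(sprintf("  autofluorescence (G, C): %.3g, %.3g a.u.\n",
              object@autofluorG, object@autofluorC))
  cat(sprintf("  failed-cross fraction: %.3g\n", object@failFraction))
  invisible(NULL)
})

#' Empirical-Bayes variance prior for the moderated t-test
#'
#' A scaled inverse-chi-square prior on the per-protein replicate variance,
#' with prior degrees of freedom \code{df0} (possibly infinite) and prior
#' variance \code{s02}. \code{df0 = 0} encodes "no moderation" (ordinary
#' pooled t), the fallback when too few variances are available for the fit.
#'
#' @slot df0 prior degrees of freedom (>= 0, may be Inf)
#' @slot s02 prior variance (> 0, NA when df0 = 0)
#' @seealso [fitVariancePrior()], [moderatedT()]
#' @name VariancePrior-class
#' @exportClass VariancePrior
setClass("VariancePrior",
  representation(df0 = "numeric", s02 = "numeric"),
  prototype(df0 = 0, s02 = NA_real_))

setValidity("VariancePrior", function(object) {
  if (length(object@df0) != 1L || length(object@s02) != 1L)
    return("df0 and s02 must be scalar")
  if (is.na(object@df0) || object@df0 < 0)
    return("df0 must be >= 0 (possibly Inf)")
  if (object@df0 > 0 && (is.na(object@s02) || object@s02 <= 0))
    return("s02 must be > 0 when df0 > 0")
  TRUE
})

#' @param df0,s02 see slots
#' @return a [VariancePrior-class] object
#' @rdname VariancePrior-class
#' @export
VariancePrior <- function(df0, s02 = NA_real_) {
  new("VariancePrior", df0 = as.numeric(df0), s02 = as.numeric(s02))
}

setMethod("show", "VariancePrior", function(object) {
  cat(sprintf("VariancePrior: df0 = %s, s02 = %s\n",
              format(object@df0), format(object@s02)))
  invisible(NULL)
})

#' Hit-calling thresholds
#'
#' The screen's volcano subsetting uses strict inequalities: a protein is a
#' hit in a mutant when p-value < \code{pMax} and net delta-score (the
#' absolute mCherry/sfGFP delta-score) > \code{netDeltaMin}; the strong tier
#' additionally requires net delta-score > \code{strongDeltaMin}.
#'
#' @slot pMax maximum raw p-value (default 0.1)
#' @slot netDeltaMin minimum net delta-score (default 0.2)
#' @slot strongDeltaMin minimum net delta-score for the strong tier (0.5)
#' @name HitThresholds-class
#' @exportClass HitThresholds
setClass("HitThresholds",
  representation(pMax = "numeric", netDeltaMin = "numeric",
                 strongDeltaMin = "numeric"),
  prototype(pMax = 0.1, netDeltaMin = 0.2, strongDeltaMin = 0.5))

setValidity("HitThresholds", function(object) {
  if (object@pMax <= 0 || object@pMax > 1)
    return("pMax must be in (0, 1]")
  if (object@netDeltaMin < 0 || object@netDeltaMin > object@strongDeltaMin)
    return("need 0 <= netDeltaMin <= strongDeltaMin")
  TRUE
})

#' @param pMax,netDeltaMin,strongDeltaMin see slots
#' @return a [HitThresholds-class] object
#' @rdname HitThresholds-class
#' @export
HitThresholds <- function(pMax = 0.1, netDeltaMin = 0.2,
                          strongDeltaMin = 0.5) {
  new("HitThresholds", pMax = pMax, netDeltaMin = netDeltaMin,
      strongDeltaMin = strongDeltaMin)
}

setMethod("show", "HitThresholds", function(object) {
  cat(sprintf(
    "HitThresholds: p < %g, net delta > %g (strong tier > %g)\n",
    object@pMax, object@netDeltaMin, object@strongDeltaMin))
  invisible(NULL)
})

#' A complete synthetic tFT screen with ground truth
#'
#' Container returned by [simulateScreen()]: the plate layout, the simulated
#' colony readings, the per-strain truth table (injected stability and
#' abundance shifts together with the realized kinetic rates), and the
#' per-colony truth flags (failed crosses).
#'
#' @slot layout plate layout data.frame (see [readPlateLayout()])
#' @slot readings colony readings data.frame (see [readColonyReadings()])
#' @slot strains per (protein, genotype) truth: injected shifts + realized
#'   rates
#' @slot colonies per-colony truth: strain, role, failed-cross flag
#' @name TFTScreen-class
#' @exportClass TFTScreen
setClass("TFTScreen",
  representation(layout = "data.frame", readings = "data.frame",
                 strains = "data.frame", colonies = "data.frame"))

setValidity("TFTScreen", function(object) {
  chk <- validateLayout(object@layout)
  if (!isTRUE(chk)) return(chk)
  chk <- validateReadings(object@readings)
  if (!isTRUE(chk)) return(chk)
  if (nrow(object@readings) != nrow(object@layout))
    return("readings and layout must describe the same positions")
  TRUE
})

setMethod("show", "TFTScreen", function(object) {
  lay <- object@layout
  cat("TFTScreen\n")
  cat(sprintf("  %d plates, %d positions (%d sample, %d control, %d reference)\n",
              length(unique(lay$plate_id)), nrow(lay),
              sum(lay$role == "sample"), sum(lay$role == "negative_control"),
              sum(lay$role == "reference")))
  cat(sprintf("  %d proteins x %d genotypes; %d failed-cross colonies\n",
              length(unique(object$strains$protein_id)),
              length(unique(object$strains$genotype)),
              sum(object@colonies$failed)))
  invisible(NULL)
})

#' @export
setMethod("$", "TFTScreen", function(x, name) slot(x, name))

#' Accessors for TFTScreen components
#'
#' @param x a [TFTScreen-class] object
#' @return the corresponding data.frame
#' @name screen-accessors
#' @export
screenLayout <- function(x) x@layout

#' @rdname screen-accessors
#' @export
screenReadings <- function(x) x@readings

#' @rdname screen-accessors
#' @export
screenTruth <- function(x) x@strains

#' @rdname screen-accessors
#' @export
screenColonyTruth <- function(x) x@colonies
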