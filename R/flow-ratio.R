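# Flow-cytometry readout of the timer: per independent repeat the
# population mCherry/sfGFP ratio, then the WT/mutant ratio-of-ratios.
# Values > 1 indicate destabilization in the mutant, < 1 stabilization.

#' Simulate per-cell flow-cytometry intensities for one strain
#'
#' Cells draw a common lognormal expression factor (shared by both
#' channels, so it cancels from population ratios) plus independent
#' per-channel lognormal noise around the timer's closed-form steady
#' state; each repeat additionally gets its own per-channel lognormal
#' gain factor, the source of the between-repeat variance the t-test
#' uses.
#'
#' @param p a [TimerParams-class]
#' @param strainId,genotype identifiers stored in the output
#' @param nCells cells per repeat (default 20000)
#' @param nRepeats independent measurements (default 3)
#' @param cellSdLog sdlog of the shared per-cell expression factor
#' @param channelSdLog sdlog of the per-cell, per-channel noise
#' @param repeatSdLog sdlog of the per-repeat, per-channel gain
#' @param seed RNG seed
#' @return per-cell data.frame: strain_id, genotype, replicate, mCherry,
#'   sfGFP
#' @export
simulateFlowSample <- function(p, strainId = "strain", genotype = "WT",
                               nCells = 20000, nRepeats = 3,
                               cellSdLog = 0.35, channelSdLog = 0.15,
                               repeatSdLog = 0.03, seed = 1) {
  stopifnot(is(p, "TimerParams"))
  validObject(p)
  ss <- steadyStateIntensities(p)
  set.seed(seed)
  n <- nCells * nRepeats
  expr <- stats::rlnorm(n, 0, cellSdLog)
  gainG <- rep(stats::rlnorm(nRepeats, 0, repeatSdLog), each = nCells)
  gainC <- rep(stats::rlnorm(nRepeats, 0, repeatSdLog), each = nCells)
  data.frame(
    strain_id = strainId, genotype = genotype,
    replicate = rep(seq_len(nRepeats), each = nCells),
    mCherry = ss[["mCherry"]] * expr * gainC *
      stats::rlnorm(n, 0, channelSdLog),
    sfGFP = ss[["sfGFP"]] * expr * gainG *
      stats::rlnorm(n, 0, channelSdLog),
    stringsAsFactors = FALSE)
}

#' Per-repeat population mCherry/sfGFP ratios
#'
#' Per repeat the population ratio is \code{mean(mCherry)/mean(sfGFP)}
#' over cells passing the positivity filter (both channels > 0); the
#' mean-of-per-cell-ratios variant is offered as an alternative but is
#' sensitive to dim cells.
#'
#' @param cells per-cell data.frame (strain_id, genotype, replicate,
#'   mCherry, sfGFP), one strain
#' @param method \code{"mean_of_means"} (default) or
#'   \code{"mean_of_cell_ratios"}
#' @param minCells minimum cells per repeat after filtering (default 100)
#' @return named numeric vector of per-repeat ratios (names = replicate)
#' @export
sampleRatio <- function(cells, method = c("mean_of_means",
                                          "mean_of_cell_ratios"),
                        minCells = 100L) {
  method <- match.arg(method)
  if (length(unique(cells$strain_id)) > 1L)
    stop("sampleRatio expects cells of a single strain")
  keep <- cells$mCherry > 0 & cells$sfGFP > 0
  cells <- cells[keep, , drop = FALSE]
  counts <- table(cells$replicate)
  if (any(counts < minCells))
    stop(sprintf("fewer than %d positive cells in repeat(s): %s", minCells,
                 paste(names(counts)[counts < minCells], collapse = ", ")))
  reps <- split(cells, cells$replicate)
  vapply(reps, function(r) {
    if (method == "mean_of_means") {
      mg <- mean(r$sfGFP)
      if (mg == 0) stop("zero mean sfGFP in a repeat")
      mean(r$mCherry) / mg
    } else {
      mean(r$mCherry / r$sfGFP)
    }
  }, numeric(1))
}

#' WT/mutant ratio-of-ratios with a Student's t-test
#'
#' Repeats are paired by acquisition index: the reported statistic is the
#' mean +/- SD of the per-repeat \code{WT/mutant} ratios. The p-value
#' comes from an unpaired two-sided two-sample Student's t-test comparing
#' the WT and mutant per-repeat ratios under equal variances. Values > 1
#' indicate destabilization in the mutant, < 1 stabilization.
#'
#' @param wt,mut per-repeat ratios from [sampleRatio()] (equal length)
#' @return list: ratio_wt_over_mut, sd, per_repeat (the paired ratios),
#'   t, df, p_value (NA with < 2 repeats)
#' @export
ratioOfRatios <- function(wt, mut) {
  if (length(wt) != length(mut))
    stop("equal repeat counts required (repeats are paired by index)")
  if (any(c(wt, mut) <= 0)) stop("ratios must be > 0")
  paired <- wt / mut
  res <- list(ratio_wt_over_mut = mean(paired),
              sd = stats::sd(paired), per_repeat = paired)
  if (length(wt) < 2L) {
    res$t <- NA_real_; res$df <- NA_real_; res$p_value <- NA_real_
    return(res)
  }
  if (stats::var(wt) + stats::var(mut) == 0) {
    res$t <- 0; res$df <- 2 * (length(wt) - 1L); res$p_value <- 1
    return(res)
  }
  tt <- stats::t.test(wt, mut, var.equal = TRUE)
  res$t <- unname(tt$statistic)
  res$df <- unname(tt$parameter)
  res$p_value <- tt$p.value
  res
}
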