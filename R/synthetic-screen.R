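# Plate geometry of the 1536-colony format and the block design used by the
# generator: 3 adjacent technical-replicate sample colonies followed by 3
# adjacent untagged negative-control colonies (one 6-column block per
# protein x genotype), 8 blocks per row; row 1 of every plate holds the
# reference strain set.

.PLATE_FORMATS <- list(`1536` = c(rows = 32L, cols = 48L))
.BLOCK_W <- 6L

#' The pmt deletion genotypes screened against wild type
#'
#' @return character vector of the three deletion genotype names
#'   (pmt1/pmt2/pmt4 with the Unicode delta suffix)
#' @export
pmtMutants <- function() c("pmt1\u0394", "pmt2\u0394", "pmt4\u0394")

#' Build a strain truth table with injected stability/abundance shifts
#'
#' For every protein x genotype the generator realizes the injected shifts
#' exactly through the closed-form steady state: the mutant degradation
#' rate is the analytic inverse of \code{ratio_WT * exp(-stabilityShift)}
#' (so the downstream WT-minus-mutant delta-score of the mCherry/sfGFP
#' log-ratio equals \code{stabilityShift}; negative values = stabilized),
#' and the mutant synthesis rate is chosen so the log sfGFP steady state
#' moves by exactly \code{abundanceShift} (mutant minus WT; positive =
#' more abundant). WT rows always have both shifts 0.
#'
#' @param nProteins number of tagged proteins
#' @param mutants mutant genotype names (WT is always added)
#' @param stabilityShift injected stability shifts: scalar, vector of
#'   length \code{nProteins} (recycled across mutants), or
#'   \code{nProteins x length(mutants)} matrix
#' @param abundanceShift injected log-abundance shifts, same shapes
#' @param baseParams [TimerParams-class] of the wild-type fusions
#' @param betaSdLog per-protein lognormal spread of the synthesis rate
#'   (expression levels vary across proteins; 0 for identical strains)
#' @param seed RNG seed for the synthesis-rate draws
#' @return data.frame with one row per protein x genotype: protein_id,
#'   genotype, beta, k_deg, m_g, m_c, stability_shift, abundance_shift
#' @export
strainSpecs <- function(nProteins, mutants = pmtMutants(),
                        stabilityShift = 0, abundanceShift = 0,
                        baseParams = TimerParams(), betaSdLog = 0.3,
                        seed = 1) {
  stopifnot(nProteins >= 1)
  validObject(baseParams)
  expand <- function(x, what) {
    if (is.matrix(x)) {
      if (!all(dim(x) == c(nProteins, length(mutants))))
        stop(sprintf("%s matrix must be nProteins x nMutants", what))
      x
    } else {
      matrix(rep_len(x, nProteins), nProteins, length(mutants))
    }
  }
  stab <- expand(stabilityShift, "stabilityShift")
  abun <- expand(abundanceShift, "abundanceShift")

  mG <- baseParams@mG; mC <- baseParams@mC
  kWT <- baseParams@kDeg
  rWT <- .ratioFromKdeg(kWT, mG, mC)
  # attainable stability shifts given the WT operating point
  loShift <- log(rWT)            # ratio -> 1 as kDeg -> 0
  hiShift <- log(rWT / (mC / mG))
  bad <- stab <= loShift | stab >= hiShift
  if (any(bad))
    stop(sprintf(
      "stability shifts must lie in the attainable open interval (%.4g, %.4g) for the WT operating point",
      loShift, hiShift))

  ids <- sprintf("P%04d", seq_len(nProteins))
  set.seed(seed)
  betaWT <- baseParams@beta * exp(stats::rnorm(nProteins, 0, betaSdLog))

  gfpGain <- function(k) (1 / k) * .ssFraction(mG, k)   # I_g / beta
  rows <- vector("list", (length(mutants) + 1L))
  rows[[1L]] <- data.frame(
    protein_id = ids, genotype = "WT", beta = betaWT, k_deg = kWT,
    m_g = mG, m_c = mC, stability_shift = 0, abundance_shift = 0,
    stringsAsFactors = FALSE)
  for (j in seq_along(mutants)) {
    rMut <- rWT * exp(-stab[, j])
    kMut <- inferKdegFromRatio(rMut, mG, mC)
    betaMut <- betaWT * exp(abun[, j]) * gfpGain(kWT) / gfpGain(kMut)
    rows[[j + 1L]] <- data.frame(
      protein_id = ids, genotype = mutants[j], beta = betaMut,
      k_deg = kMut, m_g = mG, m_c = mC,
      stability_shift = stab[, j], abundance_shift = abun[, j],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$protein_id, match(out$genotype, c("WT", mutants))), ,
      drop = FALSE]
}

#' Lay out a screen on 1536-colony plates
#'
#' Every protein x genotype occupies one 6-column block: 3 adjacent sample
#' colonies then 3 adjacent untagged negative-control colonies, all in one
#' row. All genotype blocks of a protein are placed consecutively, so a
#' protein's wild-type and mutant crosses always share a plate and every
#' per-plate normalization constant cancels from its delta-scores. Row 1 of
#' each plate is reserved for the reference strain set used by per-plate
#' normalization; unused positions are marked \code{empty}.
#'
#' @param nProteins number of tagged proteins
#' @param genotypes genotypes screened, WT first (one block each per
#'   protein)
#' @param plateFormat colony format; only 1536 (32 x 48) is supported
#' @param nReference reference colonies placed on every plate (>= 3)
#' @param seed RNG seed; proteins are assigned to blocks in a seeded
#'   random order
#' @param maxPlates error if the layout would need more plates than this
#' @return layout data.frame: plate_id, row, col, strain_id, protein_id,
#'   genotype, role (empty string marks absent fields)
#' @export
buildLayout <- function(nProteins, genotypes = c("WT", pmtMutants()),
                        plateFormat = 1536, nReference = 8, seed = 1,
                        maxPlates = Inf) {
  stopifnot(nProteins >= 1, nReference >= 3)
  fmt <- .PLATE_FORMATS[[as.character(plateFormat)]]
  if (is.null(fmt)) stop("unsupported plate format: ", plateFormat)
  nr <- fmt["rows"]; nc <- fmt["cols"]
  if (nReference > nc) stop("nReference exceeds plate width")
  blocksPerRow <- nc %/% .BLOCK_W
  blocksPerPlate <- (nr - 1L) * blocksPerRow      # row 1 is the reference row
  blocksPerProtein <- length(genotypes)
  proteinsPerPlate <- blocksPerPlate %/% blocksPerProtein
  if (proteinsPerPlate < 1L)
    stop("too many genotypes for one plate")
  nPlates <- ceiling(nProteins / proteinsPerPlate)
  if (nPlates > maxPlates)
    stop(sprintf("capacity exceeded: layout requires %d plates", nPlates))

  ids <- sprintf("P%04d", seq_len(nProteins))
  set.seed(seed)
  ids <- ids[sample.int(nProteins)]

  blocks <- data.frame(
    protein_id = rep(ids, each = blocksPerProtein),
    genotype = rep(genotypes, times = nProteins),
    stringsAsFactors = FALSE)
  b <- seq_len(nrow(blocks)) - 1L
  plateIdx <- (b %/% blocksPerProtein) %/% proteinsPerPlate
  slot <- b - plateIdx * proteinsPerPlate * blocksPerProtein
  blockRow <- 2L + slot %/% blocksPerRow
  blockCol0 <- (slot %% blocksPerRow) * .BLOCK_W

  sampleRows <- data.frame(
    plate_id = rep(sprintf("plate%02d", plateIdx + 1L), each = 3L),
    row = rep(blockRow, each = 3L),
    col = rep(blockCol0, each = 3L) + rep(1:3, nrow(blocks)),
    strain_id = rep(paste(blocks$protein_id, blocks$genotype, sep = "_"),
                    each = 3L),
    protein_id = rep(blocks$protein_id, each = 3L),
    genotype = rep(blocks$genotype, each = 3L),
    role = "sample", stringsAsFactors = FALSE)
  controlRows <- sampleRows
  controlRows$col <- controlRows$col + 3L
  controlRows$strain_id <- paste0("ctrl_", controlRows$strain_id)
  controlRows$role <- "negative_control"

  plates <- sprintf("plate%02d", seq_len(nPlates))
  refRows <- data.frame(
    plate_id = rep(plates, each = nReference),
    row = 1L,
    col = rep(seq_len(nReference), times = nPlates),
    strain_id = rep(sprintf("ref_%02d", seq_len(nReference)),
                    times = nPlates),
    protein_id = "", genotype = "WT", role = "reference",
    stringsAsFactors = FALSE)

  used <- rbind(sampleRows, controlRows, refRows)
  full <- expand.grid(plate_id = plates, row = seq_len(nr),
                      col = seq_len(nc), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$plate_id, d$row, d$col)
  emptyRows <- full[!(key(full) %in% key(used)), , drop = FALSE]
  if (nrow(emptyRows)) {
    emptyRows$strain_id <- ""
    emptyRows$protein_id <- ""
    emptyRows$genotype <- ""
    emptyRows$role <- "empty"
  }
  out <- rbind(used, emptyRows[names(used)])
  out <- out[order(out$plate_id, out$row, out$col), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate plate-reader readings for a layout
#'
#' Sample and reference colonies get
#' \code{size * steadyState * exp(eps) + autofluorescence} per channel with
#' \code{eps ~ N(0, sigmaChannel^2)} i.i.d. per colony and channel; the
#' lognormal colony-size factor is shared by both channels of a colony.
#' Negative-control, empty and failed-cross colonies carry autofluorescence
#' only; failed crosses additionally get a colony size far below the
#' exclusion threshold.
#'
#' @param layout layout data.frame from [buildLayout()]
#' @param specs strain truth table from [strainSpecs()]
#' @param noise a [NoiseModel-class] object
#' @param seed RNG seed; the same seed reproduces the readings exactly
#' @param refParams [TimerParams-class] of the reference strains
#' @return list with \code{readings} (plate_id, row, col, mCherry, sfGFP,
#'   colony_size) and \code{colonies} (per-colony truth incl. the
#'   failed-cross flag)
#' @export
simulateReadings <- function(layout, specs, noise = NoiseModel(), seed = 1,
                             refParams = TimerParams()) {
  chk <- validateLayout(layout)
  if (!isTRUE(chk)) stop(chk)
  validObject(noise)
  validObject(refParams)
  n <- nrow(layout)
  isSample <- layout$role == "sample"
  isRef <- layout$role == "reference"

  specKey <- paste(specs$protein_id, specs$genotype)
  idx <- match(paste(layout$protein_id, layout$genotype)[isSample], specKey)
  if (anyNA(idx)) {
    miss <- unique(paste(layout$protein_id, layout$genotype)[isSample][is.na(idx)])
    stop("layout sample positions without a strain spec: ",
         paste(miss, collapse = ", "))
  }

  set.seed(seed)
  failed <- logical(n)
  failed[isSample] <- stats::runif(sum(isSample)) < noise@failFraction
  sizeFactor <- stats::rlnorm(n, 0, noise@sigmaSize)
  sizeFactor[failed] <- stats::runif(sum(failed), 0.02, 0.15)
  sizeFactor[layout$role == "empty"] <- 0
  epsG <- stats::rnorm(n, 0, noise@sigmaChannel)
  epsC <- stats::rnorm(n, 0, noise@sigmaChannel)

  ssG <- ssC <- numeric(n)                 # background carriers only
  live <- isSample & !failed
  liveIdx <- idx[!failed[isSample]]
  sp <- specs[liveIdx, , drop = FALSE]
  totalLive <- sp$beta / sp$k_deg
  ssG[live] <- totalLive * .ssFraction(sp$m_g, sp$k_deg)
  ssC[live] <- totalLive * .ssFraction(sp$m_c, sp$k_deg)
  ssRef <- steadyStateIntensities(refParams)
  ssG[isRef] <- ssRef[["sfGFP"]] - refParams@bgG
  ssC[isRef] <- ssRef[["mCherry"]] - refParams@bgC

  readings <- data.frame(
    plate_id = layout$plate_id, row = layout$row, col = layout$col,
    mCherry = sizeFactor * ssC * exp(epsC) + noise@autofluorC * exp(epsC),
    sfGFP   = sizeFactor * ssG * exp(epsG) + noise@autofluorG * exp(epsG),
    colony_size = sizeFactor, stringsAsFactors = FALSE)
  colonies <- data.frame(
    plate_id = layout$plate_id, row = layout$row, col = layout$col,
    strain_id = layout$strain_id, role = layout$role, failed = failed,
    stringsAsFactors = FALSE)
  list(readings = readings, colonies = colonies)
}

#' Simulate a complete synthetic tFT screen
#'
#' Convenience wrapper chaining [strainSpecs()], [buildLayout()] and
#' [simulateReadings()] with seeds derived from one master seed.
#'
#' @inheritParams strainSpecs
#' @inheritParams buildLayout
#' @param noise a [NoiseModel-class]
#' @param seed master seed; layout, strain and reading seeds are derived
#'   from it
#' @return a [TFTScreen-class] object
#' @examples
#' scr <- simulateScreen(6, mutants = pmtMutants()[1], seed = 7)
#' scr
#' @export
simulateScreen <- function(nProteins, mutants = pmtMutants(),
                           stabilityShift = 0, abundanceShift = 0,
                           noise = NoiseModel(), baseParams = TimerParams(),
                           betaSdLog = 0.3, nReference = 8, seed = 1) {
  specs <- strainSpecs(nProteins, mutants, stabilityShift, abundanceShift,
                       baseParams, betaSdLog, seed = seed)
  layout <- buildLayout(nProteins, genotypes = c("WT", mutants),
                        nReference = nReference, seed = seed + 1L)
  sim <- simulateReadings(layout, specs, noise, seed = seed + 2L,
                          refParams = baseParams)
  new("TFTScreen", layout = layout, readings = sim$readings,
      strains = specs, colonies = sim$colonies)
}
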