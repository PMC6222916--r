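# Colony-level cleanup, in the fixed order: size-based exclusion ->
# background correction -> log transform -> per-plate normalization to the
# reference strain set. The order matters: background subtraction is an
# intensity-scale operation and must precede the log transform.

.posKey <- function(d) paste(d$plate_id, d$row, d$col)

.joinLayout <- function(readings, layout) {
  idx <- match(.posKey(readings), .posKey(layout))
  if (anyNA(idx))
    stop("readings contain positions absent from the layout")
  cbind(readings,
        layout[idx, c("strain_id", "protein_id", "genotype", "role"),
               drop = FALSE])
}

#' Exclude failed crosses by colony size
#'
#' Sample colonies smaller than \code{sizeThreshold} times the median
#' colony size of their plate (over all non-empty positions, so the
#' reference is robust to failures) are dropped as failed crosses after
#' haploid selection. Non-sample colonies are never excluded here.
#'
#' @param readings colony readings data.frame
#' @param layout matching layout data.frame
#' @param sizeThreshold fraction of the per-plate median colony size,
#'   in (0, 1)
#' @return list with \code{readings} (surviving rows) and \code{excluded}
#'   (log of dropped colonies: position, strain, size, plate median)
#' @export
excludeFailed <- function(readings, layout, sizeThreshold = 0.3) {
  if (!(sizeThreshold > 0 && sizeThreshold < 1))
    stop("sizeThreshold must be in (0, 1)")
  d <- .joinLayout(readings, layout)
  s <- d$role == "sample"
  if (!all(unique(d$plate_id) %in% unique(d$plate_id[s])))
    stop("plate without sample colonies: ",
         paste(setdiff(unique(d$plate_id), unique(d$plate_id[s])),
               collapse = ", "))
  # the size reference includes controls and references so that it stays
  # robust even when a large fraction of crosses failed
  grown <- d$role != "empty"
  med <- tapply(d$colony_size[grown], d$plate_id[grown], stats::median)
  drop <- s & d$colony_size < sizeThreshold * med[d$plate_id]
  excluded <- data.frame(
    plate_id = d$plate_id[drop], row = d$row[drop], col = d$col[drop],
    strain_id = d$strain_id[drop], colony_size = d$colony_size[drop],
    plate_median = unname(med[d$plate_id[drop]]),
    stringsAsFactors = FALSE)
  list(readings = readings[!drop, , drop = FALSE], excluded = excluded)
}

#' Background-correct sample colonies against their control block
#'
#' Per channel, the mean intensity of the negative-control colonies
#' arranged next to each sample block (same plate, protein and genotype)
#' is subtracted from each sample colony of the block. Reference colonies
#' are corrected with the plate-wide mean of all negative controls.
#' Corrected intensities <= 0 in either channel cannot be
#' log-transformed; those replicates are flagged invalid and dropped.
#'
#' @param readings colony readings (after exclusion)
#' @param layout matching layout
#' @return list with \code{corrected} (sample + reference rows, corrected
#'   mCherry/sfGFP plus strain annotation) and \code{dropped} (rows lost
#'   to non-positive corrected intensities)
#' @export
backgroundCorrect <- function(readings, layout) {
  d <- .joinLayout(readings, layout)
  ctrl <- d[d$role == "negative_control", , drop = FALSE]
  blockKey <- function(x) paste(x$plate_id, x$protein_id, x$genotype)

  samp <- d[d$role == "sample", , drop = FALSE]
  if (nrow(samp)) {
    ctrlC <- tapply(ctrl$mCherry, blockKey(ctrl), mean)
    ctrlG <- tapply(ctrl$sfGFP, blockKey(ctrl), mean)
    bk <- blockKey(samp)
    if (anyNA(match(bk, names(ctrlC)))) {
      miss <- unique(bk[is.na(match(bk, names(ctrlC)))])
      stop("sample block(s) without surviving negative controls: ",
           paste(miss, collapse = "; "))
    }
    samp$mCherry <- samp$mCherry - unname(ctrlC[bk])
    samp$sfGFP <- samp$sfGFP - unname(ctrlG[bk])
  }

  ref <- d[d$role == "reference", , drop = FALSE]
  if (nrow(ref)) {
    plateC <- tapply(ctrl$mCherry, ctrl$plate_id, mean)
    plateG <- tapply(ctrl$sfGFP, ctrl$plate_id, mean)
    bgC <- plateC[ref$plate_id]
    bgG <- plateG[ref$plate_id]
    bgC[is.na(bgC)] <- 0       # plates without controls: leave unchanged
    bgG[is.na(bgG)] <- 0
    ref$mCherry <- ref$mCherry - unname(bgC)
    ref$sfGFP <- ref$sfGFP - unname(bgG)
  }

  out <- rbind(samp, ref)
  bad <- out$mCherry <= 0 | out$sfGFP <= 0
  list(corrected = out[!bad, , drop = FALSE],
       dropped = out[bad, , drop = FALSE])
}

#' Per-plate normalization to the reference strain set
#'
#' Log-transforms the corrected intensities (natural log) and subtracts,
#' per plate and channel, the median log intensity of the plate's
#' reference colonies; the reference median becomes exactly 0 on every
#' plate, making plates with different detector gains comparable.
#'
#' @param corrected corrected readings from [backgroundCorrect()] (must
#'   contain the reference rows)
#' @return data.frame of sample colonies with \code{log_mC} and
#'   \code{log_sfG} (normalized natural-log intensities) plus strain
#'   annotation
#' @export
normalizePlate <- function(corrected) {
  ref <- corrected[corrected$role == "reference", , drop = FALSE]
  nRef <- table(ref$plate_id)
  plates <- unique(corrected$plate_id)
  short <- setdiff(plates, names(nRef)[nRef >= 3])
  if (length(short))
    stop("need >= 3 reference colonies per plate; offending plate(s): ",
         paste(short, collapse = ", "))
  medC <- tapply(log(ref$mCherry), ref$plate_id, stats::median)
  medG <- tapply(log(ref$sfGFP), ref$plate_id, stats::median)
  out <- corrected
  out$log_mC <- log(out$mCherry) - unname(medC[out$plate_id])
  out$log_sfG <- log(out$sfGFP) - unname(medG[out$plate_id])
  out
}

#' Collect technical replicates into per-strain log-ratios
#'
#' Groups valid sample colonies per (protein, genotype), computes the
#' per-replicate log-ratio \code{log_mC - log_sfG}, and flags strains with
#' fewer than 2 valid replicates as untestable (replicate variance
#' undefined).
#'
#' @param normalized output of [normalizePlate()]
#' @return data.frame with one row per valid replicate: protein_id,
#'   genotype, replicate, log_mC, log_sfG, log_ratio, n_valid, testable
#' @export
collectReplicates <- function(normalized) {
  s <- normalized[normalized$role == "sample", , drop = FALSE]
  s <- s[order(s$protein_id, s$genotype, s$plate_id, s$row, s$col), ,
         drop = FALSE]
  key <- paste(s$protein_id, s$genotype)
  reps <- stats::ave(seq_along(key), key, FUN = seq_along)
  nValid <- stats::ave(seq_along(key), key, FUN = length)
  out <- data.frame(
    protein_id = s$protein_id, genotype = s$genotype, replicate = reps,
    log_mC = s$log_mC, log_sfG = s$log_sfG,
    log_ratio = s$log_mC - s$log_sfG,
    n_valid = nValid, testable = nValid >= 2L,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Run the full colony-level preprocessing chain
#'
#' Exclusion by colony size, background correction, log transform and
#' per-plate normalization, then replicate collection, in that fixed
#' order.
#'
#' @inheritParams excludeFailed
#' @return list with \code{replicates} (see [collectReplicates()]),
#'   \code{excluded} and \code{dropped} logs
#' @export
preprocessScreen <- function(readings, layout, sizeThreshold = 0.3) {
  ex <- excludeFailed(readings, layout, sizeThreshold)
  bc <- backgroundCorrect(ex$readings, layout)
  norm <- normalizePlate(bc$corrected)
  list(replicates = collectReplicates(norm),
       excluded = ex$excluded, dropped = bc$dropped)
}
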