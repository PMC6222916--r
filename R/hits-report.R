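# Hit calling uses the screen's volcano thresholds with strict
# inequalities: p-value < 0.1 and net delta-score (|delta_mC_sfG|) > 0.2,
# with a strong tier at net delta-score > 0.5.

#' Call hits against the volcano thresholds
#'
#' A record is a hit when \code{p_value < pMax} and
#' \code{|delta_mC_sfG| > netDeltaMin} (both strict); the class is
#' \code{stabilized} for negative delta-scores and \code{destabilized}
#' for positive ones, \code{none} otherwise. Hits with
#' \code{|delta_mC_sfG| > strongDeltaMin} form the strong tier.
#'
#' @param records delta-score records with p-values ([scoreScreen()])
#' @param thresholds a [HitThresholds-class]
#' @return \code{records} with \code{hit_class} and \code{strong} columns;
#'   attribute \code{nHitProteins} counts unique proteins hit in >= 1
#'   mutant (see [countHitProteins()])
#' @export
callHits <- function(records, thresholds = HitThresholds()) {
  stopifnot(is(thresholds, "HitThresholds"))
  validObject(thresholds)
  if (is.null(records$p_value))
    stop("records carry no p-values; run scoreScreen()/moderatedT() first")
  net <- abs(records$delta_mC_sfG)
  isHit <- !is.na(records$p_value) & !is.na(net) &
    records$p_value < thresholds@pMax & net > thresholds@netDeltaMin
  records$hit_class <- ifelse(!isHit, "none",
                              ifelse(records$delta_mC_sfG < 0,
                                     "stabilized", "destabilized"))
  records$strong <- isHit & net > thresholds@strongDeltaMin
  attr(records, "nHitProteins") <-
    length(unique(records$protein_id[isHit]))
  records
}

#' Count unique proteins hit in at least one mutant
#'
#' @param calls output of [callHits()]
#' @return integer count
#' @export
countHitProteins <- function(calls) {
  length(unique(calls$protein_id[calls$hit_class != "none"]))
}

# Leaf order of an hclust tree with the deterministic tie-break: at every
# merge the subtree containing the smaller original row index goes left.
.leafOrder <- function(merge) {
  ord <- vector("list", nrow(merge))
  for (k in seq_len(nrow(merge))) {
    pick <- function(j) if (j < 0) -j else ord[[j]]
    a <- pick(merge[k, 1L]); b <- pick(merge[k, 2L])
    ord[[k]] <- if (min(a) <= min(b)) c(a, b) else c(b, a)
  }
  ord[[nrow(merge)]]
}

#' Hierarchically cluster delta-score profiles across mutants
#'
#' Builds the protein x mutant delta-score matrix restricted to proteins
#' passing the thresholds in at least one mutant, imputes missing cells as
#' 0 (flagged), and clusters the rows by agglomerative hierarchical
#' clustering (Euclidean distance, complete linkage by default). Columns
#' keep their fixed mutant order. The leaf order is deterministic: at each
#' merge the subtree containing the lower original row index is placed
#' first.
#'
#' @param records scored records ([scoreScreen()] output); alternatively a
#'   numeric protein x mutant matrix (then no threshold filtering is done)
#' @param thresholds a [HitThresholds-class] used for the row filter
#' @param distMethod distance for [stats::dist()] (default
#'   \code{"euclidean"})
#' @param linkage agglomeration method for [stats::hclust()] (default
#'   \code{"complete"})
#' @return list with \code{matrix} (filtered, original row order),
#'   \code{order} (row indices in leaf order), \code{tree} (the
#'   [stats::hclust] object, NULL for < 2 rows), \code{imputed} (logical
#'   matrix of imputed cells) and \code{table} (tidy long heatmap table in
#'   leaf order)
#' @export
clusterProfiles <- function(records, thresholds = HitThresholds(),
                            distMethod = "euclidean",
                            linkage = "complete") {
  imputed <- NULL
  if (is.matrix(records)) {
    m <- records
    if (is.null(rownames(m))) rownames(m) <- sprintf("R%d", seq_len(nrow(m)))
    if (is.null(colnames(m))) colnames(m) <- sprintf("C%d", seq_len(ncol(m)))
    imputed <- is.na(m)
    m[imputed] <- 0
  } else {
    calls <- callHits(records, thresholds)
    keep <- unique(calls$protein_id[calls$hit_class != "none"])
    calls <- calls[calls$protein_id %in% keep, , drop = FALSE]
    mutants <- unique(records$mutant)
    m <- matrix(NA_real_, length(keep), length(mutants),
                dimnames = list(keep, mutants))
    m[cbind(match(calls$protein_id, keep),
            match(calls$mutant, mutants))] <- calls$delta_mC_sfG
    imputed <- is.na(m)
    m[imputed] <- 0
  }
  if (nrow(m) < 2L) {
    ord <- seq_len(nrow(m))
    tree <- NULL
  } else {
    tree <- stats::hclust(stats::dist(m, method = distMethod),
                          method = linkage)
    ord <- .leafOrder(tree$merge)
    tree$order <- ord
  }
  long <- data.frame(
    protein_id = rep(rownames(m)[ord], times = ncol(m)),
    mutant = rep(colnames(m), each = length(ord)),
    delta_mC_sfG = as.vector(m[ord, , drop = FALSE]),
    imputed = as.vector(imputed[ord, , drop = FALSE]),
    leaf_position = rep(seq_along(ord), times = ncol(m)),
    stringsAsFactors = FALSE)
  list(matrix = m, order = ord, tree = tree, imputed = imputed,
       table = long)
}

#' Tidy volcano-plot table
#'
#' One row per record: the stability delta-score on x, \code{-log10(p)}
#' on y, and a label flag marking records passing the hit thresholds
#' (consistent with [callHits()]). Zero p-values are capped at
#' \code{-log10 p = 300} and flagged.
#'
#' @param records scored records
#' @param thresholds a [HitThresholds-class]
#' @return data.frame: protein_id, mutant, delta_mC_sfG, neg_log10_p,
#'   label, p_capped
#' @export
volcanoTable <- function(records, thresholds = HitThresholds()) {
  calls <- callHits(records, thresholds)
  y <- -log10(records$p_value)
  capped <- is.finite(records$p_value) & records$p_value == 0
  y[capped] <- 300
  data.frame(
    protein_id = records$protein_id, mutant = records$mutant,
    delta_mC_sfG = records$delta_mC_sfG, neg_log10_p = y,
    label = calls$hit_class != "none", p_capped = capped,
    stringsAsFactors = FALSE)
}
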