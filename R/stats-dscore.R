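# Delta-score: the WT-minus-mutant difference of mean mCherry/sfGFP
# log-ratios. Negative values indicate stabilization of the fusion in the
# mutant, positive values destabilization. p-values come from a moderated
# t-test: the per-protein pooled replicate variance is shrunk toward an
# empirical-Bayes prior fitted across all proteins of a screen.

#' Delta-scores for one protein: wild type vs one mutant
#'
#' \code{delta_mC_sfG = mean(log_ratio WT) - mean(log_ratio mutant)}
#' (negative = stabilized in the mutant);
#' \code{delta_sfG = mean(log_sfG mutant) - mean(log_sfG WT)}
#' (positive = more abundant in the mutant). \code{s2} is the two-sample
#' pooled variance of the replicate log-ratios on
#' \code{d = n_wt + n_mut - 2} degrees of freedom.
#'
#' @param wt,mut data.frames of replicate rows (columns \code{log_ratio},
#'   \code{log_sfG}) for the two genotypes; both need >= 2 replicates
#' @return list: delta_mC_sfG, delta_sfG, n_wt, n_mut, s2, d, and the
#'   centred per-replicate log-ratio residuals
#' @export
deltaScore <- function(wt, mut) {
  nW <- nrow(wt); nM <- nrow(mut)
  if (nW < 2L || nM < 2L)
    stop("both genotypes need >= 2 valid replicates (untestable strain)")
  dRatio <- mean(wt$log_ratio) - mean(mut$log_ratio)
  dAbund <- mean(mut$log_sfG) - mean(wt$log_sfG)
  s2 <- (sum((wt$log_ratio - mean(wt$log_ratio))^2) +
         sum((mut$log_ratio - mean(mut$log_ratio))^2)) / (nW + nM - 2L)
  list(delta_mC_sfG = dRatio, delta_sfG = dAbund, n_wt = nW, n_mut = nM,
       s2 = s2, d = nW + nM - 2L,
       residuals = c(wt$log_ratio - mean(wt$log_ratio),
                     mut$log_ratio - mean(mut$log_ratio)))
}

#' Delta-score table for a whole screen
#'
#' Applies [deltaScore()] to every (protein, mutant) pair against the
#' wild-type replicates of the same protein. Pairs where either genotype
#' has fewer than 2 valid replicates are kept but flagged untestable
#' (statistics NA).
#'
#' @param replicates replicate table from [collectReplicates()]
#' @param wtGenotype name of the reference genotype (default "WT")
#' @return data.frame, one row per (protein, mutant): protein_id, mutant,
#'   n_wt, n_mut, n_replicates, delta_mC_sfG, delta_sfG, s2, d, testable
#' @export
deltaScoreTable <- function(replicates, wtGenotype = "WT") {
  mutants <- setdiff(unique(replicates$genotype), wtGenotype)
  proteins <- unique(replicates$protein_id)
  byStrain <- split(replicates,
                    paste(replicates$protein_id, replicates$genotype))
  grid <- expand.grid(protein_id = proteins, mutant = mutants,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    wt <- byStrain[[paste(grid$protein_id[i], wtGenotype)]]
    mut <- byStrain[[paste(grid$protein_id[i], grid$mutant[i])]]
    nW <- if (is.null(wt)) 0L else nrow(wt)
    nM <- if (is.null(mut)) 0L else nrow(mut)
    if (nW < 2L || nM < 2L)
      return(data.frame(protein_id = grid$protein_id[i],
                        mutant = grid$mutant[i], n_wt = nW, n_mut = nM,
                        n_replicates = nW + nM, delta_mC_sfG = NA_real_,
                        delta_sfG = NA_real_, s2 = NA_real_, d = NA_real_,
                        testable = FALSE, stringsAsFactors = FALSE))
    ds <- deltaScore(wt, mut)
    data.frame(protein_id = grid$protein_id[i], mutant = grid$mutant[i],
               n_wt = nW, n_mut = nM, n_replicates = nW + nM,
               delta_mC_sfG = ds$delta_mC_sfG, delta_sfG = ds$delta_sfG,
               s2 = ds$s2, d = ds$d, testable = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$protein_id, out$mutant), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Inverse of the trigamma function by Newton iteration on 1/trigamma
# (standard empirical-Bayes machinery for the variance-prior fit).
trigammaInverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(NaN)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, deriv = 2L)
      y <- y + dif
      if (abs(dif / y) < 1e-10) break
    }
    y
  }, numeric(1))
}

#' Fit the empirical-Bayes variance prior across proteins
#'
#' Method-of-moments fit of a scaled inverse-chi-square prior to observed
#' per-protein variances \code{s2} on \code{d} degrees of freedom, on the
#' log scale: with \code{e = log(s2) - digamma(d/2) + log(d/2)}, the prior
#' degrees of freedom solve
#' \code{trigamma(df0/2) = mean((e - mean(e))^2 * n/(n-1) - trigamma(d/2))}
#' and \code{s02 = exp(mean(e) + digamma(df0/2) - log(df0/2))}. When the
#' right-hand side is <= 0 there is no excess spread beyond sampling noise:
#' \code{df0 = Inf} and \code{s02 = mean(s2)} (the known-variance limit).
#'
#' With fewer than \code{minVariances} usable variances the fit is not
#' attempted and the no-moderation prior \code{df0 = 0} is returned with a
#' message (ordinary pooled t).
#'
#' @param s2 per-protein pooled variances
#' @param d residual degrees of freedom (scalar or vector)
#' @param minVariances minimum usable variances for the fit (default 10)
#' @return a [VariancePrior-class]
#' @export
fitVariancePrior <- function(s2, d, minVariances = 10L) {
  d <- rep_len(d, length(s2))
  ok <- is.finite(s2) & s2 > 0 & is.finite(d) & d > 0
  if (length(s2) && all(s2[is.finite(s2)] == 0))
    stop("degenerate input: all variances are zero")
  if (sum(ok) < minVariances) {
    message("fitVariancePrior: only ", sum(ok),
            " usable variances; falling back to df0 = 0 (ordinary t)")
    return(VariancePrior(df0 = 0))
  }
  s2 <- s2[ok]; d <- d[ok]
  n <- length(s2)
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  ebar <- mean(e)
  v <- mean((e - ebar)^2 * n / (n - 1) - trigamma(d / 2))
  if (v <= 0)        # no excess spread: known-variance limit
    return(VariancePrior(df0 = Inf, s02 = mean(s2)))
  df0 <- 2 * trigammaInverse(v)
  VariancePrior(df0 = df0,
                s02 = exp(ebar + digamma(df0 / 2) - log(df0 / 2)))
}

#' Moderated t-statistics and p-values for a delta-score table
#'
#' Shrinks each protein's pooled variance toward the prior,
#' \code{s2tilde = (df0 s02 + d s2) / (df0 + d)} (\code{= s02} when
#' \code{df0 = Inf}, \code{= s2} when \code{df0 = 0}), computes
#' \code{t = delta_mC_sfG / sqrt(s2tilde (1/n_wt + 1/n_mut))}, and the
#' two-sided p-value from the t distribution on \code{df_total = d + df0}
#' degrees of freedom (normal when infinite). Records with
#' \code{s2tilde = 0} get NA statistics and are flagged.
#'
#' @param records delta-score table from [deltaScoreTable()]
#' @param prior a [VariancePrior-class] from [fitVariancePrior()]
#' @return \code{records} with columns s2_tilde, t_moderated, df_total,
#'   p_value added
#' @export
moderatedT <- function(records, prior) {
  stopifnot(is(prior, "VariancePrior"))
  validObject(prior)
  df0 <- prior@df0; s02 <- prior@s02
  s2t <- if (is.infinite(df0)) {
    rep(s02, nrow(records))
  } else if (df0 == 0) {
    records$s2
  } else {
    (df0 * s02 + records$d * records$s2) / (df0 + records$d)
  }
  s2t[!records$testable] <- NA_real_
  se <- sqrt(s2t * (1 / records$n_wt + 1 / records$n_mut))
  t <- records$delta_mC_sfG / se
  t[is.finite(s2t) & s2t == 0] <- NA_real_
  dfTotal <- records$d + df0
  p <- 2 * stats::pt(abs(t), df = dfTotal, lower.tail = FALSE)
  records$s2_tilde <- s2t
  records$t_moderated <- t
  records$df_total <- dfTotal
  records$p_value <- p
  records$zero_variance <- is.finite(s2t) & s2t == 0
  records
}

#' Score a screen end to end
#'
#' Preprocessing ([preprocessScreen()]), delta-scores per protein and
#' mutant, an empirical-Bayes variance prior (fitted per mutant by
#' default, or once globally), moderated t-statistics and raw two-sided
#' p-values. Optionally appends Benjamini-Hochberg q-values as an extra
#' column (never used for threshold-based hit calls, which the screen
#' defines on raw p-values).
#'
#' @param readings colony readings data.frame (or a [TFTScreen-class])
#' @param layout layout data.frame (ignored when \code{readings} is a
#'   [TFTScreen-class])
#' @param sizeThreshold colony-size exclusion threshold (fraction of
#'   per-plate median)
#' @param priorScope \code{"per_mutant"} (default) or \code{"global"}
#' @param addBH add a Benjamini-Hochberg \code{q_value} column
#' @return delta-score record data.frame with moderated statistics
#' @examples
#' scr <- simulateScreen(8, mutants = pmtMutants()[1], seed = 3)
#' head(scoreScreen(scr))
#' @export
scoreScreen <- function(readings, layout = NULL, sizeThreshold = 0.3,
                        priorScope = c("per_mutant", "global"),
                        addBH = FALSE) {
  priorScope <- match.arg(priorScope)
  if (is(readings, "TFTScreen")) {
    layout <- screenLayout(readings)
    readings <- screenReadings(readings)
  }
  pre <- preprocessScreen(readings, layout, sizeThreshold)
  tab <- deltaScoreTable(pre$replicates)
  groups <- if (priorScope == "per_mutant") tab$mutant else
    rep("all", nrow(tab))
  parts <- lapply(split(tab, groups), function(part) {
    s2 <- part$s2[part$testable]
    prior <- if (length(s2) && all(s2[is.finite(s2)] == 0)) {
      # noise-free data: no variance to moderate; p-values stay undefined
      message("scoreScreen: all replicate variances are zero; ",
              "p-values flagged undefined")
      VariancePrior(df0 = 0)
    } else {
      fitVariancePrior(s2, part$d[part$testable])
    }
    moderatedT(part, prior)
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$protein_id, out$mutant), , drop = FALSE]
  rownames(out) <- NULL
  if (addBH)
    out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out
}
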