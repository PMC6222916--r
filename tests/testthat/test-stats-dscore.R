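repFrame <- function(logRatio, logSfG = rep(0, length(logRatio))) {
  data.frame(log_ratio = logRatio, log_sfG = logSfG)
}

test_that("delta-scores follow the WT-minus-mutant sign convention", {
  # identical replicates -> both deltas zero
  same <- repFrame(c(-0.2, -0.2, -0.2), c(0.1, 0.1, 0.1))
  ds0 <- deltaScore(same, same)
  expect_equal(ds0$delta_mC_sfG, 0)
  expect_equal(ds0$delta_sfG, 0)

  # WT mean -0.20, mutant mean -0.50 -> +0.30: destabilized
  wt <- repFrame(c(-0.1, -0.2, -0.3))
  mut <- repFrame(c(-0.4, -0.5, -0.6))
  expect_equal(deltaScore(wt, mut)$delta_mC_sfG, 0.3)

  # mutant uniformly 0.30 above WT -> -0.30: stabilized
  mutUp <- repFrame(wt$log_ratio + 0.3)
  expect_equal(deltaScore(wt, mutUp)$delta_mC_sfG, -0.3)

  # abundance is mutant minus WT on log sfGFP
  wtA <- repFrame(c(0, 0), c(1.0, 1.2))
  mutA <- repFrame(c(0, 0), c(1.5, 1.7))
  expect_equal(deltaScore(wtA, mutA)$delta_sfG, 0.5)

  # pooled variance over nW + nM - 2 degrees of freedom
  ds <- deltaScore(wt, mut)
  expect_equal(ds$d, 4)
  expect_equal(ds$s2, (var(wt$log_ratio) * 2 + var(mut$log_ratio) * 2) / 4)

  expect_error(deltaScore(repFrame(0.1), mut), "untestable")
})

test_that("swapping genotypes flips deltas and t but not p", {
  set.seed(3)
  wt <- repFrame(rnorm(3, 0, 0.1), rnorm(3))
  mut <- repFrame(rnorm(3, 0.4, 0.1), rnorm(3))
  a <- deltaScore(wt, mut)
  b <- deltaScore(mut, wt)
  expect_equal(b$delta_mC_sfG, -a$delta_mC_sfG)
  expect_equal(b$delta_sfG, -a$delta_sfG)
  expect_equal(b$s2, a$s2)

  prior <- VariancePrior(df0 = 4, s02 = 0.01)
  recA <- data.frame(delta_mC_sfG = a$delta_mC_sfG, s2 = a$s2, d = a$d,
                     n_wt = 3, n_mut = 3, testable = TRUE)
  recB <- data.frame(delta_mC_sfG = b$delta_mC_sfG, s2 = b$s2, d = b$d,
                     n_wt = 3, n_mut = 3, testable = TRUE)
  tA <- moderatedT(recA, prior)
  tB <- moderatedT(recB, prior)
  expect_equal(tB$t_moderated, -tA$t_moderated)
  expect_equal(tB$p_value, tA$p_value)
})

test_that("variance-prior fit: limits, fallback, and degenerate input", {
  # equal variances -> infinite prior df and the common value
  pr <- fitVariancePrior(rep(0.04, 50), 4)
  expect_equal(pr@df0, Inf)
  expect_equal(pr@s02, 0.04, tolerance = 1e-9)

  # too few variances -> no-moderation fallback, messaged
  expect_message(prF <- fitVariancePrior(c(0.01, 0.02), 4), "df0 = 0")
  expect_equal(prF@df0, 0)

  expect_error(fitVariancePrior(rep(0, 20), 4), "degenerate")
})

test_that("variance prior recovers known hyperparameters by Monte Carlo", {
  set.seed(2024)
  df0 <- 4; s02 <- 0.04; d <- 2; n <- 5000
  s2 <- s02 * (df0 / rchisq(n, df0)) * (rchisq(n, d) / d)
  pr <- fitVariancePrior(s2, d)
  expect_lt(abs(pr@df0 / df0 - 1), 0.2)
  expect_lt(abs(pr@s02 / s02 - 1), 0.1)
})

test_that("variance prior matches the independent limma fit", {
  set.seed(77)
  s2 <- 0.02 * (6 / rchisq(800, 6)) * (rchisq(800, 4) / 4)
  pr <- fitVariancePrior(s2, 4)
  sq <- limma::squeezeVar(s2, df = 4)
  expect_equal(pr@df0, sq$df.prior, tolerance = 1e-6)
  expect_equal(pr@s02, sq$var.prior, tolerance = 1e-6)
  # and the shrunken variances agree record by record
  rec <- data.frame(delta_mC_sfG = 1, s2 = s2, d = 4, n_wt = 3, n_mut = 3,
                    testable = TRUE)
  expect_equal(moderatedT(rec, pr)$s2_tilde, sq$var.post,
               tolerance = 1e-6)
})

test_that("moderated t reduces to the ordinary pooled t at df0 = 0", {
  set.seed(5)
  for (i in 1:20) {
    wt <- repFrame(rnorm(3, 0, 0.15))
    mut <- repFrame(rnorm(3, 0.2, 0.15))
    ds <- deltaScore(wt, mut)
    rec <- data.frame(delta_mC_sfG = ds$delta_mC_sfG, s2 = ds$s2,
                      d = ds$d, n_wt = 3, n_mut = 3, testable = TRUE)
    got <- moderatedT(rec, VariancePrior(df0 = 0))
    tt <- t.test(wt$log_ratio, mut$log_ratio, var.equal = TRUE)
    expect_equal(got$t_moderated, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(got$p_value, tt$p.value, tolerance = 1e-12)
    expect_equal(got$df_total, unname(tt$parameter))
  }
})

test_that("infinite prior df gives the known-variance normal limit", {
  rec <- data.frame(delta_mC_sfG = 0.25, s2 = 99, d = 4, n_wt = 3,
                    n_mut = 3, testable = TRUE)
  got <- moderatedT(rec, VariancePrior(df0 = Inf, s02 = 0.01))
  z <- 0.25 / sqrt(0.01 * (2 / 3))
  expect_equal(got$t_moderated, z)
  expect_equal(got$p_value, 2 * pnorm(-abs(z)), tolerance = 1e-12)

  # at large finite df0 the t tail is within 1e-3 of the normal tail
  got200 <- moderatedT(rec, VariancePrior(df0 = 200, s02 = 0.01))
  expect_lt(abs(got200$p_value - 2 * pnorm(-abs(got200$t_moderated))),
            1e-3)
})

test_that("shrinkage moves t monotonically toward the prior-variance t", {
  rec <- data.frame(delta_mC_sfG = 0.3, s2 = 0.05, d = 4, n_wt = 3,
                    n_mut = 3, testable = TRUE)
  s02 <- 0.01
  ts <- vapply(c(0, 1, 4, 16, 64, 1e4), function(df0)
    moderatedT(rec, VariancePrior(df0 = df0, s02 = s02))$t_moderated,
    numeric(1))
  tLimit <- 0.3 / sqrt(s02 * (2 / 3))
  # s2 > s02 here, so |t| increases toward the limit as df0 grows
  expect_true(all(diff(ts) > 0))
  expect_true(all(ts <= tLimit))
  expect_equal(ts[6], tLimit, tolerance = 1e-3)
})

test_that("zero shrunken variance is flagged, not propagated", {
  rec <- data.frame(delta_mC_sfG = 0.1, s2 = 0, d = 4, n_wt = 3,
                    n_mut = 3, testable = TRUE)
  got <- moderatedT(rec, VariancePrior(df0 = 0))
  expect_true(got$zero_variance)
  expect_true(is.na(got$t_moderated))
  expect_true(is.na(got$p_value))
})

test_that("untestable strains carry flags instead of statistics", {
  lay <- tinyLayout()
  red <- tinyReadings(sample_mC = c(50, 60, 1000),
                      ctrl_mC = c(100, 100, 100))
  res <- suppressMessages(scoreScreen(red, lay))
  expect_equal(nrow(res), 1)
  expect_false(res$testable)
  expect_true(is.na(res$p_value))
})
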