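test_that("strain truth tables realize injected shifts exactly", {
  specs <- strainSpecs(4, mutants = pmtMutants()[1:2],
                       stabilityShift = c(-0.3, 0.1, 0, 0.25),
                       abundanceShift = c(0.2, 0, -0.1, 0),
                       betaSdLog = 0.3, seed = 5)
  wt <- specs[specs$genotype == "WT", ]
  expect_true(all(wt$stability_shift == 0 & wt$abundance_shift == 0))

  mut <- specs[specs$genotype != "WT", ]
  m <- merge(mut, wt[c("protein_id", "beta", "k_deg")], by = "protein_id",
             suffixes = c("", "_wt"))
  ssRatio <- function(k, mG, mC) (mC / (mC + k)) / (mG / (mG + k))
  gfp <- function(beta, k, mG) beta / k * mG / (mG + k)
  # WT-minus-mutant log-ratio difference reproduces the stability shift
  expect_equal(log(ssRatio(m$k_deg_wt, m$m_g, m$m_c)) -
                 log(ssRatio(m$k_deg, m$m_g, m$m_c)),
               m$stability_shift, tolerance = 1e-12)
  # mutant-minus-WT log sfGFP reproduces the abundance shift
  expect_equal(log(gfp(m$beta, m$k_deg, m$m_g)) -
                 log(gfp(m$beta_wt, m$k_deg_wt, m$m_g)),
               m$abundance_shift, tolerance = 1e-12)
})

test_that("unattainable stability shifts are rejected", {
  # with the default operating point a shift of -2 would need ratio > 1
  expect_error(strainSpecs(1, mutants = "m", stabilityShift = -2),
               "attainable")
})

test_that("layouts have the block structure and are deterministic", {
  lay <- buildLayout(1, genotypes = "WT", nReference = 8, seed = 1)
  expect_equal(sum(lay$role == "sample"), 3)
  expect_equal(sum(lay$role == "negative_control"), 3)
  expect_equal(sum(lay$role == "reference"), 8)
  expect_equal(nrow(lay), 32 * 48)

  expect_identical(buildLayout(20, seed = 9), buildLayout(20, seed = 9))
  expect_false(identical(buildLayout(20, seed = 9),
                         buildLayout(20, seed = 10)))

  expect_error(buildLayout(1000, maxPlates = 2), "capacity exceeded")
})

test_that("every sample block is adjacent to its controls on one plate", {
  lay <- buildLayout(200, genotypes = c("WT", pmtMutants()), seed = 3)
  s <- lay[lay$role == "sample", ]
  key <- paste(s$protein_id, s$genotype)
  for (k in unique(key)) {
    blk <- s[key == k, ]
    expect_equal(nrow(blk), 3)
    expect_equal(length(unique(blk$plate_id)), 1)
    expect_equal(length(unique(blk$row)), 1)
    expect_equal(sort(diff(sort(blk$col))), c(1, 1))
    ctrl <- lay[lay$role == "negative_control" &
                  lay$protein_id == blk$protein_id[1] &
                  lay$genotype == blk$genotype[1], ]
    expect_equal(nrow(ctrl), 3)
    expect_equal(unique(ctrl$plate_id), unique(blk$plate_id))
    expect_equal(unique(ctrl$row), unique(blk$row))
    # controls sit in the 3 columns immediately right of the samples
    expect_equal(sort(ctrl$col), sort(blk$col) + 3)
  }
  # all four genotypes of a protein share a plate
  byProt <- tapply(s$plate_id, s$protein_id,
                   function(x) length(unique(x)))
  expect_true(all(byProt == 1))
  # the reference set is present on every plate
  refs <- table(lay$plate_id[lay$role == "reference"])
  expect_true(all(refs == 8))
  expect_setequal(names(refs), unique(lay$plate_id))
})

test_that("noise-free readings equal closed-form steady states", {
  specs <- strainSpecs(3, mutants = "m", stabilityShift = 0.1,
                       betaSdLog = 0.2, seed = 2)
  lay <- buildLayout(3, genotypes = c("WT", "m"), seed = 2)
  sim <- simulateReadings(lay, specs, noiseFree(), seed = 4)
  d <- merge(merge(sim$readings, lay), specs,
             by = c("protein_id", "genotype"))
  s <- d[d$role == "sample", ]
  expect_equal(s$sfGFP,
               s$beta / s$k_deg * s$m_g / (s$m_g + s$k_deg) + 40,
               tolerance = 1e-12)
  expect_equal(s$mCherry,
               s$beta / s$k_deg * s$m_c / (s$m_c + s$k_deg) + 20,
               tolerance = 1e-12)
  # controls and empties carry autofluorescence only
  bg <- d[d$role == "negative_control", ]
  expect_true(all(bg$sfGFP == 40 & bg$mCherry == 20))

  # same seed -> identical readings; different seed -> different noise
  noisy <- NoiseModel()
  r1 <- simulateReadings(lay, specs, noisy, seed = 7)$readings
  r2 <- simulateReadings(lay, specs, noisy, seed = 7)$readings
  r3 <- simulateReadings(lay, specs, noisy, seed = 8)$readings
  expect_identical(r1, r2)
  expect_false(identical(r1, r3))
})

test_that("failed crosses are flagged, small, and excluded exactly", {
  scr <- simulateScreen(40, mutants = "m", noise = NoiseModel(), seed = 12)
  truth <- screenColonyTruth(scr)
  ex <- excludeFailed(screenReadings(scr), screenLayout(scr),
                      sizeThreshold = 0.3)
  keyT <- with(truth[truth$failed, ], paste(plate_id, row, col))
  keyE <- with(ex$excluded, paste(plate_id, row, col))
  expect_setequal(keyE, keyT)

  # failed-cross fraction 1 -> every sample colony is below threshold
  allFail <- NoiseModel(failFraction = 1)
  scrF <- simulateScreen(5, mutants = "m", noise = allFail, seed = 3)
  exF <- excludeFailed(screenReadings(scrF), screenLayout(scrF))
  expect_equal(nrow(exF$excluded),
               sum(screenLayout(scrF)$role == "sample"))
})

test_that("null screens give delta-scores centered at zero", {
  scr <- simulateScreen(500, mutants = "m", seed = 21)
  res <- scoreScreen(scr)
  d <- res$delta_mC_sfG[res$testable]
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d)), 3 * se)
})

test_that("the colony-size factor cancels from the log-ratio", {
  # large size spread, no channel noise: log-ratios must be untouched
  noise <- NoiseModel(sigmaChannel = 0, sigmaSize = 0.5, failFraction = 0,
                      autofluorG = 0, autofluorC = 0)
  scr <- simulateScreen(10, mutants = "m", noise = noise, seed = 6)
  res <- scoreScreen(scr)
  expect_true(all(abs(res$delta_mC_sfG[res$testable]) < 1e-9))
})

test_that("NoiseModel validity rejects bad noise parameters", {
  expect_error(NoiseModel(sigmaChannel = -0.1), "sigmas")
  expect_error(NoiseModel(failFraction = 1.5), "failFraction")
  expect_error(NoiseModel(autofluorG = -2), "autofluorescence")
})
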