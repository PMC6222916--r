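# Shared fixtures, all generated in code.

noiseFree <- function(autofluorG = 40, autofluorC = 20) {
  NoiseModel(sigmaChannel = 0, sigmaSize = 0, failFraction = 0,
             autofluorG = autofluorG, autofluorC = autofluorC)
}

# Join scored records to the generator's truth table.
mergeTruth <- function(records, screen) {
  truth <- screenTruth(screen)
  truth <- truth[truth$genotype != "WT", , drop = FALSE]
  merge(records, truth, by.x = c("protein_id", "mutant"),
        by.y = c("protein_id", "genotype"))
}

# Minimal hand-built single-block plate: 3 samples, 3 controls, 3 refs.
tinyLayout <- function() {
  data.frame(
    plate_id = "plateA",
    row = c(2, 2, 2, 2, 2, 2, 1, 1, 1),
    col = c(1, 2, 3, 4, 5, 6, 1, 2, 3),
    strain_id = c(rep("P1_mut", 3), rep("ctrl_P1_mut", 3),
                  paste0("ref_", 1:3)),
    protein_id = c(rep("P1", 6), rep("", 3)),
    genotype = c(rep("mut", 6), rep("WT", 3)),
    role = c(rep("sample", 3), rep("negative_control", 3),
             rep("reference", 3)),
    stringsAsFactors = FALSE)
}

tinyReadings <- function(sample_mC = c(1000, 1000, 1000),
                         sample_sfG = c(2000, 2000, 2000),
                         ctrl_mC = c(90, 100, 110),
                         ctrl_sfG = c(90, 100, 110),
                         ref_mC = c(500, 500, 500),
                         ref_sfG = c(800, 800, 800),
                         sizes = rep(1, 9)) {
  data.frame(
    plate_id = "plateA",
    row = c(2, 2, 2, 2, 2, 2, 1, 1, 1),
    col = c(1, 2, 3, 4, 5, 6, 1, 2, 3),
    mCherry = c(sample_mC, ctrl_mC, ref_mC),
    sfGFP = c(sample_sfG, ctrl_sfG, ref_sfG),
    colony_size = sizes,
    stringsAsFactors = FALSE)
}
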