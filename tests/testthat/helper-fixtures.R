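# Shared fixtures: all synthetic, built in code at test time.

noiselessConfig <- function(seed = 1L)
  simulationConfig(noiseSd = 0, baselineAmplitude = 0, scaleSd = 0, seed = seed)

# References generated noiseless and left unprocessed: the exact regressors
# of the noiseless composition model.
rawReferenceSet <- function(config = noiselessConfig())
  ReferenceSet(makeReferenceSpectrum("CG", config),
               makeReferenceSpectrum("AT", config))

randomDNA <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A small cohort table built by hand (6 subjects) for smoke contracts.
toyCohort <- function() {
  data.frame(
    sample_id = sprintf("T%02d", 1:6),
    group = rep(c("cancer", "control"), each = 3),
    gender = c("Female", "Male", "Male", "Female", "Female", "Male"),
    age_band = rep("61-100", 6),
    pack_years_band = c("0", "21-100", "21-100", "0", "1-20", "0"),
    stage_band = c("I-II", "III-IV", "III-IV", NA, NA, NA),
    histology = c("Adeno", "Squamous", "Squamous", NA, NA, NA),
    level_p16 = c(0.20, 0.10, 0.00, 0.00, 0.01, 0.00),
    state_p16 = c("methylated", "methylated", "unmethylated",
                  "unmethylated", "unmethylated", "unmethylated"),
    level_MGMT = c(0.00, 0.30, 0.06, 0.00, 0.00, 0.02),
    state_MGMT = c("unmethylated", "methylated", "methylated",
                   "unmethylated", "unmethylated", "unmethylated"),
    level_RASSF1 = c(0.12, 0.00, 0.00, 0.00, 0.00, 0.00),
    state_RASSF1 = c("methylated", "unmethylated", "unmethylated",
                     "unmethylated", "unmethylated", "unmethylated"),
    stringsAsFactors = FALSE)
}
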