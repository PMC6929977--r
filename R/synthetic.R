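# Synthetic SERS generator: stands in for the Raman instrument so that the
# whole pipeline (preprocess -> unmix -> quantify -> evaluate) runs offline.

#' Default SERS peak table for double-stranded DNA
#'
#' The sixteen bands observed in SERS spectra of dsCG/dsAT oligonucleotides
#' between 644 and 1636 cm^-1, with their base-pair attribution: four bands
#' belong to dsCG only (644, 1354, 1550 plus the C/G modes), five to dsAT
#' only, the rest are shared by both duplexes. Unique bands carry amplitude
#' on one channel only; shared bands respond to both. Band heights are a
#' modelling choice (the attribution fixes which are zero, not the ratios).
#'
#' @return data.frame with columns center (cm^-1), width (FWHM, cm^-1),
#'   amplitude_cg, amplitude_at.
#' @export
defaultPeakTable <- function() {
  data.frame(
    center = c(644, 684, 734, 788, 1024, 1098, 1188, 1240,
               1270, 1336, 1354, 1378, 1484, 1550, 1575, 1636),
    width  = 12,
    amplitude_cg = c(1.0, 0,   0,   0.7, 0.7, 0.7, 0.7, 0.7,
                     0.7, 0,   1.0, 0.7, 0.7, 1.0, 0,   0.7),
    amplitude_at = c(0,   1.0, 1.0, 0.7, 0.7, 0.7, 0.7, 0.7,
                     0.7, 1.0, 0,   0.7, 0.7, 0,   1.0, 0.7))
}

#' Simulation parameters for the synthetic SERS instrument
#'
#' @slot gridMin,gridMax,gridStep wavenumber grid (cm^-1).
#' @slot peaks data.frame of Lorentzian bands (see [defaultPeakTable()]).
#' @slot noiseSd additive Gaussian noise sigma, relative to the maximum
#'   noiseless peak height.
#' @slot baselineAmplitude amplitude of the random smooth (quadratic)
#'   baseline, relative to the maximum peak height.
#' @slot scaleSd sigma of the per-spectrum lognormal intensity scale
#'   (substrate/focus variability).
#' @slot seed integer; together with the inputs it fully determines every
#'   generated spectrum.
#' @seealso [simulationConfig()], [makeReferenceSpectrum()],
#'   [makeProductSpectrum()]
#' @export
setClass("SimulationConfig",
  representation(gridMin = "numeric", gridMax = "numeric", gridStep = "numeric",
                 peaks = "data.frame", noiseSd = "numeric",
                 baselineAmplitude = "numeric", scaleSd = "numeric",
                 seed = "integer"))

setValidity("SimulationConfig", function(object) {
  if (object@gridMax <= object@gridMin) return("gridMax must exceed gridMin")
  if (object@gridStep <= 0) return("gridStep must be positive")
  need <- c("center", "width", "amplitude_cg", "amplitude_at")
  if (!all(need %in% names(object@peaks)))
    return(sprintf("peak table must have columns %s", paste(need, collapse = ", ")))
  if (nrow(object@peaks) && any(object@peaks$width <= 0))
    return("peak widths must be positive")
  if (nrow(object@peaks) &&
      any(object@peaks$amplitude_cg < 0 | object@peaks$amplitude_at < 0))
    return("peak amplitudes must be non-negative")
  if (object@noiseSd < 0 || object@baselineAmplitude < 0 || object@scaleSd < 0)
    return("noise parameters must be non-negative")
  TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: grid %.0f-%.0f step %.3g cm^-1, %d peaks, noiseSd=%.3g, baseline=%.3g, scaleSd=%.3g, seed=%d\n",
    object@gridMin, object@gridMax, object@gridStep, nrow(object@peaks),
    object@noiseSd, object@baselineAmplitude, object@scaleSd, object@seed))
})

#' Construct a SimulationConfig
#'
#' Defaults describe the study conditions of the verification simulation:
#' 600-1700 cm^-1 grid at 1 cm^-1, the [defaultPeakTable()] bands, additive
#' noise sigma 1% of the maximum peak, random quadratic baseline of 5%
#' amplitude, and a 5% lognormal per-spectrum intensity scale.
#'
#' @param gridMin,gridMax,gridStep wavenumber grid (cm^-1).
#' @param peaks Lorentzian band table (see [defaultPeakTable()]).
#' @param noiseSd,baselineAmplitude,scaleSd noise model, all relative to the
#'   maximum noiseless peak height; set all three to 0 for noiseless spectra.
#' @param seed integer master seed.
#' @return A [SimulationConfig-class].
#' @export
simulationConfig <- function(gridMin = 600, gridMax = 1700, gridStep = 1,
                             peaks = defaultPeakTable(), noiseSd = 0.01,
                             baselineAmplitude = 0.05, scaleSd = 0.05,
                             seed = 1L) {
  new("SimulationConfig", gridMin = gridMin, gridMax = gridMax,
      gridStep = gridStep, peaks = peaks, noiseSd = noiseSd,
      baselineAmplitude = baselineAmplitude, scaleSd = scaleSd,
      seed = as.integer(seed))
}

simGrid <- function(config) seq(config@gridMin, config@gridMax, by = config@gridStep)

# Evaluate an RNG-using expression under a fixed seed, leaving the global RNG
# state untouched.
withSeed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Sum of Lorentzian lines over a grid; amplitudes is the per-band height
# column to use.
lorentzianSum <- function(grid, peaks, amplitudes) {
  y <- numeric(length(grid))
  gamma <- peaks$width / 2
  for (i in seq_len(nrow(peaks))) {
    if (amplitudes[i] == 0) next
    y <- y + amplitudes[i] * gamma[i]^2 / ((grid - peaks$center[i])^2 + gamma[i]^2)
  }
  y
}

# Noiseless model spectra of the two pure references.
pureSignal <- function(kind, config) {
  grid <- simGrid(config)
  amp <- switch(kind, CG = config@peaks$amplitude_cg,
                AT = config@peaks$amplitude_at,
                stopArgument("kind must be 'CG' or 'AT'"))
  lorentzianSum(grid, config@peaks, amp)
}

# Instrument effects: y = scale * signal + baseline + noise, all relative to
# the maximum noiseless peak height of the two references (so noise does not
# shrink when the CG-poor component dominates).
addInstrumentEffects <- function(signal, config, seed) {
  grid <- simGrid(config)
  refMax <- max(max(pureSignal("CG", config)), max(pureSignal("AT", config)))
  withSeed(seed, {
    scale <- if (config@scaleSd > 0) stats::rlnorm(1, 0, config@scaleSd) else 1
    x01 <- (grid - min(grid)) / (max(grid) - min(grid))
    coefs <- stats::runif(3)
    baseline <- if (config@baselineAmplitude > 0)
      config@baselineAmplitude * refMax * (coefs[1] + coefs[2] * x01 + coefs[3] * x01^2)
    else numeric(length(grid))
    noise <- if (config@noiseSd > 0)
      stats::rnorm(length(grid), 0, config@noiseSd * refMax)
    else numeric(length(grid))
    scale * signal + baseline + noise
  })
}

#' Generate a dsCG or dsAT reference spectrum
#'
#' Sum of Lorentzian bands from the configured peak table (using the CG or
#' AT amplitude channel), plus the configured baseline, intensity scale and
#' additive noise. The same configuration always yields the identical
#' spectrum.
#'
#' @param kind "CG" or "AT".
#' @param config a [SimulationConfig-class].
#' @param seed RNG seed for the instrument effects; defaults to the
#'   config seed.
#' @return A [Spectrum-class] with kind and seed recorded in its metadata.
#' @examples
#' cg <- makeReferenceSpectrum("CG", simulationConfig(noiseSd = 0,
#'   baselineAmplitude = 0, scaleSd = 0))
#' @export
makeReferenceSpectrum <- function(kind, config, seed = config@seed) {
  kind <- match.arg(kind, c("CG", "AT"))
  if (nrow(config@peaks) == 0L)
    stopArgument("empty peak table: nothing to simulate")
  signal <- pureSignal(kind, config)
  y <- addInstrumentEffects(signal, config, seed)
  Spectrum(simGrid(config), y, meta = list(kind = kind, seed = seed))
}

#' Generate a PCR-product spectrum at a given CG base-pair fraction
#'
#' The noiseless signal is the composition-weighted peak model
#' `f_cg * S_CG + (1 - f_cg) * S_AT` (mixing at the model level, not of
#' noisy realizations); instrument baseline, intensity scale and noise are
#' then added.
#'
#' @param fCG CG base-pair fraction in [0, 1].
#' @param config a [SimulationConfig-class].
#' @param seed RNG seed for the instrument effects; defaults to config seed.
#' @return A [Spectrum-class].
#' @export
makeProductSpectrum <- function(fCG, config, seed = config@seed) {
  if (!is.numeric(fCG) || length(fCG) != 1L || is.na(fCG) || fCG < 0 || fCG > 1)
    stopArgument("fCG must be a single value in [0, 1]")
  if (nrow(config@peaks) == 0L)
    stopArgument("empty peak table: nothing to simulate")
  signal <- fCG * pureSignal("CG", config) + (1 - fCG) * pureSignal("AT", config)
  y <- addInstrumentEffects(signal, config, seed)
  Spectrum(simGrid(config), y, meta = list(f_cg = fCG, seed = seed))
}

#' Simulate the verification set: genes x methylation levels x replicates
#'
#' For every gene, a dilution series of known methylation levels (default
#' 0%, 1%, 5%, 25%, 50%, 75%, 100%) measured in triplicate: each spectrum is
#' a PCR product generated at `f_cg = cgFractionAtLevel(calib, m)` with its
#' own instrument noise draw. Spectrum metadata carries gene, true level and
#' replicate; the full design is recoverable via [verificationLabels()].
#'
#' @param calibs named list of [GeneCalibration-class] (default the three
#'   study genes).
#' @param levels methylation levels to simulate.
#' @param reps replicates per gene x level.
#' @param config a [SimulationConfig-class]; its seed determines every draw.
#' @return Named list of [Spectrum-class], names like "p16_m25_r1".
#' @examples
#' vs <- simulateVerificationSet(config = simulationConfig(seed = 7))
#' length(vs)  # 3 genes x 7 levels x 3 reps = 63
#' @export
simulateVerificationSet <- function(calibs = studyCalibrations(),
                                    levels = c(0, 0.01, 0.05, 0.25, 0.5, 0.75, 1),
                                    reps = 3L,
                                    config = simulationConfig()) {
  if (reps < 1L) stopArgument("reps must be >= 1")
  out <- list()
  idx <- 0L
  for (g in seq_along(calibs)) {
    calib <- calibs[[g]]
    for (m in levels) {
      fCG <- cgFractionAtLevel(calib, m)
      for (r in seq_len(reps)) {
        idx <- idx + 1L
        subSeed <- (config@seed + 7919 * idx) %% 2147483647
        s <- makeProductSpectrum(fCG, config, seed = subSeed)
        s@meta$gene <- calib@geneName
        s@meta$true_m <- m
        s@meta$rep <- r
        out[[sprintf("%s_m%g_r%d", calib@geneName, round(100 * m, 2), r)]] <- s
      }
    }
  }
  out
}

#' Labels table of a simulated spectrum collection
#'
#' @param spectra named list of [Spectrum-class] from
#'   [simulateVerificationSet()].
#' @return data.frame with columns sample, gene, true_m, rep.
#' @export
verificationLabels <- function(spectra) {
  do.call(rbind, lapply(names(spectra), function(id) {
    m <- spectra[[id]]@meta
    data.frame(sample = id, gene = m$gene, true_m = m$true_m, rep = m$rep,
               stringsAsFactors = FALSE)
  }))
}
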