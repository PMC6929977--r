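#' Unmix a spectrum into dsCG and dsAT components by least squares
#'
#' Ordinary least squares of the target spectrum on the two reference
#' spectra over the whole grid. Coefficients are unconstrained: negative
#' values are permitted and propagate to (possibly negative) methylation
#' levels. With `withIntercept = FALSE` (the default; spectra are baseline
#' corrected first) the fit is scale-equivariant, which makes the
#' renormalized CG fraction scale-invariant.
#'
#' @param target a [Spectrum-class] on the reference grid (use [resample()]
#'   first if needed).
#' @param refs a [ReferenceSet-class].
#' @param withIntercept also fit a constant term?
#' @param conditionLimit reject reference pairs whose design matrix
#'   condition number exceeds this (near-collinear references make the
#'   coefficients meaningless).
#' @return A [DeconvolutionResult-class].
#' @examples
#' cfg <- simulationConfig(noiseSd = 0, baselineAmplitude = 0, scaleSd = 0)
#' refs <- ReferenceSet(makeReferenceSpectrum("CG", cfg),
#'                      makeReferenceSpectrum("AT", cfg))
#' mlrDeconvolve(makeProductSpectrum(0.3, cfg), refs)
#' @export
mlrDeconvolve <- function(target, refs, withIntercept = FALSE,
                          conditionLimit = 1e8) {
  stopifnot(is(target, "Spectrum"), is(refs, "ReferenceSet"))
  if (!identical(target@wavenumbers, refs@sCG@wavenumbers))
    stopArgument("target and references are on different wavenumber grids; resample first")
  y <- target@intensities
  X <- cbind(cg = refs@sCG@intensities, at = refs@sAT@intensities)
  if (withIntercept) X <- cbind(X, intercept = 1)
  if (kappa(X, exact = TRUE) > conditionLimit)
    stopNumerical(sprintf(
      "reference spectra are near-collinear (condition number > %.3g); deconvolution is ill-posed",
      conditionLimit))
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  fitted <- as.numeric(X %*% beta)
  resid <- fitted - y
  # centered R^2 with an intercept, uncentered without (no constant in model)
  denom <- if (withIntercept) sum((y - mean(y))^2) else sum(y^2)
  r2 <- if (denom > 0) max(0, min(1, 1 - sum((y - fitted)^2) / denom)) else NA_real_
  new("DeconvolutionResult",
      cCG = unname(beta["cg"]), cAT = unname(beta["at"]),
      intercept = if (withIntercept) unname(beta["intercept"]) else NA_real_,
      fitted = Spectrum(target@wavenumbers, fitted,
                        meta = list(role = "fitted")),
      difference = Spectrum(target@wavenumbers, resid,
                            meta = list(role = "difference")),
      rSquared = r2)
}

#' CG base-pair fraction from fitted unmixing coefficients
#'
#' Renormalizes the two coefficients, `c_CG / (c_CG + c_AT)`, so the
#' composition estimate is invariant to the overall intensity scale of the
#' target spectrum (normalization conventions cancel).
#'
#' @param result a [DeconvolutionResult-class].
#' @return The CG base-pair fraction estimate.
#' @export
cgFractionFromCoefficients <- function(result) {
  total <- result@cCG + result@cAT
  if (!is.finite(total) || total <= 0)
    stopNumerical(sprintf(
      "non-physical fit: c_CG + c_AT = %.4g <= 0, deconvolution failed", total))
  result@cCG / total
}

#' Call the binary methylation state
#'
#' Methylated when the estimated level is at least the threshold (default
#' 5%); everything below it, including negative estimates, is unmethylated.
#'
#' @param level methylation level estimate(s).
#' @param threshold calling threshold (default 0.05).
#' @return character vector, "methylated"/"unmethylated".
#' @export
callState <- function(level, threshold = 0.05) {
  ifelse(level >= threshold, "methylated", "unmethylated")
}

#' Estimate the methylation level of a sample from its spectrum
#'
#' The composed quantification pipeline for one gene: preprocess the target
#' spectrum, unmix it against the dsCG/dsAT references, renormalize the
#' coefficients into a CG base-pair fraction, and invert the gene
#' calibration into a methylation level; the binary state is called at the
#' 5% threshold. Several replicate spectra may be given; their levels are
#' averaged and retained individually.
#'
#' @param target a [Spectrum-class], or a list of replicate spectra of the
#'   same sample.
#' @param refs a [ReferenceSet-class] (already preprocessed).
#' @param calib a [GeneCalibration-class].
#' @param prep a [preprocessingConfig()] applied to each target, or NULL to
#'   skip preprocessing.
#' @param withIntercept passed to [mlrDeconvolve()].
#' @param threshold state-calling threshold.
#' @return A [MethylationEstimate-class].
#' @examples
#' cfg <- simulationConfig(noiseSd = 0, baselineAmplitude = 0, scaleSd = 0)
#' refs <- ReferenceSet(makeReferenceSpectrum("CG", cfg),
#'                      makeReferenceSpectrum("AT", cfg))
#' calib <- studyCalibrations()$p16
#' s <- makeProductSpectrum(cgFractionAtLevel(calib, 0.25), cfg)
#' estimateMethylation(s, refs, calib, prep = NULL)
#' @export
estimateMethylation <- function(target, refs, calib,
                                prep = preprocessingConfig(),
                                withIntercept = FALSE, threshold = 0.05) {
  targets <- if (is(target, "Spectrum")) list(target) else target
  if (!length(targets)) stopArgument("no target spectra given")
  levels <- vapply(targets, function(s) {
    if (!is.null(prep)) s <- preprocess(s, prep)
    if (!identical(s@wavenumbers, refs@sCG@wavenumbers))
      s <- resample(s, refs@sCG@wavenumbers)
    res <- mlrDeconvolve(s, refs, withIntercept = withIntercept)
    methylationFromCgFraction(calib, cgFractionFromCoefficients(res))
  }, numeric(1))
  level <- mean(levels)
  f0 <- calibrationF0(calib)
  new("MethylationEstimate", gene = calib@geneName,
      cgFraction = f0 + level * (calibrationF100(calib) - f0),
      level = level, state = callState(level, threshold),
      replicateLevels = levels)
}

#' Build a preprocessed dsCG/dsAT reference set
#'
#' Generates (or accepts) the two reference spectra and runs them through
#' the same preprocessing chain as the samples.
#'
#' @param config a [SimulationConfig-class] used to generate the references;
#'   by default they are generated noiseless (reference solutions are
#'   measured under favourable conditions and averaged).
#' @param prep a [preprocessingConfig()], or NULL for none.
#' @param sCG,sAT optionally, measured reference [Spectrum-class] objects
#'   to use instead of generated ones.
#' @return A [ReferenceSet-class].
#' @export
makeReferenceSet <- function(config = simulationConfig(),
                             prep = preprocessingConfig(),
                             sCG = NULL, sAT = NULL) {
  if (is.null(sCG) || is.null(sAT)) {
    clean <- simulationConfig(gridMin = config@gridMin, gridMax = config@gridMax,
                              gridStep = config@gridStep, peaks = config@peaks,
                              noiseSd = 0, baselineAmplitude = 0, scaleSd = 0,
                              seed = config@seed)
    if (is.null(sCG)) sCG <- makeReferenceSpectrum("CG", clean)
    if (is.null(sAT)) sAT <- makeReferenceSpectrum("AT", clean)
  }
  if (!is.null(prep)) {
    sCG <- preprocess(sCG, prep)
    sAT <- preprocess(sAT, prep)
  }
  ReferenceSet(sCG, sAT)
}

#' Quantify a labelled spectrum collection
#'
#' Runs [estimateMethylation()] on every spectrum of a simulated (or read)
#' collection, then averages replicates per gene x sample label.
#'
#' @param spectra named list of [Spectrum-class] with gene/true_m/rep
#'   metadata (see [simulateVerificationSet()]).
#' @param refs a [ReferenceSet-class].
#' @param calibs named list of [GeneCalibration-class]; genes are matched by
#'   name.
#' @param prep a [preprocessingConfig()] or NULL.
#' @param withIntercept passed to [mlrDeconvolve()].
#' @return data.frame with one row per spectrum: sample, gene, true_m, rep,
#'   c_cg, c_at, r_squared, cg_fraction, level, state.
#' @export
quantifySpectra <- function(spectra, refs, calibs,
                            prep = preprocessingConfig(),
                            withIntercept = FALSE) {
  rows <- lapply(names(spectra), function(id) {
    s <- spectra[[id]]
    gene <- s@meta$gene
    calib <- calibs[[gene]]
    if (is.null(calib))
      stopArgument(sprintf("no calibration for gene '%s' (sample %s)", gene, id))
    sp <- if (!is.null(prep)) preprocess(s, prep) else s
    if (!identical(sp@wavenumbers, refs@sCG@wavenumbers))
      sp <- resample(sp, refs@sCG@wavenumbers)
    res <- mlrDeconvolve(sp, refs, withIntercept = withIntercept)
    f <- cgFractionFromCoefficients(res)
    lvl <- methylationFromCgFraction(calib, f)
    data.frame(sample = id, gene = gene,
               true_m = if (is.null(s@meta$true_m)) NA_real_ else s@meta$true_m,
               rep = if (is.null(s@meta$rep)) 1L else s@meta$rep,
               c_cg = res@cCG, c_at = res@cAT, r_squared = res@rSquared,
               cg_fraction = f, level = lvl, state = callState(lvl),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Average replicate estimates per gene and true level
#'
#' @param quantified output of [quantifySpectra()].
#' @return data.frame per (gene, true_m): mean estimated level, replicate
#'   count, absolute error.
#' @export
aggregateReplicates <- function(quantified) {
  key <- interaction(quantified$gene, quantified$true_m, drop = TRUE)
  rows <- lapply(split(quantified, key), function(d) data.frame(
    gene = d$gene[1], true_m = d$true_m[1], n_rep = nrow(d),
    level = mean(d$level), abs_error = abs(mean(d$level) - d$true_m[1]),
    stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$gene, out$true_m), ]
}
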