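#' @import methods
NULL

#' Spectrum: a wavenumber grid with matched intensities
#'
#' The universal data currency of the pipeline: a Raman/SERS spectrum as a
#' strictly increasing wavenumber grid (cm^-1) with one intensity per grid
#' point (arbitrary units) and free-form metadata (sample id, gene, replicate,
#' preprocessing history).
#'
#' @slot wavenumbers numeric, strictly increasing, in cm^-1.
#' @slot intensities numeric, same length as `wavenumbers`.
#' @slot meta named list of annotations.
#'
#' @seealso [Spectrum()], [readSpectrum()], [preprocess()]
#' @export
setClass("Spectrum",
  representation(wavenumbers = "numeric", intensities = "numeric",
                 meta = "list"),
  prototype(meta = list()))

setValidity("Spectrum", function(object) {
  w <- object@wavenumbers
  y <- object@intensities
  if (length(w) != length(y))
    return("wavenumbers and intensities must have equal length")
  if (length(w) < 16L)
    return("a Spectrum needs at least 16 points")
  if (anyNA(w) || any(!is.finite(w)))
    return("wavenumbers must be finite")
  if (any(diff(w) <= 0))
    return("wavenumbers must be strictly increasing")
  TRUE
})

#' Construct a Spectrum
#'
#' @param wavenumbers strictly increasing numeric grid (cm^-1).
#' @param intensities numeric intensities, one per grid point.
#' @param meta named list of annotations.
#' @return A [Spectrum-class] object.
#' @examples
#' s <- Spectrum(600:700, sin(600:700 / 50))
#' s
#' @export
Spectrum <- function(wavenumbers, intensities, meta = list()) {
  new("Spectrum", wavenumbers = as.numeric(wavenumbers),
      intensities = as.numeric(intensities), meta = meta)
}

#' @describeIn Spectrum-class number of grid points.
#' @param x a Spectrum.
#' @export
setMethod("length", "Spectrum", function(x) length(x@wavenumbers))

setMethod("show", "Spectrum", function(object) {
  w <- object@wavenumbers
  cat(sprintf("Spectrum: %d points, %.0f-%.0f cm^-1\n",
              length(w), min(w), max(w)))
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), unlist(lapply(object@meta, format)),
                         sep = "=", collapse = ", "), "\n")
})

#' @rdname Spectrum-class
#' @param object a Spectrum.
#' @export
setGeneric("wavenumbers", function(object) standardGeneric("wavenumbers"))

#' @rdname Spectrum-class
#' @export
setMethod("wavenumbers", "Spectrum", function(object) object@wavenumbers)

#' @rdname Spectrum-class
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @rdname Spectrum-class
#' @export
setMethod("intensities", "Spectrum", function(object) object@intensities)

#' @rdname Spectrum-class
#' @export
setGeneric("spectrumMeta", function(object) standardGeneric("spectrumMeta"))

#' @rdname Spectrum-class
#' @export
setMethod("spectrumMeta", "Spectrum", function(object) object@meta)

#' GeneCalibration: the linear methylation-level / CG-fraction map
#'
#' Per-amplicon constants fixing the linear relation between population
#' methylation level m and the CG base-pair fraction f of the bisulfite-PCR
#' product: f(m) = (N0 + m * nCpG) / L, where L is the amplicon length in
#' base pairs, nCpG the number of CpG dinucleotides on the top strand, and N0
#' the number of C:G base pairs in the fully unmethylated converted duplex.
#'
#' @slot geneName character label.
#' @slot ampliconLength integer, L (bp).
#' @slot nCpG integer, CpG dinucleotide count.
#' @slot cgCountAtZero integer, N0.
#'
#' @seealso [calibrationFromSequence()], [calibrationFromConstants()],
#'   [cgFractionAtLevel()], [methylationFromCgFraction()]
#' @export
setClass("GeneCalibration",
  representation(geneName = "character", ampliconLength = "integer",
                 nCpG = "integer", cgCountAtZero = "integer"))

setValidity("GeneCalibration", function(object) {
  L <- object@ampliconLength; n <- object@nCpG; N0 <- object@cgCountAtZero
  if (length(L) != 1L || length(n) != 1L || length(N0) != 1L)
    return("all constants must be scalar")
  if (n < 1L) return("amplicon must contain at least one CpG")
  if (2L * n > L) return("nCpG cannot exceed L/2")
  if (N0 < 0L || N0 > L - n)
    return("cgCountAtZero must satisfy 0 <= N0 <= L - nCpG")
  TRUE
})

setMethod("show", "GeneCalibration", function(object) {
  cat(sprintf(
    "GeneCalibration '%s': L=%d bp, nCpG=%d, N0=%d, f0=%.4f, f100=%.4f\n",
    object@geneName, object@ampliconLength, object@nCpG,
    object@cgCountAtZero, calibrationF0(object), calibrationF100(object)))
})

#' @rdname GeneCalibration-class
#' @param calib a GeneCalibration.
#' @return `calibrationF0`/`calibrationF100`: CG base-pair fraction of the PCR
#'   product at 0% / 100% methylation.
#' @export
calibrationF0 <- function(calib) calib@cgCountAtZero / calib@ampliconLength

#' @rdname GeneCalibration-class
#' @export
calibrationF100 <- function(calib)
  (calib@cgCountAtZero + calib@nCpG) / calib@ampliconLength

#' ReferenceSet: preprocessed dsCG/dsAT reference spectra on a common grid
#'
#' The two regressors of the spectral unmixing step: SERS spectra of pure
#' double-stranded CG and pure double-stranded AT oligonucleotides.
#'
#' @slot sCG [Spectrum-class], dsCG reference.
#' @slot sAT [Spectrum-class], dsAT reference.
#' @seealso [mlrDeconvolve()]
#' @export
setClass("ReferenceSet", representation(sCG = "Spectrum", sAT = "Spectrum"))

setValidity("ReferenceSet", function(object) {
  if (!isTRUE(all.equal(object@sCG@wavenumbers, object@sAT@wavenumbers,
                        tolerance = 0)) &&
      !identical(object@sCG@wavenumbers, object@sAT@wavenumbers))
    return("dsCG and dsAT references must share an identical wavenumber grid")
  TRUE
})

#' Construct a ReferenceSet
#' @param sCG,sAT dsCG and dsAT reference [Spectrum-class] objects on the same
#'   wavenumber grid.
#' @return A [ReferenceSet-class].
#' @export
ReferenceSet <- function(sCG, sAT) new("ReferenceSet", sCG = sCG, sAT = sAT)

setMethod("show", "ReferenceSet", function(object) {
  cat(sprintf("ReferenceSet: dsCG + dsAT on %d-point grid %.0f-%.0f cm^-1\n",
              length(object@sCG), min(object@sCG@wavenumbers),
              max(object@sCG@wavenumbers)))
})

#' DeconvolutionResult: fitted composition of a sample spectrum
#'
#' Result of ordinary least squares of a sample spectrum on the dsCG and dsAT
#' references: the two coefficients, the optional intercept, the fitted
#' spectrum, the difference spectrum (fitted - target) and the goodness of
#' fit.
#'
#' @slot cCG numeric coefficient on the dsCG reference.
#' @slot cAT numeric coefficient on the dsAT reference.
#' @slot intercept numeric; NA when fitted without intercept.
#' @slot fitted,difference [Spectrum-class] on the target grid.
#' @slot rSquared fit quality in [0, 1].
#' @seealso [mlrDeconvolve()], [cgFractionFromCoefficients()]
#' @export
setClass("DeconvolutionResult",
  representation(cCG = "numeric", cAT = "numeric", intercept = "numeric",
                 fitted = "Spectrum", difference = "Spectrum",
                 rSquared = "numeric"))

setMethod("show", "DeconvolutionResult", function(object) {
  cat(sprintf("DeconvolutionResult: c_CG=%.4f, c_AT=%.4f%s, R^2=%.4f\n",
              object@cCG, object@cAT,
              if (is.na(object@intercept)) ""
              else sprintf(", intercept=%.4g", object@intercept),
              object@rSquared))
})

#' MethylationEstimate: quantified methylation of one sample/gene
#'
#' @slot gene character gene label.
#' @slot cgFraction estimated CG base-pair fraction.
#' @slot level continuous methylation level (unclipped; may fall outside
#'   [0, 1]).
#' @slot state "methylated" or "unmethylated" at the active threshold
#'   (default 5%).
#' @slot replicateLevels per-replicate levels when replicates were averaged.
#' @seealso [estimateMethylation()], [callState()]
#' @export
setClass("MethylationEstimate",
  representation(gene = "character", cgFraction = "numeric",
                 level = "numeric", state = "character",
                 replicateLevels = "numeric"))

setMethod("show", "MethylationEstimate", function(object) {
  cat(sprintf("MethylationEstimate '%s': f_CG=%.4f, level=%.4f (%s)\n",
              object@gene, object@cgFraction, object@level, object@state))
})
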