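#' Preprocessing parameters
#'
#' Bundles the parameters of the three-step preprocessing chain applied to
#' every spectrum before unmixing: Savitzky-Golay smoothing, asymmetric
#' least squares (AsLS) baseline subtraction, and normalization. Any step
#' can be disabled.
#'
#' @param smooth apply Savitzky-Golay smoothing?
#' @param window odd filter window length in points.
#' @param polyOrder polynomial order of the SG filter (< window).
#' @param baseline apply AsLS baseline subtraction?
#' @param lambda AsLS smoothness penalty on the estimated baseline. The
#'   default 1e7 keeps the baseline stiff on a 1 cm^-1 grid; soft penalties
#'   (1e5 and below) let the baseline climb into the dense peak bed of DNA
#'   spectra and bias the downstream composition estimate.
#' @param p AsLS asymmetry: weight given to points above the baseline.
#' @param iterations AsLS reweighting iterations.
#' @param normalize one of "max" (divide by maximum intensity), "area"
#'   (divide by trapezoidal area), "none".
#' @return A list with class `preprocessingConfig`.
#' @export
preprocessingConfig <- function(smooth = TRUE, window = 11L, polyOrder = 3L,
                                baseline = TRUE, lambda = 1e7, p = 0.01,
                                iterations = 10L,
                                normalize = c("max", "area", "none")) {
  normalize <- match.arg(normalize)
  if (window %% 2L == 0L)
    stopArgument("Savitzky-Golay window must be odd")
  if (polyOrder >= window)
    stopArgument("Savitzky-Golay polynomial order must be below the window length")
  structure(list(smooth = smooth, window = as.integer(window),
                 polyOrder = as.integer(polyOrder), baseline = baseline,
                 lambda = lambda, p = p, iterations = as.integer(iterations),
                 normalize = normalize),
            class = "preprocessingConfig")
}

#' Asymmetric least squares baseline estimate
#'
#' Whittaker-smoother baseline with asymmetric weights: points above the
#' running baseline get weight `p`, points below get `1 - p`, so the smooth
#' curve hugs the lower envelope of the spectrum and ignores peaks.
#'
#' @param y numeric intensities.
#' @param lambda second-difference smoothness penalty.
#' @param p asymmetry weight in (0, 1), typically 0.001-0.1.
#' @param iterations number of reweighting passes.
#' @return Numeric baseline, same length as `y`.
#' @export
aslsBaseline <- function(y, lambda = 1e5, p = 0.01, iterations = 10L) {
  m <- length(y)
  D <- Matrix::bandSparse(m - 2L, m,
                          k = 0:2,
                          diagonals = list(rep(1, m - 2L), rep(-2, m - 2L),
                                           rep(1, m - 2L)))
  DtD <- lambda * Matrix::crossprod(D)
  w <- rep(1, m)
  z <- y
  for (it in seq_len(iterations)) {
    W <- Matrix::Diagonal(m, w)
    z <- as.numeric(Matrix::solve(W + DtD, w * y))
    w <- ifelse(y > z, p, 1 - p)
  }
  z
}

#' Preprocess a spectrum
#'
#' Applies, in order and as enabled by `config`: Savitzky-Golay smoothing,
#' AsLS baseline subtraction, normalization. The wavenumber grid is never
#' changed; the metadata records the steps applied.
#'
#' @param spectrum a [Spectrum-class].
#' @param config a [preprocessingConfig()].
#' @return The preprocessed [Spectrum-class].
#' @examples
#' cfg <- simulationConfig(seed = 1)
#' s <- makeReferenceSpectrum("CG", cfg)
#' preprocess(s, preprocessingConfig())
#' @export
preprocess <- function(spectrum, config = preprocessingConfig()) {
  stopifnot(is(spectrum, "Spectrum"))
  if (!inherits(config, "preprocessingConfig"))
    stopArgument("config must come from preprocessingConfig()")
  y <- spectrum@intensities
  steps <- character(0)
  if (isTRUE(config$smooth)) {
    if (config$window > length(y))
      stopArgument("Savitzky-Golay window exceeds spectrum length")
    y <- signal::sgolayfilt(y, p = config$polyOrder, n = config$window)
    steps <- c(steps, sprintf("sgolay(window=%d,order=%d)",
                              config$window, config$polyOrder))
  }
  if (isTRUE(config$baseline)) {
    y <- y - aslsBaseline(y, config$lambda, config$p, config$iterations)
    steps <- c(steps, sprintf("asls(lambda=%.3g,p=%.3g,iter=%d)",
                              config$lambda, config$p, config$iterations))
  }
  if (config$normalize == "max") {
    mx <- max(y)
    if (mx <= 0) stopNumerical("cannot max-normalize: maximum intensity <= 0")
    y <- y / mx
    steps <- c(steps, "normalize(max)")
  } else if (config$normalize == "area") {
    area <- sum(diff(spectrum@wavenumbers) * (y[-1] + y[-length(y)]) / 2)
    if (area <= 0) stopNumerical("cannot area-normalize: area <= 0")
    y <- y / area
    steps <- c(steps, "normalize(area)")
  }
  meta <- spectrum@meta
  meta$preprocessing <- paste(c(meta$preprocessing, steps), collapse = "; ")
  Spectrum(spectrum@wavenumbers, y, meta)
}
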