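test_that("spectrum files round-trip values and metadata", {
  s <- makeReferenceSpectrum("CG", simulationConfig(seed = 3))
  s@meta$sample <- "rep1"
  path <- tempfile(fileext = ".csv")
  writeSpectrum(s, path)
  r <- readSpectrum(path)
  expect_equal(intensities(r), intensities(s), tolerance = 1e-9)
  expect_equal(wavenumbers(r), wavenumbers(s), tolerance = 1e-9)
  expect_equal(spectrumMeta(r)$sample, "rep1")
})

test_that("a plain two-column file parses to the stated grid", {
  path <- tempfile()
  writeLines(sprintf("%d,0.0", 600:1700), path)
  s <- readSpectrum(path)
  expect_equal(length(s), 1101L)
  expect_true(all(intensities(s) == 0))
})

test_that("spectrum parsing reports bad rows and bad grids", {
  path <- tempfile()
  writeLines(c("600,1.0", "601,2.0", "oops,xx", "603,1.0"), path)
  expect_error(readSpectrum(path), "line 3", class = "msersDataError")
  writeLines(c("600,1.0", "600,2.0", "601,1.0"), path)
  expect_error(readSpectrum(path), "non-monotone", class = "msersDataError")
  expect_error(readSpectrum(tempfile()), "not found", class = "msersDataError")
})

test_that("spectrum bundles round-trip a collection", {
  cfg <- noiselessConfig()
  spectra <- list(a = makeReferenceSpectrum("CG", cfg),
                  b = makeReferenceSpectrum("AT", cfg))
  path <- tempfile(fileext = ".csv")
  writeSpectrumBundle(spectra, path)
  back <- readSpectrumBundle(path)
  expect_named(back, c("a", "b"))
  expect_equal(intensities(back$a), intensities(spectra$a), tolerance = 1e-9)
})

test_that("resampling is exact on shared points and refuses extrapolation", {
  s <- Spectrum(600:700, (600:700) * 0.5)   # linear ramp
  expect_identical(resample(s, wavenumbers(s)), s)
  grid <- seq(610.5, 680.5, by = 2.5)
  r <- resample(s, grid)
  expect_equal(intensities(r), grid * 0.5, tolerance = 1e-12)
  expect_error(resample(s, seq(650, 710, 5)), "beyond source range",
               class = "msersArgumentError")
})

test_that("Spectrum validity catches malformed grids", {
  expect_error(Spectrum(c(1:8, 8:15), rep(0, 16)), "increasing")
  expect_error(Spectrum(1:20, 1:19), "equal length")
  expect_error(Spectrum(1:10, 1:10), "16")
})

test_that("Savitzky-Golay smoothing reproduces polynomials up to its order", {
  w <- 600:700
  x <- (w - 650) / 50
  s <- Spectrum(w, 1 + 2 * x - 0.5 * x^2 + 0.25 * x^3)
  out <- preprocess(s, preprocessingConfig(smooth = TRUE, window = 11L,
                                           polyOrder = 3L, baseline = FALSE,
                                           normalize = "none"))
  expect_equal(intensities(out), intensities(s), tolerance = 1e-9)
  expect_identical(wavenumbers(out), wavenumbers(s))
})

test_that("smoothing conserves the interior mean of smooth spectra", {
  s <- makeReferenceSpectrum("AT", noiselessConfig())
  out <- preprocess(s, preprocessingConfig(baseline = FALSE, normalize = "none"))
  interior <- 20:(length(s) - 20)
  expect_equal(mean(intensities(out)[interior]),
               mean(intensities(s)[interior]), tolerance = 1e-5)
})

test_that("baseline correction recovers a baseline-distorted spectrum", {
  cfg <- noiselessConfig()
  clean <- makeReferenceSpectrum("CG", cfg)
  w <- wavenumbers(clean)
  distorted <- Spectrum(w, intensities(clean) + 0.001 * (w - min(w)))
  prep <- preprocessingConfig(smooth = FALSE, baseline = TRUE,
                              normalize = "none")
  rec <- preprocess(distorted, prep)
  # off-peak regions (>25 cm^-1 from every band) return close to the
  # baseline-free truth, relative to the maximum peak height
  centers <- defaultPeakTable()$center
  offpeak <- vapply(w, function(x) all(abs(x - centers) > 25), logical(1))
  err <- abs(intensities(rec) - intensities(clean))[offpeak]
  expect_lt(max(err) / max(intensities(clean)), 0.06)
})

test_that("baseline correction of a baseline-free spectrum keeps band heights", {
  cfg <- noiselessConfig()
  for (kind in c("CG", "AT")) {
    s <- makeReferenceSpectrum(kind, cfg)
    out <- preprocess(s, preprocessingConfig(smooth = FALSE, baseline = TRUE,
                                             normalize = "none"))
    pk <- defaultPeakTable()
    centers <- pk$center[pk[[paste0("amplitude_",
                                    tolower(kind))]] > 0]
    idx <- match(centers, wavenumbers(s))
    rel <- abs(intensities(out)[idx] - intensities(s)[idx]) /
      intensities(s)[idx]
    expect_lt(max(rel), 0.10)
  }
})

test_that("normalization modes behave and max-normalization is idempotent", {
  s <- makeReferenceSpectrum("CG", noiselessConfig())
  prep <- preprocessingConfig(smooth = FALSE, baseline = FALSE,
                              normalize = "max")
  once <- preprocess(s, prep)
  expect_equal(max(intensities(once)), 1)
  twice <- preprocess(once, prep)
  expect_equal(intensities(twice), intensities(once), tolerance = 1e-15)
  area <- preprocess(s, preprocessingConfig(smooth = FALSE, baseline = FALSE,
                                            normalize = "area"))
  w <- wavenumbers(area); y <- intensities(area)
  expect_equal(sum(diff(w) * (y[-1] + y[-length(y)]) / 2), 1, tolerance = 1e-12)
})

test_that("preprocessing validates its configuration", {
  s <- Spectrum(1:20, rep(1, 20))
  expect_error(preprocessingConfig(window = 10L), "odd",
               class = "msersArgumentError")
  expect_error(preprocessingConfig(window = 5L, polyOrder = 5L),
               class = "msersArgumentError")
  expect_error(preprocess(s, preprocessingConfig(window = 21L)),
               "exceeds", class = "msersArgumentError")
  expect_error(preprocess(s, list()), class = "msersArgumentError")
})

test_that("preprocessing never changes the grid and records its steps", {
  s <- makeReferenceSpectrum("AT", simulationConfig(seed = 8))
  out <- preprocess(s, preprocessingConfig())
  expect_identical(wavenumbers(out), wavenumbers(s))
  expect_match(spectrumMeta(out)$preprocessing, "sgolay")
  expect_match(spectrumMeta(out)$preprocessing, "asls")
  expect_match(spectrumMeta(out)$preprocessing, "normalize")
})
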