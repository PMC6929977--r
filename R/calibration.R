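#' Simulate bisulfite conversion of a DNA strand
#'
#' Applies the bisulfite conversion rule to the top strand of an amplicon:
#' every cytosine that is not a methylated CpG cytosine deaminates to uracil
#' and is read as thymine after PCR; methylated CpG cytosines are protected
#' and remain cytosine. A/G/T positions are untouched.
#'
#' @param sequence character, DNA using the A/C/G/T alphabet
#'   (case-insensitive; returned uppercase).
#' @param methylatedCpG logical vector with one flag per CpG dinucleotide on
#'   the strand, in 5'-to-3' order: TRUE protects that CpG's cytosine.
#' @return The converted sequence, same length as the input.
#' @examples
#' bisulfiteConvert("ACGTC", TRUE)   # methylated CpG retained -> "ACGTT"
#' bisulfiteConvert("ACGTC", FALSE)  # unmethylated CpG converted -> "ATGTT"
#' @export
bisulfiteConvert <- function(sequence, methylatedCpG = logical(0)) {
  if (length(sequence) != 1L || !is.character(sequence))
    stopArgument("sequence must be a single character string")
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  if (length(chars) && !all(chars %in% c("A", "C", "G", "T")))
    stopArgument(sprintf(
      "invalid alphabet: sequence contains characters other than A/C/G/T (%s)",
      paste(unique(setdiff(chars, c("A", "C", "G", "T"))), collapse = ",")))
  n <- length(chars)
  # CpG cytosine positions on this strand
  cpgC <- if (n >= 2L) which(chars[-n] == "C" & chars[-1L] == "G") else integer(0)
  methylatedCpG <- as.logical(methylatedCpG)
  if (length(methylatedCpG) != length(cpgC))
    stopArgument(sprintf(
      "flag count mismatch: sequence has %d CpG site(s) but %d flag(s) given",
      length(cpgC), length(methylatedCpG)))
  out <- chars
  isC <- out == "C"
  protected <- rep(FALSE, n)
  protected[cpgC[methylatedCpG]] <- TRUE
  out[isC & !protected] <- "T"
  paste(out, collapse = "")
}

#' Derive a calibration from an amplicon sequence
#'
#' Counts the amplicon length L, the CpG dinucleotides nCpG on the top
#' strand, and N0 = the number of C:G base pairs remaining in the fully
#' unmethylated converted duplex (every C or G position of
#' `bisulfiteConvert(amplicon, all FALSE)`). Each methylated CpG retains one
#' C:G pair, so the CG base-pair fraction at methylation level m is
#' f(m) = (N0 + m * nCpG) / L.
#'
#' @param geneName character label.
#' @param amplicon character, top strand of the PCR target (A/C/G/T).
#' @return A [GeneCalibration-class].
#' @examples
#' calibrationFromSequence("toy", "TACGGATCGA")  # L=10, nCpG=2, N0=3
#' @export
calibrationFromSequence <- function(geneName, amplicon) {
  chars <- strsplit(toupper(amplicon), "", fixed = TRUE)[[1]]
  L <- length(chars)
  converted <- bisulfiteConvert(amplicon,
    rep(FALSE, cpgCount(amplicon)))
  nCpG <- cpgCount(amplicon)
  if (nCpG < 1L)
    stopArgument(sprintf(
      "degenerate calibration for '%s': amplicon has no CpG site (slope would be zero)",
      geneName))
  conv <- strsplit(converted, "", fixed = TRUE)[[1]]
  N0 <- sum(conv %in% c("C", "G"))
  new("GeneCalibration", geneName = as.character(geneName),
      ampliconLength = as.integer(L), nCpG = as.integer(nCpG),
      cgCountAtZero = as.integer(N0))
}

cpgCount <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 2L) return(0L)
  sum(chars[-n] == "C" & chars[-1L] == "G")
}

#' Read calibrations from a FASTA file of amplicon sequences
#'
#' @param path FASTA file; each record id is used as the gene name.
#' @return A named list of [GeneCalibration-class] objects.
#' @export
calibrationsFromFasta <- function(path) {
  if (!file.exists(path)) stopData(sprintf("FASTA file not found: %s", path))
  seqs <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(seqs), function(i)
    calibrationFromSequence(names(seqs)[i], as.character(seqs[[i]])))
  names(out) <- names(seqs)
  out
}

#' Build a calibration from published constants
#'
#' Instantiates a calibration from the amplicon length, the CpG count, and
#' one printed CG-percentage endpoint (at either 0% or 100% methylation),
#' recovering the integer base-pair count N0 behind the printed fraction.
#' Useful when only the primer table and the printed CG ranges of an assay
#' are available, not the full amplicon sequence.
#'
#' @param geneName character label.
#' @param L amplicon length in bp.
#' @param nCpG number of CpG sites.
#' @param f0,f100 CG base-pair fraction at 0% or 100% methylation; give
#'   exactly one.
#' @param tol rounding tolerance, in base pairs, allowed between
#'   `endpoint * L` and the nearest integer (printed percentages are rounded).
#' @return A [GeneCalibration-class].
#' @examples
#' p16 <- calibrationFromConstants("p16", L = 93, nCpG = 7, f0 = 0.5484)
#' calibrationF100(p16) * 100  # 62.37
#' @export
calibrationFromConstants <- function(geneName, L, nCpG, f0 = NULL,
                                     f100 = NULL, tol = 0.05) {
  if (is.null(f0) == is.null(f100))
    stopArgument("give exactly one of f0 or f100")
  endpoint <- if (is.null(f0)) f100 else f0
  if (!is.numeric(endpoint) || length(endpoint) != 1L ||
      endpoint <= 0 || endpoint > 1)
    stopArgument("endpoint fraction must lie in (0, 1]")
  raw <- endpoint * L
  cgAtEndpoint <- round(raw)
  if (abs(raw - cgAtEndpoint) > tol)
    stopArgument(sprintf(
      "inconsistent constants for '%s': %.4f * %d = %.4f is %.4f bp from an integer (tolerance %.2f)",
      geneName, endpoint, L, raw, abs(raw - cgAtEndpoint), tol))
  N0 <- if (is.null(f0)) cgAtEndpoint - as.integer(nCpG) else cgAtEndpoint
  new("GeneCalibration", geneName = as.character(geneName),
      ampliconLength = as.integer(L), nCpG = as.integer(nCpG),
      cgCountAtZero = as.integer(N0))
}

#' The three study-gene calibrations
#'
#' Calibrations of the p16, MGMT and RASSF1 promoter amplicons used
#' throughout the examples and the verification simulation, built from the
#' published assay constants: p16 93 bp / 7 CpG / f0 54.84%, MGMT 98 bp /
#' 12 CpG / f0 34.69%, RASSF1 136 bp / 12 CpG / f100 46.32%.
#'
#' @return Named list of three [GeneCalibration-class] objects.
#' @examples
#' sapply(studyCalibrations(), calibrationF100) * 100
#' @export
studyCalibrations <- function() {
  list(
    p16    = calibrationFromConstants("p16",    L = 93,  nCpG = 7,  f0   = 0.5484),
    MGMT   = calibrationFromConstants("MGMT",   L = 98,  nCpG = 12, f0   = 0.3469),
    RASSF1 = calibrationFromConstants("RASSF1", L = 136, nCpG = 12, f100 = 0.4632))
}

#' Forward map: CG base-pair fraction at a methylation level
#'
#' f(m) = (N0 + m * nCpG) / L. Levels outside [0, 1] are allowed so that the
#' map composes exactly with its inverse on estimated (possibly negative)
#' levels.
#'
#' @param calib a [GeneCalibration-class].
#' @param m methylation level(s), dimensionless fraction.
#' @return CG base-pair fraction(s).
#' @export
cgFractionAtLevel <- function(calib, m) {
  (calib@cgCountAtZero + m * calib@nCpG) / calib@ampliconLength
}

#' Inverse map: methylation level from a CG base-pair fraction
#'
#' m = (f - f0) / (f100 - f0). Values below 0 or above 1 are returned
#' unclipped; downstream state calling treats negative levels as
#' unmethylated.
#'
#' @param calib a [GeneCalibration-class].
#' @param f CG base-pair fraction(s).
#' @return Methylation level(s), unclipped.
#' @export
methylationFromCgFraction <- function(calib, f) {
  f0 <- calibrationF0(calib)
  (f - f0) / (calibrationF100(calib) - f0)
}

#' Export calibrations as a table
#'
#' @param calibs list of [GeneCalibration-class] objects.
#' @return data.frame with columns gene, L, n_cpg, N0, f0, f100.
#' @export
calibrationTable <- function(calibs) {
  if (is(calibs, "GeneCalibration")) calibs <- list(calibs)
  do.call(rbind, lapply(calibs, function(cc) data.frame(
    gene = cc@geneName, L = cc@ampliconLength, n_cpg = cc@nCpG,
    N0 = cc@cgCountAtZero, f0 = calibrationF0(cc), f100 = calibrationF100(cc),
    stringsAsFactors = FALSE)))
}
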