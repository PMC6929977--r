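# Simulated clinical cohorts: group sizes and clinical-category marginals
# follow the study population (48 NSCLC cases, 51 controls); per-gene
# methylation levels follow zero-inflated truncated normals with
# configurable clinical association effects.

#' Cohort simulation parameters
#'
#' @slot nCancer,nControl integer group sizes.
#' @slot genes character vector of gene names.
#' @slot levelModel list per group ("cancer", "control"), each with elements
#'   `pi` (per-gene probability that the gene is methylated), `posMean`,
#'   `posSd` (truncated-normal positive component on [0.05, 1]).
#' @slot marginals list of named probability vectors for the clinical
#'   categoricals: `gender`, `age`, `packYears` (lists with cancer/control
#'   entries), `stage`, `histology` (cancer only).
#' @slot effects list of clinical association effect sizes (see
#'   [cohortConfig()]).
#' @slot targetAnyGene numeric, design targets: expected fraction of
#'   subjects with at least one methylated gene, per group.
#' @slot seed integer.
#' @export
setClass("CohortConfig",
  representation(nCancer = "integer", nControl = "integer",
                 genes = "character", levelModel = "list",
                 marginals = "list", effects = "list",
                 targetAnyGene = "numeric", seed = "integer"))

setValidity("CohortConfig", function(object) {
  if (object@nCancer < 0L || object@nControl < 0L)
    return("group sizes must be non-negative")
  for (nm in c("gender", "age", "packYears")) {
    for (grp in c("cancer", "control")) {
      p <- object@marginals[[nm]][[grp]]
      if (is.null(p)) return(sprintf("marginals$%s$%s missing", nm, grp))
      if (abs(sum(p) - 1) > 1e-8)
        return(sprintf("marginals$%s$%s must sum to 1", nm, grp))
      if (any(p < 0)) return(sprintf("marginals$%s$%s has negative mass", nm, grp))
    }
  }
  for (nm in c("stage", "histology")) {
    p <- object@marginals[[nm]]
    if (abs(sum(p) - 1) > 1e-8) return(sprintf("marginals$%s must sum to 1", nm))
    if (any(p < 0)) return(sprintf("marginals$%s has negative mass", nm))
  }
  for (grp in c("cancer", "control")) {
    lm <- object@levelModel[[grp]]
    if (is.null(lm)) return(sprintf("levelModel$%s missing", grp))
    if (any(lm$pi < 0 | lm$pi > 1))
      return("methylation probabilities must lie in [0, 1]")
  }
  TRUE
})

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf(
    "CohortConfig: %d cancer + %d control subjects, genes %s, seed=%d\n",
    object@nCancer, object@nControl, paste(object@genes, collapse = "/"),
    object@seed))
})

#' Construct a CohortConfig
#'
#' Defaults emulate the study population: 48 cancer and 51 control subjects
#' with the published clinical-category marginals; independent per-gene
#' methylation with probability 0.5 (cancer) / 0.041 (control) per gene, so
#' the expected any-gene-methylated fractions are 1 - (1-pi)^3 = 87.5% and
#' 11.8%; methylated genes draw their level from a truncated normal on
#' [0.05, 1] whose means put the group mean-level gap near 5 percentage
#' points. Effects: `p16PackYearsShift` adds to the p16 positive-component
#' mean per smoking band (never/moderate/heavy), `p16HistologyShift` adds
#' for large-cell and squamous histology, `rassf1StageDelta` is added
#' to / subtracted from the RASSF1 methylation probability for stage III-IV /
#' I-II cancer subjects.
#'
#' @param nCancer,nControl group sizes.
#' @param genes gene names.
#' @param levelModel,marginals,effects see [CohortConfig-class]; defaults
#'   used where omitted.
#' @param seed integer.
#' @return A [CohortConfig-class].
#' @export
cohortConfig <- function(nCancer = 48L, nControl = 51L,
                         genes = c("p16", "MGMT", "RASSF1"),
                         levelModel = NULL, marginals = NULL, effects = NULL,
                         seed = 1L) {
  ngene <- length(genes)
  if (is.null(levelModel))
    levelModel <- list(
      cancer  = list(pi = rep(0.5, ngene),  posMean = 0.11, posSd = 0.06),
      control = list(pi = rep(0.041, ngene), posMean = 0.08, posSd = 0.03))
  if (is.null(marginals))
    marginals <- list(
      gender = list(cancer  = c(Female = 21, Male = 27) / 48,
                    control = c(Female = 27, Male = 24) / 51),
      age = list(cancer  = c(`1-40` = 6, `41-60` = 7, `61-100` = 35) / 48,
                 control = c(`1-40` = 6, `41-60` = 10, `61-100` = 35) / 51),
      packYears = list(cancer  = c(`0` = 13, `1-20` = 13, `21-100` = 22) / 48,
                       control = c(`0` = 22, `1-20` = 10, `21-100` = 19) / 51),
      stage = c(`I-II` = 15, `III-IV` = 33) / 48,
      histology = c(Adeno = 18, `Large cell` = 6, Squamous = 24) / 48)
  if (is.null(effects))
    effects <- list(p16PackYearsShift = c(`0` = 0, `1-20` = 0.02, `21-100` = 0.04),
                    p16HistologyShift = c(Adeno = 0, `Large cell` = 0.04,
                                          Squamous = 0.04),
                    rassf1StageDelta = 0.15)
  cfg <- tryCatch(new("CohortConfig", nCancer = as.integer(nCancer),
             nControl = as.integer(nControl), genes = genes,
             levelModel = levelModel, marginals = marginals,
             effects = effects,
             targetAnyGene = c(
               cancer  = 1 - prod(1 - levelModel$cancer$pi),
               control = 1 - prod(1 - levelModel$control$pi)),
             seed = as.integer(seed)),
    error = function(e) stopConfig(conditionMessage(e)))
  cfg
}

# Truncated-normal draw on [lo, hi] by inverse-CDF (vectorized, deterministic
# given the RNG stream).
rtruncnorm <- function(n, mean, sd, lo = 0.05, hi = 1) {
  pLo <- stats::pnorm(lo, mean, sd)
  pHi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, pLo, pHi), mean, sd)
}

#' Simulate a clinical cohort
#'
#' Draws, per subject: group, the clinical categoricals from the configured
#' marginals, a per-gene methylation indicator and level from the
#' group-specific zero-inflated truncated normal, with the configured
#' clinical effects (p16 level shifts with smoking and histology, RASSF1
#' methylation frequency with stage). States are called at the 5% threshold.
#'
#' @param config a [CohortConfig-class].
#' @param threshold state-calling threshold on levels (default 0.05).
#' @return data.frame with one row per subject: sample_id, group, gender,
#'   age_band, pack_years_band, stage_band, histology, then per-gene
#'   `level_<gene>` and `state_<gene>` columns.
#' @examples
#' cohort <- simulateCohort(cohortConfig(seed = 11))
#' table(cohort$group)
#' @export
simulateCohort <- function(config = cohortConfig(), threshold = 0.05) {
  stopifnot(is(config, "CohortConfig"))
  n <- config@nCancer + config@nControl
  genes <- config@genes
  withSeed(config@seed, {
    group <- c(rep("cancer", config@nCancer), rep("control", config@nControl))
    drawCat <- function(p, k) sample(names(p), k, replace = TRUE, prob = p)
    gender <- age <- pack <- stage <- histology <- character(n)
    for (grp in c("cancer", "control")) {
      sel <- group == grp
      gender[sel] <- drawCat(config@marginals$gender[[grp]], sum(sel))
      age[sel]    <- drawCat(config@marginals$age[[grp]], sum(sel))
      pack[sel]   <- drawCat(config@marginals$packYears[[grp]], sum(sel))
    }
    isCa <- group == "cancer"
    stage[!isCa] <- NA_character_; histology[!isCa] <- NA_character_
    if (any(isCa)) {
      stage[isCa]     <- drawCat(config@marginals$stage, sum(isCa))
      histology[isCa] <- drawCat(config@marginals$histology, sum(isCa))
    }
    levels <- matrix(0, n, length(genes), dimnames = list(NULL, genes))
    for (j in seq_along(genes)) {
      gene <- genes[j]
      for (i in seq_len(n)) {
        lm <- config@levelModel[[group[i]]]
        pi <- lm$pi[j]
        mu <- lm$posMean
        if (gene == "RASSF1" && group[i] == "cancer" && !is.na(stage[i])) {
          d <- config@effects$rassf1StageDelta
          pi <- min(1, max(0, pi + if (stage[i] == "III-IV") d else -d))
        }
        if (gene == "p16") {
          mu <- mu + unname(config@effects$p16PackYearsShift[pack[i]])
          if (group[i] == "cancer" && !is.na(histology[i]))
            mu <- mu + unname(config@effects$p16HistologyShift[histology[i]])
        }
        if (stats::runif(1) < pi)
          levels[i, j] <- rtruncnorm(1, mu, lm$posSd)
      }
    }
    df <- data.frame(
      sample_id = sprintf("S%03d", seq_len(n)), group = group,
      gender = gender, age_band = age, pack_years_band = pack,
      stage_band = stage, histology = histology, stringsAsFactors = FALSE)
    for (gene in genes) {
      df[[paste0("level_", gene)]] <- levels[, gene]
      df[[paste0("state_", gene)]] <- ifelse(levels[, gene] >= threshold,
                                             "methylated", "unmethylated")
    }
    df
  })
}

#' Design target for any-gene methylation frequency
#'
#' @param config a [CohortConfig-class].
#' @return Named numeric: expected fraction of subjects with at least one
#'   methylated gene, per group, implied by the configured per-gene
#'   methylation probabilities.
#' @export
anyGeneTargets <- function(config) config@targetAnyGene
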