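#' @import methods
NULL

#' Harmonized instrument set
#'
#' Holds, for each instrumental SNP, the exposure effect \eqn{\gamma_i} and
#' outcome effect \eqn{\alpha_i} aligned to a shared effect allele, together
#' with their standard errors and the bookkeeping flags produced during
#' harmonization. SNPs excluded on the way (irreconcilable alleles,
#' strand-ambiguous palindromes) are carried in the \code{exclusions} slot so
#' that input SNPs are always accounted for.
#'
#' @slot rsid character SNP identifiers.
#' @slot effectAllele,otherAllele shared allele coding after alignment.
#' @slot gamma,seGamma SNP-exposure effects and standard errors.
#' @slot alpha,seAlpha SNP-outcome effects and standard errors.
#' @slot eafExposure,eafOutcome effect-allele frequencies (NA when absent).
#' @slot flipped logical; outcome effect was sign-flipped during alignment.
#' @slot palindromic logical; allele pair is A/T or C/G.
#' @slot exclusions data.frame with columns \code{rsid}, \code{reason}.
#'
#' @export
setClass("HarmonizedInstruments",
  representation(
    rsid = "character",
    effectAllele = "character",
    otherAllele = "character",
    gamma = "numeric",
    seGamma = "numeric",
    alpha = "numeric",
    seAlpha = "numeric",
    eafExposure = "numeric",
    eafOutcome = "numeric",
    flipped = "logical",
    palindromic = "logical",
    exclusions = "data.frame"
  ),
  prototype(exclusions = data.frame(rsid = character(), reason = character(),
                                    stringsAsFactors = FALSE))
)

setValidity("HarmonizedInstruments", function(object) {
  n <- length(object@rsid)
  lens <- c(
    length(object@effectAllele), length(object@otherAllele),
    length(object@gamma), length(object@seGamma),
    length(object@alpha), length(object@seAlpha),
    length(object@eafExposure), length(object@eafOutcome),
    length(object@flipped), length(object@palindromic)
  )
  if (any(lens != n)) return("all per-SNP slots must have equal length")
  if (any(!is.na(object@seGamma) & object@seGamma <= 0)) return("seGamma must be > 0")
  if (any(!is.na(object@seAlpha) & object@seAlpha <= 0)) return("seAlpha must be > 0")
  if (anyDuplicated(object@rsid)) return("rsid must be unique")
  if (!all(c("rsid", "reason") %in% names(object@exclusions)))
    return("exclusions must have columns rsid, reason")
  TRUE
})

#' One method's causal estimate
#'
#' A causal-effect estimate on the log-odds scale with its standard error,
#' 95\% confidence interval, odds-ratio transform and two-sided p-value.
#' \code{se} and the intervals may be NA for bootstrap-based estimators run
#' with \code{nBoot = 0}.
#'
#' @slot method character method label (e.g. "IVW (random)").
#' @slot beta,se estimate and standard error on the log-odds scale.
#' @slot ciLow,ciHigh 95\% confidence limits on the log-odds scale.
#' @slot oddsRatio,orCiLow,orCiHigh exponentiated estimate and limits.
#' @slot pval two-sided normal p-value.
#' @slot nSnps number of instruments used.
#'
#' @export
setClass("MREstimate",
  representation(
    method = "character",
    beta = "numeric",
    se = "numeric",
    ciLow = "numeric",
    ciHigh = "numeric",
    oddsRatio = "numeric",
    orCiLow = "numeric",
    orCiHigh = "numeric",
    pval = "numeric",
    nSnps = "integer"
  )
)

setValidity("MREstimate", function(object) {
  if (length(object@beta) != 1L) return("beta must be length 1")
  if (!is.na(object@se) && object@se < 0) return("se must be >= 0")
  if (!is.na(object@ciLow) && !is.na(object@ciHigh) &&
      !(object@ciLow <= object@beta && object@beta <= object@ciHigh))
    return("ci must bracket beta")
  if (!is.na(object@oddsRatio) &&
      abs(object@oddsRatio - exp(object@beta)) > 1e-8 * max(1, object@oddsRatio))
    return("oddsRatio must equal exp(beta)")
  TRUE
})

#' MR-Egger pleiotropy intercept
#'
#' The intercept \eqn{\beta_0} of the MR-Egger regression: the estimated
#' average directional pleiotropic effect across instruments. An intercept
#' p-value above 0.05 is conventionally read as no evidence of horizontal
#' pleiotropy.
#'
#' @slot intercept,se estimate and standard error.
#' @slot ciLow,ciHigh 95\% confidence limits.
#' @slot pval two-sided normal p-value.
#'
#' @export
setClass("PleiotropyResult",
  representation(
    intercept = "numeric",
    se = "numeric",
    ciLow = "numeric",
    ciHigh = "numeric",
    pval = "numeric"
  )
)

setValidity("PleiotropyResult", function(object) {
  if (!(object@ciLow <= object@intercept && object@intercept <= object@ciHigh))
    return("ci must bracket intercept")
  if (object@se <= 0) return("se must be > 0")
  TRUE
})

#' Cochran's Q heterogeneity result
#'
#' @slot method "IVW" or "MR Egger".
#' @slot q Cochran's Q statistic.
#' @slot qDf degrees of freedom (J - 1 for IVW, J - 2 for Egger).
#' @slot qPval upper-tail chi-square probability.
#'
#' @export
setClass("HeterogeneityResult",
  representation(
    method = "character",
    q = "numeric",
    qDf = "integer",
    qPval = "numeric"
  )
)

setValidity("HeterogeneityResult", function(object) {
  if (object@q < 0) return("q must be >= 0")
  if (object@qDf < 0) return("qDf must be >= 0")
  TRUE
})

#' Leave-one-out sensitivity result
#'
#' @slot omitted character rsids, one per sub-estimate.
#' @slot estimates list of \linkS4class{MREstimate}, each omitting one SNP.
#' @slot full the all-SNP \linkS4class{MREstimate} for comparison.
#'
#' @export
setClass("LeaveOneOutResult",
  representation(
    omitted = "character",
    estimates = "list",
    full = "MREstimate"
  )
)

setValidity("LeaveOneOutResult", function(object) {
  if (length(object@omitted) != length(object@estimates))
    return("one estimate per omitted SNP required")
  if (!all(vapply(object@estimates, is, logical(1), "MREstimate")))
    return("estimates must all be MREstimate")
  TRUE
})

#' Instrument strength summary
#'
#' Per-SNP F statistics \eqn{(\beta/se)^2}, the variance in the exposure
#' explained by the instruments \eqn{R^2 = \sum 2 f_j (1-f_j) \beta_j^2}
#' (standardized-trait approximation), and the aggregate F statistic
#' \eqn{((n-k-1)/k) R^2/(1-R^2)}. The aggregate is NA when effect-allele
#' frequencies are missing.
#'
#' @slot perSnpF numeric per-SNP F statistics.
#' @slot meanF mean of \code{perSnpF}.
#' @slot r2Explained exposure variance explained, NA without eaf.
#' @slot aggregateF aggregate F, NA without eaf.
#'
#' @export
setClass("InstrumentStrength",
  representation(
    perSnpF = "numeric",
    meanF = "numeric",
    r2Explained = "numeric",
    aggregateF = "numeric"
  )
)

setValidity("InstrumentStrength", function(object) {
  if (length(object@perSnpF) &&
      abs(object@meanF - mean(object@perSnpF)) > 1e-10 * max(1, abs(object@meanF)))
    return("meanF must equal mean(perSnpF)")
  TRUE
})

#' Simulation configuration
#'
#' Parameters of the two-sample summary-statistics generator. Exposure
#' effects \eqn{\gamma_j} have magnitude drawn from
#' Normal(gammaMean, gammaSd); outcome effects are
#' \eqn{\alpha_j = \beta \gamma_j + \delta_j} with per-SNP direct
#' (pleiotropic) effects \eqn{\delta_j ~ Normal(pleioMean, pleioSd)}.
#' Standard errors follow the per-allele approximation
#' \eqn{1/\sqrt{2 f (1-f) n}}.
#'
#' @slot nSnps number of instruments J.
#' @slot betaTrue true causal effect (log-odds scale).
#' @slot gammaMean,gammaSd magnitude distribution of exposure effects.
#' @slot mafLow,mafHigh minor-allele-frequency bounds (Uniform draw).
#' @slot nExposure,nOutcome GWAS sample sizes of the two non-overlapping samples.
#' @slot pleioMean,pleioSd directional mean and spread of direct effects.
#' @slot insideViolation logical; make \eqn{\delta_j} depend linearly on \eqn{\gamma_j}.
#' @slot gammaSigns "random" or "positive" orientation of exposure effects.
#' @slot nPalindromic how many SNPs receive A/T or C/G allele pairs.
#' @slot seed integer RNG seed.
#'
#' @export
setClass("SimulationConfig",
  representation(
    nSnps = "integer",
    betaTrue = "numeric",
    gammaMean = "numeric",
    gammaSd = "numeric",
    mafLow = "numeric",
    mafHigh = "numeric",
    nExposure = "integer",
    nOutcome = "integer",
    pleioMean = "numeric",
    pleioSd = "numeric",
    insideViolation = "logical",
    gammaSigns = "character",
    nPalindromic = "integer",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  if (object@nSnps < 1L) return("nSnps must be >= 1")
  if (object@gammaSd < 0 || object@pleioSd < 0) return("sds must be >= 0")
  if (!(object@mafLow > 0 && object@mafLow <= object@mafHigh && object@mafHigh < 1))
    return("need 0 < mafLow <= mafHigh < 1")
  if (object@nExposure < 1L || object@nOutcome < 1L) return("sample sizes must be >= 1")
  if (!object@gammaSigns %in% c("random", "positive"))
    return("gammaSigns must be 'random' or 'positive'")
  if (object@nPalindromic < 0L || object@nPalindromic > object@nSnps)
    return("nPalindromic must be in [0, nSnps]")
  TRUE
})

#' Simulation ground truth
#'
#' The generating parameters and per-SNP latent effects behind one simulated
#' exposure/outcome pair, kept for recovery tests.
#'
#' @slot config the \linkS4class{SimulationConfig} used.
#' @slot gamma,delta per-SNP true exposure effects and direct effects.
#' @slot betaTrue the true causal effect.
#' @slot seed the seed used.
#'
#' @export
setClass("SimulationTruth",
  representation(
    config = "SimulationConfig",
    gamma = "numeric",
    delta = "numeric",
    betaTrue = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationTruth", function(object) {
  if (length(object@gamma) != object@config@nSnps ||
      length(object@delta) != object@config@nSnps)
    return("per-SNP truth vectors must have length nSnps")
  TRUE
})

#' Full analysis bundle
#'
#' Everything one pipeline run produces: the per-method causal estimates,
#' the Egger pleiotropy intercept, IVW and Egger heterogeneity tests,
#' leave-one-out estimates, the per-SNP Wald-ratio table, instrument
#' strength, and the stage-by-stage exclusion ledger.
#'
#' @slot estimates named list of \linkS4class{MREstimate}.
#' @slot pleiotropy \linkS4class{PleiotropyResult} or NULL (J < 3).
#' @slot heterogeneity list of \linkS4class{HeterogeneityResult}.
#' @slot leaveOneOut \linkS4class{LeaveOneOutResult} or NULL.
#' @slot waldTable data.frame of per-SNP ratios and SEs.
#' @slot strength \linkS4class{InstrumentStrength} or NULL.
#' @slot instruments the \linkS4class{HarmonizedInstruments} analysed.
#' @slot ledger data.frame of per-stage input/output/excluded counts.
#' @slot config list echo of the run configuration.
#'
#' @export
setClass("MRAnalysis",
  representation(
    estimates = "list",
    pleiotropy = "ANY",
    heterogeneity = "list",
    leaveOneOut = "ANY",
    waldTable = "data.frame",
    strength = "ANY",
    instruments = "HarmonizedInstruments",
    ledger = "data.frame",
    config = "list"
  )
)

setValidity("MRAnalysis", function(object) {
  if (!all(vapply(object@estimates, is, logical(1), "MREstimate")))
    return("estimates must all be MREstimate")
  j <- length(object@instruments@rsid)
  ns <- vapply(object@estimates, function(e) e@nSnps, integer(1))
  if (length(ns) && any(ns != j))
    return("every estimate's nSnps must equal the harmonized instrument count")
  TRUE
})
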