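#' Number of instruments
#' @param x a \linkS4class{HarmonizedInstruments} object
#' @return integer count of retained SNPs
#' @export
setGeneric("nInstruments", function(x) standardGeneric("nInstruments"))

#' @rdname nInstruments
#' @export
setMethod("nInstruments", "HarmonizedInstruments", function(x) length(x@rsid))

#' Exclusion report accessor
#' @param x a \linkS4class{HarmonizedInstruments} object
#' @return data.frame with columns \code{rsid}, \code{reason}
#' @export
setGeneric("exclusions", function(x) standardGeneric("exclusions"))

#' @rdname exclusions
#' @export
setMethod("exclusions", "HarmonizedInstruments", function(x) x@exclusions)

#' @export
setMethod("length", "HarmonizedInstruments", function(x) length(x@rsid))

#' Subset an instrument set
#'
#' Standard single-bracket subsetting over SNPs; the exclusion report is
#' carried through unchanged.
#'
#' @param x a \linkS4class{HarmonizedInstruments} object
#' @param i index vector
#' @param j,...,drop ignored
#' @export
setMethod("[", "HarmonizedInstruments", function(x, i, j, ..., drop = FALSE) {
  new("HarmonizedInstruments",
      rsid = x@rsid[i], effectAllele = x@effectAllele[i],
      otherAllele = x@otherAllele[i],
      gamma = x@gamma[i], seGamma = x@seGamma[i],
      alpha = x@alpha[i], seAlpha = x@seAlpha[i],
      eafExposure = x@eafExposure[i], eafOutcome = x@eafOutcome[i],
      flipped = x@flipped[i], palindromic = x@palindromic[i],
      exclusions = x@exclusions)
})

#' @export
setMethod("as.data.frame", "HarmonizedInstruments", function(x, ...) {
  data.frame(rsid = x@rsid, effect_allele = x@effectAllele,
             other_allele = x@otherAllele,
             gamma = x@gamma, se_gamma = x@seGamma,
             alpha = x@alpha, se_alpha = x@seAlpha,
             eaf_exposure = x@eafExposure, eaf_outcome = x@eafOutcome,
             flipped = x@flipped, palindromic = x@palindromic,
             stringsAsFactors = FALSE)
})

#' @export
setMethod("as.data.frame", "MREstimate", function(x, ...) {
  data.frame(method = x@method, nsnp = x@nSnps, beta = x@beta, se = x@se,
             ci_low = x@ciLow, ci_high = x@ciHigh,
             or = x@oddsRatio, or_ci_low = x@orCiLow, or_ci_high = x@orCiHigh,
             pval = x@pval, stringsAsFactors = FALSE)
})

setMethod("show", "HarmonizedInstruments", function(object) {
  cat("HarmonizedInstruments with", length(object@rsid), "SNPs",
      sprintf("(%d flipped, %d palindromic, %d excluded)\n",
              sum(object@flipped), sum(object@palindromic),
              nrow(object@exclusions)))
  if (length(object@rsid)) {
    df <- as.data.frame(object)
    print(utils::head(df, 6L), row.names = FALSE)
    if (nrow(df) > 6L) cat("...", nrow(df) - 6L, "more SNPs\n")
  }
  invisible(object)
})

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("%s estimate (%d SNPs)\n", object@method, object@nSnps))
  cat(sprintf("  beta = %.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
              object@beta, object@se, object@ciLow, object@ciHigh, object@pval))
  cat(sprintf("  OR = %.4f, 95%% CI [%.4f, %.4f]\n",
              object@oddsRatio, object@orCiLow, object@orCiHigh))
  invisible(object)
})

setMethod("show", "PleiotropyResult", function(object) {
  cat(sprintf("MR-Egger intercept %.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
              object@intercept, object@se, object@ciLow, object@ciHigh,
              object@pval))
  cat(if (object@pval > 0.05) "  no evidence of horizontal pleiotropy (p > 0.05)\n"
      else "  evidence of horizontal pleiotropy (p <= 0.05)\n")
  invisible(object)
})

setMethod("show", "HeterogeneityResult", function(object) {
  cat(sprintf("Cochran's Q (%s): Q = %.3f, df = %d, p = %.3g\n",
              object@method, object@q, object@qDf, object@qPval))
  invisible(object)
})

setMethod("show", "LeaveOneOutResult", function(object) {
  cat("Leave-one-out analysis over", length(object@omitted), "SNPs\n")
  b <- vapply(object@estimates, function(e) e@beta, numeric(1))
  cat(sprintf("  sub-estimate range [%.4f, %.4f]; full estimate %.4f\n",
              min(b), max(b), object@full@beta))
  invisible(object)
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nSnps, "SNPs, true beta", object@betaTrue, "\n")
  cat(sprintf("  gamma ~ %s|N(%.3g, %.3g)|, maf ~ U(%.2f, %.2f)\n",
              if (object@gammaSigns == "random") "+/-" else "",
              object@gammaMean, object@gammaSd, object@mafLow, object@mafHigh))
  cat(sprintf("  pleiotropy N(%.3g, %.3g)%s, n_exp = %d, n_out = %d, seed = %d\n",
              object@pleioMean, object@pleioSd,
              if (object@insideViolation) " (InSIDE violated)" else "",
              object@nExposure, object@nOutcome, object@seed))
  invisible(object)
})

setMethod("show", "MRAnalysis", function(object) {
  cat("MRAnalysis of", length(object@instruments@rsid), "harmonized instruments\n")
  for (e in object@estimates)
    cat(sprintf("  %-28s beta %8.4f  se %7.4f  OR %6.3f  p %.3g\n",
                e@method, e@beta, e@se, e@oddsRatio, e@pval))
  if (!is.null(object@pleiotropy))
    cat(sprintf("  Egger intercept %.4f (p = %.3g)\n",
                object@pleiotropy@intercept, object@pleiotropy@pval))
  for (h in object@heterogeneity)
    cat(sprintf("  Q (%s) = %.3f on %d df, p = %.3g\n",
                h@method, h@q, h@qDf, h@qPval))
  invisible(object)
})
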