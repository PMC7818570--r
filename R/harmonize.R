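COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Align exposure and outcome records to a shared effect allele
#'
#' Joins the two record sets on rsid and reconciles allele coding. If the
#' outcome alleles match the exposure alleles the outcome effect is kept;
#' if they are swapped, the outcome beta is sign-flipped and its
#' effect-allele frequency reflected (1 - eaf); if they are the strand
#' complement of the exposure alleles they are complemented first and the
#' same logic applied; anything else is excluded as irreconcilable.
#' Palindromic (A/T, C/G) SNPs are flagged. Harmonization is involutive:
#' running it on already-aligned records changes nothing.
#'
#' @param exposure,outcome canonical summary-statistic data.frames.
#' @return a \linkS4class{HarmonizedInstruments}; SNPs excluded during
#'   alignment appear in \code{exclusions(x)}.
#' @export
harmonize <- function(exposure, outcome) {
  shared <- intersect(exposure$rsid, outcome$rsid)
  ex <- exposure[match(shared, exposure$rsid), , drop = FALSE]
  ou <- outcome[match(shared, outcome$rsid), , drop = FALSE]

  n <- length(shared)
  keep <- logical(n)
  flip <- logical(n)
  reason <- character(n)
  for (i in seq_len(n)) {
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ou$effect_allele[i]; oa_y <- ou$other_allele[i]
    if (ea_y == ea_x && oa_y == oa_x) {
      keep[i] <- TRUE
    } else if (ea_y == oa_x && oa_y == ea_x) {
      keep[i] <- TRUE; flip[i] <- TRUE
    } else {
      ca <- COMPLEMENT[[ea_y]]; co <- COMPLEMENT[[oa_y]]
      if (ca == ea_x && co == oa_x) {
        keep[i] <- TRUE
      } else if (ca == oa_x && co == ea_x) {
        keep[i] <- TRUE; flip[i] <- TRUE
      } else {
        reason[i] <- "irreconcilable alleles"
      }
    }
  }

  alpha <- ifelse(flip, -ou$beta, ou$beta)
  eafOut <- ifelse(flip, 1 - ou$eaf, ou$eaf)
  palindromic <- ex$effect_allele == COMPLEMENT[ex$other_allele]

  excl <- data.frame(rsid = shared[!keep], reason = reason[!keep],
                     stringsAsFactors = FALSE)
  obj <- new("HarmonizedInstruments",
             rsid = shared[keep],
             effectAllele = ex$effect_allele[keep],
             otherAllele = ex$other_allele[keep],
             gamma = ex$beta[keep], seGamma = ex$se[keep],
             alpha = alpha[keep], seAlpha = ou$se[keep],
             eafExposure = ex$eaf[keep], eafOutcome = eafOut[keep],
             flipped = flip[keep], palindromic = unname(palindromic[keep]),
             exclusions = excl)
  stopIfNot(length(obj@rsid) > 0, "no instruments survive harmonization")
  obj
}

#' Remove strand-ambiguous palindromic SNPs
#'
#' Removes palindromic instruments whose exposure-side minor allele
#' frequency, min(eaf, 1 - eaf), is strictly greater than
#' \code{mafThreshold}: near 0.5 the strand cannot be resolved from
#' frequency. Palindromic SNPs without an exposure eaf are removed with
#' reason "indeterminate strand". Non-palindromic SNPs are always retained;
#' palindromes at or below the threshold are retained under the
#' forward-strand assumption.
#'
#' @param instruments a \linkS4class{HarmonizedInstruments}.
#' @param mafThreshold removal threshold on the minor-allele frequency
#'   (default 0.3).
#' @return a \linkS4class{HarmonizedInstruments} with the removals appended
#'   to the exclusion report.
#' @export
dropPalindromic <- function(instruments, mafThreshold = 0.3) {
  maf <- pmin(instruments@eafExposure, 1 - instruments@eafExposure)
  noEaf <- instruments@palindromic & is.na(maf)
  highMaf <- instruments@palindromic & !is.na(maf) & maf > mafThreshold
  drop <- noEaf | highMaf
  excl <- rbind(
    instruments@exclusions,
    data.frame(rsid = instruments@rsid[drop],
               reason = ifelse(noEaf[drop], "indeterminate strand",
                               sprintf("palindromic with MAF > %g", mafThreshold)),
               stringsAsFactors = FALSE))
  out <- instruments[!drop]
  out@exclusions <- excl
  out
}
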