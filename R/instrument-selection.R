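#' Instrument-selection configuration
#'
#' Thresholds of the instrument-selection pipeline: genome-wide significance
#' (strictly below \code{pThreshold}), LD clumping (strictly above
#' \code{clumpR2} excluded), proxy substitution (strictly above
#' \code{proxyR2Min} accepted) and the palindromic minor-allele-frequency
#' rule (strictly above \code{palindromeMafThreshold} removed).
#'
#' @param pThreshold genome-wide significance threshold.
#' @param clumpR2 LD r-squared above which SNPs are clumped away.
#' @param proxyR2Min minimum proxy r-squared.
#' @param palindromeMafThreshold palindromic MAF removal threshold.
#' @param blacklist character vector of confounder-associated rsids.
#' @return list of class \code{SelectionConfig}.
#' @export
selectionConfig <- function(pThreshold = 5e-8, clumpR2 = 0.001,
                            proxyR2Min = 0.8, palindromeMafThreshold = 0.3,
                            blacklist = character()) {
  stopIfNot(pThreshold > 0 && pThreshold < 1, "pThreshold must be in (0,1)")
  stopIfNot(clumpR2 >= 0 && clumpR2 < proxyR2Min && proxyR2Min <= 1,
            "need 0 <= clumpR2 < proxyR2Min <= 1")
  structure(list(pThreshold = pThreshold, clumpR2 = clumpR2,
                 proxyR2Min = proxyR2Min,
                 palindromeMafThreshold = palindromeMafThreshold,
                 blacklist = as.character(blacklist)),
            class = "SelectionConfig")
}

#' Genome-wide significance filter
#'
#' Keeps records with p-value strictly below the threshold, preserving
#' input order.
#'
#' @param records canonical summary-statistic data.frame.
#' @param pThreshold significance threshold (default 5e-8).
#' @return filtered data.frame.
#' @export
filterGenomeWide <- function(records, pThreshold = 5e-8) {
  out <- records[records$pval < pThreshold, , drop = FALSE]
  stopIfNot(nrow(out) > 0,
            sprintf("no SNP passes the genome-wide threshold p < %g", pThreshold))
  rownames(out) <- NULL
  out
}

# symmetric lookup of r2 for one rsid against a set; absent pairs are 0
ldAgainst <- function(ld, rsid, others) {
  r2 <- stats::setNames(rep(0, length(others)), others)
  hit <- ld$rsid_a == rsid & ld$rsid_b %in% others
  r2[ld$rsid_b[hit]] <- pmax(r2[ld$rsid_b[hit]], ld$r2[hit])
  hit <- ld$rsid_b == rsid & ld$rsid_a %in% others
  r2[ld$rsid_a[hit]] <- pmax(r2[ld$rsid_a[hit]], ld$r2[hit])
  r2
}

#' Greedy LD clumping
#'
#' Repeatedly takes the unclaimed SNP with the lowest p-value as an index
#' SNP and discards every remaining SNP with r-squared strictly above
#' \code{clumpR2} against any retained index. Equal-p ties break
#' lexicographically by rsid; pairs absent from the LD table count as
#' unlinked (r2 = 0). Retained SNPs are returned in original file order.
#'
#' @param records canonical summary-statistic data.frame.
#' @param ld LD data.frame with columns rsid_a, rsid_b, r2.
#' @param clumpR2 exclusion threshold (default 0.001).
#' @return clumped data.frame with attribute \code{clumped} naming the
#'   discarded rsids.
#' @export
ldClump <- function(records, ld, clumpR2 = 0.001) {
  if (is.null(ld) || nrow(ld) == 0) {
    attr(records, "clumped") <- character(0)
    return(records)
  }
  ord <- order(records$pval, records$rsid)
  queue <- records$rsid[ord]
  kept <- character(0)
  dropped <- character(0)
  while (length(queue)) {
    idx <- queue[1]
    kept <- c(kept, idx)
    queue <- queue[-1]
    if (length(queue)) {
      r2 <- ldAgainst(ld, idx, queue)
      gone <- names(r2)[r2 > clumpR2]
      dropped <- c(dropped, gone)
      queue <- setdiff(queue, gone)
    }
  }
  out <- records[records$rsid %in% kept, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "clumped") <- dropped
  out
}

#' Proxy substitution for instruments missing from the outcome set
#'
#' Each requested rsid absent from \code{available} is replaced by its
#' highest-r2 proxy with r2 strictly above \code{proxyR2Min} that is present
#' in \code{available}; ties break lexicographically. Unresolvable SNPs are
#' reported as dropped, never fatal.
#'
#' @param requested character vector of instrument rsids.
#' @param available character vector of rsids present in the outcome data.
#' @param proxies data.frame with columns rsid, proxy_rsid, r2.
#' @param proxyR2Min minimum acceptable proxy r-squared (default 0.8).
#' @return list with \code{mapping} (data.frame requested/used) and
#'   \code{dropped} (character vector).
#' @export
substituteProxies <- function(requested, available, proxies = NULL,
                              proxyR2Min = 0.8) {
  used <- stats::setNames(as.character(requested), requested)
  dropped <- character(0)
  for (snp in requested) {
    if (snp %in% available) next
    cand <- if (is.null(proxies)) data.frame() else
      proxies[proxies$rsid == snp & proxies$r2 > proxyR2Min &
              proxies$proxy_rsid %in% available, , drop = FALSE]
    if (nrow(cand) == 0) {
      used[snp] <- NA_character_
      dropped <- c(dropped, snp)
    } else {
      cand <- cand[order(-cand$r2, cand$proxy_rsid), , drop = FALSE]
      used[snp] <- cand$proxy_rsid[1]
    }
  }
  mapping <- data.frame(requested = as.character(requested),
                        used = unname(used[as.character(requested)]),
                        stringsAsFactors = FALSE)
  if (length(dropped))
    message("substituteProxies: ", length(dropped),
            " SNP(s) without an acceptable proxy dropped: ",
            paste(dropped, collapse = ", "))
  list(mapping = mapping[!is.na(mapping$used), , drop = FALSE],
       dropped = dropped)
}

#' Remove confounder-associated SNPs
#'
#' Drops records whose rsid appears on the blacklist (SNPs known to
#' associate with confounders of the exposure-outcome relation, e.g. from a
#' GWAS-Catalog lookup).
#'
#' @param records canonical summary-statistic data.frame.
#' @param blacklist character vector of rsids.
#' @return filtered data.frame with attribute \code{removed}.
#' @export
excludeConfounders <- function(records, blacklist = character()) {
  hit <- records$rsid %in% blacklist
  if (any(hit))
    message("excludeConfounders: removed ", sum(hit), " blacklisted SNP(s): ",
            paste(records$rsid[hit], collapse = ", "))
  out <- records[!hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- records$rsid[hit]
  out
}

#' Instrument-strength statistics
#'
#' Per-SNP F statistics \eqn{(\beta_j/se_j)^2}; the exposure variance
#' explained \eqn{R^2 = \sum_j 2 f_j (1-f_j) \beta_j^2} when effect-allele
#' frequencies are present; and the aggregate
#' \eqn{F = ((n-k-1)/k)\, R^2/(1-R^2)}. With any eaf missing the aggregate
#' is reported as NA while per-SNP F values are still returned.
#'
#' @param records canonical summary-statistic data.frame (exposure side).
#' @param nExposure exposure GWAS sample size.
#' @param k instrument count (defaults to \code{nrow(records)}).
#' @return an \linkS4class{InstrumentStrength}.
#' @export
instrumentStrength <- function(records, nExposure, k = nrow(records)) {
  stopIfNot(all(records$se > 0), "instrumentStrength needs se > 0")
  perF <- (records$beta / records$se)^2
  if (any(is.na(records$eaf))) {
    r2 <- NA_real_
    aggF <- NA_real_
  } else {
    r2 <- sum(2 * records$eaf * (1 - records$eaf) * records$beta^2)
    aggF <- ((nExposure - k - 1) / k) * r2 / (1 - r2)
  }
  new("InstrumentStrength", perSnpF = perF, meanF = mean(perF),
      r2Explained = r2, aggregateF = aggF)
}

#' Full instrument-selection pipeline
#'
#' Applies, in fixed order: the genome-wide p-value filter, confounder
#' exclusion, and greedy LD clumping. Per-stage counts are recorded in the
#' \code{ledger} attribute.
#'
#' @param records canonical exposure summary-statistic data.frame.
#' @param config a \code{\link{selectionConfig}}.
#' @param ld optional LD data.frame for clumping.
#' @return selected instruments with a \code{ledger} attribute (data.frame
#'   stage/n_in/n_out/n_excluded).
#' @export
selectInstruments <- function(records, config = selectionConfig(), ld = NULL) {
  ledger <- data.frame(stage = character(), n_in = integer(),
                       n_out = integer(), n_excluded = integer(),
                       stringsAsFactors = FALSE)
  note <- function(stage, nin, nout) {
    ledger <<- rbind(ledger, data.frame(stage = stage, n_in = nin,
                                        n_out = nout,
                                        n_excluded = nin - nout))
  }
  s1 <- filterGenomeWide(records, config$pThreshold)
  note("genome_wide_filter", nrow(records), nrow(s1))
  s2 <- excludeConfounders(s1, config$blacklist)
  note("confounder_exclusion", nrow(s1), nrow(s2))
  s3 <- ldClump(s2, ld, config$clumpR2)
  note("ld_clumping", nrow(s2), nrow(s3))
  attr(s3, "ledger") <- ledger
  s3
}
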