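#' Column dialect of a summary-statistics file
#'
#' Maps the canonical field names (\code{rsid}, \code{effect_allele},
#' \code{other_allele}, \code{eaf}, \code{beta}, \code{se}, \code{pval},
#' \code{n}) to the column headers used by a particular source file, plus the
#' missing-value sentinel. Every canonical field except \code{eaf} and
#' \code{n} must be mapped; set \code{eaf} or \code{n} to \code{NA} if the
#' source lacks them.
#'
#' @param rsid,effect_allele,other_allele,eaf,beta,se,pval,n column headers
#'   in the source file.
#' @param na missing-value sentinel string.
#' @return a list of class \code{ColumnDialect}.
#' @examples
#' d <- columnDialect(rsid = "SNP", beta = "Effect", se = "StdErr",
#'                    pval = "P", effect_allele = "A1", other_allele = "A2")
#' @export
columnDialect <- function(rsid = "rsid", effect_allele = "effect_allele",
                          other_allele = "other_allele", eaf = "eaf",
                          beta = "beta", se = "se", pval = "pval", n = "n",
                          na = "NA") {
  d <- list(rsid = rsid, effect_allele = effect_allele,
            other_allele = other_allele, eaf = eaf, beta = beta, se = se,
            pval = pval, n = n, na = na)
  mandatory <- c("rsid", "effect_allele", "other_allele", "beta", "se", "pval")
  for (f in mandatory)
    stopIfNot(is.character(d[[f]]) && !is.na(d[[f]]) && nzchar(d[[f]]),
              paste0("mandatory field '", f, "' must be mapped to a column name"))
  structure(d, class = "ColumnDialect")
}

#' Read and validate GWAS summary statistics
#'
#' Reads a tab-delimited summary-statistics file, remaps columns through the
#' dialect, upper-cases alleles, and drops rows violating the record
#' invariants (alleles outside A/C/G/T or identical, non-positive or missing
#' standard error, p-value outside (0, 1], allele frequency outside [0, 1],
#' non-finite effect, duplicated rsid). P-values of exactly 0 are clamped to
#' 1e-300 with a warning. Dropped rows are counted in the \code{"dropped"}
#' attribute and itemised in the \code{"dropLog"} attribute.
#'
#' @param path path to a tab-delimited file with a header row.
#' @param dialect a \code{\link{columnDialect}}.
#' @return data.frame with canonical columns \code{rsid, effect_allele,
#'   other_allele, eaf, beta, se, pval, n}; attributes \code{dropped}
#'   (integer) and \code{dropLog} (data.frame of rsid/reason).
#' @export
readSummaryStats <- function(path, dialect = columnDialect()) {
  stopIfNot(file.exists(path), paste0("summary-statistics file not found: ", path))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           na.strings = dialect$na, stringsAsFactors = FALSE,
                           check.names = FALSE)
  mandatory <- c("rsid", "effect_allele", "other_allele", "beta", "se", "pval")
  for (f in mandatory)
    stopIfNot(dialect[[f]] %in% names(raw),
              paste0("column '", dialect[[f]], "' (field ", f, ") missing from ", path))

  pull <- function(f, as = as.numeric) {
    col <- dialect[[f]]
    if (is.null(col) || is.na(col) || !col %in% names(raw))
      return(rep(NA_real_, nrow(raw)))
    suppressWarnings(as(raw[[col]]))
  }
  rec <- data.frame(
    rsid = as.character(raw[[dialect$rsid]]),
    effect_allele = toupper(as.character(raw[[dialect$effect_allele]])),
    other_allele = toupper(as.character(raw[[dialect$other_allele]])),
    eaf = pull("eaf"),
    beta = pull("beta"),
    se = pull("se"),
    pval = pull("pval"),
    n = pull("n"),
    stringsAsFactors = FALSE
  )

  zeroP <- !is.na(rec$pval) & rec$pval == 0
  if (any(zeroP)) {
    warning(sum(zeroP), " p-value(s) of exactly 0 clamped to 1e-300")
    rec$pval[zeroP] <- 1e-300
  }

  bases <- c("A", "C", "G", "T")
  reason <- rep(NA_character_, nrow(rec))
  flag <- function(bad, why) reason[is.na(reason) & bad] <<- why
  flag(is.na(rec$rsid) | !nzchar(rec$rsid), "missing rsid")
  flag(!(rec$effect_allele %in% bases) | !(rec$other_allele %in% bases),
       "allele outside A/C/G/T")
  flag(rec$effect_allele == rec$other_allele, "identical alleles")
  flag(!is.finite(rec$beta), "missing or non-finite beta")
  flag(!is.finite(rec$se) | rec$se <= 0, "non-positive se")
  flag(!is.finite(rec$pval) | rec$pval <= 0 | rec$pval > 1, "p-value outside (0,1]")
  flag(!is.na(rec$eaf) & (rec$eaf < 0 | rec$eaf > 1), "eaf outside [0,1]")
  flag(duplicated(rec$rsid), "duplicated rsid")

  keep <- is.na(reason)
  dropLog <- data.frame(rsid = rec$rsid[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)
  out <- rec[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(dropLog))
    message("readSummaryStats: dropped ", nrow(dropLog), " of ", nrow(rec),
            " rows (", paste(unique(dropLog$reason), collapse = "; "), ")")
  stopIfNot(nrow(out) > 0, paste0("no valid summary-statistic rows in ", path))
  attr(out, "dropped") <- nrow(dropLog)
  attr(out, "dropLog") <- dropLog
  out
}

#' Write summary statistics in the canonical dialect
#'
#' @param records data.frame with canonical columns.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSummaryStats <- function(records, path) {
  writeTsv(records[, c("rsid", "effect_allele", "other_allele", "eaf",
                       "beta", "se", "pval", "n")], path)
}

# tab-delimited writer keeping 15 significant digits so numeric round-trips
# are lossless well past the 12 digits the package guarantees
writeTsv <- function(df, path) {
  fmt <- df
  for (col in names(fmt))
    if (is.numeric(fmt[[col]]))
      fmt[[col]] <- ifelse(is.na(fmt[[col]]), NA,
                           sprintf("%.15g", fmt[[col]]))
  utils::write.table(fmt, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE)
  invisible(path)
}

#' Read a pairwise LD table
#'
#' Expected columns: \code{rsid_a}, \code{rsid_b}, \code{r2}. Pairs absent
#' from the table are treated downstream as unlinked (r2 = 0).
#'
#' @param path tab-delimited file.
#' @return data.frame with the three columns.
#' @export
readLdTable <- function(path) {
  ld <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopIfNot(all(c("rsid_a", "rsid_b", "r2") %in% names(ld)),
            "LD table needs columns rsid_a, rsid_b, r2")
  ld
}

#' Read a proxy-SNP table
#'
#' Expected columns: \code{rsid}, \code{proxy_rsid}, \code{r2}.
#'
#' @param path tab-delimited file.
#' @return data.frame with the three columns.
#' @export
readProxyTable <- function(path) {
  px <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopIfNot(all(c("rsid", "proxy_rsid", "r2") %in% names(px)),
            "proxy table needs columns rsid, proxy_rsid, r2")
  px
}

#' Write all result tables of an analysis
#'
#' Emits five tab-delimited tables into \code{outDir}: per-method estimates
#' (\code{estimates.tsv}), heterogeneity tests (\code{heterogeneity.tsv}),
#' the Egger pleiotropy intercept (\code{pleiotropy.tsv}), per-SNP Wald
#' ratios (\code{single_snp.tsv}) and leave-one-out estimates
#' (\code{leave_one_out.tsv}).
#'
#' @param bundle an \linkS4class{MRAnalysis}.
#' @param outDir output directory, created if needed.
#' @return character vector of the files written.
#' @export
writeResultsTables <- function(bundle, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stopIfNot(dir.exists(outDir), paste0("cannot create output directory ", outDir))
  paths <- character(0)
  put <- function(df, name) {
    p <- file.path(outDir, name)
    writeTsv(df, p)
    paths <<- c(paths, p)
  }

  put(do.call(rbind, lapply(bundle@estimates, as.data.frame)), "estimates.tsv")

  het <- do.call(rbind, lapply(bundle@heterogeneity, function(h)
    data.frame(type = bundle@config$exposure_name %||% "exposure",
               method = h@method, Q = h@q, Q_df = h@qDf, Q_pval = h@qPval,
               stringsAsFactors = FALSE)))
  if (is.null(het))
    het <- data.frame(type = character(), method = character(), Q = numeric(),
                      Q_df = integer(), Q_pval = numeric())
  put(het, "heterogeneity.tsv")

  pl <- bundle@pleiotropy
  pldf <- if (is.null(pl)) {
    data.frame(exposure = character(), outcome = character(),
               intercept = numeric(), ci_low = numeric(), ci_high = numeric(),
               pval = numeric())
  } else {
    data.frame(exposure = bundle@config$exposure_name %||% "exposure",
               outcome = bundle@config$outcome_name %||% "outcome",
               intercept = pl@intercept, ci_low = pl@ciLow,
               ci_high = pl@ciHigh, pval = pl@pval, stringsAsFactors = FALSE)
  }
  put(pldf, "pleiotropy.tsv")

  put(bundle@waldTable, "single_snp.tsv")

  loo <- bundle@leaveOneOut
  loodf <- if (is.null(loo)) {
    data.frame(omitted = character(), beta = numeric(), se = numeric(),
               ci_low = numeric(), ci_high = numeric(), pval = numeric())
  } else {
    rows <- lapply(seq_along(loo@omitted), function(i) {
      e <- loo@estimates[[i]]
      data.frame(omitted = loo@omitted[i], beta = e@beta, se = e@se,
                 ci_low = e@ciLow, ci_high = e@ciHigh, pval = e@pval,
                 stringsAsFactors = FALSE)
    })
    f <- loo@full
    rows <- c(rows, list(data.frame(omitted = "none (all SNPs)", beta = f@beta,
                                    se = f@se, ci_low = f@ciLow,
                                    ci_high = f@ciHigh, pval = f@pval,
                                    stringsAsFactors = FALSE)))
    do.call(rbind, rows)
  }
  put(loodf, "leave_one_out.tsv")

  paths
}

`%||%` <- function(a, b) if (is.null(a)) b else a
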