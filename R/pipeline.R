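#' Assemble a run configuration
#'
#' @param exposure,outcome paths to summary-statistic files, or data.frames
#'   already in canonical form.
#' @param exposureDialect,outcomeDialect \code{\link{columnDialect}}s used
#'   when reading from file.
#' @param ld optional LD table (path or data.frame) for clumping.
#' @param proxies optional proxy table (path or data.frame).
#' @param blacklist confounder rsids: character vector or path to a
#'   one-rsid-per-line file.
#' @param selection a \code{\link{selectionConfig}}.
#' @param nBoot bootstrap draws for median/mode standard errors.
#' @param seed RNG seed for all stochastic estimators (required).
#' @param bandwidthFactor mode-estimator bandwidth multiplier.
#' @param outDir optional output directory for result tables and run log.
#' @param exposureName,outcomeName labels used in result tables.
#' @return list of class \code{RunConfig}.
#' @export
runConfig <- function(exposure, outcome,
                      exposureDialect = columnDialect(),
                      outcomeDialect = columnDialect(),
                      ld = NULL, proxies = NULL, blacklist = character(),
                      selection = selectionConfig(),
                      nBoot = 1000L, seed = 1L, bandwidthFactor = 1,
                      outDir = NULL,
                      exposureName = "exposure", outcomeName = "outcome") {
  stopIfNot(!is.null(seed) && is.finite(seed), "a seed is required")
  structure(list(exposure = exposure, outcome = outcome,
                 exposureDialect = exposureDialect,
                 outcomeDialect = outcomeDialect,
                 ld = ld, proxies = proxies, blacklist = blacklist,
                 selection = selection, nBoot = as.integer(nBoot),
                 seed = as.integer(seed), bandwidthFactor = bandwidthFactor,
                 outDir = outDir, exposure_name = exposureName,
                 outcome_name = outcomeName),
            class = "RunConfig")
}

#' Read a run configuration from a YAML file
#'
#' Recognised keys mirror \code{\link{runConfig}} arguments in snake_case:
#' \code{exposure}, \code{outcome}, \code{ld}, \code{proxies},
#' \code{blacklist}, \code{p_threshold}, \code{clump_r2}, \code{proxy_r2_min},
#' \code{palindrome_maf_threshold}, \code{n_boot}, \code{seed},
#' \code{bandwidth_factor}, \code{out_dir}, \code{exposure_name},
#' \code{outcome_name}. Relative paths are resolved against the YAML file's
#' directory.
#'
#' @param path YAML file.
#' @return list of class \code{RunConfig}.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.null(p) || file.exists(p)) p else file.path(base, p)
  blk <- y$blacklist %||% character()
  if (is.character(blk) && length(blk) == 1 && file.exists(rel(blk)))
    blk <- readLines(rel(blk), warn = FALSE)
  runConfig(
    exposure = rel(y$exposure), outcome = rel(y$outcome),
    ld = rel(y$ld), proxies = rel(y$proxies), blacklist = blk,
    selection = selectionConfig(
      pThreshold = y$p_threshold %||% 5e-8,
      clumpR2 = y$clump_r2 %||% 0.001,
      proxyR2Min = y$proxy_r2_min %||% 0.8,
      palindromeMafThreshold = y$palindrome_maf_threshold %||% 0.3,
      blacklist = blk),
    nBoot = y$n_boot %||% 1000L,
    seed = y$seed %||% stop("config must carry a seed"),
    bandwidthFactor = y$bandwidth_factor %||% 1,
    outDir = y$out_dir,
    exposureName = y$exposure_name %||% "exposure",
    outcomeName = y$outcome_name %||% "outcome")
}

loadRecords <- function(x, dialect) {
  if (is.character(x)) readSummaryStats(x, dialect) else x
}

loadTable <- function(x, reader) {
  if (is.null(x)) NULL else if (is.character(x)) reader(x) else x
}

#' Run the full two-sample MR pipeline
#'
#' Executes, in fixed order: read and validate both summary-statistic sets;
#' genome-wide p-value filtering, confounder exclusion and LD clumping of
#' the exposure records; proxy substitution for selected SNPs absent from
#' the outcome set; allele harmonization; palindromic-SNP removal; then the
#' full estimator battery, the Egger pleiotropy test, IVW and Egger
#' heterogeneity tests, the per-SNP Wald table, instrument strength and a
#' leave-one-out analysis. When \code{outDir} is set, all result tables and
#' a YAML run log (config echo, seed, package version, per-stage counts)
#' are written; re-running an identical config reproduces every output.
#'
#' @param config a \code{\link{runConfig}} or \code{\link{readRunConfig}} result.
#' @return an \linkS4class{MRAnalysis}.
#' @export
runFullAnalysis <- function(config) {
  exposure <- loadRecords(config$exposure, config$exposureDialect)
  outcome <- loadRecords(config$outcome, config$outcomeDialect)
  ld <- loadTable(config$ld, readLdTable)
  proxies <- loadTable(config$proxies, readProxyTable)

  selected <- selectInstruments(exposure, config$selection, ld)
  ledger <- attr(selected, "ledger")
  note <- function(stage, nin, nout) {
    ledger <<- rbind(ledger, data.frame(stage = stage, n_in = nin,
                                        n_out = nout, n_excluded = nin - nout))
  }

  sub <- substituteProxies(selected$rsid, outcome$rsid, proxies,
                           config$selection$proxyR2Min)
  note("proxy_substitution", nrow(selected), nrow(sub$mapping))
  selected <- selected[selected$rsid %in% sub$mapping$requested, , drop = FALSE]
  outcomeUse <- outcome[match(sub$mapping$used, outcome$rsid), , drop = FALSE]
  outcomeUse$rsid <- sub$mapping$requested

  harm <- harmonize(selected, outcomeUse)
  note("harmonization", nrow(selected), nInstruments(harm))
  harm <- dropPalindromic(harm, config$selection$palindromeMafThreshold)
  note("palindromic_removal",
       ledger$n_out[ledger$stage == "harmonization"], nInstruments(harm))

  j <- nInstruments(harm)
  estimates <- mrAll(harm, nBoot = config$nBoot, seed = config$seed,
                     bandwidthFactor = config$bandwidthFactor)
  egger <- if (j >= 3) mrEgger(harm) else NULL
  het <- tryCatch(heterogeneityTests(harm), error = function(e) list())
  loo <- if (j >= 3) leaveOneOut(harm) else NULL
  strength <- tryCatch(instrumentStrength(selected,
                                          selected$n[1] %||% NA_integer_),
                       error = function(e) NULL)

  bundle <- new("MRAnalysis",
                estimates = estimates,
                pleiotropy = if (is.null(egger)) NULL else egger$pleiotropy,
                heterogeneity = het,
                leaveOneOut = loo,
                waldTable = waldRatios(harm),
                strength = strength,
                instruments = harm,
                ledger = ledger,
                config = list(exposure_name = config$exposure_name,
                              outcome_name = config$outcome_name,
                              seed = config$seed, n_boot = config$nBoot,
                              p_threshold = config$selection$pThreshold,
                              clump_r2 = config$selection$clumpR2,
                              proxy_r2_min = config$selection$proxyR2Min,
                              palindrome_maf_threshold =
                                config$selection$palindromeMafThreshold))

  if (!is.null(config$outDir)) {
    paths <- writeResultsTables(bundle, config$outDir)
    log <- c(bundle@config,
             list(package_version = as.character(utils::packageVersion("tsmr")),
                  stages = split(ledger[, c("n_in", "n_out", "n_excluded")],
                                 seq_len(nrow(ledger))) |>
                    stats::setNames(ledger$stage) |> lapply(as.list)))
    yaml::write_yaml(log, file.path(config$outDir, "run_log.yaml"))
  }
  bundle
}
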