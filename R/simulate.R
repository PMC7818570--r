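#' Build a simulation configuration
#'
#' Defaults describe a realistic two-sample setting for a standardized serum
#' lipid exposure measured in a GLGC-sized GWAS (n = 187,365) against a
#' CKDGen-sized binary-outcome GWAS (n = 117,165): lead-SNP exposure effects
#' around 0.1 SD per allele, minor-allele frequencies between 0.1 and 0.4,
#' and standard errors from the per-allele variance approximation
#' \eqn{1/\sqrt{2 f (1-f) n}}, which puts per-SNP F statistics well into the
#' hundreds, far above the F > 10 weak-instrument rule of thumb.
#'
#' @param nSnps number of instruments J.
#' @param betaTrue true causal effect of exposure on outcome (log-odds).
#' @param gammaMean,gammaSd mean and sd of the exposure-effect magnitude.
#' @param mafLow,mafHigh bounds of the Uniform minor-allele-frequency draw.
#' @param nExposure,nOutcome sample sizes of the two GWAS.
#' @param pleioMean,pleioSd mean and sd of per-SNP direct effects
#'   \eqn{\delta_j} on the outcome (directional pleiotropy when the mean is
#'   nonzero; heterogeneity when the sd is nonzero).
#' @param insideViolation if TRUE, \eqn{\delta_j} gains the linear dependence
#'   \eqn{0.5 \gamma_j} on the instrument effect, violating InSIDE.
#' @param gammaSigns "random" gives each \eqn{\gamma_j} a random sign;
#'   "positive" orients all instruments to the exposure-raising allele.
#' @param nPalindromic number of SNPs assigned A/T or C/G allele pairs.
#' @param seed RNG seed; identical seeds give identical output.
#' @return a \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nSnps = 30L, betaTrue = -0.28,
                             gammaMean = 0.1, gammaSd = 0.05,
                             mafLow = 0.1, mafHigh = 0.4,
                             nExposure = 187365L, nOutcome = 117165L,
                             pleioMean = 0, pleioSd = 0,
                             insideViolation = FALSE,
                             gammaSigns = "random",
                             nPalindromic = 0L, seed = 1L) {
  new("SimulationConfig", nSnps = as.integer(nSnps), betaTrue = betaTrue,
      gammaMean = gammaMean, gammaSd = gammaSd, mafLow = mafLow,
      mafHigh = mafHigh, nExposure = as.integer(nExposure),
      nOutcome = as.integer(nOutcome), pleioMean = pleioMean,
      pleioSd = pleioSd, insideViolation = insideViolation,
      gammaSigns = gammaSigns, nPalindromic = as.integer(nPalindromic),
      seed = as.integer(seed))
}

# slope of the delta-on-gamma dependence used when InSIDE is violated
INSIDE_SLOPE <- 0.5

PALINDROMIC_PAIRS <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                            ncol = 2, byrow = TRUE)
NONPALINDROMIC_PAIRS <- matrix(c("A", "G", "G", "A", "C", "T", "T", "C",
                                 "A", "C", "C", "A", "G", "T", "T", "G"),
                               ncol = 2, byrow = TRUE)

#' Simulate a two-sample exposure/outcome summary-statistics pair
#'
#' For each SNP j: draw maf ~ U(mafLow, mafHigh); a true exposure effect
#' \eqn{\gamma_j} with magnitude |Normal(gammaMean, gammaSd)| and sign per
#' \code{gammaSigns}; a direct effect \eqn{\delta_j ~ Normal(pleioMean,
#' pleioSd)} (plus \eqn{0.5\gamma_j} under \code{insideViolation}); the true
#' outcome effect \eqn{\alpha_j = \beta \gamma_j + \delta_j}. Observed
#' effects are drawn around the truths with standard errors
#' \eqn{1/\sqrt{2 f (1-f) n}} for the respective sample sizes; the two
#' samples are independent (no overlap). P-values are two-sided normal.
#' The first \code{nPalindromic} SNPs receive complementary (A/T or C/G)
#' allele pairs.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with elements \code{exposure} and \code{outcome} (canonical
#'   summary-statistic data.frames) and \code{truth}
#'   (\linkS4class{SimulationTruth}).
#' @export
simulatePair <- function(config) {
  validObject(config)
  withLocalSeed(config@seed, {
    J <- config@nSnps
    rsid <- sprintf("rs%07d", seq_len(J))
    maf <- stats::runif(J, config@mafLow, config@mafHigh)

    mag <- abs(stats::rnorm(J, config@gammaMean, config@gammaSd))
    sgn <- if (config@gammaSigns == "positive") rep(1, J)
           else sample(c(-1, 1), J, replace = TRUE)
    gamma <- sgn * mag

    delta <- stats::rnorm(J, config@pleioMean, config@pleioSd)
    if (config@insideViolation) delta <- delta + INSIDE_SLOPE * gamma
    alphaTrue <- config@betaTrue * gamma + delta

    seG <- 1 / sqrt(2 * maf * (1 - maf) * config@nExposure)
    seA <- 1 / sqrt(2 * maf * (1 - maf) * config@nOutcome)
    gammaHat <- stats::rnorm(J, gamma, seG)
    alphaHat <- stats::rnorm(J, alphaTrue, seA)

    nPal <- config@nPalindromic
    pal <- PALINDROMIC_PAIRS[sample(nrow(PALINDROMIC_PAIRS), J, replace = TRUE), ,
                             drop = FALSE]
    non <- NONPALINDROMIC_PAIRS[sample(nrow(NONPALINDROMIC_PAIRS), J,
                                       replace = TRUE), , drop = FALSE]
    isPal <- seq_len(J) <= nPal
    ea <- ifelse(isPal, pal[, 1], non[, 1])
    oa <- ifelse(isPal, pal[, 2], non[, 2])

    mkRecords <- function(beta, se, n) {
      data.frame(rsid = rsid, effect_allele = ea, other_allele = oa,
                 eaf = maf, beta = beta, se = se,
                 pval = pmax(2 * stats::pnorm(-abs(beta / se)), 1e-300),
                 n = rep(as.integer(n), J), stringsAsFactors = FALSE)
    }
    list(
      exposure = mkRecords(gammaHat, seG, config@nExposure),
      outcome = mkRecords(alphaHat, seA, config@nOutcome),
      truth = new("SimulationTruth", config = config, gamma = gamma,
                  delta = delta, betaTrue = config@betaTrue,
                  seed = config@seed)
    )
  })
}

#' Simulate LD and proxy tables consistent with a configuration
#'
#' Emits a pairwise LD table holding \code{nPairsLinked} disjoint SNP pairs
#' at \code{r2Linked} plus background pairs below 0.001, and a proxy table
#' mapping each of the first \code{nPairsLinked} SNPs to an \code{rsp}-named
#' proxy at r2 > 0.8.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param nPairsLinked number of linked pairs (at most nSnps/2).
#' @param r2Linked the r-squared of the linked pairs.
#' @return list with data.frames \code{ld} (rsid_a, rsid_b, r2) and
#'   \code{proxies} (rsid, proxy_rsid, r2).
#' @export
simulateLdTables <- function(config, nPairsLinked, r2Linked = 0.5) {
  stopIfNot(2 * nPairsLinked <= config@nSnps,
            "nPairsLinked must be at most nSnps/2")
  withLocalSeed(config@seed + 1L, {
    J <- config@nSnps
    rsid <- sprintf("rs%07d", seq_len(J))
    aIdx <- seq_len(nPairsLinked) * 2L - 1L
    linked <- data.frame(rsid_a = rsid[aIdx], rsid_b = rsid[aIdx + 1L],
                         r2 = rep(r2Linked, nPairsLinked),
                         stringsAsFactors = FALSE)
    nBack <- min(J, 10L)
    bg <- data.frame(
      rsid_a = sample(rsid, nBack, replace = TRUE),
      rsid_b = sample(rsid, nBack, replace = TRUE),
      r2 = stats::runif(nBack, 0, 0.0009), stringsAsFactors = FALSE)
    bg <- bg[bg$rsid_a != bg$rsid_b, , drop = FALSE]
    proxies <- if (nPairsLinked > 0) {
      data.frame(rsid = rsid[aIdx],
                 proxy_rsid = sub("^rs", "rsp", rsid[aIdx]),
                 r2 = stats::runif(nPairsLinked, 0.85, 0.99),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(rsid = character(), proxy_rsid = character(), r2 = numeric())
    }
    list(ld = rbind(linked, bg), proxies = proxies)
  })
}

#' Named simulation scenario presets
#'
#' Fixed study conditions used throughout calibration and recovery tests:
#' \describe{
#'   \item{null}{no causal effect (beta = 0), no pleiotropy, J = 50 —
#'     type-I-error and CI-coverage calibration.}
#'   \item{causal}{beta = -0.28 (the protective total-cholesterol direction,
#'     OR about 0.76), balanced pleiotropy, J = 30 — recovery.}
#'   \item{directional_pleiotropy}{beta = -0.28 plus directional per-SNP
#'     direct effects (mean 0.01, sd 0.005) with instruments oriented to the
#'     exposure-raising allele and InSIDE holding — Egger-intercept
#'     recovery; IVW is biased here.}
#'   \item{heterogeneous}{beta = -0.28, balanced but dispersed direct
#'     effects (sd 0.01) so Cochran's Q is expected well above its degrees
#'     of freedom.}
#' }
#'
#' @param name one of "null", "causal", "directional_pleiotropy",
#'   "heterogeneous".
#' @param seed RNG seed stored in the config.
#' @return a \linkS4class{SimulationConfig}.
#' @export
scenarioPreset <- function(name = c("null", "causal", "directional_pleiotropy",
                                    "heterogeneous"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
    null = simulationConfig(nSnps = 50L, betaTrue = 0, pleioMean = 0,
                            pleioSd = 0, seed = seed),
    causal = simulationConfig(nSnps = 30L, betaTrue = -0.28, pleioMean = 0,
                              pleioSd = 0, seed = seed),
    directional_pleiotropy = simulationConfig(nSnps = 30L, betaTrue = -0.28,
                                              pleioMean = 0.01, pleioSd = 0.005,
                                              gammaSigns = "positive",
                                              seed = seed),
    heterogeneous = simulationConfig(nSnps = 30L, betaTrue = -0.28,
                                     pleioMean = 0, pleioSd = 0.01,
                                     seed = seed)
  )
}

#' Write a simulated pair plus truth to disk
#'
#' Writes exposure and outcome records in the canonical dialect and the
#' truth as a tab-delimited per-SNP table headed by comment lines carrying
#' the configuration.
#'
#' @param sim result of \code{\link{simulatePair}}.
#' @param outDir output directory, created if needed.
#' @return character vector of file paths.
#' @export
writeSimulatedPair <- function(sim, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  ep <- file.path(outDir, "exposure.tsv")
  op <- file.path(outDir, "outcome.tsv")
  tp <- file.path(outDir, "truth.tsv")
  writeSummaryStats(sim$exposure, ep)
  writeSummaryStats(sim$outcome, op)
  cfg <- sim$truth@config
  hdr <- sprintf(
    "# nSnps=%d betaTrue=%.15g gammaMean=%.15g gammaSd=%.15g mafLow=%.15g mafHigh=%.15g nExposure=%d nOutcome=%d pleioMean=%.15g pleioSd=%.15g insideViolation=%s gammaSigns=%s nPalindromic=%d seed=%d",
    cfg@nSnps, cfg@betaTrue, cfg@gammaMean, cfg@gammaSd, cfg@mafLow,
    cfg@mafHigh, cfg@nExposure, cfg@nOutcome, cfg@pleioMean, cfg@pleioSd,
    cfg@insideViolation, cfg@gammaSigns, cfg@nPalindromic, cfg@seed)
  con <- file(tp, "w")
  writeLines(hdr, con)
  close(con)
  tdf <- data.frame(rsid = sim$exposure$rsid, gamma_true = sim$truth@gamma,
                    delta_true = sim$truth@delta)
  fmt <- tdf
  for (col in c("gamma_true", "delta_true"))
    fmt[[col]] <- sprintf("%.15g", fmt[[col]])
  suppressWarnings(utils::write.table(fmt, tp, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  c(ep, op, tp)
}
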