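# Fixture builders and independent oracles shared across test files.

# canonical summary-stat data.frame from vectors
makeRecords <- function(rsid, beta, se, pval = NULL,
                        effect_allele = NULL, other_allele = NULL,
                        eaf = NULL, n = 100000L) {
  j <- length(rsid)
  if (is.null(pval)) pval <- 2 * pnorm(-abs(beta / se))
  if (is.null(effect_allele)) effect_allele <- rep("A", j)
  if (is.null(other_allele)) other_allele <- rep("G", j)
  if (is.null(eaf)) eaf <- rep(0.25, j)
  data.frame(rsid = rsid, effect_allele = effect_allele,
             other_allele = other_allele, eaf = eaf, beta = beta, se = se,
             pval = pval, n = rep(n, length.out = j),
             stringsAsFactors = FALSE)
}

# HarmonizedInstruments straight from effect vectors
makeInstruments <- function(gamma, alpha, seGamma = NULL, seAlpha = NULL,
                            eaf = NULL, palindromic = NULL) {
  j <- length(gamma)
  if (is.null(seGamma)) seGamma <- rep(0.003, j)
  if (is.null(seAlpha)) seAlpha <- rep(0.004, j)
  if (is.null(eaf)) eaf <- rep(0.25, j)
  if (is.null(palindromic)) palindromic <- rep(FALSE, j)
  new("HarmonizedInstruments",
      rsid = sprintf("rs%03d", seq_len(j)),
      effectAllele = rep("A", j), otherAllele = rep("G", j),
      gamma = gamma, seGamma = seGamma, alpha = alpha, seAlpha = seAlpha,
      eafExposure = eaf, eafOutcome = eaf,
      flipped = rep(FALSE, j), palindromic = palindromic,
      exclusions = data.frame(rsid = character(), reason = character(),
                              stringsAsFactors = FALSE))
}

# a reproducible random fixture on realistic scales
randomInstruments <- function(j, seed, pleio = 0) {
  set.seed(seed)
  gamma <- sample(c(-1, 1), j, TRUE) * abs(rnorm(j, 0.1, 0.05))
  seGamma <- runif(j, 0.002, 0.005)
  seAlpha <- runif(j, 0.003, 0.006)
  alpha <- -0.28 * gamma + rnorm(j, pleio, 0) + rnorm(j, 0, seAlpha)
  makeInstruments(rnorm(j, gamma, seGamma), alpha, seGamma, seAlpha)
}

# simulate one pair under a config and harmonize it
simHarmonized <- function(config) {
  sim <- simulatePair(config)
  harmonize(sim$exposure, sim$outcome)
}

# independent weighted-regression oracle built on stats::lm
lmOriginOracle <- function(h) {
  w <- 1 / h@seAlpha^2
  fit <- lm(h@alpha ~ 0 + h@gamma, weights = w)
  s <- summary(fit)
  beta <- unname(coef(fit)[1])
  # rescale lm's residual-variance-based se to the fixed-effect (scale 1) se
  seFixed <- unname(s$coefficients[1, 2] / s$sigma)
  q <- sum(w * residuals(fit)^2)
  list(beta = beta, seFixed = seFixed, q = q,
       seRandom = seFixed * max(1, sqrt(q / (length(h@gamma) - 1))))
}

lmEggerOracle <- function(h) {
  s <- sign(h@gamma); s[s == 0] <- 1
  g <- abs(h@gamma); a <- s * h@alpha
  w <- 1 / h@seAlpha^2
  fit <- lm(a ~ g, weights = w)
  sm <- summary(fit)
  q <- sum(w * residuals(fit)^2)
  df <- length(g) - 2
  scl <- max(1, sqrt(q / df)) / sm$sigma
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       seIntercept = unname(sm$coefficients[1, 2]) * scl,
       seSlope = unname(sm$coefficients[2, 2]) * scl, q = q)
}

# brute-force greedy clump oracle: explicit pass over p-sorted SNPs with
# symmetric matrix lookup (independent of the package's sparse-table walk)
greedyClumpOracle <- function(records, ldMatrix, clumpR2) {
  ord <- order(records$pval, records$rsid)
  ids <- records$rsid[ord]
  kept <- character(0)
  for (id in ids) {
    linked <- FALSE
    for (k in kept)
      if (ldMatrix[id, k] > clumpR2) { linked <- TRUE; break }
    if (!linked) kept <- c(kept, id)
  }
  sort(kept)
}

# cumulative-weight interpolation oracle written out stepwise
weightedMedianOracle <- function(b, w) {
  o <- order(b); b <- b[o]; w <- w[o] / sum(w)
  cum <- cumsum(w) - w / 2
  if (cum[1] >= 0.5) return(b[1])
  if (cum[length(cum)] <= 0.5) return(b[length(b)])
  below <- max(which(cum < 0.5))
  above <- below + 1
  b[below] + (b[above] - b[below]) * (0.5 - cum[below]) / (cum[above] - cum[below])
}
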