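#' Per-SNP Wald ratios
#'
#' The single-instrument causal estimate for each SNP:
#' \eqn{\hat\beta_i = \alpha_i/\gamma_i} with first-order standard error
#' \eqn{\sigma_{\alpha i}/|\gamma_i|}. SNPs with a zero exposure effect are
#' excluded with a warning.
#'
#' @param instruments a \linkS4class{HarmonizedInstruments}.
#' @return data.frame with columns \code{rsid}, \code{ratio}, \code{se}.
#' @export
waldRatios <- function(instruments) {
  zero <- instruments@gamma == 0
  if (any(zero)) {
    warning(sum(zero), " SNP(s) with zero exposure effect excluded from Wald ratios")
    instruments <- instruments[!zero]
  }
  data.frame(rsid = instruments@rsid,
             ratio = instruments@alpha / instruments@gamma,
             se = instruments@seAlpha / abs(instruments@gamma),
             stringsAsFactors = FALSE)
}

#' Upper-tail chi-square probability
#'
#' The regularized upper incomplete gamma function
#' \eqn{\Gamma(df/2, q/2)/\Gamma(df/2)}, i.e. P(X > q) for a chi-square
#' variable on \code{df} degrees of freedom; at df = 2 it reduces to
#' \eqn{e^{-q/2}}. Monotone decreasing in q.
#'
#' @param q nonnegative statistic (vectorized).
#' @param df positive degrees of freedom.
#' @return upper-tail probability.
#' @export
chi2UpperTail <- function(q, df) {
  stopIfNot(all(q >= 0), "q must be >= 0")
  stats::pchisq(q, df, lower.tail = FALSE)
}

#' Cochran's Q heterogeneity statistic
#'
#' For the IVW model, \eqn{Q = \sum_i w_i (\hat\beta_i - \beta_{ref})^2}
#' over the Wald ratios with weights \eqn{w_i = (\sigma_{\alpha i}/|\gamma_i|)^{-2}}
#' on J - 1 degrees of freedom. For the Egger model,
#' \eqn{Q = \sum_i \sigma_{\alpha i}^{-2} (\alpha_i - \beta_0 - \beta \gamma_i)^2}
#' on J - 2 degrees of freedom, with instruments oriented so every
#' \eqn{\gamma_i \ge 0} as in the Egger fit.
#'
#' @param instruments a \linkS4class{HarmonizedInstruments}.
#' @param betaRef the slope around which residuals are taken.
#' @param method "ivw" (1 fitted parameter) or "egger" (2).
#' @param intercept the Egger intercept (ignored for ivw).
#' @return a \linkS4class{HeterogeneityResult}.
#' @export
cochransQ <- function(instruments, betaRef, method = c("ivw", "egger"),
                      intercept = 0) {
  method <- match.arg(method)
  j <- nInstruments(instruments)
  stopIfNot(j > 0, "no instruments")
  if (method == "ivw") {
    df <- j - 1L
    stopIfNot(df > 0, "Cochran's Q (IVW) needs at least 2 instruments")
    wr <- waldRatios(instruments)
    q <- sum((wr$ratio - betaRef)^2 / wr$se^2)
    label <- "Inverse variance weighted"
  } else {
    df <- j - 2L
    stopIfNot(df > 0, "Cochran's Q (Egger) needs at least 3 instruments")
    s <- sign(instruments@gamma)
    resid <- s * instruments@alpha - intercept - betaRef * abs(instruments@gamma)
    q <- sum(resid^2 / instruments@seAlpha^2)
    label <- "MR Egger"
  }
  new("HeterogeneityResult", method = label, q = q, qDf = as.integer(df),
      qPval = chi2UpperTail(q, df))
}

#' Inverse-variance-weighted estimator
#'
#' Weighted regression of outcome effects on exposure effects through the
#' origin with weights \eqn{\sigma_{\alpha i}^{-2}}:
#' \deqn{\hat\beta = \sum \gamma_i \alpha_i \sigma_{\alpha i}^{-2} /
#'       \sum \gamma_i^2 \sigma_{\alpha i}^{-2},}
#' equivalently the inverse-variance-weighted mean of the Wald ratios. The
#' fixed-effect standard error is \eqn{(\sum \gamma_i^2
#' \sigma_{\alpha i}^{-2})^{-1/2}}; the multiplicative random-effects model
#' (default) inflates it by \eqn{\max(1, \sqrt{Q/(J-1)})}. With a single
#' instrument the estimate is that SNP's Wald ratio.
#'
#' @param instruments a \linkS4class{HarmonizedInstruments}.
#' @param effectsModel "random_multiplicative" (default) or "fixed".
#' @return an \linkS4class{MREstimate}.
#' @export
mrIvw <- function(instruments, effectsModel = c("random_multiplicative", "fixed")) {
  effectsModel <- match.arg(effectsModel)
  zero <- instruments@gamma == 0
  if (all(zero)) stop("all exposure effects are zero; IVW undefined")
  if (any(zero)) instruments <- instruments[!zero]
  g <- instruments@gamma
  a <- instruments@alpha
  w <- 1 / instruments@seAlpha^2
  j <- length(g)
  beta <- sum(g * a * w) / sum(g^2 * w)
  se <- 1 / sqrt(sum(g^2 * w))
  label <- "Inverse variance weighted"
  if (j == 1L) {
    return(makeEstimate("Wald ratio", beta, se, 1L))
  }
  if (effectsModel == "random_multiplicative") {
    q <- sum(w * (a - beta * g)^2)
    se <- se * max(1, sqrt(q / (j - 1)))
  } else {
    label <- "Inverse variance weighted (fixed effects)"
  }
  makeEstimate(label, beta, se, j)
}

# weighted least squares of a on (1, g), weights w; returns coefs, cov
# with residual scale floored at 1, and the unscaled Q
wlsWithIntercept <- function(g, a, w) {
  x <- cbind(intercept = 1, slope = g)
  xtwx <- crossprod(x, x * w)
  coefs <- solve(xtwx, crossprod(x, a * w))
  resid <- a - x %*% coefs
  q <- sum(w * resid^2)
  df <- length(a) - 2L
  scale2 <- max(1, q / df)
  list(intercept = coefs[1], slope = coefs[2],
       cov = solve(xtwx) * scale2, q = q, df = df)
}

#' MR-Egger regression
#'
#' Instruments are first oriented so every exposure effect is nonnegative
#' (sign-flipping \eqn{(\gamma_i, \alpha_i)} pairs), then outcome effects
#' are regressed on exposure effects by weighted least squares with a free
#' intercept and weights \eqn{\sigma_{\alpha i}^{-2}}. The slope is the
#' pleiotropy-corrected causal effect; the intercept \eqn{\beta_0} estimates
#' the average directional pleiotropic effect, and an intercept p-value
#' above 0.05 is read as no evidence of horizontal pleiotropy. Standard
#' errors use a residual scale floored at 1
#' (\eqn{\max(1, \sqrt{Q_{Egger}/(J-2))}}).
#'
#' @param instruments a \linkS4class{HarmonizedInstruments} with at least 3 SNPs.
#' @return list with \code{estimate} (\linkS4class{MREstimate} for the
#'   slope), \code{pleiotropy} (\linkS4class{PleiotropyResult}) and
#'   \code{heterogeneity} (\linkS4class{HeterogeneityResult}, Egger Q).
#' @export
mrEgger <- function(instruments) {
  j <- nInstruments(instruments)
  stopIfNot(j >= 3, "MR-Egger needs at least 3 instruments")
  s <- sign(instruments@gamma)
  s[s == 0] <- 1
  g <- abs(instruments@gamma)
  a <- s * instruments@alpha
  w <- 1 / instruments@seAlpha^2
  fit <- wlsWithIntercept(g, a, w)
  seSlope <- sqrt(fit$cov[2, 2])
  seInt <- sqrt(fit$cov[1, 1])
  pleio <- new("PleiotropyResult", intercept = fit$intercept, se = seInt,
               ciLow = fit$intercept - CI_Z * seInt,
               ciHigh = fit$intercept + CI_Z * seInt,
               pval = zPval(fit$intercept, seInt))
  het <- new("HeterogeneityResult", method = "MR Egger", q = fit$q,
             qDf = as.integer(fit$df), qPval = chi2UpperTail(fit$q, fit$df))
  list(estimate = makeEstimate("MR Egger", fit$slope, seSlope, j),
       pleiotropy = pleio, heterogeneity = het)
}

#' Heterogeneity tests for the IVW and Egger models
#'
#' The pair of Cochran's Q statistics conventionally reported together:
#' IVW Q around the IVW estimate on J - 1 df, and Egger (Rucker) Q around
#' the Egger fit on J - 2 df.
#'
#' @param instruments a \linkS4class{HarmonizedInstruments}.
#' @return named list of \linkS4class{HeterogeneityResult} ("egger", "ivw").
#' @export
heterogeneityTests <- function(instruments) {
  ivwBeta <- mrIvw(instruments, "fixed")@beta
  out <- list()
  if (nInstruments(instruments) >= 3)
    out$egger <- mrEgger(instruments)$heterogeneity
  out$ivw <- cochransQ(instruments, ivwBeta, "ivw")
  out
}

#' Profile maximum-likelihood estimator
#'
#' Treats each \eqn{(\hat\gamma_i, \hat\alpha_i)} as independent normals
#' around \eqn{(g_i, \beta g_i)} with known standard errors and profiles out
#' the latent effects \eqn{g_i}, leaving
#' \deqn{-2\,\mathrm{pl}(\beta) = \sum_i
#'   (\hat\alpha_i - \beta\hat\gamma_i)^2 /
#'   (\sigma_{\alpha i}^2 + \beta^2 \sigma_{\gamma i}^2),}
#' minimized numerically. The standard error comes from the observed
#' information (numerical curvature) of the profile likelihood. As
#' \eqn{\sigma_\gamma \to 0} the estimate converges to fixed-effect IVW.
#'
#' @param instruments a \linkS4class{HarmonizedInstruments} with >= 2 SNPs.
#' @return an \linkS4class{MREstimate}.
#' @export
mrMaxLik <- function(instruments) {
  j <- nInstruments(instruments)
  stopIfNot(j >= 2, "maximum likelihood needs at least 2 instruments")
  g <- instruments@gamma; a <- instruments@alpha
  s2a <- instruments@seAlpha^2; s2g <- instruments@seGamma^2
  nll <- function(b) sum((a - b * g)^2 / (s2a + b^2 * s2g))
  r <- a / ifelse(g == 0, NA, g)
  span <- range(r, na.rm = TRUE)
  lo <- span[1] - max(1, diff(span)); hi <- span[2] + max(1, diff(span))
  opt <- stats::optimize(nll, c(lo, hi), tol = 1e-12)
  beta <- opt$minimum
  h <- 1e-5 * max(1, abs(beta))
  curv <- (nll(beta + h) - 2 * nll(beta) + nll(beta - h)) / h^2
  if (!is.finite(curv) || curv <= 0)
    stop("maximum likelihood: non-positive curvature at the optimum")
  se <- sqrt(2 / curv)
  makeEstimate("Maximum likelihood", beta, se, j)
}

# cumulative-weight interpolation at probability 0.5
weightedMedianCore <- function(b, w) {
  o <- order(b)
  b <- b[o]; w <- w[o]
  cw <- (cumsum(w) - 0.5 * w) / sum(w)
  if (cw[1] >= 0.5) return(b[1])
  if (cw[length(cw)] <= 0.5) return(b[length(b)])
  k <- max(which(cw < 0.5))
  b[k] + (b[k + 1] - b[k]) * (0.5 - cw[k]) / (cw[k + 1] - cw[k])
}

penalizedWeights <- function(r, w) {
  b0 <- weightedMedianCore(r, w)
  qj <- w * (r - b0)^2
  w * pmin(1, 20 * chi2UpperTail(qj, 1))
}

#' Weighted-median estimator
#'
#' Orders the Wald ratios and takes the value at cumulative standardized
#' inverse-variance weight 0.5, interpolating linearly with each SNP's
#' cumulative weight reduced by half its own weight. Consistent when valid
#' instruments carry more than half the weight. The penalized variant
#' down-weights outlying SNPs by \eqn{\min(1, 20 p_i)}, where \eqn{p_i} is
#' the upper-tail chi-square(1) probability of the SNP's contribution to
#' Cochran's Q about the unpenalized weighted median. The standard error is
#' a seeded parametric bootstrap (ratios resampled from their normal
#' errors); with \code{nBoot = 0} only the point estimate is returned.
#'
#' @param instruments a \linkS4class{HarmonizedInstruments} with >= 3 SNPs.
#' @param penalized apply the outlier penalty.
#' @param nBoot bootstrap draws for the standard error (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return an \linkS4class{MREstimate}.
#' @export
mrMedian <- function(instruments, penalized = FALSE, nBoot = 1000L, seed = 1L) {
  j <- nInstruments(instruments)
  stopIfNot(j >= 3, "weighted median needs at least 3 instruments")
  wr <- waldRatios(instruments)
  w <- 1 / wr$se^2
  point <- function(r) {
    wEff <- if (penalized) penalizedWeights(r, w) else w
    weightedMedianCore(r, wEff)
  }
  beta <- point(wr$ratio)
  se <- NA_real_
  if (nBoot > 0) {
    boots <- withLocalSeed(seed, {
      vapply(seq_len(nBoot), function(b)
        point(stats::rnorm(j, wr$ratio, wr$se)), numeric(1))
    })
    se <- stats::sd(boots)
  }
  makeEstimate(if (penalized) "Penalized weighted median" else "Weighted median",
               beta, se, j)
}

# kernel density argmax of the ratios; bandwidth = phi * modified Silverman
modeCore <- function(r, w, phi) {
  w <- w / sum(w)
  spread <- min(stats::sd(r), stats::mad(r))
  if (spread == 0) spread <- stats::sd(r)
  if (!is.finite(spread) || spread == 0) return(r[1])
  h <- phi * 0.9 * spread * length(r)^(-1 / 5)
  dens <- function(x) vapply(x, function(xi)
    sum(w * stats::dnorm((xi - r) / h)) / h, numeric(1))
  grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = 512L)
  fx <- dens(grid)
  k <- which.max(fx)
  lo <- grid[max(1L, k - 1L)]; hi <- grid[min(length(grid), k + 1L)]
  stats::optimize(dens, c(lo, hi), maximum = TRUE, tol = 1e-10)$maximum
}

#' Mode-based estimator
#'
#' The argmax of a normal-kernel-smoothed density of the Wald ratios, with
#' bandwidth \code{bandwidthFactor} times the modified Silverman rule
#' \eqn{0.9 \min(sd, mad) J^{-1/5}}. The simple mode weights every SNP
#' equally; the weighted mode weights each kernel by the ratio's inverse
#' variance. Consistent when the largest group of instruments sharing a
#' causal estimate is valid (the ZEMPA assumption). Standard error by
#' seeded parametric bootstrap.
#'
#' @param instruments a \linkS4class{HarmonizedInstruments} with >= 3 SNPs.
#' @param weighted use inverse-variance kernel weights.
#' @param bandwidthFactor multiplier on the Silverman bandwidth (default 1).
#' @param nBoot bootstrap draws (default 1000); 0 skips the standard error.
#' @param seed RNG seed for the bootstrap.
#' @return an \linkS4class{MREstimate}.
#' @export
mrMode <- function(instruments, weighted = FALSE, bandwidthFactor = 1,
                   nBoot = 1000L, seed = 1L) {
  j <- nInstruments(instruments)
  stopIfNot(j >= 3, "mode estimator needs at least 3 instruments")
  wr <- waldRatios(instruments)
  w <- if (weighted) 1 / wr$se^2 else rep(1, j)
  beta <- modeCore(wr$ratio, w, bandwidthFactor)
  se <- NA_real_
  if (nBoot > 0) {
    boots <- withLocalSeed(seed, {
      vapply(seq_len(nBoot), function(b)
        modeCore(stats::rnorm(j, wr$ratio, wr$se), w, bandwidthFactor),
        numeric(1))
    })
    se <- stats::sd(boots)
  }
  makeEstimate(if (weighted) "Weighted mode" else "Simple mode", beta, se, j)
}

rapsScore <- function(b, tau2, g, a, s2a, s2g) {
  sum((a - b * g) * g / (s2a + b^2 * s2g + tau2))
}

#' Robust adjusted profile score (RAPS)
#'
#' Solves the adjusted profile-score equation
#' \deqn{\sum_i (\hat\alpha_i - \beta\hat\gamma_i)\hat\gamma_i /
#'       (\sigma_{\alpha i}^2 + \beta^2\sigma_{\gamma i}^2 + \tau^2) = 0,}
#' which accounts for measurement error in the SNP-exposure effects. With
#' \code{overdispersion = TRUE} the systematic-pleiotropy variance
#' \eqn{\tau^2} is estimated jointly from the second moment of the
#' standardized residuals (floored at 0); otherwise \eqn{\tau^2 = 0}. The
#' standard error is the sandwich estimate from the score and its
#' derivative.
#'
#' @param instruments a \linkS4class{HarmonizedInstruments} with >= 3 SNPs.
#' @param overdispersion estimate \eqn{\tau^2} jointly.
#' @return an \linkS4class{MREstimate}.
#' @export
mrRaps <- function(instruments, overdispersion = FALSE) {
  j <- nInstruments(instruments)
  stopIfNot(j >= 3, "RAPS needs at least 3 instruments")
  g <- instruments@gamma; a <- instruments@alpha
  s2a <- instruments@seAlpha^2; s2g <- instruments@seGamma^2

  solveBeta <- function(tau2) {
    r <- a / ifelse(g == 0, NA, g)
    span <- range(r, na.rm = TRUE)
    width <- max(1, diff(span))
    lo <- span[1] - width; hi <- span[2] + width
    f <- function(b) rapsScore(b, tau2, g, a, s2a, s2g)
    for (k in 1:6) {
      if (sign(f(lo)) != sign(f(hi)))
        return(stats::uniroot(f, c(lo, hi), tol = 1e-12)$root)
      lo <- lo - width * 2^k; hi <- hi + width * 2^k
    }
    stop("RAPS: no root of the profile score in [", lo, ", ", hi, "]")
  }

  tau2 <- 0
  beta <- solveBeta(tau2)
  if (overdispersion) {
    for (it in 1:50) {
      momEq <- function(t2) {
        d <- s2a + beta^2 * s2g + t2
        sum(((a - beta * g)^2 - d) / d^2)
      }
      tau2New <- if (momEq(0) <= 0) 0 else {
        up <- stats::var(a - beta * g) + max(s2a)
        while (momEq(up) > 0) up <- up * 4
        stats::uniroot(momEq, c(0, up), tol = 1e-12)$root
      }
      betaNew <- solveBeta(tau2New)
      done <- abs(betaNew - beta) < 1e-10 && abs(tau2New - tau2) < 1e-12
      beta <- betaNew; tau2 <- tau2New
      if (done) break
    }
  }

  d <- s2a + beta^2 * s2g + tau2
  psi <- (a - beta * g) * g / d
  dpsi <- (-g^2 * d - (a - beta * g) * g * 2 * beta * s2g) / d^2
  se <- sqrt(sum(psi^2)) / abs(sum(dpsi))
  est <- makeEstimate(if (overdispersion)
    "Robust adjusted profile score (overdispersed)" else
    "Robust adjusted profile score (RAPS)", beta, se, j)
  attr(est, "tau2") <- tau2
  est
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the causal effect J times, omitting each SNP in turn, plus
#' the all-SNP estimate for comparison, flagging results driven by a single
#' instrument.
#'
#' @param instruments a \linkS4class{HarmonizedInstruments} with >= 3 SNPs.
#' @param method estimator to apply ("ivw" only, the conventional choice).
#' @param effectsModel forwarded to \code{\link{mrIvw}}.
#' @return a \linkS4class{LeaveOneOutResult}.
#' @export
leaveOneOut <- function(instruments, method = "ivw",
                        effectsModel = "random_multiplicative") {
  stopIfNot(identical(method, "ivw"), "only method = 'ivw' is supported")
  j <- nInstruments(instruments)
  stopIfNot(j >= 3, "leave-one-out needs at least 3 instruments")
  subs <- lapply(seq_len(j), function(i)
    mrIvw(instruments[-i], effectsModel))
  new("LeaveOneOutResult", omitted = instruments@rsid,
      estimates = subs, full = mrIvw(instruments, effectsModel))
}

#' Run the full estimator battery
#'
#' IVW (multiplicative random effects and fixed effects), MR-Egger,
#' maximum likelihood, weighted and penalized weighted median, simple and
#' weighted mode, and RAPS. Estimators whose preconditions fail (too few
#' instruments, no score root) are skipped with a message.
#'
#' @param instruments a \linkS4class{HarmonizedInstruments}.
#' @param nBoot bootstrap draws for median/mode standard errors.
#' @param seed RNG seed for bootstraps.
#' @param bandwidthFactor mode bandwidth multiplier.
#' @return named list of \linkS4class{MREstimate}.
#' @export
mrAll <- function(instruments, nBoot = 1000L, seed = 1L, bandwidthFactor = 1) {
  runs <- list(
    ivw = function() mrIvw(instruments, "random_multiplicative"),
    ivw_fixed = function() mrIvw(instruments, "fixed"),
    egger = function() mrEgger(instruments)$estimate,
    max_lik = function() mrMaxLik(instruments),
    weighted_median = function() mrMedian(instruments, FALSE, nBoot, seed),
    penalized_weighted_median = function() mrMedian(instruments, TRUE, nBoot,
                                                    seed + 1L),
    simple_mode = function() mrMode(instruments, FALSE, bandwidthFactor,
                                    nBoot, seed + 2L),
    weighted_mode = function() mrMode(instruments, TRUE, bandwidthFactor,
                                      nBoot, seed + 3L),
    raps = function() mrRaps(instruments)
  )
  out <- list()
  for (nm in names(runs)) {
    est <- tryCatch(runs[[nm]](), error = function(e) {
      message("estimator '", nm, "' unavailable: ", conditionMessage(e))
      NULL
    })
    if (!is.null(est)) out[[nm]] <- est
  }
  out
}
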