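# internal helpers shared across modules

# run expr under a local RNG state so callers' streams are untouched
withLocalSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# two-sided normal p-value for an estimate/se pair
zPval <- function(beta, se) 2 * stats::pnorm(-abs(beta / se))

CI_Z <- stats::qnorm(0.975)

# assemble an MREstimate from beta/se on the log-odds scale
makeEstimate <- function(method, beta, se, nSnps) {
  if (is.na(se)) {
    ciLow <- ciHigh <- pval <- NA_real_
  } else {
    ciLow <- beta - CI_Z * se
    ciHigh <- beta + CI_Z * se
    pval <- zPval(beta, se)
  }
  new("MREstimate", method = method, beta = beta, se = se,
      ciLow = ciLow, ciHigh = ciHigh,
      oddsRatio = exp(beta), orCiLow = exp(ciLow), orCiHigh = exp(ciHigh),
      pval = pval, nSnps = as.integer(nSnps))
}

stopIfNot <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
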