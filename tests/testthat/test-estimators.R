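test_that("Wald ratios follow the closed form and drop zero-gamma SNPs", {
  h <- makeInstruments(gamma = c(0.1, 0.2), alpha = c(0.02, 0),
                       seAlpha = c(0.01, 0.01))
  wr <- waldRatios(h)
  expect_equal(wr$ratio, c(0.2, 0))
  expect_equal(wr$se, c(0.1, 0.05))

  set.seed(12)
  g <- rnorm(5, 0.1, 0.03); a <- rnorm(5, -0.03, 0.01); s <- runif(5, 0.005, 0.01)
  wr <- waldRatios(makeInstruments(g, a, seAlpha = s))
  expect_equal(wr$ratio, a / g)
  expect_equal(wr$se, s / abs(g))

  hz <- makeInstruments(gamma = c(0.1, 0), alpha = c(0.02, 0.01))
  expect_warning(wr <- waldRatios(hz), "zero exposure effect")
  expect_equal(nrow(wr), 1L)
})

test_that("IVW matches a weighted-least-squares-through-origin oracle to 1e-10", {
  h <- randomInstruments(10, seed = 31)
  want <- lmOriginOracle(h)
  fixed <- mrIvw(h, "fixed")
  rand <- mrIvw(h, "random_multiplicative")
  expect_equal(fixed@beta, want$beta, tolerance = 1e-10)
  expect_equal(fixed@se, want$seFixed, tolerance = 1e-10)
  expect_equal(rand@beta, want$beta, tolerance = 1e-10)
  expect_equal(rand@se, want$seRandom, tolerance = 1e-10)
  expect_equal(fixed@oddsRatio, exp(fixed@beta))
  expect_equal(fixed@ciLow, fixed@beta - qnorm(0.975) * fixed@se)

  # collinear noise-free fixture: exact slope, zero heterogeneity
  g <- seq(0.05, 0.2, length.out = 7)
  hc <- makeInstruments(g, -0.28 * g)
  expect_equal(mrIvw(hc, "fixed")@beta, -0.28, tolerance = 1e-12)
  expect_equal(cochransQ(hc, -0.28, "ivw")@q, 0, tolerance = 1e-12)

  # J = 2 identical SNPs: estimate equals the common Wald ratio
  h2 <- makeInstruments(c(0.1, 0.1), c(0.03, 0.03))
  expect_equal(mrIvw(h2, "fixed")@beta, 0.3, tolerance = 1e-12)
})

test_that("MR-Egger matches a weighted-regression oracle and recovers exact lines", {
  h <- randomInstruments(12, seed = 55)
  want <- lmEggerOracle(h)
  got <- mrEgger(h)
  expect_equal(got$estimate@beta, want$slope, tolerance = 1e-10)
  expect_equal(got$pleiotropy@intercept, want$intercept, tolerance = 1e-10)
  expect_equal(got$estimate@se, want$seSlope, tolerance = 1e-10)
  expect_equal(got$pleiotropy@se, want$seIntercept, tolerance = 1e-10)
  expect_equal(got$heterogeneity@q, want$q, tolerance = 1e-10)
  expect_equal(got$heterogeneity@qDf, 10L)

  # exact line alpha = 0.1 + 0.5 gamma with positive gammas
  g <- seq(0.05, 0.3, length.out = 6)
  hl <- makeInstruments(g, 0.1 + 0.5 * g)
  fit <- mrEgger(hl)
  expect_equal(fit$estimate@beta, 0.5, tolerance = 1e-10)
  expect_equal(fit$pleiotropy@intercept, 0.1, tolerance = 1e-10)
  expect_equal(fit$heterogeneity@q, 0, tolerance = 1e-10)

  expect_error(mrEgger(makeInstruments(c(0.1, 0.2), c(0.01, 0.02))),
               "at least 3")
})

test_that("chi-square tail obeys its closed-form identities and Cochran's Q uses them", {
  expect_equal(chi2UpperTail(1.462, 2), exp(-0.731), tolerance = 1e-12)
  expect_equal(chi2UpperTail(0, 5), 1)
  qs <- seq(0.1, 30, by = 0.3)
  expect_true(all(diff(chi2UpperTail(qs, 4)) < 0))

  # all ratios equal: Q = 0, p = 1
  g <- c(0.1, 0.15, 0.2)
  heq <- makeInstruments(g, 0.4 * g)
  q <- cochransQ(heq, mrIvw(heq, "fixed")@beta, "ivw")
  expect_equal(q@q, 0, tolerance = 1e-12)
  expect_equal(q@qPval, 1)
  expect_equal(q@qDf, 2L)
})

test_that("maximum likelihood matches a grid-search oracle and the small-sigma-gamma limit", {
  h <- randomInstruments(10, seed = 77)
  nllOracle <- function(b)
    sum((h@alpha - b * h@gamma)^2 / (h@seAlpha^2 + b^2 * h@seGamma^2))
  grid <- seq(-1, 1, by = 1e-4)
  bGrid <- grid[which.min(vapply(grid, nllOracle, numeric(1)))]
  got <- mrMaxLik(h)
  expect_equal(got@beta, bGrid, tolerance = 2e-4)

  # sigma_gamma -> 0: converges to fixed-effect IVW
  h0 <- h
  h0@seGamma <- rep(1e-10, 10)
  expect_equal(mrMaxLik(h0)@beta, mrIvw(h0, "fixed")@beta, tolerance = 1e-4)
  expect_equal(mrMaxLik(h0)@se, mrIvw(h0, "fixed")@se, tolerance = 1e-4)

  # collinear noise-free fixture: exact slope
  g <- seq(0.05, 0.2, length.out = 5)
  expect_equal(mrMaxLik(makeInstruments(g, -0.28 * g))@beta, -0.28,
               tolerance = 1e-8)
})

test_that("the weighted median interpolates cumulative weight exactly as specified", {
  # 3 equal-weight ratios: middle element
  h3 <- makeInstruments(rep(0.1, 3), 0.1 * c(0.1, 0.2, 0.9))
  expect_equal(mrMedian(h3, nBoot = 0)@beta, 0.2, tolerance = 1e-12)

  # all ratios equal c: estimate c with small bootstrap se
  hc <- makeInstruments(seq(0.1, 0.2, length.out = 4), 0.05 * seq(0.1, 0.2, length.out = 4),
                        seAlpha = rep(1e-4, 4))
  est <- mrMedian(hc, nBoot = 200, seed = 9)
  expect_equal(est@beta, 0.05, tolerance = 1e-10)
  expect_lt(est@se, 0.005)

  # 7-ratio unequal-weight fixture against the stepwise interpolation oracle
  h7 <- randomInstruments(7, seed = 13)
  wr <- waldRatios(h7)
  expect_equal(mrMedian(h7, nBoot = 0)@beta,
               weightedMedianOracle(wr$ratio, 1 / wr$se^2), tolerance = 1e-12)

  # dominant weight: converges to that SNP's Wald ratio
  hd <- makeInstruments(c(0.1, 0.1, 0.1), c(0.05, 0.01, 0.03),
                        seAlpha = c(1e-6, 0.05, 0.05))
  expect_equal(mrMedian(hd, nBoot = 0)@beta, 0.5, tolerance = 1e-6)

  # penalized variant down-weights the planted outlier
  g <- rep(0.1, 9)
  a <- 0.1 * c(rep(0.2, 8), 3)
  hp <- makeInstruments(g, a, seAlpha = rep(0.005, 9))
  pen <- mrMedian(hp, penalized = TRUE, nBoot = 0)
  expect_equal(pen@beta, 0.2, tolerance = 0.02)
  expect_identical(pen@method, "Penalized weighted median")
})

test_that("mode estimators match a dense-grid density oracle and find the majority mode", {
  h9 <- randomInstruments(9, seed = 17)
  wr <- waldRatios(h9)
  for (weighted in c(FALSE, TRUE)) {
    w <- if (weighted) 1 / wr$se^2 else rep(1, 9)
    w <- w / sum(w)
    spread <- min(sd(wr$ratio), mad(wr$ratio))
    bw <- 0.9 * spread * 9^(-1 / 5)
    grid <- seq(min(wr$ratio) - 3 * bw, max(wr$ratio) + 3 * bw, by = 1e-4)
    dens <- vapply(grid, function(x) sum(w * dnorm((x - wr$ratio) / bw)), numeric(1))
    expect_equal(mrMode(h9, weighted = weighted, nBoot = 0)@beta,
                 grid[which.max(dens)], tolerance = 2e-4)
  }

  # all ratios equal c
  g <- seq(0.1, 0.2, length.out = 4)
  expect_equal(mrMode(makeInstruments(g, 0.3 * g), nBoot = 0)@beta, 0.3,
               tolerance = 1e-6)

  # bimodal: 5 tight ratios near 0.2, 2 near 0.9 -> majority mode wins
  gb <- rep(0.1, 7)
  ab <- 0.1 * c(0.19, 0.2, 0.2, 0.21, 0.2, 0.89, 0.91)
  expect_equal(mrMode(makeInstruments(gb, ab), nBoot = 0)@beta, 0.2,
               tolerance = 0.05)
})

test_that("RAPS solves the profile-score equation to bisection accuracy and hits known limits", {
  h <- randomInstruments(20, seed = 99)
  got <- mrRaps(h)
  score <- function(b)
    sum((h@alpha - b * h@gamma) * h@gamma / (h@seAlpha^2 + b^2 * h@seGamma^2))
  # independent bisection oracle
  lo <- -2; hi <- 2
  stopifnot(sign(score(lo)) != sign(score(hi)))
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (sign(score(mid)) == sign(score(lo))) lo <- mid else hi <- mid
  }
  expect_equal(got@beta, (lo + hi) / 2, tolerance = 1e-8)
  expect_equal(score(got@beta), 0, tolerance = 1e-6)

  # sigma_gamma -> 0, tau2 = 0: IVW limit
  h0 <- h
  h0@seGamma <- rep(1e-10, 20)
  expect_equal(mrRaps(h0)@beta, mrIvw(h0, "fixed")@beta, tolerance = 1e-4)

  # collinear noise-free: exact slope
  g <- seq(0.05, 0.2, length.out = 5)
  expect_equal(mrRaps(makeInstruments(g, -0.28 * g))@beta, -0.28,
               tolerance = 1e-8)

  # overdispersed variant estimates a nonnegative tau2 and keeps the root property
  hov <- randomInstruments(20, seed = 101)
  hov@alpha <- hov@alpha + rnorm(20, 0, 0.01)
  est <- mrRaps(hov, overdispersion = TRUE)
  tau2 <- attr(est, "tau2")
  expect_gte(tau2, 0)
  scoreOv <- function(b)
    sum((hov@alpha - b * hov@gamma) * hov@gamma /
        (hov@seAlpha^2 + b^2 * hov@seGamma^2 + tau2))
  expect_equal(scoreOv(est@beta), 0, tolerance = 1e-6)
})

test_that("leave-one-out returns J sub-estimates and isolates a planted outlier", {
  h <- makeInstruments(rep(0.1, 4), 0.1 * c(0.199, 0.2, 0.2, 0.201),
                       seAlpha = rep(0.004, 4))
  loo <- leaveOneOut(h)
  expect_length(loo@omitted, 4L)
  expect_true(all(vapply(loo@estimates, function(e) e@nSnps, integer(1)) == 3L))
  full <- loo@full
  for (e in loo@estimates)
    expect_true(e@beta >= full@ciLow && e@beta <= full@ciHigh)

  # planted outlier: its omission moves the estimate farthest
  g <- rep(0.1, 6)
  a <- 0.1 * c(0.2, 0.21, 0.19, 0.2, 0.2, 1.5)
  ho <- makeInstruments(g, a, seAlpha = rep(0.004, 6))
  loo <- leaveOneOut(ho)
  shift <- abs(vapply(loo@estimates, function(e) e@beta, numeric(1)) -
               loo@full@beta)
  expect_equal(which.max(shift), 6L)
})

test_that("slope estimators are equivariant under negating all outcome effects", {
  h <- randomInstruments(12, seed = 7)
  hneg <- h
  hneg@alpha <- -h@alpha
  expect_equal(mrIvw(hneg)@beta, -mrIvw(h)@beta, tolerance = 1e-12)
  expect_equal(mrEgger(hneg)$estimate@beta, -mrEgger(h)$estimate@beta,
               tolerance = 1e-10)
  expect_equal(mrMaxLik(hneg)@beta, -mrMaxLik(h)@beta, tolerance = 1e-6)
  expect_equal(mrRaps(hneg)@beta, -mrRaps(h)@beta, tolerance = 1e-8)
  expect_equal(mrMedian(hneg, nBoot = 0)@beta, -mrMedian(h, nBoot = 0)@beta,
               tolerance = 1e-10)
})

test_that("the estimator battery reports every available method with coherent metadata", {
  h <- randomInstruments(10, seed = 23)
  ests <- mrAll(h, nBoot = 50, seed = 3)
  expect_setequal(names(ests),
                  c("ivw", "ivw_fixed", "egger", "max_lik", "weighted_median",
                    "penalized_weighted_median", "simple_mode", "weighted_mode",
                    "raps"))
  for (e in ests) {
    expect_s4_class(e, "MREstimate")
    expect_identical(e@nSnps, 10L)
    expect_equal(e@oddsRatio, exp(e@beta))
  }
  # with 2 SNPs the >= 3 methods drop out gracefully
  h2 <- makeInstruments(c(0.1, 0.2), c(0.03, 0.05))
  ests2 <- suppressMessages(mrAll(h2, nBoot = 0))
  expect_setequal(names(ests2), c("ivw", "ivw_fixed", "max_lik"))
})
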