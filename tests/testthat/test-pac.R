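# build a series with beta amplitude modulated by phrase-band phase
coupledSeries <- function(n, rate = 150, depth = 0.8,
                          phaseBand = c(0.6, 1.3), carrier = c(16, 25)) {
  slow <- bandpassFilter(rnorm(n), phaseBand[1], phaseBand[2], rate)
  phi <- Arg(analyticSignal(slow))
  beta <- bandpassFilter(rnorm(n), carrier[1], carrier[2], rate)
  beta <- beta / sd(beta)
  slow / sd(slow) + 0.6 * (1 + depth * cos(phi)) * beta + 0.3 * rnorm(n)
}

test_that("phase-power MI is null for independent bands", {
  # Band-limited samples are autocorrelated, so the i.i.d. bias correction
  # leaves a small positive offset under independence. The correct null
  # reference is therefore a matched construction with no possible
  # coupling: phase from one noise realisation, power from another. The
  # same-series MI (disjoint bands of white noise) must be
  # indistinguishable from that null, and both must be tiny.
  set.seed(40)
  rate <- 150
  phrase <- bandSpec("phrase", 0.6, 1.3)
  beta <- bandSpec("beta", 13, 30)
  crossMI <- function(a, b) {
    trim <- round(0.5 * rate)
    keep <- (trim + 1):(length(a) - trim)
    ph <- bandpassAnalytic(a, phrase, rate)[keep]
    phasor <- ph / Mod(ph)
    pw <- Mod(bandpassAnalytic(b, beta, rate)[keep])^2
    gaussianMI(cbind(copulaNormalise(Re(phasor)),
                     copulaNormalise(Im(phasor))),
               copulaNormalise(pw), clamp = FALSE)
  }
  n <- 8 * rate
  same <- replicate(100, phasePowerMI(rnorm(n), phrase, beta, rate,
                                      clamp = FALSE))
  cross <- replicate(100, crossMI(rnorm(n), rnorm(n)))
  expect_gt(t.test(same, cross)$p.value, 0.01)
  expect_lt(abs(mean(same)), 0.03)
})

test_that("injected coupling is detected and agrees with a binned oracle", {
  rate <- 150
  phrase <- bandSpec("phrase", 0.6, 1.3)
  beta <- bandSpec("beta", 13, 30)
  n <- 30 * rate

  # binned modulation-index oracle on the same signals: mean power per
  # phase bin, then normalised entropy deficit (independent of the copula
  # MI implementation)
  binnedMI <- function(x) {
    trim <- round(0.5 * rate)
    keep <- (trim + 1):(n - trim)
    phi <- Arg(bandpassAnalytic(x, phrase, rate)[keep])
    pw <- Mod(bandpassAnalytic(x, beta, rate)[keep])^2
    bins <- cut(phi, seq(-pi, pi, length.out = 9))
    m <- tapply(pw, bins, mean)
    p <- m / sum(m)
    (log(8) + sum(p * log(p))) / log(8)
  }

  set.seed(41)
  obs <- coupledSeries(n)
  null <- replicate(40, coupledSeries(n, depth = 0))
  miObs <- phasePowerMI(obs, phrase, beta, rate)
  miNull <- apply(null, 2, phasePowerMI, phrase, beta, rate)
  expect_gt(miObs, quantile(miNull, 0.99))

  # the oracle sees the same coupling on the same signals
  expect_gt(binnedMI(obs), max(apply(null[, 1:20], 2, binnedMI)))
})

test_that("PAC MI is invariant to amplitude-vs-power and additive offsets", {
  set.seed(42)
  rate <- 150
  phrase <- bandSpec("phrase", 0.6, 1.3)
  beta <- bandSpec("beta", 13, 30)
  x <- coupledSeries(20 * rate)

  # additive constant changes nothing (filters remove DC)
  expect_equal(phasePowerMI(x + 400, phrase, beta, rate),
               phasePowerMI(x, phrase, beta, rate), tolerance = 1e-6)

  # amplitude vs squared amplitude: identical under the copula step
  trim <- round(0.5 * rate)
  keep <- (trim + 1):(length(x) - trim)
  ph <- bandpassAnalytic(x, phrase, rate)[keep]
  phasor <- ph / Mod(ph)
  expect_true(all(abs(Mod(phasor) - 1) < 1e-12))  # unit-phasor contract
  pw <- Mod(bandpassAnalytic(x, beta, rate)[keep])^2
  sc <- cbind(copulaNormalise(Re(phasor)), copulaNormalise(Im(phasor)))
  expect_identical(gaussianMI(sc, copulaNormalise(pw)),
                   gaussianMI(sc, copulaNormalise(sqrt(pw))))

  # phase band must lie below the power band
  expect_error(phasePowerMI(x, beta, phrase, rate), "below the power band")
  expect_error(phasePowerMI(numeric(3000), phrase, beta, rate),
               "degenerate phase")
})

test_that("region PAC contrast reduces to the single-point case and is seeded", {
  cfg <- tinyCfg(gridDims = c(2, 2, 2), effectRegion = 1:4, pacRegion = 1:4,
                 nTrials = 12)
  corpus <- generateCorpus(cfg)
  p1 <- generateParticipant(cfg, corpus, seed = 5)
  phrase <- bandSpec("phrase", 0.6, 1.3)
  beta <- bandSpec("beta", 13, 30)

  res <- pacConditionContrast(p1, phrase, beta, region = 2, nRepeats = 3,
                              seed = 11)
  expect_length(res$correct, 1)
  expect_equal(res$meanCorrect, res$correct)  # degenerate average

  res2 <- pacConditionContrast(p1, phrase, beta, region = 2, nRepeats = 3,
                               seed = 11)
  expect_identical(res$correct, res2$correct)

  expect_error(pacConditionContrast(p1, phrase, beta, region = integer()),
               "empty region")
  expect_error(pacWholeGridContrast(list(p1), phrase, beta),
               "insufficient sample")
})
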