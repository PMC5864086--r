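test_that("the generator is fully deterministic under the master seed", {
  cfg <- tinyCfg(nSentences = 4, nTrials = 5, nParticipants = 2,
                 gridDims = c(2, 2, 2), effectRegion = 1:2, pacRegion = 1:2)
  c1 <- generateCorpus(cfg); c2 <- generateCorpus(cfg)
  expect_identical(annotations(c1), annotations(c2))
  expect_identical(envelopes(c1), envelopes(c2))

  s1 <- generateStudy(cfg, corpus = c1)
  s2 <- generateStudy(cfg, corpus = c1)
  expect_identical(s1$participants[[1]]@neural, s2$participants[[1]]@neural)
  expect_identical(trialLabels(s1$participants[[2]]),
                   trialLabels(s2$participants[[2]]))
})

test_that("corpus rates hit the configured category targets", {
  cfg <- synthConfig(masterSeed = 7)  # full 90-sentence corpus
  corpus <- generateCorpus(cfg)
  targets <- cfg$rateMeans
  sds <- cfg$rateSDs
  for (cat in names(targets)) {
    rs <- ratesFromOnsets(annotations(corpus), cat)
    # corpus mean is an average of nSentences independent rate draws, so it
    # should sit within the near-certain (3 SEM) band of the target
    sem <- sds[[cat]] / sqrt(cfg$nSentences)
    expect_lt(abs(rs@mean - targets[[cat]]), 3 * sem)
  }

  # words vary in duration more than phrases, as in natural speech
  cvPhrase <- ratesFromOnsets(annotations(corpus), "phrase")@cv
  cvWord <- ratesFromOnsets(annotations(corpus), "word")@cv
  expect_gt(cvWord, cvPhrase)

  # derived bands bracket the targets
  bands <- deriveCorpusBands(corpus)
  for (cat in names(targets)) {
    expect_lt(bands[[cat]]@fLo, targets[[cat]])
    expect_gt(bands[[cat]]@fHi, targets[[cat]])
  }
})

test_that("average envelope spectrum peaks at the phrasal rhythm", {
  cfg <- synthConfig(nSentences = 30, masterSeed = 8)
  corpus <- generateCorpus(cfg)
  avg <- Reduce(`+`, lapply(envelopes(corpus), function(e)
    powerSpectrum(e, sampleRate(corpus))$power)) / 30
  fGrid <- powerSpectrum(envelopes(corpus)[[1]], 150)$frequency
  # a local maximum of the average spectrum falls inside the phrase band
  lowFreq <- fGrid <= 2
  fPeak <- fGrid[lowFreq][which.max(avg[lowFreq])]
  expect_gte(fPeak, 0.6)
  expect_lte(fPeak, 1.3)
})

test_that("every annotated onset coincides with a local envelope rise", {
  cfg <- tinyCfg(nSentences = 6)
  corpus <- generateCorpus(cfg)
  ann <- annotations(corpus)
  bad <- 0L
  for (i in seq_len(nrow(ann))) {
    env <- envelopes(corpus)[[ann$sentence_id[i]]]
    idx <- floor(ann$onset_s[i] * sampleRate(corpus)) + 1L
    win <- diff(env)[max(1L, idx - 1L):min(length(env) - 1L, idx + 1L)]
    if (!any(win > 0)) bad <- bad + 1L
  }
  expect_identical(bad, 0L)
})

test_that("labels, counts, and the equalised subsample size are consistent", {
  mkTrials <- function(nc, ni) {
    n <- nc + ni
    new("TrialSet", speech = rep(list(numeric(4)), n),
        neural = rep(list(matrix(0, 4, 1)), n),
        labels = factor(rep(c("correct", "incorrect"), c(nc, ni)),
                        levels = c("correct", "incorrect")),
        grid = cbind(1, 1, 1), rate = 150, band = NULL, analytic = FALSE)
  }
  expect_equal(labelCounts(mkTrials(70, 30))$subsampleSize, 24)
  expect_equal(labelCounts(mkTrials(50, 50))$subsampleSize, 40)
  expect_equal(labelCounts(mkTrials(10, 0))$subsampleSize, 0)

  # generated labels are approximately Bernoulli(pCorrect)
  cfg <- tinyCfg(nTrials = 200, gridDims = c(1, 1, 1), effectRegion = 1,
                 pacRegion = 1, pacAmplitude = 0)
  p1 <- generateParticipant(cfg, generateCorpus(cfg), seed = 3)
  frac <- mean(trialLabels(p1) == "correct")
  expect_lt(abs(frac - 0.7), 3 * sqrt(0.7 * 0.3 / 200))
})

test_that("tracking and coupling exist only where they are injected", {
  cfg <- tinyCfg(nTrials = 12, gridDims = c(2, 2, 2), effectRegion = 1:2,
                 pacRegion = 1:2, trackingSnrCorrect = 1,
                 trackingSnrIncorrect = 1)
  corpus <- generateCorpus(cfg)
  p1 <- generateParticipant(cfg, corpus, seed = 9)
  an <- analyticTrials(p1, bandSpec("phrase", 0.6, 1.3))
  mi <- trackingMI(an)
  expect_gt(min(mi[1:2]), max(mi[3:8]))

  pac <- pacMI(p1, gridPoints = c(1, 5), phaseBand = bandSpec("phrase", 0.6, 1.3),
               powerBand = bandSpec("beta", 13, 30))
  expect_gt(pac[1], pac[2] + 0.02)

  # snr = 0 everywhere: effect region indistinguishable from the rest
  cfg0 <- tinyCfg(nTrials = 12, gridDims = c(2, 2, 2), effectRegion = 1:2,
                  pacRegion = 1:2, trackingSnrCorrect = 0,
                  trackingSnrIncorrect = 0, pacAmplitude = 0)
  p0 <- generateParticipant(cfg0, corpus, seed = 9)
  mi0 <- trackingMI(analyticTrials(p0, bandSpec("phrase", 0.6, 1.3)))
  expect_lt(mean(mi0[1:2]), max(mi0[3:8]) + 0.05)
})
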