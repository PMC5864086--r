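# Small study configurations used across tests: a 4x4x4 grid with a 2x2x2
# effect cube keeps full-pipeline runs in the seconds range.
tinyCfg <- function(...) {
  defaults <- list(nSentences = 10, nTrials = 16, nParticipants = 4,
                   gridDims = c(4, 4, 4),
                   effectRegion = centralRegion(c(4, 4, 4), 2),
                   masterSeed = 42)
  do.call(synthConfig, utils::modifyList(defaults, list(...)))
}

# Hand-built analytic TrialSet: neural at point 1 is the speech envelope
# delayed by `lagMs` plus noise at the given SNR; remaining points are
# independent noise. Bypasses the corpus generator for focused tests.
toyTracking <- function(nTrialsToy = 10, nSec = 6, rate = 150,
                        lagMs = 100, snr = 1.5, nNull = 2,
                        band = bandSpec("phrase", 0.6, 1.3), seed = 1) {
  set.seed(seed)
  L <- round(lagMs * rate / 1000)
  n <- nSec * rate
  speech <- list(); neural <- list()
  for (i in seq_len(nTrialsToy)) {
    env <- abs(stats::filter(rnorm(n + L), rep(1, 15), sides = 1))
    env[is.na(env)] <- 0
    sp <- env[(L + 1):(n + L)]
    delayed <- env[1:n]
    X <- matrix(rnorm(n * (1 + nNull)), n, 1 + nNull)
    X[, 1] <- X[, 1] + snr * (delayed - mean(delayed)) / sd(delayed)
    speech[[i]] <- sp
    neural[[i]] <- X
  }
  raw <- new("TrialSet", speech = speech, neural = neural,
             labels = factor(rep(c("correct", "incorrect"),
                                 length.out = nTrialsToy),
                             levels = c("correct", "incorrect")),
             grid = cbind(seq_len(1 + nNull) * 6, 0, 0), rate = rate,
             band = NULL, analytic = FALSE)
  analyticTrials(raw, band)
}
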