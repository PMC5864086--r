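#' Stimulus-brain lag grid
#'
#' Inclusive arithmetic sequence of stimulus-to-brain lags in ms. The
#' canonical grid, 60 to 140 ms in 20-ms steps, has 5 lags spanning the
#' typical auditory response latency range; MI is summed over these lags to
#' avoid spurious single-lag results.
#'
#' @param loMs,hiMs first and last lag in ms.
#' @param stepMs step in ms; must divide \code{hiMs - loMs}.
#' @return numeric vector of lags (ms).
#' @examples
#' lagGrid()  # 60 80 100 120 140
#' @export
lagGrid <- function(loMs = 60, hiMs = 140, stepMs = 20) {
  if (stepMs <= 0 || (hiMs - loMs) %% stepMs != 0)
    stop("invalid grid: step must be positive and divide hiMs - loMs")
  seq(loMs, hiMs, by = stepMs)
}

#' Band-limit a trial set and take analytic signals
#'
#' Filters every speech and neural series of a raw \code{TrialSet} to
#' \code{band} (zero-phase Butterworth), takes the analytic signal, and
#' discards \code{edgeTrimSec} seconds at each end of every trial to
#' suppress filter transients.
#'
#' @param trials a raw (real-valued) \code{\linkS4class{TrialSet}}.
#' @param band a \code{\linkS4class{BandSpec}}.
#' @param order Butterworth order (default 3, as for all analysis bands).
#' @param edgeTrimSec seconds trimmed from each trial edge (default 0.5).
#' @return an analytic \code{\linkS4class{TrialSet}} filtered to \code{band}.
#' @export
analyticTrials <- function(trials, band, order = 3, edgeTrimSec = 0.5) {
  if (trials@analytic) stop("trials are already analytic")
  rate <- trials@rate
  trim <- round(edgeTrimSec * rate)
  keepIdx <- function(n) {
    if (n <= 2 * trim + rate / 2)
      stop("trial too short for edge trimming: unusable trial")
    (trim + 1L):(n - trim)
  }
  speech <- lapply(trials@speech, function(s) {
    a <- bandpassAnalytic(as.numeric(s), band, rate, order)
    a[keepIdx(length(a))]
  })
  neural <- lapply(trials@neural, function(m) {
    flt <- apply(m, 2L, function(col)
      analyticSignal(bandpassFilter(col, band@fLo, band@fHi, rate, order)))
    flt[keepIdx(nrow(m)), , drop = FALSE]
  })
  initialize(trials, speech = speech, neural = neural, band = band,
             analytic = TRUE)
}

# lag in samples for a given rate
.lagSamples <- function(lagsMs, rate) as.integer(round(lagsMs * rate / 1000))

# z-score then rank-normalise the real and imaginary parts of a complex
# concatenated series; returns an n x 2 score matrix
.complexScores <- function(z) {
  re <- Re(z); im <- Im(z)
  cbind(.copnorm((re - mean(re)) / stats::sd(re)),
        .copnorm((im - mean(im)) / stats::sd(im)))
}

# Lag-summed copula MI between a list of speech trials and, per grid point,
# a list of neural trials. Pairing within trial i uses the first
# min(length) samples: speech(t) against neural(t + lag). Speech scores are
# shared across grid points per lag.
.trackingMICore <- function(spList, neList, gridPoints, lagsSamp,
                            biasCorrect = TRUE) {
  nt <- length(spList)
  lens <- vapply(seq_len(nt), function(i)
    min(length(spList[[i]]), nrow(neList[[i]])), integer(1))
  if (any(lens <= max(lagsSamp) + 4L))
    stop("trial too short for the requested lags")
  out <- numeric(length(gridPoints))
  for (L in lagsSamp) {
    sx <- .complexScores(unlist(lapply(seq_len(nt), function(i)
      spList[[i]][seq_len(lens[i] - L)])))
    for (k in seq_along(gridPoints)) {
      g <- gridPoints[k]
      ny <- .complexScores(unlist(lapply(seq_len(nt), function(i)
        neList[[i]][(L + 1L):lens[i], g])))
      out[k] <- out[k] + .gcmi(sx, ny, biasCorrect = biasCorrect)
    }
  }
  out
}

.checkAnalytic <- function(trials) {
  if (!trials@analytic)
    stop("trials must be band-filtered and analytic; see analyticTrials()")
}

#' Lag-summed speech-tracking MI
#'
#' For each requested grid point, computes the mutual information between
#' the band-limited speech envelope and the neural signal: at each lag,
#' speech samples at time t are paired with neural samples at t + lag
#' within each trial (the overhang is trimmed), pairs are concatenated
#' across trials, real and imaginary parts are z-scored separately, and the
#' 2-D x 2-D Gaussian-copula MI is computed; values are summed across lags.
#'
#' @param trials an analytic \code{\linkS4class{TrialSet}}.
#' @param gridPoints integer indices (default: all grid points).
#' @param lagsMs lag grid in ms (default \code{lagGrid()}).
#' @param biasCorrect passed to the MI estimator.
#' @return numeric vector of lag-summed MI (bits), one per grid point.
#' @export
trackingMI <- function(trials, gridPoints = seq_len(nGridPoints(trials)),
                       lagsMs = lagGrid(), biasCorrect = TRUE) {
  .checkAnalytic(trials)
  if (nTrials(trials) < 2L) stop("need at least 2 trials")
  .trackingMICore(trials@speech, trials@neural, gridPoints,
                  .lagSamples(lagsMs, trials@rate), biasCorrect)
}

#' Tracking MI as an MIMap
#'
#' @inheritParams trackingMI
#' @param condition condition label recorded in the map.
#' @return an \code{\linkS4class{MIMap}} over all grid points.
#' @export
trackingMIMap <- function(trials, lagsMs = lagGrid(), biasCorrect = TRUE,
                          condition = "all") {
  mi <- trackingMI(trials, lagsMs = lagsMs, biasCorrect = biasCorrect)
  new("MIMap", mi = mi, grid = trials@grid, band = trials@band,
      lagsMs = lagsMs, condition = condition,
      nTrialsUsed = nTrials(trials), nRepeats = 1L)
}

# derangement: permutation with no fixed point
.derangement <- function(n) {
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n))) return(p)
  }
}

#' Trial-shuffling surrogate MI
#'
#' Null MI obtained by destroying the speech-brain pairing: the assignment
#' of speech trials to neural trials is permuted (permutations with fixed
#' points are redrawn) \code{nIter} times and the lag-summed MI averaged
#' across iterations. Because sentences share their coarse envelope
#' structure, a single shuffle does not fully destroy the dependence, hence
#' the averaging over many shuffles. Mismatched trial lengths are handled by
#' pairing the first min(length) samples.
#'
#' @inheritParams trackingMI
#' @param nIter number of shuffles (default 50).
#' @param seed RNG seed for reproducible surrogates.
#' @return numeric vector of surrogate MI (bits), one per grid point.
#' @export
surrogateShuffle <- function(trials,
                             gridPoints = seq_len(nGridPoints(trials)),
                             lagsMs = lagGrid(), nIter = 50, seed = NULL,
                             biasCorrect = TRUE) {
  .checkAnalytic(trials)
  nt <- nTrials(trials)
  if (nt < 3L) stop("insufficient trials for surrogate shuffling (need >= 3)")
  if (!is.null(seed)) set.seed(seed)
  lagsSamp <- .lagSamples(lagsMs, trials@rate)
  acc <- numeric(length(gridPoints))
  for (it in seq_len(nIter)) {
    p <- .derangement(nt)
    acc <- acc + .trackingMICore(trials@speech[p], trials@neural,
                                 gridPoints, lagsSamp, biasCorrect)
  }
  acc / nIter
}

#' Time-reversal surrogate MI
#'
#' Null MI obtained by reversing each speech trial in time (before the
#' analytic transform) and computing the lag-summed MI between the forward
#' neural series and the reversed speech. The reversal is applied to the
#' band-filtered real speech series (zero-phase filtering commutes with
#' time reversal) and the analytic transform recomputed on the reversed
#' series.
#'
#' @inheritParams trackingMI
#' @return numeric vector of surrogate MI (bits), one per grid point.
#' @export
surrogateTimeReverse <- function(trials,
                                 gridPoints = seq_len(nGridPoints(trials)),
                                 lagsMs = lagGrid(), biasCorrect = TRUE) {
  .checkAnalytic(trials)
  spRev <- lapply(trials@speech, function(s) analyticSignal(rev(Re(s))))
  .trackingMICore(spRev, trials@neural, gridPoints,
                  .lagSamples(lagsMs, trials@rate), biasCorrect)
}

#' Surrogate MI as an MIMap
#'
#' @inheritParams surrogateShuffle
#' @param scheme surrogate construction: trial shuffling or time reversal.
#' @return an \code{\linkS4class{MIMap}} with condition \code{"surrogate"}.
#' @export
surrogateMIMap <- function(trials, lagsMs = lagGrid(),
                           scheme = c("shuffle", "timereverse"),
                           nIter = 50, seed = NULL, biasCorrect = TRUE) {
  scheme <- match.arg(scheme)
  mi <- switch(scheme,
    shuffle = surrogateShuffle(trials, lagsMs = lagsMs, nIter = nIter,
                               seed = seed, biasCorrect = biasCorrect),
    timereverse = surrogateTimeReverse(trials, lagsMs = lagsMs,
                                       biasCorrect = biasCorrect))
  new("MIMap", mi = mi, grid = trials@grid, band = trials@band,
      lagsMs = lagsMs, condition = "surrogate",
      nTrialsUsed = nTrials(trials),
      nRepeats = if (scheme == "shuffle") as.integer(nIter) else 1L)
}

#' Correct-versus-incorrect tracking contrast
#'
#' Computes condition-specific MI maps with equalised trial counts: per
#' repeat, floor(frac x min(n_correct, n_incorrect)) trials are drawn
#' without replacement from each condition, the lag-summed MI is computed
#' per grid point, and maps are averaged across repeats.
#'
#' @inheritParams trackingMI
#' @param frac fraction of the minimally available trial count (default 0.8).
#' @param nRepeats number of random trial selections averaged (default 20).
#' @param seed RNG seed.
#' @return list with elements \code{correct} and \code{incorrect}, each an
#'   \code{\linkS4class{MIMap}}, plus \code{nSubsample}.
#' @export
conditionContrast <- function(trials, lagsMs = lagGrid(), frac = 0.8,
                              nRepeats = 20, seed = NULL,
                              biasCorrect = TRUE) {
  .checkAnalytic(trials)
  lab <- trials@labels
  idxC <- which(lab == "correct"); idxI <- which(lab == "incorrect")
  if (length(idxC) < 5L || length(idxI) < 5L)
    stop("missing condition: need >= 5 trials per label")
  m <- floor(frac * min(length(idxC), length(idxI)))
  if (!is.null(seed)) set.seed(seed)
  lagsSamp <- .lagSamples(lagsMs, trials@rate)
  accC <- accI <- numeric(nGridPoints(trials))
  gp <- seq_len(nGridPoints(trials))
  for (r in seq_len(nRepeats)) {
    sC <- sample(idxC, m); sI <- sample(idxI, m)
    accC <- accC + .trackingMICore(trials@speech[sC], trials@neural[sC],
                                   gp, lagsSamp, biasCorrect)
    accI <- accI + .trackingMICore(trials@speech[sI], trials@neural[sI],
                                   gp, lagsSamp, biasCorrect)
  }
  mk <- function(mi, cond) new("MIMap", mi = mi / nRepeats,
                               grid = trials@grid, band = trials@band,
                               lagsMs = lagsMs, condition = cond,
                               nTrialsUsed = as.integer(m),
                               nRepeats = as.integer(nRepeats))
  list(correct = mk(accC, "correct"), incorrect = mk(accI, "incorrect"),
       nSubsample = m)
}
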