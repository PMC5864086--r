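#' Phase-power mutual information (cross-frequency coupling)
#'
#' Quantifies phase-amplitude coupling as the Gaussian-copula MI between
#' the phase of a slow band and the power of a faster band of the same
#' series. The phase channel is the analytic signal of the phase-band
#' filtered series divided by its magnitude (a unit phasor, entering as cos
#' and sin, 2 dimensions); the power channel is the squared magnitude of
#' the analytic signal of the power-band filtered series (1 dimension).
#' Because the copula step is invariant to monotone marginal transforms,
#' using amplitude instead of power gives the identical MI.
#'
#' @param x real numeric series.
#' @param phaseBand,powerBand \code{\linkS4class{BandSpec}} objects with
#'   \code{phaseBand@fHi < powerBand@fLo} (e.g. phrase 0.6-1.3 Hz phase vs
#'   beta 13-30 Hz power).
#' @param rate sampling rate in Hz.
#' @param order Butterworth order (default 3).
#' @param edgeTrimSec seconds trimmed from each end after filtering.
#' @param biasCorrect,clamp passed to the MI estimator.
#' @return MI in bits (single numeric).
#' @export
phasePowerMI <- function(x, phaseBand, powerBand, rate, order = 3,
                         edgeTrimSec = 0.5, biasCorrect = TRUE,
                         clamp = TRUE) {
  if (phaseBand@fHi >= powerBand@fLo)
    stop("phase band must lie strictly below the power band")
  n <- length(x)
  trim <- round(edgeTrimSec * rate)
  keep <- (trim + 1L):(n - trim)
  ph <- bandpassAnalytic(x, phaseBand, rate, order)[keep]
  mag <- Mod(ph)
  if (any(mag < 1e-12)) stop("degenerate phase: zero-magnitude analytic samples")
  phasor <- ph / mag
  pw <- Mod(bandpassAnalytic(x, powerBand, rate, order)[keep])^2
  .gcmi(cbind(.copnorm(Re(phasor)), .copnorm(Im(phasor))),
        cbind(.copnorm(pw)), biasCorrect = biasCorrect, clamp = clamp)
}

# Filter and trim all trials once: per trial, unit phasor and power matrices
# (time x selected grid points). Reused across subsample repeats.
.pacPrep <- function(trials, gridPoints, phaseBand, powerBand, order = 3,
                     edgeTrimSec = 0.5) {
  if (trials@analytic)
    stop("PAC needs raw (broadband) trials, not analytic ones")
  if (phaseBand@fHi >= powerBand@fLo)
    stop("phase band must lie strictly below the power band")
  rate <- trials@rate
  trim <- round(edgeTrimSec * rate)
  lapply(trials@neural, function(m) {
    keep <- (trim + 1L):(nrow(m) - trim)
    ph <- vapply(gridPoints, function(g)
      bandpassAnalytic(m[, g], phaseBand, rate, order)[keep],
      complex(length(keep)))
    mag <- Mod(ph)
    if (any(mag < 1e-12))
      stop("degenerate phase: zero-magnitude analytic samples")
    pw <- vapply(gridPoints, function(g)
      Mod(bandpassAnalytic(m[, g], powerBand, rate, order)[keep])^2,
      numeric(length(keep)))
    list(phasor = ph / mag, power = pw)
  })
}

# concatenated-trial PAC MI per prepared grid point for a trial subset
.pacMIFromPrep <- function(prep, trialIdx, biasCorrect = TRUE) {
  nG <- ncol(prep[[1L]]$phasor)
  vapply(seq_len(nG), function(k) {
    phasor <- unlist(lapply(trialIdx, function(i) prep[[i]]$phasor[, k]))
    pw <- unlist(lapply(trialIdx, function(i) prep[[i]]$power[, k]))
    .gcmi(cbind(.copnorm(Re(phasor)), .copnorm(Im(phasor))),
          cbind(.copnorm(pw)), biasCorrect = biasCorrect)
  }, numeric(1))
}

#' Concatenated-trial PAC per grid point
#'
#' Trials are filtered, trimmed, concatenated, and the phase-power MI
#' computed per grid point.
#'
#' @param trials a raw \code{\linkS4class{TrialSet}}.
#' @param gridPoints integer indices (default: all grid points).
#' @inheritParams phasePowerMI
#' @return numeric vector of PAC MI (bits), one per requested grid point.
#' @export
pacMI <- function(trials, gridPoints = seq_len(nGridPoints(trials)),
                  phaseBand, powerBand, order = 3, edgeTrimSec = 0.5,
                  biasCorrect = TRUE) {
  prep <- .pacPrep(trials, gridPoints, phaseBand, powerBand, order,
                   edgeTrimSec)
  .pacMIFromPrep(prep, seq_len(nTrials(trials)), biasCorrect)
}

#' Correct-versus-incorrect PAC contrast in a region
#'
#' Per repeat and condition, an equal-size trial subsample
#' (floor(frac x min(n_correct, n_incorrect))) is drawn, trials are
#' concatenated, and the phase-power MI computed for every grid point in
#' \code{region}; values are averaged over repeats (per point) and over the
#' region (summary means).
#'
#' @inheritParams pacMI
#' @param region integer grid-point indices forming the region of interest.
#' @param frac fraction of the minimal trial count (default 0.8).
#' @param nRepeats subsample repeats (default 50).
#' @param seed RNG seed.
#' @return list with per-point vectors \code{correct}, \code{incorrect},
#'   region means \code{meanCorrect}, \code{meanIncorrect}, and
#'   \code{nSubsample}.
#' @export
pacConditionContrast <- function(trials, phaseBand, powerBand,
                                 region = seq_len(nGridPoints(trials)),
                                 frac = 0.8, nRepeats = 50, seed = NULL,
                                 order = 3, edgeTrimSec = 0.5,
                                 biasCorrect = TRUE) {
  if (!length(region)) stop("empty region")
  lab <- trials@labels
  idxC <- which(lab == "correct"); idxI <- which(lab == "incorrect")
  if (!length(idxC) || !length(idxI))
    stop("missing condition: both labels must be present")
  m <- floor(frac * min(length(idxC), length(idxI)))
  if (m < 1L) stop("too few trials for subsampling")
  prep <- .pacPrep(trials, region, phaseBand, powerBand, order, edgeTrimSec)
  if (!is.null(seed)) set.seed(seed)
  accC <- accI <- numeric(length(region))
  for (r in seq_len(nRepeats)) {
    accC <- accC + .pacMIFromPrep(prep, sample(idxC, m), biasCorrect)
    accI <- accI + .pacMIFromPrep(prep, sample(idxI, m), biasCorrect)
  }
  accC <- accC / nRepeats; accI <- accI / nRepeats
  list(correct = accC, incorrect = accI,
       meanCorrect = mean(accC), meanIncorrect = mean(accI),
       nSubsample = m, nRepeats = nRepeats,
       phaseBand = phaseBand, powerBand = powerBand)
}

#' Whole-grid PAC contrast across participants
#'
#' Computes the per-grid-point correct/incorrect PAC contrast for every
#' participant (equalised subsamples, \code{nRepeats} repeats) and the
#' group-level dependent-t map of the differences. The map is intended to
#' feed \code{\link{clusterPermutation}} with one-sided cluster selection
#' (the hypothesis is coupling larger for correct trials).
#'
#' @param study list of raw \code{\linkS4class{TrialSet}} objects, one per
#'   participant, sharing a grid.
#' @inheritParams pacConditionContrast
#' @param nRepeats subsample repeats per participant (default 20).
#' @return list with \code{tmap} (\code{\linkS4class{TMap}}), participant x
#'   grid matrices \code{correct}, \code{incorrect}, and \code{diffs}.
#' @export
pacWholeGridContrast <- function(study, phaseBand, powerBand, frac = 0.8,
                                 nRepeats = 20, seed = NULL, order = 3,
                                 edgeTrimSec = 0.5, biasCorrect = TRUE) {
  if (length(study) < 2L)
    stop("insufficient sample: need >= 2 participants for a group t map")
  nG <- nGridPoints(study[[1L]])
  corr <- inc <- matrix(0, length(study), nG)
  for (p in seq_along(study)) {
    res <- pacConditionContrast(
      study[[p]], phaseBand, powerBand, region = seq_len(nG), frac = frac,
      nRepeats = nRepeats, seed = if (is.null(seed)) NULL else seed + p,
      order = order, edgeTrimSec = edgeTrimSec, biasCorrect = biasCorrect)
    corr[p, ] <- res$correct; inc[p, ] <- res$incorrect
  }
  list(tmap = pairedTMap(corr, inc), correct = corr, incorrect = inc,
       diffs = corr - inc)
}
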