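#' Synthetic study configuration
#'
#' Parameters of the synthetic corpus and neural data generator. The
#' defaults emulate the study conditions the pipeline is designed for:
#' 90 sentences of a fixed 7-element structure with category rates of
#' 1.0 +/- 0.1 (phrases), 2.4 +/- 0.3 (words), 3.8 +/- 0.4 (syllables) and
#' 10.4 +/- 0.8 Hz (phonemes); 20 participants with ~70% correct trials; a
#' regular 3-D source grid (8 x 8 x 8 at 6 mm) containing a compact 3 x 3
#' x 3 effect region where the neural signal tracks the speech envelope at
#' a 100-ms lag, more strongly on correct trials; and delta-phase to
#' beta-power coupling of configurable depth in the same region.
#'
#' @param nSentences sentences in the corpus.
#' @param rate sampling rate of envelopes and neural series (Hz).
#' @param rateMeans,rateSDs named per-category means and SDs (Hz) of the
#'   per-sentence event rates.
#' @param eventCounts events per sentence per category (phrases are the
#'   first two clauses; 11 words cover the 7 structural slots).
#' @param ioiSdlog log-normal sd of within-sentence inter-onset intervals.
#' @param durJitterSdlog extra log-normal jitter on event durations.
#' @param durFrac event duration as a fraction of its inter-onset interval.
#' @param attackSec envelope attack time per event (s).
#' @param pauseFloor residual envelope level in the inter-phrase pause.
#' @param envWeights envelope weight per category.
#' @param nParticipants,nTrials,pCorrect study dimensions and the
#'   probability of a correct trial label.
#' @param gridDims,gridSpacing 3-D lattice dimensions and spacing (mm).
#' @param effectRegion grid indices tracking speech (default: central
#'   3 x 3 x 3 cube).
#' @param pacRegion grid indices with phase-amplitude coupling (default:
#'   the effect region).
#' @param trackingSnrCorrect,trackingSnrIncorrect amplitude ratio of the
#'   delayed envelope to the 1/f noise for each label.
#' @param neuralLagMs stimulus-to-brain lag of the tracked envelope (ms).
#' @param pacDepthCorrect,pacDepthIncorrect modulation depth in [0, 1] of
#'   beta amplitude by phrasal-band phase for each label.
#' @param pacAmplitude amplitude of the beta carrier relative to noise SD.
#' @param pacCarrierBand,pacPhaseBand carrier and modulating bands (Hz).
#'   The carrier default (16-25 Hz) sits inside the beta analysis band but
#'   clear of the alpha band edge, so coupling is beta-specific as it is in
#'   the data the generator emulates.
#' @param noiseExponent spectral slope of the 1/f background noise.
#' @param masterSeed seed from which all randomness derives.
#' @return a validated list of class \code{"synthConfig"}.
#' @export
synthConfig <- function(nSentences = 90, rate = 150,
                        rateMeans = c(phrase = 1.0, word = 2.4,
                                      syllable = 3.8, phoneme = 10.4),
                        rateSDs = c(phrase = 0.1, word = 0.3,
                                    syllable = 0.4, phoneme = 0.8),
                        eventCounts = c(phrase = 2, word = 11,
                                        syllable = 18, phoneme = 48),
                        ioiSdlog = c(phrase = 0, word = 0.42,
                                     syllable = 0.28, phoneme = 0.30),
                        durJitterSdlog = c(phrase = 0.25, word = 0,
                                           syllable = 0, phoneme = 0),
                        durFrac = 0.85, attackSec = 0.02, pauseFloor = 0.25,
                        envWeights = c(phrase = 1, word = 0.8,
                                       syllable = 0.5, phoneme = 0.5),
                        nParticipants = 20, nTrials = 40, pCorrect = 0.7,
                        gridDims = c(8, 8, 8), gridSpacing = 6,
                        effectRegion = NULL, pacRegion = NULL,
                        trackingSnrCorrect = 0.6,
                        trackingSnrIncorrect = 0.2,
                        neuralLagMs = 100,
                        pacDepthCorrect = 0.8, pacDepthIncorrect = 0,
                        pacAmplitude = 0.6,
                        pacCarrierBand = c(16, 25),
                        pacPhaseBand = c(0.6, 1.3),
                        noiseExponent = 1, masterSeed = 1) {
  cfg <- as.list(environment())
  if (is.null(cfg$effectRegion))
    cfg$effectRegion <- centralRegion(gridDims, 3L)
  if (is.null(cfg$pacRegion)) cfg$pacRegion <- cfg$effectRegion
  stopifnot(all(rateMeans > 0), all(rateSDs >= 0),
            pCorrect > 0, pCorrect < 1,
            trackingSnrCorrect >= 0, trackingSnrIncorrect >= 0,
            pacDepthCorrect >= 0, pacDepthCorrect <= 1,
            pacDepthIncorrect >= 0, pacDepthIncorrect <= 1,
            all(eventCounts >= 2))
  if (any(cfg$effectRegion < 1 | cfg$effectRegion > prod(gridDims)))
    stop("invalid config: effect region outside the grid")
  class(cfg) <- "synthConfig"
  cfg
}

#' Central cubic region of a lattice
#'
#' Grid indices of a centred \code{size}^3 cube, in the column-major index
#' convention of \code{\link{gridCoordinates}}.
#'
#' @param gridDims 3-element lattice dimensions.
#' @param size cube edge length.
#' @return integer vector of grid indices.
#' @export
centralRegion <- function(gridDims, size = 3L) {
  lo <- pmax(1L, floor((gridDims - size) / 2) + 1L)
  ix <- expand.grid(x = lo[1L]:(lo[1L] + size - 1L),
                    y = lo[2L]:(lo[2L] + size - 1L),
                    z = lo[3L]:(lo[3L] + size - 1L))
  as.integer(ix$x + (ix$y - 1L) * gridDims[1L] +
               (ix$z - 1L) * gridDims[1L] * gridDims[2L])
}

#' Coordinates of a regular lattice
#'
#' @param gridDims 3-element lattice dimensions.
#' @param spacing lattice spacing (mm).
#' @return n x 3 coordinate matrix in mm (column-major point order).
#' @export
gridCoordinates <- function(gridDims, spacing = 6) {
  g <- expand.grid(x = seq_len(gridDims[1L]), y = seq_len(gridDims[2L]),
                   z = seq_len(gridDims[3L]))
  as.matrix(g) * spacing
}

# one smoothed event pulse added in place: fast half-sine attack (so every
# onset is a local envelope rise even under overlapping decays), half-cosine
# decay over the remaining duration
.addPulse <- function(env, t, onset, dur, weight, attackSec) {
  a <- min(attackSec, 0.3 * dur)
  idx <- which(t >= onset & t <= onset + dur)
  if (!length(idx)) return(env)
  tau <- t[idx] - onset
  p <- ifelse(tau < a, sin(pi * tau / (2 * a)),
              cos(pi * (tau - a) / (2 * (dur - a))))
  env[idx] <- env[idx] + weight * p
  env
}

# Annotation/envelope consistency guard: in rare pulse collisions (a fast
# onset during steep overlapping decays inside the pause) the summed
# envelope can fail to rise at an annotated onset. Add a small onset burst,
# just above the local decay, so every onset is a local rise by
# construction.
.ensureOnsetRises <- function(env, t, onsets, rate) {
  for (pass in 1:3) {
    fixed <- TRUE
    for (o in onsets) {
      idx <- floor(o * rate) + 1L
      j <- max(1L, idx - 1L):min(length(env) - 1L, idx + 1L)
      win <- env[j + 1L] - env[j]
      if (!any(win > 0)) {
        env <- .addPulse(env, t, o, 0.06, 1.5 * max(-win) + 1e-3, 0.013)
        fixed <- FALSE
      }
    }
    if (fixed) break
  }
  env
}

#' Generate a synthetic sentence corpus
#'
#' Draws, per sentence and linguistic category, a target rate from the
#' configured normal distribution, then inter-onset intervals (log-normal,
#' rescaled so the per-sentence rate is exact) and event durations
#' (\code{durFrac} of the interval, with category-specific jitter). The
#' wideband envelope is composed as a weighted sum of smoothed pulse
#' trains, one per category, so that phrasal, word, syllable and phoneme
#' rhythms are all present at their configured rates and every annotated
#' onset coincides with an envelope rise.
#'
#' @param cfg a \code{\link{synthConfig}}.
#' @param seed RNG seed (default: the config's master seed).
#' @return a \code{\linkS4class{SentenceCorpus}}.
#' @export
generateCorpus <- function(cfg, seed = cfg$masterSeed) {
  set.seed(seed)
  cats <- names(cfg$rateMeans)
  annL <- list(); envL <- list()
  for (s in seq_len(cfg$nSentences)) {
    sid <- sprintf("s%03d", s)
    rows <- list()
    for (cat in cats) {
      r <- max(stats::rnorm(1, cfg$rateMeans[[cat]], cfg$rateSDs[[cat]]),
               0.25 * cfg$rateMeans[[cat]])
      n <- cfg$eventCounts[[cat]]
      ioi <- if (n == 2L) 1 / r else {
        raw <- stats::rlnorm(n - 1L, 0, cfg$ioiSdlog[[cat]])
        raw / mean(raw) / r
      }
      onsets <- c(0, cumsum(ioi))
      dur <- cfg$durFrac * c(ioi, mean(ioi)) *
        stats::rlnorm(n, 0, cfg$durJitterSdlog[[cat]])
      rows[[cat]] <- data.frame(sentence_id = sid, category = cat,
                                onset_s = onsets, duration_s = dur,
                                stringsAsFactors = FALSE)
    }
    ann <- do.call(rbind, c(rows, make.row.names = FALSE))
    tEnd <- max(ann$onset_s + ann$duration_s) + 0.2
    t <- seq(0, tEnd, by = 1 / cfg$rate)
    trains <- lapply(cats, function(cat) {
      d <- rows[[cat]]
      tr <- numeric(length(t))
      for (i in seq_len(nrow(d)))
        tr <- .addPulse(tr, t, d$onset_s[i], d$duration_s[i], 1,
                        cfg$attackSec)
      tr
    })
    names(trains) <- cats
    fast <- Reduce(`+`, lapply(setdiff(cats, "phrase"), function(cat)
      cfg$envWeights[[cat]] * trains[[cat]]))
    # the two opening phrases gate the faster material: energy dips in the
    # pause between them, which carries the phrasal rhythm of the corpus
    p2 <- rows$phrase
    phraseEnd <- max(p2$onset_s + p2$duration_s)
    gate <- cfg$pauseFloor +
      (1 - cfg$pauseFloor) * pmin(1, trains$phrase + (t > phraseEnd))
    env <- cfg$envWeights[["phrase"]] * trains$phrase + fast * gate
    env <- .ensureOnsetRises(env, t, ann$onset_s, cfg$rate)
    annL[[s]] <- ann
    envL[[sid]] <- env
  }
  new("SentenceCorpus",
      annotations = do.call(rbind, c(annL, make.row.names = FALSE)),
      envelopes = envL, rate = cfg$rate)
}

# 1/f^exponent noise matrix (n x k), columns independent, unit variance
.pinkNoise <- function(n, k, exponent = 1) {
  W <- matrix(stats::rnorm(n * k), n, k)
  if (exponent == 0) return(W)
  f <- pmin(seq_len(n) - 1L, n - (seq_len(n) - 1L))
  amp <- c(0, 1 / f[-1L]^(exponent / 2))
  X <- Re(stats::mvfft(stats::mvfft(W) * amp, inverse = TRUE)) / n
  sweep(X, 2L, apply(X, 2L, stats::sd), "/")
}

#' Generate one participant's trial set
#'
#' Per trial, a sentence is drawn from the corpus and labelled correct with
#' probability \code{pCorrect}. Neural series are 1/f noise; at effect
#' region points the standardised envelope, delayed by \code{neuralLagMs},
#' is added with the label's SNR. At PAC region points a band-limited beta
#' carrier is added whose amplitude is 1 + depth(label) x cos(phrasal-band
#' phase of that point's own series).
#'
#' @param cfg a \code{\link{synthConfig}}.
#' @param corpus a \code{\linkS4class{SentenceCorpus}} from
#'   \code{\link{generateCorpus}}.
#' @param seed RNG seed for this participant.
#' @return a raw \code{\linkS4class{TrialSet}}.
#' @export
generateParticipant <- function(cfg, corpus, seed) {
  set.seed(seed)
  rate <- cfg$rate
  nG <- prod(cfg$gridDims)
  grid <- gridCoordinates(cfg$gridDims, cfg$gridSpacing)
  L <- as.integer(round(cfg$neuralLagMs * rate / 1000))
  ids <- names(corpus@envelopes)
  pick <- sample(ids, cfg$nTrials, replace = cfg$nTrials > length(ids))
  labels <- factor(ifelse(stats::runif(cfg$nTrials) < cfg$pCorrect,
                          "correct", "incorrect"),
                   levels = c("correct", "incorrect"))
  phaseBand <- bandSpec("phrasal", cfg$pacPhaseBand[1L], cfg$pacPhaseBand[2L])
  speech <- vector("list", cfg$nTrials)
  neural <- vector("list", cfg$nTrials)
  for (tr in seq_len(cfg$nTrials)) {
    env <- corpus@envelopes[[pick[tr]]]
    n <- length(env)
    if (n <= L + rate) stop("invalid duration: trial shorter than lag + trim")
    envStd <- (env - mean(env)) / stats::sd(env)
    envDel <- c(numeric(L), envStd[seq_len(n - L)])
    snr <- if (labels[tr] == "correct") cfg$trackingSnrCorrect else
      cfg$trackingSnrIncorrect
    depth <- if (labels[tr] == "correct") cfg$pacDepthCorrect else
      cfg$pacDepthIncorrect
    X <- .pinkNoise(n, nG, cfg$noiseExponent)
    X[, cfg$effectRegion] <- X[, cfg$effectRegion] + snr * envDel
    if (cfg$pacAmplitude > 0) {
      for (g in cfg$pacRegion) {
        ph <- bandpassAnalytic(X[, g], phaseBand, rate)
        cosPhi <- Re(ph / Mod(ph))
        carrier <- bandpassFilter(stats::rnorm(n), cfg$pacCarrierBand[1L],
                                  cfg$pacCarrierBand[2L], rate)
        carrier <- carrier / stats::sd(carrier)
        X[, g] <- X[, g] + cfg$pacAmplitude * (1 + depth * cosPhi) * carrier
      }
    }
    speech[[tr]] <- env
    neural[[tr]] <- X
  }
  new("TrialSet", speech = speech, neural = neural, labels = labels,
      grid = grid, rate = rate, band = NULL, analytic = FALSE)
}

#' Generate a full synthetic study
#'
#' A shared corpus plus one \code{\linkS4class{TrialSet}} per participant,
#' each with its own deterministic seed derived from the master seed.
#'
#' @param cfg a \code{\link{synthConfig}}.
#' @param corpus optional pre-generated corpus.
#' @param seed master seed (default from the config).
#' @return list with \code{corpus} and \code{participants} (list of
#'   \code{\linkS4class{TrialSet}}).
#' @export
generateStudy <- function(cfg, corpus = NULL, seed = cfg$masterSeed) {
  if (is.null(corpus)) corpus <- generateCorpus(cfg, seed)
  participants <- lapply(seq_len(cfg$nParticipants), function(p)
    generateParticipant(cfg, corpus, seed = (seed + 7919L * p) %% .Machine$integer.max))
  list(corpus = corpus, participants = participants)
}

#' Label counts and subsample size
#'
#' Counts correct and incorrect trials and the equalised subsample size
#' floor(frac x min(n_correct, n_incorrect)) used by the condition
#' contrasts (e.g. 70/30 trials at frac 0.8 give 24).
#'
#' @param trials a \code{\linkS4class{TrialSet}}.
#' @param frac subsampling fraction (default 0.8).
#' @return list with \code{nCorrect}, \code{nIncorrect},
#'   \code{subsampleSize}.
#' @export
labelCounts <- function(trials, frac = 0.8) {
  nc <- sum(trials@labels == "correct")
  ni <- sum(trials@labels == "incorrect")
  list(nCorrect = nc, nIncorrect = ni,
       subsampleSize = floor(frac * min(nc, ni)))
}
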