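#' Greenwood cochlear frequency-position map
#'
#' Maps relative cochlear position x in [0, 1] (apex to base) to frequency
#' via F(x) = A (10^(a x) - k) with the standard human constants
#' A = 165.4, a = 2.1, k = 0.88, and back. Used to place filterbank edges
#' at equal distances along the cochlea.
#'
#' @param x relative cochlear position(s) in [0, 1].
#' @param f frequency (Hz).
#' @return \code{greenwoodFrequency}: frequency in Hz;
#'   \code{greenwoodPosition}: relative position in [0, 1].
#' @examples
#' greenwoodPosition(greenwoodFrequency(0.5))
#' @export
greenwoodFrequency <- function(x) 165.4 * (10^(2.1 * x) - 0.88)

#' @rdname greenwoodFrequency
#' @export
greenwoodPosition <- function(f) log10(f / 165.4 + 0.88) / 2.1

#' Cochlear-spaced filterbank edges
#'
#' Partition [fLo, fHi] into \code{nBands} contiguous bands whose edges are
#' equidistant on the Greenwood cochlear map. Because the map is compressive,
#' low-frequency bands come out narrower in Hz than high-frequency ones.
#'
#' @param nBands number of bands (>= 1).
#' @param fLo,fHi outer edges in Hz (0 < fLo < fHi).
#' @return numeric matrix with columns \code{fLo}, \code{fHi}, one row per
#'   band; edges strictly increasing, first = fLo, last = fHi.
#' @examples
#' cochlearBandEdges(8, 100, 8000)
#' @export
cochlearBandEdges <- function(nBands, fLo = 100, fHi = 8000) {
  if (nBands < 1L) stop("'nBands' must be >= 1")
  if (!(fLo > 0 && fHi > fLo)) stop("invalid range: need 0 < fLo < fHi")
  xs <- seq(greenwoodPosition(fLo), greenwoodPosition(fHi),
            length.out = nBands + 1L)
  edges <- greenwoodFrequency(xs)
  edges[1L] <- fLo; edges[nBands + 1L] <- fHi  # exact outer edges
  cbind(fLo = edges[-(nBands + 1L)], fHi = edges[-1L])
}

#' Event rates of a linguistic category across a corpus
#'
#' For each sentence, the category's rate is the reciprocal of its mean
#' inter-onset interval. Summaries (mean, sd, min, max) are taken across
#' sentences; the coefficient of variation is computed from the pooled
#' event durations (population SD / mean).
#'
#' @param ann annotation data.frame with columns \code{sentence_id},
#'   \code{category}, \code{onset_s}, \code{duration_s}.
#' @param category one of \code{"phrase"}, \code{"word"}, \code{"syllable"},
#'   \code{"phoneme"} (any label present in \code{ann}).
#' @return a \code{\linkS4class{RateSummary}}.
#' @examples
#' ann <- data.frame(sentence_id = "s1", category = "word",
#'                   onset_s = c(0, 1, 2), duration_s = 0.8)
#' ratesFromOnsets(ann, "word")
#' @export
ratesFromOnsets <- function(ann, category) {
  sub <- ann[ann$category == category, , drop = FALSE]
  if (!nrow(sub)) stop("no annotations for category '", category, "'")
  bySent <- split(sub, sub$sentence_id)
  rates <- vapply(bySent, function(d) {
    if (nrow(d) < 2L)
      stop("rate undefined: sentence '", d$sentence_id[1L],
           "' has < 2 onsets in category '", category, "'")
    1 / mean(diff(sort(d$onset_s)))
  }, numeric(1))
  dur <- sub$duration_s
  cv <- sqrt(mean((dur - mean(dur))^2)) / mean(dur)  # population SD
  new("RateSummary", category = category, perSentenceRates = rates,
      mean = mean(rates), sd = stats::sd(rates), min = min(rates),
      max = max(rates), cv = cv)
}

#' Derive a stimulus-specific frequency band
#'
#' The band edges are the minimum and maximum per-sentence rates of the
#' category across the corpus, rounded to \code{digits} decimals (printed
#' bands use 1 decimal).
#'
#' @param summary a \code{\linkS4class{RateSummary}}.
#' @param digits decimals for rounding the edges.
#' @return a \code{\linkS4class{BandSpec}} named after the category.
#' @examples
#' ann <- data.frame(sentence_id = rep(c("a", "b"), each = 3),
#'                   category = "phrase",
#'                   onset_s = c(0, 1.667, 3.334, 0, 0.769, 1.538),
#'                   duration_s = 0.5)
#' deriveBand(ratesFromOnsets(ann, "phrase"))  # 0.6-1.3 Hz
#' @export
deriveBand <- function(summary, digits = 1) {
  lo <- round(summary@min, digits)
  hi <- round(summary@max, digits)
  if (lo >= hi) stop("degenerate band: rounded min equals rounded max")
  bandSpec(summary@category, lo, hi)
}

#' Derive the stress timescale from the syllable band
#'
#' Treating every \code{everyNth} syllable as stressed divides both syllable
#' band edges by \code{everyNth} (rounded to 1 decimal): the canonical
#' syllable band 2.8-4.8 Hz yields a stress band of 0.9-1.6 Hz.
#'
#' @param syllableBand a \code{\linkS4class{BandSpec}}.
#' @param everyNth stress interval in syllables (>= 1).
#' @return a \code{\linkS4class{BandSpec}} named \code{"stress"}.
#' @examples
#' deriveStressBand(bandSpec("syllable", 2.8, 4.8))
#' @export
deriveStressBand <- function(syllableBand, everyNth = 3) {
  if (everyNth < 1) stop("'everyNth' must be >= 1")
  bandSpec(if (everyNth == 1) syllableBand@name else "stress",
           round(syllableBand@fLo / everyNth, 1),
           round(syllableBand@fHi / everyNth, 1))
}

#' Canonical stimulus-specific and control bands
#'
#' \code{canonicalBands} returns the four corpus-derived linguistic bands:
#' phrase 0.6-1.3, word 1.8-3.0, syllable 2.8-4.8, phoneme 8-12.4 Hz.
#' \code{powerBands} returns the fixed beta (13-30), alpha (8-12) and theta
#' (4-8) bands used for cross-frequency coupling and its controls.
#' \code{genericBands} returns the seven overlapping 2-Hz-wide bands from
#' 0 to 8 Hz in 1-Hz steps used as a frequency-agnostic control.
#'
#' @return a named list of \code{\linkS4class{BandSpec}} objects.
#' @examples
#' length(genericBands())  # 7
#' @export
canonicalBands <- function() {
  list(phrase   = bandSpec("phrase",   0.6, 1.3),
       word     = bandSpec("word",     1.8, 3.0),
       syllable = bandSpec("syllable", 2.8, 4.8),
       phoneme  = bandSpec("phoneme",  8.0, 12.4))
}

#' @rdname canonicalBands
#' @export
powerBands <- function() {
  list(beta  = bandSpec("beta",  13, 30),
       alpha = bandSpec("alpha",  8, 12),
       theta = bandSpec("theta",  4,  8))
}

#' @rdname canonicalBands
#' @export
genericBands <- function() {
  lapply(0:6, function(lo) bandSpec(sprintf("%d-%dHz", lo, lo + 2), lo, lo + 2))
}
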