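#' @import methods
NULL

#' Frequency band specification
#'
#' A named frequency band with lower and upper edge in Hz. Bands are either
#' derived from the timing statistics of a speech corpus (see
#' \code{\link{deriveBand}}) or fixed a priori (e.g. beta, 13--30 Hz).
#' A lower edge of exactly 0 Hz denotes a low-pass band and is permitted
#' only for the generic band sweep.
#'
#' @slot name character, label of the band (e.g. \code{"phrase"}).
#' @slot fLo numeric, lower edge in Hz (>= 0).
#' @slot fHi numeric, upper edge in Hz (> fLo).
#'
#' @seealso \code{\link{bandSpec}}, \code{\link{canonicalBands}}
#' @exportClass BandSpec
setClass("BandSpec",
         representation(name = "character", fLo = "numeric", fHi = "numeric"))

setValidity("BandSpec", function(object) {
  msg <- NULL
  if (length(object@name) != 1L) msg <- c(msg, "'name' must be a single string")
  if (length(object@fLo) != 1L || length(object@fHi) != 1L)
    msg <- c(msg, "band edges must be single numbers")
  else {
    if (!is.finite(object@fLo) || object@fLo < 0)
      msg <- c(msg, "'fLo' must be finite and >= 0")
    if (!is.finite(object@fHi) || object@fHi <= object@fLo)
      msg <- c(msg, "'fHi' must be finite and > 'fLo' (degenerate band)")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a BandSpec
#'
#' @param name band label.
#' @param fLo lower edge in Hz.
#' @param fHi upper edge in Hz.
#' @return A \code{\linkS4class{BandSpec}} object.
#' @examples
#' bandSpec("phrase", 0.6, 1.3)
#' @export
bandSpec <- function(name, fLo, fHi) {
  new("BandSpec", name = as.character(name), fLo = as.numeric(fLo),
      fHi = as.numeric(fHi))
}

setMethod("show", "BandSpec", function(object) {
  cat(sprintf("BandSpec '%s': %.2f-%.2f Hz\n",
              object@name, object@fLo, object@fHi))
})

#' Per-category event rate summary
#'
#' Summary of per-sentence event rates (1 / mean inter-onset interval) of a
#' linguistic category across a corpus, plus the coefficient of variation of
#' the pooled event durations.
#'
#' @slot category character, linguistic category.
#' @slot perSentenceRates numeric, one rate (Hz) per sentence.
#' @slot mean,sd,min,max numeric summaries of the per-sentence rates (Hz).
#' @slot cv numeric, sd/mean of the pooled event durations (dimensionless).
#'
#' @seealso \code{\link{ratesFromOnsets}}
#' @exportClass RateSummary
setClass("RateSummary",
         representation(category = "character", perSentenceRates = "numeric",
                        mean = "numeric", sd = "numeric", min = "numeric",
                        max = "numeric", cv = "numeric"))

setValidity("RateSummary", function(object) {
  msg <- NULL
  if (any(object@perSentenceRates <= 0)) msg <- c(msg, "rates must be positive")
  if (object@min > object@mean || object@mean > object@max)
    msg <- c(msg, "min <= mean <= max violated")
  if (object@cv < 0) msg <- c(msg, "cv must be >= 0")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "RateSummary", function(object) {
  cat(sprintf(
    "RateSummary '%s': %d sentences, %.2f +/- %.2f Hz (range %.2f-%.2f), cv(durations) = %.2f\n",
    object@category, length(object@perSentenceRates), object@mean, object@sd,
    object@min, object@max, object@cv))
})

#' Sentence corpus: annotations and wideband envelopes
#'
#' Container for a sentence corpus: onset/duration annotations per linguistic
#' category plus the wideband amplitude envelope of every sentence at a
#' common sampling rate.
#'
#' @slot annotations data.frame with columns \code{sentence_id},
#'   \code{category}, \code{onset_s}, \code{duration_s}.
#' @slot envelopes named list of non-negative numeric vectors, one per
#'   sentence, at \code{rate} Hz.
#' @slot rate numeric, envelope sampling rate in Hz (canonically 150).
#'
#' @seealso \code{\link{generateCorpus}}, \code{\link{readAnnotations}}
#' @exportClass SentenceCorpus
setClass("SentenceCorpus",
         representation(annotations = "data.frame", envelopes = "list",
                        rate = "numeric"))

setValidity("SentenceCorpus", function(object) {
  msg <- NULL
  need <- c("sentence_id", "category", "onset_s", "duration_s")
  if (!all(need %in% names(object@annotations)))
    msg <- c(msg, paste("annotations must have columns:",
                        paste(need, collapse = ", ")))
  else {
    if (any(object@annotations$duration_s <= 0))
      msg <- c(msg, "durations must be > 0")
    ord <- tapply(object@annotations$onset_s,
                  paste(object@annotations$sentence_id,
                        object@annotations$category),
                  function(o) all(diff(o) > 0))
    if (!all(unlist(ord)))
      msg <- c(msg, "onsets must be strictly increasing within sentence/category")
  }
  if (length(object@rate) != 1L || object@rate <= 0)
    msg <- c(msg, "'rate' must be a single positive number")
  if (length(object@envelopes) &&
      any(vapply(object@envelopes, function(e) any(e < 0), logical(1))))
    msg <- c(msg, "envelopes must be non-negative")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "SentenceCorpus", function(object) {
  cat(sprintf("SentenceCorpus: %d sentences, %d annotation rows, envelopes at %g Hz\n",
              length(object@envelopes), nrow(object@annotations), object@rate))
})

#' Per-participant trial set
#'
#' Trials of paired speech-envelope and source-level neural time series on a
#' 3-D grid, with a correct/incorrect comprehension label per trial. Series
#' are either raw real-valued signals or, after
#' \code{\link{analyticTrials}}, complex analytic signals band-limited to
#' \code{band}.
#'
#' @slot speech list (one per trial) of numeric or complex vectors.
#' @slot neural list (one per trial) of matrices, time x grid point.
#' @slot labels factor with levels \code{correct}, \code{incorrect}.
#' @slot grid numeric matrix, grid point coordinates in mm (n x 3).
#' @slot rate numeric, sampling rate in Hz.
#' @slot band ANY, \code{\linkS4class{BandSpec}} after filtering, else NULL.
#' @slot analytic logical, TRUE once series are complex analytic signals.
#'
#' @seealso \code{\link{generateParticipant}}, \code{\link{analyticTrials}}
#' @exportClass TrialSet
setClass("TrialSet",
         representation(speech = "list", neural = "list", labels = "factor",
                        grid = "matrix", rate = "numeric", band = "ANY",
                        analytic = "logical"))

setValidity("TrialSet", function(object) {
  msg <- NULL
  nt <- length(object@speech)
  if (length(object@neural) != nt)
    msg <- c(msg, "speech and neural must have one entry per trial")
  if (length(object@labels) != nt)
    msg <- c(msg, "one label per trial required")
  if (!all(levels(object@labels) %in% c("correct", "incorrect")))
    msg <- c(msg, "labels must be 'correct'/'incorrect'")
  lenOK <- vapply(seq_len(nt), function(i) {
    length(object@speech[[i]]) == nrow(object@neural[[i]])
  }, logical(1))
  if (nt && !all(lenOK))
    msg <- c(msg, "speech and neural series must share length within a trial")
  if (ncol(object@grid) != 3L)
    msg <- c(msg, "grid must be an n x 3 coordinate matrix")
  if (anyDuplicated(object@grid))
    msg <- c(msg, "grid coordinates must be unique")
  if (nt && ncol(object@neural[[1L]]) != nrow(object@grid))
    msg <- c(msg, "neural columns must match grid points")
  if (!is.null(object@band) && !is(object@band, "BandSpec"))
    msg <- c(msg, "band must be NULL or a BandSpec")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "TrialSet", function(object) {
  bd <- if (is.null(object@band)) "broadband" else
    sprintf("%s (%.2f-%.2f Hz)", object@band@name, object@band@fLo, object@band@fHi)
  cat(sprintf(
    "TrialSet: %d trials (%d correct / %d incorrect), %d grid points, %g Hz, %s%s\n",
    length(object@speech), sum(object@labels == "correct"),
    sum(object@labels == "incorrect"), nrow(object@grid), object@rate, bd,
    if (object@analytic) ", analytic" else ""))
})

#' Mutual-information map over source grid points
#'
#' Lag-summed mutual information (bits) between the speech envelope and the
#' neural signal at every grid point, with provenance.
#'
#' @slot mi numeric, MI in bits per grid point (>= 0).
#' @slot grid numeric matrix, grid coordinates (n x 3), in mm.
#' @slot band ANY, the \code{\linkS4class{BandSpec}} analysed.
#' @slot lagsMs numeric, stimulus-brain lags (ms) summed over.
#' @slot condition character, one of \code{all}, \code{correct},
#'   \code{incorrect}, \code{surrogate}.
#' @slot nTrialsUsed integer, trials entering each MI estimate.
#' @slot nRepeats integer, subsample/surrogate repeats averaged.
#'
#' @exportClass MIMap
setClass("MIMap",
         representation(mi = "numeric", grid = "matrix", band = "ANY",
                        lagsMs = "numeric", condition = "character",
                        nTrialsUsed = "integer", nRepeats = "integer"))

setValidity("MIMap", function(object) {
  msg <- NULL
  if (any(object@mi < 0)) msg <- c(msg, "MI values must be >= 0")
  if (length(object@mi) != nrow(object@grid))
    msg <- c(msg, "one MI value per grid point required")
  if (!object@condition %in% c("all", "correct", "incorrect", "surrogate"))
    msg <- c(msg, "unknown condition")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "MIMap", function(object) {
  cat(sprintf(
    "MIMap [%s, %s]: %d grid points, lags {%s} ms, MI %.4g-%.4g bits (%d trials, %d repeats)\n",
    if (is.null(object@band)) "broadband" else object@band@name,
    object@condition, length(object@mi),
    paste(object@lagsMs, collapse = ","), min(object@mi), max(object@mi),
    object@nTrialsUsed, object@nRepeats))
})

#' Group-level t map
#'
#' Dependent-samples t statistic per grid point, with degrees of freedom.
#'
#' @slot t numeric, t statistic per grid point (finite; zero-variance points
#'   are forced to 0 and flagged in \code{zeroVar}).
#' @slot df integer, degrees of freedom (participants - 1).
#' @slot zeroVar integer, indices where the difference variance was zero.
#' @exportClass TMap
setClass("TMap",
         representation(t = "numeric", df = "integer", zeroVar = "integer"))

setValidity("TMap", function(object) {
  msg <- NULL
  if (any(!is.finite(object@t))) msg <- c(msg, "t values must be finite")
  if (object@df < 1L) msg <- c(msg, "df must be >= 1")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "TMap", function(object) {
  cat(sprintf("TMap: %d grid points, df = %d, t range %.2f to %.2f\n",
              length(object@t), object@df, min(object@t), max(object@t)))
})
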