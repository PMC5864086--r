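#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers, so user code
#' never touches slots directly.
#'
#' @param x an object.
#' @return \code{nTrials}, \code{nGridPoints}: integer counts;
#'   \code{gridCoords}: n x 3 coordinate matrix (mm); \code{trialLabels}:
#'   factor of correct/incorrect labels; \code{sampleRate}: Hz;
#'   \code{miValues}: numeric MI vector (bits); \code{bandOf}: the
#'   \code{\linkS4class{BandSpec}} (or NULL); \code{tValues}: numeric t map.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))
#' @rdname accessors
#' @export
setGeneric("nGridPoints", function(x) standardGeneric("nGridPoints"))
#' @rdname accessors
#' @export
setGeneric("gridCoords", function(x) standardGeneric("gridCoords"))
#' @rdname accessors
#' @export
setGeneric("trialLabels", function(x) standardGeneric("trialLabels"))
#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("miValues", function(x) standardGeneric("miValues"))
#' @rdname accessors
#' @export
setGeneric("bandOf", function(x) standardGeneric("bandOf"))
#' @rdname accessors
#' @export
setGeneric("tValues", function(x) standardGeneric("tValues"))

#' @rdname accessors
setMethod("nTrials", "TrialSet", function(x) length(x@speech))
#' @rdname accessors
setMethod("nGridPoints", "TrialSet", function(x) nrow(x@grid))
#' @rdname accessors
setMethod("nGridPoints", "MIMap", function(x) length(x@mi))
#' @rdname accessors
setMethod("gridCoords", "TrialSet", function(x) x@grid)
#' @rdname accessors
setMethod("gridCoords", "MIMap", function(x) x@grid)
#' @rdname accessors
setMethod("trialLabels", "TrialSet", function(x) x@labels)
#' @rdname accessors
setMethod("sampleRate", "TrialSet", function(x) x@rate)
#' @rdname accessors
setMethod("sampleRate", "SentenceCorpus", function(x) x@rate)
#' @rdname accessors
setMethod("miValues", "MIMap", function(x) x@mi)
#' @rdname accessors
setMethod("bandOf", "TrialSet", function(x) x@band)
#' @rdname accessors
setMethod("bandOf", "MIMap", function(x) x@band)
#' @rdname accessors
setMethod("tValues", "TMap", function(x) x@t)

#' Annotations and envelopes of a corpus
#'
#' @param x a \code{\linkS4class{SentenceCorpus}}.
#' @return \code{annotations}: the annotation data.frame;
#'   \code{envelopes}: named list of envelope vectors.
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))
#' @rdname annotations
#' @export
setGeneric("envelopes", function(x) standardGeneric("envelopes"))
#' @rdname annotations
setMethod("annotations", "SentenceCorpus", function(x) x@annotations)
#' @rdname annotations
setMethod("envelopes", "SentenceCorpus", function(x) x@envelopes)

#' Subset a TrialSet by trial index
#'
#' @param x a \code{\linkS4class{TrialSet}}.
#' @param i integer or logical trial indices.
#' @param j,...,drop ignored.
#' @return a \code{\linkS4class{TrialSet}} with the selected trials.
#' @export
setMethod("[", "TrialSet", function(x, i, j, ..., drop = FALSE) {
  initialize(x, speech = x@speech[i], neural = x@neural[i],
             labels = x@labels[i])
})
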