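#' Read linguistic annotations
#'
#' Reads onset/duration annotations of linguistic events. Two dialects are
#' supported: a tab-separated table with columns \code{sentence_id},
#' \code{category}, \code{onset_s}, \code{duration_s}
#' (\code{readAnnotations}), and Praat TextGrid interval tiers whose tier
#' names give the category (\code{readTextGrid}; import only). Times are in
#' seconds from sentence audio onset.
#'
#' @param path path to the annotation file.
#' @return data.frame with columns \code{sentence_id}, \code{category},
#'   \code{onset_s}, \code{duration_s}, ordered by onset within
#'   sentence/category.
#' @export
readAnnotations <- function(path) {
  ann <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("sentence_id", "category", "onset_s", "duration_s")
  if (!all(need %in% names(ann)))
    stop("annotation file must have columns: ", paste(need, collapse = ", "))
  validateAnnotations(ann[need])
}

#' @rdname readAnnotations
#' @param sentenceId sentence identifier to attach (TextGrids hold one
#'   sentence each).
#' @export
readTextGrid <- function(path, sentenceId = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  num <- function(l) as.numeric(sub(".*=\\s*", "", l))
  str <- function(l) gsub('.*=\\s*"(.*)"\\s*$', "\\1", l)
  tierStarts <- grep("item\\s*\\[[0-9]+\\]", lines)
  if (!length(tierStarts)) stop("no interval tiers found in TextGrid")
  out <- list()
  bounds <- c(tierStarts, length(lines) + 1L)
  for (k in seq_along(tierStarts)) {
    block <- lines[bounds[k]:(bounds[k + 1L] - 1L)]
    if (!any(grepl("IntervalTier", block))) next
    tierName <- str(block[grep("^\\s*name\\s*=", block)[1L]])
    xmin <- num(block[grep("^\\s*xmin\\s*=", block)])
    xmax <- num(block[grep("^\\s*xmax\\s*=", block)])
    text <- str(block[grep("^\\s*text\\s*=", block)])
    # first xmin/xmax pair describes the tier itself, not an interval
    xmin <- xmin[-1L]; xmax <- xmax[-1L]
    keep <- !is.na(text) & nzchar(trimws(text))
    if (!any(keep)) next
    out[[tierName]] <- data.frame(
      sentence_id = sentenceId, category = tierName,
      onset_s = xmin[keep], duration_s = xmax[keep] - xmin[keep],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no labelled intervals found in TextGrid")
  validateAnnotations(do.call(rbind, c(out, make.row.names = FALSE)))
}

#' Validate an annotation table
#'
#' Checks the annotation invariants: positive durations and strictly
#' increasing onsets within each sentence/category; rows are returned
#' ordered by onset.
#'
#' @param ann annotation data.frame.
#' @return the validated, ordered data.frame (invisibly errors otherwise).
#' @export
validateAnnotations <- function(ann) {
  if (any(!is.finite(ann$onset_s)) || any(!is.finite(ann$duration_s)))
    stop("non-finite onset or duration")
  if (any(ann$duration_s <= 0)) stop("durations must be > 0")
  ann <- ann[order(ann$sentence_id, ann$category, ann$onset_s), , drop = FALSE]
  ok <- tapply(ann$onset_s, paste(ann$sentence_id, ann$category),
               function(o) all(diff(o) > 0))
  if (!all(unlist(ok)))
    stop("onsets must be strictly increasing within sentence/category")
  rownames(ann) <- NULL
  ann
}
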