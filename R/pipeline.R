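#' Pipeline configuration
#'
#' Analysis settings for the end-to-end pipeline. The defaults are the
#' canonical analysis parameters: lags 60-140 ms in 20-ms steps, 50
#' trial-shuffle surrogate iterations, 80% equalised subsampling with 20
#' repeats for the tracking contrast, 50 repeats for the PAC region test
#' and 20 for the whole-grid PAC contrast, 1000 cluster permutations at a
#' 5% cluster alpha, third-order filters and 0.5-s edge trims. Tests and
#' examples scale these down via the arguments.
#'
#' @param lagsMs stimulus-brain lag grid (ms).
#' @param surrogateNIter trial-shuffle iterations.
#' @param surrogateScheme \code{"shuffle"} or \code{"timereverse"}.
#' @param frac equalised subsample fraction.
#' @param trackingRepeats,pacRegionRepeats,pacWholeGridRepeats subsample
#'   repeats for the three contrast analyses.
#' @param nPerm cluster permutations.
#' @param clusterAlpha cluster significance level.
#' @param filterOrder Butterworth order for all analysis bands.
#' @param edgeTrimSec seconds trimmed per trial edge after filtering.
#' @param masterSeed seed fanned out to all stochastic steps.
#' @return a list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(lagsMs = lagGrid(), surrogateNIter = 50,
                           surrogateScheme = c("shuffle", "timereverse"),
                           frac = 0.8, trackingRepeats = 20,
                           pacRegionRepeats = 50, pacWholeGridRepeats = 20,
                           nPerm = 1000, clusterAlpha = 0.05,
                           filterOrder = 3, edgeTrimSec = 0.5,
                           masterSeed = 1) {
  cfg <- as.list(environment())
  cfg$surrogateScheme <- match.arg(surrogateScheme)
  class(cfg) <- "pipelineConfig"
  cfg
}

# stable content hash (djb2) of a config echoed into every output sidecar
.configHash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(unclass(x)), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Derive the stimulus-specific bands of a corpus
#'
#' Applies \code{\link{ratesFromOnsets}} and \code{\link{deriveBand}} to
#' every linguistic category present in the corpus annotations.
#'
#' @param corpus a \code{\linkS4class{SentenceCorpus}}.
#' @return named list of \code{\linkS4class{BandSpec}} objects.
#' @export
deriveCorpusBands <- function(corpus) {
  cats <- intersect(c("phrase", "word", "syllable", "phoneme"),
                    unique(annotations(corpus)$category))
  bands <- lapply(cats, function(cat)
    deriveBand(ratesFromOnsets(annotations(corpus), cat)))
  names(bands) <- cats
  bands
}

#' Overall speech tracking versus surrogate
#'
#' Per participant: band-filter the trials, compute the lag-summed tracking
#' MI at every grid point using all trials, and the matching surrogate map.
#' Comprehension labels are never read on this path.
#'
#' @param participants list of raw \code{\linkS4class{TrialSet}} objects.
#' @param band a \code{\linkS4class{BandSpec}}.
#' @param config a \code{\link{pipelineConfig}}.
#' @return list of participant x grid matrices \code{true} and
#'   \code{surrogate}.
#' @export
overallTracking <- function(participants, band, config = pipelineConfig()) {
  nG <- nGridPoints(participants[[1L]])
  true <- surr <- matrix(0, length(participants), nG)
  for (p in seq_along(participants)) {
    an <- analyticTrials(participants[[p]], band,
                         order = config$filterOrder,
                         edgeTrimSec = config$edgeTrimSec)
    true[p, ] <- trackingMI(an, lagsMs = config$lagsMs)
    surr[p, ] <- if (config$surrogateScheme == "shuffle") {
      surrogateShuffle(an, lagsMs = config$lagsMs,
                       nIter = config$surrogateNIter,
                       seed = config$masterSeed + 101L * p)
    } else {
      surrogateTimeReverse(an, lagsMs = config$lagsMs)
    }
  }
  list(true = true, surrogate = surr)
}

# per-participant condition contrast matrices for one band
.contrastMatrices <- function(participants, band, config) {
  nG <- nGridPoints(participants[[1L]])
  corr <- inc <- matrix(0, length(participants), nG)
  for (p in seq_along(participants)) {
    an <- analyticTrials(participants[[p]], band,
                         order = config$filterOrder,
                         edgeTrimSec = config$edgeTrimSec)
    cc <- conditionContrast(an, lagsMs = config$lagsMs, frac = config$frac,
                            nRepeats = config$trackingRepeats,
                            seed = config$masterSeed + 211L * p)
    corr[p, ] <- miValues(cc$correct)
    inc[p, ] <- miValues(cc$incorrect)
  }
  list(correct = corr, incorrect = inc)
}

# peak grid points (largest |t|) of significant clusters, up to `maxPeaks`
.clusterPeaks <- function(clusterRes, maxPeaks = 3L) {
  tab <- clusterRes$clusters
  sig <- which(tab$significant)
  if (!length(sig)) return(integer())
  peaks <- vapply(sig, function(k) {
    members <- which(clusterRes$membership == tab$id[k])
    members[which.max(abs(clusterRes$tmap@t[members]))]
  }, integer(1))
  unique(peaks)[seq_len(min(maxPeaks, length(unique(peaks))))]
}

#' Run the full analysis pipeline
#'
#' Executes the complete analysis graph on a (synthetic or imported) study:
#' stimulus-specific band derivation from the corpus annotations; per band,
#' the overall tracking-versus-surrogate cluster test and the
#' correct-versus-incorrect contrast cluster test; FDR-corrected post-hoc t
#' tests at cluster peak grid points across all bands; the PAC region test
#' (phrase phase x beta power plus three control band pairs,
#' FDR-corrected) in the tracking contrast cluster; the one-sided
#' whole-grid PAC cluster contrast; and, optionally, the generic-band
#' sweep. Returns all tables and matrices plus a run manifest carrying the
#' config and its hash.
#'
#' @param study list with \code{corpus} and \code{participants}, as
#'   returned by \code{\link{generateStudy}}.
#' @param config a \code{\link{pipelineConfig}}.
#' @param bands optional named band list (default: derived from the corpus;
#'   the first band plays the phrasal role, the second the word role).
#' @param pacRegion optional grid indices for the PAC region test
#'   (default: the significant contrast cluster of the first band, falling
#'   back to the peak-t point).
#' @param genericSweep also run the seven-band generic sweep (slow).
#' @param outDir optional directory; result tables and a JSON manifest are
#'   written there.
#' @return a list with components \code{bands}, \code{overall},
#'   \code{contrast}, \code{posthoc}, \code{pacRegion}, \code{pacWholeGrid},
#'   \code{generic} (or NULL) and \code{manifest}.
#' @export
runFullAnalysis <- function(study, config = pipelineConfig(), bands = NULL,
                            pacRegion = NULL, genericSweep = FALSE,
                            outDir = NULL) {
  corpus <- study$corpus
  participants <- study$participants
  if (length(participants) < 2L)
    stop("contract failed: need >= 2 participants")
  if (is.null(bands)) bands <- deriveCorpusBands(corpus)
  grid <- gridCoords(participants[[1L]])
  adjacency <- gridAdjacency(grid)
  tCrit <- criticalT(length(participants))

  overall <- list(); contrast <- list()
  contrastMats <- list()
  for (bn in names(bands)) {
    band <- bands[[bn]]
    ov <- overallTracking(participants, band, config)
    overall[[bn]] <- c(ov, list(
      cluster = clusterPermutation(ov$true - ov$surrogate, adjacency,
                                   nPerm = config$nPerm, tCrit = tCrit,
                                   clusterAlpha = config$clusterAlpha,
                                   seed = config$masterSeed + 31L)))
    cm <- .contrastMatrices(participants, band, config)
    contrastMats[[bn]] <- cm
    contrast[[bn]] <- c(cm, list(
      cluster = clusterPermutation(cm$correct - cm$incorrect, adjacency,
                                   nPerm = config$nPerm, tCrit = tCrit,
                                   clusterAlpha = config$clusterAlpha,
                                   seed = config$masterSeed + 47L)))
  }

  # post-hoc peak tests: peak points of significant contrast clusters,
  # tested in every band, FDR-corrected together
  peaks <- unique(unlist(lapply(contrast, function(x)
    .clusterPeaks(x$cluster))))
  posthoc <- NULL
  if (length(peaks)) {
    rows <- list()
    for (bn in names(bands)) {
      d <- contrastMats[[bn]]$correct - contrastMats[[bn]]$incorrect
      for (pk in peaks) {
        tt <- stats::t.test(d[, pk])
        rows[[length(rows) + 1L]] <- data.frame(
          band = bn, peak = pk, t = unname(tt$statistic),
          p = tt$p.value)
      }
    }
    posthoc <- do.call(rbind, rows)
    posthoc$pFDR <- fdrAdjust(posthoc$p)$adjusted
  }

  # PAC region: contrast cluster of the first band, else its peak t point
  if (is.null(pacRegion)) {
    c1 <- contrast[[1L]]$cluster
    sig <- which(c1$clusters$significant & c1$clusters$sign == "pos")
    pacRegion <- if (length(sig)) {
      which(c1$membership == c1$clusters$id[sig[1L]])
    } else {
      which.max(c1$tmap@t)
    }
  }
  pw <- powerBands()
  phraseBand <- bands[[1L]]
  wordBand <- if (length(bands) >= 2L) bands[[2L]] else bands[[1L]]
  pairs <- list(phrase_beta = list(phraseBand, pw$beta),
                phrase_alpha = list(phraseBand, pw$alpha),
                phrase_theta = list(phraseBand, pw$theta),
                word_beta = list(wordBand, pw$beta))
  pacRows <- list()
  for (pn in names(pairs)) {
    mC <- mI <- numeric(length(participants))
    for (p in seq_along(participants)) {
      res <- pacConditionContrast(
        participants[[p]], pairs[[pn]][[1L]], pairs[[pn]][[2L]],
        region = pacRegion, frac = config$frac,
        nRepeats = config$pacRegionRepeats,
        seed = config$masterSeed + 307L * p,
        order = config$filterOrder, edgeTrimSec = config$edgeTrimSec)
      mC[p] <- res$meanCorrect; mI[p] <- res$meanIncorrect
    }
    tt <- stats::t.test(mC, mI, paired = TRUE)
    pacRows[[pn]] <- data.frame(pair = pn, t = unname(tt$statistic),
                                p = tt$p.value)
  }
  pacTab <- do.call(rbind, pacRows)
  pacTab$pFDR <- fdrAdjust(pacTab$p)$adjusted

  wg <- pacWholeGridContrast(participants, phraseBand, pw$beta,
                             frac = config$frac,
                             nRepeats = config$pacWholeGridRepeats,
                             seed = config$masterSeed + 401L,
                             order = config$filterOrder,
                             edgeTrimSec = config$edgeTrimSec)
  wgCluster <- clusterPermutation(wg$diffs, adjacency, nPerm = config$nPerm,
                                  tCrit = tCrit,
                                  clusterAlpha = config$clusterAlpha,
                                  sided = "one",
                                  seed = config$masterSeed + 419L)

  generic <- if (genericSweep)
    genericBandSweep(study, config, adjacency = adjacency) else NULL

  manifest <- list(nParticipants = length(participants),
                   bands = lapply(bands, function(b)
                     c(fLo = b@fLo, fHi = b@fHi)),
                   config = unclass(config),
                   configHash = .configHash(config),
                   tCrit = tCrit,
                   pacRegionSize = length(pacRegion))
  out <- list(bands = bands, overall = overall, contrast = contrast,
              posthoc = posthoc, pacRegion = list(region = pacRegion,
                                                  table = pacTab),
              pacWholeGrid = list(tmap = wg$tmap, cluster = wgCluster),
              generic = generic, manifest = manifest)
  if (!is.null(outDir)) .writeResults(out, grid, outDir)
  out
}

#' Generic 2-Hz band sweep
#'
#' Runs the correct-versus-incorrect contrast and cluster test in seven
#' overlapping generic bands, 0-8 Hz in 2-Hz windows stepped by 1 Hz, as a
#' frequency-agnostic control for the stimulus-specific bands.
#'
#' @param study list with \code{corpus} and \code{participants}.
#' @param config a \code{\link{pipelineConfig}}.
#' @param adjacency optional precomputed neighbour list.
#' @return named list, one entry per band, each with \code{band},
#'   \code{correct}, \code{incorrect} matrices and \code{cluster} results.
#' @export
genericBandSweep <- function(study, config = pipelineConfig(),
                             adjacency = NULL) {
  participants <- study$participants
  if (is.null(adjacency))
    adjacency <- gridAdjacency(gridCoords(participants[[1L]]))
  tCrit <- criticalT(length(participants))
  out <- list()
  for (band in genericBands()) {
    cm <- .contrastMatrices(participants, band, config)
    out[[band@name]] <- list(
      band = band, correct = cm$correct, incorrect = cm$incorrect,
      cluster = clusterPermutation(cm$correct - cm$incorrect, adjacency,
                                   nPerm = config$nPerm, tCrit = tCrit,
                                   clusterAlpha = config$clusterAlpha,
                                   seed = config$masterSeed + 503L))
  }
  out
}

# write cluster tables, posthoc/PAC tables and the manifest
.writeResults <- function(res, grid, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, f) utils::write.table(
    d, file.path(outDir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  for (bn in names(res$contrast)) {
    wt(res$overall[[bn]]$cluster$clusters,
       sprintf("overall_clusters_%s.tsv", bn))
    wt(res$contrast[[bn]]$cluster$clusters,
       sprintf("contrast_clusters_%s.tsv", bn))
  }
  if (!is.null(res$posthoc)) wt(res$posthoc, "posthoc_peaks.tsv")
  wt(res$pacRegion$table, "pac_region.tsv")
  wt(res$pacWholeGrid$cluster$clusters, "pac_wholegrid_clusters.tsv")
  jsonlite::write_json(res$manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' Write an MI map as tabular text with a JSON sidecar
#'
#' @param map an \code{\linkS4class{MIMap}}.
#' @param path output path for the table; a \code{.json} sidecar with the
#'   provenance (band, lags, condition, trial counts) is written next to it.
#' @return invisibly, the table written.
#' @export
writeMIMap <- function(map, path) {
  grid <- gridCoords(map)
  d <- data.frame(grid_index = seq_len(nGridPoints(map)),
                  x_mm = grid[, 1L], y_mm = grid[, 2L], z_mm = grid[, 3L],
                  mi_bits = miValues(map))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(band = if (is.null(bandOf(map))) NULL else
    c(name = bandOf(map)@name, fLo = bandOf(map)@fLo, fHi = bandOf(map)@fHi),
    lags_ms = map@lagsMs, condition = map@condition,
    n_trials_used = map@nTrialsUsed, n_repeats = map@nRepeats)
  jsonlite::write_json(side, paste0(sub("\\.[^.]+$", "", path), ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(d)
}
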