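#' Analytic signal via the frequency domain
#'
#' Returns the complex analytic signal x + i H(x), where H is the Hilbert
#' transform, computed by zeroing negative frequencies of the DFT.
#'
#' @param x real numeric vector.
#' @return complex vector of the same length; Re() is the input.
#' @export
analyticSignal <- function(x) {
  n <- length(x)
  if (n == 0L) stop("empty input")
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Zero-phase Butterworth band-pass filter
#'
#' Third-order (by default) Butterworth filter applied forward and reverse
#' (zero phase, effective order doubled). A lower edge of 0 Hz yields a
#' low-pass filter, as needed for the 0-2 Hz generic band.
#'
#' @param x real numeric vector.
#' @param fLo,fHi band edges in Hz.
#' @param rate sampling rate in Hz.
#' @param order filter order (3 as used for all analysis bands).
#' @return filtered numeric vector, same length as \code{x}.
#' @export
bandpassFilter <- function(x, fLo, fHi, rate, order = 3) {
  as.numeric(signal::filtfilt(.butterDesign(fLo, fHi, rate, order), x))
}

# filter designs are deterministic in (fLo, fHi, rate, order); cache them
.filterCache <- new.env(parent = emptyenv())

.butterDesign <- function(fLo, fHi, rate, order) {
  if (fHi >= rate / 2) stop("upper band edge must be below the Nyquist rate")
  key <- paste(fLo, fHi, rate, order, sep = "|")
  flt <- .filterCache[[key]]
  if (is.null(flt)) {
    flt <- if (fLo <= 0) {
      signal::butter(order, fHi / (rate / 2), type = "low")
    } else {
      signal::butter(order, c(fLo, fHi) / (rate / 2), type = "pass")
    }
    .filterCache[[key]] <- flt
  }
  flt
}

#' Band-limited analytic signal
#'
#' Zero-phase band-pass filter a series to \code{band}, then take the
#' analytic signal. The real and imaginary parts are used downstream as a
#' two-dimensional representation of band-limited phase and amplitude.
#'
#' @param x real numeric vector at \code{rate} Hz.
#' @param band a \code{\linkS4class{BandSpec}}.
#' @param rate sampling rate in Hz.
#' @param order Butterworth order (default 3).
#' @return complex vector, the analytic signal of the band-filtered input.
#' @examples
#' x <- sin(2 * pi * 1 * seq(0, 10, by = 1/150))
#' a <- bandpassAnalytic(x, bandSpec("phrase", 0.6, 1.3), 150)
#' @export
bandpassAnalytic <- function(x, band, rate, order = 3) {
  minLen <- ceiling(2 * rate / max(band@fLo, 0.5))
  if (length(x) < minLen)
    stop("series too short for the ", band@name,
         " band: unusable trial (need >= ", minLen, " samples)")
  # remove DC first: an offset is a step at the series edges and would ring
  # through narrow low-frequency bands far beyond the usual edge trim
  analyticSignal(bandpassFilter(x - mean(x), band@fLo, band@fHi, rate, order))
}

#' Wideband speech envelope
#'
#' Computes the wideband amplitude envelope of a speech waveform: the signal
#' is filtered into \code{nBands} bands between \code{fRange[1]} and
#' \code{fRange[2]} Hz, spaced equidistantly on the cochlear (Greenwood)
#' map, with zero-phase third-order Butterworth filters; the magnitudes of
#' the analytic signals of all bands are averaged and the result resampled
#' to \code{outRate} Hz.
#'
#' @param audio numeric vector, mono PCM waveform (a multi-column matrix is
#'   averaged across channels with a warning).
#' @param rate audio sampling rate in Hz (>= 16000 for the default range).
#' @param nBands number of cochlear bands (default 8).
#' @param fRange two-element range in Hz (default 100-8000).
#' @param outRate output envelope rate in Hz (default 150).
#' @return non-negative numeric envelope at \code{outRate} Hz.
#' @export
extractWidebandEnvelope <- function(audio, rate, nBands = 8,
                                    fRange = c(100, 8000), outRate = 150) {
  if (is.matrix(audio) && ncol(audio) > 1L) {
    warning("multi-channel audio averaged to mono")
    audio <- rowMeans(audio)
  }
  audio <- as.numeric(audio)
  if (length(audio) == 0L) stop("empty input audio")
  if (rate < 2 * fRange[2L])
    stop("audio rate too low for the requested band range")
  if (length(audio) < rate) stop("audio must be at least 1 s long")
  edges <- cochlearBandEdges(nBands, fRange[1L], fRange[2L])
  # an audio rate of exactly 2 x fHi puts the top edge on the Nyquist
  # frequency; pull it just below so the filter remains realisable
  edges[nBands, 2L] <- min(edges[nBands, 2L], 0.499 * rate)
  env <- rowMeans(vapply(seq_len(nBands), function(b) {
    Mod(analyticSignal(bandpassFilter(audio, edges[b, 1L], edges[b, 2L],
                                      rate, order = 3)))
  }, numeric(length(audio))))
  out <- as.numeric(signal::resample(env, p = outRate, q = rate))
  pmax(out, 0)  # resampling FIR can undershoot slightly
}

#' Welch power spectral density on a fixed frequency grid
#'
#' Welch's averaged periodogram with Hann-windowed, 50%-overlapping
#' segments, zero-padded so the native resolution matches the grid step,
#' evaluated on \code{fGrid} (default 0.1 to 12 Hz in 0.1-Hz steps).
#'
#' @param x real numeric vector.
#' @param rate sampling rate in Hz.
#' @param fGrid frequencies (Hz) at which to report power.
#' @param segSeconds nominal segment length in seconds (shorter signals use
#'   one segment spanning the signal).
#' @return data.frame with columns \code{frequency} (Hz), \code{power}.
#' @examples
#' x <- sin(2 * pi * 1 * seq(0, 20, by = 1/150))
#' ps <- powerSpectrum(x, 150)
#' ps$frequency[which.max(ps$power)]  # 1 Hz
#' @export
powerSpectrum <- function(x, rate, fGrid = seq(0.1, 12, by = 0.1),
                          segSeconds = 10) {
  x <- as.numeric(x)
  if (length(x) < rate) stop("insufficient data for a spectral estimate")
  seg <- min(length(x), round(segSeconds * rate))
  step <- max(1L, floor(seg / 2))
  starts <- seq(1L, length(x) - seg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg) / (seg + 1))  # Hann
  fStep <- min(diff(fGrid))
  nfft <- max(seg, 2^ceiling(log2(rate / fStep)))
  psd <- 0
  for (s in starts) {
    chunk <- x[s:(s + seg - 1L)]
    chunk <- (chunk - mean(chunk)) * win
    X <- stats::fft(c(chunk, numeric(nfft - seg)))
    psd <- psd + Mod(X)^2
  }
  psd <- psd / (length(starts) * sum(win^2) * rate)
  freqs <- (seq_len(nfft) - 1L) * rate / nfft
  keep <- freqs <= max(fGrid) + 1
  pw <- stats::approx(freqs[keep], psd[keep], xout = fGrid, rule = 2)$y
  data.frame(frequency = fGrid, power = pmax(pw, 0))
}

#' Read a mono PCM WAV file
#'
#' Minimal RIFF/WAVE reader for uncompressed integer PCM (8/16/32 bit) and
#' 32-bit float audio. Multi-channel files are averaged to mono with a
#' warning. Samples are scaled to [-1, 1].
#'
#' @param path path to a .wav file.
#' @return list with \code{samples} (numeric) and \code{rate} (Hz).
#' @export
readWavMono <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (hdr != "RIFF") stop("not a RIFF file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (readChar(con, 4, useBytes = TRUE) != "WAVE") stop("not a WAVE file")
  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audioFormat = sum(as.integer(raw[1:2]) * c(1, 256)),
        nChannels   = sum(as.integer(raw[3:4]) * c(1, 256)),
        rate        = sum(as.integer(raw[5:8]) * 256^(0:3)),
        bits        = sum(as.integer(raw[15:16]) * c(1, 256)))
    } else if (id == "data") {
      if (is.null(fmt)) stop("malformed WAV: data before fmt")
      n <- sz %/% (fmt$bits / 8)
      data <- if (fmt$audioFormat == 3L) {
        readBin(con, "numeric", n, size = 4, endian = "little")
      } else if (fmt$bits == 8L) {
        (readBin(con, "integer", n, size = 1, signed = FALSE) - 128) / 128
      } else {
        readBin(con, "integer", n, size = fmt$bits / 8, signed = TRUE,
                endian = "little") / 2^(fmt$bits - 1)
      }
      break
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
  }
  if (is.null(data)) stop("no data chunk found")
  if (fmt$nChannels > 1L) {
    warning("multi-channel audio averaged to mono")
    data <- rowMeans(matrix(data, ncol = fmt$nChannels, byrow = TRUE))
  }
  list(samples = as.numeric(data), rate = fmt$rate)
}
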