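#' Standard EEG frequency bands
#'
#' The five canonical bands used for differential-entropy features:
#' Delta 1-4 Hz, Theta 4-8 Hz, Alpha 8-14 Hz, Beta 14-31 Hz, Gamma 31-50 Hz.
#'
#' @return data.frame with columns \code{name}, \code{lowHz}, \code{highHz}.
#' @export
eegBands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             lowHz = c(1, 4, 8, 14, 31),
             highHz = c(4, 8, 14, 31, 50),
             stringsAsFactors = FALSE)
}

checkBands <- function(bands) {
  stopifnot(is.data.frame(bands),
            all(c("name", "lowHz", "highHz") %in% names(bands)))
  if (any(bands$lowHz <= 0) || any(bands$highHz <= bands$lowHz))
    msmraStop("msmra_invalid_band", "bands must satisfy 0 < lowHz < highHz")
  invisible(bands)
}

## Minimum signal length filtfilt tolerates for an order-n Butterworth
## band-pass (2n coefficients per side, tripled for edge padding).
minFilterLength <- function(order) 3L * (2L * order + 1L)

bandFilterCoefs <- function(lowHz, highHz, fs, order = 4L) {
  nyq <- fs / 2
  if (highHz >= nyq)
    msmraStop("msmra_invalid_band",
              "band %g-%g Hz exceeds the Nyquist frequency %g Hz",
              lowHz, highHz, nyq)
  if (lowHz <= 0) {
    signal::butter(order, highHz / nyq, type = "low")
  } else {
    signal::butter(order, c(lowHz, highHz) / nyq, type = "pass")
  }
}

#' Zero-phase band-pass filter a recording
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass to every
#' channel. Shape, sampling rate, trial boundaries and labels are preserved.
#'
#' @param recording an [EEGRecording-class].
#' @param band one row of [eegBands()] (or any list with \code{lowHz},
#'   \code{highHz}).
#' @param order Butterworth order (applied twice by filtfilt).
#' @return A filtered [EEGRecording-class].
#' @export
bandpassFilter <- function(recording, band, order = 4L) {
  stopifnot(is(recording, "EEGRecording"))
  if (ncol(recording@signal) < minFilterLength(order))
    msmraStop("msmra_too_short",
              "signal has %d samples; band-pass filtering needs at least %d",
              ncol(recording@signal), minFilterLength(order))
  bf <- bandFilterCoefs(band$lowHz, band$highHz, recording@fs, order)
  filt <- t(apply(recording@signal, 1L, function(ch)
    signal::filtfilt(bf, ch)))
  out <- recording
  out@signal <- filt
  out
}

#' Differential entropy of one feature window
#'
#' Under a Gaussian model of the band-filtered window, the differential
#' entropy has the closed form \code{0.5 * log(2 * pi * e * sigma^2)} (nats),
#' with \code{sigma^2} the unbiased sample variance — a log-variance band
#' feature.
#'
#' @param samples numeric vector of at least 2 samples.
#' @return Differential entropy in nats.
#' @export
computeDEWindow <- function(samples) {
  if (length(samples) < 2L)
    msmraStop("msmra_degenerate_window", "a DE window needs at least 2 samples")
  v <- var(samples)
  if (!is.finite(v) || v <= 0)
    msmraStop("msmra_degenerate_window",
              "zero-variance window: differential entropy is -Inf")
  0.5 * log(2 * pi * exp(1) * v)
}

#' Extract differential-entropy band features from a recording
#'
#' Reproduces the standard EEG preprocessing chain: optionally resample to
#' 200 Hz, band-filter each trial per band (zero-phase Butterworth), cut each
#' trial into non-overlapping windows of \code{windowS} seconds, compute the
#' Gaussian differential entropy per window, channel and band, and flatten to
#' a windows x (channels x bands) matrix in channel-major band-minor order
#' (310 columns for 62 channels and the 5 standard bands). Each window
#' inherits its trial's label. Trials shorter than one window are skipped
#' with a warning.
#'
#' @param recording an [EEGRecording-class].
#' @param bands band table as from [eegBands()].
#' @param windowS window length in seconds (1 s, non-overlapping, by default).
#' @param order Butterworth order.
#' @param preFilterHz optional broad-band pre-filter upper edge (e.g. 75);
#'   \code{NULL} skips the stage since the per-band filters already confine
#'   the spectrum to the band union.
#' @param targetFs recordings at other rates are polyphase-resampled to this
#'   rate first; \code{NULL} disables resampling.
#' @return A [FeatureTensor-class].
#' @export
extractDEFeatures <- function(recording, bands = eegBands(), windowS = 1,
                              order = 4L, preFilterHz = NULL,
                              targetFs = NULL) {
  stopifnot(is(recording, "EEGRecording"))
  checkBands(bands)
  if (nrow(recording@trials) == 0L)
    msmraStop("msmra_empty_input", "recording has no trials")
  if (!is.null(targetFs) && recording@fs != targetFs)
    recording <- resampleRecording(recording, targetFs)
  fs <- recording@fs
  if (!is.null(preFilterHz))
    recording <- bandpassFilter(recording,
                                list(lowHz = 0, highHz = preFilterHz), order)
  nCh <- nrow(recording@signal)
  nBand <- nrow(bands)
  wlen <- as.integer(round(windowS * fs))
  filts <- lapply(seq_len(nBand), function(b)
    bandFilterCoefs(bands$lowHz[b], bands$highHz[b], fs, order))

  rows <- list()
  labs <- integer(0)
  for (t in seq_len(nrow(recording@trials))) {
    a <- recording@trials[t, 1L]
    b <- recording@trials[t, 2L]
    seg <- recording@signal[, a:(b - 1L), drop = FALSE]
    nw <- ncol(seg) %/% wlen
    if (nw == 0L) {
      msmraWarn("trial %d (%d samples) shorter than one %gs window; skipped",
                t, ncol(seg), windowS)
      next
    }
    if (ncol(seg) < minFilterLength(order))
      msmraStop("msmra_too_short",
                "trial %d too short for the band-pass filter warm-up", t)
    ## filter the whole trial once per band, then window the filtered trace
    featsTrial <- matrix(NA_real_, nrow = nw, ncol = nCh * nBand)
    for (bi in seq_len(nBand)) {
      for (ch in seq_len(nCh)) {
        y <- signal::filtfilt(filts[[bi]], seg[ch, ])
        for (w in seq_len(nw)) {
          win <- y[((w - 1L) * wlen + 1L):(w * wlen)]
          featsTrial[w, (ch - 1L) * nBand + bi] <- computeDEWindow(win)
        }
      }
    }
    rows[[length(rows) + 1L]] <- featsTrial
    labs <- c(labs, rep.int(recording@labels[t], nw))
  }
  if (length(rows) == 0L)
    msmraStop("msmra_empty_input",
              "no trial long enough to hold a single window")
  featureTensor(do.call(rbind, rows), labs, windowS = windowS,
                subjectId = recording@subjectId,
                sessionId = recording@sessionId)
}

#' Polyphase-resample a recording to a new sampling rate
#'
#' @param recording an [EEGRecording-class].
#' @param newFs target rate in Hz.
#' @return The resampled [EEGRecording-class]; trial boundaries are rescaled.
#' @export
resampleRecording <- function(recording, newFs = 200) {
  stopifnot(is(recording, "EEGRecording"))
  if (recording@fs == newFs) return(recording)
  frac <- ratioFraction(newFs / recording@fs)
  p <- frac[1L]; q <- frac[2L]
  sig <- t(apply(recording@signal, 1L, function(ch)
    as.numeric(signal::resample(ch, p, q))))
  scale <- newFs / recording@fs
  trials <- cbind(pmax(1L, as.integer(floor((recording@trials[, 1L] - 1L) * scale)) + 1L),
                  pmin(ncol(sig) + 1L, as.integer(floor((recording@trials[, 2L] - 1L) * scale)) + 1L))
  eegRecording(sig, newFs, trials, recording@labels,
               recording@subjectId, recording@sessionId)
}

## Small rational approximation of a resampling ratio (continued fractions).
ratioFraction <- function(x, maxDen = 1000L) {
  a0 <- floor(x); p0 <- a0; q0 <- 1; p1 <- 1; q1 <- 0
  r <- x - a0
  while (r > 1e-12 && q0 <= maxDen) {
    r <- 1 / r
    a <- floor(r)
    pn <- a * p0 + p1; qn <- a * q0 + q1
    if (qn > maxDen) break
    p1 <- p0; q1 <- q0; p0 <- pn; q0 <- qn
    r <- r - a
  }
  c(as.integer(p0), as.integer(q0))
}

#' Standardize the feature columns of one recording
#'
#' Per-recording, per-column z-scoring: each feature column is centred and
#' scaled to unit variance using statistics of this recording only, so target
#' statistics never leak into the sources. Constant columns map to zero.
#'
#' @param tensor a [FeatureTensor-class].
#' @param ifNormalized behaviour when the tensor is already normalized:
#'   \code{"error"} (default) or \code{"noop"}.
#' @return The standardized [FeatureTensor-class] with \code{normalized = TRUE}.
#' @export
normalizeFeatures <- function(tensor, ifNormalized = c("error", "noop")) {
  stopifnot(is(tensor, "FeatureTensor"))
  ifNormalized <- match.arg(ifNormalized)
  if (isNormalized(tensor)) {
    if (ifNormalized == "noop") return(tensor)
    msmraStop("msmra_already_normalized", "tensor is already normalized")
  }
  x <- tensor@values
  mu <- colMeans(x)
  s <- apply(x, 2L, sd)
  z <- sweep(x, 2L, mu, "-")
  nz <- s > 1e-12
  z[, nz] <- sweep(z[, nz, drop = FALSE], 2L, s[nz], "/")
  z[, !nz] <- 0
  out <- tensor
  out@values <- z
  out@normalized <- TRUE
  validObject(out)
  out
}
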