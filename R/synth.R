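#' Generate a synthetic subject x session grid of feature recordings
#'
#' Emulates the structure of a multi-subject, multi-session EEG feature
#' corpus: every recording draws class-conditional Gaussian features in
#' \code{dim} dimensions with balanced labels, and each recording carries its
#' own covariate shift composed of three parts, all scaled by
#' \code{deltaDomain}:
#' \itemize{
#' \item a recording-wide mean offset \code{~ N(0, deltaDomain^2 I)};
#' \item a per-column variance scale (log-normal, sdlog
#'   \code{0.15 * deltaDomain});
#' \item a rotation of every class mean within the plane spanned by the
#'   class direction and a recording-specific orthogonal direction, with
#'   displacement magnitude \code{|N(0, deltaDomain^2)|} and the class-mean
#'   norm preserved.
#' }
#' The first two components are per-column affine maps, which per-recording
#' z-scoring removes exactly; the rotation is not removable by
#' standardization and is what makes unsupervised alignment matter on the
#' normalized pipeline. Class means sit \code{deltaClass} noise-SDs apart
#' along random orthogonal directions. Fully reproducible from the seed.
#'
#' @param config a [SynthConfig-class].
#' @return List of \code{nSubjects * nSessions} [FeatureTensor-class]
#'   recordings with subject ids \code{"s01"...} and session ids
#'   \code{"sess1"...}.
#' @export
generateFeatureGrid <- function(config = synthConfig()) {
  stopifnot(is(config, "SynthConfig"))
  set.seed(config@seed)
  M <- config@nClasses
  d <- config@dim
  nRec <- config@nSubjects * config@nSessions

  ## orthonormal directions: M class directions + partner directions used by
  ## the per-recording rotations (recycled if the grid is very large)
  nPartner <- min(d - M, nRec * M)
  if (nPartner < 1L)
    msmraStop("msmra_invalid_config", "dim too small for the class structure")
  Q <- qr.Q(qr(matrix(rnorm(d * (M + nPartner)), d, M + nPartner)))
  V <- Q[, seq_len(M), drop = FALSE]
  W <- Q[, M + seq_len(nPartner), drop = FALSE]

  ## each class mean sits deltaClass noise-SDs out along its own direction
  ## (pairwise distance sqrt(2) * deltaClass * noiseSd)
  mus <- V * (config@deltaClass * config@noiseSd)
  muNorm <- sqrt(colSums(mus^2))

  out <- vector("list", nRec)
  rec <- 0L
  for (s in seq_len(config@nSubjects)) {
    for (k in seq_len(config@nSessions)) {
      rec <- rec + 1L
      ## coherent recording rotation: every class direction tilts by the
      ## same angle toward a recording-specific orthogonal direction, so the
      ## class geometry is preserved while the class subspace re-orients —
      ## the kind of shift per-column standardization cannot remove. The
      ## tilt displaces each class mean by exactly deltaDomain noise-SDs.
      muRec <- mus
      if (config@deltaDomain > 0 && muNorm[1] > 0) {
        delta <- config@deltaDomain * config@noiseSd
        phi <- 2 * asin(min(delta / (2 * muNorm[1]), 1))
        for (a in seq_len(M)) {
          w <- W[, ((rec - 1L) * M + a - 1L) %% nPartner + 1L]
          muRec[, a] <- cos(phi) * mus[, a] + sin(phi) * muNorm[a] * w
        }
      }
      offset <- rnorm(d, 0, config@deltaDomain * config@noiseSd)
      scale <- exp(rnorm(d, 0, 0.15 * config@deltaDomain))
      labels <- sample(rep_len(0:(M - 1L), config@windows))
      eps <- matrix(rnorm(config@windows * d, 0, config@noiseSd),
                    config@windows, d)
      X <- t(muRec[, labels + 1L, drop = FALSE]) +
        matrix(offset, config@windows, d, byrow = TRUE) +
        sweep(eps, 2L, scale, "*")
      out[[rec]] <- featureTensor(
        X, labels, windowS = 1, layout = "synthetic",
        subjectId = sprintf("s%02d", s), sessionId = sprintf("sess%d", k))
    }
  }
  out
}

#' Generate a synthetic raw EEG recording with known band powers
#'
#' Each trial is a sum of band-limited Gaussian noise processes, one per
#' standard band, scaled so each channel's component has exactly the
#' requested standard deviation for the trial's class. The differential
#' entropy of band b is then analytically \code{0.5 * log(2*pi*e *
#' var_b)} up to the extraction filter's pass-band gain, so doubling a
#' band's power shifts that band's DE by \code{log(2)/2}.
#'
#' @param channels number of channels.
#' @param fs sampling rate; must exceed 100 Hz so the Gamma band (31-50 Hz)
#'   is below Nyquist.
#' @param trials number of trials.
#' @param trialS trial length in seconds.
#' @param bandPowers numeric matrix, classes x 5, of per-band variances
#'   (columns in the order of [eegBands()]); a vector is treated as one
#'   class. Zero entries produce an exactly-zero component.
#' @param seed RNG seed.
#' @param subjectId,sessionId identifiers.
#' @return An [EEGRecording-class] with trial labels cycling through the
#'   classes.
#' @export
generateRawEEG <- function(channels = 62L, fs = 200, trials = 3L, trialS = 10,
                           bandPowers, seed = 1L,
                           subjectId = "s01", sessionId = "sess1") {
  if (fs / 2 <= 50)
    msmraStop("msmra_invalid_config",
              "fs/2 = %g Hz does not cover the Gamma band (31-50 Hz)", fs / 2)
  if (is.vector(bandPowers)) bandPowers <- matrix(bandPowers, nrow = 1L)
  bands <- eegBands()
  stopifnot(ncol(bandPowers) == nrow(bands))
  set.seed(seed)
  nPer <- as.integer(round(trialS * fs))
  M <- nrow(bandPowers)
  labels <- rep_len(0:(M - 1L), trials)
  sig <- matrix(0, channels, trials * nPer)
  filts <- lapply(seq_len(nrow(bands)), function(b)
    bandFilterCoefs(bands$lowHz[b], bands$highHz[b], fs))
  for (t in seq_len(trials)) {
    cols <- ((t - 1L) * nPer + 1L):(t * nPer)
    for (b in seq_len(nrow(bands))) {
      v <- bandPowers[labels[t] + 1L, b]
      if (v <= 0) next
      for (ch in seq_len(channels)) {
        y <- signal::filtfilt(filts[[b]], rnorm(nPer))
        sig[ch, cols] <- sig[ch, cols] + y * sqrt(v) / sd(y)
      }
    }
  }
  boundaries <- cbind(seq(1L, by = nPer, length.out = trials),
                      seq(nPer + 1L, by = nPer, length.out = trials))
  eegRecording(sig, fs, boundaries, labels, subjectId, sessionId)
}

#' The package's reference synthetic transfer suite
#'
#' Generates the default grid ([synthConfig()]: 5 subjects x 2 sessions,
#' 3 classes, 310 features, 200 windows per recording, class separation
#' 3 sigma, domain shift 1.5 sigma) and returns its 10 cross-subject
#' leave-one-out partitions (2 source domains each).
#'
#' @param seed grid seed.
#' @param config optional [SynthConfig-class] overriding the defaults
#'   (seed is still taken from \code{seed}).
#' @return List of [DomainPartition-class] objects.
#' @export
defaultSynthSuite <- function(seed = 1L, config = NULL) {
  if (is.null(config)) config <- synthConfig(seed = seed)
  else config@seed <- as.integer(seed)
  grid <- generateFeatureGrid(config)
  leaveOneOutSplits(grid, "cross_subject")
}
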