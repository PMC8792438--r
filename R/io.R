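#' Write / read the package's native feature container
#'
#' A single-file serialized container holding the feature matrix, labels,
#' layout, window length and provenance attributes (documented in the
#' README). \code{writeRecordingContainer} / \code{readRecordingContainer}
#' are the raw-signal counterparts used by the CLI's extract-features stage.
#'
#' @param tensor a [FeatureTensor-class].
#' @param path file path.
#' @return \code{writeFeatureContainer} returns \code{path} invisibly;
#'   \code{readFeatureContainer} returns a [FeatureTensor-class].
#' @export
writeFeatureContainer <- function(tensor, path) {
  stopifnot(is(tensor, "FeatureTensor"))
  saveRDS(list(format = "msmra-feature-container", version = 1L,
               values = tensor@values, labels = tensor@labels,
               layout = tensor@layout, window_s = tensor@windowS,
               normalized = tensor@normalized,
               subject_id = tensor@subjectId, session_id = tensor@sessionId),
          path)
  invisible(path)
}

#' Read a feature container
#'
#' Two dialects are supported. \code{"native_container"} round-trips the
#' package's own format. \code{"mat_extracted_features"} reads an
#' uncompressed MAT v5 file laid out as per-trial numeric arrays of shape
#' channels x bands x windows (the extracted-features convention of the
#' public EEG corpora); trials are concatenated and flattened channel-major
#' band-minor into a windows x (channels*bands) matrix. MAT files carry no
#' labels, so \code{labels} (one per trial) must be given for that dialect.
#'
#' @param path file path.
#' @param dialect \code{"native_container"} or \code{"mat_extracted_features"}.
#' @param labels per-trial integer labels (MAT dialect only).
#' @param pattern regular expression selecting MAT variables (default: all
#'   numeric 3-D arrays, in file order).
#' @param windowS,subjectId,sessionId metadata for the MAT dialect.
#' @return A [FeatureTensor-class].
#' @export
readFeatureContainer <- function(path,
                                 dialect = c("native_container",
                                             "mat_extracted_features"),
                                 labels = NULL, pattern = NULL, windowS = 1,
                                 subjectId = "s01", sessionId = "sess1") {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    msmraStop("msmra_io", "file not found: %s", path)
  if (dialect == "native_container") {
    obj <- tryCatch(readRDS(path), error = function(e)
      msmraStop("msmra_parse", "cannot parse %s: %s", path,
                conditionMessage(e)))
    if (!identical(obj$format, "msmra-feature-container"))
      msmraStop("msmra_dialect", "%s is not a feature container", path)
    return(featureTensor(obj$values, obj$labels, windowS = obj$window_s,
                         layout = obj$layout, normalized = obj$normalized,
                         subjectId = obj$subject_id,
                         sessionId = obj$session_id))
  }
  vars <- readMat5(path)
  is3d <- vapply(vars, function(v) is.array(v) && length(dim(v)) == 3L,
                 logical(1))
  vars <- vars[is3d]
  if (!is.null(pattern)) vars <- vars[grepl(pattern, names(vars))]
  if (length(vars) == 0L)
    msmraStop("msmra_layout", "no channels x bands x windows arrays in %s", path)
  dims <- dim(vars[[1L]])
  rows <- list(); labs <- integer(0)
  if (is.null(labels)) labels <- rep.int(0L, length(vars))
  if (length(labels) != length(vars))
    msmraStop("msmra_layout", "%d trials in file but %d labels given",
              length(vars), length(labels))
  for (t in seq_along(vars)) {
    a <- vars[[t]]
    if (!all(dim(a)[1:2] == dims[1:2]))
      msmraStop("msmra_layout",
                "trial %d is %d x %d (channels x bands); expected %d x %d",
                t, dim(a)[1L], dim(a)[2L], dims[1L], dims[2L])
    nw <- dim(a)[3L]
    ## channel-major band-minor: column (ch-1)*bands + b
    m <- matrix(NA_real_, nw, dims[1L] * dims[2L])
    for (w in seq_len(nw)) m[w, ] <- as.vector(t(a[, , w]))
    rows[[t]] <- m
    labs <- c(labs, rep.int(as.integer(labels[t]), nw))
  }
  featureTensor(do.call(rbind, rows), labs, windowS = windowS,
                subjectId = subjectId, sessionId = sessionId)
}

#' @rdname writeFeatureContainer
#' @param recording an [EEGRecording-class].
#' @export
writeRecordingContainer <- function(recording, path) {
  stopifnot(is(recording, "EEGRecording"))
  saveRDS(list(format = "msmra-recording-container", version = 1L,
               signal = recording@signal, fs = recording@fs,
               trials = recording@trials, labels = recording@labels,
               subject_id = recording@subjectId,
               session_id = recording@sessionId), path)
  invisible(path)
}

#' @rdname writeFeatureContainer
#' @export
readRecordingContainer <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    msmraStop("msmra_parse", "cannot parse %s: %s", path, conditionMessage(e)))
  if (!identical(obj$format, "msmra-recording-container"))
    msmraStop("msmra_dialect", "%s is not a recording container", path)
  eegRecording(obj$signal, obj$fs, obj$trials, obj$labels,
               obj$subject_id, obj$session_id)
}

## ---- minimal MAT v5 reader ----------------------------------------------
## Uncompressed level-5 MAT files with numeric (real) arrays only, which is
## all the extracted-features dialect needs. Compressed elements raise a
## clear error. Little-endian files only (the indicator bytes are checked).

mat5Types <- c(miINT8 = 1, miUINT8 = 2, miINT16 = 3, miUINT16 = 4,
               miINT32 = 5, miUINT32 = 6, miSINGLE = 7, miDOUBLE = 9,
               miINT64 = 12, miUINT64 = 13, miMATRIX = 14,
               miCOMPRESSED = 15, miUTF8 = 16)

readMat5 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 128L)
  if (length(header) < 128L)
    msmraStop("msmra_parse", "truncated MAT header in %s at offset %d",
              path, length(header))
  endian <- rawToChar(header[127:128])
  if (endian != "IM")
    msmraStop("msmra_parse",
              "unsupported byte order indicator '%s' (big-endian?)", endian)
  vars <- list()
  offset <- 128L
  repeat {
    tag <- readBin(con, "raw", 8L)
    if (length(tag) == 0L) break
    if (length(tag) < 8L)
      msmraStop("msmra_parse", "truncated element tag at offset %d", offset)
    type <- readBinInt(tag[1:4])
    nbytes <- readBinInt(tag[5:8])
    if (type == mat5Types[["miCOMPRESSED"]])
      msmraStop("msmra_parse",
                "compressed MAT element at offset %d is not supported", offset)
    payload <- readBin(con, "raw", nbytes)
    if (length(payload) < nbytes)
      msmraStop("msmra_parse", "truncated element at offset %d: want %d bytes, got %d",
                offset + 8L, nbytes, length(payload))
    pad <- (8L - nbytes %% 8L) %% 8L
    if (pad) readBin(con, "raw", pad)
    offset <- offset + 8L + nbytes + pad
    if (type == mat5Types[["miMATRIX"]]) {
      v <- parseMat5Matrix(payload)
      if (!is.null(v)) vars[[v$name]] <- v$value
    }
  }
  vars
}

readBinInt <- function(r) {
  sum(as.integer(r) * 256^(seq_along(r) - 1L))
}

## Walk the sub-elements of an miMATRIX payload.
parseMat5Matrix <- function(buf) {
  pos <- 1L
  nextElement <- function() {
    if (pos + 7L > length(buf) + 1L) return(NULL)
    t4 <- readBinInt(buf[pos:(pos + 3L)])
    if (t4 > 65535) {  # small data element: size in the upper 16 bits
      type <- t4 %% 65536
      nb <- t4 %/% 65536
      data <- if (nb) buf[(pos + 4L):(pos + 3L + nb)] else raw(0)
      pos <<- pos + 8L
    } else {
      type <- t4
      nb <- readBinInt(buf[(pos + 4L):(pos + 7L)])
      data <- if (nb) buf[(pos + 8L):(pos + 7L + nb)] else raw(0)
      pad <- (8L - nb %% 8L) %% 8L
      pos <<- pos + 8L + nb + pad
    }
    list(type = type, data = data)
  }
  flags <- nextElement()
  dims <- nextElement()
  nameEl <- nextElement()
  dataEl <- nextElement()
  if (is.null(flags) || is.null(dims) || is.null(nameEl) || is.null(dataEl))
    msmraStop("msmra_parse", "malformed MAT matrix element")
  klass <- as.integer(flags$data[1L])
  if (!klass %in% 6:13) return(NULL)  # numeric array classes only
  dm <- vapply(seq_len(length(dims$data) %/% 4L), function(k)
    readBinInt(dims$data[((k - 1L) * 4L + 1L):(k * 4L)]), numeric(1))
  name <- rawToChar(nameEl$data)
  vals <- decodeMat5Numeric(dataEl)
  if (length(vals) != prod(dm))
    msmraStop("msmra_parse", "MAT variable %s: %d values for dims %s",
              name, length(vals), paste(dm, collapse = "x"))
  value <- if (length(dm) > 1L) array(vals, dim = dm) else vals
  list(name = name, value = value)
}

decodeMat5Numeric <- function(el) {
  r <- el$data
  switch(as.character(el$type),
    "1" = as.numeric(readBin(r, "integer", length(r), size = 1L, signed = TRUE,
                             endian = "little")),
    "2" = as.numeric(readBin(r, "integer", length(r), size = 1L, signed = FALSE,
                             endian = "little")),
    "3" = as.numeric(readBin(r, "integer", length(r) %/% 2L, size = 2L,
                             signed = TRUE, endian = "little")),
    "4" = as.numeric(readBin(r, "integer", length(r) %/% 2L, size = 2L,
                             signed = FALSE, endian = "little")),
    "5" = as.numeric(readBin(r, "integer", length(r) %/% 4L, size = 4L,
                             endian = "little")),
    "6" = as.numeric(readBin(r, "integer", length(r) %/% 4L, size = 4L,
                             endian = "little")),
    "7" = as.numeric(readBin(r, "double", length(r) %/% 4L, size = 4L,
                             endian = "little")),
    "9" = readBin(r, "double", length(r) %/% 8L, size = 8L, endian = "little"),
    msmraStop("msmra_parse", "unsupported MAT numeric storage type %d",
              el$type))
}

## ---- manifests and result tables -----------------------------------------

#' Write a run manifest
#'
#' Records everything needed to re-execute a run bit-comparably: the full
#' training configuration, seeds, package version, the partition manifests
#' and the per-split results.
#'
#' @param path output JSON path.
#' @param config a [TrainConfig-class].
#' @param splits list of [DomainPartition-class] (optional).
#' @param results per-split results data.frame (optional).
#' @param extra named list merged into the manifest.
#' @return \code{path}, invisibly.
#' @export
writeRunManifest <- function(path, config, splits = NULL, results = NULL,
                             extra = list()) {
  stopifnot(is(config, "TrainConfig"))
  man <- c(list(
    package = "msmra",
    version = as.character(utils::packageVersion("msmra")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = list(lr = config@lr, batch_size = config@batchSize,
                  epochs = config@epochs,
                  alpha_per_step = config@alphaPerStep,
                  normalize = config@normalize, mdsfe = config@mdsfe,
                  adapt = config@adapt, seed = config@seed,
                  kernel = list(family = config@kernel@family,
                                num_kernels = config@kernel@numKernels,
                                spread_factor = config@kernel@spreadFactor,
                                biased = config@kernel@biased)),
    partitions = if (is.null(splits)) NULL else
      lapply(splits, partitionManifest),
    results = results), extra)
  jsonlite::write_json(man[!vapply(man, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeRunManifest
#' @export
readRunManifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a results table as CSV
#'
#' Fixed column order: split_id, scenario, n_domains, accuracy, seed.
#'
#' @param results data.frame as produced by [runScenario()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeResultsTable <- function(results, path) {
  cols <- c("split_id", "scenario", "n_domains", "accuracy", "seed")
  stopifnot(all(cols %in% names(results)))
  utils::write.csv(results[, cols], path, row.names = FALSE)
  invisible(path)
}
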