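# Readers/writers for the on-disk formats the tool touches. Neural
# recordings travel as MATLAB level-5 MAT files and audio as RIFF/WAV;
# both codecs are implemented here directly (uncompressed numeric/char MAT
# arrays; PCM16/float32 WAV), which covers the round trip this package
# needs. Labels are plain tab-separated text.

## ---- MAT v5 ----------------------------------------------------------------

matPad <- function(n) (8 - n %% 8) %% 8

writeMatSub <- function(con, type, raw) {
  writeBin(as.integer(c(type, length(raw))), con, size = 4, endian = "little")
  writeBin(raw, con)
  pad <- matPad(length(raw))
  if (pad) writeBin(raw(pad), con)
}

writeMatVar <- function(con, name, value) {
  if (is.character(value)) {
    stopifnot(length(value) == 1)
    chars <- utf8ToInt(value)
    dataRaw <- writeBin(as.integer(chars), raw(), size = 2,
                        endian = "little")
    cls <- 4L  # mxCHAR_CLASS
    dataType <- 4L  # miUINT16
    dims <- c(1L, length(chars))
  } else {
    value <- as.matrix(value)
    dataRaw <- writeBin(as.numeric(value), raw(), size = 8,
                        endian = "little")
    cls <- 6L  # mxDOUBLE_CLASS
    dataType <- 9L  # miDOUBLE
    dims <- dim(value)
  }
  body <- rawConnection(raw(0), "wb")
  on.exit(close(body), add = TRUE)
  writeMatSub(body, 6L, writeBin(as.integer(c(cls, 0L)), raw(), size = 4,
                                 endian = "little"))
  writeMatSub(body, 5L, writeBin(as.integer(dims), raw(), size = 4,
                                 endian = "little"))
  writeMatSub(body, 1L, as.raw(utf8ToInt(name)))
  writeMatSub(body, dataType, dataRaw)
  payload <- rawConnectionValue(body)
  writeBin(as.integer(c(14L, length(payload))), con, size = 4,
           endian = "little")
  writeBin(payload, con)
}

#' Write variables to a MATLAB level-5 MAT file
#'
#' Supports numeric matrices/vectors (stored as double arrays) and single
#' character strings (stored as char arrays), uncompressed.
#'
#' @param path output file.
#' @param vars named list of variables.
#' @export
writeMat5 <- function(path, vars) {
  stopifnot(length(names(vars)) == length(vars), all(nzchar(names(vars))))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  desc <- sprintf("MATLAB 5.0 MAT-file, written by neurovad")
  hdr <- raw(116)
  db <- utf8ToInt(desc)
  hdr[seq_along(db)] <- as.raw(db)
  hdr[(length(db) + 1):116] <- as.raw(32L)
  writeBin(hdr, con)
  writeBin(raw(8), con)  # subsystem offset
  writeBin(as.raw(c(0x00, 0x01)), con)  # version 0x0100, little-endian
  writeBin(charToRaw("IM"), con)
  for (nm in names(vars)) writeMatVar(con, nm, vars[[nm]])
  invisible(path)
}

readMatSub <- function(buf, pos) {
  tag <- readBin(buf[pos:(pos + 3)], "integer", 1, size = 4,
                 endian = "little")
  small <- bitwAnd(bitwShiftR(tag, 16), 0xFFFF)
  if (small != 0) {  # small data element: size in upper 16 bits
    type <- bitwAnd(tag, 0xFFFF)
    size <- small
    data <- buf[(pos + 4):(pos + 3 + size)]
    return(list(type = type, data = data, next_ = pos + 8))
  }
  type <- tag
  size <- readBin(buf[(pos + 4):(pos + 7)], "integer", 1, size = 4,
                  endian = "little")
  data <- if (size > 0) buf[(pos + 8):(pos + 7 + size)] else raw(0)
  list(type = type, data = data, next_ = pos + 8 + size + matPad(size))
}

parseMatVar <- function(buf) {
  pos <- 1
  flags <- readMatSub(buf, pos); pos <- flags$next_
  cls <- as.integer(flags$data[1])
  dimsEl <- readMatSub(buf, pos); pos <- dimsEl$next_
  dims <- readBin(dimsEl$data, "integer", length(dimsEl$data) / 4, size = 4,
                  endian = "little")
  nameEl <- readMatSub(buf, pos); pos <- nameEl$next_
  name <- rawToChar(nameEl$data)
  dataEl <- readMatSub(buf, pos)
  n <- prod(dims)
  value <- switch(as.character(dataEl$type),
    "9" = readBin(dataEl$data, "numeric", n, size = 8, endian = "little"),
    "5" = as.numeric(readBin(dataEl$data, "integer", n, size = 4,
                             endian = "little")),
    "4" = readBin(dataEl$data, "integer", n, size = 2, signed = FALSE,
                  endian = "little"),
    "2" = as.integer(dataEl$data),
    "1" = as.integer(dataEl$data),
    stop("unsupported MAT data type ", dataEl$type))
  if (cls == 4L) {  # char array
    value <- intToUtf8(value)
  } else {
    value <- matrix(value, dims[1], dims[2])
  }
  list(name = name, value = value)
}

#' Read a MATLAB level-5 MAT file
#'
#' Reads uncompressed double and char arrays. Compressed elements (as
#' produced by MATLAB's default save) are not supported and raise an error.
#'
#' @param path MAT file.
#' @return named list of variables.
#' @export
readMat5 <- function(path) {
  buf <- readBin(path, "raw", file.size(path))
  if (length(buf) < 128) stop("not a MAT v5 file: truncated header")
  if (rawToChar(buf[127:128]) != "IM")
    stop("unsupported MAT file endianness or not a MAT v5 file")
  out <- list()
  pos <- 129
  while (pos + 7 <= length(buf)) {
    type <- readBin(buf[pos:(pos + 3)], "integer", 1, size = 4,
                    endian = "little")
    size <- readBin(buf[(pos + 4):(pos + 7)], "integer", 1, size = 4,
                    endian = "little")
    if (type == 15) stop("compressed MAT elements are not supported")
    if (type != 14) stop("unexpected top-level MAT element type ", type)
    v <- parseMatVar(buf[(pos + 8):(pos + 7 + size)])
    out[[v$name]] <- v$value
    pos <- pos + 8 + size + matPad(size)
  }
  out
}

#' Write a recording to a MAT v5 file
#'
#' Variables: \code{samples} (samples x channels double), \code{sample_rate}
#' (scalar), \code{grid_of_channel} (1 x C), \code{channel_ids} and
#' \code{bad_channels} (semicolon-joined char arrays).
#'
#' @param rec a \linkS4class{RawRecording}.
#' @param path output path.
#' @export
writeRecording <- function(rec, path) {
  stopifnot(is(rec, "RawRecording"))
  writeMat5(path, list(
    samples = rec@samples,
    sample_rate = rec@sampleRate,
    grid_of_channel = matrix(as.numeric(rec@gridOfChannel), 1),
    channel_ids = paste(rec@channelIds, collapse = ";"),
    bad_channels = paste(rec@badChannels, collapse = ";")))
}

#' Read a recording from a MAT v5 file
#'
#' @param path MAT file.
#' @param spec named list mapping slots to MAT variable names (defaults
#'   match \code{\link{writeRecording}}).
#' @param expectedRate if given, error when the stored rate differs.
#' @return A \linkS4class{RawRecording}.
#' @export
readRecording <- function(path,
                          spec = list(samples = "samples",
                                      sampleRate = "sample_rate",
                                      gridOfChannel = "grid_of_channel",
                                      channelIds = "channel_ids",
                                      badChannels = "bad_channels"),
                          expectedRate = NULL) {
  vars <- readMat5(path)
  need <- c("samples", "sampleRate")
  for (k in need)
    if (is.null(vars[[spec[[k]]]]))
      stop("MAT file is missing variable '", spec[[k]], "'")
  samples <- vars[[spec$samples]]
  rate <- as.numeric(vars[[spec$sampleRate]])[1]
  if (!is.null(expectedRate) && rate != expectedRate)
    stop("sampling rate mismatch: file has ", rate, ", expected ",
         expectedRate)
  splitIds <- function(x) if (is.null(x) || !nzchar(x)) character() else
    strsplit(x, ";", fixed = TRUE)[[1]]
  ids <- splitIds(vars[[spec$channelIds %||% "channel_ids"]])
  if (!length(ids)) ids <- paste0("ch", seq_len(ncol(samples)))
  grid <- vars[[spec$gridOfChannel %||% "grid_of_channel"]]
  grid <- if (is.null(grid)) rep(1L, ncol(samples)) else as.integer(grid)
  RawRecording(samples, sampleRate = rate, channelIds = ids,
               gridOfChannel = grid,
               badChannels = splitIds(vars[[spec$badChannels %||%
                                              "bad_channels"]]))
}

## ---- WAV -------------------------------------------------------------------

#' Write a mono waveform to a WAV file
#'
#' @param wave numeric vector in [-1, 1] (clipped).
#' @param rate sampling rate, Hz.
#' @param path output path.
#' @param format \code{"float32"} (IEEE float) or \code{"pcm16"}.
#' @export
writeWav <- function(wave, rate, path, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  n <- length(wave)
  bytesPer <- if (format == "float32") 4L else 2L
  dataSize <- n * bytesPer
  fmtCode <- if (format == "float32") 3L else 1L
  writeBin(charToRaw("RIFF"), con)
  writeBin(as.integer(36 + dataSize), con, size = 4, endian = "little")
  writeBin(charToRaw("WAVEfmt "), con)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(as.integer(fmtCode), con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")  # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * bytesPer), con, size = 4, endian = "little")
  writeBin(as.integer(bytesPer), con, size = 2, endian = "little")
  writeBin(as.integer(8L * bytesPer), con, size = 2, endian = "little")
  writeBin(charToRaw("data"), con)
  writeBin(as.integer(dataSize), con, size = 4, endian = "little")
  w <- pmin(pmax(wave, -1), 1)
  if (format == "float32") {
    writeBin(as.numeric(w), con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(round(w * 32767)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file (PCM16 or float32)
#'
#' @param path WAV file.
#' @return list with \code{wave} (numeric, [-1, 1] scale) and \code{rate}.
#' @export
readWav <- function(path) {
  buf <- readBin(path, "raw", file.size(path))
  if (length(buf) < 44 || rawToChar(buf[1:4]) != "RIFF" ||
      rawToChar(buf[9:12]) != "WAVE")
    stop("not a RIFF/WAVE file")
  pos <- 13
  fmt <- NULL; dataRaw <- NULL
  while (pos + 8 <= length(buf)) {
    cid <- rawToChar(buf[pos:(pos + 3)])
    csz <- readBin(buf[(pos + 4):(pos + 7)], "integer", 1, size = 4,
                   endian = "little")
    body <- buf[(pos + 8):min(pos + 7 + csz, length(buf))]
    if (cid == "fmt ") fmt <- body
    if (cid == "data") dataRaw <- body
    pos <- pos + 8 + csz + csz %% 2
  }
  if (is.null(fmt) || is.null(dataRaw)) stop("missing fmt or data chunk")
  code <- readBin(fmt[1:2], "integer", 1, size = 2, endian = "little")
  nch <- readBin(fmt[3:4], "integer", 1, size = 2, endian = "little")
  rate <- readBin(fmt[5:8], "integer", 1, size = 4, endian = "little")
  bits <- readBin(fmt[15:16], "integer", 1, size = 2, endian = "little")
  if (nch != 1) stop("only mono WAV is supported")
  wave <- if (code == 3 && bits == 32) {
    readBin(dataRaw, "numeric", length(dataRaw) / 4, size = 4,
            endian = "little")
  } else if (code == 1 && bits == 16) {
    readBin(dataRaw, "integer", length(dataRaw) / 2, size = 2,
            endian = "little") / 32767
  } else stop("unsupported WAV encoding (format ", code, ", ", bits,
              " bits)")
  list(wave = wave, rate = rate)
}

## ---- label files -----------------------------------------------------------

#' Write a label sequence as tab-separated text
#'
#' Header comments carry the frame shift, start time and class map;
#' columns are \code{frame_index}, \code{time_s}, \code{label}.
#'
#' @param labels a \linkS4class{LabelSequence}.
#' @param path output path.
#' @export
writeLabels <- function(labels, path) {
  stopifnot(is(labels, "LabelSequence"))
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c(
    sprintf("# frame_shift_ms: %g", labels@frameShift),
    sprintf("# start_time_s: %g", labels@startTime),
    sprintf("# classes: %s",
            paste(sprintf("%s=%s", names(labels@classes), labels@classes),
                  collapse = ",")),
    "frame_index\ttime_s\tlabel"), con)
  if (length(labels@labels)) {
    idx <- seq_along(labels@labels) - 1L
    writeLines(sprintf("%d\t%.3f\t%d", idx,
                       labels@startTime + idx * labels@frameShift / 1000,
                       labels@labels), con)
  }
  invisible(path)
}

#' Read a label sequence written by \code{\link{writeLabels}}
#'
#' @param path label file.
#' @return A \linkS4class{LabelSequence}.
#' @export
readLabels <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getField <- function(key, default) {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(m)) return(default)
    trimws(sub(paste0("^# ", key, ":"), "", m[1]))
  }
  shift <- as.numeric(getField("frame_shift_ms", "10"))
  start <- as.numeric(getField("start_time_s", "0"))
  clsStr <- getField("classes", "0=non-speech,1=speech")
  kv <- strsplit(strsplit(clsStr, ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
  classes <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body)) body <- body[-1]  # column header
  lab <- integer(length(body))
  for (i in seq_along(body)) {
    parts <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    v <- suppressWarnings(as.numeric(parts))
    if (length(parts) != 3 || anyNA(v))
      stop("malformed label row at line ",
           i + length(hdr) + 1L, ": '", body[i], "'")
    lab[i] <- as.integer(v[3])
  }
  LabelSequence(lab, frameShift = shift, startTime = start,
                classes = classes)
}

## ---- manifests and configuration ------------------------------------------

#' Read a dataset manifest (YAML)
#'
#' The manifest lists per-day recordings and role assignments:
#' \preformatted{
#' days:
#'   - day_id: 1
#'     recording: day1.mat
#'     audio: day1.wav        # optional
#'     baseline: [0, 30]      # seconds
#'     trials: day1_trials.tsv
#' roles: {test: [1], validation: [2], development: [], train: [3, 4]}
#' channels: {selected: [...], bad: [...]}
#' }
#'
#' @param path YAML manifest.
#' @param checkPaths verify that referenced files exist.
#' @return validated manifest list.
#' @export
readManifest <- function(path, checkPaths = TRUE) {
  m <- yaml::read_yaml(path)
  if (is.null(m$days) || !length(m$days)) stop("manifest lists no days")
  for (d in m$days) {
    if (is.null(d$day_id) || is.null(d$recording))
      stop("each day needs day_id and recording")
    if (checkPaths) {
      base <- dirname(path)
      p <- file.path(base, d$recording)
      if (!file.exists(p)) stop("recording not found: ", p)
    }
  }
  roles <- m$roles
  if (!is.null(roles)) {
    all <- unlist(roles)
    if (anyDuplicated(all)) stop("role assignments must be disjoint")
  }
  m
}

#' Read a run configuration (YAML)
#'
#' One declarative file covering the session generator, the clustering
#' hyperparameters, the classifier training setup and global seeds;
#' command-line flags override these values.
#'
#' @param path YAML file with optional sections \code{session},
#'   \code{ticc}, \code{training}, \code{seed}, \code{manifest}.
#' @return list with entries \code{session} (\code{\link{sessionConfig}}),
#'   \code{ticc} (\code{\link{ticcHyperparams}}), \code{training}
#'   (\code{\link{trainingConfig}}), \code{seed}, \code{manifest}.
#' @export
readConfig <- function(path) {
  y <- if (is.null(path)) list() else yaml::read_yaml(path)
  list(
    session = do.call(sessionConfig, y$session %||% list()),
    ticc = do.call(ticcHyperparams, y$ticc %||% list()),
    training = do.call(trainingConfig, y$training %||% list()),
    seed = y$seed %||% 1L,
    manifest = y$manifest
  )
}
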