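# Minimal EDF (European Data Format) reader/writer: 16-bit integer samples,
# ASCII header of 256 bytes + 256 per signal, equal sampling rate on all
# signals, 1 s data records. Covers what the simulate/load round trip needs;
# EDF+ annotations are not parsed.

edfField <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)  # left-justified, space padded
}

# symmetric physical range [-pm, pm] formatted to fit the 8-char fields,
# rounded outward so no sample falls outside the written range
edfPhysRange <- function(pm, width = 8) {
  for (digits in 7:1) {
    up <- signif(pm * (1 + 10^(1 - digits)), digits)
    hiS <- formatC(up, format = "g", digits = digits, width = 1)
    loS <- paste0("-", hiS)
    if (nchar(loS) <= width && as.numeric(hiS) >= pm)
      return(c(loS, hiS))
  }
  stop("cannot format physical range for EDF header")
}

#' Write a recording as an EDF file
#'
#' Samples are scaled to the 16-bit EDF integer range per channel; the
#' physical unit written is microvolts and the data-record duration is 1 s,
#' so the sampling rate must be a whole number. The signal is zero-padded
#' to a whole number of records.
#'
#' @param rec an [EEGRecording-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [loadRecording()]
#' @export
writeRecordingEDF <- function(rec, path) {
  stopifnot(is(rec, "EEGRecording"))
  fs <- samplingRate(rec)
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF export requires an integer sampling rate")
  fs <- as.integer(round(fs))
  x <- signalMatrix(rec)
  ns <- nrow(x)
  ndr <- as.integer(ceiling(ncol(x) / fs))
  npad <- ndr * fs - ncol(x)
  if (npad > 0) x <- cbind(x, matrix(0, ns, npad))

  physMin <- physMax <- character(ns)
  dig <- matrix(0L, ns, ncol(x))
  for (i in seq_len(ns)) {
    pm <- max(abs(range(x[i, ])), 1e-6)
    rng <- edfPhysRange(pm)
    loS <- rng[1]; hiS <- rng[2]
    lo <- as.numeric(loS); hi <- as.numeric(hiS)
    physMin[i] <- loS; physMax[i] <- hiS
    d <- round((x[i, ] - lo) / (hi - lo) * 65535 - 32768)
    dig[i, ] <- as.integer(pmin(32767, pmax(-32768, d)))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edfField("0", 8),
    edfField("X X X X", 80),
    edfField("Startdate X X X X", 80),
    edfField("01.01.00", 8), edfField("00.00.00", 8),
    edfField(256 * (ns + 1), 8),
    edfField("", 44),
    edfField(ndr, 8), edfField("1", 8), edfField(ns, 4),
    paste(vapply(channelLabels(rec), edfField, "", width = 16),
          collapse = ""),
    paste(vapply(rep("", ns), edfField, "", width = 80), collapse = ""),
    paste(vapply(rep("uV", ns), edfField, "", width = 8), collapse = ""),
    paste(vapply(physMin, edfField, "", width = 8), collapse = ""),
    paste(vapply(physMax, edfField, "", width = 8), collapse = ""),
    paste(vapply(rep(-32768L, ns), edfField, "", width = 8), collapse = ""),
    paste(vapply(rep(32767L, ns), edfField, "", width = 8), collapse = ""),
    paste(vapply(rep("", ns), edfField, "", width = 80), collapse = ""),
    paste(vapply(rep(fs, ns), edfField, "", width = 8), collapse = ""),
    paste(vapply(rep("", ns), edfField, "", width = 32), collapse = ""))
  writeChar(hdr, con, eos = NULL)
  for (r in seq_len(ndr)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

readEDFHeader <- function(con) {
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8); patient <- rd(80); recording <- rd(80)
  date <- rd(8); time <- rd(8)
  nbytes <- as.integer(rd(8)); reserved <- rd(44)
  ndr <- as.integer(rd(8)); recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  per <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- per(16); transducer <- per(80); dimension <- per(8)
  physMin <- as.numeric(per(8)); physMax <- as.numeric(per(8))
  digMin <- as.numeric(per(8)); digMax <- as.numeric(per(8))
  prefilter <- per(80); spr <- as.integer(per(8)); per(32)
  list(ndr = ndr, recDur = recDur, ns = ns, labels = labels,
       dimension = dimension, physMin = physMin, physMax = physMax,
       digMin = digMin, digMax = digMax, spr = spr, nbytes = nbytes)
}

readRecordingEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- readEDFHeader(con)
  if (any(is.na(h$spr)) || h$recDur <= 0)
    stop("EDF format error: missing sampling information")
  fsPer <- h$spr / h$recDur
  if (length(unique(fsPer)) != 1L)
    stop("EDF signals disagree on sampling rate")
  fs <- fsPer[1]
  out <- matrix(0, h$ns, h$ndr * h$spr[1])
  scale <- (h$physMax - h$physMin) / (h$digMax - h$digMin)
  for (r in seq_len(h$ndr)) {
    for (i in seq_len(h$ns)) {
      d <- readBin(con, "integer", n = h$spr[i], size = 2, signed = TRUE,
                   endian = "little")
      cols <- ((r - 1) * h$spr[i] + 1):(r * h$spr[i])
      out[i, cols] <- h$physMin[i] + (d - h$digMin[i]) * scale[i]
    }
  }
  # convert to microvolts where the declared unit allows it
  unitScale <- vapply(h$dimension, function(u) {
    switch(tolower(u), "uv" = 1, "µv" = 1, "mv" = 1000, "v" = 1e6, 1)
  }, 1)
  out <- out * unitScale
  EEGRecording(out, fs, normalizeChannelLabels(h$labels))
}
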