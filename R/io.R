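# canonical capitalisation of the 10-20 labels used for matching
TEN_TWENTY <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                "T3", "T7", "C3", "Cz", "C4", "T4", "T8",
                "T5", "P7", "P3", "Pz", "P4", "T6", "P8",
                "O1", "Oz", "O2", "A1", "A2", "FCz", "AFz")

normalizeChannelLabels <- function(labels) {
  labels <- trimws(sub("^EEG[ _]*", "", labels, ignore.case = TRUE))
  hit <- match(toupper(labels), toupper(TEN_TWENTY))
  ifelse(is.na(hit), labels, TEN_TWENTY[hit])
}

#' Load a recording from EDF or delimited text
#'
#' Delimited files carry one column per channel, a header row of channel
#' labels, and comma or tab separation; the sampling rate must be supplied
#' either via `fs` or a JSON sidecar (`<path>.json` with an `fs` entry),
#' since the text format has no header field for it. Channel labels are
#' normalised to canonical 10-20 capitalisation where they match.
#'
#' @param path file path.
#' @param format `"edf"`, `"delimited"`, or `"auto"` (by file extension).
#' @param fs sampling rate (Hz) for delimited input.
#' @return an [EEGRecording-class].
#' @export
loadRecording <- function(path, format = c("auto", "edf", "delimited"),
                          fs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
              else "delimited"
  if (format == "edf") return(readRecordingEDF(path))

  if (is.null(fs)) {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar))
      fs <- jsonlite::fromJSON(sidecar)$fs
  }
  if (is.null(fs) || !is.numeric(fs) || length(fs) != 1L)
    stop("format error: no sampling rate declared for delimited recording")
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE)
  labels <- normalizeChannelLabels(colnames(tab))
  if (anyDuplicated(toupper(labels)))
    stop("format error: duplicate channel labels")
  EEGRecording(t(as.matrix(tab)), fs, labels)
}

#' Write / read tap-event tables
#'
#' Three-column TSV: `onset_sample` (1-based), `onset_seconds`, `label`.
#'
#' @param events an [EventList-class].
#' @param path file path.
#' @return `writeEvents` returns `path` invisibly; `readEvents` returns an
#'   [EventList-class].
#' @export
writeEvents <- function(events, path) {
  stopifnot(is(events, "EventList"))
  tab <- data.frame(onset_sample = eventOnsets(events),
                    onset_seconds = (eventOnsets(events) - 1) /
                      samplingRate(events),
                    label = eventLabels(events))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeEvents
#' @param fs sampling rate (Hz) the onset samples refer to.
#' @export
readEvents <- function(path, fs) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  EventList(tab$onset_sample, tab$label, fs)
}
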