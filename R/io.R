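#' Read an EEG recording from disk
#'
#' Supports two on-disk layouts: EDF (European Data Format, 16-bit) and plain
#' delimited text matrices with one row per channel and a single header line
#' of channel names (tab or comma, auto-detected). A JSON sidecar
#' \code{<path>.json} with fields \code{subject_id}, \code{group},
#' \code{scores} is merged in when present.
#'
#' @param path file to read.
#' @param format \code{"edf"}, \code{"matrix"}, or \code{"auto"} (by file
#'   extension).
#' @param fs sampling rate in Hz; required for matrix files (EDF carries its
#'   own).
#' @param channels optional channel names overriding those stored in the file.
#' @param ... passed to \code{\link{eeg_recording}} (e.g. \code{subject_id}).
#' @return An \code{eeg_recording}.
#' @seealso \code{\link{write_recording}}
#' @export
read_recording <- function(path, format = c("auto", "edf", "matrix"),
                           fs = NULL, channels = NULL, ...) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "matrix"
  }
  if (format == "edf") {
    ed <- read_edf(path)
    if (is.null(fs)) fs <- ed$fs
    if (is.null(channels)) channels <- ed$channels
    dat <- ed$data
  } else {
    if (is.null(fs)) stop("fs must be supplied for matrix-format files")
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
    header <- strsplit(first, sep, fixed = TRUE)[[1L]]
    dat <- as.matrix(read.table(path, header = FALSE, sep = sep, skip = 1L))
    dimnames(dat) <- NULL
    if (nrow(dat) != length(header))
      stop("matrix file is malformed: header names ", length(header),
           " channels but the body has ", nrow(dat), " rows")
    if (is.null(channels)) channels <- header
  }
  meta <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) meta <- read_subject_sidecar(sidecar)
  args <- modifyList(meta, list(...))
  do.call(eeg_recording,
          c(list(data = dat, fs = fs, channels = channels), args))
}

#' Write an EEG recording to disk
#'
#' Matrix format: delimited text, one header line of channel names, then one
#' row per channel (so a file row is a channel's time series). EDF: 16-bit
#' European Data Format via the package's own writer. Subject metadata
#' (id, group, scores) goes to a JSON sidecar \code{<path>.json}.
#'
#' @param rec an \code{eeg_recording}.
#' @param path output file.
#' @param format \code{"matrix"} (default for non-.edf paths) or \code{"edf"}.
#' @param sep field separator for matrix format (default tab).
#' @param digits significant digits retained in matrix format.
#' @return \code{path}, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "edf", "matrix"),
                            sep = "\t", digits = 10L) {
  validate_recording(rec)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "matrix"
  }
  if (format == "edf") {
    write_edf(rec, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(rec$channels, collapse = sep), con)
    write.table(signif(rec$data, digits), con, sep = sep, col.names = FALSE,
                row.names = FALSE)
  }
  meta <- list(subject_id = rec$subject_id)
  if (!is.null(rec$group)) meta$group <- rec$group
  if (!is.null(rec$scores)) meta$scores <- as.list(rec$scores)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

read_subject_sidecar <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list()
  if (!is.null(meta$subject_id)) out$subject_id <- meta$subject_id
  if (!is.null(meta$group)) out$group <- meta$group
  if (!is.null(meta$scores) && length(meta$scores))
    out$scores <- unlist(meta$scores)
  out
}
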