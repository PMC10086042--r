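#' Construct and validate an EEG recording
#'
#' The basic container for a multichannel EEG signal: a channels x samples
#' numeric matrix in microvolts plus sampling rate and channel metadata.
#'
#' @param data numeric matrix, channels in rows, samples in columns (microvolts).
#' @param fs sampling rate in Hz (scalar, > 0).
#' @param channels character vector of unique channel names, one per row of
#'   \code{data}. Defaults to rownames of \code{data} or \code{Ch1..ChN}.
#' @param positions optional two-column matrix of 2-D scalp coordinates, one
#'   row per channel (used for topographic plots and canonical template
#'   construction). When channel names match the standard 10-20 montage the
#'   positions are filled in automatically.
#' @param subject_id subject identifier string.
#' @param group optional group label (e.g. \code{"patient"} / \code{"control"}).
#' @param scores optional named numeric vector of clinical scores
#'   (e.g. \code{c("UPDRS-III" = 16, MoCA = 26)}).
#'
#' @return An object of class \code{eeg_recording}: a list with elements
#'   \code{data}, \code{fs}, \code{channels}, \code{positions},
#'   \code{subject_id}, \code{group}, \code{scores}.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(3 * 100), 3), fs = 100)
#' n_samples(rec)
#' @export
eeg_recording <- function(data, fs, channels = NULL, positions = NULL,
                          subject_id = "anonymous", group = NULL,
                          scores = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(channels)) {
    channels <- rownames(data)
    if (is.null(channels)) channels <- paste0("Ch", seq_len(nrow(data)))
  }
  if (is.null(positions) && all(channels %in% rownames(standard_1020_positions()))) {
    positions <- standard_1020_positions()[channels, , drop = FALSE]
  }
  rec <- structure(
    list(data = data, fs = as.numeric(fs), channels = as.character(channels),
         positions = positions, subject_id = as.character(subject_id),
         group = if (is.null(group)) NULL else as.character(group),
         scores = scores),
    class = "eeg_recording")
  validate_recording(rec)
}

#' Validate an EEG recording
#'
#' Checks the structural invariants: at least 3 channels and 2 samples,
#' positive sampling rate, unique channel names, finite data, and positions
#' (when present) aligned with the channels.
#'
#' @param rec an \code{eeg_recording}.
#' @return The recording, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.matrix(rec$data) || !is.numeric(rec$data))
    stop("recording data must be a numeric matrix (channels x samples)")
  if (nrow(rec$data) < 3L) stop("recording must have at least 3 channels")
  if (ncol(rec$data) < 2L) stop("recording must have at least 2 samples")
  if (!is.numeric(rec$fs) || length(rec$fs) != 1L || !is.finite(rec$fs) || rec$fs <= 0)
    stop("sampling rate fs must be a positive finite scalar")
  if (length(rec$channels) != nrow(rec$data))
    stop("one channel name per data row is required (got ", length(rec$channels),
         " names for ", nrow(rec$data), " rows)")
  if (anyDuplicated(rec$channels))
    stop("duplicate channel names: ",
         paste(unique(rec$channels[duplicated(rec$channels)]), collapse = ", "))
  if (anyNA(rec$data) || any(!is.finite(rec$data)))
    stop("recording contains non-finite samples; clean the data before analysis")
  if (!is.null(rec$positions)) {
    pos <- as.matrix(rec$positions)
    if (nrow(pos) != nrow(rec$data) || ncol(pos) != 2L)
      stop("positions must be a (n_channels x 2) coordinate matrix")
  }
  invisible(rec)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  if (!is.null(x$group)) cat("  group:", x$group, "\n")
  if (!is.null(x$scores))
    cat("  scores:", paste(names(x$scores), signif(x$scores, 4),
                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of channels / samples / duration of a recording
#' @param rec an \code{eeg_recording}.
#' @return integer count (or duration in seconds).
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname n_channels
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @rdname n_channels
#' @export
duration <- function(rec) ncol(rec$data) / rec$fs

#' Re-reference a recording to the common average
#'
#' Subtracts, at every sample, the mean over channels, so each column of the
#' data matrix has zero mean. Topographic (microstate) clustering operates on
#' the shape of the scalp map, which is only defined relative to a reference;
#' the common average is the standard choice. Idempotent.
#'
#' @param rec an \code{eeg_recording}.
#' @return The recording with average-referenced data.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(30), 3) + 5, fs = 10)
#' max(abs(colMeans(average_reference(rec)$data)))  # ~ 0
#' @export
average_reference <- function(rec) {
  validate_recording(rec)
  rec$data <- sweep(rec$data, 2L, colMeans(rec$data))
  rec
}

#' Standard 10-20 montage coordinates
#'
#' Approximate 2-D scalp-projection coordinates (nose up, left ear to the
#' left, unit head radius) for the 19 electrodes of the international 10-20
#' system. Used as defaults for recordings on this montage, for topographic
#' plots, and to construct the canonical microstate template shapes.
#'
#' @return A 19 x 2 numeric matrix with rownames \code{Fp1 ... Pz} and
#'   columns \code{x} (left-right) and \code{y} (posterior-anterior).
#' @export
standard_1020_positions <- function() {
  pos <- rbind(
    Fp1 = c(-0.31,  0.95), Fp2 = c( 0.31,  0.95),
    F7  = c(-0.81,  0.59), F3  = c(-0.55,  0.48), Fz = c(0, 0.50),
    F4  = c( 0.55,  0.48), F8  = c( 0.81,  0.59),
    T7  = c(-1.00,  0.00), C3  = c(-0.50,  0.00), Cz = c(0, 0.00),
    C4  = c( 0.50,  0.00), T8  = c( 1.00,  0.00),
    P7  = c(-0.81, -0.59), P3  = c(-0.55, -0.48), Pz = c(0, -0.50),
    P4  = c( 0.55, -0.48), P8  = c( 0.81, -0.59),
    O1  = c(-0.31, -0.95), O2  = c( 0.31, -0.95))
  colnames(pos) <- c("x", "y")
  pos
}

#' Channel names of the standard 10-20 montage, in conventional order
#' @return character vector of 19 channel names.
#' @export
standard_1020_channels <- function() rownames(standard_1020_positions())
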