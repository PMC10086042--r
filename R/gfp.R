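#' Global field power
#'
#' GFP at sample \eqn{t} is the root-mean-square deviation of the scalp
#' potential from its instantaneous channel mean:
#' \deqn{GFP(t) = \sqrt{\frac{1}{n}\sum_{i=1}^{n} [u_i(t) - \bar u(t)]^2}}
#' i.e. the per-sample population standard deviation across channels. Peaks
#' of the GFP mark moments of maximal topographic signal-to-noise and supply
#' the maps used for microstate clustering.
#'
#' @param rec an \code{eeg_recording}.
#' @return A \code{gfp_series}: list with \code{values} (length
#'   \code{n_samples}, microvolts, non-negative) and \code{peak_indices}
#'   (empty until \code{\link{detect_gfp_peaks}} is run).
#' @examples
#' rec <- eeg_recording(rbind(c(1, 2), c(-1, 2), c(0, 2)), fs = 2)
#' compute_gfp(rec)$values  # population SD across channels per sample
#' @export
compute_gfp <- function(rec) {
  validate_recording(rec)
  centered <- sweep(rec$data, 2L, colMeans(rec$data))
  structure(list(values = sqrt(colMeans(centered^2)),
                 peak_indices = integer(0)),
            class = "gfp_series")
}

#' Detect GFP peaks
#'
#' Strict local maxima of the GFP curve (endpoints excluded), thinned so that
#' retained peaks are at least \code{min_distance} samples apart; when two
#' candidate peaks are closer, the larger one wins.
#'
#' @param gfp a \code{gfp_series} from \code{\link{compute_gfp}}.
#' @param min_distance minimum separation between retained peaks, in samples
#'   (default 1 = keep all strict local maxima).
#' @return The \code{gfp_series} with \code{peak_indices} filled in
#'   (strictly increasing). A monotone series yields an empty peak set with a
#'   warning.
#' @export
detect_gfp_peaks <- function(gfp, min_distance = 1L) {
  stopifnot(inherits(gfp, "gfp_series"), min_distance >= 1L)
  v <- gfp$values
  n <- length(v)
  cand <- which(v[2:(n - 1L)] > v[1:(n - 2L)] & v[2:(n - 1L)] > v[3:n]) + 1L
  if (length(cand) == 0L) {
    warning("no GFP peaks found (monotone or flat series)")
    gfp$peak_indices <- integer(0)
    return(gfp)
  }
  if (min_distance > 1L && length(cand) > 1L) {
    keep <- logical(length(cand))
    taken <- integer(0)
    for (i in order(v[cand], decreasing = TRUE)) {
      if (!length(taken) || all(abs(cand[i] - taken) >= min_distance)) {
        keep[i] <- TRUE
        taken <- c(taken, cand[i])
      }
    }
    cand <- cand[keep]
  }
  gfp$peak_indices <- sort(cand)
  gfp
}

#' Topographic maps at GFP peaks
#'
#' Convenience extractor: the average-referenced scalp maps at the detected
#' GFP peak samples, as a (n_peaks x n_channels) matrix ready for
#' \code{\link{fit_microstates}}.
#'
#' @param rec an \code{eeg_recording}.
#' @param gfp a peak-detected \code{gfp_series} for \code{rec}; computed
#'   (with \code{min_distance_ms}) when missing.
#' @param min_distance_ms peak separation in milliseconds when \code{gfp} is
#'   computed here (default 10 ms).
#' @return matrix of zero-mean peak maps, one row per peak.
#' @export
gfp_peak_maps <- function(rec, gfp = NULL, min_distance_ms = 10) {
  validate_recording(rec)
  if (is.null(gfp)) {
    gfp <- detect_gfp_peaks(compute_gfp(rec),
                            max(1L, round(min_distance_ms / 1000 * rec$fs)))
  }
  if (!length(gfp$peak_indices)) stop("no GFP peaks available")
  maps <- t(rec$data[, gfp$peak_indices, drop = FALSE])
  maps - rowMeans(maps)
}
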