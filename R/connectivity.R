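#' Instantaneous phase via the analytic signal
#'
#' Per channel, computes the analytic signal (the channel plus i times its
#' quadrature, built with the FFT one-sided-spectrum construction) and
#' returns its angle in radians, in (-pi, pi]. Meant to run on band-limited
#' data (after \code{\link{bandpass_fir}}), where the instantaneous phase is
#' well defined.
#'
#' @param rec an \code{eeg_recording}.
#' @return A \code{phase_matrix}: list with \code{phase}
#'   (n_channels x n_samples, radians), \code{channels}, \code{fs}.
#' @examples
#' t <- seq(0, 1, by = 1 / 200)
#' rec <- eeg_recording(rbind(cos(2 * pi * 8 * t),
#'                            cos(2 * pi * 8 * t - pi / 4),
#'                            sin(2 * pi * 8 * t)), fs = 200)
#' ph <- instantaneous_phase(rec)
#' @export
instantaneous_phase <- function(rec) {
  validate_recording(rec)
  if (any(apply(rec$data, 1L, function(x) diff(range(x))) == 0))
    stop("instantaneous phase undefined for a constant channel")
  ph <- t(apply(rec$data, 1L, function(x) Arg(analytic_signal(x))))
  structure(list(phase = ph, channels = rec$channels, fs = rec$fs),
            class = "phase_matrix")
}

analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Phase lag index over a sample window
#'
#' For each channel pair (i, j), the PLI is the absolute time average of the
#' sign of the sine of the instantaneous phase difference:
#' \deqn{PLI_{ij} = | \langle sign[ \sin(\phi_i(t_k) - \phi_j(t_k)) ] \rangle |}
#' over the samples of the window. It measures the asymmetry of the
#' phase-difference distribution: 1 means perfect non-zero-lag phase
#' locking, 0 means no coupling or coupling at exactly zero (or pi) lag,
#' which makes the index insensitive to volume conduction. \code{sign(0)}
#' is 0, so identical channels score exactly 0.
#'
#' @param phase a \code{phase_matrix} (or bare n_channels x n_samples
#'   matrix of radians).
#' @param start first sample of the window (1-based).
#' @param end sample after the last one (exclusive); the window is
#'   \code{start:(end - 1)} and must hold at least 2 samples.
#' @return symmetric n_channels x n_channels matrix with zero diagonal and
#'   entries in [0, 1].
#' @export
pli <- function(phase, start = 1L, end = NULL) {
  ph <- if (inherits(phase, "phase_matrix")) phase$phase else as.matrix(phase)
  if (is.null(end)) end <- ncol(ph) + 1L
  if (start < 1L || end > ncol(ph) + 1L || end - start < 2L)
    stop("window [", start, ", ", end, ") must lie in the recording and ",
         "hold at least 2 samples")
  nc <- nrow(ph)
  pairs <- which(upper.tri(matrix(0, nc, nc)), arr.ind = TRUE)
  seg <- ph[, start:(end - 1L), drop = FALSE]
  d <- seg[pairs[, 1L], , drop = FALSE] - seg[pairs[, 2L], , drop = FALSE]
  v <- abs(rowMeans(sign(sin(d))))
  adj <- matrix(0, nc, nc)
  adj[pairs] <- v
  adj[pairs[, c(2L, 1L)]] <- v
  adj
}

#' Build a dynamic network sequence under the SN, MN or MCN scheme
#'
#' Computes one PLI adjacency matrix per analysis window. Schemes:
#' \describe{
#'   \item{SN}{fixed sliding windows of \code{window_len} samples advanced
#'     by \code{step}, dropped when they would overrun the recording;}
#'   \item{MN}{one window per contiguous microstate window of \code{seq}
#'     holding at least \code{min_window} samples (shorter windows are
#'     skipped and counted);}
#'   \item{MCN}{the MN windows additionally partitioned by microstate
#'     class.}
#' }
#' Run this on the band-pass filtered recording; the instantaneous phase is
#' extracted internally (or pass a precomputed \code{phase}).
#'
#' @param rec an \code{eeg_recording} (band-limited).
#' @param scheme \code{"SN"}, \code{"MN"} or \code{"MCN"}.
#' @param seq a \code{microstate_sequence} aligned to \code{rec}
#'   (required for MN/MCN).
#' @param window_len,step SN window length and hop, in samples (required
#'   for SN).
#' @param min_window minimum usable window length in samples (default 5,
#'   i.e. 10 ms at 500 Hz); applies to MN/MCN.
#' @param phase optional precomputed \code{phase_matrix} for \code{rec}.
#' @return A \code{network_set}: \code{scheme}, \code{windows} (list of
#'   entries with \code{adjacency}, \code{start}, \code{end},
#'   \code{class}, \code{n_samples}), \code{by_class} (MCN: named list of
#'   window indices per class), \code{v} (window count; per class for
#'   MCN), \code{n_skipped}, \code{channels}, \code{class_names}.
#' @export
build_networks <- function(rec, scheme = c("SN", "MN", "MCN"), seq = NULL,
                           window_len = NULL, step = NULL, min_window = 5L,
                           phase = NULL) {
  scheme <- match.arg(scheme)
  validate_recording(rec)
  if (is.null(phase)) phase <- instantaneous_phase(rec)
  ns <- ncol(phase$phase)
  n_skipped <- 0L

  if (scheme == "SN") {
    if (is.null(window_len) || is.null(step))
      stop("SN scheme requires window_len and step")
    starts <- seq(1L, ns - window_len + 1L, by = step)
    spans <- data.frame(start = starts, end = starts + window_len,
                        class = NA_integer_)
    class_names <- NULL
  } else {
    if (is.null(seq) || !inherits(seq, "microstate_sequence"))
      stop(scheme, " scheme requires a microstate_sequence")
    if (length(seq$labels) != ns)
      stop("microstate sequence (", length(seq$labels),
           " samples) does not align with the recording (", ns, ")")
    spans <- seq$windows
    long_enough <- (spans$end - spans$start) >= min_window
    n_skipped <- sum(!long_enough)
    if (n_skipped > 0L)
      message(n_skipped, " microstate window(s) shorter than ", min_window,
              " samples skipped")
    spans <- spans[long_enough, , drop = FALSE]
    class_names <- seq$class_names
  }
  if (nrow(spans) == 0L) stop("no usable windows for scheme ", scheme)

  windows <- lapply(seq_len(nrow(spans)), function(r) {
    list(adjacency = pli(phase, spans$start[r], spans$end[r]),
         start = spans$start[r], end = spans$end[r],
         class = spans$class[r],
         n_samples = spans$end[r] - spans$start[r])
  })

  by_class <- NULL
  v <- length(windows)
  if (scheme == "MCN") {
    cls <- spans$class
    by_class <- lapply(seq_along(class_names), function(k) which(cls == k))
    names(by_class) <- class_names
    v <- vapply(by_class, length, integer(1L))
    thin <- names(v)[v > 0L & v < 2L]
    if (length(thin))
      warning("class(es) ", paste(thin, collapse = ", "),
              " have fewer than 2 usable windows; their variability ",
              "statistics will be unavailable")
  }
  structure(list(scheme = scheme, windows = windows, by_class = by_class,
                 v = v, n_skipped = n_skipped, channels = rec$channels,
                 class_names = class_names),
            class = "network_set")
}

#' @export
print.network_set <- function(x, ...) {
  cat(sprintf("<network_set> scheme %s: %d windows, %d channels\n",
              x$scheme, length(x$windows), length(x$channels)))
  if (x$scheme == "MCN")
    cat("  per class:", paste(names(x$v), x$v, sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' Adjacency matrices of a network set as a list
#'
#' @param netset a \code{network_set}.
#' @param class optional class name (MCN) restricting the windows.
#' @return list of symmetric adjacency matrices in window order.
#' @export
adjacencies <- function(netset, class = NULL) {
  idx <- seq_along(netset$windows)
  if (!is.null(class)) {
    if (is.null(netset$by_class)) stop("class subsetting needs an MCN set")
    idx <- netset$by_class[[class]]
  }
  lapply(netset$windows[idx], `[[`, "adjacency")
}
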