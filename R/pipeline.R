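#' Full cohort pipeline: preprocess, segment, network sequences, variability
#'
#' Runs the complete analysis on a list of recordings: band-pass filtering
#' and average referencing, GFP-peak map extraction, group-level microstate
#' template fitting (one template set per group by default, mirroring the
#' two-group clinical design; \code{template_mode = "shared"} fits one set
#' on everyone), canonical A-D ordering, per-subject backfitting, network
#' construction under the requested schemes, and per-subject variability
#' profiles.
#'
#' @param recordings list of \code{eeg_recording} objects (group labels
#'   required for \code{template_mode = "per_group"}).
#' @param schemes character subset of \code{c("SN", "MN", "MCN")}.
#' @param band band-pass edges in Hz; NULL skips filtering (for data that
#'   is already band-limited, e.g. the synthetic generator's output).
#' @param k,n_init,smooth_min_duration microstate parameters (see
#'   \code{\link{fit_microstates}}, \code{\link{backfit}}).
#' @param gfp_min_distance_ms GFP peak separation.
#' @param max_maps_per_subject cap on peak maps entering the group
#'   clustering (subsampled deterministically when exceeded).
#' @param sn_window,sn_step SN sliding-window parameters, samples.
#' @param min_window minimum usable microstate-window length, samples.
#' @param template_mode \code{"per_group"} (default) or \code{"shared"}.
#' @param order_canonically permute fitted classes against the canonical
#'   A-D maps (needs channel positions).
#' @param drop_degenerate passed to \code{\link{variability_profile}};
#'   defaults to TRUE here because short microstate windows routinely
#'   saturate the PLI.
#' @return list with \code{profiles} (named by scheme: lists of
#'   \code{variability_profile}), \code{models} (fitted
#'   \code{microstate_model}s by group), \code{sequences} (per-subject
#'   \code{microstate_sequence}s).
#' @export
cohort_variability <- function(recordings,
                               schemes = c("SN", "MN", "MCN"),
                               band = c(2, 20), k = 4L, n_init = 20L,
                               smooth_min_duration = 20,
                               gfp_min_distance_ms = 10,
                               max_maps_per_subject = 2000L,
                               sn_window = 1000L, sn_step = 500L,
                               min_window = 5L,
                               template_mode = c("per_group", "shared"),
                               order_canonically = TRUE,
                               drop_degenerate = TRUE) {
  template_mode <- match.arg(template_mode)
  schemes <- match.arg(schemes, several.ok = TRUE)
  need_ms <- any(schemes %in% c("MN", "MCN"))

  prepped <- lapply(recordings, function(r) {
    if (!is.null(band)) r <- bandpass_fir(r, band[1L], band[2L])
    average_reference(r)
  })
  groups <- vapply(prepped, function(r)
    if (is.null(r$group)) NA_character_ else r$group, character(1L))

  models <- sequences <- NULL
  if (need_ms) {
    peak_maps <- lapply(prepped, function(r) {
      m <- gfp_peak_maps(r, min_distance_ms = gfp_min_distance_ms)
      if (nrow(m) > max_maps_per_subject)
        m <- m[seq(1L, nrow(m), length.out = max_maps_per_subject), ,
               drop = FALSE]
      m
    })
    grp_of <- if (template_mode == "per_group") groups
              else rep("all", length(prepped))
    if (anyNA(grp_of))
      stop("per-group template fitting requires group labels on every recording")
    models <- lapply(split(peak_maps, grp_of), function(maps)
      fit_microstates(maps, k = k, n_init = n_init))
    if (order_canonically) {
      pos <- prepped[[1L]]$positions
      canon <- if (is.null(pos)) NULL else canonical_microstate_maps(pos)
      if (!is.null(canon) && nrow(canon) == k)
        models <- lapply(models, order_classes, canonical = canon)
    }
    sequences <- lapply(seq_along(prepped), function(i)
      backfit(prepped[[i]], models[[grp_of[i]]],
              smooth_min_duration = smooth_min_duration))
  }

  profiles <- stats::setNames(
    replicate(length(schemes), vector("list", length(prepped)),
              simplify = FALSE), schemes)
  for (i in seq_along(prepped)) {
    r <- prepped[[i]]
    ph <- instantaneous_phase(r)          # shared across schemes
    for (sc in schemes) {
      nets <- build_networks(
        r, scheme = sc,
        seq = if (sc == "SN") NULL else sequences[[i]],
        window_len = sn_window, step = sn_step, min_window = min_window,
        phase = ph)
      profiles[[sc]][[i]] <- variability_profile(
        nets, subject_id = r$subject_id, group = r$group, scores = r$scores,
        drop_degenerate = drop_degenerate)
    }
  }
  list(profiles = profiles, models = models, sequences = sequences)
}
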