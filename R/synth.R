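#' Configuration for the synthetic EEG generator
#'
#' Describes a resting-state recording that alternates among \code{k_states}
#' quasi-stable scalp topographies with exponential-like dwell times, while
#' channel pairs follow state-specific phase-coupling patterns that are
#' re-drawn at a controllable per-class switching rate. Defaults mirror a
#' typical clinical resting-EEG protocol: 19 channels on the 10-20 montage,
#' 500 Hz sampling, four states dwelling around 60 ms.
#'
#' @param n_channels number of channels (19 uses the 10-20 montage names).
#' @param fs sampling rate, Hz.
#' @param duration recording length, seconds.
#' @param k_states number of topographic states (>= 2).
#' @param mean_state_duration mean dwell time, ms.
#' @param duration_jitter extra uniform jitter on dwell times, ms.
#' @param snr linear amplitude ratio of the template-projected oscillatory
#'   component to the additive noise.
#' @param switching_rate coupling-pattern redraws per second of elapsed
#'   time, per class; scalar or per-class vector. Pattern lifetimes are
#'   quasi-regular (1/rate with 25 percent uniform jitter), matching the
#'   slow, sustained reconfiguration timescale of dynamic functional
#'   connectivity; 0 keeps one pattern for the whole recording.
#' @param lag_spread half-width (radians) of the uniform per-channel phase
#'   lags that make up a coupling pattern; pairs whose lag difference is
#'   small relative to the noise-induced phase jitter read out as low PLI,
#'   larger lags as high PLI, so the lag vector is the state's connectivity
#'   fingerprint.
#' @param phase_noise_sd per-sample random-walk step SD (radians) of the
#'   shared carrier oscillator; sets the phase jitter scale.
#' @param group_effects optional list with named-vector elements
#'   \code{switching} and/or \code{synchrony}: per-class multipliers
#'   (names among the class letters) applied to the switching rate and
#'   (inversely) to the class's lag spread, the hook for injecting
#'   group-level effects.
#' @param templates optional (k_states x n_channels) matrix of template
#'   topographies shared across recordings. Microstate maps are canonical
#'   across people, so cohort simulations must use one template set for
#'   every subject (otherwise class identities do not correspond between
#'   subjects); the default uses the canonical A-D shapes for the 19-channel
#'   montage with k = 4, and seeded random near-orthogonal maps otherwise.
#' @param template_jitter SD of per-subject Gaussian perturbation added to
#'   the shared templates (individual topographic variability); rows are
#'   re-centered and re-normalized.
#' @param seed integer RNG seed; fixed seed gives bit-identical output.
#' @param subject_id,group recording metadata.
#' @return a \code{synth_config} list.
#' @export
synth_config <- function(n_channels = 19L, fs = 500, duration = 300,
                         k_states = 4L, mean_state_duration = 60,
                         duration_jitter = 0, snr = 10,
                         switching_rate = 0.033, lag_spread = 0.8,
                         phase_noise_sd = 0.15,
                         group_effects = NULL, templates = NULL,
                         template_jitter = 0.1, seed = 1L,
                         subject_id = "synthetic", group = NULL) {
  cfg <- list(n_channels = as.integer(n_channels), fs = fs,
              duration = duration, k_states = as.integer(k_states),
              mean_state_duration = mean_state_duration,
              duration_jitter = duration_jitter, snr = snr,
              switching_rate = switching_rate,
              lag_spread = lag_spread,
              phase_noise_sd = phase_noise_sd,
              group_effects = group_effects,
              templates = templates, template_jitter = template_jitter,
              seed = as.integer(seed),
              subject_id = subject_id, group = group)
  with(cfg, {
    stopifnot(n_channels >= 3L, fs > 0, duration > 0, k_states >= 2L,
              mean_state_duration > 0, duration_jitter >= 0, snr > 0,
              all(switching_rate >= 0), lag_spread > 0, lag_spread <= pi,
              phase_noise_sd > 0, template_jitter >= 0)
  })
  if (!is.null(templates)) {
    templates <- as.matrix(templates)
    stopifnot(nrow(templates) == cfg$k_states,
              ncol(templates) == cfg$n_channels)
  }
  structure(cfg, class = "synth_config")
}

# near-orthogonal unit-norm zero-mean template topographies
make_templates <- function(k, n_ch) {
  base <- qr.Q(qr(matrix(rnorm(n_ch * k), n_ch, k)))
  tmpl <- t(base) + 0.25 * matrix(rnorm(k * n_ch), k, n_ch)
  normalize_maps(tmpl)
}

normalize_maps <- function(tmpl) {
  tmpl <- tmpl - rowMeans(tmpl)
  tmpl / sqrt(rowSums(tmpl^2))
}

# cohort-level template set: canonical A-D shapes when the montage allows,
# seeded random near-orthogonal maps otherwise
base_templates <- function(cfg) {
  if (!is.null(cfg$templates)) return(normalize_maps(cfg$templates))
  if (cfg$n_channels == 19L && cfg$k_states == 4L)
    return(study_templates())
  make_templates(cfg$k_states, cfg$n_channels)
}

#' Study-like microstate template set for simulations
#'
#' The canonical A-D shapes blended toward their Gram-Schmidt
#' orthogonalization just enough that every pairwise absolute spatial
#' correlation is at most 0.5 (the literal canonical maps share the
#' anterior-posterior gradient and correlate up to ~0.7, which makes
#' clustering recovery experiments ill-posed). Deterministic.
#'
#' @return 4 x 19 matrix of unit-norm zero-mean maps, rows A-D.
#' @export
study_templates <- function() {
  canon <- canonical_microstate_maps()
  orth <- t(qr.Q(qr(t(canon))))
  orth <- orth * sign(rowSums(orth * canon))   # align polarity with canonical
  for (alpha in seq(1, 0, by = -0.05)) {
    bl <- normalize_maps(alpha * canon + (1 - alpha) * orth)
    cc <- abs(spatial_correlation(bl, bl))
    if (max(cc[upper.tri(cc)]) <= 0.5) break
  }
  rownames(bl) <- rownames(canon)
  bl
}

# alternating state sequence with exponential-like dwell times
sample_state_sequence <- function(cfg) {
  n <- round(cfg$duration * cfg$fs)
  min_samp <- 2L
  labels <- integer(n)
  pos <- 1L
  state <- sample.int(cfg$k_states, 1L)
  while (pos <= n) {
    dwell_ms <- rexp(1L, 1 / cfg$mean_state_duration)
    if (cfg$duration_jitter > 0)
      dwell_ms <- dwell_ms + runif(1L, -cfg$duration_jitter, cfg$duration_jitter)
    len <- max(min_samp, round(dwell_ms / 1000 * cfg$fs))
    end <- min(pos + len - 1L, n)
    labels[pos:end] <- state
    pos <- end + 1L
    state <- sample(setdiff(seq_len(cfg$k_states), state), 1L)
  }
  labels
}

#' Generate a synthetic EEG recording with known ground truth
#'
#' Builds \code{k_states} near-orthogonal template topographies, samples an
#' alternating state sequence, and synthesizes band-limited channel signals
#' as a phase-lagged shared oscillator: within a state window, channel i is
#' its template weight times \code{cos(Phi(t) + theta_i)}, where
#' \code{Phi(t)} is a frequency-wandering carrier and the lag vector
#' \code{theta} is the state's current coupling pattern. At the moments of
#' maximal field power the scalp map is proportional to the template (what
#' microstate segmentation recovers), while pairwise phase lags
#' \code{theta_i - theta_j} set each pair's PLI (what the network stage
#' recovers). Patterns are re-drawn at the class's switching rate, so
#' higher switching produces higher temporal variability of that class's
#' networks. White noise is added at the configured linear SNR.
#'
#' @param cfg a \code{\link{synth_config}}.
#' @return list with \code{recording} (\code{eeg_recording}),
#'   \code{sequence} (ground-truth \code{microstate_sequence}),
#'   \code{templates} (k x n_channels), \code{coupling} (data.frame:
#'   window \code{start}, \code{end}, \code{class}, \code{pattern});
#'   \code{rates} (resolved per-class switching rates, per second).
#' @export
generate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  k <- cfg$k_states; nch <- cfg$n_channels; fs <- cfg$fs
  class_names <- LETTERS[seq_len(k)]

  rates <- rep_len(cfg$switching_rate, k)
  names(rates) <- class_names
  sync <- rep(1, k); names(sync) <- class_names
  if (!is.null(cfg$group_effects)) {
    ge <- cfg$group_effects
    if (!is.null(ge$switching))
      rates[names(ge$switching)] <- rates[names(ge$switching)] * ge$switching
    if (!is.null(ge$synchrony))
      sync[names(ge$synchrony)] <- sync[names(ge$synchrony)] * ge$synchrony
  }

  templates <- base_templates(cfg)
  if (cfg$template_jitter > 0)
    templates <- normalize_maps(
      templates + matrix(rnorm(k * nch, 0, cfg$template_jitter), k, nch))
  labels <- sample_state_sequence(cfg)
  wins <- windows_from_labels(labels)
  n_per_class <- tabulate(wins$class, nbins = k)
  if (any(n_per_class < 2L))
    stop("duration too short: class(es) ",
         paste(class_names[n_per_class < 2L], collapse = ", "),
         " have fewer than 2 windows")
  n <- length(labels)

  # state-specific coupling patterns (per-channel carrier lags + carrier
  # frequency), redrawn at each class's switching rate; synchrony effects
  # shrink the class's lag spread
  draw_pattern <- function(cl) {
    list(lags = runif(nch, -cfg$lag_spread, cfg$lag_spread) / sync[cl],
         freq = runif(1L, 5, 14))
  }
  patterns <- vector("list", k)
  pattern_id <- integer(k)
  next_id <- 0L
  next_redraw <- rep(Inf, k)             # wall-clock time of the next redraw
  signal <- matrix(0, n, nch)
  win_pattern <- integer(nrow(wins))
  phi <- runif(1L, 0, 2 * pi)            # carrier phase, continuous across windows
  for (r in seq_len(nrow(wins))) {
    cl <- wins$class[r]
    t0 <- (wins$start[r] - 1L) / fs
    if (is.null(patterns[[cl]]) || t0 >= next_redraw[cl]) {
      patterns[[cl]] <- draw_pattern(cl)
      next_id <- next_id + 1L
      pattern_id[cl] <- next_id
      next_redraw[cl] <- if (rates[cl] > 0)
        t0 + runif(1L, 0.75, 1.25) / rates[cl] else Inf
    }
    win_pattern[r] <- pattern_id[cl]
    pat <- patterns[[cl]]
    idx <- wins$start[r]:(wins$end[r] - 1L)
    m <- length(idx)
    carrier <- phi + cumsum(2 * pi * pat$freq / fs +
                              rnorm(m, 0, cfg$phase_noise_sd))
    phi <- carrier[m]
    signal[idx, ] <- cos(outer(carrier, pat$lags, "+")) *
      rep(templates[cl, ], each = m)
  }

  noise <- matrix(rnorm(n * nch), n, nch)
  unit <- function(m) m / sqrt(mean(m^2))
  data <- 10 * t(cfg$snr * unit(signal) + unit(noise))   # nch x n, ~uV scale

  channels <- if (nch == 19L) standard_1020_channels()
              else paste0("Ch", seq_len(nch))
  rec <- eeg_recording(data, fs = fs, channels = channels,
                       subject_id = cfg$subject_id, group = cfg$group)
  sequence <- structure(list(labels = labels, windows = wins,
                             class_names = class_names, fs = fs),
                        class = "microstate_sequence")
  list(recording = rec, sequence = sequence, templates = templates,
       coupling = cbind(wins, pattern = win_pattern), rates = rates)
}

#' Generate a two-group synthetic cohort with clinical scores
#'
#' Draws independent recordings per subject from the two group
#' configurations, with per-subject lognormal jitter on the class switching
#' rates (so subjects differ within a group), and attaches synthetic
#' clinical scores to the patient group through a stated linear link: the
#' motor score increases with the subject's realized class-B switching rate
#' and the cognition score increases with the realized class-C switching
#' rate, each plus Gaussian noise, making Spearman-recovery analyses
#' calibrated against known monotone relationships.
#'
#' @param cfg_control,cfg_patient \code{\link{synth_config}}s for the two
#'   groups (group effects usually live in \code{cfg_patient$group_effects}).
#' @param n_control,n_patient group sizes.
#' @param seed cohort-level seed (drives per-subject seeds and jitter).
#' @param rate_jitter_sd SD of the per-subject lognormal switching-rate
#'   jitter.
#' @param score_noise_sd SD of the Gaussian noise on the score links, in
#'   score units.
#' @return a \code{synth_cohort}: list with \code{recordings} (list of
#'   \code{eeg_recording} with group labels and scores), \code{truth}
#'   (per-subject ground truth from \code{\link{generate_recording}} minus
#'   the recording itself), and \code{seed}.
#' @export
generate_cohort <- function(cfg_control, cfg_patient,
                            n_control = 22L, n_patient = 29L, seed = 1L,
                            rate_jitter_sd = 0.15, score_noise_sd = 0.5) {
  stopifnot(inherits(cfg_control, "synth_config"),
            inherits(cfg_patient, "synth_config"))
  set.seed(seed)
  n_total <- n_control + n_patient
  subj_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  specs <- c(
    lapply(seq_len(n_control), function(i)
      list(cfg = cfg_control, id = sprintf("ctrl%02d", i), group = "control")),
    lapply(seq_len(n_patient), function(i)
      list(cfg = cfg_patient, id = sprintf("pd%02d", i), group = "patient")))
  jitter <- matrix(rnorm(n_total * cfg_control$k_states, 0, rate_jitter_sd),
                   n_total)
  score_eps <- matrix(rnorm(n_total * 2L, 0, score_noise_sd), n_total)

  recordings <- vector("list", n_total)
  truth <- vector("list", n_total)
  log_rates <- matrix(NA_real_, n_total, cfg_control$k_states)
  for (i in seq_len(n_total)) {
    cfg <- specs[[i]]$cfg
    cfg$seed <- subj_seeds[i]
    cfg$subject_id <- specs[[i]]$id
    cfg$group <- specs[[i]]$group
    base <- rep_len(cfg$switching_rate, cfg$k_states)
    cfg$switching_rate <- base * exp(jitter[i, ])
    out <- generate_recording(cfg)
    recordings[[i]] <- out$recording
    truth[[i]] <- out[c("sequence", "templates", "coupling", "rates")]
    log_rates[i, ] <- log(out$rates)
  }
  # synthetic clinical scores for the patient group, linear in the realized
  # (log) switching rates of classes B and C
  pat <- which(vapply(specs, function(s) s$group == "patient", logical(1L)))
  zb <- scale(log_rates[pat, min(2L, ncol(log_rates))])[, 1L]
  zc <- scale(log_rates[pat, min(3L, ncol(log_rates))])[, 1L]
  for (jj in seq_along(pat)) {
    i <- pat[jj]
    recordings[[i]]$scores <- c(
      "UPDRS-III" = 15.8 + 7.5 * (zb[jj] + score_eps[i, 1L]),
      "MoCA" = 26.2 + 2.9 * (zc[jj] + score_eps[i, 2L]))
  }
  structure(list(recordings = recordings, truth = truth, seed = seed),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  gr <- table(vapply(x$recordings, function(r) r$group, character(1L)))
  cat("<synth_cohort>", paste(names(gr), gr, sep = ":", collapse = " "),
      "subjects\n")
  invisible(x)
}
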