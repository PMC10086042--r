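# shared small fixtures, built in code

# sinusoidal multichannel recording: freqs per channel, optional phase shifts
sine_recording <- function(freqs, fs = 250, duration = 2, phases = 0,
                           amp = 1) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  phases <- rep_len(phases, length(freqs))
  dat <- t(mapply(function(f, p) amp * cos(2 * pi * f * t - p),
                  freqs, phases))
  eeg_recording(dat, fs = fs)
}

# random valid recording
random_recording <- function(nch = 5, ns = 400, fs = 200, seed = 1) {
  set.seed(seed)
  eeg_recording(matrix(rnorm(nch * ns), nch), fs = fs)
}

# list of random symmetric zero-diagonal adjacency matrices in [0, 1]
random_networks <- function(v = 8, n = 19, seed = 1) {
  set.seed(seed)
  lapply(seq_len(v), function(i) {
    m <- matrix(runif(n * n), n)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    m
  })
}

# brute-force oracles for the variability statistics (naive loops, written
# independently of the vectorized implementations)
temporal_variability_naive <- function(nets, i) {
  v <- length(nets)
  tot <- 0
  for (p in seq_len(v)) for (q in seq_len(v)) {
    if (p == q) next
    tot <- tot + cor(nets[[p]][i, -i], nets[[q]][i, -i])
  }
  1 - tot / (v * (v - 1))
}

spatial_variability_naive <- function(nets, i) {
  n <- nrow(nets[[1]])
  others <- setdiff(seq_len(n), i)
  tot <- 0
  cnt <- 0
  for (j in others) for (h in others) {
    if (j == h) next
    sj <- vapply(nets, function(f) f[i, j], numeric(1))
    sh <- vapply(nets, function(f) f[i, h], numeric(1))
    tot <- tot + cor(sj, sh)
    cnt <- cnt + 1
  }
  1 - tot / cnt
}

# naive per-pair PLI loop (vectorization oracle)
pli_naive <- function(phase, start, end) {
  ph <- if (inherits(phase, "phase_matrix")) phase$phase else phase
  n <- nrow(ph)
  out <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- 0
    for (t in start:(end - 1)) s <- s + sign(sin(ph[i, t] - ph[j, t]))
    out[i, j] <- out[j, i] <- abs(s / (end - start))
  }
  out
}

# permutation-matched label agreement between a ground-truth sequence and a
# backfit sequence, given true and fitted templates
matched_agreement <- function(true_templates, model, true_labels, fit_labels) {
  perm <- apply(abs(spatial_correlation(true_templates, model$templates)),
                1, which.max)
  mean(perm[true_labels] == fit_labels, na.rm = TRUE)
}
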