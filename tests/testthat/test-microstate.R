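test_that("GFP equals the per-sample population SD across channels", {
  # all channels equal -> 0; (+1, -1) -> 1
  rec <- eeg_recording(rbind(c(3, 1), c(3, -1), c(3, 0)), fs = 2)
  g <- compute_gfp(rec)
  expect_equal(g$values[1], 0)
  set.seed(7)
  rec2 <- random_recording(nch = 19, ns = 50)
  g2 <- compute_gfp(rec2)
  pop_sd <- apply(rec2$data, 2, function(x) sqrt(mean((x - mean(x))^2)))
  expect_equal(g2$values, pop_sd, tolerance = 1e-12)
  # two-channel closed form on a 3-channel montage analog:
  rec3 <- eeg_recording(rbind(c(1), c(-1), c(1)) %*% t(c(1, 1)), fs = 2)
  expect_equal(compute_gfp(rec3)$values,
               rep(sqrt(mean((c(1, -1, 1) - 1 / 3)^2)), 2))
})

test_that("GFP peak detection finds interior strict maxima with spacing", {
  g <- structure(list(values = c(0, 1, 0, 2, 0), peak_indices = integer(0)),
                 class = "gfp_series")
  expect_identical(detect_gfp_peaks(g, 1)$peak_indices, c(2L, 4L))
  ramp <- structure(list(values = 1:10 / 10, peak_indices = integer(0)),
                    class = "gfp_series")
  expect_warning(out <- detect_gfp_peaks(ramp), "no GFP peaks")
  expect_length(out$peak_indices, 0)
  # rectified 10 Hz sinusoid at 500 Hz: peaks every ~25 samples
  v <- abs(sin(2 * pi * 10 * seq(0, 1, by = 1 / 500)))
  gs <- structure(list(values = v, peak_indices = integer(0)),
                  class = "gfp_series")
  pk <- detect_gfp_peaks(gs, 5)$peak_indices
  expect_equal(median(diff(pk)), 25, tolerance = 0.1)
  # min_distance thinning keeps the larger of two close peaks
  g2 <- structure(list(values = c(0, 3, 0, 5, 0, 0, 0, 2, 0),
                       peak_indices = integer(0)), class = "gfp_series")
  expect_identical(detect_gfp_peaks(g2, 3)$peak_indices, c(4L, 8L))
})

test_that("modified K-means recovers templates from noiseless flipped maps", {
  set.seed(3)
  tmpl <- matrix(rnorm(4 * 19), 4)
  tmpl <- tmpl - rowMeans(tmpl)
  tmpl <- qr.Q(qr(t(tmpl)))[, 1:4]        # orthonormal columns
  tmpl <- t(tmpl)
  tmpl <- (tmpl - rowMeans(tmpl)) / sqrt(rowSums((tmpl - rowMeans(tmpl))^2))
  maps <- tmpl[rep(1:4, each = 50), ] * runif(200, 0.5, 2)
  flip <- sample(c(-1, 1), 200, replace = TRUE)
  maps <- maps * flip
  mod <- fit_microstates(maps, k = 4, n_init = 10, seed = 1)
  cc <- abs(spatial_correlation(tmpl, mod$templates))
  expect_true(all(apply(cc, 1, max) > 0.999))
  expect_gt(mod$gev, 0.999)
  expect_equal(nrow(mod$templates), 4)    # k classes returned
  # sign-flip invariance of the fit
  mod2 <- fit_microstates(maps * -1, k = 4, n_init = 10, seed = 1)
  expect_equal(abs(spatial_correlation(mod$templates, mod2$templates)),
               abs(spatial_correlation(mod$templates, mod$templates)),
               tolerance = 1e-6)
  expect_error(fit_microstates(maps[1:3, ], k = 4), "at least k")
})

test_that("noisy template recovery stays accurate at SNR 10", {
  set.seed(11)
  hits <- replicate(10, {
    tmpl <- matrix(rnorm(4 * 19), 4)
    tmpl <- (tmpl - rowMeans(tmpl))
    tmpl <- tmpl / sqrt(rowSums(tmpl^2))
    maps <- tmpl[rep(1:4, each = 40), ] + matrix(rnorm(160 * 19, 0, 0.1 / sqrt(19)), 160)
    mod <- fit_microstates(maps, k = 4, n_init = 10,
                           seed = sample.int(1e6, 1))
    mean(apply(abs(spatial_correlation(tmpl, mod$templates)), 1, max))
  })
  expect_gt(mean(hits), 0.95)
})

test_that("backfit labels a pure template signal as one full window", {
  set.seed(5)
  mod <- fit_microstates(matrix(rnorm(40 * 19), 40), k = 4, n_init = 3,
                         seed = 1)
  env <- 1 + 0.5 * sin(seq(0, 6 * pi, length.out = 300))
  dat <- t(outer(env, mod$templates[2, ]))
  rec <- eeg_recording(dat, fs = 500,
                       channels = paste0("Ch", 1:19))
  sq <- backfit(rec, mod, smooth_min_duration = 0)
  expect_true(all(sq$labels == 2))
  expect_equal(nrow(sq$windows), 1)
  expect_equal(sq$windows$start, 1)
  expect_equal(sq$windows$end, 301)
})

test_that("backfit recovers alternating templates exactly without noise", {
  set.seed(6)
  mod <- fit_microstates(matrix(rnorm(40 * 19), 40), k = 4, n_init = 3,
                         seed = 1)
  # alternate classes 1 and 3 every 20 samples (40 ms at 500 Hz)
  lab <- rep(rep(c(1L, 3L), each = 20), 10)
  dat <- t(mod$templates[lab, ] * (1 + 0.2 * sin(seq_along(lab))))
  rec <- eeg_recording(dat, fs = 500)
  sq <- backfit(rec, mod, smooth_min_duration = 0)
  expect_identical(sq$labels, lab)
  expect_equal(nrow(sq$windows), 20)
  expect_true(all(sq$windows$end - sq$windows$start == 20))
  # windows exactly tile the labeled samples
  expect_equal(sum(sq$windows$end - sq$windows$start), length(lab))
})

test_that("flat samples get the unassigned sentinel and are excluded", {
  set.seed(8)
  mod <- fit_microstates(matrix(rnorm(40 * 10), 40), k = 2, n_init = 3,
                         seed = 1)
  dat <- t(mod$templates[rep(1L, 50), ])
  dat[, 10:12] <- 0                      # flat maps
  rec <- eeg_recording(dat, fs = 100)
  sq <- backfit(rec, mod, smooth_min_duration = 0)
  expect_true(all(is.na(sq$labels[10:12])))
  expect_false(any(is.na(sq$labels[-(10:12)])))
  spans <- unlist(lapply(seq_len(nrow(sq$windows)), function(r)
    sq$windows$start[r]:(sq$windows$end[r] - 1)))
  expect_false(any(10:12 %in% spans))
})

test_that("class ordering recovers a shuffled canonical permutation", {
  canon <- canonical_microstate_maps()
  mod <- structure(list(templates = canon[c(3, 1, 4, 2), ],
                        class_names = LETTERS[1:4], gev = 1, seed = 1),
                   class = "microstate_model")
  out <- order_classes(mod)
  expect_equal(out$templates, canon, ignore_attr = TRUE)
  expect_identical(out$class_names, c("A", "B", "C", "D"))
  # identity case
  mod2 <- structure(list(templates = canon, class_names = LETTERS[1:4],
                         gev = 1, seed = 1), class = "microstate_model")
  expect_equal(order_classes(mod2)$templates, canon, ignore_attr = TRUE)
})

test_that("noisy shuffled templates are re-ordered correctly almost always", {
  canon <- canonical_microstate_maps()
  # recovered ordering must align each output row with its canonical class
  set.seed(22)
  good <- replicate(100, {
    perm <- sample(4)
    noisy <- canon[perm, ] + matrix(rnorm(4 * 19, 0, 0.1 / sqrt(19)), 4)
    mod <- structure(list(templates = noisy, class_names = LETTERS[1:4],
                          gev = 1, seed = 1), class = "microstate_model")
    out <- order_classes(mod)
    all(apply(abs(spatial_correlation(canon, out$templates)), 1,
              which.max) == 1:4)
  })
  expect_gte(mean(good), 0.95)
})

test_that("model JSON round-trip preserves templates and metadata", {
  set.seed(9)
  mod <- fit_microstates(matrix(rnorm(60 * 19), 60), k = 4, n_init = 3,
                         seed = 5)
  path <- tempfile(fileext = ".json")
  write_microstate_model(mod, path)
  back <- read_microstate_model(path)
  expect_equal(back$templates, mod$templates, ignore_attr = TRUE)
  expect_identical(back$class_names, mod$class_names)
  expect_equal(back$gev, mod$gev)
})
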