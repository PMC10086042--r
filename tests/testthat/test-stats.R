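test_that("pooled t-test matches the textbook closed form", {
  set.seed(51)
  for (i in 1:5) {
    a <- rnorm(7 + i); b <- rnorm(5 + i, 0.5)
    ht <- independent_ttest(a, b)
    na <- length(a); nb <- length(b)
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    t_manual <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    expect_equal(ht$t, t_manual, tolerance = 1e-12)
    expect_equal(ht$df, na + nb - 2)
    expect_equal(ht$p, 2 * pt(-abs(t_manual), na + nb - 2), tolerance = 1e-12)
  }
  a <- c(1, 2, 3, 4)
  expect_equal(independent_ttest(a, a)$t, 0)
  expect_equal(independent_ttest(a, a)$p, 1)
  jit <- c(0, 1e-9, -1e-9, 0)
  expect_lt(independent_ttest(jit, 1 + jit)$p, 1e-3)
  expect_error(independent_ttest(c(1, 1), c(1, 1)), "zero-variance")
  expect_error(independent_ttest(1, c(1, 2)), "at least 2")
})

test_that("BH adjustment matches a brute-force step-up implementation", {
  bh_naive <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- numeric(n)
    prev <- 1
    for (k in n:1) {
      val <- min(prev, p[o[k]] * n / k)
      adj[o[k]] <- val
      prev <- val
    }
    adj
  }
  expect_equal(fdr_adjust(0.03), 0.03)                       # single p
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))                                  # hand-computed
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  set.seed(53)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    expect_equal(fdr_adjust(p), bh_naive(p), tolerance = 1e-12)
  }
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  p <- runif(6)
  expect_true(all(fdr_adjust(p) >= p))                       # adjusted >= raw
})

test_that("Spearman correlation endpoints and nulls behave", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_cor(x, exp(x))$rho, 1)               # monotone map
  expect_equal(spearman_cor(x, -x)$rho, -1)
  expect_error(spearman_cor(x, rep(2, 6)), "constant")
  expect_error(spearman_cor(1:2, 1:3), "lengths differ")
  set.seed(55)
  sims <- replicate(2000, spearman_cor(runif(30), runif(30))$p)
  expect_equal(mean(sims < 0.05), 0.05, tolerance = 0.2)
})

test_that("t-test type-I error is calibrated under the null", {
  set.seed(57)
  rej <- replicate(4000, independent_ttest(rnorm(12), rnorm(12))$p < 0.05)
  expect_equal(mean(rej), 0.05, tolerance = 0.2)
})

make_group_profiles <- function(n_per_group, channels, classes = LETTERS[1:4],
                                seed = 1, shift = NULL) {
  # shift: list(class=, channels=, statistic=, delta=) applied to patients
  set.seed(seed)
  profs <- list()
  for (g in c("control", "patient")) for (i in seq_len(n_per_group)) {
    tab <- expand.grid(channel = channels, class = classes,
                       stringsAsFactors = FALSE)[, c("class", "channel")]
    tab$temporal <- rnorm(nrow(tab), 1, 0.1)
    tab$spatial <- rnorm(nrow(tab), 0.8, 0.1)
    tab$v_used <- 20L
    if (g == "patient" && !is.null(shift)) {
      sel <- tab$class == shift$class & tab$channel %in% shift$channels
      tab[[shift$statistic]][sel] <- tab[[shift$statistic]][sel] + shift$delta
    }
    wb <- do.call(rbind, lapply(split(tab, tab$class), function(d)
      data.frame(class = d$class[1], temporal = mean(d$temporal),
                 spatial = mean(d$spatial), v_used = 20L)))
    profs[[length(profs) + 1]] <-
      structure(list(scheme = "MCN", table = tab, whole_brain = wb,
                     channels = channels,
                     subject_id = paste0(g, i), group = g, scores = NULL),
                class = "variability_profile")
  }
  profs
}

test_that("group maps recover injected channel effects and stay null otherwise", {
  ch <- paste0("Ch", 1:19)
  hit_channels <- c("Ch3", "Ch7", "Ch11", "Ch15", "Ch19")
  set.seed(61)
  hits <- 0; false_pos <- 0; null_sig <- 0
  n_seeds <- 10
  for (s in 1:n_seeds) {
    profs <- make_group_profiles(12, ch, seed = s,
                                 shift = list(class = "B",
                                              channels = hit_channels,
                                              statistic = "temporal",
                                              delta = 0.3))  # +3 SD
    gm <- topographic_group_map(profs)
    sig <- gm$channel[gm$class == "B" & gm$statistic == "temporal" &
                        gm$p_adj < 0.01]
    if (setequal(sig, hit_channels)) hits <- hits + 1
    other <- gm[!(gm$class == "B" & gm$statistic == "temporal"), ]
    false_pos <- false_pos + sum(other$p_adj < 0.01)
    null_profs <- make_group_profiles(12, ch, seed = 1000 + s)
    nm <- topographic_group_map(null_profs)
    null_sig <- null_sig + sum(nm$p_adj < 0.05)
  }
  expect_gte(hits / n_seeds, 0.9)
  expect_lt(null_sig / n_seeds, 1)          # null: ~0 significant channels
  # direction flags: patients shifted up -> control < patient
  profs <- make_group_profiles(12, ch, seed = 99,
                               shift = list(class = "B",
                                            channels = hit_channels,
                                            statistic = "temporal",
                                            delta = 0.3))
  gm <- topographic_group_map(profs)
  d <- gm[gm$class == "B" & gm$statistic == "temporal" &
            gm$channel %in% hit_channels, ]
  expect_true(all(d$direction == "control<patient"))
  expect_true(all(d$t < 0))
})

test_that("direction flags are antisymmetric under group swap", {
  ch <- paste0("Ch", 1:6)
  profs <- make_group_profiles(8, ch, classes = c("A", "B"), seed = 71,
                               shift = list(class = "A", channels = ch[1:2],
                                            statistic = "spatial",
                                            delta = 0.4))
  gm <- topographic_group_map(profs)
  swapped <- lapply(profs, function(p) {
    p$group <- if (p$group == "control") "patient" else "control"
    p
  })
  gs <- topographic_group_map(swapped)
  expect_equal(gs$t, -gm$t, tolerance = 1e-12)
  expect_true(all(gs$direction != gm$direction |
                    gs$p_adj > 0.999))      # identical means never flagged
})

test_that("single-channel family leaves the adjusted p equal to the raw p", {
  profs <- make_group_profiles(8, "Cz", classes = "A", seed = 81)
  gm <- topographic_group_map(profs)
  expect_equal(gm$p_adj, gm$p)
})

test_that("whole-brain tables adjust across classes and report tiers", {
  ch <- paste0("Ch", 1:19)
  profs <- make_group_profiles(14, ch, seed = 91,
                               shift = list(class = "B", channels = ch,
                                            statistic = "temporal",
                                            delta = 0.15))
  wb <- whole_brain_comparison(profs, statistic = "temporal")
  expect_equal(nrow(wb), 4)
  bb <- wb[wb$class == "B", ]
  expect_lt(bb$t, 0)                        # patient higher -> negative t
  expect_lt(bb$p_adj, 0.05)
  expect_true(all(wb$p_adj >= wb$p))
})

test_that("clinical correlation maps recover a monotone link", {
  ch <- paste0("Ch", 1:6)
  set.seed(95)
  profs <- make_group_profiles(15, ch, classes = c("A", "B"), seed = 95)
  patients <- Filter(function(p) p$group == "patient", profs)
  # give each patient a score tied to class-B Ch1 temporal variability
  patients <- lapply(patients, function(p) {
    v <- p$table$temporal[p$table$class == "B" & p$table$channel == "Ch1"]
    p$scores <- c(UPDRS = 10 + 20 * v + rnorm(1, 0, 0.3))
    p
  })
  cm <- clinical_correlation_map(patients, "UPDRS")
  row <- cm[cm$class == "B" & cm$channel == "Ch1" &
              cm$statistic == "temporal", ]
  expect_gt(row$rho, 0.5)
  expect_equal(row$n, 15)
  expect_error(clinical_correlation_map(patients[1:2], "UPDRS"), "fewer than 3")
})
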