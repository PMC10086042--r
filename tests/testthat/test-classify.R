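make_profile <- function(id, group, channels, classes = c("A", "B"),
                         seed = 1, na_class = NULL, scores = NULL) {
  set.seed(seed)
  tab <- expand.grid(channel = channels, class = classes,
                     stringsAsFactors = FALSE)[, c("class", "channel")]
  tab$temporal <- runif(nrow(tab))
  tab$spatial <- runif(nrow(tab))
  tab$v_used <- 10L
  if (!is.null(na_class)) {
    tab$temporal[tab$class == na_class] <- NA
    tab$spatial[tab$class == na_class] <- NA
  }
  wb <- do.call(rbind, lapply(split(tab, tab$class), function(d)
    data.frame(class = d$class[1], temporal = mean(d$temporal),
               spatial = mean(d$spatial), v_used = 10L)))
  structure(list(scheme = "MCN", table = tab, whole_brain = wb,
                 channels = channels, subject_id = id, group = group,
                 scores = scores),
            class = "variability_profile")
}

test_that("feature tables have deterministic layout and dimensions", {
  ch <- paste0("Ch", 1:19)
  profs <- lapply(1:6, function(i)
    make_profile(paste0("s", i), if (i <= 3) "control" else "patient",
                 ch, classes = LETTERS[1:4], seed = i))
  ft <- build_feature_table(profs)
  expect_equal(dim(ft$matrix), c(6, 19 * 2 * 4))       # k=4 MCN: 152 features
  expect_equal(ft$feature_names[1], "A_T_Ch1")
  expect_equal(ft$feature_names[20], "A_S_Ch1")        # T block before S block
  expect_equal(ft$feature_names[39], "B_T_Ch1")        # class-major
  # MN-style (single "all" class): 2 * n_channels features
  profs_mn <- lapply(profs, function(p) {
    p$scheme <- "MN"
    p$table <- p$table[p$table$class == "A", ]
    p$table$class <- "all"
    p
  })
  expect_equal(ncol(build_feature_table(profs_mn)$matrix), 38)
  expect_error(build_feature_table(c(profs[1], profs_mn[2])), "schemes")
})

test_that("subjects with missing class features are dropped or imputed", {
  ch <- paste0("Ch", 1:4)
  profs <- lapply(1:6, function(i)
    make_profile(paste0("s", i), if (i <= 3) "control" else "patient", ch,
                 seed = i, na_class = if (i == 2) "B" else NULL))
  expect_warning(ft <- build_feature_table(profs), "dropped")
  expect_equal(nrow(ft$matrix), 5)
  expect_false("s2" %in% ft$subject_ids)
  expect_warning(ft2 <- build_feature_table(profs, impute = TRUE), "imputed")
  expect_equal(nrow(ft2$matrix), 6)
  expect_false(anyNA(ft2$matrix))
})

test_that("metrics match closed-form confusion-matrix arithmetic", {
  truth <- c(rep("patient", 4), rep("control", 4))
  pred <- c("patient", "patient", "patient", "control",
            rep("control", 4))
  m <- compute_metrics(truth, pred, scores = c(4, 3, 2, 0, 1, 0, 0, 0),
                       positive = "patient")
  expect_equal(m$sensitivity, 0.75)      # TP=3 FN=1
  expect_equal(m$specificity, 1)         # TN=4 FP=0
  expect_equal(m$accuracy, 0.875)
  expect_equal(m$f1, 2 * 1 * 0.75 / 1.75, tolerance = 1e-12)  # 85.71 %
  # perfect prediction with monotone scores
  m2 <- compute_metrics(truth, truth, scores = c(4:1, 0, -1, -2, -3),
                        positive = "patient")
  expect_equal(unlist(m2), c(accuracy = 1, sensitivity = 1, specificity = 1,
                             f1 = 1, auc = 1))
  expect_error(compute_metrics(rep("a", 4), rep("a", 4), positive = "a"),
               "both classes")
})

test_that("trapezoidal AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  truth <- rep(c("patient", "control"), each = 50)
  scores <- rnorm(100) + (truth == "patient") * 1.2
  m <- compute_metrics(truth, ifelse(scores > 0.6, "patient", "control"),
                       scores = scores, positive = "patient")
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = scores, levels = c("control", "patient"),
    direction = "<", quiet = TRUE)))
  expect_equal(m$auc, ref, tolerance = 1e-12)
})

test_that("random scores give AUC near one half", {
  set.seed(33)
  truth <- rep(c("patient", "control"), each = 1000)
  m <- compute_metrics(truth, sample(truth), scores = rnorm(2000),
                       positive = "patient")
  expect_equal(m$auc, 0.5, tolerance = 0.1)
})

test_that("cross-validation is reproducible and records folds x repeats trials", {
  set.seed(41)
  x <- matrix(rnorm(40 * 6), 40)
  y <- rep(c("control", "patient"), each = 20)
  r1 <- cross_validate(x, folds = 5, repeats = 10, seed = 7, labels = y)
  r2 <- cross_validate(x, folds = 5, repeats = 10, seed = 7, labels = y)
  expect_equal(nrow(r1$trials), 50)
  expect_identical(r1$trials, r2$trials)               # same seed, same result
  r3 <- cross_validate(x, folds = 5, repeats = 10, seed = 8, labels = y)
  expect_false(identical(r1$trials, r3$trials))
  expect_error(cross_validate(x[c(1:3, 21:23), ], folds = 5,
                              labels = y[c(1:3, 21:23)]), "at least")
})

test_that("separable clouds classify near perfectly; permuted labels at chance", {
  set.seed(43)
  n <- 20
  x <- rbind(matrix(rnorm(n * 4, -5), n), matrix(rnorm(n * 4, 5), n))
  y <- rep(c("control", "patient"), each = n)
  rep_sep <- cross_validate(x, folds = 5, repeats = 10, seed = 1, labels = y)
  expect_gte(rep_sep$summary$mean[rep_sep$summary$metric == "accuracy"], 0.99)
  xnull <- matrix(rnorm(100 * 8), 100)
  ynull <- sample(rep(c("control", "patient"), each = 50))
  rep_null <- cross_validate(xnull, folds = 5, repeats = 10, seed = 2,
                             labels = ynull)
  expect_equal(rep_null$summary$mean[rep_null$summary$metric == "accuracy"],
               0.5, tolerance = 0.1)
})

test_that("standardization statistics come from the training folds only", {
  set.seed(47)
  n <- 30
  x <- matrix(rnorm(n * 4), n)
  # a label-dependent constant feature makes any test-fold contamination of
  # the scaling statistics immediately visible
  y <- rep(c("control", "patient"), each = n / 2)
  x[, 4] <- ifelse(y == "patient", 50, -50) + rnorm(n, 0, 0.1)
  r <- cross_validate(x, folds = 5, repeats = 2, seed = 3, labels = y)
  for (sc in r$scaling[c(1, 4, 8)]) {
    train <- which(r$folds[sc$repeat_i, ] != sc$fold)
    expect_equal(sc$center, colMeans(x[train, , drop = FALSE]),
                 tolerance = 1e-12)
    expect_equal(sc$scale, apply(x[train, , drop = FALSE], 2, sd),
                 tolerance = 1e-12)
  }
  # stratification: each fold of each repeat contains both classes
  for (rep_i in seq_len(nrow(r$folds)))
    for (f in 1:5)
      expect_equal(sort(unique(y[r$folds[rep_i, ] == f])),
                   c("control", "patient"))
})
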