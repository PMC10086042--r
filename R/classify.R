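#' Assemble an SVM feature table from variability profiles
#'
#' One row per subject; features are the per-channel temporal and spatial
#' variability values, ordered deterministically: class-major (MCN only),
#' temporal before spatial, channels innermost, named
#' \code{<class>_<T|S>_<channel>}. SN/MN tables have
#' \code{2 * n_channels} features; MCN tables \code{2 * n_channels * k}.
#' Subjects with missing class-level features are dropped with a warning by
#' default, or mean-imputed with \code{impute = TRUE}; either way the action
#' is recorded in the table's \code{provenance}.
#'
#' @param profiles list of \code{variability_profile} objects sharing
#'   scheme and channel set.
#' @param impute replace missing feature values by the across-subject mean
#'   of that feature instead of dropping the subject.
#' @return A \code{feature_table}: \code{matrix} (subjects x features),
#'   \code{feature_names}, \code{labels} (factor), \code{subject_ids},
#'   \code{scheme}, \code{provenance}.
#' @export
build_feature_table <- function(profiles, impute = FALSE) {
  stopifnot(length(profiles) >= 1L)
  scheme <- profiles[[1L]]$scheme
  channels <- profiles[[1L]]$channels
  for (p in profiles) {
    if (!identical(p$scheme, scheme)) stop("profiles mix schemes")
    if (!identical(p$channels, channels)) stop("profiles mix channel sets")
  }
  classes <- unique(profiles[[1L]]$table$class)
  feature_names <- unlist(lapply(classes, function(cl)
    c(paste(cl, "T", channels, sep = "_"),
      paste(cl, "S", channels, sep = "_"))))

  mat <- t(vapply(profiles, function(p) {
    unlist(lapply(classes, function(cl) {
      d <- p$table[p$table$class == cl, ]
      d <- d[match(channels, d$channel), ]
      c(d$temporal, d$spatial)
    }))
  }, numeric(length(feature_names))))
  colnames(mat) <- feature_names
  labels <- vapply(profiles, function(p)
    if (is.null(p$group)) NA_character_ else p$group, character(1L))
  subject_ids <- vapply(profiles, `[[`, character(1L), "subject_id")

  provenance <- character(0)
  incomplete <- apply(mat, 1L, anyNA)
  if (any(incomplete)) {
    if (impute) {
      for (j in which(apply(mat, 2L, anyNA))) {
        fill <- mean(mat[, j], na.rm = TRUE)
        mat[is.na(mat[, j]), j] <- fill
      }
      provenance <- paste0("mean-imputed missing features for subject(s): ",
                           paste(subject_ids[incomplete], collapse = ", "))
    } else {
      provenance <- paste0("dropped subject(s) with missing features: ",
                           paste(subject_ids[incomplete], collapse = ", "))
      mat <- mat[!incomplete, , drop = FALSE]
      labels <- labels[!incomplete]
      subject_ids <- subject_ids[!incomplete]
    }
    warning(provenance)
  }
  structure(list(matrix = mat, feature_names = feature_names,
                 labels = factor(labels), subject_ids = subject_ids,
                 scheme = scheme, provenance = provenance),
            class = "feature_table")
}

#' Binary classification metrics
#'
#' Accuracy, sensitivity (recall of the positive class), specificity, F1
#' score, and AUC from a trapezoidal ROC curve swept over the decision
#' scores. All returned on the [0, 1] scale.
#'
#' @param truth factor/vector of true binary labels (both classes present).
#' @param predicted predicted labels, same levels.
#' @param scores numeric decision values, larger = more positive-class.
#' @param positive the positive-class label (the patient group for
#'   sensitivity).
#' @return named list: \code{accuracy}, \code{sensitivity},
#'   \code{specificity}, \code{f1}, \code{auc}.
#' @examples
#' compute_metrics(c(1, 1, 1, 1, 0, 0, 0, 0),
#'                 c(1, 1, 1, 0, 0, 0, 0, 0),
#'                 scores = c(3, 2, 2, 1, 1, 0, 0, 0), positive = 1)
#' @export
compute_metrics <- function(truth, predicted, scores = NULL, positive) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted lengths differ")
  pos <- truth == as.character(positive)
  if (!any(pos) || all(pos))
    stop("both classes must be present in truth")
  pred_pos <- predicted == as.character(positive)
  tp <- sum(pos & pred_pos); fn <- sum(pos & !pred_pos)
  tn <- sum(!pos & !pred_pos); fp <- sum(!pos & pred_pos)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  auc <- if (is.null(scores)) NA_real_ else trapezoid_auc(pos, scores)
  list(accuracy = (tp + tn) / length(truth),
       sensitivity = recall,
       specificity = tn / (tn + fp),
       f1 = f1,
       auc = auc)
}

# ROC by threshold sweep over the observed scores, trapezoidal integration
# (ties between classes contribute half, as in the Mann-Whitney statistic)
trapezoid_auc <- function(pos, scores) {
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(s) mean(scores[pos] >= s), numeric(1L)), 1)
  fpr <- c(0, vapply(thr, function(s) mean(scores[!pos] >= s), numeric(1L)), 1)
  sum(diff(fpr) * (head(tpr, -1L) + tail(tpr, -1L)) / 2)
}

#' Repeated stratified cross-validation with a linear SVM
#'
#' The fixed-classifier comparison harness: per repeat, subjects are
#' stratified by group into \code{folds} folds; per trial a linear-kernel
#' SVM (cost 1, no class weights) is fit on the training folds and
#' evaluated on the held-out fold. Features are standardized using
#' training-fold statistics only. With folds = 5 and repeats = 10 this
#' yields the conventional 50 trials, summarized as mean and SD per metric.
#'
#' @param table a \code{feature_table} (or plain matrix plus \code{labels}).
#' @param folds number of folds (>= 2; every class must have >= folds
#'   subjects).
#' @param repeats number of repetitions with fresh fold assignments.
#' @param seed integer seed making fold assignment reproducible.
#' @param positive positive-class label; defaults to \code{"patient"} when
#'   present among the labels, else the second factor level.
#' @param labels group labels when \code{table} is a bare matrix.
#' @return A \code{classification_report}: \code{summary} (data.frame of
#'   mean/sd per metric), \code{trials} (per-trial metric data.frame),
#'   \code{roc} (vertically averaged ROC points), \code{folds}
#'   (repeats x subjects fold-assignment matrix), \code{scaling}
#'   (per-trial standardization centers/scales, for auditability),
#'   \code{config}.
#' @export
cross_validate <- function(table, folds = 5L, repeats = 10L, seed = 1L,
                           positive = NULL, labels = NULL) {
  if (inherits(table, "feature_table")) {
    x <- table$matrix
    y <- table$labels
  } else {
    x <- as.matrix(table)
    if (is.null(labels)) stop("labels required with a bare feature matrix")
    y <- factor(labels)
  }
  if (nlevels(y) != 2L) stop("binary classification requires 2 groups, got ",
                             nlevels(y))
  if (folds < 2L) stop("folds must be >= 2")
  if (any(table(y) < folds))
    stop("every class needs at least `folds` subjects")
  if (is.null(positive))
    positive <- if ("patient" %in% levels(y)) "patient" else levels(y)[2L]

  set.seed(seed)
  trial_rows <- list()
  roc_curves <- list()
  scaling <- list()
  fold_assignments <- matrix(NA_integer_, repeats, length(y))
  for (rep_i in seq_len(repeats)) {
    fold_of <- integer(length(y))
    for (lv in levels(y)) {
      idx <- sample(which(y == lv))
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold_assignments[rep_i, ] <- fold_of
    for (fold_i in seq_len(folds)) {
      test <- which(fold_of == fold_i)
      train <- which(fold_of != fold_i)
      if (nlevels(droplevels(y[train])) < 2L)
        stop("a class is absent from the training folds")
      mu <- colMeans(x[train, , drop = FALSE])
      sdev <- apply(x[train, , drop = FALSE], 2L, sd)
      sdev[sdev == 0] <- 1
      xtr <- scale(x[train, , drop = FALSE], center = mu, scale = sdev)
      xte <- scale(x[test, , drop = FALSE], center = mu, scale = sdev)
      fit <- e1071::svm(x = xtr, y = y[train], kernel = "linear", cost = 1,
                        scale = FALSE)
      pred <- predict(fit, xte, decision.values = TRUE)
      dv <- drop(attr(pred, "decision.values"))
      # orient decision values so larger = more positive-class
      dv_name <- colnames(attr(pred, "decision.values"))[1L]
      first <- strsplit(dv_name, "/", fixed = TRUE)[[1L]][1L]
      score <- if (identical(first, as.character(positive))) dv else -dv
      m <- compute_metrics(y[test], pred, scores = score, positive = positive)
      trial_rows[[length(trial_rows) + 1L]] <-
        data.frame(repeat_i = rep_i, fold = fold_i,
                   accuracy = m$accuracy, sensitivity = m$sensitivity,
                   specificity = m$specificity, f1 = m$f1, auc = m$auc)
      roc_curves[[length(roc_curves) + 1L]] <-
        list(pos = y[test] == positive, scores = score)
      scaling[[length(scaling) + 1L]] <-
        list(repeat_i = rep_i, fold = fold_i, center = mu, scale = sdev)
    }
  }
  trials <- do.call(rbind, trial_rows)
  metric_names <- c("accuracy", "sensitivity", "specificity", "f1", "auc")
  summary_df <- data.frame(
    metric = metric_names,
    mean = vapply(metric_names, function(m) mean(trials[[m]]), numeric(1L)),
    sd = vapply(metric_names, function(m) sd(trials[[m]]), numeric(1L)),
    row.names = NULL)

  fpr_grid <- seq(0, 1, by = 0.02)
  tpr_mat <- vapply(roc_curves, function(rc) {
    thr <- sort(unique(rc$scores), decreasing = TRUE)
    tpr <- c(0, vapply(thr, function(s) mean(rc$scores[rc$pos] >= s), numeric(1L)), 1)
    fpr <- c(0, vapply(thr, function(s) mean(rc$scores[!rc$pos] >= s), numeric(1L)), 1)
    vapply(fpr_grid, function(g) max(tpr[fpr <= g]), numeric(1L))
  }, numeric(length(fpr_grid)))
  roc <- data.frame(fpr = fpr_grid, tpr = rowMeans(tpr_mat))

  structure(list(summary = summary_df, trials = trials, roc = roc,
                 folds = fold_assignments, scaling = scaling,
                 config = list(folds = folds, repeats = repeats, seed = seed,
                               positive = positive)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %d trials (%d-fold x %d repeats)\n",
              nrow(x$trials), x$config$folds, x$config$repeats))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    if (s$metric[i] == "auc")
      cat(sprintf("  %-12s %.2f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
    else
      cat(sprintf("  %-12s %.2f%% +/- %.4f\n", s$metric[i],
                  100 * s$mean[i], s$sd[i]))
  }
  invisible(x)
}
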