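#' Spatial correlation between scalp maps
#'
#' Pearson correlation across channels of two (sets of) zero-mean maps; with
#' centered maps this is the cosine similarity of the centered vectors.
#' Polarity-invariant comparisons use its absolute value.
#'
#' @param maps matrix (n_maps x n_channels) or vector.
#' @param templates matrix (k x n_channels) or vector.
#' @return (n_maps x k) matrix of correlations.
#' @export
spatial_correlation <- function(maps, templates) {
  if (is.vector(maps)) maps <- matrix(maps, nrow = 1L)
  if (is.vector(templates)) templates <- matrix(templates, nrow = 1L)
  mc <- maps - rowMeans(maps)
  tc <- templates - rowMeans(templates)
  mn <- sqrt(rowSums(mc^2)); tn <- sqrt(rowSums(tc^2))
  if (any(mn == 0) || any(tn == 0))
    stop("spatial correlation undefined for a flat (zero-variance) map")
  (mc / mn) %*% t(tc / tn)
}

#' Fit microstate templates by polarity-invariant modified K-means
#'
#' Clusters GFP-peak topographies into \code{k} template maps. Unlike
#' ordinary K-means, assignment ignores map polarity (a map and its sign
#' flip belong to the same state): each map goes to the template with
#' maximal squared spatial correlation, and each template is updated as the
#' dominant eigenvector of its assigned maps' outer-product sum (the
#' polarity-blind least-squares topography). Iterations continue until the
#' relative change in global explained variance (GEV) falls below
#' \code{tol}; the best of \code{n_init} random restarts by GEV is kept.
#'
#' @param maps (n_maps x n_channels) matrix of zero-channel-mean maps, e.g.
#'   from \code{\link{gfp_peak_maps}}; a list of such matrices (one per
#'   recording) is concatenated, which is how group-level template sets are
#'   fit.
#' @param k number of classes (default 4, the conventional A-D set).
#' @param n_init random restarts (default 20).
#' @param max_iter iteration cap per restart.
#' @param tol relative-GEV convergence threshold.
#' @param seed integer seed controlling the restarts.
#' @return A \code{microstate_model}: \code{templates} (k x n_channels,
#'   unit-norm zero-mean rows), \code{class_names}, \code{gev},
#'   \code{seed}, \code{n_iter}, \code{restart_gev}.
#' @export
fit_microstates <- function(maps, k = 4L, n_init = 20L, max_iter = 300L,
                            tol = 1e-6, seed = 1L) {
  if (is.list(maps)) maps <- do.call(rbind, maps)
  maps <- as.matrix(maps)
  if (nrow(maps) < k) stop("need at least k = ", k, " maps, got ", nrow(maps))
  maps <- maps - rowMeans(maps)
  norms <- sqrt(rowSums(maps^2))
  ok <- norms > 0
  if (!all(ok)) { maps <- maps[ok, , drop = FALSE]; norms <- norms[ok] }
  n_maps <- nrow(maps); n_ch <- ncol(maps)
  X <- maps / norms                      # unit-norm rows; corr == cosine
  w <- norms^2                           # GEV weights: squared map strength
  total_w <- sum(w)

  set.seed(seed)
  best <- list(gev = -Inf)
  restart_gev <- numeric(n_init)
  for (init in seq_len(n_init)) {
    tmpl <- X[sample.int(n_maps, k), , drop = FALSE]
    gev_prev <- -Inf; it <- 0L
    repeat {
      it <- it + 1L
      cmat <- X %*% t(tmpl)              # maps x k correlations
      lab <- max.col(cmat^2, ties.method = "first")
      c2 <- cmat[cbind(seq_len(n_maps), lab)]^2
      for (j in seq_len(k)) {
        idx <- which(lab == j)
        if (!length(idx)) {              # empty cluster: reseed from worst fit
          idx <- which.min(c2)
          lab[idx] <- j
          c2[idx] <- 1
        }
        Xi <- X[idx, , drop = FALSE]
        S <- crossprod(Xi * sqrt(w[idx]))
        v <- eigen(S, symmetric = TRUE)$vectors[, 1L]
        v <- v - mean(v)
        tmpl[j, ] <- v / sqrt(sum(v^2))
      }
      cmat <- X %*% t(tmpl)
      lab <- max.col(cmat^2, ties.method = "first")
      gev <- sum(w * cmat[cbind(seq_len(n_maps), lab)]^2) / total_w
      if (it >= max_iter || (is.finite(gev_prev) &&
          abs(gev - gev_prev) <= tol * max(gev_prev, .Machine$double.eps)))
        break
      gev_prev <- gev
    }
    restart_gev[init] <- gev
    if (gev > best$gev)
      best <- list(templates = tmpl, gev = gev, n_iter = it)
  }
  structure(list(templates = best$templates,
                 class_names = LETTERS[seq_len(k)],
                 gev = best$gev, seed = seed, n_iter = best$n_iter,
                 restart_gev = restart_gev),
            class = "microstate_model")
}

#' @export
print.microstate_model <- function(x, ...) {
  cat(sprintf("<microstate_model> k = %d (%s), %d channels, GEV = %.4f\n",
              nrow(x$templates), paste(x$class_names, collapse = ""),
              ncol(x$templates), x$gev))
  invisible(x)
}

#' Backfit microstate templates to a continuous recording
#'
#' Labels every sample with the class of maximal absolute spatial
#' correlation between its (average-referenced) topography and the model
#' templates, then merges label runs shorter than
#' \code{smooth_min_duration} into whichever neighboring class correlates
#' better with the run's samples. Flat (zero-variance) samples receive the
#' unassigned sentinel \code{NA} and are excluded from windows.
#'
#' @param rec an \code{eeg_recording} with the model's channel count.
#' @param model a \code{microstate_model}.
#' @param smooth_min_duration minimum run duration in milliseconds
#'   (default 20 ms; 0 disables smoothing).
#' @return A \code{microstate_sequence}: \code{labels} (integer class index
#'   per sample, \code{NA} = unassigned), \code{windows} (data.frame with
#'   \code{start}, \code{end} exclusive, \code{class}, 1-based sample
#'   indexing), \code{class_names}, \code{fs}.
#' @export
backfit <- function(rec, model, smooth_min_duration = 20) {
  validate_recording(rec)
  stopifnot(inherits(model, "microstate_model"))
  if (ncol(model$templates) != n_channels(rec))
    stop("model has ", ncol(model$templates), " channels but recording has ",
         n_channels(rec))
  maps <- t(rec$data)
  maps <- maps - rowMeans(maps)
  norms <- sqrt(rowSums(maps^2))
  flat <- norms == 0
  cmat <- matrix(0, nrow(maps), nrow(model$templates))
  if (any(!flat))
    cmat[!flat, ] <- (maps[!flat, , drop = FALSE] / norms[!flat]) %*%
      t(model$templates)
  acmat <- abs(cmat)
  labels <- max.col(acmat, ties.method = "first")
  labels[flat] <- NA_integer_

  min_len <- max(1L, round(smooth_min_duration / 1000 * rec$fs))
  if (min_len > 1L) labels <- smooth_labels(labels, acmat, min_len)

  structure(list(labels = labels,
                 windows = windows_from_labels(labels),
                 class_names = model$class_names, fs = rec$fs),
            class = "microstate_sequence")
}

# merge runs shorter than min_len into the neighbor class with the higher
# mean absolute correlation over the run's samples; batched sweeps until
# stable (runs bounded by unassigned samples on both sides are kept as-is)
smooth_labels <- function(labels, acmat, min_len) {
  for (pass in seq_len(50L)) {
    r <- rle(ifelse(is.na(labels), -1L, labels))
    len <- r$lengths; val <- r$values
    ends <- cumsum(len); starts <- ends - len + 1L
    short <- which(len < min_len & val != -1L)
    iso <- vapply(short, function(j) {
      l <- if (j > 1L) val[j - 1L] else -1L
      rg <- if (j < length(val)) val[j + 1L] else -1L
      l == -1L && rg == -1L
    }, logical(1L))
    short <- short[!iso]
    if (!length(short)) break
    for (i in short) {
      left <- if (i > 1L && val[i - 1L] != -1L) val[i - 1L] else NA_integer_
      right <- if (i < length(val) && val[i + 1L] != -1L) val[i + 1L] else NA_integer_
      span <- starts[i]:ends[i]
      target <- if (is.na(left)) right
        else if (is.na(right)) left
        else if (mean(acmat[span, left]) >= mean(acmat[span, right])) left
        else right
      labels[span] <- target
    }
  }
  labels
}

#' Contiguous class windows from a label sequence
#'
#' @param labels integer vector of per-sample class indices (\code{NA}
#'   allowed for unassigned samples).
#' @return data.frame with columns \code{start}, \code{end} (exclusive,
#'   1-based) and \code{class}; one row per maximal run of a single class,
#'   unassigned runs omitted.
#' @export
windows_from_labels <- function(labels) {
  r <- rle(ifelse(is.na(labels), -1L, labels))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != -1L
  data.frame(start = starts[keep], end = ends[keep] + 1L,
             class = r$values[keep])
}

#' @export
print.microstate_sequence <- function(x, ...) {
  tab <- table(factor(x$windows$class, levels = seq_along(x$class_names),
                      labels = x$class_names))
  cat(sprintf("<microstate_sequence> %d samples, %d windows (%s)\n",
              length(x$labels), nrow(x$windows),
              paste(names(tab), tab, sep = ":", collapse = " ")))
  invisible(x)
}

#' Canonical microstate template shapes for a montage
#'
#' Synthetic approximations of the four literature template maps, built from
#' electrode geometry: A and B are the two diagonal left/right
#' posterior-anterior gradients, C the symmetric anterior-posterior
#' gradient, and D a fronto-central focal map. These are idealized
#' constructions (not empirical grand averages) sufficient to give fitted
#' templates stable A-D names via \code{\link{order_classes}}.
#'
#' @param positions (n_channels x 2) electrode coordinates; default the
#'   standard 10-20 montage.
#' @return 4 x n_channels matrix of unit-norm zero-mean maps, rows A-D.
#' @export
canonical_microstate_maps <- function(positions = standard_1020_positions()) {
  positions <- as.matrix(positions)
  x <- positions[, 1L]; y <- positions[, 2L]
  maps <- rbind(
    A = -x + y,                                   # left-posterior / right-anterior
    B = x + y,                                    # right-posterior / left-anterior
    C = y,                                        # anterior-posterior
    D = exp(-((x / 0.6)^2 + ((y - 0.35) / 0.6)^2)))  # fronto-central focus
  maps <- maps - rowMeans(maps)
  maps / sqrt(rowSums(maps^2))
}

#' Order fitted microstate classes against canonical maps
#'
#' Permutes model templates so that total absolute spatial correlation with
#' the canonical reference maps is maximal (exhaustive optimal assignment),
#' and names the classes accordingly.
#'
#' @param model a \code{microstate_model} with k classes.
#' @param canonical (k x n_channels) reference maps, rows in the desired
#'   class order; default \code{\link{canonical_microstate_maps}()}.
#' @return The re-ordered \code{microstate_model}; element \code{ordering}
#'   records the permutation applied (new position -> old template row).
#' @export
order_classes <- function(model, canonical = canonical_microstate_maps()) {
  stopifnot(inherits(model, "microstate_model"))
  k <- nrow(model$templates)
  if (nrow(canonical) != k)
    stop("model has ", k, " classes but ", nrow(canonical),
         " canonical maps were given")
  score <- abs(spatial_correlation(canonical, model$templates)) # k x k
  perms <- all_permutations(k)
  totals <- vapply(perms, function(p) sum(score[cbind(seq_len(k), p)]),
                   numeric(1L))
  p <- perms[[which.max(totals)]]
  model$templates <- model$templates[p, , drop = FALSE]
  rn <- rownames(canonical)
  model$class_names <- if (!is.null(rn)) rn else LETTERS[seq_len(k)]
  model$ordering <- p
  model
}

all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- all_permutations(k - 1L)
  out <- vector("list", k * length(sub))
  idx <- 0L
  for (p in sub) for (pos in 0:(k - 1L)) {   # insert k into every slot
    idx <- idx + 1L
    out[[idx]] <- append(p, k, after = pos)
  }
  out
}
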