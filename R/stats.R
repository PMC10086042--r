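#' Two-sample pooled-variance t-test
#'
#' Student's independent-sample t-test (pooled variance,
#' \code{n_a + n_b - 2} degrees of freedom, two-sided), the conventional
#' group-comparison test for channel-wise variability maps; Welch's
#' unequal-variance form is available via \code{welch = TRUE}.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @param welch use the Welch approximation instead of pooled variance.
#' @return list with \code{t}, \code{p}, \code{df}, \code{mean_diff}
#'   (\code{mean(a) - mean(b)}).
#' @export
independent_ttest <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations")
  if (var(a) + var(b) == 0) stop("degenerate zero-variance groups")
  ht <- t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_diff = mean(a) - mean(b))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjusted p-values, order-preserving with the
#' input (monotonicity enforced).
#'
#' @param pvals numeric vector of p-values in [0, 1] (NA passed through).
#' @return adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(pvals) {
  finite <- pvals[!is.na(pvals)]
  if (any(finite < 0 | finite > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Midrank-tied Spearman correlation; the two-sided p-value uses the
#' t-distribution approximation on the rank correlation.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with \code{rho}, \code{p}, \code{n}.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("constant vector: rank correlation undefined")
  ht <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ht$estimate), p = ht$p.value, n = length(x))
}

# split cohort labels into (control, patient) levels with sane defaults
resolve_group_levels <- function(groups, control = NULL, patient = NULL) {
  lv <- unique(stats::na.omit(as.character(groups)))
  if (length(lv) != 2L) stop("exactly two groups required, got: ",
                             paste(lv, collapse = ", "))
  if (is.null(control))
    control <- if ("control" %in% lv) "control" else lv[1L]
  if (is.null(patient)) patient <- setdiff(lv, control)
  if (!all(c(control, patient) %in% lv)) stop("unknown group labels")
  c(control = control, patient = patient)
}

#' Channel-wise group comparison maps
#'
#' For every (class, channel, statistic) cell of a cohort of variability
#' profiles: group means/SDs, pooled t-test (t computed as control minus
#' patient, matching the convention that a negative t means the patient
#' group is higher), Benjamini-Hochberg adjustment across the channels of
#' each (class, statistic) family, significance tiers at adjusted p < 0.05
#' and < 0.01, and the direction of the difference.
#'
#' @param profiles list of \code{variability_profile} objects with group
#'   labels (or a tidy table from \code{\link{profiles_to_table}}).
#' @param control,patient group label strings; by default \code{"control"}
#'   and the remaining label.
#' @param family FDR family: \code{"per_map"} (channels within one class x
#'   statistic map, the default) or \code{"global"} (all cells at once).
#' @param welch use Welch's t-test.
#' @return A \code{group_stats} data.frame: \code{class}, \code{channel},
#'   \code{statistic}, \code{mean_control}, \code{sd_control},
#'   \code{mean_patient}, \code{sd_patient}, \code{t}, \code{p},
#'   \code{p_adj}, \code{tier} (\code{"ns"}, \code{"p<0.05"},
#'   \code{"p<0.01"}), \code{direction} (\code{"control>patient"} /
#'   \code{"control<patient"}).
#' @export
topographic_group_map <- function(profiles, control = NULL, patient = NULL,
                                  family = c("per_map", "global"),
                                  welch = FALSE) {
  family <- match.arg(family)
  tab <- if (is.data.frame(profiles)) profiles else profiles_to_table(profiles)
  lv <- resolve_group_levels(tab$group, control, patient)
  long <- rbind(
    data.frame(tab[c("subject", "group", "class", "channel")],
               statistic = "temporal", value = tab$temporal),
    data.frame(tab[c("subject", "group", "class", "channel")],
               statistic = "spatial", value = tab$spatial))

  cells <- unique(long[c("class", "channel", "statistic")])
  res <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    d <- long[long$class == cells$class[i] &
              long$channel == cells$channel[i] &
              long$statistic == cells$statistic[i], ]
    a <- d$value[d$group == lv["control"]]
    b <- d$value[d$group == lv["patient"]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L) {
      warning("class ", cells$class[i], " ", cells$statistic[i],
              ": too few complete subjects in a group; cell skipped")
      return(NULL)
    }
    ht <- independent_ttest(a, b, welch = welch)
    data.frame(class = cells$class[i], channel = cells$channel[i],
               statistic = cells$statistic[i],
               mean_control = mean(a), sd_control = sd(a),
               mean_patient = mean(b), sd_patient = sd(b),
               t = ht$t, p = ht$p)
  }))
  if (family == "per_map") {
    res$p_adj <- NA_real_
    for (key in unique(paste(res$class, res$statistic))) {
      idx <- paste(res$class, res$statistic) == key
      res$p_adj[idx] <- fdr_adjust(res$p[idx])
    }
  } else {
    res$p_adj <- fdr_adjust(res$p)
  }
  res$tier <- ifelse(res$p_adj < 0.01, "p<0.01",
              ifelse(res$p_adj < 0.05, "p<0.05", "ns"))
  res$direction <- ifelse(res$t >= 0, "control>patient", "control<patient")
  rownames(res) <- NULL
  class(res) <- c("group_stats", class(res))
  res
}

#' Whole-brain group comparison per microstate class
#'
#' Averages each subject's per-channel variability over the whole montage,
#' then compares groups per class with pooled t-tests (t = control minus
#' patient) and FDR adjustment across the classes, separately for the
#' temporal and spatial statistics.
#'
#' @inheritParams topographic_group_map
#' @param statistic \code{"temporal"}, \code{"spatial"}, or both (default).
#' @return data.frame: \code{statistic}, \code{class}, group means/SDs,
#'   \code{t}, \code{p}, \code{p_adj}, \code{tier}.
#' @export
whole_brain_comparison <- function(profiles, control = NULL, patient = NULL,
                                   statistic = c("temporal", "spatial"),
                                   welch = FALSE) {
  statistic <- match.arg(statistic, several.ok = TRUE)
  lv <- resolve_group_levels(
    vapply(profiles, function(p)
      if (is.null(p$group)) NA_character_ else p$group, character(1L)),
    control, patient)
  wb <- do.call(rbind, lapply(profiles, function(p)
    cbind(data.frame(subject = p$subject_id, group = p$group), p$whole_brain)))
  out <- list()
  for (st in statistic) {
    classes <- unique(wb$class)
    block <- do.call(rbind, lapply(classes, function(cl) {
      d <- wb[wb$class == cl, ]
      a <- d[[st]][d$group == lv["control"]]
      b <- d[[st]][d$group == lv["patient"]]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) < 2L || length(b) < 2L) return(NULL)
      ht <- independent_ttest(a, b, welch = welch)
      data.frame(statistic = st, class = cl,
                 mean_control = mean(a), sd_control = sd(a),
                 mean_patient = mean(b), sd_patient = sd(b),
                 t = ht$t, p = ht$p)
    }))
    block$p_adj <- fdr_adjust(block$p)
    out[[st]] <- block
  }
  res <- do.call(rbind, out)
  res$tier <- ifelse(res$p_adj < 0.01, "p<0.01",
              ifelse(res$p_adj < 0.05, "p<0.05", "ns"))
  rownames(res) <- NULL
  res
}

#' Spearman correlations between variability and clinical scores
#'
#' For each (class, channel, statistic) cell, correlates the subjects'
#' variability values with a named clinical score (subjects lacking the
#' score are excluded), with FDR adjustment across the channels of each
#' (class, statistic) family.
#'
#' @param profiles list of \code{variability_profile} objects carrying
#'   \code{scores}.
#' @param score name of the clinical score (e.g. \code{"UPDRS-III"}).
#' @param group optional group label restricting the subjects (clinical
#'   correlations are usually computed within the patient group).
#' @return data.frame: \code{score}, \code{class}, \code{channel},
#'   \code{statistic}, \code{rho}, \code{p}, \code{p_adj}, \code{n}.
#' @export
clinical_correlation_map <- function(profiles, score, group = NULL) {
  if (!is.null(group))
    profiles <- Filter(function(p) identical(p$group, group), profiles)
  keep <- Filter(function(p) !is.null(p$scores) && score %in% names(p$scores) &&
                   !is.na(p$scores[[score]]), profiles)
  if (length(keep) < 3L) stop("fewer than 3 subjects carry score ", score)
  tab <- profiles_to_table(keep)
  sc <- vapply(keep, function(p) p$scores[[score]], numeric(1L))
  names(sc) <- vapply(keep, `[[`, character(1L), "subject_id")
  long <- rbind(
    data.frame(tab[c("subject", "class", "channel")],
               statistic = "temporal", value = tab$temporal),
    data.frame(tab[c("subject", "class", "channel")],
               statistic = "spatial", value = tab$spatial))
  cells <- unique(long[c("class", "channel", "statistic")])
  res <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    d <- long[long$class == cells$class[i] &
              long$channel == cells$channel[i] &
              long$statistic == cells$statistic[i], ]
    v <- d$value[match(names(sc), d$subject)]
    ok <- !is.na(v)
    if (sum(ok) < 3L || sd(v[ok]) == 0) return(NULL)
    r <- spearman_cor(v[ok], sc[ok])
    data.frame(score = score, class = cells$class[i],
               channel = cells$channel[i], statistic = cells$statistic[i],
               rho = r$rho, p = r$p, n = r$n)
  }))
  res$p_adj <- NA_real_
  for (key in unique(paste(res$class, res$statistic))) {
    idx <- paste(res$class, res$statistic) == key
    res$p_adj[idx] <- fdr_adjust(res$p[idx])
  }
  rownames(res) <- NULL
  res
}
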