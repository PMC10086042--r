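#' Temporal variability of a channel's connectivity profile
#'
#' Given an ordered sequence of v connectivity networks, channel i's
#' "functional architecture" in window p is its connection row
#' \eqn{F_p(i,:)} with the diagonal self-entry removed (length
#' n_channels - 1). Temporal variability is one minus the mean Pearson
#' correlation over all ordered pairs of windows:
#' \deqn{T_i = 1 - \frac{1}{v(v-1)} \sum_{p \ne q} corr(F_p(i,:), F_q(i,:))}
#' (equal to the unordered-pair mean, since correlation is symmetric).
#' \eqn{T_i \in [0, 2]}: 0 when the architecture never changes, large when
#' successive networks are uncorrelated or anti-correlated.
#'
#' @param nets list of symmetric adjacency matrices, all the same size
#'   (v >= 2).
#' @param channel channel index i.
#' @return scalar \eqn{T_i}.
#' @export
temporal_variability <- function(nets, channel) {
  v <- length(nets)
  if (v < 2L) stop("temporal variability needs at least 2 networks, got ", v)
  rows <- vapply(nets, function(f) f[channel, -channel], numeric(nrow(nets[[1L]]) - 1L))
  # rows: (n_channels - 1) x v; columns are the per-window architectures
  sds <- apply(rows, 2L, sd)
  if (any(sds == 0))
    stop("zero-variance architecture for channel ", channel, " in window(s) ",
         paste(which(sds == 0), collapse = ", "))
  cc <- cor(rows)
  1 - (sum(cc) - v) / (v * (v - 1))
}

#' Spatial variability of a channel's connection time courses
#'
#' For channel i, each other channel j defines a "spatial functional
#' connectivity sequence" \eqn{F_s(i,j) = [F_1(i,j), ..., F_v(i,j)]}: the
#' time course of that single connection across windows. Spatial
#' variability is one minus the mean Pearson correlation over all ordered
#' pairs of distinct sequences:
#' \deqn{S_i = 1 - \frac{1}{(n-1)(n-2)} \sum_{j \ne h,\; j,h \ne i}
#'   corr(F_s(i,j), F_s(i,h))}
#' For the 19-channel montage the normalizer is 1/(18 x 17). \eqn{S_i} is
#' low when all of channel i's connections wax and wane together, high when
#' they evolve independently.
#'
#' @param nets list of symmetric adjacency matrices (v >= 2, >= 3 channels).
#' @param channel channel index i.
#' @return scalar \eqn{S_i}.
#' @export
spatial_variability <- function(nets, channel) {
  v <- length(nets)
  if (v < 2L) stop("spatial variability needs at least 2 networks, got ", v)
  n <- nrow(nets[[1L]])
  if (n < 3L) stop("spatial variability needs at least 3 channels")
  seqs <- t(vapply(nets, function(f) f[channel, -channel], numeric(n - 1L)))
  # seqs: v x (n - 1); column j is the time course of connection (i, j)
  sds <- apply(seqs, 2L, sd)
  if (any(sds == 0)) {
    others <- seq_len(n)[-channel]
    stop("constant connectivity sequence for pair(s) (", channel, ", ",
         paste(others[sds == 0], collapse = "), ("), ")")
  }
  cc <- cor(seqs)
  m <- n - 1L
  1 - (sum(cc) - m) / (m * (m - 1L))
}

#' Per-channel variability profile of a network set
#'
#' Computes \eqn{T_i} and \eqn{S_i} for every channel: over all windows for
#' SN and MN sets, and separately per microstate class for MCN sets.
#' Whole-brain values are the means of the per-channel values. Classes that
#' fail the preconditions (fewer than 2 usable windows) are reported as
#' missing (\code{NA}) with a warning, never as zero.
#'
#' @param netset a \code{network_set} from \code{\link{build_networks}}.
#' @param subject_id,group carried through to the profile for cohort
#'   assembly; default taken from the recording that built the set when
#'   available.
#' @param scores optional named numeric clinical scores carried through.
#' @param drop_degenerate degenerate-data policy for real-world network
#'   sequences, where the PLI of a short window can saturate: windows in
#'   which some channel's connection row is constant are dropped, and
#'   connections whose PLI time course is constant across windows are
#'   excluded from the spatial average (the normalizer shrinks to the
#'   remaining ordered pairs). Both actions are counted and reported in a
#'   warning -- never a silent zero-correlation substitution. With the
#'   default \code{FALSE}, degenerate data raises an error naming the
#'   window or pair.
#' @return A \code{variability_profile}: \code{scheme}, \code{table}
#'   (data.frame: \code{class}, \code{channel}, \code{temporal},
#'   \code{spatial}, \code{v_used}), \code{whole_brain} (data.frame:
#'   \code{class}, \code{temporal}, \code{spatial}, \code{v_used}),
#'   \code{channels}, \code{subject_id}, \code{group}, \code{scores}.
#' @export
variability_profile <- function(netset, subject_id = "anonymous",
                                group = NULL, scores = NULL,
                                drop_degenerate = FALSE) {
  stopifnot(inherits(netset, "network_set"))
  nch <- length(netset$channels)
  groups_of_nets <- if (netset$scheme == "MCN") {
    lapply(netset$by_class, function(idx)
      lapply(netset$windows[idx], `[[`, "adjacency"))
  } else {
    list(all = lapply(netset$windows, `[[`, "adjacency"))
  }
  if (drop_degenerate) {
    n_dropped <- 0L
    groups_of_nets <- lapply(groups_of_nets, function(nets) {
      ok <- vapply(nets, function(f) {
        all(vapply(seq_len(nch), function(i) sd(f[i, -i]) > 0, logical(1L)))
      }, logical(1L))
      n_dropped <<- n_dropped + sum(!ok)
      nets[ok]
    })
    if (n_dropped > 0L)
      warning(n_dropped, " window(s) with a constant connection row dropped")
  }

  rows <- list()
  for (cls in names(groups_of_nets)) {
    nets <- groups_of_nets[[cls]]
    v <- length(nets)
    if (v < 2L) {
      warning("class ", cls, ": only ", v,
              " usable window(s); variability reported as missing")
      tv <- sv <- rep(NA_real_, nch)
    } else if (drop_degenerate) {
      tv <- vapply(seq_len(nch), function(i)
        temporal_variability(nets, i), numeric(1L))
      n_excluded <- 0L
      sv <- vapply(seq_len(nch), function(i) {
        r <- spatial_variability_tolerant(nets, i)
        n_excluded <<- n_excluded + r$n_excluded
        r$value
      }, numeric(1L))
      if (n_excluded > 0L)
        warning("class ", cls, ": ", n_excluded,
                " constant connection time course(s) excluded from the ",
                "spatial average")
    } else {
      tv <- vapply(seq_len(nch), function(i)
        tryCatch(temporal_variability(nets, i), error = function(e) {
          stop("class ", cls, ": ", conditionMessage(e), call. = FALSE)
        }), numeric(1L))
      sv <- vapply(seq_len(nch), function(i)
        tryCatch(spatial_variability(nets, i), error = function(e) {
          stop("class ", cls, ": ", conditionMessage(e), call. = FALSE)
        }), numeric(1L))
    }
    rows[[cls]] <- data.frame(class = cls, channel = netset$channels,
                              temporal = tv, spatial = sv, v_used = v)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  wb <- do.call(rbind, lapply(split(tab, tab$class), function(d)
    data.frame(class = d$class[1L], temporal = mean(d$temporal),
               spatial = mean(d$spatial), v_used = d$v_used[1L])))
  rownames(wb) <- NULL
  structure(list(scheme = netset$scheme, table = tab, whole_brain = wb,
                 channels = netset$channels, subject_id = subject_id,
                 group = group, scores = scores),
            class = "variability_profile")
}

#' @export
print.variability_profile <- function(x, ...) {
  cat(sprintf("<variability_profile> %s, scheme %s, %d channels\n",
              x$subject_id, x$scheme, length(x$channels)))
  print(x$whole_brain)
  invisible(x)
}

# spatial variability with constant (uninformative) connection sequences
# excluded from the pair average; returns the exclusion count alongside
spatial_variability_tolerant <- function(nets, channel) {
  v <- length(nets)
  n <- nrow(nets[[1L]])
  seqs <- t(vapply(nets, function(f) f[channel, -channel], numeric(n - 1L)))
  keep <- apply(seqs, 2L, sd) > 0
  n_excluded <- sum(!keep)
  if (sum(keep) < 2L)
    return(list(value = NA_real_, n_excluded = n_excluded))
  cc <- cor(seqs[, keep, drop = FALSE])
  m <- sum(keep)
  list(value = 1 - (sum(cc) - m) / (m * (m - 1L)), n_excluded = n_excluded)
}

#' Export a cohort of variability profiles as one tidy table
#'
#' @param profiles list of \code{variability_profile} objects.
#' @return data.frame with columns \code{subject}, \code{group},
#'   \code{scheme}, \code{class}, \code{channel}, \code{temporal},
#'   \code{spatial}, \code{v_used}.
#' @export
profiles_to_table <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) {
    cbind(data.frame(subject = p$subject_id,
                     group = if (is.null(p$group)) NA_character_ else p$group,
                     scheme = p$scheme),
          p$table)
  }))
}
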