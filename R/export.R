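#' Persist and restore a microstate model as JSON
#'
#' @param model a \code{microstate_model}.
#' @param path JSON file path.
#' @return \code{path} (write) or the restored model (read).
#' @export
write_microstate_model <- function(model, path) {
  stopifnot(inherits(model, "microstate_model"))
  jsonlite::write_json(
    list(templates = model$templates, class_names = model$class_names,
         gev = model$gev, seed = model$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_microstate_model
#' @export
read_microstate_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(templates = as.matrix(obj$templates),
                 class_names = obj$class_names,
                 gev = obj$gev, seed = obj$seed),
            class = "microstate_model")
}

#' Export a microstate sequence as delimited tables
#'
#' Writes two tab-separated files: \code{<stem>_labels.tsv}
#' (\code{sample}, \code{label}) and \code{<stem>_windows.tsv}
#' (\code{start}, \code{end}, \code{class}).
#'
#' @param seq a \code{microstate_sequence}.
#' @param stem output path stem.
#' @return the two paths, invisibly.
#' @export
write_microstate_sequence <- function(seq, stem) {
  stopifnot(inherits(seq, "microstate_sequence"))
  p1 <- paste0(stem, "_labels.tsv")
  p2 <- paste0(stem, "_windows.tsv")
  write.table(data.frame(sample = seq_along(seq$labels), label = seq$labels),
              p1, sep = "\t", row.names = FALSE, quote = FALSE)
  w <- seq$windows
  w$class <- seq$class_names[w$class]
  write.table(w, p2, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2))
}

#' Export a network set as matrix files plus a JSON manifest
#'
#' Writes one tab-separated adjacency matrix per window
#' (\code{<stem>_w<index>.tsv}) and \code{<stem>_manifest.json} describing
#' scheme, spans, classes and window counts.
#'
#' @param netset a \code{network_set}.
#' @param stem output path stem.
#' @return the manifest path, invisibly.
#' @export
write_network_set <- function(netset, stem) {
  stopifnot(inherits(netset, "network_set"))
  files <- character(length(netset$windows))
  for (i in seq_along(netset$windows)) {
    files[i] <- sprintf("%s_w%04d.tsv", stem, i)
    adj <- netset$windows[[i]]$adjacency
    dimnames(adj) <- list(netset$channels, netset$channels)
    write.table(adj, files[i], sep = "\t", quote = FALSE)
  }
  manifest <- list(
    scheme = netset$scheme,
    channels = netset$channels,
    v = as.list(netset$v),
    n_skipped = netset$n_skipped,
    windows = lapply(seq_along(netset$windows), function(i) {
      w <- netset$windows[[i]]
      list(file = basename(files[i]), start = w$start, end = w$end,
           class = if (is.na(w$class)) NULL else netset$class_names[w$class],
           n_samples = w$n_samples)
    }))
  mpath <- paste0(stem, "_manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}

#' Export a classification report
#'
#' Writes \code{<stem>_report.json} (summary and config),
#' \code{<stem>_trials.tsv} (per-trial metrics) and \code{<stem>_roc.tsv}
#' (averaged ROC points).
#'
#' @param report a \code{classification_report}.
#' @param stem output path stem.
#' @return the JSON path, invisibly.
#' @export
write_classification_report <- function(report, stem) {
  stopifnot(inherits(report, "classification_report"))
  jsonlite::write_json(list(summary = report$summary, config = report$config),
                       paste0(stem, "_report.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  write.table(report$trials, paste0(stem, "_trials.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(report$roc, paste0(stem, "_roc.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(paste0(stem, "_report.json"))
}
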