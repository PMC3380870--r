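# Text-format readers and writers: log-odds matrices, signals graphs,
# attachments, chain traces and key-value run configurations.

#' Read / write a log-odds matrix as tab-separated text
#'
#' Layout: first row holds the signal labels, first column the effect
#' labels, cells the decimal log-odds values.
#'
#' @param path file path.
#' @return \code{read_logodds}: a validated log-odds matrix.
#' @export
read_logodds <- function(path) {
  x <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
  log_odds(as.matrix(x))
}

#' @rdname read_logodds
#' @param r log-odds matrix.
#' @export
write_logodds <- function(r, path) {
  utils::write.table(r, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Write a signals graph
#'
#' Three formats: \code{"adjacency"} (tab-separated matrix with labels),
#' \code{"edges"} (two-column source/target list of off-diagonal edges) and
#' \code{"dot"} (Graphviz DOT for visualization).
#'
#' @param g signals graph.
#' @param path file path.
#' @param format output format.
#' @export
write_signals_graph <- function(g, path,
                                format = c("adjacency", "edges", "dot")) {
  format <- match.arg(format)
  check_signals_graph(g)
  labs <- rownames(g)
  if (format == "adjacency") {
    utils::write.table(g, path, sep = "\t", quote = FALSE, col.names = NA)
  } else {
    idx <- which(g == 1 & row(g) != col(g), arr.ind = TRUE)
    if (format == "edges") {
      utils::write.table(data.frame(source = labs[idx[, 1]],
                                    target = labs[idx[, 2]]),
                         path, sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      lines <- c("digraph signals {",
                 paste0("  \"", labs, "\";"),
                 if (nrow(idx)) paste0("  \"", labs[idx[, 1]], "\" -> \"",
                                       labs[idx[, 2]], "\";"),
                 "}")
      writeLines(lines, path)
    }
  }
  invisible(path)
}

#' Read a signals graph from a tab-separated adjacency file
#'
#' @param path file path (layout as written by
#'   \code{\link{write_signals_graph}} with \code{format = "adjacency"}).
#' @return a validated signals graph.
#' @export
read_signals_graph <- function(path) {
  x <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
  signals_graph(as.matrix(x))
}

#' Write / read an effects attachment
#'
#' Two-column tab-separated text: the first column is the signal (the null
#' node is written as \code{\link{null_label}()}), the second the attached
#' effect gene.
#'
#' @param a effects attachment.
#' @param path file path.
#' @param include_null also write effects attached to the null node.
#' @export
write_attachment <- function(a, path, include_null = TRUE) {
  labs <- attr(a, "signal_labels")
  tgt <- unclass(a)
  sig <- ifelse(is.na(tgt), null_label(), labs[tgt])
  d <- data.frame(signal = sig, effect = names(a))
  if (!include_null) d <- d[d$signal != null_label(), ]
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_attachment
#' @param signal_labels signal labels of the model the attachment refers
#'   to (needed to map labels back to indices).
#' @export
read_attachment <- function(path, signal_labels) {
  d <- utils::read.delim(path, header = FALSE,
                         col.names = c("signal", "effect"))
  tgt <- as.character(d$signal)
  tgt[tgt == null_label()] <- NA_character_
  effects_attachment(tgt, signal_labels = signal_labels,
                     effect_labels = as.character(d$effect))
}

#' Persist a chain trace
#'
#' Tab-separated file with one row per recorded sample: the step index, the
#' score, and the flattened (column-major) adjacency bits of the mapped
#' graph.
#'
#' @param trace a \code{"nem_chain"} object.
#' @param path file path.
#' @export
write_trace <- function(trace, path) {
  bits <- t(vapply(trace$graphs, function(g) as.integer(g),
                   integer(length(trace$graphs[[1]]))))
  d <- data.frame(step = trace$steps, score = trace$scores, bits)
  labs <- rownames(trace$graphs[[1]])
  names(d)[-(1:2)] <- paste0(rep(labs, each = length(labs)), ".",
                             rep(labs, length(labs)))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a key-value run configuration
#'
#' Plain-text configuration: one \code{key = value} pair per line, \code{#}
#' comments allowed.  Values are coerced to numeric where possible.  Keys
#' mirror the arguments of \code{\link{mc_eminem_config}} plus \code{seed}.
#'
#' @param path file path.
#' @return named list of settings.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) .stop_input("malformed config line(s): ",
                            paste(lines[bad], collapse = "; "))
  vals <- lapply(kv, function(p) {
    v <- utils::type.convert(p[2], as.is = TRUE)
    v
  })
  stats::setNames(vals, vapply(kv, `[`, "", 1L))
}

#' @rdname read_config
#' @param config named list (e.g. from \code{\link{mc_eminem_config}}).
#' @export
write_config <- function(config, path) {
  writeLines(paste(names(config), unlist(config), sep = " = "), path)
  invisible(path)
}
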