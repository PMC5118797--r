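## Tabular and graph text output. Tables round-trip numeric values at full
## double precision (%.17g); graphs are written as a sectioned TSV
## (nodes, then edges) and as JSON.

#' Write a table as TSV with a header row
#'
#' Numeric columns are serialized with 17 significant digits so a
#' write/read round trip reproduces the stored doubles exactly.
#'
#' @param records data.frame, non-empty.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_table <- function(records, path) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(records) == 0L) stopf("refusing to write an empty table")
  out <- records
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stopf("cannot write table to '%s'", path)
  invisible(path)
}

#' Read a TSV written by \code{write_table}
#' @param path file path.
#' @return data.frame.
#' @export
read_table <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write an interaction network as a sectioned TSV or JSON
#'
#' TSV layout: a \code{# nodes} section (one label per line) followed by a
#' \code{# edges} section (\code{i<TAB>j<TAB>weight}); an edgeless network
#' writes the node list and an empty edge section.
#'
#' @param network an \code{interaction_network}
#'   (see \code{\link{build_network}}).
#' @param path output file.
#' @param format \code{"tsv"} or \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
write_graph_file <- function(network, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  nodes <- network$nodes
  edges <- network$edges
  if (format == "json") {
    jsonlite::write_json(
      list(nodes = nodes,
           edges = if (nrow(edges)) edges else data.frame(),
           i_min = network$i_min),
      path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
    return(invisible(path))
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# nodes", con)
  writeLines(as.character(nodes), con)
  writeLines("# edges", con)
  if (nrow(edges))
    writeLines(sprintf("%s\t%s\t%.17g", edges$i, edges$j, edges$strength), con)
  invisible(path)
}

#' Read a sectioned TSV graph written by \code{write_graph_file}
#' @param path file path.
#' @return list with \code{nodes} (character) and \code{edges} (data.frame
#'   \code{i}, \code{j}, \code{strength}).
#' @export
read_graph_file <- function(path) {
  lines <- readLines(path)
  ni <- which(lines == "# nodes")
  ei <- which(lines == "# edges")
  if (length(ni) != 1L || length(ei) != 1L) stopf("not a graph file: %s", path)
  nodes <- lines[seq.int(ni + 1L, ei - 1L)]
  nodes <- nodes[nzchar(nodes)]
  edge_lines <- if (ei < length(lines)) lines[seq.int(ei + 1L, length(lines))]
                else character()
  edge_lines <- edge_lines[nzchar(edge_lines)]
  if (length(edge_lines)) {
    parts <- do.call(rbind, strsplit(edge_lines, "\t", fixed = TRUE))
    edges <- data.frame(i = parts[, 1], j = parts[, 2],
                        strength = as.numeric(parts[, 3]),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(i = character(), j = character(),
                        strength = numeric(), stringsAsFactors = FALSE)
  }
  list(nodes = nodes, edges = edges)
}
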