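#' Interaction network container
#'
#' A bait--prey interaction network with per-edge score annotations. Edges are
#' directed bait -> prey as scored, but pairs are canonicalized so that an
#' interaction observed from both bait directions appears once.
#'
#' @param edges data.frame with at least columns `bait` and `prey`; any
#'   additional columns (wdn, enrichment, rescued, module, relative
#'   abundance, ...) are carried as edge attributes.
#' @param allow_empty accept an empty edge set (with a warning).
#' @return object of class `interaction_network`.
#' @export
interaction_network <- function(edges, allow_empty = TRUE) {
  edges <- as.data.frame(edges)
  if (!all(c("bait", "prey") %in% names(edges))) {
    stop("edges must have columns 'bait' and 'prey'")
  }
  if (nrow(edges) == 0L && !allow_empty) stop("empty interaction network")
  if (nrow(edges) == 0L) warning("empty interaction network")
  if (anyDuplicated(edge_key(edges$bait, edges$prey))) {
    stop("duplicate (bait, prey) pair after canonicalization")
  }
  rownames(edges) <- NULL
  structure(list(edges = edges), class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  nodes <- unique(c(x$edges$bait, x$edges$prey))
  cat("interaction_network:", nrow(x$edges), "interactions,",
      length(nodes), "proteins\n")
  invisible(x)
}

#' Proteins of an interaction network
#'
#' @param network an `interaction_network`.
#' @return character vector of node identifiers.
#' @export
network_nodes <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  unique(c(network$edges$bait, network$edges$prey))
}

#' Write an interaction network to disk
#'
#' Supported formats: `edge-table` (tab-delimited with header, one row per
#' edge, all attributes), `sif` (Cytoscape simple interaction format,
#' `bait pp prey`), `graphml` (all edge attributes, via igraph).
#'
#' @param network an `interaction_network`.
#' @param path output file.
#' @param format one of `"edge-table"`, `"sif"`, `"graphml"`.
#' @return invisibly, `path`.
#' @export
write_network <- function(network, path,
                          format = c("edge-table", "sif", "graphml")) {
  stopifnot(inherits(network, "interaction_network"))
  if (length(format) == 1L &&
      !format %in% c("edge-table", "sif", "graphml")) {
    stop("unknown network format: ", format)
  }
  format <- match.arg(format)
  edges <- network$edges
  if (format == "edge-table") {
    write_tsv(edges, path)
  } else if (format == "sif") {
    lines <- paste(edges$bait, "pp", edges$prey, sep = "\t")
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n")
  } else {
    g <- igraph::graph_from_data_frame(
      cbind(data.frame(from = edges$bait, to = edges$prey),
            edges[, setdiff(names(edges), c("bait", "prey")), drop = FALSE]),
      directed = FALSE
    )
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a network edge table written by [write_network()]
#'
#' @param path path to an edge-table file.
#' @return an `interaction_network`.
#' @export
read_network <- function(path) {
  interaction_network(read_delim_auto(path))
}
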