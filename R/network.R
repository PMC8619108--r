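#' Build a weighted social contact network
#'
#' Aggregates the contact table into an undirected weighted graph: nodes are
#' animal ids (isolated animals are retained so the full group is always
#' shown), edge weight is the contact frequency between the pair, counted
#' either in per-frame contact rows (\code{unit = "frames"}, default) or in
#' merged episodes (\code{unit = "episodes"}). Filtering by contact type can
#' only decrease edge weights; head-head and head-tail weights partition the
#' all-type weight.
#'
#' @param table A \code{\link{build_contact_table}} result.
#' @param type_filter \code{"all"}, \code{"head-head"} or \code{"head-tail"}.
#' @param unit \code{"frames"} or \code{"episodes"}.
#' @param ids Node set; defaults to the table's tracked ids.
#' @param gap_tolerance Episode gap tolerance when \code{unit = "episodes"}.
#' @return An object of class \code{social_network}: list with the
#'   \code{igraph} graph, \code{type_filter} and \code{unit}.
#' @export
build_social_network <- function(table,
                                 type_filter = c("all", "head-head", "head-tail"),
                                 unit = c("frames", "episodes"),
                                 ids = NULL, gap_tolerance = NULL) {
  type_filter <- match.arg(type_filter)
  unit <- match.arg(unit)
  ids <- ids %||% attr(table, "ids")
  if (is.null(ids)) ids <- sort(unique(c(table$id_a, table$id_b)))
  ev <- as.data.frame(table)
  if (type_filter != "all") ev <- ev[ev$type == type_filter, , drop = FALSE]
  if (unit == "episodes") {
    attr(ev, "gap_tolerance") <- attr(table, "gap_tolerance")
    units <- contact_episodes(ev, gap_tolerance)
  } else {
    units <- ev
  }
  if (nrow(units)) {
    agg <- stats::aggregate(list(weight = rep(1L, nrow(units))),
                            by = list(id_a = units$id_a, id_b = units$id_b),
                            FUN = sum)
  } else {
    agg <- data.frame(id_a = integer(0), id_b = integer(0), weight = integer(0))
  }
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(agg$id_a), to = as.character(agg$id_b),
                   weight = as.integer(agg$weight)),
    directed = FALSE,
    vertices = data.frame(name = as.character(ids)))
  structure(list(graph = g, type_filter = type_filter, unit = unit),
            class = "social_network")
}

#' Edge list of a social network
#'
#' @param net A \code{social_network}.
#' @return Data frame \code{from}, \code{to}, \code{weight} (integer).
#' @export
network_edges <- function(net) {
  e <- igraph::as_data_frame(net$graph, what = "edges")
  if (nrow(e) == 0) {
    return(data.frame(from = integer(0), to = integer(0), weight = integer(0)))
  }
  data.frame(from = as.integer(e$from), to = as.integer(e$to),
             weight = as.integer(e$weight))
}

#' Export / import a social network
#'
#' \code{"csv"} writes an edge-list CSV (\code{from,to,weight}) plus the
#' node set in a \code{# nodes:} header comment; \code{"graphml"} writes
#' GraphML with \code{weight} edge attributes and \code{type_filter} /
#' \code{unit} graph attributes. Both round-trip through
#' \code{import_network}.
#'
#' @param net A \code{social_network}.
#' @param path Output file path.
#' @param format \code{"csv"} or \code{"graphml"}.
#' @return \code{export_network} returns \code{path} invisibly;
#'   \code{import_network} returns a \code{social_network}.
#' @export
export_network <- function(net, path, format = c("csv", "graphml")) {
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_pigtrackr("directory does not exist: ", dir)
  if (format == "csv") {
    nodes <- igraph::V(net$graph)$name
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(paste0("# nodes: ", paste(nodes, collapse = " ")),
                 paste0("# type_filter: ", net$type_filter),
                 paste0("# unit: ", net$unit)), con)
    utils::write.csv(network_edges(net), con, row.names = FALSE)
  } else {
    g <- net$graph
    g <- igraph::set_graph_attr(g, "type_filter", net$type_filter)
    g <- igraph::set_graph_attr(g, "unit", net$unit)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname export_network
#' @export
import_network <- function(path, format = c("csv", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_pigtrackr("no such file: ", path)
  if (format == "csv") {
    hdr <- readLines(path, n = 3)
    nodes <- strsplit(sub("^# nodes: ?", "", hdr[1]), " ")[[1]]
    nodes <- nodes[nzchar(nodes)]
    type_filter <- sub("^# type_filter: ", "", hdr[2])
    unit <- sub("^# unit: ", "", hdr[3])
    e <- utils::read.csv(path, comment.char = "#")
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(e$from), to = as.character(e$to),
                 weight = as.integer(e$weight)),
      directed = FALSE, vertices = data.frame(name = nodes))
    structure(list(graph = g, type_filter = type_filter, unit = unit),
              class = "social_network")
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    igraph::E(g)$weight <- as.integer(round(igraph::E(g)$weight))
    structure(list(graph = igraph::as_undirected(g, mode = "each"),
                   type_filter = igraph::graph_attr(g, "type_filter") %||% "all",
                   unit = igraph::graph_attr(g, "unit") %||% "frames"),
              class = "social_network")
  }
}

#' @export
print.social_network <- function(x, ...) {
  cat("Social network (", x$type_filter, ", unit = ", x$unit, "): ",
      igraph::vcount(x$graph), " animals, ", igraph::ecount(x$graph),
      " edges\n", sep = "")
  e <- network_edges(x)
  if (nrow(e)) print(e)
  invisible(x)
}

#' Plot a social network
#'
#' Nodes are labelled by animal id; edge thickness is proportional to the
#' contact frequency. The layout is seeded, hence reproducible.
#'
#' @param x A \code{social_network}.
#' @param seed Layout seed (default 1).
#' @param file Optional output file; \code{.pdf} renders to PDF, otherwise
#'   PNG.
#' @param ... Passed to \code{igraph::plot.igraph}.
#' @return The layout matrix, invisibly.
#' @export
plot.social_network <- function(x, seed = 1, file = NULL, ...) {
  lay <- with_seed(seed, igraph::layout_with_fr(x$graph))
  w <- igraph::E(x$graph)$weight
  render <- function() {
    igraph::plot.igraph(
      x$graph, layout = lay,
      edge.width = if (length(w)) 1 + 4 * w / max(w) else 1,
      vertex.color = "lightsteelblue", vertex.label.color = "black",
      main = paste0("Social contacts (", x$type_filter, ")"), ...)
  }
  if (!is.null(file)) {
    if (grepl("\\.pdf$", file)) pdf(file) else grDevices::png(file)
    on.exit(dev.off())
    render()
  } else {
    render()
  }
  invisible(lay)
}
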