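#' Convert between collaboration networks and igraph graphs
#'
#' Vertex attributes carry the discipline, ring and the two flags (stored
#' numerically for portable GraphML round-trips); the tie value is stored as
#' the edge attribute `value`.  District and timepoint become graph
#' attributes.
#'
#' @param network a [collab_network()].
#' @return `as_igraph()` returns an igraph graph; `from_igraph()` a
#'   [collab_network()].
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "collab_network"))
  a <- network$actors
  vdf <- data.frame(
    name = a$actor_id,
    discipline = ifelse(is.na(a$discipline), "", a$discipline),
    ring = as.numeric(a$ring),
    program = as.numeric(a$is_program_participant %in% TRUE),
    responded = as.numeric(a$responded %in% TRUE),
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(network$ties, directed = TRUE,
                                     vertices = vdf)
  igraph::graph_attr(g, "district") <-
    ifelse(is.na(network$district), "", network$district)
  igraph::graph_attr(g, "timepoint") <-
    ifelse(is.na(network$timepoint), "", network$timepoint)
  g
}

#' @rdname as_igraph
#' @param g an igraph graph.
#' @export
from_igraph <- function(g) {
  stopifnot(igraph::is_igraph(g))
  vdf <- igraph::as_data_frame(g, what = "vertices")
  edf <- igraph::as_data_frame(g, what = "edges")
  ids <- if ("name" %in% names(vdf)) {
    as.character(vdf$name)
  } else {
    as.character(seq_len(igraph::vcount(g)))
  }
  ring <- if ("ring" %in% names(vdf)) {
    r <- suppressWarnings(as.numeric(vdf$ring))
    as.integer(ifelse(is.finite(r), round(r), NA))
  } else {
    rep(NA_integer_, length(ids))
  }
  disc <- if ("discipline" %in% names(vdf)) {
    ifelse(nzchar(vdf$discipline), as.character(vdf$discipline),
           NA_character_)
  } else {
    rep(NA_character_, length(ids))
  }
  actors <- data.frame(actor_id = ids, discipline = disc, ring = ring,
                       stringsAsFactors = FALSE)
  if ("program" %in% names(vdf)) {
    actors$is_program_participant <- as.numeric(vdf$program) == 1
  }
  if ("responded" %in% names(vdf)) {
    actors$responded <- as.numeric(vdf$responded) == 1
  }
  value <- if ("value" %in% names(edf)) {
    v <- as.numeric(edf$value)
    ifelse(is.finite(v), v, NA_real_)
  } else if ("weight" %in% names(edf)) {
    v <- as.numeric(edf$weight)
    ifelse(is.finite(v) & v != 0, v, NA_real_)
  } else {
    rep(NA_real_, nrow(edf))
  }
  ties <- data.frame(source = as.character(edf$from),
                     target = as.character(edf$to),
                     value = value, stringsAsFactors = FALSE)
  gattr <- function(nm) {
    x <- tryCatch(igraph::graph_attr(g, nm), error = function(e) NULL)
    if (is.null(x) || !nzchar(x)) NA_character_ else as.character(x)
  }
  collab_network(actors, ties, district = gattr("district"),
                 timepoint = gattr("timepoint"))
}

#' Read and write networks in standard file formats
#'
#' GraphML is the canonical, attribute-rich interchange format and
#' round-trips actors, arcs, values and the ring/discipline attributes
#' exactly.  Pajek NET preserves actor names, arc direction and values
#' (unrated ties are stored as weight 0, outside the 1-10 rating range);
#' delimited edge lists preserve arcs and values only.  Both lossy formats
#' are read back with unknown ring and discipline.
#'
#' @param network a [collab_network()].
#' @param path file path.
#' @param format one of `"graphml"`, `"pajek"`, `"edgelist"`.
#' @return `read_network()` returns a [collab_network()];
#'   `write_network()` returns the path invisibly.
#' @export
write_network <- function(network, path,
                          format = c("graphml", "pajek", "edgelist")) {
  format <- match.arg(format)
  stopifnot(inherits(network, "collab_network"))
  if (format == "graphml") {
    igraph::write_graph(as_igraph(network), path, format = "graphml")
  } else if (format == "pajek") {
    g <- as_igraph(network)
    igraph::E(g)$weight <- ifelse(is.na(network$ties$value), 0,
                                  network$ties$value)
    igraph::V(g)$id <- igraph::V(g)$name
    igraph::write_graph(g, path, format = "pajek")
  } else {
    utils::write.table(network$ties, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path,
                         format = c("graphml", "pajek", "edgelist")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "graphml") {
    g <- tryCatch(
      igraph::read_graph(path, format = "graphml"),
      error = function(e) stop("malformed GraphML file '", path, "': ",
                               conditionMessage(e), call. = FALSE))
    from_igraph(g)
  } else if (format == "pajek") {
    g <- tryCatch(
      igraph::read_graph(path, format = "pajek"),
      error = function(e) stop("malformed Pajek file '", path, "': ",
                               conditionMessage(e), call. = FALSE))
    if (is.null(igraph::V(g)$name) && !is.null(igraph::V(g)$id)) {
      igraph::V(g)$name <- igraph::V(g)$id
    }
    from_igraph(g)
  } else {
    df <- tryCatch(read_tie_list_bare(path),
                   error = function(e) stop("malformed edge list '", path,
                                            "': ", conditionMessage(e),
                                            call. = FALSE))
    ids <- unique(c(df$source, df$target))
    actors <- data.frame(actor_id = ids, discipline = NA_character_,
                         ring = NA_integer_, stringsAsFactors = FALSE)
    actors$is_program_participant <- NA
    actors$responded <- TRUE
    collab_network(actors, df)
  }
}

# edge list without the timepoint column: source, target, value
read_tie_list_bare <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("source", "target"), names(df))
  if (length(miss)) {
    stop("missing column(s) ", paste(miss, collapse = ", "))
  }
  df$source <- as.character(df$source)
  df$target <- as.character(df$target)
  if (!"value" %in% names(df)) df$value <- NA_real_
  df$value <- as.numeric(df$value)
  df[c("source", "target", "value")]
}
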