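.ring_colors <- c(`1` = "gold", `2` = "palegreen3", `3` = "steelblue1")

#' Render a sociogram of a collaboration network
#'
#' Draws actors as colored squares (ring 1 yellow, ring 2 green, ring 3
#' blue), sized linearly by out-degree — actors with missing out-degree
#' (non-responders) are drawn at the minimum size.  Edges are black in
#' `edge_mode = "plain"`; in `edge_mode = "reciprocity"` reciprocal contacts
#' are blue and one-sided contacts red.  The seeded force-directed layout is
#' deterministic for a fixed seed.
#'
#' @param network a non-empty [collab_network()].
#' @param file optional PNG output path; when `NULL`, plots on the current
#'   device.
#' @param edge_mode `"plain"` or `"reciprocity"`.
#' @param layout_seed integer seed for the force-directed layout.
#' @param min_size,size_per_contact node size at out-degree 0/NA and the
#'   linear increment per reported contact.
#' @return Invisibly, a list with the layout coordinates, node sizes and
#'   colors, and edge colors.
#' @export
render_sociogram <- function(network, file = NULL,
                             edge_mode = c("plain", "reciprocity"),
                             layout_seed = 1L, min_size = 5,
                             size_per_contact = 1.5) {
  edge_mode <- match.arg(edge_mode)
  stopifnot(inherits(network, "collab_network"))
  if (nrow(network$actors) == 0L) stop("empty network")

  od <- out_degrees(network)
  sizes <- min_size + size_per_contact * ifelse(is.na(od), 0, od)
  ring <- as.character(network$actors$ring)
  vcol <- unname(ifelse(ring %in% names(.ring_colors),
                        .ring_colors[ring], "grey70"))

  if (nrow(network$ties)) {
    key <- paste(network$ties$source, network$ties$target, sep = "\r")
    rkey <- paste(network$ties$target, network$ties$source, sep = "\r")
    mutual <- key %in% rkey
    ecol <- if (edge_mode == "reciprocity") {
      ifelse(mutual, "blue", "red")
    } else {
      rep("black", nrow(network$ties))
    }
  } else {
    ecol <- character()
  }

  g <- as_igraph(network)
  lay <- withr::with_seed(layout_seed, igraph::layout_with_fr(g))

  draw <- function() {
    igraph::plot.igraph(
      g, layout = lay, vertex.shape = "square", vertex.size = sizes,
      vertex.color = vcol, vertex.label.cex = 0.6,
      vertex.label.color = "black", edge.color = ecol,
      edge.arrow.size = 0.3,
      main = paste(stats::na.omit(c(network$district, network$timepoint)),
                   collapse = " ")
    )
    present <- sort(unique(network$actors$ring))
    present <- present[!is.na(present)]
    if (length(present)) {
      graphics::legend(
        "topleft", bty = "n", pch = 15, pt.cex = 1.5,
        col = .ring_colors[as.character(present)],
        legend = sprintf("ring %d", present))
    }
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 900, res = 120)
    on.exit(grDevices::dev.off(), add = TRUE)
    draw()
  } else {
    draw()
  }
  invisible(list(layout = lay, sizes = sizes, vertex_colors = vcol,
                 edge_colors = ecol))
}
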