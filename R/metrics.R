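# Metric cores operate on integer edge indices so the same code path serves
# the exported functions and exhaustive small-graph checks.

# dyad census of a simple directed graph given integer endpoints in 1..n
.dyad_census_core <- function(src, dst, n) {
  n_arcs <- length(src)
  key <- (src - 1L) * n + dst
  rkey <- (dst - 1L) * n + src
  mutual_arcs <- sum(key %in% rkey)
  mut <- mutual_arcs %/% 2L
  asym <- n_arcs - mutual_arcs
  c(mutual = mut, asymmetric = asym,
    null = n * (n - 1L) %/% 2L - mut - asym)
}

.edge_index <- function(network) {
  ids <- network$actors$actor_id
  list(src = match(network$ties$source, ids),
       dst = match(network$ties$target, ids),
       n = length(ids), ids = ids)
}

.maybe_subset <- function(network, rings) {
  if (is.null(rings)) network else induce_subset(network, rings)
}

#' Out-degree of every actor (number of reported contacts)
#'
#' The number of professionals an actor named as collaboration contacts.
#' For actors who did not respond at this timepoint the out-degree is not
#' zero but *missing*: their outgoing nominations were never observed.
#'
#' @param network a [collab_network()].
#' @return Named integer vector with `NA` for non-responders.
#' @export
out_degrees <- function(network) {
  stopifnot(inherits(network, "collab_network"))
  ids <- network$actors$actor_id
  od <- tabulate(match(network$ties$source, ids), nbins = length(ids))
  od[!network$actors$responded %in% TRUE] <- NA_integer_
  stats::setNames(as.integer(od), ids)
}

#' @rdname out_degrees
#' @param actor a single actor identifier.
#' @export
out_degree <- function(network, actor) {
  od <- out_degrees(network)
  if (!actor %in% names(od)) stop("unknown actor: ", actor)
  od[[actor]]
}

#' Average out-degree over a ring subset
#'
#' Mean number of reported contacts per professional, computed over the
#' actors in the subset whose out-degree is observed (responders); actors
#' with missing outgoing ties enter neither numerator nor denominator.
#'
#' @param network a [collab_network()].
#' @param rings ring subset defining the induced subgraph (default all).
#' @return Mean out-degree.
#' @export
average_degree <- function(network, rings = c(1, 2, 3)) {
  sub <- induce_subset(network, rings)
  d <- out_degrees(sub)
  d <- d[!is.na(d)]
  if (!length(d)) stop("no actor with a defined out-degree in subset")
  mean(d)
}

#' Network density
#'
#' Proportion of existing directed relationships out of the `n * (n - 1)`
#' possible ones; 0 means no relations, 1 a fully connected network.  When
#' the subset includes ring 3, non-responders still count in the denominator
#' although their out-ties are structurally missing, which biases density
#' downward (this matches how both reporting subsets are tabulated).
#'
#' @param network a [collab_network()].
#' @param rings optional ring subset (`NULL` = whole network).
#' @return Density in \[0, 1\].
#' @export
net_density <- function(network, rings = NULL) {
  sub <- .maybe_subset(network, rings)
  n <- nrow(sub$actors)
  if (n < 2L) stop("density needs at least 2 actors")
  nrow(sub$ties) / (n * (n - 1L))
}

#' Dyad census
#'
#' Counts of mutual, asymmetric and null dyads (unordered actor pairs).
#'
#' @param network a [collab_network()].
#' @param rings optional ring subset.
#' @return Named integer vector `c(mutual, asymmetric, null)`.
#' @export
dyad_census <- function(network, rings = NULL) {
  sub <- .maybe_subset(network, rings)
  e <- .edge_index(sub)
  .dyad_census_core(e$src, e$dst, e$n)
}

#' Reciprocity of contacts
#'
#' Default (`method = "dyad"`): the ratio of mutually connected pairs to all
#' connected pairs — the proportion of potential reciprocal relationships
#' that are actually reciprocal.  `method = "arc"` gives the alternative
#' arc-based ratio, the probability that the reverse of an observed arc also
#' exists.
#'
#' @param network a [collab_network()].
#' @param rings optional ring subset.
#' @param method `"dyad"` (default) or `"arc"`.
#' @return Reciprocity in \[0, 1\].
#' @export
reciprocity <- function(network, rings = NULL, method = c("dyad", "arc")) {
  method <- match.arg(method)
  sub <- .maybe_subset(network, rings)
  e <- .edge_index(sub)
  dc <- .dyad_census_core(e$src, e$dst, e$n)
  if (dc[["mutual"]] + dc[["asymmetric"]] == 0L) {
    stop("no connected dyads in subset")
  }
  if (method == "dyad") {
    dc[["mutual"]] / (dc[["mutual"]] + dc[["asymmetric"]])
  } else {
    2 * dc[["mutual"]] / (2 * dc[["mutual"]] + dc[["asymmetric"]])
  }
}

#' E-I index decomposition for one ring
#'
#' Splits the contacts involving a group into internal ones (both endpoints
#' in the group) and external ones, and forms the E-I index
#' `(E - I) / (E + I)`: -1 when all contacts are internal to the group, +1
#' when all are external.  With the default `mode = "boundary"` an external
#' contact is any arc crossing the group boundary in either direction, so
#' two complementary groups share one external count; `mode = "source"`
#' counts only arcs sent by group members.
#'
#' @param network a [collab_network()].
#' @param group ring label (1, 2 or 3) of the group of interest.
#' @param rings optional ring subset to restrict the network first.
#' @param mode `"boundary"` (default) or `"source"`.
#' @return Object of class `ei_decomposition` with internal/external contact
#'   counts, per-capita internal/external average degree, and `ei_index`
#'   (`NA` when the group has no contacts at all).
#' @export
ei_decomposition <- function(network, group, rings = NULL,
                             mode = c("boundary", "source")) {
  mode <- match.arg(mode)
  if (length(group) != 1L || !group %in% 1:3) {
    stop("unknown group label: ", paste(group, collapse = ", "))
  }
  sub <- .maybe_subset(network, rings)
  in_g <- sub$actors$ring == as.integer(group)
  n_group <- sum(in_g)
  if (n_group == 0L) stop("no actors in group ", group)
  gids <- sub$actors$actor_id[in_g]
  sg <- sub$ties$source %in% gids
  tg <- sub$ties$target %in% gids
  internal <- sum(sg & tg)
  external <- if (mode == "boundary") sum(xor(sg, tg)) else sum(sg & !tg)
  ei <- if (internal + external > 0) {
    (external - internal) / (external + internal)
  } else {
    NA_real_
  }
  structure(list(group = as.integer(group), mode = mode, n_group = n_group,
                 internal_contacts = internal, external_contacts = external,
                 internal_avg_degree = internal / n_group,
                 external_avg_degree = external / n_group,
                 ei_index = ei),
            class = "ei_decomposition")
}

#' @export
print.ei_decomposition <- function(x, ...) {
  cat(sprintf(
    "<ei_decomposition> ring %d (n=%d, %s): internal %d, external %d, E-I %s\n",
    x$group, x$n_group, x$mode, x$internal_contacts, x$external_contacts,
    ifelse(is.na(x$ei_index), "NA", sprintf("%.3f", x$ei_index))))
  invisible(x)
}

#' Discipline-diversity index of one actor
#'
#' Heterogeneity of an actor's collaboration contacts across disciplines,
#' based on incoming nominations (being chosen by others is more reliable
#' than self-reported out-ties).  With `R_i` the actor's in-degree, `R_divi`
#' the in-ties received from *other* disciplines, `D_i` the number of
#' disciplines present in the network minus the actor's own, and `D_divi`
#' the distinct other disciplines among the in-ties:
#' `P_iR = R_divi / R_i`, `D_iD = D_divi / D_i`, and the diversity score is
#' `H_i = P_iR * D_iD` in \[0, 1\] (0 fully homogeneous, 1 maximally
#' heterogeneous).  Actors with no in-ties get a missing score; a network
#' with a single discipline has no defined diversity.  In-ties from actors
#' of unknown discipline count in `R_i` but not in `R_divi`/`D_divi`.
#'
#' @param network a [collab_network()].
#' @param actor a single actor identifier.
#' @param rings optional ring subset to restrict the network first.
#' @return Object of class `diversity_components` housing `r_i`, `r_div_i`,
#'   `d_i`, `d_div_i`, `p_ir`, `d_id` and `h_i`.
#' @export
diversity_index <- function(network, actor, rings = NULL) {
  sub <- .maybe_subset(network, rings)
  ids <- sub$actors$actor_id
  if (!actor %in% ids) stop("unknown actor: ", actor)
  disc <- sub$actors$discipline
  own <- disc[match(actor, ids)]
  n_disc <- length(unique(disc[!is.na(disc)]))
  if (n_disc < 2L) stop("diversity undefined: fewer than 2 disciplines in the network")
  d_i <- n_disc - 1L

  src <- sub$ties$source[sub$ties$target == actor]
  r_i <- length(src)
  src_disc <- disc[match(src, ids)]
  other <- !is.na(src_disc) & src_disc != own
  r_div <- sum(other)
  d_div <- length(unique(src_disc[other]))

  if (r_i == 0L) {
    p_ir <- d_id <- h_i <- NA_real_
  } else {
    p_ir <- r_div / r_i
    d_id <- d_div / d_i
    h_i <- p_ir * d_id
  }
  structure(list(actor = actor, r_i = r_i, r_div_i = r_div,
                 d_i = d_i, d_div_i = d_div,
                 p_ir = p_ir, d_id = d_id, h_i = h_i),
            class = "diversity_components")
}

#' @export
print.diversity_components <- function(x, ...) {
  cat(sprintf(
    "<diversity> '%s': R_i=%d, R_divi=%d, D_i=%d, D_divi=%d, P_iR=%s, D_iD=%s, H_i=%s\n",
    x$actor, x$r_i, x$r_div_i, x$d_i, x$d_div_i,
    ifelse(is.na(x$p_ir), "NA", sprintf("%.3f", x$p_ir)),
    ifelse(is.na(x$d_id), "NA", sprintf("%.3f", x$d_id)),
    ifelse(is.na(x$h_i), "NA", sprintf("%.3f", x$h_i))))
  invisible(x)
}

#' Mean and SD of the diversity index over a ring subset
#'
#' Sample mean and sample standard deviation (n - 1 denominator) of `H_i`
#' over the actors of the induced subset with a defined score (in-degree at
#' least 1).
#'
#' @param network a [collab_network()].
#' @param rings ring subset (default rings 1 and 2, the responder subset the
#'   diversity row is reported for).
#' @return List with `mean`, `sd` and `n` (number of defined scores).
#' @export
mean_diversity <- function(network, rings = c(1, 2)) {
  sub <- induce_subset(network, rings)
  h <- vapply(sub$actors$actor_id,
              function(a) diversity_index(sub, a)$h_i, numeric(1))
  h <- h[!is.na(h)]
  if (length(h) < 2L) {
    stop("fewer than 2 actors with a defined diversity score")
  }
  list(mean = mean(h), sd = stats::sd(h), n = length(h))
}

#' Mean value an actor places on their contacts
#'
#' Arithmetic mean of the 1-10 ratings the actor gave to their nominated
#' contacts; unrated ties are skipped and actors with no rated out-ties
#' (including non-responders) get a missing value.
#'
#' @param network a [collab_network()].
#' @param actor a single actor identifier.
#' @return Mean rating in \[1, 10\], or `NA`.
#' @export
mean_tie_value <- function(network, actor) {
  stopifnot(inherits(network, "collab_network"))
  if (!actor %in% network$actors$actor_id) stop("unknown actor: ", actor)
  v <- network$ties$value[network$ties$source == actor]
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  mean(v)
}

#' Mean and SD of per-actor contact values over a ring subset
#'
#' @param network a [collab_network()].
#' @param rings ring subset (default rings 1 and 2).
#' @return List with `mean`, `sd` and `n` over actors with a defined mean
#'   contact value.
#' @export
tie_value_summary <- function(network, rings = c(1, 2)) {
  sub <- induce_subset(network, rings)
  v <- vapply(sub$actors$actor_id,
              function(a) mean_tie_value(sub, a), numeric(1))
  v <- v[!is.na(v)]
  if (!length(v)) return(list(mean = NA_real_, sd = NA_real_, n = 0L))
  list(mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
       n = length(v))
}
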