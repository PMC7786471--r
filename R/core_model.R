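#' Discipline categories observed in community districts
#'
#' The finite set of professional disciplines the package recognises by
#' default, and the default mixing proportions used by the synthetic cohort
#' generator.  The mix reflects a typical community-district workforce caring
#' for older people, in which social care workers and district nurses are the
#' most frequent disciplines.
#'
#' @return `default_disciplines()` returns a character vector of category
#'   names; `default_discipline_mix()` a named numeric vector of proportions
#'   summing to 1.
#' @export
default_disciplines <- function() {
  c("general practitioner", "practice nurse", "physiotherapist",
    "social care worker", "social care prescriber", "district nurse",
    "pharmacist", "specialist geriatric medicine", "dietician")
}

#' @rdname default_disciplines
#' @export
default_discipline_mix <- function() {
  w <- c(8, 6, 2, 15, 7, 10, 4, 1, 1)
  stats::setNames(w / sum(w), default_disciplines())
}

#' Construct a collaboration network
#'
#' A directed valued network over one district's roster at one timepoint.
#' Actors carry a discipline, a ring label (1 = program participant, 2 =
#' consented non-participant responder, 3 = nominated non-responder), a
#' program-participation flag and a responded-at-this-timepoint flag.  Ties
#' are directed nominations ego -> alter with an optional value in \[1, 10\].
#'
#' The constructor checks structure and types only; substantive invariants
#' (no self-ties, non-responders without out-ties, ...) are reported by
#' [validate_network()] so that faulty survey data can be inspected rather
#' than rejected outright.
#'
#' @param actors data frame with columns `actor_id`, `discipline`, `ring`
#'   and optionally `is_program_participant` (default `ring == 1`) and
#'   `responded` (default `ring %in% c(1, 2)`).
#' @param ties data frame with columns `source`, `target` and optionally
#'   `value`; `NULL` for an empty tie set.
#' @param district district label.
#' @param timepoint `"T0"`, `"T1"` or `NA`.
#' @return An object of class `collab_network`.
#' @export
collab_network <- function(actors, ties = NULL, district = NA_character_,
                           timepoint = NA_character_) {
  stopifnot(is.data.frame(actors))
  req <- c("actor_id", "discipline", "ring")
  miss <- setdiff(req, names(actors))
  if (length(miss)) {
    stop("`actors` is missing column(s): ", paste(miss, collapse = ", "))
  }
  actors <- as.data.frame(actors, stringsAsFactors = FALSE)
  actors$actor_id <- as.character(actors$actor_id)
  actors$discipline <- as.character(actors$discipline)
  actors$ring <- as.integer(actors$ring)
  if (!"is_program_participant" %in% names(actors)) {
    actors$is_program_participant <- actors$ring == 1L
  }
  if (!"responded" %in% names(actors)) {
    actors$responded <- actors$ring %in% c(1L, 2L)
  }
  actors$is_program_participant <- as.logical(actors$is_program_participant)
  actors$responded <- as.logical(actors$responded)
  actors <- actors[c("actor_id", "discipline", "ring",
                     "is_program_participant", "responded")]
  rownames(actors) <- NULL

  if (is.null(ties)) {
    ties <- data.frame(source = character(), target = character(),
                       value = numeric(), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(ties))
  miss <- setdiff(c("source", "target"), names(ties))
  if (length(miss)) {
    stop("`ties` is missing column(s): ", paste(miss, collapse = ", "))
  }
  ties <- as.data.frame(ties, stringsAsFactors = FALSE)
  ties$source <- as.character(ties$source)
  ties$target <- as.character(ties$target)
  if (!"value" %in% names(ties)) ties$value <- NA_real_
  ties$value <- as.numeric(ties$value)
  ties <- ties[c("source", "target", "value")]
  rownames(ties) <- NULL

  if (!is.na(timepoint) && !timepoint %in% c("T0", "T1")) {
    stop("`timepoint` must be \"T0\", \"T1\" or NA")
  }

  structure(list(actors = actors, ties = ties,
                 district = as.character(district),
                 timepoint = as.character(timepoint)),
            class = "collab_network")
}

#' @export
print.collab_network <- function(x, ...) {
  cat(sprintf("<collab_network> %d actors, %d ties",
              nrow(x$actors), nrow(x$ties)))
  if (!is.na(x$district)) cat(sprintf(" | district: %s", x$district))
  if (!is.na(x$timepoint)) cat(sprintf(" | timepoint: %s", x$timepoint))
  cat("\n")
  rt <- table(factor(x$actors$ring, levels = 1:3))
  cat(sprintf("  rings: 1=%d, 2=%d, 3=%d\n", rt[[1]], rt[[2]], rt[[3]]))
  invisible(x)
}

#' Report invariant violations in a collaboration network
#'
#' Checks the study-design invariants of the ring model: unique actor
#' identifiers, ring labels in \{1, 2, 3\}, the ring-1/program-participation
#' equivalence, no responder flag on ring-3 actors, tie endpoints on the
#' roster, no self-ties, tie values in \[1, 10\], at most one tie per ordered
#' pair, and no outgoing ties from actors who did not respond at this
#' timepoint.  The result is sorted, so it is independent of the order in
#' which ties are stored, and the check is idempotent.
#'
#' @param network a [collab_network()].
#' @return Character vector of human-readable violations; empty if the
#'   network is well formed.
#' @export
validate_network <- function(network) {
  stopifnot(inherits(network, "collab_network"))
  a <- network$actors
  t <- network$ties
  v <- character()

  dup <- unique(a$actor_id[duplicated(a$actor_id)])
  for (id in dup) v <- c(v, sprintf("actor '%s': duplicate actor_id", id))
  bad <- a$actor_id[is.na(a$ring) | !a$ring %in% 1:3]
  for (id in bad) v <- c(v, sprintf("actor '%s': ring must be 1, 2 or 3", id))
  mism <- a$actor_id[!is.na(a$ring) &
                       ((a$ring == 1L) != (a$is_program_participant %in% TRUE))]
  for (id in mism) {
    v <- c(v, sprintf(
      "actor '%s': ring 1 and program participation must coincide", id))
  }
  r3resp <- a$actor_id[a$ring %in% 3L & a$responded %in% TRUE]
  for (id in r3resp) {
    v <- c(v, sprintf("actor '%s': ring-3 actor marked as responder", id))
  }

  known <- a$actor_id
  unk <- unique(c(t$source[!t$source %in% known],
                  t$target[!t$target %in% known]))
  for (id in unk) v <- c(v, sprintf("tie endpoint '%s' not on roster", id))
  self <- t$source[t$source == t$target]
  for (id in unique(self)) {
    v <- c(v, sprintf("tie '%s'->'%s': self-tie not allowed", id, id))
  }
  badv <- which(!is.na(t$value) & (t$value < 1 | t$value > 10))
  for (i in badv) {
    v <- c(v, sprintf("tie '%s'->'%s': value %g outside [1, 10]",
                      t$source[i], t$target[i], t$value[i]))
  }
  key <- paste(t$source, t$target, sep = "\r")
  for (k in unique(key[duplicated(key)])) {
    p <- strsplit(k, "\r", fixed = TRUE)[[1]]
    v <- c(v, sprintf("tie '%s'->'%s': more than one tie for ordered pair",
                      p[1], p[2]))
  }
  nonresp <- a$actor_id[!a$responded %in% TRUE]
  badsrc <- unique(t$source[t$source %in% nonresp])
  for (id in badsrc) {
    v <- c(v, sprintf(
      "actor '%s': non-responder has outgoing ties (out-ties are missing by design)",
      id))
  }
  sort(v)
}

#' Pair two timepoints of one district into a pre/post study
#'
#' The comprehensive roster built at the first timepoint is reused at the
#' second, so both networks must cover the same actor set with identical
#' ring labels; only the responded flags may differ between timepoints.
#'
#' @param t0,t1 [collab_network()] objects at the first and second timepoint.
#' @return Object of class `pre_post_study` with elements `t0`, `t1` and
#'   `roster`.
#' @export
pre_post_study <- function(t0, t1) {
  stopifnot(inherits(t0, "collab_network"), inherits(t1, "collab_network"))
  if (!setequal(t0$actors$actor_id, t1$actors$actor_id)) {
    stop("t0 and t1 must share the same roster (the comprehensive list is reused)")
  }
  m <- match(t0$actors$actor_id, t1$actors$actor_id)
  if (!identical(t0$actors$ring, t1$actors$ring[m])) {
    stop("ring classification must be identical at both timepoints")
  }
  structure(list(t0 = t0, t1 = t1, roster = t0$actors$actor_id),
            class = "pre_post_study")
}

#' @export
print.pre_post_study <- function(x, ...) {
  cat(sprintf("<pre_post_study> %d actors | T0: %d ties, T1: %d ties\n",
              length(x$roster), nrow(x$t0$ties), nrow(x$t1$ties)))
  invisible(x)
}

#' Restrict a network to a subset of rings
#'
#' Returns the subgraph induced by the actors whose ring label is in
#' `rings`; ties with either endpoint outside the subset are dropped.
#' Mirrors the two reporting subsets "rings 1 and 2" and "rings 1, 2 and 3".
#'
#' @param network a [collab_network()].
#' @param rings integer vector, subset of `c(1, 2, 3)`.
#' @return A [collab_network()].
#' @export
induce_subset <- function(network, rings) {
  stopifnot(inherits(network, "collab_network"))
  rings <- as.integer(rings)
  if (!length(rings) || !all(rings %in% 1:3)) {
    stop("`rings` must be a non-empty subset of c(1, 2, 3)")
  }
  keep <- network$actors$ring %in% rings
  actors <- network$actors[keep, , drop = FALSE]
  ids <- actors$actor_id
  ties <- network$ties[network$ties$source %in% ids &
                         network$ties$target %in% ids, , drop = FALSE]
  collab_network(actors, ties, district = network$district,
                 timepoint = network$timepoint)
}
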