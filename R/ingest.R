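#' Build a district roster from ego-nomination responses
#'
#' The network boundary combines a snowball step (the egos' nominations) with
#' a fixed list: the roster is the union of all responding egos and every
#' alter they nominated, in first-seen order.  Self-nominations are dropped
#' with a warning.  A response with no nominations is represented by a row
#' whose `alter` is `NA`, which keeps the ego on the roster.
#'
#' @param nominations data frame with columns `ego` and `alter` (one row per
#'   nomination, in survey order).
#' @return Character vector of unique actor identifiers, first-seen order.
#' @export
build_roster <- function(nominations) {
  stopifnot(is.data.frame(nominations))
  if (!all(c("ego", "alter") %in% names(nominations))) {
    stop("`nominations` needs columns `ego` and `alter`")
  }
  if (!nrow(nominations)) stop("no responses")
  nominations$ego <- as.character(nominations$ego)
  nominations$alter <- as.character(nominations$alter)
  self <- !is.na(nominations$alter) & nominations$ego == nominations$alter
  if (any(self)) {
    warning(sprintf("dropped %d self-nomination(s): %s", sum(self),
                    paste(unique(nominations$ego[self]), collapse = ", ")))
    nominations <- nominations[!self, , drop = FALSE]
  }
  # interleave ego, alter row by row so order of first appearance is kept
  seen <- as.vector(t(as.matrix(nominations[c("ego", "alter")])))
  unique(seen[!is.na(seen)])
}

#' Classify roster actors into rings
#'
#' Ring 1: program participants.  Ring 2: professionals who responded to the
#' survey (at either timepoint) but did not attend the program.  Ring 3: all
#' remaining nominated professionals, whose outgoing ties are missing.
#' The three rings partition the roster.
#'
#' @param roster character vector of actor identifiers.
#' @param program_ids identifiers of program participants (subset of roster).
#' @param responder_ids identifiers of actors who responded at least once.
#' @return Named integer vector mapping `actor_id` to ring 1, 2 or 3.
#' @export
classify_rings <- function(roster, program_ids, responder_ids) {
  roster <- as.character(roster)
  program_ids <- as.character(program_ids)
  responder_ids <- as.character(responder_ids)
  if (!all(program_ids %in% roster)) {
    stop("program participant outside network boundary: ",
         paste(setdiff(program_ids, roster), collapse = ", "))
  }
  if (!all(responder_ids %in% roster)) {
    stop("responder outside network boundary: ",
         paste(setdiff(responder_ids, roster), collapse = ", "))
  }
  ring <- rep(3L, length(roster))
  ring[roster %in% responder_ids] <- 2L
  ring[roster %in% program_ids] <- 1L
  stats::setNames(ring, roster)
}

#' Assemble a directed valued network from one survey wave
#'
#' One arc is created per (ego, alter) nomination, carrying its 1-10 value.
#' Non-responders contribute no out-arcs but keep every in-arc.  Exact
#' duplicate nominations collapse to a single arc; the same ordered pair
#' with conflicting values is an error (it signals a data-entry fault).
#' Alters nominated outside the roster are appended as ring-3 actors with a
#' warning.
#'
#' @param nominations data frame with columns `ego`, `alter` and optionally
#'   `value`; rows with `NA` alter mark a response without nominations.
#' @param roster actor identifiers delimiting the network boundary.
#' @param rings named integer vector as returned by [classify_rings()].
#' @param disciplines optional named character vector `actor_id -> discipline`.
#' @param responders identifiers of actors who responded at *this* timepoint;
#'   defaults to the egos appearing in `nominations`.
#' @param timepoint,district network labels.
#' @return A [collab_network()].
#' @export
assemble_network <- function(nominations, roster, rings, disciplines = NULL,
                             responders = NULL, timepoint = NA_character_,
                             district = NA_character_) {
  stopifnot(is.data.frame(nominations))
  if (!all(c("ego", "alter") %in% names(nominations))) {
    stop("`nominations` needs columns `ego` and `alter`")
  }
  nominations$ego <- as.character(nominations$ego)
  nominations$alter <- as.character(nominations$alter)
  if (!"value" %in% names(nominations)) nominations$value <- NA_real_
  nominations$value <- as.numeric(nominations$value)
  roster <- as.character(roster)

  if (is.null(responders)) responders <- unique(nominations$ego)
  responders <- as.character(responders)
  bad <- setdiff(unique(nominations$ego), roster)
  if (length(bad)) {
    stop("response ego not on roster: ", paste(bad, collapse = ", "))
  }
  bad <- setdiff(unique(nominations$ego), responders)
  if (length(bad)) {
    stop("nominations from actor(s) not marked as responders: ",
         paste(bad, collapse = ", "))
  }

  self <- !is.na(nominations$alter) & nominations$ego == nominations$alter
  if (any(self)) {
    warning(sprintf("dropped %d self-nomination(s): %s", sum(self),
                    paste(unique(nominations$ego[self]), collapse = ", ")))
    nominations <- nominations[!self, , drop = FALSE]
  }
  nominations <- nominations[!is.na(nominations$alter), , drop = FALSE]
  nominations <- unique(nominations[c("ego", "alter", "value")])
  key <- paste(nominations$ego, nominations$alter, sep = "\r")
  if (anyDuplicated(key)) {
    k <- strsplit(key[duplicated(key)][1], "\r", fixed = TRUE)[[1]]
    stop(sprintf("conflicting nomination: '%s'->'%s' listed with different values",
                 k[1], k[2]))
  }

  extra <- setdiff(unique(nominations$alter), roster)
  if (length(extra)) {
    warning("nominated actor(s) outside roster added as ring 3: ",
            paste(extra, collapse = ", "))
    roster <- c(roster, extra)
    rings <- c(rings, stats::setNames(rep(3L, length(extra)), extra))
  }

  disc <- rep(NA_character_, length(roster))
  if (!is.null(disciplines)) {
    disc <- as.character(disciplines[roster])
  }
  actors <- data.frame(
    actor_id = roster,
    discipline = disc,
    ring = as.integer(rings[roster]),
    is_program_participant = as.integer(rings[roster]) == 1L,
    responded = roster %in% responders,
    stringsAsFactors = FALSE
  )
  ties <- data.frame(source = nominations$ego, target = nominations$alter,
                     value = nominations$value, stringsAsFactors = FALSE)
  collab_network(actors, ties, district = district, timepoint = timepoint)
}

#' Survey response rate over the network boundary
#'
#' @param roster actor identifiers delimiting the boundary.
#' @param responder_ids identifiers of actors who responded.
#' @return Proportion of the roster that responded, in \[0, 1\].
#' @export
response_rate <- function(roster, responder_ids) {
  roster <- unique(as.character(roster))
  responder_ids <- unique(as.character(responder_ids))
  if (!length(roster)) stop("empty roster")
  if (!all(responder_ids %in% roster)) {
    stop("responder outside network boundary: ",
         paste(setdiff(responder_ids, roster), collapse = ", "))
  }
  length(responder_ids) / length(roster)
}

#' Read and write the actor attribute table
#'
#' Tab-delimited text with header columns `actor_id`, `discipline`,
#' `district`, `program`, `responded_t0`, `responded_t1`; flags are stored
#' as 0/1.
#'
#' @param path file path.
#' @return `read_actor_table()` returns a data frame with logical flag
#'   columns.
#' @export
read_actor_table <- function(path) {
  req <- c("actor_id", "discipline", "district", "program",
           "responded_t0", "responded_t1")
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  miss <- setdiff(req, hdr)
  if (length(miss)) {
    stop("malformed actor table '", path, "': missing column(s) ",
         paste(miss, collapse = ", "))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(actor_id = "character",
                                         discipline = "character",
                                         district = "character"))
  for (cl in c("program", "responded_t0", "responded_t1")) {
    df[[cl]] <- as.logical(as.integer(df[[cl]]))
  }
  df
}

#' @rdname read_actor_table
#' @param actors data frame in the actor-table layout.
#' @export
write_actor_table <- function(actors, path) {
  out <- actors
  for (cl in c("program", "responded_t0", "responded_t1")) {
    out[[cl]] <- as.integer(out[[cl]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write the tie list
#'
#' Tab-delimited text with header columns `timepoint`, `source`, `target`,
#' `value`; unrated ties have an empty value field, rated ties are written
#' with one decimal place.
#'
#' @param path file path.
#' @return `read_tie_list()` returns a data frame.
#' @export
read_tie_list <- function(path) {
  req <- c("timepoint", "source", "target", "value")
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  miss <- setdiff(req, hdr)
  if (length(miss)) {
    stop("malformed tie list '", path, "': missing column(s) ",
         paste(miss, collapse = ", "))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(timepoint = "character",
                                         source = "character",
                                         target = "character"))
  df$value <- as.numeric(df$value)
  df
}

#' @rdname read_tie_list
#' @param ties data frame in the tie-list layout.
#' @export
write_tie_list <- function(ties, path) {
  out <- ties
  out$value <- ifelse(is.na(out$value), "",
                      formatC(out$value, format = "f", digits = 1))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Build per-district pre/post studies from survey tables
#'
#' Combines the actor attribute table and the two-timepoint tie list into
#' one [pre_post_study()] per district.  Ring classification uses response
#' at either timepoint (responding once places an actor in ring 2), and the
#' roster of a district additionally includes any alter nominated by that
#' district's egos, so both timepoints share one boundary.
#'
#' @param actor_table data frame as returned by [read_actor_table()].
#' @param tie_list data frame as returned by [read_tie_list()].
#' @return Named list of [pre_post_study()] objects, one per district.
#' @export
build_study_from_tables <- function(actor_table, tie_list) {
  stopifnot(is.data.frame(actor_table), is.data.frame(tie_list))
  studies <- list()
  for (d in unique(actor_table$district)) {
    at <- actor_table[actor_table$district == d, , drop = FALSE]
    dt <- tie_list[tie_list$source %in% at$actor_id, , drop = FALSE]
    roster <- unique(c(at$actor_id, dt$target))
    rings <- classify_rings(
      roster,
      program_ids = at$actor_id[at$program],
      responder_ids = at$actor_id[at$responded_t0 | at$responded_t1]
    )
    disciplines <- stats::setNames(at$discipline, at$actor_id)
    nets <- lapply(c("T0", "T1"), function(tp) {
      noms <- dt[dt$timepoint == tp, , drop = FALSE]
      names(noms)[names(noms) == "source"] <- "ego"
      names(noms)[names(noms) == "target"] <- "alter"
      resp_col <- if (tp == "T0") "responded_t0" else "responded_t1"
      assemble_network(noms[c("ego", "alter", "value")], roster, rings,
                       disciplines = disciplines,
                       responders = at$actor_id[at[[resp_col]]],
                       timepoint = tp, district = d)
    })
    studies[[d]] <- pre_post_study(nets[[1]], nets[[2]])
  }
  studies
}
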