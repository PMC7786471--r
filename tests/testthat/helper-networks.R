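# Fixture builders and independent oracles shared across the suite.

# Build a network from "A->B"-style edge strings.
net_from_edges <- function(edges = character(), ids = NULL, rings = NULL,
                           disciplines = NULL, responded = NULL,
                           values = NULL, district = NA_character_,
                           timepoint = NA_character_) {
  if (length(edges)) {
    parts <- strsplit(edges, "->", fixed = TRUE)
    ties <- data.frame(
      source = trimws(vapply(parts, `[`, character(1), 1)),
      target = trimws(vapply(parts, `[`, character(1), 2)),
      value = if (is.null(values)) NA_real_ else values,
      stringsAsFactors = FALSE
    )
  } else {
    ties <- NULL
  }
  if (is.null(ids)) {
    ids <- unique(c(ties$source, ties$target))
  }
  n <- length(ids)
  if (is.null(rings)) rings <- rep(2L, n)
  if (is.null(disciplines)) {
    disciplines <- rep_len(c("general practitioner", "district nurse",
                             "social care worker"), n)
  }
  actors <- data.frame(actor_id = ids, discipline = disciplines,
                       ring = rings, stringsAsFactors = FALSE)
  if (!is.null(responded)) actors$responded <- responded
  collab_network(actors, ties, district = district, timepoint = timepoint)
}

# Erdos-Renyi style random network; all actors respond, rings alternate 1/2.
random_net <- function(n, p, seed, n_disc = 3) {
  withr::with_seed(seed, {
    ids <- sprintf("a%02d", seq_len(n))
    a <- matrix(stats::runif(n * n) < p, n, n)
    diag(a) <- FALSE
    idx <- which(a, arr.ind = TRUE)
    ties <- data.frame(source = ids[idx[, 1]], target = ids[idx[, 2]],
                       value = round(stats::runif(nrow(idx), 1, 10), 1),
                       stringsAsFactors = FALSE)
    actors <- data.frame(
      actor_id = ids,
      discipline = rep_len(sprintf("disc%d", seq_len(n_disc)), n),
      ring = rep_len(c(1L, 2L), n), stringsAsFactors = FALSE)
    collab_network(actors, ties)
  })
}

# Brute-force oracles: enumerate ordered pairs / unordered dyads directly.
oracle_arc_count <- function(net) {
  key <- paste(net$ties$source, net$ties$target)
  ids <- net$actors$actor_id
  cnt <- 0L
  for (i in ids) {
    for (j in ids) {
      if (i != j && paste(i, j) %in% key) cnt <- cnt + 1L
    }
  }
  cnt
}

oracle_density <- function(net) {
  n <- nrow(net$actors)
  oracle_arc_count(net) / (n * (n - 1))
}

oracle_dyad_reciprocity <- function(net) {
  key <- paste(net$ties$source, net$ties$target)
  ids <- net$actors$actor_id
  mut <- asym <- 0L
  n <- length(ids)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      fw <- paste(ids[i], ids[j]) %in% key
      bw <- paste(ids[j], ids[i]) %in% key
      if (fw && bw) mut <- mut + 1L else if (fw || bw) asym <- asym + 1L
    }
  }
  if (mut + asym == 0L) return(NA_real_)
  mut / (mut + asym)
}
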