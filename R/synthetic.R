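#' Configuration of a synthetic district cohort
#'
#' Parameters of the generative model for a single community district
#' observed at two timepoints.  The roster holds `n_program` ring-1 actors
#' (program participants), `n_ring2` consented responders and `n_ring3`
#' nominated non-responders whose outgoing ties are masked.  Arcs are
#' independent Bernoulli draws: at T0 every ordered pair gets an arc with
#' probability `base_density`; at T1 the arc probability of a source actor
#' is raised by `effect_ring1` (ring 1) or `spill_over` (ring 2), modelling
#' the direct intervention effect and its spill-over onto non-participants.
#' After the base draw, the reverse of each existing arc is added with
#' probability `reciprocity_boost`, which produces realistic reciprocity
#' levels.  Tie values are Gaussian with mean `value_mean` and SD
#' `value_sd`, clamped to \[1, 10\] and rounded to one decimal.
#'
#' Defaults mirror a typical study district: 7 program participants, 9
#' further responders, 33 nominated non-responders, a discipline mix led by
#' social care workers and district nurses, baseline arc probability 0.2
#' and contact values around 7.5.
#'
#' @param n_program number of ring-1 actors (>= 1; studies use 7-10).
#' @param n_ring2,n_ring3 numbers of ring-2 and ring-3 actors.
#' @param discipline_weights named probability weights over disciplines.
#' @param base_density baseline arc probability p0.
#' @param effect_ring1 additive T1 arc-probability increase for ring-1 sources.
#' @param spill_over additive T1 increase for ring-2 sources.
#' @param reciprocity_boost probability that an arc induces its reverse.
#' @param value_mean,value_sd tie-rating distribution parameters.
#' @param seed optional integer seed for [generate_district()].
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_program = 7, n_ring2 = 9, n_ring3 = 33,
                          discipline_weights = default_discipline_mix(),
                          base_density = 0.2, effect_ring1 = 0.15,
                          spill_over = 0.08, reciprocity_boost = 0.3,
                          value_mean = 7.5, value_sd = 0.6, seed = NULL) {
  n_program <- .assert_count(n_program, "n_program", min = 1L)
  n_ring2 <- .assert_count(n_ring2, "n_ring2")
  n_ring3 <- .assert_count(n_ring3, "n_ring3")
  .assert_prob(base_density, "base_density")
  .assert_prob(effect_ring1, "effect_ring1")
  .assert_prob(spill_over, "spill_over")
  .assert_prob(reciprocity_boost, "reciprocity_boost")
  if (!is.numeric(value_mean) || value_mean < 1 || value_mean > 10) {
    stop("`value_mean` must be in [1, 10]")
  }
  if (!is.numeric(value_sd) || value_sd < 0) {
    stop("`value_sd` must be non-negative")
  }
  if (is.null(names(discipline_weights)) ||
      any(discipline_weights < 0) || sum(discipline_weights) <= 0) {
    stop("`discipline_weights` must be named non-negative weights")
  }
  structure(list(n_program = n_program, n_ring2 = n_ring2,
                 n_ring3 = n_ring3,
                 discipline_weights = discipline_weights,
                 base_density = base_density, effect_ring1 = effect_ring1,
                 spill_over = spill_over,
                 reciprocity_boost = reciprocity_boost,
                 value_mean = value_mean, value_sd = value_sd,
                 seed = seed),
            class = "cohort_config")
}

.draw_adjacency <- function(pmat, boost) {
  n <- nrow(pmat)
  a <- matrix(stats::runif(n * n) < pmat, n, n)
  diag(a) <- FALSE
  if (boost > 0) {
    add <- t(a) & (matrix(stats::runif(n * n), n, n) < boost)
    diag(add) <- FALSE
    a <- a | add
  }
  a
}

#' Generate one synthetic district at two timepoints
#'
#' Simulates the study conditions of [cohort_config()] and returns both the
#' observed study (ring-3 out-ties masked, as under unit non-response) and
#' the counterfactual complete-observation networks used as ground truth.
#' The truth networks keep the ring labels but flag every actor as a
#' responder, so they deliberately fail the study-level validation rule
#' that ring-3 actors never respond.
#'
#' @param config a [cohort_config()].
#' @param district district label (also prefixes actor identifiers).
#' @param seed integer seed; identical seed and config give identical output.
#' @return Object of class `district_sim` with elements `study`
#'   ([pre_post_study()]), `truth` (list of unmasked T0/T1 networks),
#'   `config` and `district`.
#' @export
generate_district <- function(config, district = "district 1",
                              seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  run <- function() {
    n1 <- config$n_program
    n2 <- config$n_ring2
    n3 <- config$n_ring3
    n <- n1 + n2 + n3
    prefix <- gsub("[^A-Za-z0-9]+", "", district)
    ids <- sprintf("%s_%03d", prefix, seq_len(n))
    ring <- rep(1:3, c(n1, n2, n3))
    w <- config$discipline_weights
    disc <- sample(names(w), n, replace = TRUE, prob = w)
    actors <- data.frame(actor_id = ids, discipline = disc, ring = ring,
                         is_program_participant = ring == 1L,
                         responded = ring != 3L, stringsAsFactors = FALSE)

    p0 <- matrix(config$base_density, n, n)
    eff <- c(config$effect_ring1, config$spill_over, 0)[ring]
    p1 <- .clamp(p0 + matrix(eff, n, n), 0, 1)
    a0 <- .draw_adjacency(p0, config$reciprocity_boost)
    a1 <- .draw_adjacency(p1, config$reciprocity_boost)

    arcs_to_ties <- function(a) {
      idx <- which(a, arr.ind = TRUE)
      idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
      v <- round(.clamp(stats::rnorm(nrow(idx), config$value_mean,
                                     config$value_sd), 1, 10), 1)
      data.frame(source = ids[idx[, 1]], target = ids[idx[, 2]],
                 value = v, stringsAsFactors = FALSE)
    }
    ties0 <- arcs_to_ties(a0)
    ties1 <- arcs_to_ties(a1)

    truth_actors <- actors
    truth_actors$responded <- TRUE
    truth <- list(
      t0 = collab_network(truth_actors, ties0, district, "T0"),
      t1 = collab_network(truth_actors, ties1, district, "T1")
    )
    mask <- function(ties) {
      src_ring <- ring[match(ties$source, ids)]
      ties[src_ring != 3L, , drop = FALSE]
    }
    study <- pre_post_study(
      collab_network(actors, mask(ties0), district, "T0"),
      collab_network(actors, mask(ties1), district, "T1")
    )
    structure(list(study = study, truth = truth, config = config,
                   district = district),
              class = "district_sim")
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

#' @export
print.district_sim <- function(x, ...) {
  cat(sprintf("<district_sim> %s | ", x$district))
  print(x$study)
  invisible(x)
}

#' Generate a full synthetic study over several districts
#'
#' Simulates the default three-district design (rosters of 7+9+33, 8+11+56
#' and 7+13+49 actors across rings 1/2/3) or any list of per-district
#' configuration overrides.  A single seed governs the whole study;
#' per-district sub-seeds are derived from it deterministically.
#'
#' @param seed integer seed.
#' @param districts optional named list; each element is a list of
#'   [cohort_config()] arguments for one district.
#' @return Named list of [generate_district()] results.
#' @export
generate_study <- function(seed = 1L, districts = NULL) {
  if (is.null(districts)) {
    districts <- list(
      "district 1" = list(n_program = 7, n_ring2 = 9, n_ring3 = 33),
      "district 2" = list(n_program = 8, n_ring2 = 11, n_ring3 = 56),
      "district 3" = list(n_program = 7, n_ring2 = 13, n_ring3 = 49)
    )
  }
  if (is.null(names(districts)) || any(!nzchar(names(districts)))) {
    names(districts) <- sprintf("district %d", seq_along(districts))
  }
  sub_seeds <- withr::with_seed(
    seed, sample.int(.Machine$integer.max - 1L, length(districts)))
  sims <- Map(function(args, d, s) {
    cfg <- do.call(cohort_config, args)
    generate_district(cfg, district = d, seed = s)
  }, districts, names(districts), sub_seeds)
  sims
}

.as_studies <- function(x) {
  if (inherits(x, "district_sim")) x <- list("district 1" = x)
  if (inherits(x, "pre_post_study")) x <- list("district 1" = x)
  lapply(x, function(el) if (inherits(el, "district_sim")) el$study else el)
}

#' Export a study to survey-format files
#'
#' Writes the actor attribute table (`actors.tsv`) and the two-timepoint tie
#' list (`ties.tsv`) in the delimited formats read by [read_actor_table()]
#' and [read_tie_list()]; tie values are serialized with one decimal place
#' and non-responders contribute no tie rows.  The files round-trip through
#' [ingest_survey_files()] to the identical networks.
#'
#' @param sims a [generate_district()]/[generate_study()] result, a
#'   [pre_post_study()], or a named list of either.
#' @param dir output directory (created if missing).
#' @return Invisibly, the two file paths.
#' @export
export_survey_files <- function(sims, dir) {
  studies <- .as_studies(sims)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  arows <- list()
  trows <- list()
  for (d in names(studies)) {
    st <- studies[[d]]
    a0 <- st$t0$actors
    a1 <- st$t1$actors
    arows[[d]] <- data.frame(
      actor_id = a0$actor_id, discipline = a0$discipline,
      district = d, program = a0$is_program_participant,
      responded_t0 = a0$responded,
      responded_t1 = a1$responded[match(a0$actor_id, a1$actor_id)],
      stringsAsFactors = FALSE
    )
    for (tp in c("T0", "T1")) {
      net <- if (tp == "T0") st$t0 else st$t1
      if (nrow(net$ties)) {
        trows[[paste(d, tp)]] <- cbind(timepoint = tp, net$ties)
      }
    }
  }
  apath <- file.path(dir, "actors.tsv")
  tpath <- file.path(dir, "ties.tsv")
  write_actor_table(do.call(rbind, arows), apath)
  tl <- if (length(trows)) {
    do.call(rbind, trows)
  } else {
    data.frame(timepoint = character(), source = character(),
               target = character(), value = numeric())
  }
  rownames(tl) <- NULL
  write_tie_list(tl, tpath)
  invisible(c(actors = apath, ties = tpath))
}

#' Read survey-format files back into per-district studies
#'
#' @param dir directory containing `actors.tsv` and `ties.tsv` as written by
#'   [export_survey_files()].
#' @return Named list of [pre_post_study()] objects.
#' @export
ingest_survey_files <- function(dir) {
  build_study_from_tables(read_actor_table(file.path(dir, "actors.tsv")),
                          read_tie_list(file.path(dir, "ties.tsv")))
}
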