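.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full survey-to-report pipeline
#'
#' Executes ingest (or simulation), metrics, pre/post comparison, report
#' and figures in one call, logging each stage.  The configuration is a
#' list or a path to a JSON file with either
#' \describe{
#'   \item{`simulate`}{`TRUE`, or a named list of per-district
#'     [cohort_config()] argument lists, to generate synthetic survey data;}
#'   \item{`survey`}{a list with `actor_table` and `tie_list` paths to
#'     ingest real survey files.}
#' }
#' plus optional `seed` and `out_dir`.  Errors are reported with the name
#' of the stage that raised them.
#'
#' @param config list or path to a JSON configuration file.
#' @param out_dir output directory (overrides `config$out_dir`).
#' @param seed integer seed (overrides `config$seed`).
#' @param figures render sociogram PNGs per district and timepoint.
#' @return Invisibly, a list with the `report` ([build_report()]),
#'   per-district `comparisons`, the `studies`, and the written `files`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL,
                         figures = TRUE) {
  if (is.character(config)) {
    config <- .stage("config", {
      if (!file.exists(config)) stop("config file not found: ", config)
      jsonlite::read_json(config, simplifyVector = TRUE)
    })
  }
  stopifnot(is.list(config))
  seed <- seed %||% config$seed %||% 1L
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("[config] no output directory given")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  studies <- if (!is.null(config$simulate) &&
                 !identical(config$simulate, FALSE)) {
    message("stage simulate: generating synthetic survey data (seed ",
            seed, ")")
    sims <- .stage("simulate", {
      districts <- if (is.list(config$simulate)) config$simulate else NULL
      generate_study(seed = seed, districts = districts)
    })
    .as_studies(sims)
  } else {
    message("stage ingest: reading survey files")
    .stage("ingest", {
      sv <- config$survey
      if (is.null(sv$actor_table) || is.null(sv$tie_list)) {
        stop("config$survey must name `actor_table` and `tie_list` files")
      }
      if (!file.exists(sv$actor_table)) {
        stop("actor table not found: ", sv$actor_table)
      }
      if (!file.exists(sv$tie_list)) {
        stop("tie list not found: ", sv$tie_list)
      }
      build_study_from_tables(read_actor_table(sv$actor_table),
                              read_tie_list(sv$tie_list))
    })
  }

  message("stage report: computing descriptive statistics for ",
          length(studies), " district(s)")
  report <- .stage("report", build_report(studies))
  comparisons <- .stage("compare",
                        lapply(studies, compare_networks, rings = c(1, 2)))

  files <- character()
  report_tsv <- file.path(out_dir, "report.tsv")
  utils::write.table(as.data.frame(report), report_tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  report_json <- file.path(out_dir, "report.json")
  jsonlite::write_json(as.data.frame(report), report_json,
                       auto_unbox = TRUE, digits = NA, na = "null")
  files <- c(files, report_tsv, report_json)

  if (isTRUE(figures)) {
    message("stage figures: rendering sociograms")
    .stage("figures", {
      for (d in names(studies)) {
        for (tp in c("T0", "T1")) {
          net <- if (tp == "T0") studies[[d]]$t0 else studies[[d]]$t1
          slug <- gsub("[^A-Za-z0-9]+", "_", d)
          for (mode in c("plain", "reciprocity")) {
            f <- file.path(out_dir,
                           sprintf("sociogram_%s_%s_%s.png", slug, tp, mode))
            nn <- if (mode == "reciprocity") {
              induce_subset(net, c(1, 2))
            } else {
              net
            }
            render_sociogram(nn, file = f, edge_mode = mode,
                             layout_seed = seed)
            files <- c(files, f)
          }
        }
      }
    })
  }
  message("pipeline complete: ", length(files), " file(s) in ", out_dir)
  invisible(list(report = report, comparisons = comparisons,
                 studies = studies, files = files))
}
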