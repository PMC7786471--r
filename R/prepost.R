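#' Paired t test on pre/post actor measurements
#'
#' Classical paired t test on the differences `post - pre`, pairing by
#' actor.  Pairs with a missing value at either timepoint are dropped before
#' testing; at least two complete pairs are required.  Differences with zero
#' variance (e.g. identical vectors) yield `t = 0` with a warning instead of
#' failing, `p = 1`, and a degenerate confidence interval at the mean
#' difference.
#'
#' @param pre,post numeric vectors of equal length.
#' @param conf_level confidence level of the interval (default 0.95).
#' @return Object of class `paired_t_result` with `t_statistic`,
#'   `degrees_of_freedom`, two-sided `p_value`, `ci_low`/`ci_high` for the
#'   mean difference, `mean_difference`, `n_pairs` and `n_dropped`.
#' @export
paired_t_test <- function(pre, post, conf_level = 0.95) {
  if (length(pre) != length(post)) {
    stop("pre and post must have equal length (paired by actor)")
  }
  keep <- !is.na(pre) & !is.na(post)
  d <- post[keep] - pre[keep]
  n <- length(d)
  if (n < 2L) stop("insufficient pairs (need at least 2 complete pairs)")
  m <- mean(d)
  s <- stats::sd(d)
  df <- n - 1L
  if (s == 0) {
    warning("zero-variance differences; t statistic set to 0")
    tt <- 0
    p <- 1
    ci <- c(m, m)
  } else {
    se <- s / sqrt(n)
    tt <- m / se
    p <- 2 * stats::pt(-abs(tt), df)
    q <- stats::qt(1 - (1 - conf_level) / 2, df)
    ci <- c(m - q * se, m + q * se)
  }
  structure(list(t_statistic = tt, degrees_of_freedom = df, p_value = p,
                 ci_low = ci[1], ci_high = ci[2], mean_difference = m,
                 n_pairs = n, n_dropped = sum(!keep),
                 conf_level = conf_level),
            class = "paired_t_result")
}

#' @export
print.paired_t_result <- function(x, ...) {
  cat(sprintf(
    "Paired t test: t = %.3f, df = %d, p = %.4g, %d%% CI [%.3f, %.3f], n = %d\n",
    x$t_statistic, x$degrees_of_freedom, x$p_value,
    round(100 * x$conf_level), x$ci_low, x$ci_high, x$n_pairs))
  if (x$n_dropped > 0) {
    cat(sprintf("  (%d incomplete pair(s) dropped)\n", x$n_dropped))
  }
  invisible(x)
}

.safe_metric <- function(expr) {
  tryCatch(expr, error = function(e) NA_real_)
}

.per_actor_diversity <- function(network, rings) {
  sub <- induce_subset(network, rings)
  vapply(sub$actors$actor_id, function(a) {
    tryCatch(diversity_index(sub, a)$h_i, error = function(e) NA_real_)
  }, numeric(1))
}

.per_actor_value <- function(network, rings) {
  sub <- induce_subset(network, rings)
  vapply(sub$actors$actor_id,
         function(a) mean_tie_value(sub, a), numeric(1))
}

#' Compare the two timepoints of a pre/post study
#'
#' Network-level metrics (average degree, density, reciprocity, per-ring
#' E-I index) are reported as T0 value, T1 value and change (T1 - T0;
#' density and reciprocity changes are percentage points when multiplied by
#' 100).  Actor-level measures (diversity index, mean contact value) are
#' compared with a paired t test over the ring-1/ring-2 actors that have a
#' defined value at both timepoints; positive t means an increase.
#'
#' @param study a [pre_post_study()].
#' @param rings ring subset used for the network metrics (default rings 1
#'   and 2).
#' @return Object of class `network_comparison` with a `metrics` data frame
#'   and `diversity_test` / `value_test` [paired_t_test()] results (`NULL`
#'   when a test is not computable).
#' @export
compare_networks <- function(study, rings = c(1, 2)) {
  stopifnot(inherits(study, "pre_post_study"))
  t0 <- study$t0
  t1 <- study$t1
  rows <- list(
    c(metric = "avg_degree",
      t0 = .safe_metric(average_degree(t0, rings)),
      t1 = .safe_metric(average_degree(t1, rings))),
    c(metric = "density",
      t0 = .safe_metric(net_density(t0, rings)),
      t1 = .safe_metric(net_density(t1, rings))),
    c(metric = "reciprocity",
      t0 = .safe_metric(reciprocity(t0, rings)),
      t1 = .safe_metric(reciprocity(t1, rings)))
  )
  present <- sort(unique(t0$actors$ring))
  for (r in intersect(rings, present)) {
    rows <- c(rows, list(c(
      metric = sprintf("ei_ring%d", r),
      t0 = .safe_metric(ei_decomposition(t0, r, rings)$ei_index),
      t1 = .safe_metric(ei_decomposition(t1, r, rings)$ei_index))))
  }
  metrics <- data.frame(
    metric = vapply(rows, `[[`, character(1), "metric"),
    t0 = as.numeric(vapply(rows, `[[`, character(1), "t0")),
    t1 = as.numeric(vapply(rows, `[[`, character(1), "t1")),
    stringsAsFactors = FALSE
  )
  metrics$change <- metrics$t1 - metrics$t0

  pair_rings <- intersect(rings, c(1, 2))
  div_test <- val_test <- NULL
  if (length(pair_rings)) {
    h0 <- .per_actor_diversity(t0, pair_rings)
    h1 <- .per_actor_diversity(t1, pair_rings)
    div_test <- tryCatch(paired_t_test(h0, h1), error = function(e) NULL)
    v0 <- .per_actor_value(t0, pair_rings)
    v1 <- .per_actor_value(t1, pair_rings)
    val_test <- tryCatch(paired_t_test(v0, v1), error = function(e) NULL)
  }
  structure(list(metrics = metrics, diversity_test = div_test,
                 value_test = val_test, rings = rings),
            class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf("<network_comparison> rings %s\n",
              paste(x$rings, collapse = "+")))
  print(x$metrics, row.names = FALSE, digits = 3)
  if (!is.null(x$diversity_test)) {
    cat("diversity: ")
    print(x$diversity_test)
  }
  if (!is.null(x$value_test)) {
    cat("value:     ")
    print(x$value_test)
  }
  invisible(x)
}

.report_row <- function(district, subset, timepoint, metric, value,
                        applicable = TRUE) {
  data.frame(district = district, subset = subset, timepoint = timepoint,
             metric = metric, value = as.numeric(value),
             applicable = applicable, stringsAsFactors = FALSE)
}

#' Descriptive pre/post report over districts
#'
#' Builds the long-format descriptive table of network development: for
#' every district, for both reporting subsets ("rings 1+2" and
#' "rings 1+2+3") and both timepoints, the number of actors, average
#' out-degree, density (percent), and per-ring E-I decomposition
#' (internal/external contacts and average degrees, E-I index for rings 1
#' and 2); reciprocity (percent), diversity mean/SD and contact-value
#' mean/SD are reported for the rings 1+2 subset only and marked
#' not-applicable (`applicable = FALSE`, `NA` value) for the ring-3
#' inclusive subset, where the missing out-ties of non-responders would
#' distort them.  Paired t tests for diversity and value are attached per
#' district with a blank timepoint.
#'
#' @param studies a [pre_post_study()] or a named list of them (one per
#'   district).
#' @return Data frame of class `metrics_report` with columns `district`,
#'   `subset`, `timepoint`, `metric`, `value`, `applicable`.
#' @export
build_report <- function(studies) {
  if (inherits(studies, "pre_post_study")) {
    studies <- list("district 1" = studies)
  }
  stopifnot(length(studies) >= 1)
  if (is.null(names(studies)) || any(!nzchar(names(studies)))) {
    names(studies) <- sprintf("district %d", seq_along(studies))
  }
  subsets <- list("rings 1+2" = c(1, 2), "rings 1+2+3" = c(1, 2, 3))
  out <- list()
  for (d in names(studies)) {
    study <- studies[[d]]
    for (sname in names(subsets)) {
      s <- subsets[[sname]]
      full <- setequal(s, c(1, 2, 3))
      for (tp in c("T0", "T1")) {
        net <- induce_subset(if (tp == "T0") study$t0 else study$t1, s)
        add <- function(metric, value, applicable = TRUE) {
          out[[length(out) + 1]] <<- .report_row(d, sname, tp, metric,
                                                 value, applicable)
        }
        add("n_actors", nrow(net$actors))
        add("avg_degree", .safe_metric(average_degree(net)))
        add("density_pct", 100 * .safe_metric(net_density(net)))
        for (r in intersect(s, c(1, 2))) {
          ei <- tryCatch(ei_decomposition(net, r), error = function(e) NULL)
          pre <- sprintf("ring%d", r)
          add(paste0("internal_contacts_", pre),
              if (is.null(ei)) NA else ei$internal_contacts)
          add(paste0("external_contacts_", pre),
              if (is.null(ei)) NA else ei$external_contacts)
          add(paste0("internal_avg_degree_", pre),
              if (is.null(ei)) NA else ei$internal_avg_degree)
          add(paste0("external_avg_degree_", pre),
              if (is.null(ei)) NA else ei$external_avg_degree)
          add(paste0("ei_index_", pre),
              if (is.null(ei)) NA else ei$ei_index)
        }
        if (full) {
          add("reciprocity_pct", NA, applicable = FALSE)
          add("diversity_mean", NA, applicable = FALSE)
          add("diversity_sd", NA, applicable = FALSE)
          add("value_mean", NA, applicable = FALSE)
          add("value_sd", NA, applicable = FALSE)
        } else {
          add("reciprocity_pct", 100 * .safe_metric(reciprocity(net)))
          md <- tryCatch(mean_diversity(net, rings = c(1, 2)),
                         error = function(e) list(mean = NA, sd = NA))
          add("diversity_mean", md$mean)
          add("diversity_sd", md$sd)
          tv <- tie_value_summary(net, rings = c(1, 2))
          add("value_mean", tv$mean)
          add("value_sd", tv$sd)
        }
      }
    }
    cmp <- compare_networks(study, rings = c(1, 2))
    addt <- function(metric, value, applicable = TRUE) {
      out[[length(out) + 1]] <<- .report_row(d, "rings 1+2", NA_character_,
                                             metric, value, applicable)
    }
    for (nm in c("diversity", "value")) {
      tst <- cmp[[paste0(nm, "_test")]]
      addt(paste0(nm, "_t"), if (is.null(tst)) NA else tst$t_statistic)
      addt(paste0(nm, "_p"), if (is.null(tst)) NA else tst$p_value)
      addt(paste0(nm, "_ci_low"), if (is.null(tst)) NA else tst$ci_low)
      addt(paste0(nm, "_ci_high"), if (is.null(tst)) NA else tst$ci_high)
      out[[length(out) + 1]] <- .report_row(d, "rings 1+2+3", NA_character_,
                                            paste0(nm, "_t"), NA,
                                            applicable = FALSE)
    }
  }
  report <- do.call(rbind, out)
  class(report) <- c("metrics_report", "data.frame")
  report
}

#' @export
print.metrics_report <- function(x, digits = 2, ...) {
  df <- as.data.frame(x)
  for (d in unique(df$district)) {
    cat(sprintf("== %s ==\n", d))
    dd <- df[df$district == d, , drop = FALSE]
    dd$cell <- ifelse(!dd$applicable, "N.A.",
                      ifelse(is.na(dd$value), "-",
                             formatC(dd$value, format = "fg",
                                     digits = digits + 2)))
    dd$col <- paste(dd$subset,
                    ifelse(is.na(dd$timepoint), "test", dd$timepoint))
    mets <- unique(dd$metric)
    cols <- unique(dd$col)
    m <- matrix("", nrow = length(mets), ncol = length(cols),
                dimnames = list(mets, cols))
    m[cbind(match(dd$metric, mets), match(dd$col, cols))] <- dd$cell
    print(as.data.frame(m), ...)
  }
  invisible(x)
}
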