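#' Run the full sensitivity-analysis pipeline
#'
#' Orchestrates the package's whole workflow over a study table: pooling,
#' one-sample-removed, outlier diagnostics, the publication-bias battery
#' and range triangulation for the full distribution and for every
#' moderator sub-distribution, plus the moderator crossing (each
#' moderator's levels crossed with the frame-of-reference moderator, when
#' present). Sub-distributions below `min_k_bias` studies keep their
#' pooled statistics but skip the bias battery, and every skipped
#' analysis is logged with its reason.
#'
#' With `outlier_policy = "report_both"` (the default) the entire run is
#' repeated with the flagged outliers excluded, and both report sets are
#' returned; `"exclude"` reports only the outlier-excluded run,
#' `"include"` only the full-data run.
#'
#' @param data A study table (validated on entry).
#' @param moderators Moderator columns to analyse; default: all
#'   non-reserved columns.
#' @param cross_with Moderator to cross the others with; default
#'   `"frame_of_reference"` when present, otherwise none.
#' @param min_k_bias Minimum k for the bias battery (default 10).
#' @param outlier_policy `"report_both"`, `"include"` or `"exclude"`.
#' @param alpha Significance level shared by the battery.
#' @param digits Reporting precision for triangulation.
#' @param label Label of the full distribution.
#' @param seed Recorded in the metadata (the pipeline itself is
#'   deterministic).
#' @return An object of class `sensitivity_report`: a list with
#'   `table1` (battery rows), `table2` (triangulation rows), `table3`
#'   (between-group Q tests), `funnel`, `cumulative`, `outliers`,
#'   `excluded` (the outlier-excluded twin, under `report_both`),
#'   `log`, `metadata`.
#' @export
run_sensitivity_pipeline <- function(data, moderators = NULL, cross_with = NULL,
                                     min_k_bias = 10,
                                     outlier_policy = c("report_both", "include", "exclude"),
                                     alpha = 0.05, digits = 2,
                                     label = "All samples", seed = NULL) {
  outlier_policy <- match.arg(outlier_policy)
  if (min_k_bias < 3) abort("`min_k_bias` must be at least 3.")
  data <- validate_meta_data(data)
  moderators <- moderators %||% moderator_columns(data)
  missing_mods <- setdiff(moderators, names(data))
  if (length(missing_mods) > 0) {
    abort(paste0("Moderator column(s) not found: ", paste(missing_mods, collapse = ", ")))
  }
  if (is.null(cross_with) && "frame_of_reference" %in% moderators) {
    cross_with <- "frame_of_reference"
  }
  if (!is.null(cross_with) && !cross_with %in% moderators) {
    abort("`cross_with` must be one of the analysed moderators.")
  }

  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  # outlier handling on the full distribution
  outliers <- tibble::tibble(study_id = character(), flagged = logical())
  flagged <- character()
  if (nrow(data) >= 3) {
    diag <- influence_diagnostics(data)
    flagged <- flag_outliers(diag)
    outliers <- diag
    note("outlier screen: %d of %d studies flagged%s", length(flagged), nrow(data),
         if (length(flagged) > 0) paste0(" (", paste(flagged, collapse = ", "), ")") else "")
  } else {
    note("outlier screen skipped: k < 3")
  }

  analyse_set <- function(dat) {
    dists <- list(list(label = label, data = dat))
    for (m in moderators) {
      for (lev in sort(unique(as.character(dat[[m]])))) {
        dists <- c(dists, list(list(
          label = sprintf("%s: %s", m, lev),
          data = dat[as.character(dat[[m]]) == lev, , drop = FALSE]
        )))
        if (!is.null(cross_with) && m != cross_with) {
          for (f in sort(unique(as.character(dat[[cross_with]])))) {
            sub <- dat[as.character(dat[[m]]) == lev &
                         as.character(dat[[cross_with]]) == f, , drop = FALSE]
            if (nrow(sub) > 0) {
              dists <- c(dists, list(list(
                label = sprintf("%s: %s & %s: %s", m, lev, cross_with, f),
                data = sub
              )))
            }
          }
        }
      }
    }
    batteries <- lapply(dists, function(d) {
      b <- bias_battery(d$data, label = d$label, min_k = min_k_bias, alpha = alpha)
      for (msg in b$skipped_reasons) note("[%s] %s", d$label, msg)
      b
    })
    table1 <- dplyr::bind_rows(lapply(batteries, glance))
    assessed <- table1[table1$bias_assessed, , drop = FALSE]
    table2 <- if (nrow(assessed) > 0) {
      triangulate(assessed, digits = digits)
    } else {
      tibble::tibble()
    }
    q_rows <- list()
    for (m in moderators) {
      if (length(unique(as.character(dat[[m]]))) >= 2) {
        q_rows <- c(q_rows, list(subgroup_q(dat, m)))
      } else {
        note("between-group Q skipped for '%s': fewer than 2 groups", m)
      }
      if (!is.null(cross_with) && m != cross_with) {
        for (lev in sort(unique(as.character(dat[[m]])))) {
          sub <- dat[as.character(dat[[m]]) == lev, , drop = FALSE]
          if (length(unique(as.character(sub[[cross_with]]))) >= 2) {
            q <- subgroup_q(sub, cross_with)
            q$moderator <- sprintf("%s: %s | %s", m, lev, cross_with)
            q_rows <- c(q_rows, list(q))
          } else {
            note("between-group Q skipped for '%s: %s | %s': fewer than 2 groups",
                 m, lev, cross_with)
          }
        }
      }
    }
    table3 <- dplyr::bind_rows(q_rows)
    full_batt <- batteries[[1]]
    list(
      table1 = table1, table2 = table2, table3 = table3,
      funnel = full_batt$funnel %||% funnel_contours(dat),
      cumulative = full_batt$cumulative %||%
        (if (nrow(dat) >= 2) cumulative_by_precision(dat) else NULL)
    )
  }

  main <- NULL
  excluded <- NULL
  if (outlier_policy %in% c("report_both", "include")) {
    main <- analyse_set(data)
  }
  if (outlier_policy %in% c("report_both", "exclude")) {
    if (length(flagged) > 0) {
      reduced <- data[!as.character(data$id) %in% flagged, , drop = FALSE]
      note("outlier-excluded run: k = %d after removing %d flagged study(ies)",
           nrow(reduced), length(flagged))
      excluded <- analyse_set(reduced)
    } else {
      note("outlier-excluded run identical to main run: no studies flagged")
      excluded <- if (outlier_policy == "exclude") analyse_set(data) else NULL
    }
    if (outlier_policy == "exclude") {
      main <- excluded %||% analyse_set(data)
      excluded <- NULL
    }
  }

  structure(list(
    table1 = main$table1, table2 = main$table2, table3 = main$table3,
    funnel = main$funnel, cumulative = main$cumulative,
    outliers = outliers, flagged = flagged,
    excluded = excluded,
    log = log_lines,
    metadata = list(
      package = "metarange",
      version = as.character(utils::packageVersion("metarange")),
      label = label, k = nrow(data), seed = seed,
      moderators = moderators, cross_with = cross_with,
      min_k_bias = min_k_bias, outlier_policy = outlier_policy,
      alpha = alpha, digits = digits, flagged_outliers = flagged
    )
  ), class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("Sensitivity report for '%s' (k = %d)\n", x$metadata$label, x$metadata$k))
  cat(sprintf("distributions analysed: %d; flagged outliers: %s\n",
              nrow(x$table1),
              if (length(x$flagged) > 0) paste(x$flagged, collapse = ", ") else "none"))
  cat("\nTriangulation (table2):\n")
  print(x$table2)
  invisible(x)
}

#' Write a sensitivity report bundle to disk
#'
#' Serialises a [run_sensitivity_pipeline()] result to a directory:
#' `results_table1.csv` (battery rows), `ranges_table2.csv`
#' (triangulation), `subgroup_q_table3.csv`, `funnel_full.csv`,
#' `cumulative_full.csv`, `outlier_diagnostics.csv`,
#' `run_metadata.json` and `log.txt`; the outlier-excluded twin run,
#' when present, is written with an `_outlier_excluded` suffix. Output is
#' deterministic given the report (no timestamps).
#'
#' @param report A `sensitivity_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(report, dir) {
  if (!inherits(report, "sensitivity_report")) {
    abort("`report` must be a sensitivity_report object.")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    if (!is.null(x) && is.data.frame(x) && nrow(x) > 0) {
      readr::write_csv(x, file.path(dir, name))
    }
  }
  write_set <- function(set, suffix = "") {
    w(set$table1, paste0("results_table1", suffix, ".csv"))
    w(set$table2, paste0("ranges_table2", suffix, ".csv"))
    w(set$table3, paste0("subgroup_q_table3", suffix, ".csv"))
    if (!is.null(set$funnel)) {
      w(set$funnel$points, paste0("funnel_full", suffix, ".csv"))
      w(set$funnel$boundaries, paste0("funnel_contours", suffix, ".csv"))
    }
    w(set$cumulative, paste0("cumulative_full", suffix, ".csv"))
  }
  write_set(report)
  if (!is.null(report$excluded)) write_set(report$excluded, "_outlier_excluded")
  w(report$outliers, "outlier_diagnostics.csv")
  jsonlite::write_json(report$metadata, file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(report$log, file.path(dir, "log.txt"))
  invisible(dir)
}
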