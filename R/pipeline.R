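# Declarative reanalysis pipeline: read a config describing trial
# comparisons in heterogeneous summary formats, dispatch each through the
# matching reconstruction and Bayes factor path, and emit a tidy results
# table with provenance. Comparisons are analyzed strictly separately (no
# pooling, no cross-record state).

.outcome_kinds <- c("continuous_summary", "ratio_ci", "binary_counts")
.directions <- c("benefit_higher", "benefit_lower")

# Build one validated comparison_record from a plain list; `where` is the
# locator used in error messages.
.build_record <- function(rec, where) {
  for (field in c("trial_id", "outcome", "outcome_kind")) {
    if (is.null(rec[[field]]) || !nzchar(as.character(rec[[field]])[1])) {
      stop(where, ": missing field '", field, "'", call. = FALSE)
    }
  }
  kind <- as.character(rec$outcome_kind)
  if (!kind %in% .outcome_kinds) {
    stop(where, ": unknown outcome_kind '", kind, "'", call. = FALSE)
  }
  direction <- as.character(rec$direction %||% "benefit_higher")
  if (!direction %in% .directions) {
    stop(where, ": direction must be one of ",
         paste(.directions, collapse = ", "), call. = FALSE)
  }
  p <- rec$payload
  if (is.null(p)) stop(where, ": missing payload", call. = FALSE)
  payload <- tryCatch(
    switch(kind,
      continuous_summary = {
        mk_arm <- function(a, lab) {
          arm_summary(as.character(a$label %||% lab), a$n,
                      mean = a$mean, sd = a$sd,
                      median = a$median, q1 = a$q1, q3 = a$q3)
        }
        list(arm1 = mk_arm(p$arm1, "arm1"), arm2 = mk_arm(p$arm2, "arm2"))
      },
      ratio_ci = ratio_summary(p$ratio, p$ci_lower, p$ci_upper,
                               n1 = p$n1, n2 = p$n2,
                               level = p$level %||% 0.95),
      binary_counts = contingency_table_2x2(p$n1, p$y1, p$n2, p$y2)
    ),
    error = function(e) stop(where, ": ", conditionMessage(e), call. = FALSE)
  )
  structure(
    list(trial_id = as.character(rec$trial_id),
         outcome = as.character(rec$outcome),
         subgroup = if (is.null(rec$subgroup) || is.na(rec$subgroup[1])) {
           NA_character_
         } else {
           as.character(rec$subgroup)
         },
         outcome_kind = kind, direction = direction, payload = payload,
         notes = as.character(rec$notes %||% "")),
    class = "comparison_record"
  )
}

.record_key <- function(r) {
  paste(r$trial_id, r$outcome,
        ifelse(is.na(r$subgroup), "", r$subgroup), sep = "|")
}

#' Read a reanalysis configuration
#'
#' Reads trial comparisons from a JSON file (canonical dialect: an object
#' with a `comparisons` array) or a flat CSV (one comparison per row, with
#' payload fields `n1`, `n2`, `y1`, `y2`, `ratio`, `ci_lower`, `ci_upper`,
#' `level`, `mean1`, `sd1`, `median1`, `q1_1`, `q3_1` and the `2`
#' counterparts, empty where not applicable). Every record is validated;
#' all violations are reported together with record locators.
#'
#' @param path Path to a `.json` or `.csv` config.
#' @return List of `"comparison_record"` objects.
#' @seealso [run_reanalysis()], [remdesivir_trials()]
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = {
      cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
      cfg$comparisons %||% stop("config has no 'comparisons' array",
                                call. = FALSE)
    },
    csv = .csv_to_record_lists(utils::read.csv(path, stringsAsFactors = FALSE)),
    stop("unsupported config format: .", ext, call. = FALSE)
  )
  if (length(raw) == 0L) stop("config contains no comparisons", call. = FALSE)
  errors <- character(0)
  records <- vector("list", length(raw))
  for (i in seq_along(raw)) {
    where <- sprintf("record %d (%s)", i,
                     as.character(raw[[i]]$trial_id %||% "?"))
    records[[i]] <- tryCatch(.build_record(raw[[i]], where),
                             error = function(e) {
                               errors <<- c(errors, conditionMessage(e))
                               NULL
                             })
  }
  if (length(errors) > 0L) {
    stop("invalid config:\n  ", paste(errors, collapse = "\n  "),
         call. = FALSE)
  }
  keys <- vapply(records, .record_key, character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate trial_id/outcome/subgroup: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "),
         call. = FALSE)
  }
  records
}

.csv_na <- function(x) if (is.null(x) || is.na(x)) NULL else x

.csv_to_record_lists <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, , drop = FALSE]
    g <- function(col) .csv_na(row[[col]])
    kind <- as.character(row$outcome_kind)
    payload <- if (identical(kind, "binary_counts")) {
      list(n1 = g("n1"), y1 = g("y1"), n2 = g("n2"), y2 = g("y2"))
    } else if (identical(kind, "ratio_ci")) {
      list(ratio = g("ratio"), ci_lower = g("ci_lower"),
           ci_upper = g("ci_upper"), level = g("level"),
           n1 = g("n1"), n2 = g("n2"))
    } else {
      list(arm1 = list(n = g("n1"), mean = g("mean1"), sd = g("sd1"),
                       median = g("median1"), q1 = g("q1_1"), q3 = g("q3_1")),
           arm2 = list(n = g("n2"), mean = g("mean2"), sd = g("sd2"),
                       median = g("median2"), q1 = g("q1_2"), q3 = g("q3_2")))
    }
    list(trial_id = g("trial_id"), outcome = g("outcome"),
         subgroup = g("subgroup"), outcome_kind = kind,
         direction = g("direction"), payload = payload, notes = g("notes"))
  })
}

# Serialize a comparison_record back to the plain-list canonical form.
.record_to_list <- function(r) {
  payload <- switch(r$outcome_kind,
    continuous_summary = {
      arm_fields <- function(a) {
        out <- list(label = a$label, n = a$n)
        for (f in c("mean", "sd", "median", "q1", "q3")) {
          if (!is.null(a[[f]])) out[[f]] <- a[[f]]
        }
        out
      }
      list(arm1 = arm_fields(r$payload$arm1), arm2 = arm_fields(r$payload$arm2))
    },
    ratio_ci = r$payload[c("ratio", "ci_lower", "ci_upper", "level",
                           "n1", "n2")],
    binary_counts = r$payload[c("n1", "y1", "n2", "y2")]
  )
  list(trial_id = r$trial_id, outcome = r$outcome,
       subgroup = if (is.na(r$subgroup)) NULL else r$subgroup,
       outcome_kind = r$outcome_kind, direction = r$direction,
       payload = payload, notes = r$notes)
}

#' Write a reanalysis configuration (canonical JSON)
#'
#' Serializes validated records back to the canonical JSON dialect. The
#' output is canonical in the sense that writing, re-reading and writing
#' again is byte-stable.
#'
#' @param records List of `"comparison_record"` objects.
#' @param path Output `.json` path.
#' @export
write_config <- function(records, path) {
  payloads <- lapply(records, .record_to_list)
  json <- jsonlite::toJSON(list(comparisons = payloads), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Options controlling a reanalysis run
#'
#' @param scale Cauchy prior scale for the t-statistic path.
#' @param contingency_variant `"indep_binomial"` (default) or
#'   `"gd_indep_multinomial"`; see [mortality_bf()].
#' @param sensitivity If `TRUE`, a prior sensitivity curve is computed per
#'   comparison and its stability reported.
#' @param scales Grid for the sensitivity curve.
#' @return List of class `"reanalysis_options"`.
#' @export
reanalysis_options <- function(scale = sqrt(2) / 2,
                               contingency_variant = c("indep_binomial",
                                                       "gd_indep_multinomial"),
                               sensitivity = TRUE,
                               scales = default_scale_grid()) {
  structure(
    list(scale = assert_positive_scalar(scale, "scale"),
         contingency_variant = match.arg(contingency_variant),
         sensitivity = isTRUE(sensitivity),
         scales = scales),
    class = "reanalysis_options"
  )
}

# Analyze a single record; returns a one-row data frame.
.analyze_record <- function(r, options) {
  notes <- r$notes
  add_note <- function(txt) {
    if (nzchar(txt)) notes <<- paste(Filter(nzchar, c(notes, txt)),
                                     collapse = "; ")
  }
  if (r$outcome_kind == "binary_counts") {
    res <- mortality_bf(r$payload, variant = options$contingency_variant)
    prior_txt <- sprintf("Beta(%g,%g) per arm [%s]", r$payload$prior_a,
                         r$payload$prior_a, options$contingency_variant)
    sens_obj <- if (options$sensitivity) {
      sensitivity_curve(r$payload, scales = options$scales,
                        analysis_id = .record_key(r),
                        variant = options$contingency_variant)
    }
  } else {
    cmp <- if (r$outcome_kind == "ratio_ci") {
      t_from_ratio_ci(r$payload,
                      benefit = sub("benefit_", "", r$direction))
    } else {
      cmp0 <- t_from_arm_summaries(r$payload$arm1, r$payload$arm2)
      if (r$direction == "benefit_lower") cmp0$t <- -cmp0$t
      cmp0
    }
    add_note(cmp$note)
    res <- jzs_bf01(cmp, prior = prior_spec(options$scale))
    prior_txt <- sprintf("Cauchy(0, %.4f)", options$scale)
    sens_obj <- if (options$sensitivity) {
      sensitivity_curve(cmp, scales = options$scales,
                        analysis_id = .record_key(r))
    }
  }
  stable <- if (is.null(sens_obj)) NA else robustness_summary(sens_obj)$stable
  data.frame(
    trial_id = r$trial_id, outcome = r$outcome, subgroup = r$subgroup,
    test = res$test, prior = prior_txt,
    bf01 = res$bf01, bf10 = res$bf10, bf01_display = format_bf(res$bf01),
    category = res$category, sensitivity_stable = stable,
    notes = notes, error = NA_character_, stringsAsFactors = FALSE
  )
}

.failed_row <- function(r, msg) {
  data.frame(
    trial_id = r$trial_id, outcome = r$outcome, subgroup = r$subgroup,
    test = NA_character_, prior = NA_character_,
    bf01 = NA_real_, bf10 = NA_real_, bf01_display = NA_character_,
    category = NA_character_, sensitivity_stable = NA,
    notes = r$notes, error = msg, stringsAsFactors = FALSE
  )
}

#' Run the Bayesian reanalysis over a set of comparisons
#'
#' Dispatches every comparison record through the reconstruction and Bayes
#' factor path matching its `outcome_kind`, independently of all other
#' records, and returns one results row per record. Per-record failures are
#' captured in the `error` column (remaining records still run); the number
#' of failures is attached as attribute `"n_failed"`.
#'
#' @param records List of `"comparison_record"` objects from [read_config()].
#' @param options A [reanalysis_options()].
#' @return A `data.frame` (class `"reanalysis_results"`) with columns
#'   `trial_id`, `outcome`, `subgroup`, `test`, `prior`, `bf01`, `bf10`,
#'   `bf01_display`, `category`, `sensitivity_stable`, `notes`, `error`.
#' @export
#' @examples
#' records <- remdesivir_trials()
#' res <- run_reanalysis(records[1:3])
#' res[, c("trial_id", "outcome", "bf01_display", "category")]
run_reanalysis <- function(records, options = reanalysis_options()) {
  stopifnot(is.list(records), length(records) >= 1L)
  rows <- lapply(records, function(r) {
    tryCatch(.analyze_record(r, options),
             error = function(e) .failed_row(r, conditionMessage(e)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("reanalysis_results", "data.frame")
  attr(out, "n_failed") <- sum(!is.na(out$error))
  out
}

.results_columns <- c("trial_id", "outcome", "subgroup", "test", "prior",
                      "bf01", "bf10", "bf01_display", "category",
                      "sensitivity_stable", "notes", "error")

#' Write a reanalysis results table
#'
#' Writes results with a stable column order. Bayes factors are serialized
#' at 4 significant figures; the `bf01_display` column carries the
#' 2-figure display rendering of [format_bf()].
#'
#' @param rows A `"reanalysis_results"` data frame.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @export
write_results <- function(rows, path, format = c("csv", "json")) {
  format <- match.arg(format)
  out <- as.data.frame(rows)[, .results_columns, drop = FALSE]
  out$bf01 <- signif(out$bf01, 4)
  out$bf10 <- signif(out$bf10, 4)
  if (format == "csv") {
    utils::write.csv(out, path, row.names = FALSE, na = "")
  } else {
    jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' The packaged remdesivir trial comparisons
#'
#' Loads the configuration shipped with the package: the summary statistics
#' of the six remdesivir COVID-19 trials (ACTT-1 preliminary and final
#' reports, Wang et al., GS-US-540-5773, GS-US-540-5774, WHO Solidarity) as
#' transcribed from the trial publications -- recovery/improvement ratio
#' estimates with confidence intervals and per-arm death or response
#' counts, including the early-treatment (Wang) and no-ventilation
#' (Solidarity) subgroups.
#'
#' @return List of `"comparison_record"` objects, ready for
#'   [run_reanalysis()].
#' @export
#' @examples
#' length(remdesivir_trials())
remdesivir_trials <- function() {
  read_config(system.file("extdata", "remdesivir_trials.json",
                          package = "trialbf", mustWork = TRUE))
}
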