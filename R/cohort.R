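# Cohort data model, validation, I/O, flow accounting and baseline summaries.
#
# A semi-competing-risks record holds two (time, indicator) pairs per subject:
# (y1, delta1) for the non-terminal event (e.g. AD/ADRD diagnosis) and
# (y2, delta2) for the terminal event (death).  Observation of the
# non-terminal event ends at death or censoring, never the other way round,
# so valid records live on the wedge y1 <= y2, and a subject whose
# non-terminal event was not observed must have y1 == y2.

#' Construct a validated semi-competing-risks cohort
#'
#' Checks every row against the semi-competing-risks constraints and drops
#' (while counting) rows that violate them:
#' * times positive and finite, indicators in \{0, 1\};
#' * `y1 <= y2`;
#' * `delta1 == 0` implies `y1 == y2` (if the non-terminal event was not
#'   observed, observation of it ended exactly when follow-up ended).
#'
#' @param data data.frame with columns `id`, `y1`, `delta1`, `y2`, `delta2`
#'   followed by covariate columns (numeric after encoding).
#' @param covariate_names covariate columns to use; defaults to every column
#'   after the five core fields.
#' @param encoding_map optional named list recording how categorical fields
#'   were expanded to indicators (kept for reporting; reference levels etc.).
#' @return an object of class `cohort_table`: list with elements `data`
#'   (validated rows), `covariate_names`, `encoding_map`, `n_excluded_invalid`
#'   and `exclusions` (a data.frame of dropped row indices and reasons).
#' @export
as_cohort <- function(data, covariate_names = NULL, encoding_map = NULL) {
  stopifnot(is.data.frame(data))
  core <- c("id", "y1", "delta1", "y2", "delta2")
  missing_cols <- setdiff(core, names(data))
  if (length(missing_cols))
    stop_scr("missing required column(s): %s", paste(missing_cols, collapse = ", "),
             class = "schema_error")
  if (is.null(covariate_names))
    covariate_names <- setdiff(names(data), core)
  if (!all(covariate_names %in% names(data)))
    stop_scr("covariate column(s) not found: %s",
             paste(setdiff(covariate_names, names(data)), collapse = ", "),
             class = "schema_error")
  data <- data[, c(core, covariate_names), drop = FALSE]

  for (col in c("y1", "y2", "delta1", "delta2", covariate_names)) {
    if (!is.numeric(data[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(data[[col]])))))
      stop_scr("column '%s' is not numeric (first offending row: %d)",
               col, if (length(bad)) bad[1] else 1L, class = "parse_error")
    }
  }
  if (anyDuplicated(data$id))
    stop_scr("subject ids are not unique", class = "schema_error")

  reason <- rep(NA_character_, nrow(data))
  bad_time <- !is.finite(data$y1) | !is.finite(data$y2) | data$y1 <= 0 | data$y2 <= 0
  reason[bad_time] <- "nonpositive or nonfinite time"
  bad_ind <- !(data$delta1 %in% c(0, 1)) | !(data$delta2 %in% c(0, 1))
  reason[is.na(reason) & bad_ind] <- "indicator not in {0,1}"
  bad_wedge <- is.na(reason) & data$y1 > data$y2
  reason[bad_wedge] <- "y1 > y2"
  bad_cens <- is.na(reason) & data$delta1 == 0 & data$y1 < data$y2
  reason[bad_cens] <- "delta1 = 0 with y1 < y2"

  keep <- is.na(reason)
  exclusions <- data.frame(row = which(!keep), id = data$id[!keep],
                           reason = reason[!keep], stringsAsFactors = FALSE)
  out <- list(
    data = data[keep, , drop = FALSE],
    covariate_names = covariate_names,
    encoding_map = encoding_map,
    n_excluded_invalid = sum(!keep),
    exclusions = exclusions
  )
  rownames(out$data) <- NULL
  class(out) <- "cohort_table"
  out
}

#' Read a semi-competing-risks cohort from delimited text
#'
#' Expects a CSV with a header row and columns `id, y1, delta1, y2, delta2`
#' followed by covariates.  `schema` remaps nonstandard column names,
#' e.g. `list(y1 = "days_to_adrd", delta1 = "adrd")`.
#'
#' Rows violating the semi-competing-risks constraints are dropped and
#' counted in `n_excluded_invalid` (mirroring a cohort-selection exclusion
#' step); structural problems (missing columns, non-numeric times, an empty
#' file) are errors.
#'
#' @param path CSV file path.
#' @param schema optional named list mapping canonical field names to column
#'   names in the file.
#' @param covariate_names optional explicit covariate subset.
#' @return a [as_cohort()] `cohort_table`.
#' @export
read_cohort <- function(path, schema = NULL, covariate_names = NULL) {
  if (!file.exists(path))
    stop_scr("file not found: %s", path, class = "io_error")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L)
    stop_scr("empty cohort: %s has a header but no rows", path,
             class = "empty_cohort_error")
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(raw))
        stop_scr("schema maps '%s' to missing column '%s'", canon, src,
                 class = "schema_error")
      names(raw)[names(raw) == src] <- canon
    }
  }
  as_cohort(raw, covariate_names = covariate_names)
}

#' Write a cohort back to CSV
#'
#' Times are written at full double precision (17 significant digits) so a
#' write/read round trip reproduces every field bit-exactly.
#'
#' @param cohort a `cohort_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  df <- cohort$data
  for (col in names(df))
    if (is.double(df[[col]])) df[[col]] <- sprintf("%.17g", df[[col]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Covariate matrix of a cohort
#' @param cohort a `cohort_table`.
#' @return numeric matrix (n x p) with covariates as columns.
#' @export
covariate_matrix <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  as.matrix(cohort$data[, cohort$covariate_names, drop = FALSE])
}

#' Cohort-flow counts
#'
#' Tallies the flow-diagram quantities of a cohort selection: total analysed,
#' split by whether the non-terminal event occurred, deaths within each
#' group, and the number of rows excluded at validation.
#'
#' @param cohort a `cohort_table`.
#' @return object of class `flow_counts` (named list).
#' @export
flow_counts <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  d <- cohort$data
  ill <- d$delta1 == 1
  out <- list(
    n_total = nrow(d),
    n_nonterminal = sum(ill),
    n_no_nonterminal = sum(!ill),
    n_death_given_nonterminal = sum(d$delta2[ill] == 1),
    n_death_given_no_nonterminal = sum(d$delta2[!ill] == 1),
    n_excluded_invalid = cohort$n_excluded_invalid
  )
  class(out) <- "flow_counts"
  out
}

#' @export
print.flow_counts <- function(x, ...) {
  cat("Cohort flow\n")
  cat(sprintf("  analysed:                 %d (after excluding %d invalid)\n",
              x$n_total, x$n_excluded_invalid))
  cat(sprintf("  non-terminal event:       %d (%d of whom died)\n",
              x$n_nonterminal, x$n_death_given_nonterminal))
  cat(sprintf("  no non-terminal event:    %d (%d of whom died)\n",
              x$n_no_nonterminal, x$n_death_given_no_nonterminal))
  invisible(x)
}

#' Baseline-characteristics table by outcome group
#'
#' Summarises each covariate separately for subjects who did and did not
#' experience the non-terminal event: binary covariates as count (percent),
#' continuous ones as mean (SD).  Death (`delta2`) is appended as a final
#' binary row.  An empty group is marked explicitly rather than producing
#' NaN percentages.
#'
#' @param cohort a `cohort_table`.
#' @return data.frame of class `baseline_summary` with columns `variable`,
#'   `stat_no_event`, `stat_event` and numeric backing columns
#'   `value_no_event`, `value_event` (percent or mean); group sizes in
#'   attributes `n_no_event`, `n_event`.
#' @export
baseline_table <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  d <- cohort$data
  grp <- d$delta1 == 1
  n1 <- sum(!grp); n2 <- sum(grp)

  summarise_one <- function(x, sel, n) {
    if (n == 0L) return(list(label = "(empty group)", value = NA_real_))
    x <- x[sel]
    if (is_binary01(x)) {
      k <- sum(x == 1); pct <- 100 * k / n
      list(label = sprintf("%d (%.1f%%)", k, pct), value = pct)
    } else {
      list(label = sprintf("%.1f (%.1f)", mean(x), stats::sd(x)), value = mean(x))
    }
  }

  vars <- c(cohort$covariate_names, "death")
  rows <- lapply(vars, function(v) {
    x <- if (v == "death") d$delta2 else d[[v]]
    a <- summarise_one(x, !grp, n1)
    b <- summarise_one(x, grp, n2)
    data.frame(variable = v,
               stat_no_event = a$label, stat_event = b$label,
               value_no_event = a$value, value_event = b$value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_no_event") <- n1
  attr(out, "n_event") <- n2
  class(out) <- c("baseline_summary", "data.frame")
  out
}

#' @export
print.baseline_summary <- function(x, ...) {
  cat(sprintf("Baseline characteristics (no event: N = %d; event: N = %d)\n",
              attr(x, "n_no_event"), attr(x, "n_event")))
  print.data.frame(x[, c("variable", "stat_no_event", "stat_event")],
                   row.names = FALSE)
  invisible(x)
}

#' Reference baseline profile of a large MCI cohort
#'
#' Ships the baseline-characteristics counts of a real-world cohort of
#' 33,661 mild-cognitive-impairment patients (27,771 without and 5,890 with
#' a subsequent AD/ADRD diagnosis), split by outcome group.  Used to
#' calibrate the synthetic generator's default covariate prevalences and in
#' consistency checks of the summary arithmetic.
#'
#' @return data.frame with columns `variable`, `level`, `type`, per-group
#'   counts and (for continuous variables) means and SDs.
#' @export
reference_counts <- function() {
  path <- system.file("extdata", "mci_reference_counts.csv",
                      package = "semicompete", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Pooled covariate prevalences from the reference profile
#'
#' Collapses the two outcome groups of [reference_counts()] into cohort-wide
#' marginal frequencies (binary and categorical) and pooled means/SDs
#' (continuous).  The outcome rows (`death`) are dropped: they are outcomes,
#' not baseline covariates.
#'
#' @return data.frame with columns `variable`, `level`, `type`, `prob`
#'   (binary/categorical) and `mean`, `sd` (continuous).
#' @export
reference_prevalences <- function() {
  rc <- reference_counts()
  sizes <- rc[rc$type == "size", ]
  n1 <- sizes$n_no_event; n2 <- sizes$n_event
  n <- n1 + n2
  rc <- rc[!rc$type %in% c("size") & rc$variable != "death", ]
  prob <- ifelse(rc$type %in% c("binary", "categorical"),
                 (rc$n_no_event + rc$n_event) / n, NA_real_)
  # pooled mean and pooled (within-group) SD inflated by the between-group
  # mean spread, i.e. the SD of the mixture distribution
  w1 <- n1 / n; w2 <- n2 / n
  mix_mean <- w1 * rc$mean_no_event + w2 * rc$mean_event
  mix_var <- w1 * (rc$sd_no_event^2 + (rc$mean_no_event - mix_mean)^2) +
    w2 * (rc$sd_event^2 + (rc$mean_event - mix_mean)^2)
  data.frame(variable = rc$variable, level = rc$level, type = rc$type,
             prob = prob, mean = mix_mean, sd = sqrt(mix_var),
             stringsAsFactors = FALSE)
}
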