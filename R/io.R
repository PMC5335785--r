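# CSV input/output for long-format rating tables, trial metadata, and
# result reports. One judgement per row keeps the schema stable across
# variable rater counts and stages (individual vs consensus).

RATINGS_COLS <- c("trial_id", "domain", "assessor_id", "group", "stage",
                  "rating")
META_COLS <- c("trial_id", "publication_year", "min_per_arm")
REPORT_COLS <- c("domain", "design", "comparison", "kappa", "ci_low",
                 "ci_high", "band", "p_value", "estimable")

#' Read a long-format ratings table
#'
#' Expected columns: `trial_id, domain, assessor_id, group, stage, rating`.
#' Ratings are matched case-insensitively against `{low, unclear, high}`;
#' domains against the six-domain vocabulary; `group` against
#' `{minimal, intensive, reference}` and `stage` against
#' `{individual, consensus}`. `(trial_id, domain, assessor_id, stage)` must
#' be unique.
#'
#' @param path CSV file path.
#' @return A data.frame of validated rating records, in file order, with
#'   `rating` and `domain` as factors over the full vocabularies.
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_ratings(df)
}

validate_ratings <- function(df) {
  missing <- setdiff(RATINGS_COLS, names(df))
  if (length(missing)) {
    stop("ratings table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[RATINGS_COLS]
  df$rating <- as_rating(df$rating)
  df$domain <- tolower(trimws(df$domain))
  bad <- !(df$domain %in% BIAS_DOMAINS)
  if (any(bad)) {
    stop(sprintf("unknown domain(s) %s at row(s) %s; allowed: {%s}",
                 paste(unique(df$domain[bad]), collapse = ", "),
                 paste(utils::head(which(bad), 5L), collapse = ", "),
                 paste(BIAS_DOMAINS, collapse = ", ")), call. = FALSE)
  }
  df$domain <- factor(df$domain, levels = BIAS_DOMAINS)
  for (col in c("group", "stage")) {
    vocab <- if (col == "group") RATER_GROUPS else RATING_STAGES
    df[[col]] <- tolower(trimws(df[[col]]))
    bad <- !(df[[col]] %in% vocab)
    if (any(bad)) {
      stop(sprintf("unknown %s value(s) %s; allowed: {%s}", col,
                   paste(unique(df[[col]][bad]), collapse = ", "),
                   paste(vocab, collapse = ", ")), call. = FALSE)
    }
  }
  key <- paste(df$trial_id, df$domain, df$assessor_id, df$stage, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf(
      "duplicate record for (trial %s, domain %s, assessor %s, stage %s)",
      d$trial_id, d$domain, d$assessor_id, d$stage), call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Write a ratings table to CSV
#'
#' Canonical lowercase labels; round-trips through [read_ratings()]
#' without loss.
#'
#' @param ratings Data.frame of rating records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(ratings, path) {
  ratings <- validate_ratings(as.data.frame(ratings))
  out <- ratings
  out$rating <- as.character(out$rating)
  out$domain <- as.character(out$domain)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read trial metadata
#'
#' Expected columns: `trial_id, publication_year, min_per_arm` (the number
#' of patients randomized to the smallest trial arm). One row per trial.
#'
#' @param path CSV file path.
#' @return Data.frame of validated trial metadata.
#' @export
read_trial_meta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trial_meta(df)
}

validate_trial_meta <- function(df) {
  missing <- setdiff(META_COLS, names(df))
  if (length(missing)) {
    stop("metadata table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[META_COLS]
  if (anyDuplicated(df$trial_id)) {
    stop("duplicate trial_id in metadata: ",
         df$trial_id[duplicated(df$trial_id)][1L], call. = FALSE)
  }
  for (col in c("publication_year", "min_per_arm")) {
    v <- df[[col]]
    if (!is.numeric(v) || any(is.na(v)) || any(v != round(v))) {
      stop(col, " must be integer-valued", call. = FALSE)
    }
    df[[col]] <- as.integer(v)
  }
  if (any(df$publication_year < 1900)) {
    stop("publication_year must be >= 1900", call. = FALSE)
  }
  if (any(df$min_per_arm < 1)) {
    stop("min_per_arm must be >= 1", call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Assign stratification levels to trials
#'
#' Two stratifiers: publication period relative to the CONSORT 2010
#' statement (`pre2010` iff `publication_year < 2010`) and trial size
#' (`large` iff at least 50 patients were randomized per trial arm, taken
#' as the smallest arm).
#'
#' @param meta Validated trial metadata data.frame.
#' @return `meta` with factor columns `publication_period`
#'   (`pre2010`/`post2010`) and `trial_size` (`small`/`large`) appended.
#' @export
assign_strata <- function(meta) {
  meta <- validate_trial_meta(meta)
  meta$publication_period <- factor(
    ifelse(meta$publication_year < 2010, "pre2010", "post2010"),
    levels = c("pre2010", "post2010")
  )
  meta$trial_size <- factor(
    ifelse(meta$min_per_arm >= 50, "large", "small"),
    levels = c("small", "large")
  )
  meta
}

#' Write a study-results report
#'
#' Writes the per-domain kappa results of a study to a machine-readable
#' CSV (columns `domain, design, comparison, kappa, ci_low, ci_high, band,
#' p_value, estimable`) and a human-readable text summary alongside it.
#' Not-estimable entries are rendered as the literal `NE`.
#'
#' @param results A `"rob_study"` object from [run_study()], or a
#'   data.frame already in report layout.
#' @param path Output CSV path; the text summary goes to the same path
#'   with extension `.txt`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  df <- if (inherits(results, "rob_study")) as.data.frame(results)
        else as.data.frame(results)
  if (nrow(df) == 0L) stop("no results to report", call. = FALSE)
  missing <- setdiff(REPORT_COLS, names(df))
  if (length(missing)) {
    stop("report missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- df[REPORT_COLS]
  fmt <- function(x) ifelse(is.na(x), "NE", format(x, digits = 15))
  for (col in c("kappa", "ci_low", "ci_high", "p_value")) {
    out[[col]] <- fmt(out[[col]])
  }
  out$estimable <- ifelse(df$estimable, "true", "false")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)

  txt_path <- sub("\\.csv$", ".txt", path)
  if (identical(txt_path, path)) txt_path <- paste0(path, ".txt")
  lines <- c("Risk-of-bias reliability report", "")
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    lines <- c(lines, sprintf(
      "%-25s %-8s %-22s kappa=%s CI=(%s, %s) band=%s p=%s",
      r$domain, r$design, r$comparison,
      if (is.na(r$kappa)) "NE" else sprintf("%.3f", r$kappa),
      if (is.na(r$ci_low)) "NE" else sprintf("%.3f", r$ci_low),
      if (is.na(r$ci_high)) "NE" else sprintf("%.3f", r$ci_high),
      r$band,
      if (is.na(r$p_value)) "NE" else format.pval(r$p_value, digits = 3)
    ))
  }
  writeLines(lines, txt_path)
  invisible(path)
}

#' Read a study-results report CSV back
#'
#' Inverse of the CSV half of [write_report()]; `NE` entries become `NA`
#' with `estimable = FALSE`.
#'
#' @param path Report CSV path.
#' @return Data.frame in report layout.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(REPORT_COLS, names(df))
  if (length(missing)) {
    stop("report missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("kappa", "ci_low", "ci_high", "p_value")) {
    df[[col]] <- suppressWarnings(
      ifelse(df[[col]] == "NE", NA_real_, as.numeric(df[[col]]))
    )
  }
  df$estimable <- df$estimable == "true"
  df
}
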