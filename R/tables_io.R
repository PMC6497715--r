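# CSV I/O for behavioral trial tables and detected-event tables.
#
# Trial schema: trial_id, stim_time_s, rt_ms, outcome (S/F) [, valid].
# Event schema: event_id, area, t_neg_s, t_pos_prev_s, t_pos_next_s,
#   amplitude_z, globality_pct, involved_channels (';'-joined labels).

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stopf("%s: missing required column: %s", what,
          paste(missing, collapse = ", "))
}

check_numeric_col <- function(df, col, what) {
  v <- df[[col]]
  if (is.numeric(v)) return(v)
  parsed <- suppressWarnings(as.numeric(v))
  bad <- which(is.na(parsed) & !is.na(v) & trimws(v) != "")
  if (length(bad) > 0)
    stopf("%s: non-numeric value in column '%s' at row %d ('%s')",
          what, col, bad[1], v[bad[1]])
  parsed
}

#' Read a behavioral trial table
#'
#' @param path CSV file with columns `trial_id`, `stim_time_s`, `rt_ms`,
#'   `outcome` (values `S`/`F`) and optional `valid`.
#' @return A data frame of trial records with a logical `valid` column
#'   (`NA` until [filter_rts()] is applied, unless present in the file).
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("trial_id", "stim_time_s", "rt_ms", "outcome"), "trials")
  df$stim_time_s <- check_numeric_col(df, "stim_time_s", "trials")
  df$rt_ms <- check_numeric_col(df, "rt_ms", "trials")
  bad_out <- which(!df$outcome %in% c("S", "F"))
  if (length(bad_out) > 0)
    stopf("trials: outcome must be S or F (row %d: '%s')",
          bad_out[1], df$outcome[bad_out[1]])
  if (is.null(df$valid)) df$valid <- NA
  df$valid <- as.logical(df$valid)
  df
}

#' Write a behavioral trial table
#'
#' @param trials Data frame as returned by [read_trials()] or [gen_trials()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  check_columns(trials, c("trial_id", "stim_time_s", "rt_ms", "outcome"),
                "trials")
  write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

event_cols <- c("event_id", "area", "t_neg_s", "t_pos_prev_s", "t_pos_next_s",
                "amplitude_z", "globality_pct", "involved_channels")

#' Write a detected-event table
#'
#' Involved-channel sets are serialised as `;`-joined label strings and
#' survive a write/read roundtrip exactly.
#'
#' @param events Event data frame from [detect_all()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  check_columns(events, event_cols, "events")
  write.csv(events[, event_cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a detected-event table
#'
#' @param path CSV written by [write_events()].
#' @return Event data frame.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(involved_channels = "character"))
  check_columns(df, event_cols, "events")
  for (col in c("t_neg_s", "t_pos_prev_s", "t_pos_next_s", "amplitude_z",
                "globality_pct"))
    df[[col]] <- check_numeric_col(df, col, "events")
  df
}

#' Split an involved-channel string into labels
#'
#' @param s Character vector of `;`-joined label strings.
#' @return List of character vectors.
#' @export
involved_labels <- function(s) strsplit(s, ";", fixed = TRUE)
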