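.event_kinds <- c("poke_in", "poke_out", "receptacle_in", "receptacle_out",
                  "stim_on", "stim_off", "reward", "timeout_start",
                  "timeout_end", "session_end")

# kinds whose `arg` column must carry a hole index 1..5
.hole_kinds <- c("poke_in", "poke_out", "stim_on", "stim_off")

#' Read an operant session event log
#'
#' The log dialect is a minimal CSV with columns `time_s` (seconds from session
#' start, decimal), `event` (one of `poke_in`, `poke_out`, `receptacle_in`,
#' `receptacle_out`, `stim_on`, `stim_off`, `reward`, `timeout_start`,
#' `timeout_end`, `session_end`) and `arg` (hole index 1-5 for poke and
#' stimulus events, empty otherwise). Events are sorted stably by time;
#' timestamps may decrease by at most 1 ms (merge tolerance for equal-time
#' events).
#'
#' @param path Path to the event-log CSV.
#' @return A tibble of class `session_log` with columns `time_s`, `event`,
#'   `arg`.
#' @export
read_session_log <- function(path) {
  tbl <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(
                           time_s = readr::col_double(),
                           event = readr::col_character(),
                           arg = readr::col_integer()
                         ))
  .require_cols(tbl, c("time_s", "event"), path)
  if (!"arg" %in% names(tbl)) tbl$arg <- NA_integer_
  session_log(tbl$time_s, tbl$event, tbl$arg, source = path)
}

#' Construct and validate a session log
#'
#' @param time_s Numeric event times, seconds from session start.
#' @param event Character event kinds (see [read_session_log()]).
#' @param arg Integer hole index 1-5 where applicable, else `NA`.
#' @param source Optional provenance string used in error messages.
#' @return A `session_log` tibble, stably sorted by time.
#' @export
session_log <- function(time_s, event, arg = NA_integer_, source = "session log") {
  n <- length(time_s)
  tbl <- tibble(time_s = as.numeric(time_s), event = as.character(event),
                arg = as.integer(rep_len(arg, n)))
  bad_kind <- which(!tbl$event %in% .event_kinds)
  if (length(bad_kind)) {
    abort(sprintf("%s: unknown event kind '%s' at line %d",
                  source, tbl$event[bad_kind[1]], bad_kind[1] + 1L),
          class = "impulscreen_format_error")
  }
  if (n > 1) {
    drops <- diff(tbl$time_s)
    if (any(drops < -.time_tol)) {
      i <- which(drops < -.time_tol)[1]
      abort(sprintf("%s: timestamps decrease by %.4f s at line %d",
                    source, -drops[i], i + 2L),
            class = "impulscreen_validation_error")
    }
  }
  needs_hole <- tbl$event %in% .hole_kinds
  if (any(needs_hole & is.na(tbl$arg))) {
    i <- which(needs_hole & is.na(tbl$arg))[1]
    abort(sprintf("%s: event '%s' at line %d lacks a hole index",
                  source, tbl$event[i], i + 1L),
          class = "impulscreen_format_error")
  }
  if (any(!needs_hole & !is.na(tbl$arg))) {
    i <- which(!needs_hole & !is.na(tbl$arg))[1]
    abort(sprintf("%s: event '%s' at line %d must not carry a hole index",
                  source, tbl$event[i], i + 1L),
          class = "impulscreen_format_error")
  }
  if (any(needs_hole & (tbl$arg < 1L | tbl$arg > 5L), na.rm = TRUE)) {
    abort(sprintf("%s: hole index out of range 1-5", source),
          class = "impulscreen_validation_error")
  }
  tbl <- tbl[order(tbl$time_s, method = "radix"), , drop = FALSE]
  class(tbl) <- c("session_log", class(tbl))
  tbl
}

#' Write a session log to CSV
#'
#' @param log A `session_log` tibble.
#' @param path Output path.
#' @param config_hash Optional hash stamped into the comment header.
#' @return Invisibly, `path`.
#' @export
write_session_log <- function(log, path, config_hash = NULL) {
  .write_commented_table(as_tibble(log)[, c("time_s", "event", "arg")],
                         path, config_hash, delim = ",")
}

#' Write a gene-screen report
#'
#' One row per gene x comparison, all statistics and pass flags, ordered by
#' comparison name then descending `diff_mean` (rank within comparison).
#' Numbers survive a TSV round-trip to at least 6 significant digits.
#'
#' @param records Screen record tibble from [screen_comparison()] or
#'   [screen_grid()].
#' @param path Output TSV path.
#' @param config_hash Optional hash stamped into the comment header.
#' @return Invisibly, `path`.
#' @export
write_screen_report <- function(records, path, config_hash = NULL) {
  records <- as_tibble(records)
  if (nrow(records)) {
    records <- records %>%
      arrange(.data$comparison, desc(.data$diff_mean), .data$gene)
  }
  .write_commented_table(records, path, config_hash, delim = "\t")
}

#' Read back a gene-screen report
#'
#' @param path TSV written by [write_screen_report()].
#' @return A tibble of screen records.
#' @export
read_screen_report <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}
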