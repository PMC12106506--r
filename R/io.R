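trial_log_columns <- c("participant", "condition", "block", "trial", "soa_ms",
                       "audio_delay_ms", "video_delay_ms", "response", "rejected")

#' Write a trial log
#'
#' Long-format CSV, one row per trial, UTF-8, comma-separated, LF endings.
#' Missing responses are written as empty fields.
#'
#' @param trials Trial data frame ([build_design()] dialect).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  stopifnot(all(trial_log_columns %in% names(trials)))
  out <- trials[, trial_log_columns]
  out$rejected <- as.integer(out$rejected)
  con <- file(path, open = "wb")  # LF endings on every platform
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a trial log
#'
#' Validates the header and every row: `soa_ms` and delays numeric, responses
#' in \{0, 1\} (empty allowed only for design-only files), `rejected` in
#' \{0, 1\}. Malformed rows abort with their line numbers, or are dropped
#' with a warning under `permissive = TRUE`.
#'
#' @param path CSV file in the trial-log dialect.
#' @param allow_missing_response Permit empty response fields (design-only
#'   logs). Default `FALSE`.
#' @param permissive Drop malformed rows (with a warning listing data line
#'   numbers) instead of erroring. Default `FALSE`.
#' @param soa_levels Optional vector of admissible SOA levels; rows with
#'   other levels are malformed.
#' @return Typed trial data frame.
#' @export
read_trials <- function(path, allow_missing_response = FALSE,
                        permissive = FALSE, soa_levels = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  raw <- tryCatch(utils::read.csv(path, colClasses = "character"),
                  error = function(e) {
                    stop(sprintf("empty or unreadable trial log %s: %s",
                                 path, conditionMessage(e)), call. = FALSE)
                  })
  if (nrow(raw) == 0L) stop("empty trial log: no data rows", call. = FALSE)
  if (!identical(sort(names(raw)), sort(trial_log_columns))) {
    stop(sprintf("unexpected header: got [%s], need [%s]",
                 paste(names(raw), collapse = ","),
                 paste(trial_log_columns, collapse = ",")), call. = FALSE)
  }
  suppressWarnings({
    block <- as.integer(raw$block)
    trial <- as.integer(raw$trial)
    soa <- as.numeric(raw$soa_ms)
    ad <- as.numeric(raw$audio_delay_ms)
    vd <- as.numeric(raw$video_delay_ms)
    resp <- ifelse(raw$response == "", NA, raw$response)
    resp_n <- as.numeric(resp)
    rej <- as.numeric(raw$rejected)
  })
  bad <- is.na(block) | is.na(trial) | is.na(soa) | is.na(ad) | is.na(vd) |
    !(rej %in% c(0, 1)) |
    (!is.na(resp) & !(resp_n %in% c(0, 1))) |
    (is.na(resp) & !allow_missing_response) |
    raw$participant == "" | raw$condition == ""
  if (!is.null(soa_levels)) bad <- bad | !(soa %in% soa_levels)
  if (any(bad)) {
    lines <- which(bad) + 1L  # header is line 1
    if (!permissive) {
      stop(sprintf("malformed row(s) at line(s) %s of %s",
                   paste(utils::head(lines, 20), collapse = ", "), path),
           call. = FALSE)
    }
    warning(sprintf("dropped %d malformed row(s) at line(s) %s",
                    sum(bad), paste(utils::head(lines, 20), collapse = ", ")),
            call. = FALSE)
  }
  keep <- !bad
  data.frame(participant = raw$participant[keep],
             condition = raw$condition[keep],
             block = block[keep], trial = trial[keep], soa_ms = soa[keep],
             audio_delay_ms = ad[keep], video_delay_ms = vd[keep],
             response = as.integer(resp_n[keep]),
             rejected = as.logical(rej[keep]))
}
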