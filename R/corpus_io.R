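#' Write decedent records to JSONL or CSV
#'
#' @param records Data frame of records (one row per decedent).
#' @param path Output file path.
#' @param format `"jsonl"` (one JSON object per line) or `"csv"`
#'   (RFC 4180, UTF-8, header row).
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "jsonl") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    if (nrow(records)) {
      jsonlite::stream_out(records, con, verbose = FALSE, digits = NA,
                           na = "null")
    }
  } else {
    data.table::fwrite(records, path, quote = TRUE, bom = FALSE)
  }
  invisible(path)
}

#' Read decedent records from JSONL or CSV
#'
#' Malformed rows are collected into an error report attached as the
#' `"errors"` attribute rather than silently dropped; if more than 10% of
#' rows are malformed the read fails outright (the file is likely in the
#' wrong dialect).
#'
#' @param path Input file path.
#' @param format `"jsonl"` or `"csv"`.
#' @return Data frame of parsed records, with attribute `errors`: a data
#'   frame of (line, message) for rows that failed to parse or lacked an id.
#' @export
read_records <- function(path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read records: no such file: ", path)
  errors <- data.frame(line = integer(), message = character(),
                       stringsAsFactors = FALSE)
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    idx <- which(nzchar(trimws(lines)))
    # fast path: parse the whole file at once; fall back to per-line parsing
    # (with an error report) only when something in it is malformed
    whole <- tryCatch(
      jsonlite::stream_in(textConnection(lines[idx]), verbose = FALSE),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (!is.null(whole) && !is.null(whole$id) && !anyNA(whole$id)) {
      attr(whole, "errors") <- errors
      return(whole)
    }
    rows <- vector("list", length(idx))
    ok <- logical(length(idx))
    for (k in seq_along(idx)) {
      parsed <- tryCatch(
        jsonlite::fromJSON(lines[idx[k]], simplifyVector = TRUE),
        error = function(e) e
      )
      if (inherits(parsed, "error")) {
        errors <- rbind(errors, data.frame(line = idx[k],
                                           message = conditionMessage(parsed),
                                           stringsAsFactors = FALSE))
      } else if (is.null(parsed$id)) {
        errors <- rbind(errors, data.frame(line = idx[k],
                                           message = "missing id field",
                                           stringsAsFactors = FALSE))
      } else {
        rows[[k]] <- parsed
        ok[k] <- TRUE
      }
    }
    n_total <- length(idx)
    if (n_total > 0 && nrow(errors) / n_total > 0.10) {
      stop(sprintf("%d of %d rows malformed (>10%%); wrong dialect?",
                   nrow(errors), n_total))
    }
    rows <- rows[ok]
    records <- if (length(rows)) {
      data.table::setDF(data.table::rbindlist(
        lapply(rows, function(r) lapply(r, function(v) if (is.null(v)) NA else v)),
        fill = TRUE))
    } else {
      data.frame(id = character(), stringsAsFactors = FALSE)
    }
  } else {
    records <- data.table::setDF(
      data.table::fread(path, colClasses = NULL, na.strings = "NA",
                        encoding = "UTF-8", showProgress = FALSE))
    if (nrow(records)) {
      bad <- which(is.na(records$id) | !nzchar(as.character(records$id)))
      if (length(bad)) {
        errors <- data.frame(line = bad + 1L, message = "missing id field",
                             stringsAsFactors = FALSE)
        if (length(bad) / nrow(records) > 0.10) {
          stop(sprintf("%d of %d rows malformed (>10%%); wrong dialect?",
                       length(bad), nrow(records)))
        }
        records <- records[-bad, , drop = FALSE]
      }
    }
  }
  attr(records, "errors") <- errors
  records
}

#' Write / read a ground-truth table
#'
#' Truth tables (`id,category`) and labeled sets travel as plain CSV.
#'
#' @param truth Data frame with columns `id`, `category`.
#' @param path File path.
#' @return `path` (write) or the data frame (read).
#' @export
write_truth <- function(truth, path) {
  data.table::fwrite(truth, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  data.table::setDF(data.table::fread(path, showProgress = FALSE))
}

#' Apply analytic-sample exclusions
#'
#' Filters records to the analytic universe in a fixed order -- (1) age at
#' death >= 55, (2) manner of death one of suicide / undetermined /
#' accidental firearm, (3) nonempty narrative -- logging the count removed
#' at each step.  A record failing several filters is counted once, at the
#' first failing step, so retained + excluded always reconciles to the
#' input count.
#'
#' @param records Data frame of decedent records.
#' @param min_age Minimum age at death (default 55).
#' @return Object of class `ltc_analytic_sample`: list with `records` and
#'   `exclusion_log` (named integer vector: age, manner, narrative).
#' @export
build_analytic_sample <- function(records, min_age = 55) {
  manners <- c("suicide", "undetermined", "accidental_firearm")
  n0 <- nrow(records)
  keep_age <- !is.na(records$age) & records$age >= min_age
  r1 <- records[keep_age, , drop = FALSE]
  keep_manner <- r1$manner %in% manners
  r2 <- r1[keep_manner, , drop = FALSE]
  keep_narr <- !is.na(r2$narrative) & nzchar(trimws(r2$narrative))
  r3 <- r2[keep_narr, , drop = FALSE]
  log <- c(age = n0 - nrow(r1),
           manner = nrow(r1) - nrow(r2),
           narrative = nrow(r2) - nrow(r3))
  structure(list(records = r3, exclusion_log = log, n_input = n0),
            class = "ltc_analytic_sample")
}

#' @export
print.ltc_analytic_sample <- function(x, ...) {
  cat("<ltc_analytic_sample> ", nrow(x$records), " of ", x$n_input,
      " records retained\n", sep = "")
  cat("excluded:", paste(names(x$exclusion_log), x$exclusion_log,
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Recode derived fields
#'
#' Adds `race_dichotomy` (`"non-Hispanic white"` vs `"other"`), leaving the
#' original `race_eth` untouched.  Missing or empty race strings are
#' recoded to `"other"` with a warning.
#'
#' @param records Data frame of decedent records.
#' @return The records with a `race_dichotomy` column appended.
#' @export
recode_records <- function(records) {
  race <- as.character(records$race_eth)
  miss <- is.na(race) | !nzchar(trimws(race))
  if (any(miss)) {
    warning(sum(miss), " record(s) with missing race recoded to 'other'")
  }
  records$race_dichotomy <- ifelse(!miss & race == "non-Hispanic white",
                                   "non-Hispanic white", "other")
  records
}
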