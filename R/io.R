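SPECIMEN_CSV_COLUMNS <- c("specimen_id", "taxon_hint",
                          "HL", "HW", "SL", "EL", "PH", "PW", "WL", "PSL",
                          "PTL", "PTH", "PTW", "PPL", "PPH", "PPW",
                          "latitude", "longitude", "locality", "collection_note")

#' Parse a coordinate cell
#'
#' Accepts signed decimal degrees (`"11.975817"`, `"-93.02"`) and
#' hemisphere-suffixed values as printed on specimen labels
#' (`"11.975817 N"`, `"93.016897 E"`); S and W map to negative. Empty cells
#' give `NA`.
#'
#' @param x Character vector.
#' @return Numeric vector of signed decimal degrees.
#' @export
parse_coordinate <- function(x) {
  vapply(as.character(x), function(s) {
    s <- trimws(s)
    if (!nzchar(s)) return(NA_real_)
    m <- regmatches(s, regexec("^([+-]?[0-9]+(?:\\.[0-9]+)?)\\s*([NSEW]?)$", s))[[1]]
    if (!length(m))
      tk_stop(paste0("unparseable coordinate: '", s, "'"),
              "tetrakey_validation_error")
    v <- as.numeric(m[2])
    if (m[3] %in% c("S", "W")) v <- -abs(v)
    v
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read a specimen measurement CSV
#'
#' Strict reader for the fixed specimen table schema (UTF-8, comma
#' separated, `.` decimal separator): a header with exactly the declared
#' columns, one row per specimen, measurement cells in decimal mm or empty
#' (= unmeasured). No locale-dependent parsing.
#'
#' @param path CSV file path.
#' @param recorded_decimals Recording precision passed to
#'   [measurement_set()].
#' @return List of specimen entries; each is a list with `specimen_id`,
#'   `taxon_hint`, `latitude`, `longitude`, `locality`, `collection_note`,
#'   `row` (1-based data row for error reporting) and `measurements` (a
#'   [measurement_set()]).
#' @section Errors: unknown or missing columns, nonnumeric cells, and
#'   nonpositive measurement values raise a validation error naming the row
#'   and column.
#' @export
read_specimen_csv <- function(path, recorded_decimals = 3) {
  if (!file.exists(path))
    tk_stop(paste0("no such file: ", path), "tetrakey_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = character(0),
                        check.names = FALSE, fileEncoding = "UTF-8")
  extra <- setdiff(names(df), SPECIMEN_CSV_COLUMNS)
  missing <- setdiff(SPECIMEN_CSV_COLUMNS, names(df))
  if (length(extra) || length(missing))
    tk_stop(sprintf("specimen CSV header mismatch (unknown: %s; missing: %s)",
                    paste(extra, collapse = ", "),
                    paste(missing, collapse = ", ")),
            "tetrakey_validation_error")
  lapply(seq_len(nrow(df)), function(i) {
    vals <- list()
    for (f in MEASUREMENT_FIELDS) {
      cell <- trimws(df[[f]][i])
      if (!nzchar(cell)) next
      v <- suppressWarnings(as.numeric(cell))
      if (is.na(v))
        tk_stop(sprintf("row %d, column %s: nonnumeric cell '%s'", i, f, cell),
                "tetrakey_validation_error", row = i, column = f)
      vals[[f]] <- v
    }
    m <- tryCatch(
      measurement_set(vals, recorded_decimals = recorded_decimals),
      tetrakey_validation_error = function(e)
        tk_stop(sprintf("row %d, column %s: %s", i, e$field %||% "?",
                        conditionMessage(e)),
                "tetrakey_validation_error", row = i))
    list(specimen_id = df$specimen_id[i], taxon_hint = df$taxon_hint[i],
         latitude = parse_coordinate(df$latitude[i]),
         longitude = parse_coordinate(df$longitude[i]),
         locality = df$locality[i], collection_note = df$collection_note[i],
         row = i, measurements = m)
  })
}

format_reported <- function(x) {
  # reported values >= 10 are integers, below 10 one decimal
  ifelse(is.na(x), "",
         ifelse(x >= 10, sprintf("%d", as.integer(round_half_away(x))),
                sprintf("%.1f", x)))
}

#' Write an index report CSV
#'
#' One row per specimen: `specimen_id` plus the 13 indices at reporting
#' precision, and optionally the raw (unrounded) values in additional
#' columns.
#'
#' @param specimens A [read_specimen_csv()] result (or list of entries with
#'   `specimen_id` and `measurements`).
#' @param path Output CSV path.
#' @param include_raw Also write `<index>_raw` columns.
#' @return The written data.frame, invisibly.
#' @export
write_index_report <- function(specimens, path, include_raw = FALSE) {
  rows <- lapply(specimens, function(sp) {
    raw <- compute_indices(sp$measurements)
    rep <- round_index(raw)
    row <- c(list(specimen_id = sp$specimen_id),
             stats::setNames(as.list(format_reported(rep)), INDEX_NAMES))
    if (include_raw)
      row <- c(row, stats::setNames(as.list(unclass(raw)),
                                    paste0(INDEX_NAMES, "_raw")))
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(df)
}

result_to_list <- function(res) {
  list(specimen_id = res$specimen_id %||% NA_character_,
       key_id = res$key_id,
       outcome = as.list(res$outcome),
       ambiguous = res$ambiguous,
       path = if (nrow(res$path)) lapply(seq_len(nrow(res$path)), function(i)
         list(couplet = res$path$couplet[i], lead = res$path$lead[i],
              text = res$path$text[i])) else list(),
       consulted = as.list(res$consulted),
       warnings = as.list(res$warnings),
       conflicts = as.list(res$conflicts %||% character(0)))
}

#' Write an identification report
#'
#' Serializes key-traversal results with a deterministic column/key order.
#' The `text` format prints the traversal path with the verbatim lead text
#' of each decision; `json` round-trips losslessly through
#' [read_identification_report()].
#'
#' @param results List of `"traversal_result"` objects (optionally carrying
#'   a `specimen_id` element).
#' @param path Output file path.
#' @param format One of `"csv"`, `"json"`, `"text"`.
#' @param allow_empty Permit an empty result list (header-only CSV / empty
#'   JSON array).
#' @return `path`, invisibly.
#' @export
write_identification_report <- function(results, path,
                                        format = c("csv", "json", "text"),
                                        allow_empty = FALSE) {
  format <- match.arg(format)
  if (!length(results) && !allow_empty)
    tk_stop("empty results (use allow_empty = TRUE for a header-only report)",
            "tetrakey_validation_error")
  if (format == "json") {
    payload <- lapply(results, result_to_list)
    json <- jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE,
                             digits = NA)
    writeLines(json, path, useBytes = TRUE)
  } else if (format == "csv") {
    header <- c("specimen_id", "key_id", "outcome", "ambiguous", "n_steps", "path")
    rows <- vapply(results, function(res) {
      paste(c(res$specimen_id %||% "", res$key_id,
              paste(res$outcome, collapse = "|"), tolower(res$ambiguous),
              nrow(res$path),
              paste(sprintf("%d%s", res$path$couplet,
                            c("A", "B")[res$path$lead]), collapse = ">")),
            collapse = ",")
    }, character(1))
    writeLines(c(paste(header, collapse = ","), rows), path, useBytes = TRUE)
  } else {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    for (res in results) {
      writeLines(sprintf("specimen: %s", res$specimen_id %||% "<unnamed>"), con)
      writeLines(sprintf("key: %s", res$key_id), con)
      writeLines(sprintf("outcome: %s%s",
                         paste(res$outcome, collapse = " | "),
                         if (res$ambiguous) " (ambiguous)" else ""), con)
      if (nrow(res$path))
        for (i in seq_len(nrow(res$path)))
          writeLines(sprintf("  couplet %d, lead %s: %s", res$path$couplet[i],
                             c("A", "B")[res$path$lead[i]], res$path$text[i]), con)
      for (w in res$warnings) writeLines(paste("  warning:", w), con)
      writeLines("", con)
    }
  }
  invisible(path)
}

#' Read back a JSON identification report
#'
#' @param path JSON report written by [write_identification_report()].
#' @return List of result entries (plain lists, same structure as written).
#' @export
read_identification_report <- function(path) {
  jsonlite::read_json(path)
}

#' Read a character-state CSV
#'
#' Schema: `specimen_id` plus one column per character id of the key; an
#' empty cell is UNKNOWN.
#'
#' @param path CSV path.
#' @param key A [load_key()] result or key id.
#' @return List of entries `list(specimen_id, sv)` where `sv` is a
#'   [state_vector()].
#' @export
read_state_csv <- function(path, key) {
  if (is.character(key)) key <- load_key(key)
  if (!file.exists(path))
    tk_stop(paste0("no such file: ", path), "tetrakey_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = character(0),
                        check.names = FALSE, fileEncoding = "UTF-8")
  if (!"specimen_id" %in% names(df))
    tk_stop("state CSV needs a specimen_id column", "tetrakey_validation_error")
  unknown_cols <- setdiff(names(df), c("specimen_id", names(key$characters)))
  if (length(unknown_cols))
    tk_stop(paste0("state CSV has undeclared character column(s): ",
                   paste(unknown_cols, collapse = ", ")),
            "tetrakey_validation_error")
  lapply(seq_len(nrow(df)), function(i) {
    vals <- list()
    for (id in intersect(names(df), names(key$characters))) {
      cell <- trimws(df[[id]][i])
      if (!nzchar(cell)) next
      ch <- key$characters[[id]]
      vals[[id]] <- if (ch$kind %in% c("count", "quantitative")) {
        v <- suppressWarnings(as.numeric(cell))
        if (is.na(v))
          tk_stop(sprintf("row %d, column %s: nonnumeric cell '%s'", i, id, cell),
                  "tetrakey_validation_error", row = i, column = id)
        v
      } else cell
    }
    list(specimen_id = df$specimen_id[i], sv = state_vector(key, vals))
  })
}
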