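extdata <- function(...) {
  system.file("extdata", ..., package = "tetrakey", mustWork = TRUE)
}

#' Load the Indian Tetramorium species checklist
#'
#' The packaged checklist holds 42 valid species (with species group,
#' authority, endemic and exotic flags) plus 2 records excluded from the
#' Indian fauna (a misidentification resolved to *T. salvatum*, and a junior
#' homonym replaced by *T. meghalayense*), each with its exclusion reason.
#'
#' @param path Optional path to a checklist CSV with the packaged column
#'   layout; defaults to the packaged table.
#' @return A data.frame of class `"species_db"`.
#' @export
load_species_table <- function(path = NULL) {
  path <- path %||% extdata("species_table.csv")
  db <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = character(0))
  need <- c("species_group", "species", "authority", "endemic", "exotic",
            "status", "exclusion_reason")
  miss <- setdiff(need, names(db))
  if (length(miss))
    tk_stop(paste0("checklist missing column(s): ", paste(miss, collapse = ", ")),
            "tetrakey_validation_error")
  db$endemic <- tolower(db$endemic) %in% c("yes", "true", "1")
  db$exotic <- tolower(db$exotic) %in% c("yes", "true", "1")
  for (col in c("type_lat", "type_lon"))
    if (col %in% names(db)) db[[col]] <- suppressWarnings(as.numeric(db[[col]]))
  bad <- which(!db$status %in% c("valid", "excluded"))
  if (length(bad))
    tk_stop(sprintf("row %d (%s): bad status '%s'", bad[1], db$species[bad[1]],
                    db$status[bad[1]]), "tetrakey_validation_error")
  bad <- which(db$status == "excluded" & !nzchar(db$exclusion_reason))
  if (length(bad))
    tk_stop(sprintf("row %d (%s): excluded record without exclusion_reason",
                    bad[1], db$species[bad[1]]), "tetrakey_validation_error")
  bad <- which(db$endemic & db$exotic)
  if (length(bad))
    tk_stop(sprintf("row %d (%s): endemic and exotic are mutually exclusive",
                    bad[1], db$species[bad[1]]), "tetrakey_validation_error")
  class(db) <- c("species_db", "data.frame")
  db
}

#' Load the packaged type-series measurement ranges
#'
#' Only the two species described from the Andaman Islands carry published
#' worker measurement ranges; every other checklist species has none and is
#' reported `not_checkable` by [match_specimen()].
#'
#' @param path Optional path to a ranges JSON document keyed by species.
#' @return Named list; per species a list with `range`
#'   ([measurement_range()]) and `indices_printed` (named list of printed
#'   strings `c(min, max, holotype)`).
#' @export
load_species_ranges <- function(path = NULL) {
  path <- path %||% extdata("species_ranges.json")
  raw <- jsonlite::read_json(path)
  raw <- raw[setdiff(names(raw), "note")]
  lapply(raw, function(sp) {
    mm <- sp$measurements_mm
    lo <- vapply(mm, function(v) as.numeric(v[[1]]), numeric(1))
    hi <- vapply(mm, function(v) as.numeric(v[[2]]), numeric(1))
    holo <- vapply(mm, function(v) as.numeric(v[[3]]), numeric(1))
    list(range = measurement_range(lo, hi, holotype = holo, n = sp$n %||% 1L),
         indices_printed = lapply(sp$indices_printed, function(v)
           as.character(unlist(v))),
         description_discrepancies = sp$description_discrepancies,
         caveats = sp$caveats)
  })
}

#' Summary statistics of the checklist
#'
#' Counts computed solely from the record flags; the endemism rate is
#' rounded half away from zero to integer percent.
#'
#' @param db A [load_species_table()] result.
#' @return List of class `"fauna_summary"`: `n_species_valid`, `n_endemic`,
#'   `n_exotic`, `n_excluded`, `n_named_groups` (distinct groups of valid
#'   species, excluding `unclear`), `endemism_rate_percent`.
#' @export
fauna_summary <- function(db) {
  if (!nrow(db)) tk_stop("empty species table", "tetrakey_validation_error")
  valid <- db[db$status == "valid", ]
  n_valid <- nrow(valid)
  n_endemic <- sum(valid$endemic)
  out <- list(
    n_species_valid = n_valid,
    n_endemic = n_endemic,
    n_exotic = sum(valid$exotic),
    n_excluded = sum(db$status == "excluded"),
    n_named_groups = length(setdiff(unique(valid$species_group), "unclear")),
    endemism_rate_percent = as.integer(round_half_away(100 * n_endemic / n_valid))
  )
  class(out) <- "fauna_summary"
  out
}

#' @export
print.fauna_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "Indian Tetramorium checklist summary\n",
    "  valid species:     %d\n",
    "  endemic:           %d (endemism rate %d%%)\n",
    "  exotic:            %d\n",
    "  excluded records:  %d\n",
    "  named groups:      %d\n"),
    x$n_species_valid, x$n_endemic, x$endemism_rate_percent,
    x$n_exotic, x$n_excluded, x$n_named_groups))
  invisible(x)
}

#' Load the encoded species-group diagnoses
#'
#' @param path Optional path to a diagnoses JSON document.
#' @return List with `groups` (per group: `predicate`, `template`, optional
#'   `applicability_note`) and `data_notes`.
#' @export
load_group_diagnoses <- function(path = NULL) {
  path <- path %||% extdata("group_diagnoses.json")
  jsonlite::read_json(path)
}

#' Candidate species groups compatible with observed character states
#'
#' A group is a candidate when its diagnosis predicate is satisfiable given
#' the state vector: UNKNOWN characters are treated permissively, and groups
#' whose predicate is contradicted by a known state are excluded.
#'
#' @param sv A [state_vector()] over the species-group key characters (or a
#'   named list; UNKNOWN = `NA` or omitted).
#' @param diagnoses A [load_group_diagnoses()] result.
#' @return Character vector of candidate group names (sorted).
#' @export
apply_diagnosis <- function(sv, diagnoses = load_group_diagnoses()) {
  if (!inherits(sv, "state_vector"))
    sv <- state_vector(load_key("india_species_groups"), sv)
  groups <- diagnoses$groups
  hit <- vapply(groups, function(g)
    !identical(eval_predicate(g$predicate, sv), FALSE), logical(1))
  sort(names(groups)[hit])
}

#' Match a measured specimen against the checklist's type-series ranges
#'
#' For each species with published ranges, every computable index of the
#' specimen is tested against the species' feasible index interval (range
#' endpoints widened by `h`, see [index_interval()]). The match score is the
#' fraction of checkable indices that are in range; candidates are ranked by
#' score with alphabetical tie-break. Species without ranges are reported
#' `not_checkable` rather than scored 0.
#'
#' @param m A [measurement_set()].
#' @param db A [load_species_table()] result.
#' @param ranges A [load_species_ranges()] result.
#' @param h Rounding halfwidth in mm applied to the range endpoints.
#' @return data.frame of class `"match_result"`: one row per valid species,
#'   with `score`, `n_checkable`, `out_of_range` (comma-separated failing
#'   indices) and `checkable` flag.
#' @export
match_specimen <- function(m, db = load_species_table(),
                           ranges = load_species_ranges(), h = 0.005) {
  if (!inherits(m, "measurement_set")) m <- measurement_set(m)
  raw <- compute_indices(m)
  valid <- db[db$status == "valid", ]
  rows <- lapply(valid$species, function(sp) {
    rg <- ranges[[sp]]
    if (is.null(rg))
      return(data.frame(species = sp, checkable = FALSE, score = NA_real_,
                        n_checkable = 0L, out_of_range = "",
                        stringsAsFactors = FALSE))
    verdicts <- vapply(INDEX_NAMES, function(ix) {
      if (is.na(raw[[ix]])) return(NA)
      iv <- index_interval(rg$range, index = ix, h = h)
      if (any(is.na(iv))) return(NA)
      raw[[ix]] >= iv[1] && raw[[ix]] <= iv[2]
    }, logical(1))
    checkable <- !is.na(verdicts)
    if (!any(checkable))
      return(data.frame(species = sp, checkable = FALSE, score = NA_real_,
                        n_checkable = 0L, out_of_range = "",
                        stringsAsFactors = FALSE))
    data.frame(species = sp, checkable = TRUE,
               score = mean(verdicts[checkable]),
               n_checkable = sum(checkable),
               out_of_range = paste(INDEX_NAMES[checkable & !verdicts],
                                    collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(species = character(0), checkable = logical(0),
                      score = numeric(0), n_checkable = integer(0),
                      out_of_range = character(0), stringsAsFactors = FALSE)
  } else {
    ord_score <- ifelse(is.na(out$score), -1, out$score)  # not_checkable last
    out <- out[order(-ord_score, out$species), ]
    rownames(out) <- NULL
  }
  attr(out, "h") <- h
  class(out) <- c("match_result", "data.frame")
  out
}
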