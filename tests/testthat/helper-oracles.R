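# Shared fixtures and independent oracles.

# Packaged data loaded once per test run.
tk_db <- load_species_table()
tk_ranges <- load_species_ranges()
tk_diagnoses <- load_group_diagnoses()

holotype_ms <- function(species, recorded_decimals = 2) {
  measurement_set(as.list(tk_ranges[[species]]$range$holotype),
                  recorded_decimals = recorded_decimals)
}

holotype_printed <- function(species) {
  lapply(tk_ranges[[species]]$indices_printed, function(v) v[3])
}

# Independent oracle for index_interval: exhaustive grid search over the two
# widened measurement intervals (step 1e-4 mm).
grid_interval <- function(num_lo, num_hi, den_lo, den_hi, h, step = 1e-4) {
  nums <- seq(num_lo - h, num_hi + h, by = step)
  dens <- seq(den_lo - h, den_hi + h, by = step)
  ratios <- outer(nums, dens, "/") * 100
  c(min(ratios), max(ratios))
}

# Independent oracle for traverse_partial: enumerate every completion of the
# UNKNOWN characters and collect the terminals of the successful traversals.
brute_force_terminals <- function(key, sv) {
  unknown <- names(sv)[vapply(names(sv), function(id)
    is.null(sv[[id]]) || (length(sv[[id]]) == 1L && is.na(sv[[id]])), logical(1))]
  domains <- lapply(key$characters[unknown], function(ch)
    switch(ch$kind,
           boolean = c(TRUE, FALSE),
           categorical = ch$states,
           count = seq(ch$domain[1], ch$domain[2])))
  out <- character(0)
  recurse <- function(i, sv2) {
    if (i > length(unknown)) {
      res <- tryCatch(traverse(key, sv2), tetrakey_error = function(e) NULL)
      if (!is.null(res)) out <<- union(out, res$outcome)
      return(invisible(NULL))
    }
    for (v in domains[[i]]) {
      sv3 <- sv2
      sv3[[unknown[i]]] <- v
      recurse(i + 1L, sv3)
    }
  }
  recurse(1L, sv)
  sort(out)
}

# Random partial state vector over a key's characters (values from declared
# domains, each character independently left UNKNOWN).
random_partial_sv <- function(key, unknown_prob = 0.5, max_unknown = Inf) {
  vals <- list()
  ids <- names(key$characters)
  unk <- ids[stats::runif(length(ids)) < unknown_prob]
  if (length(unk) > max_unknown) unk <- sample(unk, max_unknown)
  for (id in setdiff(ids, unk)) {
    ch <- key$characters[[id]]
    dom <- switch(ch$kind,
                  boolean = c(TRUE, FALSE),
                  categorical = ch$states,
                  count = seq(ch$domain[1], ch$domain[2]))
    vals[[id]] <- sample(dom, 1)[[1]]
  }
  state_vector(key, vals)
}

specimen_df_to_ms <- function(df, i) {
  measurement_set(stats::setNames(
    as.list(suppressWarnings(as.numeric(df[i, MEASUREMENT_FIELDS]))),
    MEASUREMENT_FIELDS))
}

write_temp_key <- function(obj) {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  path
}
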