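with_seed <- function(seed, expr) {
  # run expr under a local RNG state so generators do not disturb the caller
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

rtruncnorm_range <- function(n, lo, hi) {
  # truncated normal at the range midpoint with sd = width/4 (rejection)
  if (hi - lo < 1e-12) return(rep(lo, n))
  mu <- (lo + hi) / 2; sd <- (hi - lo) / 4
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(2L * (n - length(out)), mu, sd)
    out <- c(out, draw[draw >= lo & draw <= hi])
  }
  out[seq_len(n)]
}

# Smallest upward displacement of `field` beyond its range maximum that
# pushes EVERY index involving the field outside the h-widened feasible
# interval, whatever the (in-range) partner measurement. Derived from
# monotonicity of the ratio: for field as numerator the binding case is the
# partner at its maximum; as denominator, the partner at its minimum-side
# worst case. A small safety factor keeps strict inequality.
min_clearing_displacement <- function(range, field, h = 0.005) {
  lo <- range$min; hi <- range$max
  need <- 0
  for (ix in INDEX_NAMES) {
    def <- INDEX_DEFS[[ix]]
    if (!field %in% def) next
    if (!all(def %in% names(lo))) next
    num <- def[1]; den <- def[2]
    if (field == num) {
      # need (hi_f + d)/partner > (hi_f + h)/(lo_p - h) for all partner <= hi_p
      d <- (hi[[num]] + h) * hi[[den]] / (lo[[den]] - h) - hi[[num]]
    } else {
      # need partner/(hi_f + d) < (lo_p - h)/(hi_f + h) for all partner <= hi_p
      d <- hi[[num]] * (hi[[den]] + h) / (lo[[num]] - h) - hi[[den]]
    }
    need <- max(need, d)
  }
  need * (1 + 1e-6) + 1e-9
}

#' Generate synthetic specimen measurement tables with known ground truth
#'
#' Samples each of the 14 measurements independently within the species'
#' published type-series range (`uniform` in the closed range, or
#' `truncated-normal` at the midpoint with sd = width/4). A chosen fraction
#' of rows is perturbed: one measurement (cycled over the fields) is
#' displaced upward beyond its range maximum, by the larger of
#' `perturb_magnitude` times the range width and the smallest displacement
#' that guarantees every index involving that field falls outside the
#' h-widened feasible interval of the species (so perturbed rows fail
#' exactly the affected index family under [match_specimen()]).
#' Independent per-measurement sampling ignores allometric correlation
#' between body parts; the fixtures exercise interval logic, not biology.
#'
#' @param species Species name with packaged ranges (`"jarawa"` or
#'   `"krishnani"`), or any name present in `ranges`.
#' @param n Number of specimens (>= 0).
#' @param distribution `"uniform"` or `"truncated-normal"`.
#' @param out_of_range_fraction Fraction of rows to perturb (rounded to a
#'   count).
#' @param perturb_magnitude Displacement as a fraction of the range width.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @param ranges A [load_species_ranges()] result.
#' @param h Halfwidth used for the displacement guarantee.
#' @param dir If given, write `specimens.csv` and `truth.csv` there.
#' @return List with `specimens` (data.frame in the specimen CSV schema) and
#'   `truth` (data.frame: `specimen_id`, `species`, `perturbed_field`).
#' @export
generate_specimens <- function(species, n, distribution = c("uniform", "truncated-normal"),
                               out_of_range_fraction = 0, perturb_magnitude = 0.5,
                               seed = 1L, ranges = load_species_ranges(),
                               h = 0.005, dir = NULL) {
  distribution <- match.arg(distribution)
  if (n < 0) tk_stop("n must be >= 0", "tetrakey_validation_error")
  if (out_of_range_fraction < 0 || out_of_range_fraction > 1)
    tk_stop("out_of_range_fraction must be in [0, 1]", "tetrakey_validation_error")
  rg <- ranges[[species]]
  if (is.null(rg))
    tk_stop(paste0("no packaged ranges for '", species, "'; species with ranges: ",
                   paste(names(ranges), collapse = ", ")),
            "tetrakey_validation_error")
  lo <- rg$range$min; hi <- rg$range$max
  fields <- names(lo)
  n_bad <- as.integer(round_half_away(n * out_of_range_fraction))

  draw <- with_seed(seed, {
    mat <- matrix(NA_real_, nrow = n, ncol = length(fields),
                  dimnames = list(NULL, fields))
    for (f in fields)
      mat[, f] <- if (distribution == "uniform") stats::runif(n, lo[[f]], hi[[f]])
                  else rtruncnorm_range(n, lo[[f]], hi[[f]])
    bad_rows <- if (n_bad > 0) sort(sample.int(n, n_bad)) else integer(0)
    list(mat = mat, bad_rows = bad_rows)
  })
  mat <- round(draw$mat, 3)  # recording convention: 3 decimals
  perturbed <- rep("", n)
  for (j in seq_along(draw$bad_rows)) {
    i <- draw$bad_rows[j]
    f <- fields[((j - 1L) %% length(fields)) + 1L]
    d <- max(perturb_magnitude * (hi[[f]] - lo[[f]]),
             min_clearing_displacement(rg$range, f, h))
    mat[i, f] <- round(hi[[f]] + d, 3) + 0.001  # keep clear of the bound after rounding
    perturbed[i] <- f
  }
  ids <- sprintf("SYN-%s-%04d", toupper(substr(species, 1, 3)), seq_len(n))
  specimens <- data.frame(specimen_id = ids, taxon_hint = rep(species, n),
                          stringsAsFactors = FALSE)
  for (f in MEASUREMENT_FIELDS)
    specimens[[f]] <- if (n) sprintf("%.3f", mat[, f]) else character(0)
  for (meta in c("latitude", "longitude", "locality", "collection_note"))
    specimens[[meta]] <- rep("", n)
  truth <- data.frame(specimen_id = ids, species = rep(species, n),
                      perturbed_field = perturbed, stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(specimens, file.path(dir, "specimens.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(truth, file.path(dir, "truth.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  list(specimens = specimens, truth = truth)
}

#' Generate synthetic character-state vectors with known ground truth
#'
#' Each vector instantiates the target group's diagnosis template over the
#' species-group key characters; with `unknown_rate > 0` each character is
#' independently blanked to UNKNOWN. By construction, a fully specified
#' vector traverses the species-group key to the target group, and any
#' partially blanked vector's [traverse_partial()] terminal set contains the
#' target group.
#'
#' @param group Species-group name with an encoded diagnosis.
#' @param n Number of vectors (>= 0).
#' @param unknown_rate Per-character probability of UNKNOWN.
#' @param seed Integer seed.
#' @param diagnoses A [load_group_diagnoses()] result.
#' @param dir If given, write `states.csv` and `truth.csv` there.
#' @return List with `states` (data.frame: `specimen_id` + one column per
#'   character; empty cell = UNKNOWN) and `truth` (`specimen_id`, `group`).
#' @export
generate_state_vectors <- function(group, n, unknown_rate = 0, seed = 1L,
                                   diagnoses = load_group_diagnoses(),
                                   dir = NULL) {
  if (n < 0) tk_stop("n must be >= 0", "tetrakey_validation_error")
  if (unknown_rate < 0 || unknown_rate > 1)
    tk_stop("unknown_rate must be in [0, 1]", "tetrakey_validation_error")
  g <- diagnoses$groups[[group]]
  if (is.null(g))
    tk_stop(paste0("no encoded diagnosis for group '", group, "'; groups: ",
                   paste(names(diagnoses$groups), collapse = ", ")),
            "tetrakey_validation_error")
  tmpl <- g$template
  chars <- names(tmpl)
  cells <- vapply(tmpl, function(v)
    if (is.logical(v)) tolower(as.character(v)) else as.character(v),
    character(1))
  mask <- if (n == 0) matrix(FALSE, 0, length(chars)) else
    with_seed(seed, matrix(stats::runif(n * length(chars)) < unknown_rate,
                           nrow = n, ncol = length(chars)))
  ids <- sprintf("SYN-%s-%04d", toupper(substr(group, 1, 3)), seq_len(n))
  states <- data.frame(specimen_id = ids, stringsAsFactors = FALSE)
  for (j in seq_along(chars))
    states[[chars[j]]] <- if (n) ifelse(mask[, j], "", cells[[j]]) else character(0)
  truth <- data.frame(specimen_id = ids, group = rep(group, n),
                      stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(states, file.path(dir, "states.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(truth, file.path(dir, "truth.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  list(states = states, truth = truth)
}
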