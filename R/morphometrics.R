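#' The 14 standard linear measurements (mm)
#'
#' Field order follows the conventional measurement scheme for
#' *Tetramorium* workers: head (HL, HW, SL, EL), mesosoma (PH, PW, WL,
#' PSL), petiole (PTH, PTL, PTW) and postpetiole (PPH, PPL, PPW).
#'
#' @format Character vector of field names.
#' @export
MEASUREMENT_FIELDS <- c("HL", "HW", "SL", "EL", "PH", "PW", "WL", "PSL",
                        "PTH", "PTL", "PTW", "PPH", "PPL", "PPW")

#' The 13 ratio indices and their defining measurements
#'
#' Each index is `numerator/denominator * 100`, e.g. the ocular index
#' OI = EL/HW x 100 and the cephalic index CI = HW/HL x 100.
#'
#' @format Named list; each element is `c(numerator, denominator)`.
#' @export
INDEX_DEFS <- list(
  OI   = c("EL",  "HW"),
  CI   = c("HW",  "HL"),
  SI   = c("SL",  "HW"),
  DMI  = c("PW",  "WL"),
  LMI  = c("PH",  "WL"),
  PSLI = c("PSL", "HL"),
  PeNI = c("PTW", "PW"),
  LPeI = c("PTL", "PTH"),
  DPeI = c("PTW", "PTL"),
  PpNI = c("PPW", "PW"),
  LPpI = c("PPL", "PPH"),
  DPpI = c("PPW", "PPL"),
  PPI  = c("PPW", "PTW")
)

INDEX_NAMES <- names(INDEX_DEFS)

tk_stop <- function(msg, class, ...) {
  stop(structure(class = c(class, "tetrakey_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

#' Create a measurement set for one worker specimen
#'
#' @param ... Named measurements in mm (subset of [MEASUREMENT_FIELDS]), or a
#'   single named numeric vector/list. Missing fields and `NA`s are recorded
#'   as unmeasured.
#' @param recorded_decimals Recording precision of the values, 2 or 3
#'   decimals (specimens are conventionally recorded at 3 decimals and
#'   printed at 2).
#'
#' @return A named numeric vector of length 14 with class
#'   `"measurement_set"`; unmeasured fields are `NA`.
#'
#' @details Every present value must be a strictly positive, finite length
#' representable at the declared decimal precision or coarser. Violations
#' raise a validation error naming the offending field.
#'
#' @examples
#' m <- measurement_set(HL = 0.56, HW = 0.52, EL = 0.05)
#' compute_indices(m)[["OI"]]
#' @export
measurement_set <- function(..., recorded_decimals = 3) {
  vals <- list(...)
  if (length(vals) == 1L && is.null(names(vals)) &&
      (is.numeric(vals[[1]]) || is.list(vals[[1]]))) {
    vals <- as.list(vals[[1]])
  }
  if (!recorded_decimals %in% c(2, 3))
    tk_stop("recorded_decimals must be 2 or 3", "tetrakey_validation_error")
  bad <- setdiff(names(vals), MEASUREMENT_FIELDS)
  if (length(bad))
    tk_stop(paste0("unknown measurement field(s): ", paste(bad, collapse = ", ")),
            "tetrakey_validation_error")
  m <- stats::setNames(rep(NA_real_, length(MEASUREMENT_FIELDS)), MEASUREMENT_FIELDS)
  for (f in names(vals)) {
    v <- vals[[f]]
    if (is.null(v) || length(v) == 0L || is.na(v)) next
    v <- as.numeric(v)
    if (!is.finite(v) || v <= 0)
      tk_stop(sprintf("measurement %s must be strictly positive and finite (got %s)",
                      f, format(v)), "tetrakey_validation_error", field = f)
    scaled <- v * 10^recorded_decimals
    if (abs(scaled - round(scaled)) > 1e-6)
      tk_stop(sprintf("measurement %s = %s is not representable at %d decimals",
                      f, format(v), recorded_decimals),
              "tetrakey_validation_error", field = f)
    m[[f]] <- v
  }
  structure(m, recorded_decimals = recorded_decimals, class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat("Worker measurement set (mm, recorded at",
      attr(x, "recorded_decimals"), "decimals):\n")
  print(unclass(x)[!is.na(x)])
  miss <- names(x)[is.na(x)]
  if (length(miss)) cat("unmeasured:", paste(miss, collapse = ", "), "\n")
  invisible(x)
}

#' Compute the 13 raw ratio indices of a specimen
#'
#' Raw (unrounded) index values on the x100 scale. An index is present iff
#' both of its source measurements are present; reporting precision is
#' applied separately by [round_index()].
#'
#' @param m A [measurement_set()].
#' @return Named numeric vector of the 13 indices with class `"index_set"`;
#'   absent indices are `NA`.
#' @seealso [round_index()], [index_interval()]
#' @export
compute_indices <- function(m) {
  if (!inherits(m, "measurement_set")) m <- measurement_set(m)
  idx <- vapply(INDEX_DEFS, function(def) {
    num <- m[[def[1]]]; den <- m[[def[2]]]
    if (is.na(num) || is.na(den)) NA_real_ else 100 * num / den
  }, numeric(1))
  structure(idx, class = "index_set", source = unclass(m))
}

round_half_away <- function(x, digits = 0) {
  s <- 10^digits
  scaled <- x * s
  # tolerance absorbs binary representation error of decimal inputs (9.95*10
  # is stored fractionally below 99.5)
  sign(scaled) * floor(abs(scaled) + 0.5 + abs(scaled) * 1e-12 + 1e-12) / s
}

#' Apply the reporting-precision rounding convention to a raw index
#'
#' Taxonomic descriptions print large indices as integers (e.g. CI 94) and
#' small ones at one decimal (e.g. PSLI 3.2). The rule implemented here:
#' round half away from zero to the nearest integer; if that integer is at
#' least 10, report it; otherwise report the value rounded half away from
#' zero to one decimal. This reproduces every printed index format of the
#' packaged type series, including an OI of 10 reported from a raw value of
#' 9.615.
#'
#' @param raw Nonnegative finite numeric vector of raw index values; `NA`s
#'   pass through.
#' @return Numeric vector of reported values, with attribute
#'   `rounding = "half_away_from_zero"`.
#' @export
round_index <- function(raw) {
  if (!is.numeric(raw))
    tk_stop("raw index must be numeric", "tetrakey_validation_error")
  ok <- !is.na(raw)
  if (any(!is.finite(raw[ok]) | raw[ok] < 0))
    tk_stop("raw index values must be finite and nonnegative",
            "tetrakey_validation_error")
  out <- raw
  as_int <- round_half_away(raw[ok], 0)
  out[ok] <- ifelse(as_int >= 10, as_int, round_half_away(raw[ok], 1))
  structure(out, rounding = "half_away_from_zero",
            rule = "integer when >= 10 after integer rounding, else one decimal")
}

#' Type-series measurement range
#'
#' Closed per-measurement intervals `[min, max]` in mm with sample size and
#' optional holotype point values, as printed in species descriptions
#' ("presented as minimum and maximum values with holotype measurements in
#' parentheses").
#'
#' @param min,max Named numeric vectors over (a subset of)
#'   [MEASUREMENT_FIELDS].
#' @param holotype Optional named numeric vector of holotype values.
#' @param n Sample size of the type series (>= 1).
#' @return Object of class `"measurement_range"`.
#' @export
measurement_range <- function(min, max, holotype = NULL, n = 1L) {
  fields <- names(min)
  if (is.null(fields) || !all(fields %in% MEASUREMENT_FIELDS) ||
      !identical(sort(fields), sort(names(max))))
    tk_stop("min and max must be named over the same measurement fields",
            "tetrakey_validation_error")
  max <- max[fields]
  if (n < 1) tk_stop("sample size n must be >= 1", "tetrakey_validation_error")
  if (any(min <= 0) || any(!is.finite(min)) || any(!is.finite(max)))
    tk_stop("range endpoints must be positive and finite", "tetrakey_validation_error")
  if (any(min > max))
    tk_stop(sprintf("min > max for field(s): %s",
                    paste(fields[min > max], collapse = ", ")),
            "tetrakey_validation_error")
  if (!is.null(holotype)) {
    holotype <- holotype[intersect(names(holotype), fields)]
    lo <- min[names(holotype)]; hi <- max[names(holotype)]
    off <- names(holotype)[holotype < lo - 1e-12 | holotype > hi + 1e-12]
    if (length(off))
      tk_stop(sprintf("holotype outside [min, max] for field(s): %s",
                      paste(off, collapse = ", ")), "tetrakey_validation_error")
  }
  structure(list(min = min, max = max, holotype = holotype, n = as.integer(n)),
            class = "measurement_range")
}

#' @export
print.measurement_range <- function(x, ...) {
  cat("Measurement range (mm), N =", x$n, "\n")
  df <- data.frame(min = x$min, max = x$max)
  if (!is.null(x$holotype)) df$holotype <- x$holotype[rownames(df)]
  print(df)
  invisible(x)
}

as_range <- function(r) {
  # promote a point measurement set to a degenerate range
  if (inherits(r, "measurement_range")) return(r)
  if (inherits(r, "measurement_set")) {
    v <- unclass(r)[!is.na(r)]
    return(measurement_range(v, v, n = 1L))
  }
  tk_stop("expected a measurement_set or measurement_range",
          "tetrakey_validation_error")
}

#' Feasible interval of a ratio index under rounding uncertainty
#'
#' Measurements recorded at 3 decimals but printed at 2 can differ from the
#' printed value by up to half of the last printed digit. Given printed
#' values (or a printed range), the set of index values compatible with the
#' unprinted data is an interval: with numerator in
#' `[num_min - h, num_max + h]` and denominator in
#' `[den_min - h, den_max + h]`, the ratio of positives is monotone in each
#' argument, so the bounds are attained at endpoint combinations.
#'
#' @param r A [measurement_set()] (point) or [measurement_range()].
#' @param index An index name from `names(INDEX_DEFS)`, or `NULL` if
#'   `numerator`/`denominator` are given explicitly.
#' @param numerator,denominator Measurement field names (overridden by
#'   `index`).
#' @param h Rounding halfwidth in mm: 0.005 for 2-decimal printed values,
#'   0.0005 for 3-decimal values, 0 for exact inputs.
#' @return Numeric `c(lo, hi)` on the x100 scale, class `"index_interval"`.
#'   `NA` interval (with both ends `NA`) if a required measurement is absent.
#' @export
index_interval <- function(r, index = NULL, numerator = NULL,
                           denominator = NULL, h = 0.005) {
  if (h < 0) tk_stop("h must be >= 0", "tetrakey_validation_error")
  if (!is.null(index)) {
    if (!index %in% INDEX_NAMES)
      tk_stop(paste0("unknown index: ", index), "tetrakey_validation_error")
    numerator <- INDEX_DEFS[[index]][1]
    denominator <- INDEX_DEFS[[index]][2]
  }
  if (is.null(numerator) || is.null(denominator))
    tk_stop("supply either index= or numerator= and denominator=",
            "tetrakey_validation_error")
  r <- as_range(r)
  if (!numerator %in% names(r$min) || !denominator %in% names(r$min))
    return(structure(c(NA_real_, NA_real_), class = "index_interval",
                     index = index, h = h))
  num_lo <- r$min[[numerator]] - h
  num_hi <- r$max[[numerator]] + h
  den_lo <- r$min[[denominator]] - h
  den_hi <- r$max[[denominator]] + h
  if (den_lo <= 0)
    tk_stop(sprintf("widened denominator interval for %s reaches <= 0 (h = %g)",
                    denominator, h), "tetrakey_validation_error")
  lo <- max(0, num_lo) / den_hi * 100
  hi <- num_hi / den_lo * 100
  structure(c(lo, hi), class = "index_interval", index = index, h = h)
}

#' @export
print.index_interval <- function(x, ...) {
  cat(sprintf("Index interval%s: [%.4f, %.4f] (h = %g mm)\n",
              if (!is.null(attr(x, "index"))) paste0(" ", attr(x, "index")) else "",
              x[1], x[2], attr(x, "h")))
  invisible(x)
}

printed_band <- function(s) {
  # rounding band of a printed index value: +/-0.5 for integers, +/-0.05
  # for one-decimal values (closed bands; reporting precision inferred from
  # the printed string)
  s <- trimws(as.character(s))
  if (!grepl("^[0-9]+(\\.[0-9])?$", s))
    tk_stop(paste0("unparseable printed index value: ", s),
            "tetrakey_validation_error")
  v <- as.numeric(s)
  half <- if (grepl("\\.", s)) 0.05 else 0.5
  c(v - half, v + half)
}

#' Check printed index values against measurement data
#'
#' Printed indices were computed from unprinted 3-decimal measurements, so a
#' naive recomputation from the printed 2-decimal values frequently
#' disagrees with the printed index. An index value is `consistent` when its
#' own rounding band (+/-0.5 for an integer, +/-0.05 for a one-decimal
#' value, closed) intersects the feasible interval of the index given the
#' measurement data widened by `h` ([index_interval()]). Printed ranges are
#' checked endpoint by endpoint.
#'
#' @param printed Named list or vector of printed index values as character
#'   strings (precision is read from the string: `"94"` vs `"3.2"`); each
#'   element may have length 1 (point) or 2 (range endpoints).
#' @param r A [measurement_set()] or [measurement_range()].
#' @param h Rounding halfwidth in mm applied to the measurements.
#' @return A data.frame (class `"consistency_report"`) with one row per
#'   index: printed value(s), feasible interval, and verdict in
#'   `consistent`, `inconsistent`, `not_checkable`.
#' @export
consistency_check <- function(printed, r, h = 0.005) {
  if (is.null(names(printed)) || !all(names(printed) %in% INDEX_NAMES))
    tk_stop("printed must be named by index", "tetrakey_validation_error")
  r <- as_range(r)
  rows <- lapply(names(printed), function(ix) {
    vals <- as.character(unlist(printed[[ix]]))
    iv <- tryCatch(index_interval(r, index = ix, h = h),
                   tetrakey_error = function(e) c(NA_real_, NA_real_))
    if (any(is.na(iv))) {
      verdict <- "not_checkable"
      bands <- matrix(NA_real_, nrow = length(vals), ncol = 2)
    } else {
      bands <- t(vapply(vals, printed_band, numeric(2)))
      ok <- bands[, 1] <= iv[2] & bands[, 2] >= iv[1]
      verdict <- if (all(ok)) "consistent" else "inconsistent"
    }
    data.frame(index = ix, printed = paste(vals, collapse = "-"),
               band_lo = min(bands[, 1]), band_hi = max(bands[, 2]),
               feasible_lo = iv[1], feasible_hi = iv[2],
               verdict = verdict, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "h") <- h
  class(out) <- c("consistency_report", "data.frame")
  out
}
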