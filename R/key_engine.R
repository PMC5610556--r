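PACKAGED_KEYS <- c("india_species_groups", "inglebyi_group", "tonganum_group")

key_file <- function(key_id) {
  if (file.exists(key_id)) return(key_id)
  if (key_id %in% PACKAGED_KEYS)
    return(system.file("extdata", "keys", paste0(key_id, ".json"),
                       package = "tetrakey", mustWork = TRUE))
  tk_stop(paste0("unknown key id and no such file: ", key_id,
                 " (packaged keys: ", paste(PACKAGED_KEYS, collapse = ", "), ")"),
          "tetrakey_key_schema_error")
}

key_schema_stop <- function(msg, couplet = NA) {
  tk_stop(if (is.na(couplet)) msg else sprintf("couplet %s: %s", couplet, msg),
          "tetrakey_key_schema_error", couplet = couplet)
}

# Structural validation equivalent to inst/extdata/keys/key-schema.json
# (no JSON Schema validator is available at run time).
check_key_structure <- function(k) {
  for (f in c("key_id", "title", "characters", "couplets"))
    if (is.null(k[[f]])) key_schema_stop(paste0("missing field: ", f))
  ids <- vapply(k$characters, function(ch) ch$id %||% "", character(1))
  if (anyDuplicated(ids) || any(ids == ""))
    key_schema_stop("character ids must be present and unique")
  for (ch in k$characters) {
    kind <- ch$kind %||% ""
    if (!kind %in% c("categorical", "boolean", "count", "quantitative"))
      key_schema_stop(paste0("character ", ch$id, ": bad kind '", kind, "'"))
    if (kind == "categorical" && length(ch$states) < 1)
      key_schema_stop(paste0("character ", ch$id, ": categorical without states"))
    if (kind %in% c("count", "quantitative")) {
      d <- unlist(ch$domain)
      if (length(d) != 2 || d[1] >= d[2])
        key_schema_stop(paste0("character ", ch$id, ": numeric domain must be lo < hi"))
    }
  }
  nums <- vapply(k$couplets, function(cp) as.integer(cp$number %||% NA), integer(1))
  if (any(is.na(nums)) || anyDuplicated(nums))
    key_schema_stop("couplet numbers must be present and unique")
  if (!1 %in% nums) key_schema_stop("key must contain couplet 1")
  for (cp in k$couplets) {
    if (length(cp$leads) != 2)
      key_schema_stop("exactly two leads required", cp$number)
    for (ld in cp$leads) {
      if (is.null(ld$text) || !nzchar(ld$text))
        key_schema_stop("lead without text", cp$number)
      if (is.null(ld$predicate))
        key_schema_stop("lead without predicate", cp$number)
      has_goto <- !is.null(ld$goto); has_term <- !is.null(ld$terminal)
      if (has_goto == has_term)
        key_schema_stop("each lead needs exactly one of goto/terminal", cp$number)
      if (has_goto && !(as.integer(ld$goto) %in% nums))
        key_schema_stop(sprintf("GOTO target %s does not exist", ld$goto), cp$number)
      check_predicate_structure(ld$predicate, ids, cp$number)
      if (!is.null(ld$advisory)) check_predicate_structure(ld$advisory, ids, cp$number)
    }
  }
  invisible(TRUE)
}

check_predicate_structure <- function(p, char_ids, couplet) {
  if (!is.list(p)) key_schema_stop("predicate must be an object", couplet)
  if (!is.null(p$all) || !is.null(p$any)) {
    sub <- p$all %||% p$any
    if (!length(sub)) key_schema_stop("empty all/any predicate", couplet)
    for (q in sub) check_predicate_structure(q, char_ids, couplet)
    return(invisible(TRUE))
  }
  if (!is.null(p$not)) return(check_predicate_structure(p$not, char_ids, couplet))
  if (is.null(p$char) || !p$char %in% char_ids)
    key_schema_stop(paste0("predicate references undeclared character: ",
                           p$char %||% "<missing>"), couplet)
  ops <- intersect(c("eq", "in", "le", "ge", "lt", "gt"), names(p))
  if (length(ops) != 1)
    key_schema_stop("predicate needs exactly one of eq/in/le/ge/lt/gt", couplet)
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a dichotomous identification key
#'
#' Loads one of the packaged keys (`"india_species_groups"`: 12 couplets
#' resolving the 13 Indian species groups; `"inglebyi_group"` and
#' `"tonganum_group"`: species keys with 5 terminals each) or a user JSON
#' key file conforming to the published schema
#' (`inst/extdata/keys/key-schema.json`). The key is structurally validated
#' on load; schema violations raise an error naming the offending couplet.
#'
#' @param key_id Packaged key id or path to a key JSON file.
#' @return Object of class `"dichotomous_key"`: list with `key_id`, `title`,
#'   `characters` (named list of character definitions), `couplets` (named
#'   by couplet number), `terminals`.
#' @examples
#' k <- load_key("tonganum_group")
#' k$terminals
#' @export
load_key <- function(key_id) {
  k <- jsonlite::read_json(key_file(key_id))
  check_key_structure(k)
  chars <- stats::setNames(k$characters,
                           vapply(k$characters, `[[`, character(1), "id"))
  chars <- lapply(chars, function(ch) {
    if (!is.null(ch$states)) ch$states <- unlist(ch$states)
    if (!is.null(ch$domain)) ch$domain <- unlist(ch$domain)
    ch
  })
  couplets <- stats::setNames(
    k$couplets, vapply(k$couplets, function(cp) as.character(cp$number), character(1)))
  terminals <- sort(unique(unlist(lapply(k$couplets, function(cp)
    lapply(cp$leads, function(ld) ld$terminal)))))
  structure(list(key_id = k$key_id, title = k$title, notes = unlist(k$notes),
                 characters = chars, couplets = couplets, terminals = terminals),
            class = "dichotomous_key")
}

#' @export
print.dichotomous_key <- function(x, ...) {
  cat(sprintf("Dichotomous key '%s': %d couplets, %d terminals, %d characters\n",
              x$key_id, length(x$couplets), length(x$terminals),
              length(x$characters)))
  cat(" ", x$title, "\n")
  invisible(x)
}

char_domain_values <- function(ch) {
  switch(ch$kind,
         boolean = c(TRUE, FALSE),
         categorical = ch$states,
         count = seq(ch$domain[1], ch$domain[2]),
         quantitative = tk_stop(
           paste0("quantitative character ", ch$id, " has no finite domain"),
           "tetrakey_validation_error"))
}

value_in_domain <- function(ch, v) {
  switch(ch$kind,
         boolean = is.logical(v) || v %in% c("true", "false"),
         categorical = v %in% ch$states,
         count = is.numeric(v) && v >= ch$domain[1] && v <= ch$domain[2] &&
           abs(v - round(v)) < 1e-9,
         quantitative = is.numeric(v) && v >= ch$domain[1] && v <= ch$domain[2])
}

normalize_value <- function(ch, v) {
  if (ch$kind == "boolean" && is.character(v)) return(tolower(v) == "true")
  if (ch$kind %in% c("count", "quantitative")) return(as.numeric(v))
  v
}

#' Build a specimen state vector for a key
#'
#' @param key A [load_key()] result (or key id).
#' @param ... Named character states; omit a character (or pass `NA`) to
#'   leave it UNKNOWN. A single named list may be passed instead.
#' @return Named list over all of the key's characters with class
#'   `"state_vector"`; UNKNOWN entries are `NA`.
#' @details Every supplied value must lie in its character's declared
#'   domain; unknown characters or out-of-domain values raise a validation
#'   error.
#' @export
state_vector <- function(key, ...) {
  if (is.character(key)) key <- load_key(key)
  vals <- list(...)
  if (length(vals) == 1L && is.null(names(vals)) && is.list(vals[[1]]))
    vals <- vals[[1]]
  bad <- setdiff(names(vals), names(key$characters))
  if (length(bad))
    tk_stop(paste0("undeclared character(s): ", paste(bad, collapse = ", ")),
            "tetrakey_validation_error")
  sv <- stats::setNames(vector("list", length(key$characters)), names(key$characters))
  sv[] <- NA
  for (id in names(vals)) {
    v <- vals[[id]]
    if (is.null(v) || (length(v) == 1L && is.na(v))) next
    ch <- key$characters[[id]]
    v <- normalize_value(ch, v)
    if (!value_in_domain(ch, v))
      tk_stop(sprintf("value '%s' outside domain of character %s", format(v), id),
              "tetrakey_validation_error")
    sv[[id]] <- v
  }
  structure(sv, key_id = key$key_id, class = "state_vector")
}

is_unknown <- function(sv, id) {
  v <- sv[[id]]
  is.null(v) || (length(v) == 1L && is.na(v))
}

# Kleene 3-valued evaluation: TRUE / FALSE / NA (unknown)
eval_predicate <- function(p, sv) {
  if (!is.null(p$all)) {
    vals <- vapply(p$all, function(q) eval_predicate(q, sv), logical(1))
    if (any(!vals, na.rm = TRUE)) return(FALSE)
    if (anyNA(vals)) return(NA)
    return(TRUE)
  }
  if (!is.null(p$any)) {
    vals <- vapply(p$any, function(q) eval_predicate(q, sv), logical(1))
    if (any(vals, na.rm = TRUE)) return(TRUE)
    if (anyNA(vals)) return(NA)
    return(FALSE)
  }
  if (!is.null(p$not)) return(!eval_predicate(p$not, sv))
  if (is_unknown(sv, p$char)) return(NA)
  v <- sv[[p$char]]
  if (!is.null(p[["eq"]])) return(isTRUE(all.equal(v, p[["eq"]])) || identical(v, p[["eq"]]))
  if (!is.null(p[["in"]])) return(v %in% unlist(p[["in"]]))
  if (!is.null(p[["le"]])) return(v <= p[["le"]])
  if (!is.null(p[["ge"]])) return(v >= p[["ge"]])
  if (!is.null(p[["lt"]])) return(v < p[["lt"]])
  if (!is.null(p[["gt"]])) return(v > p[["gt"]])
  tk_stop("malformed predicate", "tetrakey_key_schema_error")
}

predicate_chars <- function(p) {
  if (!is.null(p$all)) return(unique(unlist(lapply(p$all, predicate_chars))))
  if (!is.null(p$any)) return(unique(unlist(lapply(p$any, predicate_chars))))
  if (!is.null(p$not)) return(predicate_chars(p$not))
  p$char
}

key_graph <- function(key) {
  # adjacency over couplet numbers; terminals excluded
  lapply(key$couplets, function(cp)
    unlist(lapply(cp$leads, function(ld)
      if (!is.null(ld$goto)) as.integer(ld$goto) else integer(0))))
}

#' Structural diagnostics for a dichotomous key
#'
#' Reports reachability from couplet 1, cycles in the GOTO graph, terminal
#' counts (and whether terminal count equals couplets + 1 for tree-shaped
#' keys), couplets whose two lead predicates can both hold for some state
#' vector (overlap), and couplets with value combinations satisfying
#' neither lead (gaps, e.g. ommatidia counts falling between a "at most
#' five or six" and an "at least 10 or 11" lead). Diagnostics, not
#' exceptions: a structurally broken file already fails at [load_key()].
#'
#' @param key A [load_key()] result or key id.
#' @return List of class `"key_diagnostics"`; element `gaps` / `overlaps`
#'   are data.frames naming the couplet and the offending state
#'   combination.
#' @export
validate_key <- function(key) {
  if (is.character(key)) key <- load_key(key)
  adj <- key_graph(key)
  nums <- as.integer(names(key$couplets))

  reached <- integer(0); frontier <- 1L
  while (length(frontier)) {
    reached <- union(reached, frontier)
    frontier <- setdiff(unlist(adj[as.character(frontier)]), reached)
  }
  unreachable <- setdiff(nums, reached)

  # cycle detection by DFS colouring
  state <- stats::setNames(rep(0L, length(nums)), nums)
  cycles <- FALSE
  visit <- function(n) {
    if (state[[as.character(n)]] == 1L) { cycles <<- TRUE; return() }
    if (state[[as.character(n)]] == 2L) return()
    state[[as.character(n)]] <<- 1L
    for (m in adj[[as.character(n)]]) visit(m)
    state[[as.character(n)]] <<- 2L
  }
  visit(1L)

  indegree <- table(factor(unlist(adj), levels = nums))
  tree_shaped <- all(indegree <= 1)

  overlaps <- list(); gaps <- list()
  for (cp in key$couplets) {
    chars <- unique(c(predicate_chars(cp$leads[[1]]$predicate),
                      predicate_chars(cp$leads[[2]]$predicate)))
    combos <- expand.grid(lapply(key$characters[chars], char_domain_values),
                          stringsAsFactors = FALSE)
    for (i in seq_len(nrow(combos))) {
      sv <- as.list(combos[i, , drop = FALSE])
      a <- eval_predicate(cp$leads[[1]]$predicate, sv)
      b <- eval_predicate(cp$leads[[2]]$predicate, sv)
      lab <- paste(sprintf("%s=%s", chars, unlist(lapply(sv, format))),
                   collapse = ", ")
      if (isTRUE(a) && isTRUE(b))
        overlaps[[length(overlaps) + 1L]] <-
          data.frame(couplet = cp$number, states = lab)
      if (identical(a, FALSE) && identical(b, FALSE))
        gaps[[length(gaps) + 1L]] <-
          data.frame(couplet = cp$number, states = lab)
    }
  }
  empty <- data.frame(couplet = integer(0), states = character(0))
  structure(list(
    key_id = key$key_id,
    n_couplets = length(key$couplets),
    n_terminals = length(key$terminals),
    unreachable = unreachable,
    acyclic = !cycles,
    tree_shaped = tree_shaped,
    terminal_count_ok = !tree_shaped ||
      length(key$terminals) == length(key$couplets) + 1L,
    overlaps = if (length(overlaps)) do.call(rbind, overlaps) else empty,
    gaps = if (length(gaps)) do.call(rbind, gaps) else empty
  ), class = "key_diagnostics")
}

#' @export
print.key_diagnostics <- function(x, ...) {
  cat(sprintf("Key '%s': %d couplets, %d terminals\n",
              x$key_id, x$n_couplets, x$n_terminals))
  cat(sprintf("  acyclic: %s; unreachable couplets: %s\n", x$acyclic,
              if (length(x$unreachable)) paste(x$unreachable, collapse = ", ")
              else "none"))
  cat(sprintf("  tree-shaped: %s; terminals == couplets + 1: %s\n",
              x$tree_shaped, x$terminal_count_ok))
  cat(sprintf("  lead overlaps: %d; lead gaps: %d\n",
              nrow(x$overlaps), nrow(x$gaps)))
  if (nrow(x$gaps)) {
    cat("  gap states (satisfy neither lead):\n")
    for (i in seq_len(nrow(x$gaps)))
      cat(sprintf("    couplet %d: %s\n", x$gaps$couplet[i], x$gaps$states[i]))
  }
  invisible(x)
}

traversal_result <- function(key, outcomes, path, consulted,
                             ambiguous = length(outcomes) != 1L,
                             warnings = character(0), conflicts = character(0)) {
  structure(list(key_id = key$key_id, outcome = outcomes, path = path,
                 ambiguous = ambiguous, consulted = unique(consulted),
                 warnings = warnings, conflicts = conflicts),
            class = "traversal_result")
}

empty_path <- function() {
  data.frame(couplet = integer(0), lead = integer(0), text = character(0),
             stringsAsFactors = FALSE)
}

#' Traverse a key deterministically
#'
#' Walks the key from couplet 1 following the single lead whose predicate
#' holds for the specimen's state vector. All characters consulted on the
#' realized path must be known; at each couplet exactly one lead may hold.
#'
#' @param key A [load_key()] result or key id.
#' @param sv A [state_vector()].
#' @return A `"traversal_result"`: single terminal `outcome`, the ordered
#'   `path` (couplet, chosen lead, lead text), consulted characters, and any
#'   advisory warnings.
#' @section Errors:
#' * `tetrakey_ambiguous_state` if an UNKNOWN character is consulted
#'   (use [traverse_partial()] instead);
#' * `tetrakey_key_conflict` if both or neither lead holds at a couplet
#'   (e.g. an ommatidia count of 7-9 falling in the documented gap of the
#'   eye-size couplet).
#' @export
traverse <- function(key, sv) {
  if (is.character(key)) key <- load_key(key)
  path <- empty_path(); consulted <- character(0); warns <- character(0)
  current <- 1L
  for (step in seq_along(key$couplets)) {
    cp <- key$couplets[[as.character(current)]]
    vals <- vapply(cp$leads, function(ld) eval_predicate(ld$predicate, sv), logical(1))
    chars <- unique(c(predicate_chars(cp$leads[[1]]$predicate),
                      predicate_chars(cp$leads[[2]]$predicate)))
    consulted <- c(consulted, chars)
    if (anyNA(vals)) {
      unk <- chars[vapply(chars, function(id) is_unknown(sv, id), logical(1))]
      tk_stop(sprintf(
        "couplet %d consults UNKNOWN character(s) %s; use traverse_partial()",
        cp$number, paste(unk, collapse = ", ")),
        "tetrakey_ambiguous_state", couplet = cp$number, characters = unk)
    }
    if (sum(vals) != 1L)
      tk_stop(sprintf("couplet %d: %s lead satisfied by the state vector",
                      cp$number, if (any(vals)) "both leads" else "neither"),
              "tetrakey_key_conflict", couplet = cp$number)
    i <- which(vals)
    ld <- cp$leads[[i]]
    if (!is.null(ld$advisory) && identical(eval_predicate(ld$advisory, sv), FALSE))
      warns <- c(warns, sprintf(
        "couplet %d lead %d: advisory characters conflict with the chosen lead",
        cp$number, i))
    path <- rbind(path, data.frame(couplet = cp$number, lead = i,
                                   text = ld$text, stringsAsFactors = FALSE))
    if (!is.null(ld$terminal))
      return(traversal_result(key, ld$terminal, path, consulted,
                              ambiguous = FALSE, warnings = warns))
    current <- as.integer(ld$goto)
  }
  tk_stop("traversal did not terminate (cyclic key?)", "tetrakey_key_schema_error")
}

#' Set-valued traversal under partial knowledge
#'
#' Returns exactly the set of terminals reachable under some completion of
#' the UNKNOWN characters of `sv` (possible-worlds semantics). Implemented
#' by lazy value branching: when a couplet consults an UNKNOWN character,
#' the traversal branches over that character's declared domain, so a value
#' chosen on one branch stays fixed along the whole path. Known values that
#' satisfy neither lead of a couplet are dead ends (flagged as conflicts),
#' consistent with completion semantics; set such a character to UNKNOWN to
#' explore both leads instead.
#'
#' @inheritParams traverse
#' @return A `"traversal_result"` whose `outcome` is the terminal set
#'   (ambiguity flag true unless it is a singleton).
#' @export
traverse_partial <- function(key, sv) {
  if (is.character(key)) key <- load_key(key)
  consulted <- character(0); conflicts <- character(0)

  recurse <- function(current, sv) {
    cp <- key$couplets[[as.character(current)]]
    chars <- unique(c(predicate_chars(cp$leads[[1]]$predicate),
                      predicate_chars(cp$leads[[2]]$predicate)))
    consulted <<- union(consulted, chars)
    vals <- vapply(cp$leads, function(ld) eval_predicate(ld$predicate, sv), logical(1))
    if (anyNA(vals)) {
      unk <- chars[vapply(chars, function(id) is_unknown(sv, id), logical(1))][1]
      out <- character(0)
      for (v in char_domain_values(key$characters[[unk]])) {
        sv2 <- sv; sv2[[unk]] <- v
        out <- union(out, recurse(current, sv2))
      }
      return(out)
    }
    if (!any(vals)) {
      conflicts <<- union(conflicts, sprintf(
        "couplet %d: known states satisfy neither lead", cp$number))
      return(character(0))
    }
    out <- character(0)
    for (i in which(vals)) {
      ld <- cp$leads[[i]]
      out <- union(out, if (!is.null(ld$terminal)) ld$terminal
                   else recurse(as.integer(ld$goto), sv))
    }
    out
  }

  outcomes <- sort(recurse(1L, sv))
  traversal_result(key, outcomes, empty_path(), consulted,
                   ambiguous = length(outcomes) != 1L, conflicts = conflicts)
}

#' @export
print.traversal_result <- function(x, ...) {
  cat(sprintf("Key '%s' -> %s%s\n", x$key_id,
              if (length(x$outcome)) paste(x$outcome, collapse = " | ")
              else "<no outcome>",
              if (x$ambiguous) " (ambiguous)" else ""))
  if (nrow(x$path))
    for (i in seq_len(nrow(x$path)))
      cat(sprintf("  [%d%s] %s\n", x$path$couplet[i],
                  c("A", "B")[x$path$lead[i]], x$path$text[i]))
  for (w in x$warnings) cat("  warning:", w, "\n")
  for (w in x$conflicts) cat("  conflict:", w, "\n")
  invisible(x)
}
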