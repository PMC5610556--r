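test_that("packaged keys load with the expected structure", {
  k <- load_key("india_species_groups")
  expect_equal(length(k$couplets), 12)
  expect_equal(length(k$terminals), 13)
  ki <- load_key("inglebyi_group")
  expect_setequal(ki$terminals,
                  c("inglebyi", "elisabethae", "triangulatum", "myops", "jarawa"))
  kt <- load_key("tonganum_group")
  expect_setequal(kt$terminals,
                  c("krishnani", "barryi", "christiei", "tonganum", "salvatum"))
  expect_true("tonganum" %in% kt$terminals)  # retained despite exclusion
})

test_that("key schema violations are rejected with the couplet number", {
  bad <- list(
    key_id = "bad", title = "t",
    characters = list(list(id = "x", kind = "boolean", description = "d")),
    couplets = list(
      list(number = 1, leads = list(
        list(text = "a", predicate = list(char = "x", eq = TRUE), goto = 2),
        list(text = "b", predicate = list(char = "x", eq = FALSE), terminal = "t1"))),
      list(number = 2, leads = list(
        list(text = "c", predicate = list(char = "x", eq = TRUE), goto = 9),
        list(text = "d", predicate = list(char = "x", eq = FALSE), terminal = "t2")))))
  err <- tryCatch(load_key(write_temp_key(bad)), tetrakey_key_schema_error = identity)
  expect_s3_class(err, "tetrakey_key_schema_error")
  expect_match(conditionMessage(err), "couplet 2")
  expect_match(conditionMessage(err), "GOTO target 9")

  bad$couplets[[2]]$leads[[1]]$goto <- NULL
  bad$couplets[[2]]$leads[[1]]$terminal <- "t3"
  expect_silent(load_key(write_temp_key(bad)))

  bad$couplets[[1]]$leads <- bad$couplets[[1]]$leads[1]
  expect_error(load_key(write_temp_key(bad)), class = "tetrakey_key_schema_error")

  bad2 <- list(key_id = "bad2", title = "t",
               characters = list(list(id = "x", kind = "boolean", description = "d")),
               couplets = list(list(number = 1, leads = list(
                 list(text = "a", predicate = list(char = "nope", eq = TRUE),
                      terminal = "t1"),
                 list(text = "b", predicate = list(char = "x", eq = FALSE),
                      terminal = "t2")))))
  expect_error(load_key(write_temp_key(bad2)), class = "tetrakey_key_schema_error")
  expect_error(load_key("no_such_key"), class = "tetrakey_key_schema_error")
})

test_that("validate_key reports structure and exactly the documented gaps", {
  d <- validate_key("india_species_groups")
  expect_equal(d$n_couplets, 12)
  expect_equal(d$n_terminals, 13)
  expect_length(d$unreachable, 0)
  expect_true(d$acyclic)
  expect_true(d$tree_shaped)
  expect_true(d$terminal_count_ok)
  expect_equal(nrow(d$overlaps), 0)
  # documented gaps only: 10-segmented antennae at couplet 3, ommatidia 7-9
  # at couplet 8, intermediate spines at couplet 12
  expect_setequal(
    paste(d$gaps$couplet, d$gaps$states),
    c("3 antennal_segments=10",
      "8 ommatidia_longest_row=7", "8 ommatidia_longest_row=8",
      "8 ommatidia_longest_row=9",
      "12 propodeal_spines_relative=intermediate"))

  for (id in c("inglebyi_group", "tonganum_group")) {
    dk <- validate_key(id)
    expect_equal(dk$n_terminals, 5)
    expect_equal(dk$n_couplets, 4)
    expect_true(dk$acyclic && dk$tree_shaped && dk$terminal_count_ok)
    expect_length(dk$unreachable, 0)
    expect_equal(nrow(dk$overlaps), 0)
  }
  expect_equal(nrow(validate_key("tonganum_group")$gaps), 0)
})

test_that("validate_key flags overlapping leads on a synthetic key", {
  k <- list(key_id = "overlap", title = "t",
            characters = list(list(id = "x", kind = "categorical",
                                   states = list("a", "b"), description = "d")),
            couplets = list(list(number = 1, leads = list(
              list(text = "A", predicate = list(char = "x", "in" = list("a", "b")),
                   terminal = "t1"),
              list(text = "B", predicate = list(char = "x", eq = "a"),
                   terminal = "t2")))))
  d <- validate_key(load_key(write_temp_key(k)))
  expect_gt(nrow(d$overlaps), 0)
  expect_equal(d$overlaps$states[1], "x=a")
})

test_that("traverse resolves the worked specimens along the printed paths", {
  kg <- load_key("india_species_groups")
  sv_jarawa <- state_vector(kg, branched_hairs = FALSE, antennal_segments = 12,
                            head_cordate = FALSE, clypeal_lateral_ridge = "sharp_high",
                            sting_appendage = "dentiform", gaster_base_horns = TRUE,
                            ommatidia_longest_row = 3)
  res <- traverse(kg, sv_jarawa)
  expect_equal(res$outcome, "inglebyi group")
  expect_false(res$ambiguous)
  expect_equal(res$path$couplet, c(1, 3, 5, 6, 7, 8))
  expect_true("ommatidia_longest_row" %in% res$consulted)

  kt <- load_key("tonganum_group")
  res2 <- traverse(kt, state_vector(kt, propodeal_armament = "unarmed"))
  expect_equal(res2$outcome, "krishnani")
  expect_equal(nrow(res2$path), 1)
  expect_equal(res2$path$couplet, 1)
  expect_match(res2$path$text, "Propodeum unarmed without teeth or spines")

  ki <- load_key("inglebyi_group")
  res3 <- traverse(ki, state_vector(ki, eye_length_vs_scape_width = "longer"))
  expect_equal(res3$outcome, "inglebyi")
  expect_equal(nrow(res3$path), 1)
})

test_that("traverse errors: UNKNOWN consulted, gap values, advisory conflicts warn", {
  kg <- load_key("india_species_groups")
  err <- tryCatch(traverse(kg, state_vector(kg)),
                  tetrakey_ambiguous_state = identity)
  expect_s3_class(err, "tetrakey_ambiguous_state")
  expect_match(conditionMessage(err), "traverse_partial")

  # ommatidia count in the documented 7-9 gap -> KeyConflict naming couplet 8
  sv <- state_vector(kg, branched_hairs = FALSE, antennal_segments = 12,
                     head_cordate = FALSE, sting_appendage = "dentiform",
                     gaster_base_horns = TRUE, ommatidia_longest_row = 8)
  err2 <- tryCatch(traverse(kg, sv), tetrakey_key_conflict = identity)
  expect_s3_class(err2, "tetrakey_key_conflict")
  expect_equal(err2$couplet, 8)

  # advisory conflict: spatulate sting but long frontal carinae
  sv3 <- state_vector(kg, branched_hairs = FALSE, antennal_segments = 12,
                      head_cordate = FALSE, sting_appendage = "spatulate",
                      frontal_carinae = "long_well_developed",
                      antennal_scrobes = "absent")
  res3 <- traverse(kg, sv3)
  expect_equal(res3$outcome, "fergusoni group")
  expect_match(res3$warnings, "advisory", all = FALSE)
})

test_that("state vectors reject out-of-domain values and undeclared characters", {
  kg <- load_key("india_species_groups")
  expect_error(state_vector(kg, antennal_segments = 13),
               class = "tetrakey_validation_error")
  expect_error(state_vector(kg, sting_appendage = "frilly"),
               class = "tetrakey_validation_error")
  expect_error(state_vector(kg, no_such_character = 1),
               class = "tetrakey_validation_error")
})

test_that("traverse_partial: trivial cases and the armed-propodeum worked example", {
  kt <- load_key("tonganum_group")
  expect_setequal(traverse_partial(kt, state_vector(kt))$outcome, kt$terminals)
  full <- state_vector(kt, propodeal_armament = "unarmed")
  expect_equal(traverse_partial(kt, full)$outcome, traverse(kt, full)$outcome)
  armed <- traverse_partial(kt, state_vector(kt, propodeal_armament = "armed"))
  expect_setequal(armed$outcome, setdiff(kt$terminals, "krishnani"))
  expect_true(armed$ambiguous)
})

test_that("traverse_partial equals brute-force enumeration over completions", {
  set.seed(101)
  keys <- list(load_key("tonganum_group"), load_key("inglebyi_group"),
               load_key("india_species_groups"))
  for (key in keys) {
    n_draws <- if (length(key$characters) > 8) 12 else 25
    max_unknown <- if (length(key$characters) > 8) 3 else Inf
    for (i in seq_len(n_draws)) {
      sv <- random_partial_sv(key, unknown_prob = 0.5, max_unknown = max_unknown)
      expect_equal(traverse_partial(key, sv)$outcome,
                   brute_force_terminals(key, sv),
                   label = paste(key$key_id, "draw", i))
    }
  }
})

test_that("adding knowledge never enlarges the partial terminal set", {
  set.seed(202)
  key <- load_key("india_species_groups")
  for (i in 1:12) {
    sv <- random_partial_sv(key, unknown_prob = 0.6, max_unknown = 4)
    base <- traverse_partial(key, sv)$outcome
    unknowns <- names(sv)[vapply(names(sv), function(id)
      length(sv[[id]]) == 1L && is.na(sv[[id]]), logical(1))]
    if (!length(unknowns)) next
    id <- sample(unknowns, 1)
    ch <- key$characters[[id]]
    dom <- switch(ch$kind, boolean = c(TRUE, FALSE), categorical = ch$states,
                  count = seq(ch$domain[1], ch$domain[2]))
    sv2 <- sv
    sv2[[id]] <- sample(dom, 1)[[1]]
    expect_true(all(traverse_partial(key, sv2)$outcome %in% base),
                label = paste("draw", i, "known", id))
  }
})
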