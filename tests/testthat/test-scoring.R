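test_that("perfect and worst assessments hit the score boundaries", {
  sch <- default_schema()
  best <- score_cohort(perfect_assessment(sch, "best", n_rooms = 3), sch)
  expect_equal(best$overall, 100, tolerance = 1e-12)
  expect_equal(unlist(best[schema_indices(sch)$index_slug]), rep(10, 10),
               ignore_attr = TRUE, tolerance = 1e-12)
  worst <- score_cohort(worst_assessment(sch, "worst", n_rooms = 2), sch)
  expect_equal(worst$overall, 0, tolerance = 1e-12)
})

test_that("factor scoring follows the response kind contracts", {
  fac <- schema_factors(default_schema())
  flow <- fac[fac$factor_id == "water_flow", ]
  expect_equal(score_factor(flow, "1.0"), flow$weight)   # inclusive boundary
  expect_equal(score_factor(flow, "0.99"), 0)
  drink <- fac[fac$factor_id == "drinkers_per_piglet", ]
  expect_equal(score_factor(drink, "0.1"), drink$weight) # 1 drinker per 10 piglets
  dens <- fac[fac$factor_id == "stocking_density", ]
  # 0.35 m2 available per 30 kg pig comfortably exceeds 0.1 m2 / 10 kg
  expect_equal(score_factor(dens, density_per_10kg(0.35, 30)), dens$weight)
  expect_equal(score_factor(dens, density_per_10kg(0.25, 30)), 0)

  tri <- tibble::tibble(factor_id = "tri", weight = 3, kind = "categorical",
                        options = list(tibble::tibble(label = c("low", "mid", "high"),
                                                      credit = c(0, 0.5, 1))),
                        threshold = NA_real_, direction = NA_character_)
  expect_equal(score_factor(tri, "mid"), 1.5)  # 3.0 x 1/2 equal-spacing credit
  expect_error(score_factor(tri, "nope"), "nope", class = "qsc_contract_error")
  expect_error(score_factor(tri, NA), class = "qsc_missing_response_error")

  bin <- fac[fac$factor_id == "foot_baths", ]
  expect_error(score_factor(bin, "maybe"), class = "qsc_contract_error")
  expect_error(score_factor(flow, "-1"), "Negative", class = "qsc_contract_error")
})

test_that("index scores sum factor points and average across rooms", {
  sch <- default_schema()
  fac <- schema_factors(sch)
  bios <- fac$factor_id[fac$index_slug == "biosecurity"]
  resp <- tibble::tibble(factor_id = bios,
                         value = rep(c("yes", "no"), each = 4))
  res <- score_index(sch, "biosecurity", resp)
  expect_equal(res$points, 4 * 1.25)  # 4 of 8 equal-weight factors pass

  # room index with weights 10/3, 2.5, 25/6: rooms scoring 3.33 and 5.83
  msch <- mini_schema()
  rr <- rbind(
    data.frame(room_id = "A", factor_id = c("r_a", "r_b", "r_c"),
               value = c("yes", "no", "no")),
    data.frame(room_id = "B", factor_id = c("r_a", "r_b", "r_c"),
               value = c("yes", "yes", "no")))
  res <- score_index(msch, "rooms", rr)
  expect_equal(res$per_room$points, c(10 / 3, 10 / 3 + 2.5), tolerance = 1e-12)
  expect_equal(res$points, mean(c(10 / 3, 10 / 3 + 2.5)), tolerance = 1e-12)
  expect_equal(round(res$points, 2), 4.58)

  # six rooms at {10, 10, 10, 0, 0, 0} average to 5
  rr6 <- do.call(rbind, lapply(1:6, function(i) {
    data.frame(room_id = sprintf("R%d", i), factor_id = c("r_a", "r_b", "r_c"),
               value = if (i <= 3) "yes" else "no")
  }))
  expect_equal(score_index(msch, "rooms", rr6)$points, 5, tolerance = 1e-12)
  # idempotence: identical rooms give that same score
  expect_equal(score_index(msch, "rooms", rr6[rr6$room_id %in% c("R1", "R2"), ])$points,
               10, tolerance = 1e-12)
})

test_that("an assessment passing half of each equal-weight index scores 50", {
  sch <- pigqsc:::new_schema("test", lapply(1:10, function(i) {
    make_index(i, paste0("i", i),
               if (i >= 8) "room" else "farm",
               lapply(1:4, function(j) bin_factor(sprintf("q%d_%d", i, j), 2.5)))
  }))
  resp <- random_assessment(sch, "half", n_rooms = 1)
  resp$value <- rep(c("yes", "yes", "no", "no"), times = 10)
  sc <- score_cohort(resp, sch)
  expect_equal(sc$overall, 50, tolerance = 1e-12)
})

test_that("scores stay in bounds and match the brute-force oracle", {
  set.seed(101)
  for (rep in 1:25) {
    sch <- random_schema(n_idx = sample(2:4, 1))
    resp <- random_assessment(sch, "farm_x", n_rooms = sample(1:4, 1))
    sc <- score_cohort(resp, sch)
    idx_cols <- vapply(sch$indices, function(i) i$slug, character(1))
    expect_true(all(unlist(sc[idx_cols]) >= -1e-12))
    expect_true(all(unlist(sc[idx_cols]) <= 10 + 1e-12))
    expect_equal(sc$overall, oracle_overall(resp, sch, "farm_x"), tolerance = 1e-9)
    expect_equal(sc$overall, sum(unlist(sc[idx_cols])), tolerance = 1e-9)
  }
})

test_that("improving any single response never lowers a score", {
  set.seed(202)
  for (rep in 1:10) {
    sch <- random_schema(n_idx = 3)
    resp <- random_assessment(sch, "f", n_rooms = 2)
    base <- score_cohort(resp, sch)$overall
    facs <- unlist(lapply(sch$indices, function(i) i$factors), recursive = FALSE)
    names(facs) <- vapply(facs, function(f) f$id, character(1))
    for (k in sample(nrow(resp), 8)) {
      f <- facs[[resp$factor_id[k]]]
      improved <- resp
      improved$value[k] <- switch(f$response$kind,
        binary = "yes",
        categorical = f$response$options[[length(f$response$options)]]$label,
        numeric_threshold = if (f$response$direction == "<=") "0"
                            else format(f$response$threshold * 3))
      expect_gte(score_cohort(improved, sch)$overall + 1e-9, base)
    }
  }
})

test_that("room order does not affect scores", {
  set.seed(303)
  sch <- random_schema(n_idx = 3)
  resp <- random_assessment(sch, "f", n_rooms = 4)
  shuffled <- resp[sample(nrow(resp)), ]
  relabel <- c(room_1 = "room_9", room_2 = "room_3", room_3 = "room_5",
               room_4 = "room_0")
  shuffled$room_id <- ifelse(is.na(shuffled$room_id), NA,
                             relabel[shuffled$room_id])
  expect_equal(score_cohort(shuffled, sch)$overall,
               score_cohort(resp, sch)$overall, tolerance = 1e-12)
})

test_that("missing responses error in strict mode and score 0 when lenient", {
  sch <- default_schema()
  resp <- perfect_assessment(sch, "farm_a", n_rooms = 2)
  dropped <- resp[resp$factor_id != "quarantine", ]
  expect_error(score_cohort(dropped, sch), "quarantine",
               class = "qsc_missing_response_error")
  expect_warning(sc <- score_cohort(dropped, sch, lenient = TRUE), "missing")
  expect_equal(sc$overall, 100 - 1.25, tolerance = 1e-12)

  dup <- rbind(resp, resp[1, ])
  expect_error(score_cohort(dup, sch), "Duplicate", class = "qsc_contract_error")
  bad <- resp
  bad$factor_id[1] <- "not_a_factor"
  expect_error(score_cohort(bad, sch), "not_a_factor", class = "qsc_contract_error")
})

test_that("cohort scoring preserves farm order and handles empty input", {
  sch <- default_schema()
  many <- dplyr::bind_rows(lapply(sprintf("farm_%02d", 5:1), function(f)
    perfect_assessment(sch, f, n_rooms = 1)))
  sc <- score_cohort(many, sch)
  expect_identical(sc$farm_id, sprintf("farm_%02d", 5:1))
  empty <- score_cohort(perfect_assessment(sch)[0, ], sch)
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("overall", "biosecurity") %in% names(empty)))
})

test_that("a single farm with localized heating out of 23 gives 4.3% prevalence", {
  sch <- default_schema()
  farms <- sprintf("farm_%02d", 1:23)
  resp <- dplyr::bind_rows(lapply(farms, function(f)
    worst_assessment(sch, f, n_rooms = 2)))
  resp$value[resp$farm_id == "farm_07" & resp$factor_id == "heating_system"] <-
    "localized_heating"
  prev <- response_prevalence(resp, "heating_system", sch)
  expect_identical(prev$n_with_practice, 1L)
  expect_equal(round(100 * prev$prevalence, 1), 4.3)
})

test_that("assessment tables survive a write/read round trip", {
  sch <- default_schema()
  resp <- perfect_assessment(sch, "farm_rt", n_rooms = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_assessments(resp, path)
  again <- read_assessments(path)
  expect_equal(as.data.frame(again), as.data.frame(resp))
  expect_equal(score_cohort(again, sch)$overall, 100)
})
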