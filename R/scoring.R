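#' Farm assessments in long format
#'
#' An assessment is a tidy long table of checklist responses with columns
#' `farm_id`, `room_id`, `factor_id`, `value`.  Responses to farm-level
#' factors (indices 1-7) carry `room_id = NA`; responses to the room-level
#' facility factors (temperature, ventilation, floor/density) are recorded
#' once per post-weaning room.  `value` is character and is parsed according
#' to the factor's response kind: `"yes"`/`"no"` (also `true/false/1/0`) for
#' binary factors, an option label for categorical factors, and a number in
#' the threshold's units for numeric-threshold factors.
#'
#' @name qsc_assessment
NULL

TRUE_VALUES <- c("yes", "true", "1", "y")
FALSE_VALUES <- c("no", "false", "0", "n")

# vectorized credit fraction in [0,1] for responses joined to their factor
# definitions; `missing` (NA value) handled by the caller
response_credit <- function(value, kind, options, threshold, direction, factor_id) {
  credit <- rep(NA_real_, length(value))
  vlow <- tolower(trimws(value))

  is_bin <- kind == "binary"
  if (any(is_bin)) {
    ok_t <- is_bin & vlow %in% TRUE_VALUES
    ok_f <- is_bin & vlow %in% FALSE_VALUES
    credit[ok_t] <- 1
    credit[ok_f] <- 0
    bad <- is_bin & !ok_t & !ok_f & !is.na(value)
    if (any(bad)) {
      abort(sprintf("Invalid binary response for factor `%s`: \"%s\" (use yes/no)",
                    factor_id[which(bad)[1]], value[which(bad)[1]]),
            class = "qsc_contract_error")
    }
  }

  is_cat <- kind == "categorical"
  if (any(is_cat)) {
    for (i in which(is_cat & !is.na(value))) {
      opt <- options[[i]]
      j <- match(value[i], opt$label)
      if (is.na(j)) {
        abort(sprintf("Unknown option \"%s\" for factor `%s` (expected one of: %s)",
                      value[i], factor_id[i], paste(opt$label, collapse = ", ")),
              class = "qsc_contract_error")
      }
      credit[i] <- opt$credit[j]
    }
  }

  is_num <- kind == "numeric_threshold"
  if (any(is_num)) {
    x <- suppressWarnings(as.numeric(value[is_num]))
    bad <- is.na(x) & !is.na(value[is_num])
    if (any(bad)) {
      k <- which(is_num)[which(bad)[1]]
      abort(sprintf("Non-numeric response \"%s\" for threshold factor `%s`",
                    value[k], factor_id[k]), class = "qsc_contract_error")
    }
    if (any(x < 0, na.rm = TRUE)) {
      k <- which(is_num)[which(x < 0)[1]]
      abort(sprintf("Negative measured value for factor `%s`", factor_id[k]),
            class = "qsc_contract_error")
    }
    pass <- ifelse(direction[is_num] == "<=", x <= threshold[is_num],
                   x >= threshold[is_num])
    credit[is_num] <- as.numeric(pass)
  }
  credit
}

check_assessment_frame <- function(responses) {
  needed <- c("farm_id", "factor_id", "value")
  missing_cols <- setdiff(needed, names(responses))
  if (length(missing_cols) > 0) {
    abort(sprintf("Assessment table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")), class = "qsc_contract_error")
  }
  responses <- as_tibble(responses)
  if (!"room_id" %in% names(responses)) responses$room_id <- NA_character_
  responses$room_id <- as.character(responses$room_id)
  responses$room_id[responses$room_id %in% c("", "farm")] <- NA_character_
  responses$farm_id <- as.character(responses$farm_id)
  responses$factor_id <- as.character(responses$factor_id)
  responses$value <- as.character(responses$value)
  dup <- duplicated(responses[c("farm_id", "room_id", "factor_id")])
  if (any(dup)) {
    d <- responses[which(dup)[1], ]
    abort(sprintf("Duplicate response for farm `%s`%s factor `%s`",
                  d$farm_id,
                  if (is.na(d$room_id)) "" else sprintf(" room `%s`", d$room_id),
                  d$factor_id), class = "qsc_contract_error")
  }
  responses
}

# per-response points for a whole cohort; strict mode errors on any missing
# coverage, lenient scores missing as 0 with one warning
scored_responses <- function(responses, schema, lenient = FALSE) {
  responses <- check_assessment_frame(responses)
  fac <- schema_factors(schema)

  unknown <- setdiff(unique(responses$factor_id), fac$factor_id)
  if (length(unknown) > 0) {
    abort(sprintf("Response(s) reference unknown factor id(s): %s",
                  paste(unknown, collapse = ", ")), class = "qsc_contract_error")
  }

  r <- left_join(responses, fac, by = "factor_id")
  misplaced <- r$level == "farm" & !is.na(r$room_id)
  if (any(misplaced)) {
    k <- which(misplaced)[1]
    abort(sprintf("Farm-level factor `%s` answered inside room `%s` of farm `%s`",
                  r$factor_id[k], r$room_id[k], r$farm_id[k]),
          class = "qsc_contract_error")
  }
  misplaced <- r$level == "room" & is.na(r$room_id)
  if (any(misplaced)) {
    k <- which(misplaced)[1]
    abort(sprintf("Room-level factor `%s` answered without a room_id for farm `%s`",
                  r$factor_id[k], r$farm_id[k]), class = "qsc_contract_error")
  }

  farms <- unique(responses$farm_id)
  rooms <- distinct(filter(responses, !is.na(.data$room_id)),
                    .data$farm_id, .data$room_id)
  no_rooms <- setdiff(farms, rooms$farm_id)
  if (length(no_rooms) > 0 && any(fac$level == "room")) {
    abort(sprintf("Farm(s) without any post-weaning room responses: %s",
                  paste(head(no_rooms, 5), collapse = ", ")),
          class = "qsc_missing_response_error")
  }

  # full expected coverage grid: farm factors per farm, room factors per room
  grid <- bind_rows(
    tidyr::crossing(farm_id = farms, room_id = NA_character_,
                    factor_id = fac$factor_id[fac$level == "farm"]),
    tidyr::crossing(rooms, factor_id = fac$factor_id[fac$level == "room"])
  )
  missing_rows <- anti_join(grid, r, by = c("farm_id", "room_id", "factor_id"))
  value_missing <- is.na(r$value)
  n_missing <- nrow(missing_rows) + sum(value_missing)
  if (n_missing > 0) {
    if (!lenient) {
      ex <- if (nrow(missing_rows) > 0) missing_rows[1, ] else
        r[which(value_missing)[1], c("farm_id", "room_id", "factor_id")]
      abort(sprintf("Missing response: farm `%s`%s factor `%s` (%d missing in total; use lenient = TRUE to score missing answers as 0)",
                    ex$farm_id,
                    if (is.na(ex$room_id)) "" else sprintf(" room `%s`", ex$room_id),
                    ex$factor_id, n_missing),
            class = "qsc_missing_response_error")
    }
    warn(sprintf("Lenient scoring: %d missing response(s) scored as 0 points", n_missing))
    if (nrow(missing_rows) > 0) {
      missing_rows$value <- NA_character_
      r <- bind_rows(r, left_join(missing_rows, fac, by = "factor_id"))
    }
  }

  r$credit <- response_credit(r$value, r$kind, r$options, r$threshold,
                              r$direction, r$factor_id)
  r$credit[is.na(r$credit)] <- 0  # lenient-mode missing answers
  r$points <- r$weight * r$credit
  select(r, "farm_id", "room_id", "index_id", "index_slug", "level",
         "factor_id", "weight", "credit", "points")
}

#' Score a cohort of farm assessments
#'
#' Evaluates every farm in a long-format assessment table against a schema.
#' Farm-level index scores are the sum of factor points; the three room-level
#' facility indices are scored per post-weaning room and averaged (unweighted)
#' across the farm's rooms.  A farm answering every factor with best practice
#' scores exactly 10 per index and 100 overall.
#'
#' @param responses Assessment table (see [qsc_assessment]): columns
#'   `farm_id`, `room_id` (NA for farm-level answers), `factor_id`, `value`.
#' @param schema A `qsc_schema`; defaults to [default_schema()].
#' @param lenient If `TRUE`, missing responses score 0 points with a warning
#'   instead of an error (the conservative, limiting-factor reading).
#' @return A tibble with one row per farm, in first-appearance order:
#'   `farm_id`, one column per index slug (points 0-10), and `overall`
#'   (0-100).
#' @export
#' @examples
#' a <- perfect_assessment(farm_id = "demo", n_rooms = 2)
#' score_cohort(a)
score_cohort <- function(responses, schema = default_schema(), lenient = FALSE) {
  responses <- check_assessment_frame(responses)
  farm_order <- unique(responses$farm_id)
  if (length(farm_order) == 0) {
    out <- tibble(farm_id = character())
    for (s in schema_indices(schema)$index_slug) out[[s]] <- numeric()
    out$overall <- numeric()
    return(out)
  }
  sr <- scored_responses(responses, schema, lenient = lenient)

  farm_idx <- sr %>%
    filter(.data$level == "farm") %>%
    group_by(.data$farm_id, .data$index_slug) %>%
    summarise(points = sum(.data$points), .groups = "drop")
  room_idx <- sr %>%
    filter(.data$level == "room") %>%
    group_by(.data$farm_id, .data$room_id, .data$index_slug) %>%
    summarise(points = sum(.data$points), .groups = "drop") %>%
    group_by(.data$farm_id, .data$index_slug) %>%
    summarise(points = mean(.data$points), .groups = "drop")

  slugs <- schema_indices(schema)$index_slug
  wide <- bind_rows(farm_idx, room_idx) %>%
    tidyr::pivot_wider(names_from = "index_slug", values_from = "points")
  for (s in setdiff(slugs, names(wide))) wide[[s]] <- 0
  wide <- wide[match(farm_order, wide$farm_id), c("farm_id", slugs)]
  wide$overall <- rowSums(wide[slugs])
  as_tibble(wide)
}

#' Score a single farm in detail
#'
#' Like [score_cohort()] but for one farm, returning the full scorecard:
#' per-factor points, per-room points for the facility indices, per-index
#' scores and the overall 0-100 total.
#'
#' @inheritParams score_cohort
#' @return A `qsc_scorecard` object: a list with `farm_id`, `index_scores`
#'   (tibble: index_id, index_slug, index_name, level, points),
#'   `factor_points`, `room_points`, and `overall`.
#' @export
score_farm <- function(responses, schema = default_schema(), lenient = FALSE) {
  responses <- check_assessment_frame(responses)
  farms <- unique(responses$farm_id)
  if (length(farms) != 1) {
    abort(sprintf("score_farm() expects exactly one farm, got %d; use score_cohort()",
                  length(farms)), class = "qsc_contract_error")
  }
  sr <- scored_responses(responses, schema, lenient = lenient)
  info <- schema_indices(schema)

  room_points <- sr %>%
    filter(.data$level == "room") %>%
    group_by(.data$index_id, .data$index_slug, .data$room_id) %>%
    summarise(points = sum(.data$points), .groups = "drop")
  idx_room <- room_points %>%
    group_by(.data$index_id, .data$index_slug) %>%
    summarise(points = mean(.data$points), .groups = "drop")
  idx_farm <- sr %>%
    filter(.data$level == "farm") %>%
    group_by(.data$index_id, .data$index_slug) %>%
    summarise(points = sum(.data$points), .groups = "drop")

  index_scores <- info %>%
    left_join(bind_rows(idx_farm, idx_room) %>% select(-"index_slug"),
              by = "index_id") %>%
    mutate(points = ifelse(is.na(.data$points), 0, .data$points)) %>%
    select("index_id", "index_slug", "index_name", "level", "points")

  structure(list(
    farm_id = farms,
    index_scores = index_scores,
    factor_points = select(sr, "room_id", "index_slug", "factor_id",
                           "weight", "credit", "points"),
    room_points = room_points,
    overall = sum(index_scores$points)
  ), class = "qsc_scorecard")
}

#' @export
print.qsc_scorecard <- function(x, ...) {
  cat(sprintf("<qsc_scorecard> farm %s: overall %.2f / 100\n", x$farm_id, x$overall))
  df <- mutate(x$index_scores, points = round(.data$points, 2))
  print(select(df, "index_id", "index_slug", "level", "points"), n = Inf)
  invisible(x)
}

#' Score a single factor response
#'
#' @param definition One row of [schema_factors()] (or a single-row tibble
#'   selecting the factor), carrying `weight`, `kind`, `options`,
#'   `threshold`, `direction`.
#' @param value Response value (character scalar; `"yes"`/`"no"`, an option
#'   label, or a number for threshold factors).
#' @return Points awarded: `weight * credit_fraction`, in `[0, weight]`.
#' @export
#' @examples
#' fac <- schema_factors(default_schema())
#' flow <- fac[fac$factor_id == "water_flow", ]
#' score_factor(flow, "1.0")  # boundary passes inclusively -> full weight
score_factor <- function(definition, value) {
  definition <- as_tibble(definition)
  if (nrow(definition) != 1) {
    abort("`definition` must be a single factor row", class = "qsc_contract_error")
  }
  if (is.na(value)) {
    abort(sprintf("Missing response for factor `%s`", definition$factor_id),
          class = "qsc_missing_response_error")
  }
  credit <- response_credit(as.character(value), definition$kind,
                            definition$options, definition$threshold,
                            definition$direction, definition$factor_id)
  definition$weight * credit
}

#' Score one index from its factor responses
#'
#' Farm-level indices sum factor points; room-level indices are scored per
#' room (via `room_id`) and averaged.
#'
#' @param schema A `qsc_schema`.
#' @param index The index id (1-10) or slug.
#' @param responses Responses covering the index's factors (columns
#'   `factor_id`, `value`, and `room_id` for room-level indices).
#' @return A list: `index_id`, `index_slug`, `points`, `per_factor`
#'   (tibble), `per_room` (tibble, room-level only).
#' @export
score_index <- function(schema, index, responses) {
  info <- schema_indices(schema)
  row <- info[info$index_id == index | info$index_slug == index, ]
  if (nrow(row) != 1) {
    abort(sprintf("Unknown index `%s`", index), class = "qsc_contract_error")
  }
  responses <- as_tibble(responses)
  if (!"farm_id" %in% names(responses)) responses$farm_id <- "farm"
  fac <- schema_factors(schema)
  keep <- fac$factor_id[fac$index_id == row$index_id]
  responses <- filter(responses, .data$factor_id %in% keep)
  if (row$level == "room") {
    if (!"room_id" %in% names(responses) || any(is.na(responses$room_id)) ||
        nrow(responses) == 0) {
      abort(sprintf("Index `%s` is room-level: responses need a non-missing room_id",
                    row$index_slug), class = "qsc_contract_error")
    }
  } else {
    responses$room_id <- NA_character_
  }

  sub_schema <- new_schema(schema$version,
                           Filter(function(i) i$id == row$index_id, schema$indices))
  sr <- scored_responses(responses, sub_schema)
  per_room <- NULL
  if (row$level == "room") {
    per_room <- sr %>%
      group_by(.data$room_id) %>%
      summarise(points = sum(.data$points), .groups = "drop")
    points <- mean(per_room$points)
  } else {
    points <- sum(sr$points)
  }
  list(index_id = row$index_id, index_slug = row$index_slug, points = points,
       per_factor = select(sr, "room_id", "factor_id", "weight", "credit", "points"),
       per_room = per_room)
}

opt_label <- function(options, last = TRUE) {
  vapply(options, function(o) {
    if (is.null(o)) NA_character_ else if (last) o$label[nrow(o)] else o$label[1]
  }, character(1))
}

best_value <- function(kind, options, threshold, direction) {
  dplyr::case_when(
    kind == "binary" ~ "yes",
    kind == "categorical" ~ opt_label(options, last = TRUE),
    # thresholds are inclusive: the boundary value earns full credit
    TRUE ~ as.character(threshold)
  )
}

worst_value <- function(kind, options, threshold, direction) {
  dplyr::case_when(
    kind == "binary" ~ "no",
    kind == "categorical" ~ opt_label(options, last = FALSE),
    direction == "<=" ~ as.character(threshold * 2 + 1),
    TRUE ~ as.character(threshold / 2)
  )
}

assessment_template <- function(schema, farm_id, n_rooms, value_fun) {
  fac <- schema_factors(schema)
  farm_fac <- fac[fac$level == "farm", ]
  room_fac <- fac[fac$level == "room", ]
  farm_rows <- tibble(farm_id = farm_id, room_id = NA_character_,
                      factor_id = farm_fac$factor_id,
                      value = value_fun(farm_fac$kind, farm_fac$options,
                                        farm_fac$threshold, farm_fac$direction))
  room_rows <- tidyr::crossing(
    tibble(farm_id = farm_id),
    room_id = sprintf("room_%02d", seq_len(n_rooms)),
    tibble(factor_id = room_fac$factor_id,
           value = value_fun(room_fac$kind, room_fac$options,
                             room_fac$threshold, room_fac$direction)))
  bind_rows(farm_rows, room_rows)[c("farm_id", "room_id", "factor_id", "value")]
}

#' Template assessments
#'
#' `perfect_assessment()` answers every factor with the best-practice
#' response (scores 100.0); `worst_assessment()` with the worst (scores 0.0).
#' Useful as editing templates for data entry and as fixtures.
#'
#' @param schema A `qsc_schema`.
#' @param farm_id Farm identifier.
#' @param n_rooms Number of identical post-weaning rooms.
#' @return An assessment tibble (see [qsc_assessment]).
#' @export
perfect_assessment <- function(schema = default_schema(), farm_id = "farm_01",
                               n_rooms = 1) {
  assessment_template(schema, farm_id, n_rooms, best_value)
}

#' @rdname perfect_assessment
#' @export
worst_assessment <- function(schema = default_schema(), farm_id = "farm_01",
                             n_rooms = 1) {
  assessment_template(schema, farm_id, n_rooms, worst_value)
}

#' Normalize a stocking-density measurement
#'
#' The floor/density factor is thresholded in m2 per 10 kg live weight.
#' This helper converts an available area per pig and a live weight into
#' that unit, e.g. 0.35 m2 for a 30 kg pig is 0.1167 m2/10 kg, which passes
#' the 0.1 m2/10 kg requirement.
#'
#' @param area_m2 Available area per pig (m2).
#' @param weight_kg Live weight (kg).
#' @return Area per 10 kg live weight (m2/10 kg), as a character value ready
#'   for the assessment table.
#' @export
density_per_10kg <- function(area_m2, weight_kg) {
  stopifnot(area_m2 >= 0, weight_kg > 0)
  format(area_m2 / (weight_kg / 10), digits = 10)
}

#' Prevalence of a best-practice response across farms
#'
#' Share of farms giving the top-credit answer to a factor.  Room-level
#' factors count a farm when any of its rooms gives the top answer by
#' default (`any_room = TRUE`).
#'
#' @param responses Assessment table.
#' @param factor_id Factor to summarise.
#' @param schema A `qsc_schema`.
#' @param any_room For room-level factors, count a farm if any room passes
#'   (`TRUE`, default) or only if all rooms pass.
#' @return A one-row tibble: `factor_id`, `n_farms`, `n_with_practice`,
#'   `prevalence` (fraction in `[0, 1]`).
#' @export
response_prevalence <- function(responses, factor_id, schema = default_schema(),
                                any_room = TRUE) {
  responses <- check_assessment_frame(responses)
  fac <- schema_factors(schema)
  def <- fac[fac$factor_id == factor_id, ]
  if (nrow(def) != 1) {
    abort(sprintf("Unknown factor id `%s`", factor_id), class = "qsc_contract_error")
  }
  n_farms <- length(unique(responses$farm_id))
  sub <- filter(responses, .data$factor_id == !!factor_id)
  sub$credit <- response_credit(sub$value, rep(def$kind, nrow(sub)),
                                rep(def$options, nrow(sub)),
                                rep(def$threshold, nrow(sub)),
                                rep(def$direction, nrow(sub)),
                                rep(def$factor_id, nrow(sub)))
  agg <- if (any_room) max else min
  per_farm <- sub %>%
    group_by(.data$farm_id) %>%
    summarise(top = agg(.data$credit) >= 1, .groups = "drop")
  tibble(factor_id = factor_id, n_farms = n_farms,
         n_with_practice = sum(per_farm$top),
         prevalence = sum(per_farm$top) / n_farms)
}

#' Read / write long-format assessment tables
#'
#' Comma-separated UTF-8 files with a dot decimal separator and columns
#' `farm_id, room_id, factor_id, value`; `room_id` empty or `"farm"` marks
#' farm-level answers.
#'
#' @param path File path.
#' @return `read_assessments()`: an assessment tibble.
#' @export
read_assessments <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  check_assessment_frame(tbl)
}

#' @rdname read_assessments
#' @param responses Assessment tibble to write.
#' @export
write_assessments <- function(responses, path) {
  responses <- check_assessment_frame(responses)
  readr::write_csv(responses, path, na = "")
  invisible(path)
}
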