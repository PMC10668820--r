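cohort_table_columns <- function(schema = default_schema()) {
  c("farm_id", score_columns(schema), kpi_dictionary()$kpi)
}

#' Read / write cohort analysis tables
#'
#' Comma-separated UTF-8, dot decimal separator.  The header must match the
#' documented column dictionary exactly: `farm_id`, the ten index slugs and
#' `overall`, and the eleven KPI columns of [kpi_dictionary()].  Missing or
#' unknown columns and non-numeric cells are reported with names/positions.
#'
#' @param path File path.
#' @param schema Schema defining the score columns.
#' @return `read_cohort_table()`: a tibble, one row per farm.
#' @export
read_cohort_table <- function(path, schema = default_schema()) {
  if (!file.exists(path)) {
    abort(sprintf("Cohort file not found: %s", path), class = "qsc_format_error")
  }
  expected <- cohort_table_columns(schema)
  hdr <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                               show_col_types = FALSE))
  missing_cols <- setdiff(expected, hdr)
  extra_cols <- setdiff(hdr, expected)
  if (length(missing_cols) > 0 || length(extra_cols) > 0) {
    parts <- c(
      if (length(missing_cols) > 0)
        sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
      if (length(extra_cols) > 0)
        sprintf("unknown column(s): %s", paste(extra_cols, collapse = ", ")))
    abort(sprintf("Cohort table header mismatch - %s", paste(parts, collapse = "; ")),
          class = "qsc_format_error")
  }
  spec <- c(list(farm_id = readr::col_character()),
            setNames(rep(list(readr::col_double()), length(expected) - 1),
                     expected[-1]))
  tbl <- suppressWarnings(readr::read_csv(path, col_types = do.call(readr::cols, spec),
                                          show_col_types = FALSE))
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    p <- probs[1, ]
    abort(sprintf("Non-numeric cell in %s at row %d, column `%s` (got \"%s\")",
                  path, p$row - 1L, hdr[p$col], p$actual), class = "qsc_format_error")
  }
  if (anyDuplicated(tbl$farm_id)) {
    abort("Duplicate farm_id in cohort table", class = "qsc_format_error")
  }
  tbl
}

#' @rdname read_cohort_table
#' @param cohort Cohort tibble to write (full precision, round-trip safe).
#' @export
write_cohort_table <- function(cohort, path, schema = default_schema()) {
  cohort <- as_tibble(cohort)
  missing_cols <- setdiff(cohort_table_columns(schema), names(cohort))
  if (length(missing_cols) > 0) {
    abort(sprintf("Cohort table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")), class = "qsc_contract_error")
  }
  readr::write_csv(cohort[cohort_table_columns(schema)], path)
  invisible(path)
}

fmt2 <- function(x) {
  # half-up 2-decimal presentation rounding (sprintf rounds half to even)
  formatC(floor(abs(x) * 100 + 0.5) / 100 * sign(x), format = "f", digits = 2)
}

#' Format a correlation table in the published layout
#'
#' Wide layout, one row per score, one KPI per column, cells rendered as
#' `"0.59 **"` per the significance footnote.
#'
#' @param cor_tbl A `qsc_cor_table` from [correlation_table()].
#' @return A tibble of character cells.
#' @export
format_correlation_table <- function(cor_tbl) {
  stopifnot(inherits(cor_tbl, "qsc_cor_table"))
  as_tibble(cor_tbl) %>%
    mutate(cell = ifelse(is.na(.data$r), "-",
                         trimws(paste(fmt2(.data$r), .data$stars)))) %>%
    select("score", "kpi", "cell") %>%
    tidyr::pivot_wider(names_from = "kpi", values_from = "cell")
}

#' Format a group comparison in the published layout
#'
#' One row per variable, one column per group, cells as
#' `"27.73 a (0.88)"` — mean, SNK letter, SD — plus a `Total` column.
#'
#' @param cmp A `qsc_group_comparison` from [compare_groups()].
#' @return A tibble of character cells.
#' @export
format_group_comparison <- function(cmp) {
  stopifnot(inherits(cmp, "qsc_group_comparison"))
  td <- tidy(cmp)
  all_letters_shared <- td %>%
    group_by(.data$variable) %>%
    summarise(shared = length(Reduce(intersect, strsplit(.data$letters, ""))) > 0,
              .groups = "drop")
  td <- left_join(td, all_letters_shared, by = "variable") %>%
    mutate(cell = ifelse(.data$shared,
                         sprintf("%s (%s)", fmt2(.data$mean), fmt2(.data$sd)),
                         sprintf("%s %s (%s)", fmt2(.data$mean), .data$letters,
                                 fmt2(.data$sd))))
  wide <- td %>%
    select("variable", "group", "cell") %>%
    tidyr::pivot_wider(names_from = "group", values_from = "cell")
  totals <- td %>%
    group_by(.data$variable) %>%
    summarise(Total = {
      nn <- sum(.data$n)
      gm <- sum(.data$mean * .data$n) / nn
      ss <- sum((.data$n - 1) * .data$sd^2 + .data$n * (.data$mean - gm)^2)
      sprintf("%s (%s)", fmt2(gm), fmt2(sqrt(ss / (nn - 1))))
    }, .groups = "drop")
  left_join(wide, totals, by = "variable")[c("variable", cmp$group_levels, "Total")]
}

#' Render the benchmarking report files for a cohort
#'
#' Writes deterministic delimited-text reports to a directory: the score
#' table, descriptive statistics for scores and KPIs, the starred
#' correlation table (formatted and raw), and quartile group comparisons by
#' PWSY and by medication cost.
#'
#' @param cohort_tbl A cohort analysis tibble (scores + KPIs), e.g.
#'   [cohort_table()] output or [read_cohort_table()].
#' @param dir Output directory (created if absent).
#' @param schema Calculator schema (for score column names).
#' @param alpha Significance level for stars and letters.
#' @param percentile Percentile definition for the descriptives.
#' @return Invisibly, the paths written.
#' @export
render_reports <- function(cohort_tbl, dir, schema = default_schema(),
                           alpha = 0.05, percentile = "haverage") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort_tbl <- as_tibble(cohort_tbl)
  paths <- character()
  put <- function(x, name) {
    p <- file.path(dir, name)
    readr::write_csv(x, p)
    paths <<- c(paths, p)
  }
  sc <- intersect(score_columns(schema), names(cohort_tbl))
  kd <- kpi_dictionary()
  kc <- intersect(kd$kpi, names(cohort_tbl))

  rounded <- mutate(cohort_tbl, across(any_of(c(sc, kc)), ~ round(.x, 2)))
  put(rounded, "cohort_scores.csv")
  put(mutate(describe_cohort(cohort_tbl, sc, percentile = percentile),
             across(-c("variable", "n"), ~ round(.x, 2))),
      "descriptives_scores.csv")
  if (length(kc) > 0) {
    put(mutate(describe_cohort(cohort_tbl, kc, percentile = percentile),
               across(-c("variable", "n"), ~ round(.x, 2))),
        "descriptives_kpis.csv")
  }
  if (length(kc) > 0) {
    ct <- correlation_table(cohort_tbl)
    put(format_correlation_table(ct), "correlation_table.csv")
    put(mutate(tidy(ct), across(c("r", "p"), ~ round(.x, 4))),
        "correlation_cells.csv")
    for (key in intersect(c("pwsy", "medication_cost"), kc)) {
      grouped <- quartile_groups(cohort_tbl, key)
      vars <- setdiff(c("overall", kc), character())
      cmp <- compare_groups(grouped, vars, alpha = alpha)
      put(format_group_comparison(cmp), sprintf("groups_by_%s.csv", key))
    }
  }
  invisible(paths)
}
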