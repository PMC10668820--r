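#' KPI column dictionary
#'
#' The productive and health key-performance indicators collected per farm
#' over one year, with the column names the package expects in cohort tables.
#' `table4` marks the eight KPIs that appear as columns of the published
#' correlation table.
#'
#' @return A tibble: `kpi`, `label`, `units`, `table4`.
#' @export
kpi_dictionary <- function() {
  tibble::tribble(
    ~kpi,                    ~label,                                              ~units,        ~table4,
    "sows",                  "Mean number of reproductive sows",                  "sows",        FALSE,
    "pwsy",                  "Piglets weaned per sow per year",                   "piglets",     TRUE,
    "preweaning_mortality",  "Pre-weaning piglet mortality rate",                 "%",           FALSE,
    "weaning_weight",        "Piglet weight during weaning",                      "kg",          FALSE,
    "weaned_piglet_cost",    "Cost of weaned piglet",                             "EUR",         TRUE,
    "adg",                   "Average daily gain during post-weaning",            "g/day",       TRUE,
    "fcr",                   "Feed conversion ratio during post-weaning",         "",            TRUE,
    "medication_cost",       "Medication costs per piglet during post-weaning",   "EUR/piglet",  TRUE,
    "postweaning_mortality", "Post-weaning piglet mortality rate",                "%",           TRUE,
    "total_cost",            "Total cost per piglet during post-weaning",         "EUR/piglet",  TRUE,
    "cost_per_kg",           "Post-weaning cost per kg live weight",              "EUR/kg LW",   TRUE
  )
}

score_columns <- function(schema = default_schema()) {
  c(schema_indices(schema)$index_slug, "overall")
}

#' Descriptive benchmarking statistics
#'
#' Mean, sample (n-1) standard deviation, min, max and the 25th/50th/75th
#' percentiles for each requested column, one row per variable.  Percentiles
#' default to the SPSS weighted-average definition (HAVERAGE, R's quantile
#' type 6); `percentile = "linear"` selects the common linear-interpolation
#' definition (type 7).
#'
#' @param cohort A cohort tibble (farms in rows).
#' @param variables Character vector of numeric columns to describe; default
#'   all numeric columns.
#' @param percentile Percentile definition: `"haverage"` (SPSS weighted
#'   average, default) or `"linear"`.
#' @return A tibble: `variable`, `n`, `mean`, `sd`, `min`, `max`, `p25`,
#'   `p50`, `p75`.
#' @export
describe_cohort <- function(cohort, variables = NULL,
                            percentile = c("haverage", "linear")) {
  percentile <- match.arg(percentile)
  qtype <- if (percentile == "haverage") 6L else 7L
  cohort <- as_tibble(cohort)
  if (is.null(variables)) {
    variables <- names(cohort)[vapply(cohort, is.numeric, logical(1))]
  }
  unknown <- setdiff(variables, names(cohort))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown variable(s): %s", paste(unknown, collapse = ", ")),
          class = "qsc_contract_error")
  }
  purrr::map_dfr(variables, function(v) {
    x <- cohort[[v]]
    if (!is.numeric(x)) {
      abort(sprintf("Variable `%s` is not numeric", v), class = "qsc_contract_error")
    }
    x <- x[!is.na(x)]
    if (length(x) < 1) {
      abort(sprintf("Variable `%s` has no non-missing values", v),
            class = "qsc_contract_error")
    }
    q <- unname(quantile(x, c(0.25, 0.50, 0.75), type = qtype))
    tibble(variable = v, n = length(x), mean = mean(x),
           sd = if (length(x) > 1) sd(x) else 0,
           min = min(x), max = max(x), p25 = q[1], p50 = q[2], p75 = q[3])
  })
}

#' Significance stars for p-values
#'
#' The footnote rule of the published correlation table: `***` for
#' p <= 0.001, `**` for p <= 0.01, `*` for p <= 0.05, otherwise empty.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of stars.
#' @export
stars_for_p <- function(p) {
  dplyr::case_when(
    is.na(p)    ~ NA_character_,
    p <= 0.001  ~ "***",
    p <= 0.01   ~ "**",
    p <= 0.05   ~ "*",
    TRUE        ~ ""
  )
}

#' Pearson correlation with a two-tailed p-value and stars
#'
#' Product-moment correlation with the two-tailed p-value from the t
#' transform t = r sqrt((n-2)/(1-r^2)) on n-2 degrees of freedom, plus the
#' significance stars of [stars_for_p()].  Missing values are removed
#' pairwise; degenerate inputs (n < 3 or a constant vector) raise rather
#' than returning NaN.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A one-row tibble: `r`, `p`, `stars`, `n`.
#' @export
cor_with_p <- function(x, y) {
  if (length(x) != length(y)) {
    abort("x and y must have equal length", class = "qsc_contract_error")
  }
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    abort(sprintf("Need at least 3 complete pairs, got %d", length(x)),
          class = "qsc_degenerate_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Constant input: correlation undefined", class = "qsc_degenerate_error")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  p <- if (abs(r) >= 1) 0 else ct$p.value
  tibble(r = r, p = p, stars = stars_for_p(p), n = length(x))
}

#' Correlation table between index scores and KPIs
#'
#' The published validation table: Pearson correlations of the 10 index
#' scores and the overall score (rows) against the productive and health
#' KPIs (columns), each cell starred per the footnote rule.  Cells are
#' computed on pairwise-complete observations; degenerate cells (constant or
#' too few pairs) are returned as NA with a warning rather than failing the
#' whole table.
#'
#' @param cohort Cohort tibble carrying score and KPI columns.
#' @param score_cols Score columns (rows of the table); default the 10 index
#'   slugs plus `overall` that are present.
#' @param kpi_cols KPI columns; default the eight published KPI columns that
#'   are present.
#' @return A `qsc_cor_table`: a long tibble `score`, `kpi`, `n`, `r`, `p`,
#'   `stars`.  Use [format_correlation_table()] for the wide starred layout.
#' @export
correlation_table <- function(cohort, score_cols = NULL, kpi_cols = NULL) {
  cohort <- as_tibble(cohort)
  if (is.null(score_cols)) {
    score_cols <- intersect(score_columns(), names(cohort))
  }
  if (is.null(kpi_cols)) {
    kd <- kpi_dictionary()
    kpi_cols <- intersect(kd$kpi[kd$table4], names(cohort))
  }
  missing_cols <- setdiff(c(score_cols, kpi_cols), names(cohort))
  if (length(missing_cols) > 0) {
    abort(sprintf("Column(s) not in cohort: %s", paste(missing_cols, collapse = ", ")),
          class = "qsc_contract_error")
  }
  grid <- tidyr::crossing(score = factor(score_cols, levels = score_cols),
                          kpi = factor(kpi_cols, levels = kpi_cols))
  n_degenerate <- 0L
  cells <- purrr::pmap_dfr(grid, function(score, kpi) {
    cell <- tryCatch(cor_with_p(cohort[[as.character(score)]],
                                cohort[[as.character(kpi)]]),
                     qsc_degenerate_error = function(e) {
                       n_degenerate <<- n_degenerate + 1L
                       tibble(r = NA_real_, p = NA_real_,
                              stars = NA_character_, n = NA_integer_)
                     })
    mutate(cell, score = as.character(score), kpi = as.character(kpi))
  })
  if (n_degenerate > 0) {
    warn(sprintf("%d degenerate correlation cell(s) returned as NA", n_degenerate))
  }
  out <- select(cells, "score", "kpi", "n", "r", "p", "stars")
  out$score <- factor(out$score, levels = score_cols)
  out$kpi <- factor(out$kpi, levels = kpi_cols)
  structure(arrange(out, .data$score, .data$kpi), class = c("qsc_cor_table", class(out)))
}

#' Group farms into benchmarking quartiles
#'
#' Ranks farms by a KPI and splits them into the best quartile (Q1), the
#' middle half (Q2Q3) and the worst quartile (Q4).  The extreme groups hold
#' round(n/4) farms each (half-up; 6/11/6 for n = 23).  With
#' `direction = "desc"` (default) the highest values form Q1 — appropriate
#' for productivity; use `"desc"` with medication cost too when Q1 should be
#' the highest-cost group, or `"asc"` to reverse.  Ties at a group boundary
#' are broken by stable farm order and trigger a warning.
#'
#' @param cohort Cohort tibble with a `farm_id` column.
#' @param key Column name to rank by (string).
#' @param direction `"desc"` (highest = Q1, default) or `"asc"`.
#' @return The cohort tibble with an added `quartile` factor
#'   (levels Q1, Q2Q3, Q4).
#' @export
quartile_groups <- function(cohort, key, direction = c("desc", "asc")) {
  direction <- match.arg(direction)
  cohort <- as_tibble(cohort)
  if (!key %in% names(cohort)) {
    abort(sprintf("Key column `%s` not found", key), class = "qsc_contract_error")
  }
  x <- cohort[[key]]
  if (!is.numeric(x) || anyNA(x)) {
    abort(sprintf("Key column `%s` must be numeric without missing values", key),
          class = "qsc_contract_error")
  }
  n <- nrow(cohort)
  if (n < 4) {
    abort(sprintf("Need at least 4 farms to form quartiles, got %d", n),
          class = "qsc_contract_error")
  }
  n_tail <- floor(n / 4 + 0.5)  # round half up
  ord <- order(if (direction == "desc") -x else x)  # stable for ties
  grp <- rep("Q2Q3", n)
  grp[ord[seq_len(n_tail)]] <- "Q1"
  grp[ord[seq(n - n_tail + 1, n)]] <- "Q4"
  sorted <- x[ord]
  if (sorted[n_tail] == sorted[n_tail + 1] ||
      sorted[n - n_tail] == sorted[n - n_tail + 1]) {
    warn(sprintf("Tied `%s` values at a quartile boundary; ties broken by row order", key))
  }
  cohort$quartile <- factor(grp, levels = c("Q1", "Q2Q3", "Q4"))
  attr(cohort$quartile, "key") <- key
  attr(cohort$quartile, "direction") <- direction
  cohort
}
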