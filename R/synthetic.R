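#' Default per-factor base pass-rates
#'
#' The generator's response model gives each checklist factor a base
#' pass-rate (probability of the best answer for a farm of average
#' management quality).  Defaults are set per index to one tenth of the
#' published cohort's mean index score, with three factor-specific overrides
#' matching reported prevalences: localized heating is rare (4.3% of farms),
#' a programmed minimum ventilation uncommon (13%), and performance-based
#' incentive policies almost absent.
#'
#' @param schema A `qsc_schema`.
#' @return A tibble: `factor_id`, `base_rate`.
#' @export
default_factor_rates <- function(schema = default_schema()) {
  index_rates <- c(preweaning = 0.687, batch = 0.598, biosecurity = 0.511,
                   water = 0.481, feeding = 0.574, health = 0.628,
                   training = 0.493, temperature = 0.408, ventilation = 0.432,
                   floor = 0.803)
  overrides <- c(heating_system = 0.043, minimum_ventilation = 0.13,
                 incentive_policy = 0.05)
  fac <- schema_factors(schema)
  rate <- unname(index_rates[fac$index_slug])
  rate[is.na(rate)] <- 0.5
  ov <- overrides[fac$factor_id]
  rate <- ifelse(is.na(ov), rate, unname(ov))
  tibble(factor_id = fac$factor_id, base_rate = rate)
}

#' Default KPI coupling targets
#'
#' Marginal means and SDs for each productive/health KPI, and the target
#' Pearson correlation of each KPI with the farm overall score, taken from
#' the published cohort's descriptive and correlation tables: PWSY 0.592,
#' weaned-piglet cost -0.182, post-weaning ADG 0.086, FCR -0.442, medication
#' cost -0.414, post-weaning mortality -0.437, total cost -0.435, cost per
#' kg live weight -0.228.  KPIs outside the correlation table's columns
#' (sow census, pre-weaning mortality, weaning weight) are generated
#' uncoupled (rho = 0); KPIs share dependence only through the score, so
#' cross-KPI correlations are not independently targeted.
#'
#' @return A tibble: `kpi`, `rho`, `mean`, `sd`, `lower` (truncation bound).
#' @export
default_kpi_couplings <- function() {
  tibble::tribble(
    ~kpi,                    ~rho,   ~mean,  ~sd,    ~lower,
    "sows",                   0.000, 704.30, 364.42, 1,
    "pwsy",                   0.592,  24.60,   3.20, 0,
    "preweaning_mortality",   0.000,  10.28,   4.37, 0,
    "weaning_weight",         0.000,   5.67,   0.18, 0,
    "weaned_piglet_cost",    -0.182,  24.69,   3.60, 0,
    "adg",                    0.086, 310.78,  38.71, 0,
    "fcr",                   -0.442,   1.76,   0.16, 0,
    "medication_cost",       -0.414,   5.69,   1.44, 0,
    "postweaning_mortality", -0.437,   3.46,   1.47, 0,
    "total_cost",            -0.435,  45.14,   4.70, 0,
    "cost_per_kg",           -0.228,   2.33,   0.31, 0
  )
}

#' Configure the synthetic cohort generator
#'
#' A farm's management quality is a latent standard-Normal variable `u`.
#' Each checklist response is drawn from an ordered-logit model on `u`
#' (binary and threshold factors are the two-level case): the pass
#' probability is `plogis(qlogis(base_rate) + slope * u)`.  Room-level
#' factors add a per-room Normal disturbance (`room_sd`) to the farm's
#' quality.  Rooms per farm follow a discretized Normal (mean 10.52, SD
#' 5.48, minimum 3, matching the published cohort).  KPIs are then coupled
#' to the realized overall score (or to `u` with `couple_to = "latent"`)
#' at the configured target correlations.
#'
#' @param n_farms Number of farms (the study cohort had 23).
#' @param seed Integer seed; every draw of the generator is a deterministic
#'   function of (config, seed).
#' @param schema Calculator schema to generate against.
#' @param slope Latent-quality slope on the logit scale.  The default 0.4
#'   reproduces the published cohort's between-farm spread of overall scores
#'   (SD about 10 points).
#' @param room_sd SD of the per-room quality disturbance (default 0.5).
#' @param rooms_mean,rooms_sd,rooms_min Rooms-per-farm distribution.
#' @param factor_rates Tibble `factor_id`, `base_rate`; see
#'   [default_factor_rates()].
#' @param kpi_couplings Tibble `kpi`, `rho`, `mean`, `sd`, `lower`; see
#'   [default_kpi_couplings()].
#' @param truncate Clip KPIs at their lower bounds (mortality and costs
#'   cannot be negative); clipped counts are reported.
#' @param couple_to `"score"` (default; configured correlations are
#'   recovered by construction) or `"latent"` (more realistic, attenuated).
#' @return A `qsc_generator_config` list.
#' @export
generator_config <- function(n_farms = 23, seed = 1L,
                             schema = default_schema(),
                             slope = 0.4, room_sd = 0.5,
                             rooms_mean = 10.52, rooms_sd = 5.48, rooms_min = 3,
                             factor_rates = default_factor_rates(schema),
                             kpi_couplings = default_kpi_couplings(),
                             truncate = TRUE,
                             couple_to = c("score", "latent")) {
  couple_to <- match.arg(couple_to)
  stopifnot(n_farms >= 1, rooms_sd > 0, rooms_min >= 1, slope >= 0, room_sd >= 0)
  if (any(kpi_couplings$sd <= 0) || any(abs(kpi_couplings$rho) > 1)) {
    abort("KPI couplings need sd > 0 and |rho| <= 1", class = "qsc_contract_error")
  }
  if (any(factor_rates$base_rate <= 0 | factor_rates$base_rate >= 1)) {
    abort("Factor base rates must lie strictly in (0, 1)", class = "qsc_contract_error")
  }
  fac <- schema_factors(schema)
  missing_rates <- setdiff(fac$factor_id, factor_rates$factor_id)
  if (length(missing_rates) > 0) {
    abort(sprintf("No base rate for factor(s): %s",
                  paste(missing_rates, collapse = ", ")), class = "qsc_contract_error")
  }
  structure(list(n_farms = as.integer(n_farms), seed = as.integer(seed),
                 schema = schema, slope = slope, room_sd = room_sd,
                 rooms_mean = rooms_mean, rooms_sd = rooms_sd,
                 rooms_min = as.integer(rooms_min),
                 factor_rates = as_tibble(factor_rates),
                 kpi_couplings = as_tibble(kpi_couplings),
                 truncate = truncate, couple_to = couple_to),
            class = "qsc_generator_config")
}

# cumulative P(option level >= j), j = 2..k, at average quality, given the
# top-option base rate: the remaining mass is split evenly over lower options
cumulative_option_probs <- function(k, p_top) {
  j <- seq(2, k)
  p_top + (1 - p_top) * (k - j) / (k - 1)
}

#' Generate synthetic farm assessments
#'
#' Draws checklist responses for `config$n_farms` farms under the latent
#' management-quality model (see [generator_config()]).  Deterministic for a
#' fixed config (the seed is part of the config).
#'
#' @param config A `qsc_generator_config`.
#' @return An assessment tibble (see [qsc_assessment]) with the per-farm
#'   latent states in attribute `"latent"` (`farm_id`, `u`, `n_rooms`).
#' @export
generate_assessments <- function(config) {
  stopifnot(inherits(config, "qsc_generator_config"))
  set.seed(config$seed)
  n <- config$n_farms
  farm_id <- sprintf("farm_%05d", seq_len(n))
  u <- rnorm(n)
  n_rooms <- pmax(config$rooms_min,
                  as.integer(round(rnorm(n, config$rooms_mean, config$rooms_sd))))

  fac <- left_join(schema_factors(config$schema), config$factor_rates,
                   by = "factor_id")
  farm_fac <- fac[fac$level == "farm", ]
  room_fac <- fac[fac$level == "room", ]

  grid_farm <- tibble(
    farm_id = rep(farm_id, each = nrow(farm_fac)),
    room_id = NA_character_,
    fi = rep(seq_len(nrow(farm_fac)), times = n),
    u_eff = rep(u, each = nrow(farm_fac))
  )
  grid_farm$factor_id <- farm_fac$factor_id[grid_farm$fi]

  rooms <- tibble(
    farm_id = rep(farm_id, times = n_rooms),
    room_id = unlist(lapply(n_rooms, function(k) sprintf("room_%03d", seq_len(k)))),
    u_room = rep(u, times = n_rooms) + rnorm(sum(n_rooms), 0, config$room_sd)
  )
  grid_room <- tibble(
    farm_id = rep(rooms$farm_id, each = nrow(room_fac)),
    room_id = rep(rooms$room_id, each = nrow(room_fac)),
    fi = rep(seq_len(nrow(room_fac)), times = nrow(rooms)),
    u_eff = rep(rooms$u_room, each = nrow(room_fac))
  )
  grid_room$factor_id <- room_fac$factor_id[grid_room$fi]

  draw_values <- function(grid, fdefs) {
    y <- config$slope * grid$u_eff + rlogis(nrow(grid))
    value <- character(nrow(grid))
    for (i in seq_len(nrow(fdefs))) {
      rows <- grid$fi == i
      kind <- fdefs$kind[i]
      p <- fdefs$base_rate[i]
      if (kind == "categorical") {
        opt <- fdefs$options[[i]]
        k <- nrow(opt)
        cuts <- qlogis(cumulative_option_probs(k, p))
        lev <- rep(1L, sum(rows))
        for (cut in cuts) lev <- lev + as.integer(y[rows] >= -cut)
        value[rows] <- opt$label[lev]
      } else {
        pass <- y[rows] >= -qlogis(p)
        if (kind == "binary") {
          value[rows] <- ifelse(pass, "yes", "no")
        } else {
          thr <- fdefs$threshold[i]
          mag <- 0.5 * abs(rnorm(sum(rows)))
          meas <- if (identical(fdefs$direction[i], "<=")) {
            ifelse(pass, thr * (1 - pmin(mag, 0.95)), thr * (1 + mag))
          } else {
            ifelse(pass, thr * (1 + mag), thr * (1 - pmin(mag, 0.95)))
          }
          value[rows] <- formatC(meas, digits = 6, format = "g")
        }
      }
    }
    value
  }

  grid_farm$value <- draw_values(grid_farm, farm_fac)
  grid_room$value <- draw_values(grid_room, room_fac)
  out <- bind_rows(select(grid_farm, "farm_id", "room_id", "factor_id", "value"),
                   select(grid_room, "farm_id", "room_id", "factor_id", "value")) %>%
    arrange(match(.data$farm_id, farm_id))
  attr(out, "latent") <- tibble(farm_id = farm_id, u = u, n_rooms = n_rooms)
  out
}

#' Couple KPIs to overall scores
#'
#' For each KPI with target correlation rho, marginal mean mu and SD sigma:
#' `KPI_i = mu + sigma * (rho * z_i + sqrt(1 - rho^2) * eps_i)` with `z`
#' the standardized overall score and `eps` independent standard Normal, so
#' the population correlation between KPI and score is exactly rho.  Lower
#' truncation bounds (mortality and costs cannot be negative) are applied
#' afterwards by clipping, with the clipped count reported.
#'
#' @param scores A tibble with columns `farm_id` and `overall` (e.g. from
#'   [score_cohort()]), or a full cohort table.
#' @param config A `qsc_generator_config` (supplies `kpi_couplings` and
#'   `truncate`).
#' @param seed Integer seed for the noise draws (default `config$seed + 1`,
#'   so assessments and KPI noise use distinct streams).
#' @param z Optional standardized coupling variable overriding the scores
#'   (used for latent-quality coupling).
#' @return A tibble: `farm_id` plus one column per configured KPI.
#' @export
couple_kpis <- function(scores, config, seed = config$seed + 1L, z = NULL) {
  stopifnot(inherits(config, "qsc_generator_config"))
  scores <- as_tibble(scores)
  n <- nrow(scores)
  if (n == 0) abort("No scorecards to couple", class = "qsc_contract_error")
  if (is.null(z)) {
    if (n < 2 || sd(scores$overall) == 0) {
      abort("Zero variance in overall scores: cannot couple KPIs",
            class = "qsc_degenerate_error")
    }
    z <- (scores$overall - mean(scores$overall)) / sd(scores$overall)
  }
  set.seed(as.integer(seed))
  out <- tibble(farm_id = scores$farm_id)
  n_clipped <- 0L
  for (i in seq_len(nrow(config$kpi_couplings))) {
    kc <- config$kpi_couplings[i, ]
    eps <- rnorm(n)
    val <- kc$mean + kc$sd * (kc$rho * z + sqrt(1 - kc$rho^2) * eps)
    if (isTRUE(config$truncate) && is.finite(kc$lower)) {
      clip <- val < kc$lower
      n_clipped <- n_clipped + sum(clip)
      val[clip] <- kc$lower
    }
    out[[kc$kpi]] <- val
  }
  if (n_clipped > 0) {
    rlang::inform(sprintf("KPI truncation clipped %d value(s) at their lower bounds",
                          n_clipped))
  }
  out
}

#' Generate a complete synthetic cohort
#'
#' Composition of [generate_assessments()], [score_cohort()] and
#' [couple_kpis()]: a full synthetic stand-in for the study cohort —
#' checklist assessments, 0-100 scorecards and coupled KPIs — reproducible
#' bit-for-bit from (config, seed).
#'
#' @param config A `qsc_generator_config`.
#' @return A `qsc_cohort` object: list with `assessments`, `scores`,
#'   `kpis`, `latent`, `config`.  [cohort_table()] returns the joined
#'   farms-by-(scores + KPIs) analysis table.
#' @export
#' @examples
#' coh <- generate_cohort(generator_config(n_farms = 23, seed = 42))
#' cohort_table(coh)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "qsc_generator_config"))
  assessments <- generate_assessments(config)
  latent <- attr(assessments, "latent")
  scores <- score_cohort(assessments, config$schema)
  z <- if (config$couple_to == "latent") {
    (latent$u - mean(latent$u)) / sd(latent$u)
  } else NULL
  kpis <- couple_kpis(scores, config, z = z)
  structure(list(assessments = assessments, scores = scores, kpis = kpis,
                 latent = latent, config = config),
            class = "qsc_cohort")
}

#' @rdname generate_cohort
#' @param cohort A `qsc_cohort`.
#' @export
cohort_table <- function(cohort) {
  stopifnot(inherits(cohort, "qsc_cohort"))
  left_join(cohort$scores, cohort$kpis, by = "farm_id")
}

#' @export
print.qsc_cohort <- function(x, ...) {
  cat(sprintf("<qsc_cohort> %d farms, %d rooms (seed %d, coupled to %s)\n",
              nrow(x$scores), sum(x$latent$n_rooms), x$config$seed,
              x$config$couple_to))
  cat(sprintf("  mean overall score %.2f (sd %.2f)\n",
              mean(x$scores$overall), sd(x$scores$overall)))
  invisible(x)
}

#' Closed-form expected overall score of the generator
#'
#' Integrates the response model over the latent quality distribution:
#' the expected overall score is the weight-weighted sum of expected credit
#' fractions, where each cumulative pass probability is
#' `E_u[plogis(qlogis(base) + slope * u_eff)]` with `u_eff` Normal(0, 1)
#' for farm factors and Normal(0, 1 + room_sd^2) for room factors.  Used to
#' verify the simulator against its own expectation.
#'
#' @param config A `qsc_generator_config`.
#' @return Expected overall score (points, 0-100).
#' @export
expected_overall_score <- function(config) {
  stopifnot(inherits(config, "qsc_generator_config"))
  fac <- left_join(schema_factors(config$schema), config$factor_rates,
                   by = "factor_id")
  e_pass <- function(cum_p, sd_u) {
    stats::integrate(function(zz) plogis(qlogis(cum_p) + config$slope * sd_u * zz) *
                       stats::dnorm(zz), -Inf, Inf)$value
  }
  total <- 0
  for (i in seq_len(nrow(fac))) {
    sd_u <- if (fac$level[i] == "room") sqrt(1 + config$room_sd^2) else 1
    if (fac$kind[i] == "categorical") {
      opt <- fac$options[[i]]
      k <- nrow(opt)
      cum <- cumulative_option_probs(k, fac$base_rate[i])
      # E[credit] = c_1 + sum_j (c_j - c_{j-1}) P(level >= j)
      e_credit <- opt$credit[1]
      for (j in seq(2, k)) {
        e_credit <- e_credit + (opt$credit[j] - opt$credit[j - 1]) *
          e_pass(cum[j - 1], sd_u)
      }
    } else {
      e_credit <- e_pass(fac$base_rate[i], sd_u)
    }
    total <- total + fac$weight[i] * e_credit
  }
  total
}
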