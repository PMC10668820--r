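#' One-way analysis of variance
#'
#' Standard fixed-effects one-way ANOVA (between/within mean-square ratio)
#' over a list of group samples, fitted via [stats::aov()].
#'
#' @param groups A named or unnamed list of numeric vectors, one per group,
#'   each with at least 2 observations.
#' @return A one-row tibble: `f`, `p`, `df_between`, `df_within`,
#'   `ms_within`.
#' @export
#' @examples
#' oneway_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(5, 6, 7)))
oneway_anova <- function(groups) {
  groups <- check_groups(groups)
  value <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  fit <- aov(value ~ grp)
  tab <- summary(fit)[[1]]
  ms_within <- tab["Residuals", "Mean Sq"]
  if (!is.finite(ms_within) || ms_within <= 0) {
    abort("Zero within-group variance: F undefined", class = "qsc_degenerate_error")
  }
  tibble(f = tab["grp", "F value"], p = tab["grp", "Pr(>F)"],
         df_between = tab["grp", "Df"], df_within = tab["Residuals", "Df"],
         ms_within = ms_within)
}

check_groups <- function(groups) {
  if (is.data.frame(groups) || !is.list(groups)) {
    abort("`groups` must be a list of numeric vectors", class = "qsc_contract_error")
  }
  if (length(groups) < 2) {
    abort("Need at least 2 groups", class = "qsc_contract_error")
  }
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(lengths(groups) < 2)) {
    abort("Every group needs at least 2 non-missing observations",
          class = "qsc_contract_error")
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  groups
}

#' Student-Newman-Keuls post-hoc test with letter display
#'
#' Stepwise multiple comparisons on the studentized range.  Group means are
#' sorted in descending order; a comparison spanning `p` ordered means uses
#' the critical value q(1 - alpha, p, df_within), with standard error
#' sqrt(MSW / n_h) where n_h is the harmonic mean of the two group sizes
#' (reducing to the classic equal-n SNK).  Once a range is found
#' non-significant, all ranges inside it are declared homogeneous without
#' further testing (the SNK containment rule).  Groups sharing a letter are
#' not significantly different at `alpha`.
#'
#' For two groups the procedure is exactly the pooled two-sample t-test
#' (q = sqrt(2) |t|).
#'
#' @inheritParams oneway_anova
#' @param alpha Family-wise significance level (default 0.05).
#' @return A `qsc_snk` object: a tibble `group`, `n`, `mean`, `sd`,
#'   `letters`, ordered by descending mean, with the ANOVA summary in
#'   attribute `"anova"`.
#' @export
snk_test <- function(groups, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  groups <- check_groups(groups)
  av <- oneway_anova(groups)
  means <- vapply(groups, mean, numeric(1))
  ns <- lengths(groups)
  sds <- vapply(groups, sd, numeric(1))
  ord <- order(-means)
  means <- means[ord]; ns <- ns[ord]; sds <- sds[ord]
  k <- length(means)

  # homogeneous[i, j]: groups i..j (in descending-mean order) not separable
  homogeneous <- matrix(FALSE, k, k)
  diag(homogeneous) <- TRUE
  for (span in rev(seq(2, k))) {
    for (i in seq_len(k - span + 1)) {
      j <- i + span - 1
      if (covered_by_homogeneous(homogeneous, i, j)) next
      n_h <- 2 / (1 / ns[i] + 1 / ns[j])
      q_obs <- (means[i] - means[j]) / sqrt(av$ms_within / n_h)
      q_crit <- qtukey(1 - alpha, span, av$df_within)
      if (q_obs <= q_crit) homogeneous[i, j] <- TRUE
    }
  }

  letters <- letters_from_ranges(homogeneous)
  out <- tibble(group = names(means), n = as.integer(ns), mean = unname(means),
                sd = unname(sds), letters = letters)
  structure(out, class = c("qsc_snk", class(out)), anova = av, alpha = alpha)
}

covered_by_homogeneous <- function(homogeneous, i, j) {
  k <- nrow(homogeneous)
  for (a in seq_len(i)) {
    for (b in seq(j, k)) {
      if ((a < i || b > j) && homogeneous[a, b]) return(TRUE)
    }
  }
  FALSE
}

# compact letter display from the maximal homogeneous ranges; every group is
# covered (singletons get their own letter)
letters_from_ranges <- function(homogeneous) {
  k <- nrow(homogeneous)
  # maximal homogeneous intervals: [i, j] homogeneous and no strictly larger
  # homogeneous interval contains it
  is_max <- function(i, j) {
    if (!(homogeneous[i, j])) return(FALSE)
    for (a in seq_len(i)) for (b in seq(j, k)) {
      if ((a < i || b > j) && homogeneous[a, b]) return(FALSE)
    }
    TRUE
  }
  intervals <- list()
  for (i in seq_len(k)) for (j in seq(i, k)) {
    if (is_max(i, j)) intervals[[length(intervals) + 1]] <- c(i, j)
  }
  intervals <- intervals[order(vapply(intervals, `[`, numeric(1), 1))]
  lab <- rep("", k)
  for (m in seq_along(intervals)) {
    iv <- intervals[[m]]
    idx <- seq(iv[1], iv[2])
    lab[idx] <- paste0(lab[idx], letters[m])
  }
  lab
}

#' @export
print.qsc_snk <- function(x, ...) {
  av <- attr(x, "anova")
  cat(sprintf("<qsc_snk> F(%d, %d) = %.3f, p = %.4g, alpha = %g\n",
              av$df_between, av$df_within, av$f, av$p, attr(x, "alpha")))
  NextMethod()
}

#' Shapiro-Wilk normality check
#'
#' Advisory check used before the parametric quartile comparisons; it never
#' blocks the pipeline.
#'
#' @param x Numeric vector, 3 <= n <= 5000, non-constant.
#' @return A one-row tibble: `w`, `p`, `n`.
#' @export
check_normality <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3) {
    abort(sprintf("Shapiro-Wilk needs n >= 3, got %d", length(x)),
          class = "qsc_contract_error")
  }
  if (sd(x) == 0) {
    abort("Constant input: normality check undefined", class = "qsc_contract_error")
  }
  sw <- shapiro.test(x)
  tibble(w = unname(sw$statistic), p = sw$p.value, n = length(x))
}

#' Compare quartile groups on outcome variables
#'
#' The published benchmarking contrast: for each outcome variable, per-group
#' mean and SD, the one-way ANOVA F and p, and Student-Newman-Keuls letters
#' (groups sharing a letter do not differ at `alpha`).  Normality of each
#' variable is checked with Shapiro-Wilk and reported, advisory only.
#'
#' @param cohort A cohort tibble carrying a grouping column (normally the
#'   `quartile` column added by [quartile_groups()]).
#' @param variables Outcome columns to compare.
#' @param group Name of the grouping column (default `"quartile"`).
#' @param alpha Significance level for the letters (default 0.05).
#' @return A `qsc_group_comparison` object; see [tidy.qsc_group_comparison()]
#'   and [glance.qsc_group_comparison()].
#' @export
#' @examples
#' set.seed(1)
#' coh <- generate_cohort(generator_config(n_farms = 23, seed = 7))
#' tbl <- quartile_groups(cohort_table(coh), "pwsy")
#' cmp <- compare_groups(tbl, c("overall", "medication_cost"))
#' tidy(cmp)
compare_groups <- function(cohort, variables, group = "quartile", alpha = 0.05) {
  cohort <- as_tibble(cohort)
  if (!group %in% names(cohort)) {
    abort(sprintf("Grouping column `%s` not found", group), class = "qsc_contract_error")
  }
  missing_cols <- setdiff(variables, names(cohort))
  if (length(missing_cols) > 0) {
    abort(sprintf("Unknown variable(s): %s", paste(missing_cols, collapse = ", ")),
          class = "qsc_contract_error")
  }
  g <- cohort[[group]]
  if (!is.factor(g)) g <- factor(g)
  res <- purrr::map(variables, function(v) {
    grps <- split(cohort[[v]], g)
    snk <- snk_test(grps, alpha = alpha)
    norm <- tryCatch(check_normality(cohort[[v]]),
                     error = function(e) tibble(w = NA_real_, p = NA_real_,
                                                n = sum(!is.na(cohort[[v]]))))
    list(variable = v, snk = snk, normality = norm)
  })
  structure(list(results = res, group = group, alpha = alpha,
                 group_levels = levels(g)),
            class = "qsc_group_comparison")
}

#' @describeIn compare_groups Per-variable, per-group means, SDs and SNK
#'   letters as a tibble.
#' @param x A `qsc_group_comparison`.
#' @param ... Unused.
#' @export
tidy.qsc_group_comparison <- function(x, ...) {
  purrr::map_dfr(x$results, function(r) {
    mutate(as_tibble(r$snk), variable = r$variable, .before = 1)
  })
}

#' @describeIn compare_groups One row per variable: F, p, degrees of
#'   freedom, and the Shapiro-Wilk normality p.
#' @export
glance.qsc_group_comparison <- function(x, ...) {
  purrr::map_dfr(x$results, function(r) {
    av <- attr(r$snk, "anova")
    tibble(variable = r$variable, f = av$f, p = av$p,
           df_between = av$df_between, df_within = av$df_within,
           shapiro_w = r$normality$w, shapiro_p = r$normality$p)
  })
}

#' @export
print.qsc_group_comparison <- function(x, ...) {
  cat(sprintf("<qsc_group_comparison> by `%s`, alpha = %g\n", x$group, x$alpha))
  print(format_group_comparison(x), n = Inf)
  invisible(x)
}

#' @export
tidy.qsc_cor_table <- function(x, ...) {
  out <- as_tibble(x)
  out$score <- as.character(out$score)
  out$kpi <- as.character(out$kpi)
  out
}

#' @export
glance.qsc_cor_table <- function(x, ...) {
  tibble(n_cells = nrow(x),
         n_significant = sum(x$p <= 0.05, na.rm = TRUE),
         n_degenerate = sum(is.na(x$r)))
}
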