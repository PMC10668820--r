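test_that("descriptives use the sample SD and the requested percentile rule", {
  d <- describe_cohort(tibble::tibble(x = 1:23), "x")
  expect_equal(d$p50, 12)
  expect_equal(d$sd, sd(1:23))
  expect_equal(d$mean, 12)

  k <- describe_cohort(tibble::tibble(x = rep(7, 10)), "x")
  expect_equal(k$sd, 0)
  expect_equal(unlist(k[c("min", "max", "p25", "p50", "p75")]), rep(7, 5),
               ignore_attr = TRUE)

  expect_error(describe_cohort(tibble::tibble(x = 1), "y"), "y",
               class = "qsc_contract_error")
})

test_that("both percentile definitions match hand-computed formulas", {
  sets <- list(c(2.80, 4.20, 5.60, 8.40),
               c(1, 2, 3, 4, 5, 6, 7),
               sort(withr::with_seed(9, runif(23, 0, 10))),
               c(0.5, 0.5, 2, 9))
  for (x in sets) {
    for (m in c("haverage", "linear")) {
      d <- describe_cohort(tibble::tibble(x = x), "x", percentile = m)
      for (q in c(0.25, 0.5, 0.75)) {
        col <- paste0("p", q * 100)
        expect_equal(d[[col]], oracle_percentile(x, q, m), tolerance = 1e-12,
                     label = sprintf("%s %s", m, col))
      }
    }
  }
  # the two definitions genuinely differ on small n
  d6 <- describe_cohort(tibble::tibble(x = c(2.80, 4.20, 5.60, 8.40)), "x")
  d7 <- describe_cohort(tibble::tibble(x = c(2.80, 4.20, 5.60, 8.40)), "x",
                        percentile = "linear")
  expect_equal(d6$p25, 3.15)
  expect_equal(d7$p25, 3.85)
})

test_that("pearson correlation matches the product-moment formula and t transform", {
  x <- c(1.2, 3.4, 2.2, 5.9, 4.4, 0.7)
  y <- c(2.0, 3.1, 2.9, 6.5, 3.9, 1.1)
  cell <- cor_with_p(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cell$r, r_hand, tolerance = 1e-12)
  tstat <- r_hand * sqrt((6 - 2) / (1 - r_hand^2))
  expect_equal(cell$p, 2 * pt(-abs(tstat), df = 4), tolerance = 1e-12)

  expect_equal(cor_with_p(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  e <- residuals(lm(y ~ x))  # orthogonal to x by construction
  expect_lt(abs(cor_with_p(x, e)$r), 1e-12)

  expect_error(cor_with_p(x, rep(1, 6)), class = "qsc_degenerate_error")
  expect_error(cor_with_p(x[1:2], y[1:2]), class = "qsc_degenerate_error")
})

test_that("correlation is symmetric and invariant to affine rescaling", {
  withr::with_seed(4, {
    for (i in 1:5) {
      x <- rnorm(15); y <- rnorm(15)
      expect_equal(cor_with_p(x, y)$r, cor_with_p(y, x)$r, tolerance = 1e-12)
      expect_equal(cor_with_p(3 * x - 7, y / 5 + 2)$r, cor_with_p(x, y)$r,
                   tolerance = 1e-12)
    }
  })
})

test_that("significance stars follow the footnote thresholds exactly", {
  expect_identical(stars_for_p(c(0.0005, 0.001, 0.0011, 0.01, 0.011, 0.05,
                                 0.0501, 0.9, NA)),
                   c("***", "***", "**", "**", "*", "*", "", "", NA))
})

test_that("the correlation table has the published 11 x 8 layout", {
  coh <- cohort_table(generate_cohort(generator_config(n_farms = 30, seed = 5)))
  ct <- correlation_table(coh)
  expect_identical(nrow(ct), 88L)
  expect_identical(length(unique(ct$score)), 11L)
  expect_identical(length(unique(ct$kpi)), 8L)
  expect_identical(as.character(ct$score[1]), "preweaning")
  expect_identical(levels(ct$score)[11], "overall")
  wide <- format_correlation_table(ct)
  expect_identical(dim(wide), c(11L, 9L))

  coh$fcr <- 1.76  # a constant KPI degrades that column, not the table
  expect_warning(ct2 <- correlation_table(coh), "degenerate")
  expect_identical(nrow(ct2), 88L)
  expect_identical(sum(is.na(ct2$r)), 11L)
})

test_that("quartile groups partition with round(n/4)-sized extremes", {
  g8 <- quartile_groups(tibble::tibble(farm_id = letters[1:8], k = 8:1), "k")
  expect_identical(as.vector(table(g8$quartile)), c(2L, 4L, 2L))
  expect_identical(g8$farm_id[g8$quartile == "Q1"], c("a", "b"))

  withr::with_seed(6, {
    for (n in 4:40) {
      tb <- tibble::tibble(farm_id = sprintf("f%02d", 1:n), k = sample(n) + runif(n))
      gg <- quartile_groups(tb, "k")
      sizes <- table(gg$quartile)
      expect_identical(sum(sizes), as.integer(n))
      expect_identical(as.integer(sizes[["Q1"]]), as.integer(floor(n / 4 + 0.5)))
      expect_identical(sizes[["Q1"]], sizes[["Q4"]])
      rev <- quartile_groups(tb, "k", direction = "asc")
      expect_identical(gg$farm_id[gg$quartile == "Q1"],
                       rev$farm_id[rev$quartile == "Q4"])
      expect_identical(gg$farm_id[gg$quartile == "Q4"],
                       rev$farm_id[rev$quartile == "Q1"])
    }
  })
  expect_identical(as.vector(table(quartile_groups(
    tibble::tibble(farm_id = sprintf("f%02d", 1:23), k = withr::with_seed(2, rnorm(23))),
    "k")$quartile)), c(6L, 11L, 6L))

  expect_error(quartile_groups(tibble::tibble(farm_id = "a", k = 1), "k"),
               class = "qsc_contract_error")
  expect_warning(quartile_groups(tibble::tibble(farm_id = letters[1:8],
                                                k = c(1, 1, 1, 1, 2, 2, 2, 2)), "k"),
                 "Tied")
})
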