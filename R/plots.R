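#' Per-farm stacked index-score chart
#'
#' The benchmarking figure: one stacked bar per farm, segments being the ten
#' index scores (each 0-10), so bar height is the 0-100 overall score.
#'
#' @param scores A score tibble from [score_cohort()] (or a cohort table).
#' @param schema Schema defining the index columns and their order.
#' @return A ggplot object.
#' @export
plot_cohort_scores <- function(scores, schema = default_schema()) {
  slugs <- schema_indices(schema)$index_slug
  long <- as_tibble(scores) %>%
    select("farm_id", all_of(slugs)) %>%
    tidyr::pivot_longer(all_of(slugs), names_to = "index", values_to = "points") %>%
    mutate(index = factor(.data$index, levels = rev(slugs)),
           farm_id = factor(.data$farm_id, levels = unique(scores$farm_id)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$farm_id, y = .data$points,
                                     fill = .data$index)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(limits = c(0, 100)) +
    ggplot2::labs(x = "Farm", y = "Overall score (points)",
                  fill = "Index",
                  title = "Handling and hygiene index scores per farm") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @export
autoplot.qsc_scorecard <- function(object, ...) {
  df <- mutate(object$index_scores,
               index = factor(.data$index_slug, levels = .data$index_slug))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$points)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 10, linetype = "dashed") +
    ggplot2::scale_y_continuous(limits = c(0, 10.5)) +
    ggplot2::labs(x = NULL, y = "Points (0-10)",
                  title = sprintf("Farm %s: overall %.2f / 100",
                                  object$farm_id, object$overall)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.qsc_cor_table <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$kpi, y = .data$score,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(is.na(.data$r), "-",
                                                   paste0(sprintf("%.2f", .data$r),
                                                          "\n", .data$stars))),
                       size = 2.8) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "firebrick",
                                  mid = "white", high = "navy", na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "r",
                  title = "Index scores vs productive and health KPIs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
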