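#' Bar chart of methylation levels per group
#'
#' @param levels Tibble from [methylation_levels()].
#' @param group Column to place on the x axis (tidy-eval); defaults to the
#'   first non-count column.
#' @return A ggplot object: total, hemi and full methylation percentages
#'   as grouped bars.
#' @export
plot_methylation_levels <- function(levels, group = NULL) {
  group <- rlang::enquo(group)
  if (rlang::quo_is_null(group)) {
    candidates <- setdiff(names(levels),
                          c(paste0("n_", pattern_levels), "n_scored",
                            "total_pct", "hemi_pct", "full_pct"))
    if (length(candidates) == 0) {
      levels$group <- "all"
      candidates <- "group"
    }
    group <- rlang::sym(candidates[1])
  }
  long <- tidyr::pivot_longer(levels, c("total_pct", "hemi_pct", "full_pct"),
                              names_to = "level", values_to = "pct")
  long$level <- factor(long$level, levels = c("total_pct", "hemi_pct", "full_pct"),
                       labels = c("total", "hemi", "full"))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(!!group), y = .data$pct,
                                     fill = .data$level)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = rlang::as_label(group), y = "methylation level (%)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of transition-type counts
#'
#' @param table Transition-count tibble from [transition_table()] (rows
#'   from several comparisons may be bound together if `label` is set).
#' @param drop_unchanged Hide the UNCHANGED bar (usually dominant and
#'   uninformative)? Default `TRUE`.
#' @return A ggplot object with B types, C types and AMBIGUOUS counts.
#' @export
plot_transitions <- function(table, drop_unchanged = TRUE) {
  if (drop_unchanged) table <- table[table$type != "UNCHANGED", ]
  table$class <- dplyr::case_when(
    grepl("^B", table$type) ~ "methylation gain (B)",
    grepl("^C", table$type) ~ "demethylation (C)",
    TRUE ~ "ambiguous"
  )
  p <- ggplot2::ggplot(table, ggplot2::aes(x = .data$type, y = .data$n,
                                           fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "transition type", y = "number of sites", fill = NULL) +
    ggplot2::theme_minimal()
  if ("label" %in% names(table) && length(unique(table$label)) > 1) {
    p <- p + ggplot2::facet_wrap(~label)
  }
  p
}

#' Group means with Duncan letters
#'
#' @param object A `duncan_fit` from [anova_duncan()].
#' @param ... Unused.
#' @return A ggplot bar chart: group means, standard-deviation error bars,
#'   and the compact letters above each bar (groups sharing a letter do
#'   not differ at the fit's alpha).
#' @method autoplot duncan_fit
#' @export
autoplot.duncan_fit <- function(object, ...) {
  d <- object$groups
  d$group <- factor(d$group, levels = d$group)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::geom_text(ggplot2::aes(y = .data$mean + .data$sd,
                                    label = .data$letters),
                       vjust = -0.5) +
    ggplot2::labs(x = NULL, y = "mean") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
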