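#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_point
#'   geom_step labs scale_y_continuous facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Plot an insert-size distribution
#'
#' @param object An `insert_summary`.
#' @param ... Unused.
#' @return A ggplot: pair counts by insert length, with the median marked in
#'   the subtitle.
#' @method autoplot insert_summary
#' @export
autoplot.insert_summary <- function(object, ...) {
  ggplot(object$histogram, aes(x = .data$insert, y = .data$n)) +
    geom_col(width = 1, fill = "steelblue") +
    labs(x = "Insert size (bp)", y = "Read pairs",
         title = "Insert-size distribution",
         subtitle = sprintf("median %.0f bp over %d pairs",
                            object$median, object$n_pairs)) +
    theme_minimal()
}

#' Plot a substitution spectrum
#'
#' @param object An `ffpeqc_spectrum`.
#' @param ... Unused.
#' @return A ggplot: per-Mb rate per substitution class, deamination classes
#'   (C>T / G>A) highlighted.
#' @method autoplot ffpeqc_spectrum
#' @export
autoplot.ffpeqc_spectrum <- function(object, ...) {
  df <- as_tibble(object)
  df$deamination <- df$class %in% c("C>T", "G>A")
  ggplot(df, aes(x = .data$class, y = .data$rate_per_mb,
                 fill = .data$deamination)) +
    geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey55", `TRUE` = "firebrick")) +
    labs(x = "Substitution class", y = "Rate per Mb",
         title = sprintf("Base-alteration spectrum (%s)",
                         attr(object, "direction") %||% "")) +
    theme_minimal()
}

#' Plot a concordance curve
#'
#' @param object A `concordance_curve`.
#' @param ... Unused.
#' @return A ggplot of overlap fraction against the LOD threshold.
#' @method autoplot concordance_curve
#' @export
autoplot.concordance_curve <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$threshold, y = .data$overlap_fraction)) +
    geom_line(colour = "steelblue") +
    geom_point(colour = "steelblue") +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = "LOD threshold", y = "Overlap fraction",
         title = sprintf("Somatic-call concordance (%s, over %s calls)",
                         attr(object, "mode") %||% "?",
                         attr(object, "denominator") %||% "?")) +
    theme_minimal()
}

#' Plot base-quality histograms by mapping status
#'
#' @param object A `quality_summary`.
#' @param ... Unused.
#' @return A ggplot faceted by mapping status.
#' @method autoplot quality_summary
#' @export
autoplot.quality_summary <- function(object, ...) {
  ggplot(object$histogram, aes(x = .data$quality, y = .data$freq)) +
    geom_col(fill = "steelblue") +
    facet_wrap(~status) +
    labs(x = "Phred base quality", y = "Fraction of bases",
         title = "Base quality by mapping status") +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
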