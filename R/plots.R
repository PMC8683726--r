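#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_point
#'   geom_step labs theme_minimal facet_wrap scale_fill_manual
#' @export
ggplot2::autoplot

#' Plot an occupancy track
#'
#' Per-position occupancy histogram over the 35S unit.
#'
#' @param object An `occupancy_track`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot occupancy_track
#' @export
autoplot.occupancy_track <- function(object, ...) {
  ylab <- if (isTRUE(attr(object, "normalized"))) "occupancy (CPM)" else "occupancy (counts)"
  ggplot(object, aes(x = .data$position, y = .data$count)) +
    geom_col(width = 1, fill = "steelblue4") +
    labs(
      x = "position on rDNA repeat unit (nt)", y = ylab,
      title = attr(object, "library_id"),
      subtitle = attr(object, "condition")
    ) +
    theme_minimal()
}

#' Plot a differential occupancy track
#'
#' Vehicle and drug median occupancy with significance classes marked
#' below the tracks.
#'
#' @param object A `differential_track`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot differential_track
#' @export
autoplot.differential_track <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object, c("median_vehicle", "median_drug"),
    names_to = "condition", values_to = "occupancy",
    names_prefix = "median_"
  )
  sig <- filter(object, .data$sig_class != "ns")
  p <- ggplot(long, aes(x = .data$position, y = .data$occupancy,
                        colour = .data$condition)) +
    geom_line(linewidth = 0.3) +
    labs(x = "position on rDNA repeat unit (nt)",
         y = "median occupancy",
         colour = NULL) +
    theme_minimal()
  if (nrow(sig) > 0L) {
    p <- p + ggplot2::geom_rug(
      data = sig, inherit.aes = FALSE,
      aes(x = .data$position, colour = .data$sig_class),
      sides = "b", length = ggplot2::unit(0.03, "npc")
    )
  }
  p
}

#' Plot a differential sequence logo
#'
#' Signed per-base stacks whose magnitudes sum to the column
#' Jensen-Shannon divergence; positive bars mark bases enriched in the
#' first condition.
#'
#' @param object A `diff_logo`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot diff_logo
#' @export
autoplot.diff_logo <- function(object, ...) {
  conds <- attr(object, "conditions") %||% c("A", "B")
  ggplot(object, aes(x = .data$offset, y = .data$contribution,
                     fill = .data$base)) +
    geom_col(position = "stack", width = 0.85) +
    scale_fill_manual(values = c(
      A = "#109648", C = "#255C99", G = "#F7B32B", T = "#D62839"
    )) +
    labs(
      x = "offset from last incorporated nucleotide (nt)",
      y = sprintf("signed JSD share (bits; + = %s, - = %s)",
                  conds[1L], conds[2L]),
      fill = NULL
    ) +
    theme_minimal()
}

#' Plot a dose-response titration and its fitted curve
#'
#' @param object A `dose_response_fit`.
#' @param series The titration tibble the fit was computed from.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_dose_response <- function(object, series, ...) {
  conc_col <- intersect(c("concentration_uM", "concentration"), names(series))
  df <- tibble(concentration_uM = series[[conc_col[1L]]],
               signal = series$signal)
  grid <- tibble(
    concentration_uM = seq(0, max(df$concentration_uM), length.out = 200)
  )
  grid$signal <- object$amplitude *
    exp(-grid$concentration_uM * log(2) / object$ic50)
  ggplot(df, aes(x = .data$concentration_uM, y = .data$signal)) +
    geom_point() +
    geom_line(data = grid, colour = "firebrick") +
    labs(x = "[inhibitor] (uM)", y = "full-length RNA signal",
         subtitle = sprintf("IC50 = %.3g uM", object$ic50)) +
    theme_minimal()
}
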