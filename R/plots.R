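# ggplot2 autoplot methods for the package's result types.

#' @importFrom ggplot2 ggplot aes geom_col geom_line geom_point labs
#'   scale_fill_manual scale_colour_manual facet_wrap theme_minimal
#'   annotate coord_cartesian
NULL

#' Plot a distance histogram
#'
#' Intra-specific (green) and inter-specific (red) distance
#' distributions as percent of comparisons. The display cap recorded by
#' [distance_histogram()] (if any) limits the plotted range without
#' changing the normalisation.
#'
#' @param object A `distance_histogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.distance_histogram <- function(object, ...) {
  cap <- attr(object, "cap")
  df <- tibble::as_tibble(object)
  if (!is.null(cap)) df <- df[df$bin_lo < cap, , drop = FALSE]
  ggplot(df, aes(x = .data$bin_lo, y = .data$percent,
                 fill = .data$relation)) +
    geom_col(position = "identity", alpha = 0.6, just = 0,
             width = attr(object, "bin_width")) +
    scale_fill_manual(values = c(inter = "#c23b22", intra = "#3b7a3b")) +
    labs(x = "distance (substitutions/site)", y = "% of comparisons",
         fill = NULL) +
    theme_minimal()
}

#' Plot a sliding-window diversity profile
#'
#' Median nearest-neighbour percent identity against the window midpoint
#' on reference coordinates.
#'
#' @param object A `window_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.window_profile <- function(object, ...) {
  ggplot(tibble::as_tibble(object),
         aes(x = .data$midpoint, y = .data$median_identity)) +
    geom_line(colour = "#2c5d8a") +
    coord_cartesian(ylim = c(min(75, min(object$median_identity)), 100)) +
    labs(x = "window midpoint (reference position)",
         y = "median nearest-neighbour identity (%)") +
    theme_minimal()
}

#' Plot per-OTU accuracy
#'
#' Each OTU as a point in the (specificity, sensitivity) plane; the
#' residual error is its distance to the perfect corner (1, 1).
#'
#' @param object An `assembly_evaluation`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.assembly_evaluation <- function(object, ...) {
  ggplot(object$per_otu,
         aes(x = .data$specificity, y = .data$sensitivity)) +
    geom_point(alpha = 0.7, colour = "#2c5d8a") +
    annotate("point", x = 1, y = 1, shape = 3, size = 3,
             colour = "#c23b22") +
    coord_cartesian(xlim = c(0, 1.02), ylim = c(0, 1.02)) +
    labs(x = "specificity", y = "sensitivity") +
    theme_minimal()
}

#' Plot an assembly parameter sweep
#'
#' Total error per cleanup stage (lines) and the singleton percentage
#' (bars, rescaled to the error axis) against the minimum overlap
#' length, one panel per minimum identity.
#'
#' @param object An `assembly_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.assembly_sweep <- function(object, ...) {
  df <- tibble::as_tibble(object)
  scale <- max(df$total_error, 1e-9) / max(df$pct_singletons, 1e-9)
  bars <- df[df$stage == "raw", , drop = FALSE]
  ggplot(df, aes(x = .data$ml)) +
    geom_col(data = bars,
             aes(y = .data$pct_singletons * scale),
             fill = "#a8c8e8", width = 30) +
    geom_line(aes(y = .data$total_error, colour = .data$stage)) +
    geom_point(aes(y = .data$total_error, colour = .data$stage)) +
    scale_colour_manual(values = c(
      raw = "#2255aa", trimmed_clustered = "#c23b22",
      chimera_removed = "#3b7a3b"
    )) +
    facet_wrap(~mi, labeller = ggplot2::label_both) +
    ggplot2::scale_y_continuous(
      name = "total error",
      sec.axis = ggplot2::sec_axis(~. / scale, name = "% singletons")
    ) +
    labs(x = "minimum overlap length (nt)", colour = "stage") +
    theme_minimal()
}
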