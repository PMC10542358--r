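# ggplot2 views of the result objects.

#' Plot an observed-vs-expected enrichment grid
#'
#' Tiles log2(observed/expected) over (GC skew, GC fraction), red where
#' R-loop windows are enriched and blue where depleted, faceted by
#' transcribing strand. Cells with no expected mass are left blank.
#'
#' @param object An `rloop_grid` tibble from [build_obs_exp_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rloop_grid <- function(object, ...) {
  df <- filter(as_tibble(object), !is.na(.data$ratio), .data$ratio > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$skew_mid, y = .data$gc_mid,
                                   fill = log2(.data$ratio))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", midpoint = 0,
                                  name = "log2 obs/exp") +
    ggplot2::facet_wrap(ggplot2::vars(.data$facet_strand)) +
    ggplot2::labs(x = "GC skew (sense strand)", y = "GC fraction") +
    ggplot2::theme_minimal()
}

#' Plot a positional G-frequency profile
#'
#' Line plot of per-offset G frequency around sites, the view in which
#' the G-rich context of TRDMT1 targets (and its decay with distance)
#' shows up.
#'
#' @param object An `m5c_context` tibble from [extract_contexts()].
#' @param base Which base frequency to draw (default `"G"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.m5c_context <- function(object, base = "G", ...) {
  col <- paste0("freq_", base)
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$offset, y = .data[[col]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "offset from m5C site (nt, sense strand)",
                  y = paste0(base, " frequency")) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Compare top and bottom context profiles
#'
#' @param contexts Result of [compare_top_bottom_contexts()].
#' @param base Which base frequency to draw (default `"G"`).
#' @return A ggplot object with one line per group.
#' @export
plot_context_comparison <- function(contexts, base = "G") {
  col <- paste0("freq_", base)
  df <- bind_rows(
    mutate(as_tibble(contexts$top), group = "top"),
    mutate(as_tibble(contexts$bottom), group = "bottom")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data[[col]],
                                   colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "offset from m5C site (nt, sense strand)",
                  y = paste0(base, " frequency"), colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Bar plot of site-class counts
#'
#' @param class_summary Output of [summarize_site_classes()] (optionally
#'   with a `condition` column).
#' @return A ggplot object.
#' @export
plot_class_counts <- function(class_summary) {
  p <- ggplot2::ggplot(class_summary,
                       ggplot2::aes(x = .data$label, y = .data$n_sites)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "m5C sites") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
  if ("condition" %in% names(class_summary)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$condition))
  }
  p
}
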