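# ggplot2 presentations of the fitted objects.

#' @exportS3Method ggplot2::autoplot
autoplot.km_fit <- function(object, ...) {
  steps <- object$steps %>%
    group_by(group = .data$group) %>%
    dplyr::group_modify(function(df, key) {
      dplyr::bind_rows(tibble(time = 0, n_risk = max(df$n_risk),
                              n_event = 0L, n_censor = 0L, survival = 1),
                       df)
    }) %>%
    ungroup()
  ggplot2::ggplot(steps,
                  ggplot2::aes(x = .data$time, y = .data$survival,
                               colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::geom_point(data = dplyr::filter(steps, .data$n_censor > 0),
                        shape = 3, size = 1.6, show.legend = FALSE) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival probability", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.peak_pca <- function(object, samples = NULL,
                              components = c(1L, 2L), ...) {
  stopifnot(length(components) == 2L)
  pcs <- paste0("PC", components)
  df <- object$scores
  if (!is.null(samples)) {
    df <- df %>% left_join(samples, by = "sample_id")
  }
  frac <- object$explained$explained_fraction[components]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[pcs[1]]],
                                        y = .data[[pcs[2]]]))
  p <- if (!is.null(samples) && "condition" %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$condition,
                                         shape = .data$patient_id), size = 2.5)
  } else {
    p + ggplot2::geom_point(size = 2.5)
  }
  p +
    ggplot2::labs(x = sprintf("%s (%.1f%%)", pcs[1], 100 * frac[1]),
                  y = sprintf("%s (%.1f%%)", pcs[2], 100 * frac[2])) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.genotype_comparison <- function(object, ...) {
  nm <- names(object$scatter)
  ggplot2::ggplot(object$scatter,
                  ggplot2::aes(x = .data[[nm[2]]], y = .data[[nm[3]]],
                               colour = .data$set)) +
    ggplot2::geom_point(alpha = 0.6, size = 1.2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::labs(x = paste("mean log2FC,", object$labels[1]),
                  y = paste("mean log2FC,", object$labels[2]),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a subtracted signal track over a region
#'
#' @param signal Subtracted-signal tibble from [paired_subtracted_signal()].
#' @param chrom,from,to Optional region restriction.
#' @return A ggplot object.
#' @export
plot_subtracted_signal <- function(signal, chrom = NULL, from = NULL,
                                   to = NULL) {
  df <- signal
  if (!is.null(chrom)) df <- df %>% filter(.data$chrom == !!chrom)
  if (!is.null(from)) df <- df %>% filter(.data$end > from)
  if (!is.null(to)) df <- df %>% filter(.data$start < to)
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = pmin(.data$value, 0),
                                    ymax = pmax(.data$value, 0)),
                       fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::facet_wrap(~ chrom, scales = "free_x") +
    ggplot2::labs(x = "Position (bp)", y = "Mean treated - control signal") +
    ggplot2::theme_minimal()
}
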