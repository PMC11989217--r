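#' Plot moisture assessments against the moderate-withering band
#'
#' Scatter of predicted (and, when available, true) moisture per withering
#' class over the shaded 58-66% moderate band, so insufficient / moderate /
#' excessive calls can be read off directly.
#'
#' @param assessments Output of [assess_samples()] (needs
#'   `predicted_moisture`, `class_index`; `moisture` drawn as open circles if
#'   present).
#' @param lower,upper Band edges (defaults 0.58, 0.66).
#' @return A ggplot object.
#' @export
plot_withering_band <- function(assessments, lower = 0.58, upper = 0.66) {
  stopifnot(is.data.frame(assessments),
            all(c("class_index", "predicted_moisture") %in% names(assessments)))
  p <- ggplot2::ggplot(assessments,
                       ggplot2::aes(x = .data$class_index,
                                    y = .data$predicted_moisture)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = lower, ymax = upper,
                      alpha = 0.2, fill = "steelblue") +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$degree),
                         width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::labs(x = "withering class", y = "moisture (wet basis)",
                  colour = "degree") +
    ggplot2::theme_minimal()
  if ("moisture" %in% names(assessments)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(y = .data$moisture),
                                 shape = 1, size = 3, colour = "black")
  }
  p
}

#' Training-trace plot for a fitted classifier
#'
#' @param object A trained `tea_classifier`.
#' @param ... Unused.
#' @return A ggplot object showing per-epoch loss and training accuracy.
#' @export
autoplot.tea_classifier <- function(object, ...) {
  h <- tidy(object)
  long <- tidyr::pivot_longer(h, c("loss", "accuracy"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Class-mean appearance of a synthetic dataset
#'
#' Shows mean leaf-interior channel intensity per class against the class
#' moisture label — the monotone darkening contract of the generator.
#'
#' @param data Output of [generate_leaf_images()] (needs the `mask` column).
#' @return A ggplot object.
#' @export
plot_class_appearance <- function(data) {
  stopifnot(all(c("pixels", "mask", "moisture") %in% names(data)))
  means <- purrr::map_dfr(seq_len(nrow(data)), function(i) {
    px <- data$pixels[[i]]; mk <- data$mask[[i]]
    tibble(moisture = data$moisture[i],
           R = mean(px[, , 1][mk]), G = mean(px[, , 2][mk]),
           B = mean(px[, , 3][mk]))
  })
  long <- means |>
    dplyr::group_by(.data$moisture) |>
    dplyr::summarise(dplyr::across(c("R", "G", "B"), mean), .groups = "drop") |>
    tidyr::pivot_longer(c("R", "G", "B"),
                        names_to = "channel", values_to = "intensity")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$moisture, y = .data$intensity,
                                     colour = .data$channel)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(R = "firebrick", G = "forestgreen",
                                            B = "steelblue")) +
    ggplot2::labs(x = "moisture label (wet basis)",
                  y = "mean leaf-interior intensity") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
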