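#' Plot a confidence-threshold sweep
#'
#' Line plot of mean F1, miss rate and counting accuracy against the
#' confidence threshold.
#'
#' @param sweep A [threshold_sweep()] data.frame.
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep) {
  long <- rbind(
    data.frame(tau = sweep$tau, metric = "mean F1", value = sweep$mean_f1),
    data.frame(tau = sweep$tau, metric = "mean miss rate",
               value = sweep$mean_miss_rate),
    data.frame(tau = sweep$tau, metric = "mean counting accuracy",
               value = sweep$mean_counting_accuracy))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tau, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "confidence threshold", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-accession transformed assay metrics
#'
#' Bar chart (mean with per-plant points) of the transformed adult
#' survival or oviposition rate per accession.
#'
#' @param summaries A [summarize_plants()] data.frame.
#' @param metric `"AS"` or `"OR"`.
#' @return A ggplot object.
#' @export
plot_assay <- function(summaries, metric = c("AS", "OR")) {
  metric <- match.arg(metric)
  col <- paste0("transformed_", metric)
  agg <- stats::aggregate(summaries[[col]],
                          list(accession = summaries$accession), mean)
  names(agg)[2] <- "mean_value"
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$accession,
                                    y = .data$mean_value)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_point(
      data = data.frame(accession = summaries$accession,
                        value = summaries[[col]]),
      ggplot2::aes(x = .data$accession, y = .data$value)) +
    ggplot2::labs(x = NULL,
                  y = if (metric == "AS") "arcsine(sqrt(adult survival))"
                      else "sqrt(oviposition rate)") +
    ggplot2::theme_minimal()
}

#' Draw detection boxes onto an image
#'
#' @param image Numeric array `h x w x 3`.
#' @param b Box table in image coordinates.
#' @param color RGB triple for the box outline.
#' @param thickness Outline thickness in pixels.
#' @return The annotated image array.
#' @export
annotate_image <- function(image, b, color = c(1, 0.1, 0.1),
                           thickness = 2L) {
  b <- validate_boxes(b)
  h <- dim(image)[1]
  w <- dim(image)[2]
  for (i in seq_len(nrow(b))) {
    x1 <- max(1L, floor(b$x1[i]) + 1L)
    y1 <- max(1L, floor(b$y1[i]) + 1L)
    x2 <- min(w, ceiling(b$x2[i]))
    y2 <- min(h, ceiling(b$y2[i]))
    for (t in seq_len(thickness) - 1L) {
      rows <- c(min(y1 + t, h), max(y2 - t, 1L))
      cols <- c(min(x1 + t, w), max(x2 - t, 1L))
      for (ch in 1:3) {
        image[rows, x1:x2, ch] <- color[ch]
        image[y1:y2, cols, ch] <- color[ch]
      }
    }
  }
  image
}
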