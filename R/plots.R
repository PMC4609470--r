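# ggplot2 displays for the result objects.

#' @export
autoplot.ratio_spectrum <- function(object, ...) {
  bins <- object$bins %>% filter(.data$defined)
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$midpoint, y = .data$ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "grey40") +
    ggplot2::labs(
      x = "indel length (nt)", y = "insertion / deletion ratio",
      title = sprintf("%s indels", object$size_class),
      subtitle = if (!is.na(object$r_squared))
        sprintf("Pearson r² = %.2f (%s)", object$r_squared,
                ifelse(object$direction < 0, "negative", "positive"))
      else "correlation undefined") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.flank_profile <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$position, y = 100 * .data$gc,
                               colour = .data$category)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::labs(x = "position relative to indel (nt)",
                  y = "GC content (%)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.polymorphism_summary <- function(object,
                                          type = c("snp", "indel_length"),
                                          ...) {
  type <- match.arg(type)
  if (type == "snp") {
    ggplot2::ggplot(object$per_pattern,
                    ggplot2::aes(x = .data$pattern, y = .data$per_kb,
                                 fill = .data$cls)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = NULL, y = "SNPs per 1000 nt", fill = NULL) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                         hjust = 1))
  } else {
    long <- object$per_length %>%
      select("length", "n_ins", "n_del") %>%
      tidyr::pivot_longer(c("n_ins", "n_del"), names_to = "kind",
                          values_to = "n") %>%
      mutate(kind = ifelse(.data$kind == "n_ins", "insertion", "deletion"))
    ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$length), y = .data$n,
                                       fill = .data$kind)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(x = "indel length (nt)", y = "count", fill = NULL) +
      ggplot2::theme_minimal()
  }
}
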