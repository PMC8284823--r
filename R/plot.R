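#' Ternary scatter plot of ancestry fractions
#'
#' Plots individuals in the ternary simplex with corners two-European
#' (bottom left), two-Inuit (bottom right) and one-of-each (top), coloured
#' by recent-admixture category. Requires ggplot2.
#'
#' @param fractions data frame with columns `f_II`, `f_IE`, `f_EE` and
#'   optionally `category` (as produced by [run_pipeline()]'s ternary
#'   stage).
#' @param expected optional data frame of expected points (same columns
#'   plus `label`) overlaid as crosses, e.g. from [expected_ternary()]
#'   applied to [canonical_histories()].
#' @return A ggplot object.
#' @export
plot_ternary <- function(fractions, expected = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_ternary requires the ggplot2 package")
  tern_xy <- function(d)
    data.frame(d, x = d$f_II + 0.5 * d$f_IE, y = sqrt(3) / 2 * d$f_IE)
  d <- tern_xy(fractions)
  if (is.null(d$category)) d$category <- "individual"
  frame <- data.frame(x = c(0, 1, 0.5, 0), y = c(0, 0, sqrt(3) / 2, 0))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_path(data = frame, ggplot2::aes(x = x, y = y),
                       inherit.aes = FALSE, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = category),
                        alpha = 0.8, size = 1.6) +
    ggplot2::annotate("text", x = c(-0.03, 1.03, 0.5),
                      y = c(-0.04, -0.04, sqrt(3) / 2 + 0.05),
                      label = c("2 European", "2 Inuit", "1 + 1")) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "bottom")
  if (!is.null(expected)) {
    e <- tern_xy(expected)
    p <- p + ggplot2::geom_point(data = e, shape = 4, size = 3,
                                 colour = "black") +
      ggplot2::geom_text(data = e, ggplot2::aes(label = label),
                         vjust = -1, size = 3)
  }
  p
}

utils::globalVariables(c("x", "y", "category", "label"))
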