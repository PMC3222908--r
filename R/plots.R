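#' Plot class-conditional probability profiles
#'
#' Line profile of each latent class over the domain's items, the standard
#' way to read a latent class solution: the highest-risk class sits at the
#' top. Class labels include the estimated prevalence.
#'
#' @param object an `lca_fit`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot lca_fit
#' @export
autoplot.lca_fit <- function(object, ...) {
  d <- tidy(object) %>%
    mutate(class_label = sprintf("class %d (%.0f%%)", .data$class,
                                 100 * .data$pi))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$item, y = .data$rho,
                                  group = .data$class_label,
                                  colour = .data$class_label)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "endorsement probability",
                  colour = "latent class",
                  title = if (!is.na(object$domain)) object$domain else NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35, hjust = 1))
}

#' Plot the BIC model-selection curve
#'
#' @param object an `lca_selection`.
#' @param ... unused.
#' @return A ggplot of BIC against the number of classes, with the chosen
#'   model highlighted.
#' @method autoplot lca_selection
#' @export
autoplot.lca_selection <- function(object, ...) {
  ggplot2::ggplot(object$bic_table,
                  ggplot2::aes(x = .data$n_classes, y = .data$bic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chosen), size = 2.5) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = "number of classes", y = "BIC",
                  title = if (!is.na(object$domain)) object$domain else NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of odds ratios from a weighted logistic fit
#'
#' @param object a `wlogit`.
#' @param drop_intercept omit the intercept row.
#' @param ... unused.
#' @return A ggplot on the log-OR axis.
#' @method autoplot wlogit
#' @export
autoplot.wlogit <- function(object, drop_intercept = TRUE, ...) {
  d <- object$or_table
  if (drop_intercept) d <- d %>% filter(.data$term != "(Intercept)")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
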