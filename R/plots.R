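# ggplot2 views of fitted objects.

#' @export
autoplot.hslda_model <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$elbo_trace),
                       elbo = object$elbo_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$elbo)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "EM iteration", y = "Evidence lower bound",
                  title = "Variational EM convergence")
}

#' @export
autoplot.hslda_cv <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("truth", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(title = "Pooled cross-validated confusion matrix",
                  fill = "documents")
}

#' @export
autoplot.hslda_risk <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$score,
                               y = stats::reorder(.data$value, .data$score),
                               fill = .data$tier)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~ .data$class, scales = "free_y") +
    ggplot2::labs(x = "tier generative mass", y = NULL,
                  title = "Risk-factor tiers by diagnosis class")
}
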