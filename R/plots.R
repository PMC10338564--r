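## ggplot2 displays for evaluation results.

#' @importFrom ggplot2 ggplot aes geom_point geom_abline geom_col labs
#'   facet_wrap theme_minimal autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot predicted versus measured log10 kcat
#'
#' @param predictions Test tibble with `y` and `y_pred` columns (from
#'   [run_kcat_pipeline()]).
#' @return A ggplot object.
#' @export
plot_predictions <- function(predictions) {
  ggplot(predictions, aes(x = .data$y, y = .data$y_pred)) +
    geom_point(alpha = 0.4, size = 1) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey40") +
    labs(x = expression(log[10] ~ k[cat] ~ "(measured, " * s^-1 * ")"),
         y = expression(log[10] ~ k[cat] ~ "(predicted, " * s^-1 * ")")) +
    theme_minimal()
}

#' Autoplot a stratified evaluation report
#'
#' Bar panels of R^2 by identity bucket and by reaction stratum, annotated
#' with the per-stratum record counts.
#'
#' @param object A `kcat_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kcat_eval
#' @export
autoplot.kcat_eval <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(object$by_identity, facet = "max. sequence identity"),
    dplyr::mutate(object$by_reaction, facet = "reaction stratum")
  )
  ggplot(df, aes(x = .data$stratum, y = .data$r2)) +
    geom_col(fill = "grey25") +
    ggplot2::geom_text(aes(label = paste0("n=", .data$n)),
                       vjust = -0.4, size = 3) +
    facet_wrap(~facet, scales = "free_x") +
    labs(x = NULL, y = expression(R^2)) +
    theme_minimal()
}
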