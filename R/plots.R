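#' Plot a residual profile
#'
#' Needle plot of the environmental perturbation (EP) score at every
#' position; the mutated position carries the residual score.
#'
#' @param object A tibble from [residual_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.quadpot_residual_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$ep)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$position, yend = 0)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "residue position", y = "EP score") +
    ggplot2::theme_minimal()
}

#' Scatter plot of CMP against residue environment scores
#'
#' Reproduces the quadrant view of the comprehensive-mutagenesis data:
#' x = native environment score, y = CMP, optionally colored by a residue
#' category such as polarity.
#'
#' @param profile Tibble from [comprehensive_mutational_profile()].
#' @param category Optional vector aligned with `profile` rows (e.g.
#'   [residue_polarity()] of the native residues).
#' @return A ggplot object.
#' @export
plot_cmp_res <- function(profile, category = NULL) {
  df <- profile
  if (!is.null(category)) df$category <- category
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$q, y = .data$cmp)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "residue environment score (q)", y = "CMP score") +
    ggplot2::theme_minimal()
  if (is.null(category)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(color = .data$category))
  }
}

#' ROC curve of cross-validated predictions
#'
#' @param object A `quadpot_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.quadpot_cv <- function(object, ...) {
  pr <- object$predictions
  roc <- pr |>
    dplyr::group_by(repeat_id = .data$repeat_id) |>
    dplyr::group_modify(function(d, ...) {
      ord <- order(-d$prob_u)
      tibble(fpr = c(0, cumsum(d$truth[ord] == "A") / sum(d$truth == "A")),
             tpr = c(0, cumsum(d$truth[ord] == "U") / sum(d$truth == "U")))
    }) |>
    dplyr::ungroup()
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    group = .data$repeat_id)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false-positive rate (1 - specificity)",
                  y = "true-positive rate (sensitivity)") +
    ggplot2::theme_minimal()
}

#' Plot a learning curve
#'
#' Mean cross-validated BAR, MCC and AUC against training-set size, with
#' one-standard-deviation ribbons.
#'
#' @param object A `quadpot_learning_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.quadpot_learning_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"size",
                              names_to = c("metric", "stat"),
                              names_sep = "_") |>
    tidyr::pivot_wider(names_from = "stat", values_from = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$size, y = .data$mean,
                                     color = .data$metric,
                                     fill = .data$metric)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.15, color = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "training-set size", y = "mean 10-fold CV value") +
    ggplot2::theme_minimal()
}
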