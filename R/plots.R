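#' Plot per-probe posterior model probabilities
#'
#' Stacked-bar view of the posterior probability of each candidate model
#' for a subset of probes.
#'
#' @param fit A `meth_fit`.
#' @param probes Probes to show (default: the 25 with the least-null
#'   posterior).
#' @return A ggplot object.
#' @export
plot_posterior_probs <- function(fit, probes = NULL) {
  stopifnot(inherits(fit, "meth_fit"))
  if (is.null(probes)) {
    nullcol <- if ("Null" %in% colnames(fit$posterior_probs)) "Null"
               else colnames(fit$posterior_probs)[1L]
    probes <- fit$probes[order(fit$posterior_probs[, nullcol])][
      seq_len(min(25L, length(fit$probes)))]
  }
  tidy(fit) |>
    dplyr::filter(.data$probe_id %in% probes) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$probe_id,
                                 y = .data$posterior_prob,
                                 fill = .data$model)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Posterior model probability",
                  fill = "Model") +
    ggplot2::theme_minimal()
}

#' Plot differential-methylation posteriors
#'
#' Posterior mean and 95% credible interval of the difference from the
#' reference partition, per probe and cell-specific partition.
#'
#' @param diff Tibble from [differential_posterior()].
#' @param max_probes Cap on probes shown, default 50.
#' @return A ggplot object.
#' @export
plot_differential <- function(diff, max_probes = 50L) {
  show <- unique(diff$probe_id)
  show <- show[seq_len(min(max_probes, length(show)))]
  diff |>
    dplyr::filter(.data$probe_id %in% show) |>
    ggplot2::ggplot(ggplot2::aes(x = stats::reorder(.data$probe_id,
                                                    .data$posterior_mean),
                                 y = .data$posterior_mean,
                                 colour = .data$state)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high),
                             linewidth = 0.3, size = 0.2) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$partition)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Differential methylation (vs reference)",
                  colour = "State") +
    ggplot2::theme_minimal()
}

#' Plot sex-effect posteriors
#'
#' Female-minus-male posterior mean with 95% interval per probe and
#' partition; the shaded band marks differences within +/- delta.
#'
#' @param sex_tbl Tibble from [sex_effect_posterior()].
#' @param max_probes Cap on probes shown, default 50.
#' @return A ggplot object.
#' @export
plot_sex_effects <- function(sex_tbl, max_probes = 50L) {
  delta <- sex_tbl$delta[1L]
  show <- unique(sex_tbl$probe_id)
  show <- show[seq_len(min(max_probes, length(show)))]
  z <- qnorm(0.975)
  sex_tbl |>
    dplyr::filter(.data$probe_id %in% show) |>
    ggplot2::ggplot(ggplot2::aes(x = stats::reorder(.data$probe_id,
                                                    .data$posterior_mean),
                                 y = .data$posterior_mean,
                                 colour = .data$declared)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = -delta, ymax = delta, alpha = 0.15) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$posterior_mean - z * .data$posterior_sd,
      ymax = .data$posterior_mean + z * .data$posterior_sd),
      linewidth = 0.3, size = 0.2) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$partition)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Sex difference (F - M)",
                  colour = "Declared") +
    ggplot2::theme_minimal()
}
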