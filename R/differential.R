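range_prob_bins <- rbind(
  c(0.00, 0.10), c(0.10, 0.20), c(0.20, 0.30),
  c(0.30, 0.40), c(0.40, 0.50), c(0.50, Inf)
)
range_prob_labels <- c("<0.10", "0.10-0.20", "0.20-0.30",
                       "0.30-0.40", "0.40-0.50", ">0.50")

# P(lo <= |D| < hi) for D ~ N(mean, sd); bins left-closed.
folded_normal_bin_probs <- function(mean, sd) {
  cdf_abs <- function(x) {
    if (sd == 0) return(as.numeric(abs(mean) <= x))
    pnorm((x - mean) / sd) - pnorm((-x - mean) / sd)
  }
  hi <- vapply(range_prob_bins[, 2L],
               function(b) if (is.infinite(b)) 1 else cdf_abs(b), numeric(1))
  lo <- vapply(range_prob_bins[, 1L], cdf_abs, numeric(1))
  setNames(hi - lo, range_prob_labels)
}

#' Posterior summaries of differential methylation
#'
#' For each probe and each cell-specific partition p of a candidate model,
#' the difference from the reference partition has the normal posterior
#' \deqn{\mu_p - \mu_{ref} \sim N\big(\hat\mu_p - \hat\mu_{ref},\;
#'   \tfrac{g}{1+g}\tfrac{\hat\sigma^2}{n_s}
#'   (\tfrac{1}{c_p} + \tfrac{1}{c_{ref}})\big).}
#' Summaries are the posterior mean, the 95% credible interval, posterior
#' probabilities of |difference| in the bins \[0,0.10), \[0.10,0.20), ...,
#' \[0.50,Inf), and the methylation state (hypomethylated if the posterior
#' mean is negative, hypermethylated if positive, unclassified at exactly
#' zero).
#'
#' @param fit A `meth_fit`.
#' @param model Model name. Must have a reference partition; for the
#'   saturated model supply `baseline`.
#' @param probes Probe ids to summarise (default: all probes in the fit;
#'   typically a marker panel's probes).
#' @param baseline For models without a reference partition (the saturated
#'   model), the index of the partition to use as baseline.
#' @return Tibble with one row per probe x cell-specific partition:
#'   `probe_id`, `partition` (cell types, comma-joined), `posterior_mean`,
#'   `ci_low`, `ci_high`, the six bin-probability columns, and `state`.
#' @export
differential_posterior <- function(fit, model, probes = NULL,
                                   baseline = NULL) {
  stopifnot(inherits(fit, "meth_fit"), model %in% names(fit$models$models))
  mod <- fit$models$models[[model]]
  ref <- mod$reference
  if (is.na(ref)) {
    if (length(mod$partition) == 1L) {
      stop("differential_posterior: the null model has no differential ",
           "partitions")
    }
    if (is.null(baseline)) {
      stop("differential_posterior: model '", model, "' has no reference ",
           "partition; supply `baseline`")
    }
    ref <- as.integer(baseline)
    stopifnot(ref >= 1L, ref <= length(mod$partition))
  }
  if (is.null(probes)) probes <- fit$probes
  idx <- match(probes, fit$probes)
  if (anyNA(idx)) {
    stop("differential_posterior: probes not in fit: ",
         paste(head(probes[is.na(idx)], 5L), collapse = ", "))
  }

  mu <- fit$mu_hat[[model]][idx, , drop = FALSE]
  s2 <- fit$sigma2_hat[idx, model]
  w <- fit$g / (1 + fit$g)
  cs <- mod$sizes
  z975 <- qnorm(0.975)

  cell_specific <- setdiff(seq_along(mod$partition), ref)
  rows <- purrr::map_dfr(cell_specific, function(p) {
    m_diff <- mu[, p] - mu[, ref]
    v_diff <- w * s2 / fit$n_s * (1 / cs[p] + 1 / cs[ref])
    sd_diff <- sqrt(v_diff)
    bins <- t(vapply(seq_along(m_diff),
                     function(k) folded_normal_bin_probs(m_diff[k], sd_diff[k]),
                     numeric(length(range_prob_labels))))
    colnames(bins) <- paste0("pr_", gsub("[<>]", "", range_prob_labels))
    dplyr::bind_cols(
      tibble::tibble(
        probe_id = probes,
        partition = paste(mod$partition[[p]], collapse = ","),
        posterior_mean = unname(m_diff),
        posterior_sd = unname(sd_diff),
        ci_low = unname(m_diff - z975 * sd_diff),
        ci_high = unname(m_diff + z975 * sd_diff)
      ),
      tibble::as_tibble(bins)
    ) |>
      dplyr::mutate(state = dplyr::case_when(
        .data$posterior_mean < 0 ~ "hypomethylated",
        .data$posterior_mean > 0 ~ "hypermethylated",
        TRUE ~ NA_character_
      ))
  })
  attr(rows, "model") <- model
  attr(rows, "sex") <- fit$sex
  rows
}

#' Posterior assessment of sex-specific methylation differences
#'
#' For common markers, the female-minus-male difference in each
#' cell-specific partition mean has the normal posterior with mean
#' `mu_hat_F,p - mu_hat_M,p` and variance
#' `sigma2_F * g_F/((1+g_F) n_F c_p) + sigma2_M * g_M/((1+g_M) n_M c_p)`.
#' A probe is declared sex-specific when the posterior probability that the
#' absolute difference is at least `delta` exceeds `prob_threshold` in any
#' cell-specific partition.
#'
#' @param fit_f,fit_m `meth_fit` objects for female and male data over the
#'   same candidate models.
#' @param model Model name.
#' @param probes Probe ids (default: probes present in both fits).
#' @param delta Minimum absolute difference of interest, default 0.10.
#' @param prob_threshold Posterior-probability threshold, default 0.95.
#' @return Tibble, one row per probe x cell-specific partition:
#'   `probe_id`, `partition`, `posterior_mean` (female minus male),
#'   `posterior_sd`, `prob_effect` = Pr(|difference| >= delta), and
#'   per-probe `declared`.
#' @export
sex_effect_posterior <- function(fit_f, fit_m, model, probes = NULL,
                                 delta = 0.10, prob_threshold = 0.95) {
  stopifnot(inherits(fit_f, "meth_fit"), inherits(fit_m, "meth_fit"),
            model %in% names(fit_f$models$models),
            delta >= 0, prob_threshold > 0, prob_threshold < 1)
  mod_f <- fit_f$models$models[[model]]
  mod_m <- fit_m$models$models[[model]]
  if (!identical(lapply(mod_f$partition, sort),
                 lapply(mod_m$partition, sort))) {
    stop("sex_effect_posterior: partition mismatch between sexes for '",
         model, "'")
  }
  if (is.null(probes)) probes <- intersect(fit_f$probes, fit_m$probes)
  if (!length(probes)) stop("sex_effect_posterior: no probes in both fits")
  if_ <- match(probes, fit_f$probes)
  im <- match(probes, fit_m$probes)
  if (anyNA(if_) || anyNA(im)) {
    stop("sex_effect_posterior: probes missing from one of the fits")
  }

  ref <- mod_f$reference
  parts <- seq_along(mod_f$partition)
  if (!is.na(ref)) parts <- setdiff(parts, ref)
  cs <- mod_f$sizes
  wf <- fit_f$g / (1 + fit_f$g)
  wm <- fit_m$g / (1 + fit_m$g)
  s2f <- fit_f$sigma2_hat[if_, model]
  s2m <- fit_m$sigma2_hat[im, model]

  rows <- purrr::map_dfr(parts, function(p) {
    m_diff <- fit_f$mu_hat[[model]][if_, p] - fit_m$mu_hat[[model]][im, p]
    v_diff <- s2f * wf / (fit_f$n_s * cs[p]) + s2m * wm / (fit_m$n_s * cs[p])
    sd_diff <- sqrt(v_diff)
    tibble::tibble(
      probe_id = probes,
      partition = paste(mod_f$partition[[p]], collapse = ","),
      posterior_mean = unname(m_diff),
      posterior_sd = unname(sd_diff),
      prob_effect = prob_abs_diff_at_least(m_diff, sd_diff, delta)
    )
  })
  rows |>
    dplyr::group_by(.data$probe_id) |>
    dplyr::mutate(declared = any(.data$prob_effect > prob_threshold)) |>
    dplyr::ungroup() |>
    dplyr::mutate(delta = delta, prob_threshold = prob_threshold,
                  model = model)
}

#' Probability that |D| >= delta for D ~ N(mean, sd)
#'
#' @param mean,sd Posterior mean(s) and sd(s).
#' @param delta Threshold (>= 0).
#' @return Vector of probabilities.
#' @export
prob_abs_diff_at_least <- function(mean, sd, delta) {
  stopifnot(delta >= 0, all(sd >= 0))
  ifelse(sd == 0, as.numeric(abs(mean) >= delta),
         pnorm((mean - delta) / sd) + pnorm((-delta - mean) / sd))
}
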