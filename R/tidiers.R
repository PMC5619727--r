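#' Tidy a model fit into long format
#'
#' @param x A `meth_fit`.
#' @param ... Unused.
#' @return Tibble with one row per probe x model: `probe_id`, `model`,
#'   `log_marginal`, `posterior_prob`, `sigma2_hat`.
#' @method tidy meth_fit
#' @export
tidy.meth_fit <- function(x, ...) {
  tibble::tibble(
    probe_id = rep(x$probes, times = ncol(x$posterior_probs)),
    model = rep(colnames(x$posterior_probs), each = length(x$probes)),
    log_marginal = as.vector(x$log_marginal),
    posterior_prob = as.vector(x$posterior_probs),
    sigma2_hat = as.vector(x$sigma2_hat)
  )
}

#' One-row summary of a model fit
#'
#' @param x A `meth_fit`.
#' @param ... Unused.
#' @return Tibble with sex, probe/model counts, n_s, b0, g and (for EM
#'   fits) convergence information.
#' @method glance meth_fit
#' @export
glance.meth_fit <- function(x, ...) {
  tibble::tibble(
    sex = x$sex,
    n_probes = length(x$probes),
    n_models = length(x$models$models),
    n_subjects = x$n_s,
    b0 = x$b0,
    g = x$g,
    em_converged = if (is.null(x$em)) NA else x$em$converged,
    em_iterations = if (is.null(x$em)) NA_integer_ else x$em$iterations
  )
}

#' Posterior model probabilities as a wide tibble
#'
#' @param fit A `meth_fit`.
#' @return Tibble: `probe_id` plus one probability column per model.
#' @export
posterior_prob_table <- function(fit) {
  stopifnot(inherits(fit, "meth_fit"))
  dplyr::bind_cols(tibble::tibble(probe_id = fit$probes),
                   tibble::as_tibble(fit$posterior_probs))
}
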