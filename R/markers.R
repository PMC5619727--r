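#' Select CpG markers for a candidate model under a Bayes FDR
#'
#' Probes are ranked by posterior probability of the model, descending. The
#' estimated Bayes FDR of the top-r set is the mean of (1 - probability)
#' over the set; the panel is the largest prefix whose estimate does not
#' exceed `fdr_level`. Probes tied in probability enter all-or-none: the
#' tie group is included only if the estimate still passes with the whole
#' group in.
#'
#' @param fit A `meth_fit`, or a named numeric vector of posterior
#'   probabilities (names = probe ids).
#' @param model Model name (required when `fit` is a `meth_fit`).
#' @param fdr_level Bayes FDR control level, default 0.05.
#' @return A `marker_panel`: tibble of selected probes with probabilities,
#'   plus the model name, level, and realized Bayes FDR.
#' @export
select_markers <- function(fit, model = NULL, fdr_level = 0.05) {
  stopifnot(fdr_level >= 0, fdr_level < 1)
  if (inherits(fit, "meth_fit")) {
    stopifnot(!is.null(model), model %in% colnames(fit$posterior_probs))
    probs <- setNames(fit$posterior_probs[, model], fit$probes)
  } else {
    probs <- fit
    if (is.null(names(probs))) names(probs) <- paste0("probe", seq_along(probs))
    if (is.null(model)) model <- "model"
  }
  stopifnot(all(probs >= 0 & probs <= 1))

  ord <- order(probs, decreasing = TRUE)
  p_sorted <- probs[ord]
  fdr_hat <- cumsum(1 - p_sorted) / seq_along(p_sorted)
  pass <- which(fdr_hat <= fdr_level)
  r <- if (length(pass)) max(pass) else 0L
  # all-in-or-all-out on ties: shrink past any tie straddling the cut
  while (r > 0L && r < length(p_sorted) && p_sorted[r] == p_sorted[r + 1L]) {
    r <- r - 1L
    while (r > 0L && p_sorted[r] == p_sorted[r + 1L]) r <- r - 1L
  }
  sel <- if (r > 0L) tibble::tibble(
    probe_id = names(p_sorted)[seq_len(r)],
    posterior_prob = unname(p_sorted[seq_len(r)])
  ) else tibble::tibble(probe_id = character(), posterior_prob = numeric())

  structure(
    list(model = model, fdr_level = fdr_level, probes = sel,
         realized_bayes_fdr = if (r > 0L) unname(fdr_hat[r]) else 0),
    class = "marker_panel"
  )
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("<marker_panel> model ", x$model, ": ", nrow(x$probes),
      " probes at Bayes FDR <= ", x$fdr_level,
      " (realized ", signif(x$realized_bayes_fdr, 4), ")\n", sep = "")
  invisible(x)
}

#' @rdname select_markers
#' @param x A `marker_panel`.
#' @param ... Unused.
#' @method tidy marker_panel
#' @export
tidy.marker_panel <- function(x, ...) {
  dplyr::mutate(x$probes, model = x$model, .before = 1L)
}

#' Common markers across sexes
#'
#' CpGs selected for the same candidate model in both the female and male
#' panels.
#'
#' @param panel_f,panel_m `marker_panel` objects for the same model.
#' @return Character vector of common probe ids.
#' @export
common_markers <- function(panel_f, panel_m) {
  stopifnot(inherits(panel_f, "marker_panel"),
            inherits(panel_m, "marker_panel"))
  if (!identical(panel_f$model, panel_m$model)) {
    stop("common_markers: panels are for different models ('",
         panel_f$model, "' vs '", panel_m$model, "')")
  }
  intersect(panel_f$probes$probe_id, panel_m$probes$probe_id)
}

#' Marker panels for every candidate model
#'
#' @param fit A `meth_fit`.
#' @param fdr_level Bayes FDR level, default 0.05.
#' @return Named list of `marker_panel` objects, one per model.
#' @export
select_all_markers <- function(fit, fdr_level = 0.05) {
  stopifnot(inherits(fit, "meth_fit"))
  nm <- colnames(fit$posterior_probs)
  setNames(lapply(nm, function(m) select_markers(fit, m, fdr_level)), nm)
}
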