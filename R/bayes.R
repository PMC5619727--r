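#' Prior configuration for the g-prior model
#'
#' Group means are given a Zellner g-prior centred at the global mean
#' methylation level `b0` with covariance `g * sigma2 / n * (X'X)^{-1}`,
#' and the residual variance the scale-invariant prior `p(sigma2) ~ 1/sigma2`.
#'
#' @param b0 Prior centre in \[0, 1\] (global mean beta-value).
#' @param g Positive shrinkage factor; `g / (1 + g)` is the weight on the
#'   data in the posterior mean.
#' @return A `prior_config` list.
#' @export
prior_config <- function(b0, g) {
  stopifnot(is.numeric(b0), length(b0) == 1L, b0 >= 0, b0 <= 1,
            is.numeric(g), length(g) == 1L, g > 0)
  structure(list(b0 = b0, g = g), class = "prior_config")
}

# Sufficient statistics for the marginal likelihood, one probe set at a time.
# For probe k and model m the marginal depends on the data only through
#   T_k   = sum over all n*J observations of (y - b0)^2
#   B_km  = sum_p n * c_p * (zbar_pk)^2,  zbar_pk = partition mean of (y - b0)
# beta: K x n x J array. Returns list(T = K-vector, B = K x M matrix,
# P = M-vector of partition counts, N = n*J, n = n).
marginal_suffstats <- function(beta, models, b0) {
  stopifnot(is.array(beta), length(dim(beta)) == 3L)
  K <- dim(beta)[1L]; n <- dim(beta)[2L]; J <- dim(beta)[3L]
  z <- beta - b0
  Tk <- apply(z^2, 1L, sum)
  # per-cell-type means of z: K x J
  zbar_cell <- apply(z, c(1L, 3L), mean)
  if (is.null(dim(zbar_cell))) zbar_cell <- matrix(zbar_cell, nrow = K)
  M <- length(models$models)
  B <- matrix(NA_real_, K, M,
              dimnames = list(dimnames(beta)[[1L]],
                              names(models$models)))
  ct <- dimnames(beta)[[3L]]
  for (m in seq_len(M)) {
    mod <- models$models[[m]]
    if (!setequal(mod$cell_types, ct)) {
      stop("marginal_suffstats: model cell types do not match the data")
    }
    Bm <- 0
    for (p in seq_along(mod$partition)) {
      cols <- match(mod$partition[[p]], ct)
      zp <- if (length(cols) == 1L) zbar_cell[, cols]
            else rowMeans(zbar_cell[, cols, drop = FALSE])
      Bm <- Bm + n * length(cols) * zp^2
    }
    B[, m] <- Bm
  }
  list(T = Tk, B = B,
       P = vapply(models$models, function(m) length(m$partition), 0L),
       N = n * J, n = n)
}

# log marginal likelihoods from sufficient statistics at shrinkage g:
#   log p(y_k | m, g) = -(N/2) log(pi) - (P_m/2) log(1+g)
#                       + lgamma(N/2) - (N/2) log(S_km)
#   S_km = T_k - g/(1+g) * B_km
# Returns a K x M matrix.
log_marginal_matrix <- function(ss, g) {
  w <- g / (1 + g)
  S <- ss$T - w * ss$B
  S[S < 0] <- 0  # guard against roundoff; S >= T/(1+g) * ... in exact math
  if (any(S <= 0)) {
    stop("log marginal is degenerate: zero residual variation ",
         "(all values equal to the prior centre b0)")
  }
  const <- -(ss$N / 2) * log(pi) + lgamma(ss$N / 2)
  sweep(-(ss$N / 2) * log(S), 2L, (ss$P / 2) * log(1 + g), `-`) + const
}

#' Log marginal likelihood of one CpG under a candidate model
#'
#' The marginal `p(y | model, g)` integrates the Gaussian likelihood over
#' the g-prior on the partition means and the scale-invariant prior on the
#' common residual variance. With N = n * J observations, P partitions of
#' sizes c_p, and z = y - b0:
#' \deqn{\log p(y) = -\tfrac{N}{2}\log\pi - \tfrac{P}{2}\log(1+g)
#'   + \log\Gamma(\tfrac{N}{2}) - \tfrac{N}{2}\log S,}
#' \deqn{S = \sum z^2 - \tfrac{g}{1+g}\sum_p n\,c_p\,\bar z_p^2.}
#'
#' @param y n x J matrix of beta-values for one CpG (columns named by cell
#'   type, matching the model's cell types).
#' @param model A [candidate_model()].
#' @param prior A [prior_config()].
#' @return Scalar log marginal likelihood.
#' @export
log_marginal_likelihood <- function(y, model, prior) {
  stopifnot(is.matrix(y), inherits(model, "candidate_model"),
            inherits(prior, "prior_config"))
  if (is.null(colnames(y))) colnames(y) <- model$cell_types
  n <- nrow(y); J <- ncol(y)
  P <- length(model$partition)
  if (n * J <= P) {
    stop("improper marginal: n * J (", n * J,
         ") must exceed the number of partitions (", P, ")")
  }
  beta <- array(y, dim = c(1L, n, J),
                dimnames = list("k", rownames(y), colnames(y)))
  ms <- model_set(list(model))
  ss <- marginal_suffstats(beta, ms, prior$b0)
  drop(log_marginal_matrix(ss, prior$g))
}

#' Posterior model probabilities from log marginals
#'
#' Normalises prior-weighted marginal likelihoods over candidate models
#' via log-sum-exp.
#'
#' @param log_marginals Numeric vector (one CpG) or K x M matrix of log
#'   marginal likelihoods.
#' @param prior_model_probs Prior probability per model, summing to 1.
#' @return Probability vector (or matrix) with rows summing to 1.
#' @export
posterior_model_probabilities <- function(log_marginals, prior_model_probs) {
  vec <- is.null(dim(log_marginals))
  lm <- if (vec) matrix(log_marginals, nrow = 1L) else as.matrix(log_marginals)
  stopifnot(ncol(lm) == length(prior_model_probs),
            abs(sum(prior_model_probs) - 1) < 1e-8)
  if (any(is.na(lm))) stop("posterior_model_probabilities: NA log marginal")
  lw <- sweep(lm, 2L, log(prior_model_probs), `+`)
  mx <- apply(lw, 1L, max)
  if (any(!is.finite(mx))) {
    stop("posterior_model_probabilities: all log marginals are -Inf")
  }
  e <- exp(lw - mx)
  pr <- e / rowSums(e)
  dimnames(pr) <- dimnames(lm)
  if (vec) drop(pr) else pr
}

#' Posterior mean of the partition means
#'
#' Shrinks the per-partition sample means toward the prior centre:
#' `b0 + g/(1+g) * (ybar_p - b0)`. Differences between components are the
#' shrunken differences of partition sample means.
#'
#' @inheritParams log_marginal_likelihood
#' @return Numeric vector of length P (one entry per partition).
#' @export
posterior_mu <- function(y, model, prior) {
  stopifnot(is.matrix(y), inherits(model, "candidate_model"),
            inherits(prior, "prior_config"))
  if (is.null(colnames(y))) colnames(y) <- model$cell_types
  ybar_cell <- colMeans(y)
  ybar_p <- vapply(model$partition, function(g) {
    mean(ybar_cell[g])
  }, numeric(1))
  w <- prior$g / (1 + prior$g)
  prior$b0 + w * (ybar_p - prior$b0)
}

#' Posterior point estimate of the residual variance
#'
#' Under the conjugate scale-invariant prior the posterior of sigma2 is
#' inverse-gamma with shape N/2 and scale S/2 (S as in
#' [log_marginal_likelihood()]). The point estimate is the posterior mean
#' `S / (N - 2)`; when N <= 2 the posterior mean is not finite and the
#' posterior mode `S / (N + 2)` is returned with a warning.
#'
#' @inheritParams log_marginal_likelihood
#' @return Positive scalar.
#' @export
posterior_sigma2 <- function(y, model, prior) {
  stopifnot(is.matrix(y), inherits(model, "candidate_model"),
            inherits(prior, "prior_config"))
  if (is.null(colnames(y))) colnames(y) <- model$cell_types
  n <- nrow(y); J <- ncol(y); N <- n * J
  beta <- array(y, dim = c(1L, n, J),
                dimnames = list("k", rownames(y), colnames(y)))
  ms <- model_set(list(model))
  ss <- marginal_suffstats(beta, ms, prior$b0)
  S <- drop(ss$T - prior$g / (1 + prior$g) * ss$B)
  if (S <= 0) stop("posterior_sigma2: zero residual variation")
  if (N > 2) S / (N - 2)
  else {
    warning("posterior degrees of freedom <= 2; returning posterior mode")
    S / (N + 2)
  }
}

#' Empirical-Bayes EM estimate of the g-prior shrinkage factor
#'
#' Treats the per-CpG model indicator as latent. The E-step computes
#' posterior model probabilities at the current g; the M-step maximises the
#' expected complete-data log marginal over g by bracketed scalar
#' optimisation on log g. Iterates until the relative change in the
#' observed-data objective `sum_k log sum_m p(y_k|m,g) Pr(m)` falls below
#' `tol`. The converged posterior model probabilities are a free by-product.
#'
#' @param data A [meth_dataset] (or a K x n x J beta array).
#' @param models A [model_set()].
#' @param b0 Prior centre; default the grand mean of the data.
#' @param init_g Starting value, default 1.
#' @param tol Relative objective-change tolerance, default 1e-6.
#' @param max_iter Iteration cap, default 200.
#' @return List with `g` (the estimate), `trace` (tibble of g and objective
#'   per iteration), `converged`, `iterations`, and `posterior_probs`
#'   (K x M matrix at the final g).
#' @export
estimate_g_em <- function(data, models, b0 = NULL, init_g = 1,
                          tol = 1e-6, max_iter = 200L) {
  beta <- if (inherits(data, "meth_dataset")) data$beta else data
  stopifnot(inherits(models, "model_set"), init_g > 0)
  if (is.null(b0)) b0 <- mean(beta)
  ss <- marginal_suffstats(beta, models, b0)
  if (ss$N <= max(ss$P)) {
    stop("improper marginal: n * J must exceed the largest model's ",
         "partition count")
  }
  prior <- models$prior

  objective <- function(g) {
    lm <- log_marginal_matrix(ss, g)
    lw <- sweep(lm, 2L, log(prior), `+`)
    mx <- apply(lw, 1L, max)
    sum(mx + log(rowSums(exp(lw - mx))))
  }
  # expected complete-data log marginal at shrinkage g, weights q (K x M)
  m_obj <- function(logg, q) {
    g <- exp(logg)
    sum(q * log_marginal_matrix(ss, g))
  }

  g <- init_g
  obj <- objective(g)
  g_path <- g
  obj_path <- obj
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    q <- posterior_model_probabilities(log_marginal_matrix(ss, g), prior)
    if (is.null(dim(q))) q <- matrix(q, nrow = 1L)
    opt <- optimize(m_obj, interval = log(c(1e-8, 1e8)), q = q,
                    maximum = TRUE, tol = 1e-10)
    g_new <- exp(opt$maximum)
    obj_new <- objective(g_new)
    g_path <- c(g_path, g_new)
    obj_path <- c(obj_path, obj_new)
    rel <- abs(obj_new - obj) / max(1, abs(obj))
    g <- g_new
    obj <- obj_new
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("estimate_g_em: no convergence in ", max_iter,
            " iterations; returning best iterate")
  }
  lm <- log_marginal_matrix(ss, g)
  list(g = g,
       trace = tibble::tibble(iteration = seq_along(g_path) - 1L,
                              g = g_path, objective = obj_path),
       converged = converged, iterations = iter,
       posterior_probs = posterior_model_probabilities(lm, prior))
}

#' Fit the candidate models to every CpG
#'
#' Computes, for each probe, the log marginal likelihood of every candidate
#' model under the g-prior, the posterior model probabilities (with equal
#' or supplied prior model weights), and per-model posterior moments of the
#' partition means and residual variance.
#'
#' @param data A [meth_dataset].
#' @param models A [model_set()]; default enumerated from the lineage
#'   inferred from the data with complete linkage.
#' @param b0 Prior centre: `"auto"` (grand mean of the data) or a scalar.
#' @param g Shrinkage factor: `"em"` (empirical-Bayes EM estimate) or a
#'   positive scalar.
#' @param ... Passed to [estimate_g_em()] (`init_g`, `tol`, `max_iter`).
#' @return A `meth_fit` object; see [tidy.meth_fit()] and
#'   [glance.meth_fit()].
#' @export
fit_models <- function(data, models = NULL, b0 = "auto", g = "em", ...) {
  stopifnot(inherits(data, "meth_dataset"))
  if (is.null(models)) {
    models <- enumerate_candidate_models(infer_lineage(cell_type_means(data)))
  }
  stopifnot(inherits(models, "model_set"))
  b0 <- if (identical(b0, "auto")) mean(data$beta) else {
    stopifnot(is.numeric(b0), b0 >= 0, b0 <= 1); as.numeric(b0)
  }
  em <- NULL
  if (identical(g, "em")) {
    em <- estimate_g_em(data, models, b0 = b0, ...)
    g <- em$g
  } else {
    stopifnot(is.numeric(g), g > 0)
    g <- as.numeric(g)
  }

  ss <- marginal_suffstats(data$beta, models, b0)
  if (ss$N <= max(ss$P)) {
    stop("improper marginal: n * J must exceed the largest model's ",
         "partition count")
  }
  lm <- log_marginal_matrix(ss, g)
  probs <- posterior_model_probabilities(lm, models$prior)
  if (is.null(dim(probs))) {
    probs <- matrix(probs, nrow = 1L, dimnames = dimnames(lm))
  }

  w <- g / (1 + g)
  N <- ss$N
  S <- ss$T - w * ss$B                      # K x M
  sigma2 <- if (N > 2) S / (N - 2) else S / (N + 2)
  zbar_cell <- apply(data$beta - b0, c(1L, 3L), mean)  # K x J
  if (is.null(dim(zbar_cell))) zbar_cell <- matrix(zbar_cell, nrow = 1L)
  mu_hat <- lapply(models$models, function(mod) {
    P <- length(mod$partition)
    out <- matrix(NA_real_, nrow = dim(data$beta)[1L], ncol = P,
                  dimnames = list(data$probes, paste0("p", seq_len(P))))
    for (p in seq_len(P)) {
      cols <- match(mod$partition[[p]], data$cell_types)
      zp <- if (length(cols) == 1L) zbar_cell[, cols]
            else rowMeans(zbar_cell[, cols, drop = FALSE])
      out[, p] <- b0 + w * zp
    }
    out
  })

  structure(
    list(probes = data$probes, cell_types = data$cell_types,
         sex = data$sex, n_s = length(data$subjects),
         models = models, b0 = b0, g = g,
         log_marginal = lm, posterior_probs = probs,
         mu_hat = mu_hat, sigma2_hat = sigma2,
         em = if (!is.null(em)) em[c("trace", "converged", "iterations")]),
    class = "meth_fit"
  )
}

#' @export
print.meth_fit <- function(x, ...) {
  cat("<meth_fit> sex ", x$sex, ": ", length(x$probes), " probes, ",
      length(x$models$models), " candidate models, n_s = ", x$n_s,
      "\n  b0 = ", signif(x$b0, 4), ", g = ", signif(x$g, 6),
      if (!is.null(x$em)) paste0(" (EM, ", x$em$iterations, " iterations)"),
      "\n", sep = "")
  invisible(x)
}
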