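# Independent numerical oracles and small fixture builders.

# Quadrature oracle for the g-prior marginal likelihood: the partition means
# are integrated analytically (normal-normal conjugacy on the stacked
# design), leaving a 1-D integral over log sigma2 done by adaptive
# quadrature. Shares no code with the package's closed form.
oracle_log_marginal <- function(y, model, prior) {
  X <- model$design
  n <- nrow(y); J <- ncol(y); N <- n * J; P <- ncol(X)
  stopifnot(identical(colnames(y), rownames(X)))
  z <- as.vector(t(y)) - prior$b0          # stacked cell-within-subject
  Xf <- do.call(rbind, replicate(n, X, simplify = FALSE))
  g <- prior$g
  XtX <- crossprod(Xf)
  Pz <- Xf %*% solve(XtX, crossprod(Xf, z))
  S <- sum(z^2) - (g / (1 + g)) * sum(z * Pz)
  log_p_given_s2 <- function(t) {          # t = log sigma2
    s2 <- exp(t)
    -(N / 2) * log(2 * pi * s2) - (P / 2) * log(1 + g) - S / (2 * s2)
  }
  t0 <- log(S / N)
  shift <- log_p_given_s2(t0)
  val <- integrate(function(t) exp(log_p_given_s2(t) - shift),
                   -40, 40, rel.tol = 1e-12)$value
  shift + log(val)
}

# Quadrature oracle for the posterior mean of sigma2 under the same model.
oracle_posterior_sigma2 <- function(y, model, prior) {
  X <- model$design
  n <- nrow(y); N <- n * ncol(y)
  z <- as.vector(t(y)) - prior$b0
  Xf <- do.call(rbind, replicate(n, X, simplify = FALSE))
  g <- prior$g
  Pz <- Xf %*% solve(crossprod(Xf), crossprod(Xf, z))
  S <- sum(z^2) - (g / (1 + g)) * sum(z * Pz)
  kern <- function(t, extra) exp(-(N / 2) * t - S / (2 * exp(t)) + extra * t)
  num <- integrate(kern, -40, 40, extra = 1, rel.tol = 1e-12)$value
  den <- integrate(kern, -40, 40, extra = 0, rel.tol = 1e-12)$value
  num / den
}

# n x J beta matrix for one CpG with named cell-type columns
random_cpg <- function(n, J, lo = 0.2, hi = 0.8,
                       cell_types = paste0("ct", seq_len(J))) {
  matrix(runif(n * J, lo, hi), n, J, dimnames = list(NULL, cell_types))
}

# model set over J generic cell types: null, saturated, one single-cell
generic_models <- function(J, cell_types = paste0("ct", seq_len(J))) {
  ct <- sort(cell_types)
  model_set(list(
    candidate_model("Null", list(ct), cell_types = ct),
    candidate_model("All", as.list(ct), cell_types = ct),
    candidate_model(ct[1L], list(ct[1L], ct[-1L]), cell_types = ct,
                    reference = 2L)
  ))
}

# beta tensor (K x n x J) from a K x J mean matrix plus Gaussian noise
beta_tensor <- function(means, n, sigma, sex = "F") {
  K <- nrow(means); J <- ncol(means)
  beta <- aperm(array(means, dim = c(K, J, n)), c(1L, 3L, 2L)) +
    array(rnorm(K * n * J, sd = sigma), dim = c(K, n, J))
  beta <- pmin(pmax(beta, 0), 1)
  dimnames(beta) <- list(
    if (is.null(rownames(means))) sprintf("cg%04d", seq_len(K))
    else rownames(means),
    paste0("s", seq_len(n)), colnames(means))
  meth_dataset(beta, sex = sex)
}

# brute-force Bayes FDR selection: scan every prefix r, honouring the
# all-in-or-all-out tie rule, and keep the largest passing r
brute_force_select <- function(probs, level) {
  ord <- order(probs, decreasing = TRUE)
  p <- probs[ord]
  best <- 0L
  for (r in seq_along(p)) {
    if (r < length(p) && p[r] == p[r + 1L]) next  # cut inside a tie group
    if (mean(1 - p[seq_len(r)]) <= level) best <- r
  }
  names(p)[seq_len(best)]
}
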