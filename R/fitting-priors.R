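# Group-prior machinery for hierarchical fitting: each parameter has a
# fixed distribution family (Beta for bounded rates, Gamma for
# non-negative weights, Normal for signed weights) whose hyperparameters
# are refit across iterations by weighted moment matching.

#' Group prior specification
#'
#' @param families named character vector mapping parameter names to
#'   `"beta"`, `"gamma"` or `"normal"`.
#' @param par1,par2 hyperparameters: Beta(shape1, shape2),
#'   Gamma(shape, scale), Normal(mean, sd). Defaults give naive priors:
#'   Beta(1, 1), Gamma(1, 5) and Normal(0, 10).
#' @return a `group_prior` object (data frame, one row per parameter).
#' @export
group_prior <- function(families, par1 = NULL, par2 = NULL) {
  stopifnot(all(families %in% c("beta", "gamma", "normal")),
            !is.null(names(families)))
  if (is.null(par1))
    par1 <- ifelse(families == "beta", 1, ifelse(families == "gamma", 1, 0))
  if (is.null(par2))
    par2 <- ifelse(families == "beta", 1, ifelse(families == "gamma", 5, 10))
  out <- data.frame(parameter = names(families), family = unname(families),
                    par1 = unname(par1), par2 = unname(par2),
                    stringsAsFactors = FALSE)
  class(out) <- c("group_prior", "data.frame")
  out
}

#' Draw parameter vectors from a group prior
#'
#' @param prior a [group_prior()].
#' @param n number of draws.
#' @return an `n` x P matrix with named columns.
#' @export
draw_prior <- function(prior, n) {
  draws <- vapply(seq_len(nrow(prior)), function(i) {
    switch(prior$family[i],
           beta = rbeta(n, prior$par1[i], prior$par2[i]),
           gamma = rgamma(n, shape = prior$par1[i], scale = prior$par2[i]),
           normal = rnorm(n, prior$par1[i], prior$par2[i]))
  }, numeric(n))
  if (n == 1) draws <- matrix(draws, nrow = 1)
  colnames(draws) <- prior$parameter
  draws
}

#' Prior mean per parameter
#'
#' @param prior a [group_prior()].
#' @return named numeric vector of means.
#' @export
prior_mean <- function(prior) {
  m <- vapply(seq_len(nrow(prior)), function(i) {
    switch(prior$family[i],
           beta = prior$par1[i] / (prior$par1[i] + prior$par2[i]),
           gamma = prior$par1[i] * prior$par2[i],
           normal = prior$par1[i])
  }, numeric(1))
  setNames(m, prior$parameter)
}

# refit hyperparameters from pooled weighted moments (method of moments,
# per family); variances floored and Beta variance capped below the
# Bernoulli bound for stability
refit_prior <- function(prior, means, vars) {
  for (i in seq_len(nrow(prior))) {
    p <- prior$parameter[i]
    m <- means[[p]]
    v <- max(vars[[p]], 1e-6)
    if (prior$family[i] == "beta") {
      m <- min(max(m, 1e-3), 1 - 1e-3)
      v <- min(v, 0.95 * m * (1 - m))
      nu <- m * (1 - m) / v - 1
      prior$par1[i] <- min(max(m * nu, 0.05), 500)
      prior$par2[i] <- min(max((1 - m) * nu, 0.05), 500)
    } else if (prior$family[i] == "gamma") {
      m <- max(m, 1e-4)
      prior$par1[i] <- min(max(m^2 / v, 0.05), 500)
      prior$par2[i] <- m / prior$par1[i]
    } else {
      prior$par1[i] <- m
      prior$par2[i] <- max(sqrt(v), 1e-3)
    }
  }
  prior
}
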