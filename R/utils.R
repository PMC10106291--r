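#' Numerically stable softmax
#'
#' @param x numeric vector of net values.
#' @return probabilities summing to 1.
#' @export
softmax <- function(x) {
  if (any(!is.finite(x))) stop("non-finite values passed to softmax")
  e <- exp(x - max(x))
  e / sum(e)
}

#' Log-sum-exp
#'
#' @param x numeric vector.
#' @return log(sum(exp(x))) computed without overflow.
#' @export
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Highest density interval
#'
#' Narrowest interval containing a given mass of the sample (computed on
#' the sorted draws).
#'
#' @param x numeric vector of posterior draws.
#' @param mass interval mass, default 0.95.
#' @return length-2 numeric `c(lower, upper)`.
#' @export
hdi <- function(x, mass = 0.95) {
  stopifnot(length(x) > 1, mass > 0, mass < 1)
  x <- sort(x)
  n <- length(x)
  m <- max(1L, floor(mass * n))
  widths <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(widths)
  c(x[i], x[i + m])
}

#' Posterior mode via kernel density
#'
#' @param x numeric draws.
#' @return the density-maximizing value.
#' @export
posterior_mode <- function(x) {
  d <- density(x)
  d$x[which.max(d$y)]
}

# weighted mean and variance (weights sum to 1)
weighted_moments <- function(x, w) {
  m <- sum(w * x)
  v <- sum(w * x^2) - m^2
  c(mean = m, var = max(v, 0))
}
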