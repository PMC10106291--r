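# Exploratory factor analysis utilities: ML extraction with promax
# rotation and regression-method scores, plus the adequacy statistics
# (Bartlett sphericity, KMO), parallel analysis and Tucker congruence.

#' Exploratory factor analysis with promax rotation
#'
#' Maximum-likelihood factor extraction on standardized items, obliquely
#' rotated with promax (factors may correlate), with regression-method
#' factor scores. Also reports Bartlett's test of sphericity and the
#' Kaiser-Meyer-Olkin measure of sampling adequacy. A non-positive-
#' definite item correlation matrix is smoothed (ridge toward the
#' identity) with a warning.
#'
#' @param items numeric matrix or data frame, participants x items.
#' @param n_factors number of factors to extract.
#' @param rotation `"promax"` (default) or `"varimax"`.
#' @return list with `loadings` (items x factors), `factor_cor`,
#'   `scores`, `eigenvalues` (of the item correlation matrix),
#'   `bartlett` (chisq, df, p) and `kmo`.
#' @export
fit_efa <- function(items, n_factors, rotation = c("promax", "varimax")) {
  rotation <- match.arg(rotation)
  items <- as.matrix(items)
  stopifnot(n_factors >= 1, !anyNA(items))
  R <- cor(items)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    warning("item correlation matrix is not positive definite; smoothing")
    eps <- 1e-6 - min(ev)
    R <- (R + eps * diag(ncol(R))) / (1 + eps)
    items <- items  # scores still computed from raw items below
  }
  fa <- factanal(x = scale(items), factors = n_factors,
                 rotation = "none", scores = "none")
  L <- unclass(fa$loadings)
  if (n_factors > 1) {
    rot <- if (rotation == "promax") promax(L) else stats::varimax(L)
    L <- unclass(rot$loadings)
    phi <- if (rotation == "promax") {
      ri <- solve(rot$rotmat)
      tcrossprod(ri)
    } else {
      diag(n_factors)
    }
  } else {
    phi <- matrix(1, 1, 1)
  }
  colnames(L) <- paste0("F", seq_len(n_factors))
  # regression-method scores: S = Z R^-1 (L Phi)  (structure matrix)
  structure_mat <- L %*% phi
  scores <- scale(items) %*% solve(R, structure_mat)
  colnames(scores) <- colnames(L)
  list(loadings = L, factor_cor = phi, scores = scores,
       eigenvalues = eigen(cor(items), symmetric = TRUE,
                           only.values = TRUE)$values,
       bartlett = bartlett_sphericity(items), kmo = kmo(items),
       rotation = rotation)
}

#' Bartlett's test of sphericity
#'
#' Tests whether the item correlation matrix differs from the identity.
#'
#' @param items participants x items matrix.
#' @return list with `chisq`, `df`, `p`.
#' @export
bartlett_sphericity <- function(items) {
  items <- as.matrix(items)
  n <- nrow(items)
  p <- ncol(items)
  R <- cor(items)
  chisq <- -((n - 1) - (2 * p + 5) / 6) * determinant(R)$modulus[1]
  df <- p * (p - 1) / 2
  list(chisq = as.numeric(chisq), df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' @param items participants x items matrix.
#' @return overall KMO statistic.
#' @export
kmo <- function(items) {
  R <- cor(as.matrix(items))
  Q <- -stats::cov2cor(solve(R))  # partial correlations (off-diagonal)
  diag(R) <- 0
  diag(Q) <- 0
  sum(R^2) / (sum(R^2) + sum(Q^2))
}

#' Parallel analysis for the number of factors
#'
#' Compares the observed eigenvalues of the item correlation matrix with
#' the 95th percentile of eigenvalues from column-permuted null data and
#' returns how many leading observed eigenvalues exceed the null.
#'
#' @param items participants x items matrix.
#' @param n_sims number of permuted null datasets.
#' @param seed optional integer seed.
#' @param prob null quantile, default 0.95.
#' @return suggested factor count (integer).
#' @export
parallel_analysis <- function(items, n_sims = 200, seed = NULL,
                              prob = 0.95) {
  items <- as.matrix(items)
  if (!is.null(seed)) set.seed(seed)
  obs <- eigen(cor(items), symmetric = TRUE, only.values = TRUE)$values
  null_ev <- replicate(n_sims, {
    perm <- apply(items, 2, sample)
    eigen(cor(perm), symmetric = TRUE, only.values = TRUE)$values
  })
  thresh <- apply(null_ev, 1, quantile, probs = prob)
  above <- obs > thresh
  # leading run of eigenvalues above the null
  if (!above[1]) return(0L)
  which.min(c(above, FALSE)) - 1L
}

#' Tucker congruence between two loading matrices
#'
#' Factors are greedily matched by absolute congruence; signs are
#' aligned.
#'
#' @param A,B items x factors loading matrices with equal dimensions.
#' @return numeric vector of per-factor congruence coefficients (for the
#'   matched ordering of `B`'s factors).
#' @export
factor_congruence <- function(A, B) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  stopifnot(dim(A) == dim(B))
  phi <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  k <- ncol(A)
  congr <- numeric(k)
  used <- logical(k)
  for (i in seq_len(k)) {
    cands <- vapply(seq_len(k), function(j) {
      if (used[j]) return(-Inf)
      abs(phi(A[, i], B[, j]))
    }, numeric(1))
    j <- which.max(cands)
    used[j] <- TRUE
    congr[i] <- abs(phi(A[, i], B[, j]))
  }
  congr
}
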