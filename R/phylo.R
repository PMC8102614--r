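#' Phylogenetic covariance matrix
#'
#' Species-by-species matrix of shared root-to-MRCA path lengths — the
#' trait covariance implied by Brownian evolution on the tree.
#'
#' @param tree A rooted `phylo` tree with non-negative branch lengths.
#' @param scale_to_unit_height If `TRUE`, divide by the maximum
#'   root-to-tip depth so an ultrametric tree yields a unit diagonal.
#' @return A symmetric PSD matrix in tip order, with attributes
#'   `tip_order` and `height` (the depth used for scaling).
#' @export
phylo_cov <- function(tree, scale_to_unit_height = FALSE) {
  if (!inherits(tree, "phylo")) stop_domain("tree must be a 'phylo' object")
  # star phylogenies (single root polytomy) count as rooted
  if (!ape::is.rooted(tree) && tree$Nnode > 1L) {
    stop_domain("tree must be rooted")
  }
  if (any(tree$edge.length < 0)) stop_domain("negative branch lengths")
  C <- ape::vcv.phylo(tree)
  height <- max(diag(C))
  if (scale_to_unit_height) C <- C / height
  attr(C, "tip_order") <- tree$tip.label
  attr(C, "height") <- height
  C
}

# Unit-height phylogenetic *correlation* matrix used by the GLMM random
# effect; cov2cor guards against slightly non-ultrametric trees.
unit_correlation <- function(tree) {
  C <- phylo_cov(tree, scale_to_unit_height = TRUE)
  stats::cov2cor(unclass(C))
}

#' Pagel's lambda transform
#'
#' Multiplies the off-diagonal elements of a phylogenetic covariance
#' matrix by `lam`, leaving the diagonal unchanged. `lam = 1` preserves
#' the Brownian structure; `lam = 0` yields a star phylogeny.
#'
#' @param C Phylogenetic covariance (or correlation) matrix.
#' @param lam Signal strength in `[0, 1]`.
#' @return The transformed matrix.
#' @export
lambda_transform <- function(C, lam) {
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) ||
      lam < 0 || lam > 1) {
    stop_domain("lambda must be a single value in [0, 1]")
  }
  out <- lam * C
  diag(out) <- diag(C)
  out
}

# Profile log-likelihood of lambda under y ~ MVN(mu 1, sigma2 C_lambda),
# with mu and sigma2 profiled analytically.
lambda_profile_loglik <- function(y, C, lam, X = NULL) {
  n <- length(y)
  V <- lambda_transform(C, lam)
  R <- chol_psd(V)
  if (is.null(X)) X <- matrix(1, n, 1L)
  yt <- backsolve(R, y, transpose = TRUE)
  Xt <- backsolve(R, X, transpose = TRUE)
  qx <- qr(Xt)
  rss <- sum(qr.resid(qx, yt)^2)
  sigma2 <- rss / n
  logdet <- 2 * sum(log(diag(R)))
  -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
}

#' Maximum-likelihood estimate of Pagel's lambda
#'
#' Profiles the mean and rate analytically and maximizes the remaining
#' 1-D likelihood over `[0, 1]` by bounded search (tolerance 1e-6),
#' comparing the interior optimum against both boundaries.
#'
#' @param y Trait values aligned to the tree tips (>= 4 species).
#' @param tree A rooted `phylo` tree.
#' @return List of class `lambda_fit`: `lambda`, `loglik`.
#' @export
estimate_lambda <- function(y, tree) {
  n <- length(tree$tip.label)
  if (length(y) != n) stop_domain("y must be aligned to the tree tips")
  if (n < 4L) stop_domain("need at least 4 species")
  if (sd(y) == 0) stop_domain("y is constant; lambda is undefined")
  C <- unit_correlation(tree)
  f <- function(l) lambda_profile_loglik(y, C, l)
  opt <- optimize(f, c(0, 1), maximum = TRUE, tol = 1e-6)
  cand <- c(0, opt$maximum, 1)
  ll <- c(f(0), opt$objective, f(1))
  best <- which.max(ll)
  structure(list(lambda = cand[best], loglik = ll[best]),
            class = "lambda_fit")
}

#' Phylogenetic generalized least squares
#'
#' GLS regression whose error covariance is a lambda-transform of the
#' unit-height phylogenetic correlation matrix, solved through a
#' Cholesky factorization (no explicit inverse). With `lambda = "ml"`
#' the signal is chosen by profile maximum likelihood, which is the
#' default used for phylogenetic size correction.
#'
#' @param y Response aligned to tree tips.
#' @param X Design matrix including an intercept column, rows in tip
#'   order.
#' @param tree A rooted `phylo` tree.
#' @param lambda Either `"ml"` or a fixed value in `[0, 1]`.
#' @return An object of class `pgls_fit`: coefficients, residuals (tip
#'   order), `sigma2` (ML rate), `lambda`, `loglik`, standard errors,
#'   t statistics and p-values.
#' @export
pgls_fit <- function(y, X, tree, lambda = "ml") {
  n <- length(tree$tip.label)
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1L)))[
      seq_len(ncol(X))]
  }
  if (nrow(X) != n || length(y) != n) {
    stop_domain("y and X must be aligned to the tree tips")
  }
  if (!any(apply(X, 2L, function(c) all(c == c[1L]) && c[1L] != 0))) {
    stop_domain("X must include an intercept column")
  }
  qx0 <- qr(X)
  if (qx0$rank < ncol(X)) {
    bad <- colnames(X)[qx0$pivot[(qx0$rank + 1L):ncol(X)]]
    stop_domain(paste0("design matrix is rank deficient; collinear column(s): ",
                       paste(bad, collapse = ", ")))
  }
  C <- unit_correlation(tree)
  if (identical(lambda, "ml")) {
    f <- function(l) lambda_profile_loglik(y, C, l, X = X)
    opt <- optimize(f, c(0, 1), maximum = TRUE, tol = 1e-6)
    cand <- c(0, opt$maximum, 1)
    lam <- cand[which.max(c(f(0), opt$objective, f(1)))]
  } else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1) {
      stop_domain("lambda must be 'ml' or a value in [0, 1]")
    }
    lam <- lambda
  }
  V <- lambda_transform(C, lam)
  R <- chol_psd(V)
  yt <- backsolve(R, y, transpose = TRUE)
  Xt <- backsolve(R, X, transpose = TRUE)
  qx <- qr(Xt)
  beta <- qr.coef(qx, yt)
  rss <- sum(qr.resid(qx, yt)^2)
  p <- ncol(X)
  sigma2_ml <- rss / n
  sigma2_df <- rss / (n - p)
  XtX_inv <- chol2inv(qr.R(qx)[, order(qx$pivot), drop = FALSE])
  se <- sqrt(sigma2_df * diag(XtX_inv))
  resid <- drop(y - X %*% beta)
  loglik <- -0.5 * (n * log(2 * pi * sigma2_ml) +
                      2 * sum(log(diag(R))) + n)
  structure(list(
    coefficients = setNames(drop(beta), colnames(X)),
    residuals = resid,
    fitted = drop(X %*% beta),
    sigma2 = sigma2_ml,
    lambda_used = lam,
    loglik = loglik,
    se = setNames(se, colnames(X)),
    df = n - p,
    n = n
  ), class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("Phylogenetic GLS fit (lambda =", format(x$lambda_used, digits = 3),
      ", logLik =", format(x$loglik, digits = 6), ")\n")
  print(tidy.pgls_fit(x))
  invisible(x)
}

#' Tidy a PGLS fit
#' @param x A `pgls_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @exportS3Method generics::tidy
tidy.pgls_fit <- function(x, ...) {
  stat <- x$coefficients / x$se
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         std.error = unname(x$se),
         statistic = unname(stat),
         p.value = unname(2 * stats::pt(-abs(stat), df = x$df)))
}

#' Evolutionary (phylogenetic) correlation of two traits
#'
#' Correlation of the ML bivariate Brownian rate matrix, computed as the
#' correlation of phylogenetically independent contrasts through the
#' origin.
#'
#' @param x,y Trait vectors aligned to the tree tips (>= 4 species).
#' @param tree A rooted `phylo` tree.
#' @return A correlation in `[-1, 1]`.
#' @export
phylo_correlation <- function(x, y, tree) {
  if (length(tree$tip.label) < 4L) stop_domain("need at least 4 species")
  if (sd(x) == 0 || sd(y) == 0) stop_domain("zero-variance input")
  names(x) <- names(y) <- tree$tip.label
  px <- ape::pic(x, tree)
  py <- ape::pic(y, tree)
  r <- sum(px * py) / sqrt(sum(px^2) * sum(py^2))
  max(min(r, 1), -1)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from the ordinary
#' least-squares regression of predictor `j` on the remaining predictors
#' plus an intercept. Computed non-phylogenetically on the design matrix,
#' as is standard for gauging multicollinearity before model fitting.
#' Perfectly collinear columns yield `Inf` rather than an error.
#'
#' @param X Matrix or data frame of at least two predictor columns (an
#'   all-constant intercept column, if present, is ignored), with more
#'   rows than columns.
#' @return Named vector of VIFs, one per predictor.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  keep <- apply(X, 2L, function(c) sd(c) > 0)
  X <- X[, keep, drop = FALSE]
  if (ncol(X) < 2L) stop_domain("need at least 2 non-constant predictors")
  if (nrow(X) <= ncol(X)) stop_domain("need more rows than predictors")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  vapply(seq_len(ncol(X)), function(j) {
    fit <- lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) |> setNames(colnames(X))
}
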