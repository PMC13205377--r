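#' Minor-allele-frequency filter
#'
#' Removes markers whose minor allele frequency is strictly less than the
#' threshold (a marker at exactly the threshold is retained), preserving
#' marker order. Frequencies are the observed column means / 2.
#'
#' @param geno A `geno_matrix`.
#' @param threshold MAF threshold (default 0.05).
#' @return The filtered `geno_matrix`.
#' @export
maf_filter <- function(geno, threshold = 0.05) {
  maf <- pmin(geno$allele_freq, 1 - geno$allele_freq)
  keep <- maf >= threshold
  if (!any(keep)) abort("all markers removed by the MAF filter.")
  subset_markers(geno, keep)
}

#' Centre and standardize a marker matrix
#'
#' Each column j is centred by `2 p_j` and scaled by `sqrt(2 p_j (1 - p_j))`,
#' with `p_j` the observed allele frequency unless supplied.
#'
#' @param codes n x m genotype matrix (0/1/2).
#' @param freq Optional allele frequencies; default observed column means / 2.
#' @return List: `W` (standardized matrix), `freq`.
#' @export
standardize_markers <- function(codes, freq = NULL) {
  if (is.null(freq)) freq <- colMeans(codes) / 2
  v <- 2 * freq * (1 - freq)
  if (any(v == 0))
    abort("zero-variance marker column; apply maf_filter() first.")
  W <- sweep(sweep(codes, 2, 2 * freq, "-"), 2, sqrt(v), "/")
  dimnames(W) <- dimnames(codes)
  list(W = W, freq = freq)
}

#' Genomic relationship matrix
#'
#' `G = W W' / m` from the centred, standardized marker matrix `W` over the
#' `m` markers.
#'
#' @param geno A (MAF-filtered) `geno_matrix`.
#' @return List of class `grm`: `G` (n x n), `W`, `freq`, `m`.
#' @export
build_grm <- function(geno) {
  sm <- standardize_markers(geno$codes)
  G <- tcrossprod(sm$W) / ncol(sm$W)
  structure(list(G = G, W = sm$W, freq = sm$freq, m = ncol(sm$W)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm> %d animals, %d markers, mean diag %.3f\n",
              nrow(x$G), x$m, mean(diag(x$G))))
  invisible(x)
}

# restricted log-likelihood profiled in sigma2_e for a given log variance
# ratio, in the rotated (eigen) basis; returns the pieces needed downstream
profiled_reml <- function(loglam, yt, Xt, d, n, p) {
  lam <- exp(loglam)
  lam_d <- lam * d + 1
  XtL <- Xt / lam_d
  XX <- crossprod(Xt, XtL)
  b <- solve(XX, crossprod(XtL, yt))
  r <- yt - Xt %*% b
  rss <- sum(r^2 / lam_d)
  s2e <- rss / (n - p)
  ll <- -0.5 * ((n - p) * log(2 * pi * s2e) + sum(log(lam_d)) +
                  as.numeric(determinant(XX, logarithm = TRUE)$modulus) +
                  (n - p))
  list(ll = ll, lam = lam, s2e = s2e, beta = drop(b))
}

# derivative of the profiled restricted log-likelihood with respect to the
# log variance ratio (envelope theorem: the implicit dependence through the
# GLS fixed effects drops out at first order)
profiled_reml_grad <- function(loglam, yt, Xt, d, n, p) {
  lam <- exp(loglam)
  lam_d <- lam * d + 1
  XtL <- Xt / lam_d
  XX <- crossprod(Xt, XtL)
  b <- solve(XX, crossprod(XtL, yt))
  r <- drop(yt - Xt %*% b)
  rL <- r / lam_d
  rss <- sum(r * rL)
  # d/dlam of: (n - p) log(rss) + sum log(lam_d) + log det(X' L^-1 X)
  d_rss <- -sum(rL^2 * d)
  d_logdet_L <- sum(d / lam_d)
  XtLD <- Xt * (d / lam_d^2)
  d_logdet_X <- -sum(diag(solve(XX, crossprod(Xt, XtLD))))
  dF <- 0.5 * ((n - p) * d_rss / rss + d_logdet_L + d_logdet_X)
  -dF * lam   # gradient of the log-likelihood in loglam
}

# restricted log-likelihood at arbitrary (sigma2_u, sigma2_e); used for the
# observed-information standard error
reml_ll_at <- function(s2u, s2e, yt, Xt, d, n, p) {
  v <- s2u * d + s2e
  XtL <- Xt / v
  XX <- crossprod(Xt, XtL)
  b <- solve(XX, crossprod(XtL, yt))
  r <- yt - Xt %*% b
  -0.5 * ((n - p) * log(2 * pi) + sum(log(v)) +
            as.numeric(determinant(XX, logarithm = TRUE)$modulus) +
            sum(r^2 / v))
}

#' REML variance components under the GBLUP model
#'
#' Fits `y = X b + u + e` with `u ~ N(0, G sigma2_u)` and
#' `e ~ N(0, I sigma2_e)` by restricted maximum likelihood: one spectral
#' decomposition of `G`, then Brent search of the profiled criterion over the
#' log variance ratio in `[-10, 10]`. Genomic heritability is
#' `h2 = sigma2_u / (sigma2_u + sigma2_e)`; its standard error comes from the
#' observed information of the variance components by the delta method.
#'
#' @param y Numeric phenotype vector (one record per animal).
#' @param X Fixed-effect design matrix including the intercept; default
#'   intercept only.
#' @param G Genomic relationship matrix (from [build_grm()]), or `NULL` if
#'   `eigen_G` is given.
#' @param eigen_G Optional pre-computed `eigen(G, symmetric = TRUE)`; pass it
#'   when fitting several traits on one cohort.
#' @return Object of class `reml_fit`: `sigma2_u`, `sigma2_e`, `h2`, `se_h2`,
#'   `loglik`, `beta`, `boundary` flag, `n`, `p`.
#' @export
reml_fit <- function(y, X = NULL, G = NULL, eigen_G = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) abort("X is not full column rank.")
  if (is.null(eigen_G)) {
    stopifnot(nrow(G) == n)
    if (max(abs(G - t(G))) > 1e-8) abort("G must be symmetric.")
    eigen_G <- eigen(G, symmetric = TRUE)
    if (min(eigen_G$values) < -1e-6 * max(eigen_G$values))
      abort("G is not positive semidefinite within tolerance.")
  }
  d <- pmax(eigen_G$values, 0)
  U <- eigen_G$vectors
  # fit on the standardized phenotype so the optimizer path (and hence h2)
  # is exactly invariant to rescaling y; components are scaled back after
  sc <- sd(y)
  if (sc == 0) abort("phenotype is constant.")
  yt <- crossprod(U, y / sc)
  Xt <- crossprod(U, X)
  p <- ncol(X)
  obj <- function(ll) -profiled_reml(ll, yt, Xt, d, n, p)$ll
  opt <- optimize(obj, c(-10, 10), tol = 1e-10)
  lam_hat <- opt$minimum
  # golden-section search is sqrt(eps)-limited; polish the optimum with the
  # analytic gradient of the profiled criterion when it brackets a root
  gr <- function(ll) profiled_reml_grad(ll, yt, Xt, d, n, p)
  lo <- max(-10, lam_hat - 0.5)
  hi <- min(10, lam_hat + 0.5)
  g_lo <- gr(lo)
  g_hi <- gr(hi)
  if (is.finite(g_lo) && is.finite(g_hi) && g_lo > 0 && g_hi < 0) {
    lam_hat <- stats::uniroot(gr, c(lo, hi), tol = 1e-14)$root
  }
  at <- profiled_reml(lam_hat, yt, Xt, d, n, p)
  boundary <- lam_hat < -10 + 1e-3 || lam_hat > 10 - 1e-3
  s2e <- at$s2e * sc^2
  s2u <- at$lam * s2e
  h2 <- at$lam / (at$lam + 1)
  se_h2 <- h2_se_delta(at$lam * at$s2e, at$s2e, yt, Xt, d, n, p)
  structure(list(sigma2_u = s2u, sigma2_e = s2e, h2 = h2, se_h2 = se_h2,
                 loglik = at$ll - (n - p) * log(sc),
                 beta = setNames(at$beta * sc, colnames(X)),
                 boundary = boundary, n = n, p = p,
                 eigen_G = eigen_G),
            class = "reml_fit")
}

# delta-method SE of h2 from a central-difference observed information of the
# restricted log-likelihood in (sigma2_u, sigma2_e); evaluated a step inside
# the boundary when sigma2_u has collapsed to it
h2_se_delta <- function(s2u, s2e, yt, Xt, d, n, p) {
  s2u0 <- max(s2u, 1e-4 * s2e)
  f <- function(th) reml_ll_at(th[1], th[2], yt, Xt, d, n, p)
  h <- 1e-3 * c(s2u0 + s2e, s2u0 + s2e)
  H <- matrix(NA_real_, 2, 2)
  th0 <- c(s2u0, s2e)
  for (i in 1:2) for (j in 1:2) {
    ei <- ej <- c(0, 0)
    ei[i] <- h[i]
    ej[j] <- h[j]
    H[i, j] <- (f(th0 + ei + ej) - f(th0 + ei - ej) -
                  f(th0 - ei + ej) + f(th0 - ei - ej)) / (4 * h[i] * h[j])
  }
  info <- -H
  cv <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(cv)) return(NA_real_)
  s <- s2u0 + s2e
  g <- c(s2e, -s2u0) / s^2
  v <- drop(t(g) %*% cv %*% g)
  if (!is.finite(v) || v < 0) return(NA_real_)
  sqrt(v)
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf(
    "<reml_fit> h2 = %.3f (SE %.3f), sigma2_u = %.3f, sigma2_e = %.3f%s\n",
    x$h2, x$se_h2, x$sigma2_u, x$sigma2_e,
    if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' @export
tidy.reml_fit <- function(x, ...) {
  tibble(component = c("sigma2_u", "sigma2_e"),
         estimate = c(x$sigma2_u, x$sigma2_e))
}

#' @export
glance.reml_fit <- function(x, ...) {
  tibble(h2 = x$h2, se_h2 = x$se_h2, sigma2_u = x$sigma2_u,
         sigma2_e = x$sigma2_e, loglik = x$loglik, boundary = x$boundary,
         n = x$n)
}

#' Build a fixed-effect design matrix from covariates
#'
#' @param data Data frame of one time point (one row per animal).
#' @param covariates Character vector of covariate column names; factors and
#'   characters enter as dummies, numerics as slopes. Always includes an
#'   intercept.
#' @return Numeric design matrix.
#' @export
design_matrix <- function(data, covariates = c("sex", "birth_farm",
                                               "pen_density", "age",
                                               "parity")) {
  covariates <- intersect(covariates, names(data))
  if (!length(covariates)) return(matrix(1, nrow(data), 1,
                                         dimnames = list(NULL, "(Intercept)")))
  df <- dplyr::mutate(data[covariates],
                      dplyr::across(dplyr::where(is.character), factor))
  X <- model.matrix(stats::reformulate(covariates), df)
  # drop aliased columns so X is full rank
  qx <- qr(X)
  X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
}

#' Genomic heritability of a trait at one time point
#'
#' Tidy wrapper around [reml_fit()]: builds the fixed-effect design from the
#' covariate columns and fits the GBLUP REML model.
#'
#' @param data One-time-point phenotype tibble (one row per animal, same order
#'   as the GRM).
#' @param grm A `grm` from [build_grm()] (or a plain G matrix).
#' @param trait Name of the phenotype column.
#' @param covariates Covariate columns for the fixed effects.
#' @param eigen_G Optional cached eigendecomposition.
#' @return A `reml_fit`.
#' @export
fit_h2 <- function(data, grm, trait = "scale_bw",
                   covariates = c("sex", "birth_farm", "pen_density", "age",
                                  "parity"),
                   eigen_G = NULL) {
  G <- if (inherits(grm, "grm")) grm$G else grm
  reml_fit(data[[trait]], design_matrix(data, covariates), G,
           eigen_G = eigen_G)
}
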