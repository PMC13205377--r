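#' Single-marker mixed-model GWAS with fixed null variance components
#'
#' Per-marker test of `y = X b + w_j s_j + u + e` with `u ~ N(0, G sigma2_u)`.
#' The variance components are estimated once under the null model (no
#' marker) and held fixed across markers (the P3D/EMMAX approximation): the
#' data are rotated to the eigenbasis of `G`, whitened by the fixed null
#' covariance, and each marker effect is then a generalized least squares
#' estimate with a t-test on `n - p - 1` residual degrees of freedom.
#' Markers collinear with the fixed effects get effect 0 and p = 1, flagged.
#'
#' @param y Phenotype vector (one record per animal).
#' @param X Fixed-effect design matrix with intercept; default intercept only.
#' @param geno `geno_matrix` of MAF-filtered markers (same animals, same
#'   order).
#' @param grm A `grm` (or plain G matrix) built from `geno`; `NULL` uses
#'   `eigen_G`.
#' @param null_fit Optional `reml_fit` of the null model to reuse.
#' @param eigen_G Optional cached eigendecomposition of G.
#' @return Object of class `gwas_result`: tibble with `marker_id`, `effect`,
#'   `se`, `p`, `neglog10p`, `rank` (1 = strongest) and `flag`; the null
#'   variance components are in `attr(, "vc")`. Ranking is by `-log10 p`
#'   descending with ties broken by marker index.
#' @export
gwas_scan <- function(y, X = NULL, geno, grm = NULL, null_fit = NULL,
                      eigen_G = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  stopifnot(nrow(geno$codes) == n)
  if (is.null(null_fit)) {
    G <- if (inherits(grm, "grm")) grm$G else grm
    null_fit <- reml_fit(y, X, G, eigen_G = eigen_G)
  }
  eg <- null_fit$eigen_G
  v <- null_fit$sigma2_u * pmax(eg$values, 0) + null_fit$sigma2_e
  wgt <- 1 / sqrt(v)
  ys <- crossprod(eg$vectors, y) * wgt
  Xs <- crossprod(eg$vectors, X) * wgt
  # center marker codes, rotate, whiten
  Wc <- sweep(geno$codes, 2, 2 * geno$allele_freq, "-")
  Ws <- crossprod(eg$vectors, Wc) * wgt
  # residualize against fixed effects
  qx <- qr(Xs)
  My <- qr.resid(qx, ys)
  MW <- Ws - qr.fitted(qx, Ws)
  wMw <- unname(colSums(MW^2))
  wMy <- unname(drop(crossprod(MW, My)))
  yMy <- sum(My^2)
  p_fix <- ncol(X)
  df <- n - p_fix - 1
  ok <- wMw > 1e-10 * max(wMw)
  effect <- ifelse(ok, wMy / wMw, 0)
  rss <- pmax(yMy - effect * wMy, 0)
  se <- ifelse(ok, sqrt(rss / df / wMw), NA_real_)
  tval <- ifelse(ok, effect / se, 0)
  pval <- ifelse(ok, 2 * pt(abs(tval), df, lower.tail = FALSE), 1)
  pval <- pmin(pmax(pval, .Machine$double.xmin), 1)
  nlp <- -log10(pval)
  ord <- order(-nlp, seq_along(nlp))
  rank <- integer(length(nlp))
  rank[ord] <- seq_along(ord)
  res <- tibble(marker_id = colnames(geno$codes),
                effect = effect, se = se, p = pval, neglog10p = nlp,
                rank = rank, flag = !ok)
  attr(res, "vc") <- c(sigma2_u = null_fit$sigma2_u,
                       sigma2_e = null_fit$sigma2_e)
  attr(res, "null_fit") <- null_fit
  class(res) <- c("gwas_result", class(res))
  res
}

#' @export
tidy.gwas_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "gwas_result")
  attr(out, "vc") <- NULL
  attr(out, "null_fit") <- NULL
  out
}

#' Top markers of a GWAS ranking
#'
#' @param result A `gwas_result`.
#' @param k Number of top markers.
#' @return Character vector of the `k` top-ranked marker ids.
#' @export
top_markers <- function(result, k = 10) {
  result$marker_id[order(result$rank)][seq_len(k)]
}

#' Manhattan-style plot of a GWAS scan
#'
#' @param object A `gwas_result`.
#' @param highlight Optional marker ids drawn in a distinct colour.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gwas_result <- function(object, highlight = NULL, ...) {
  df <- dplyr::mutate(tidy(object), index = dplyr::row_number(),
                      hl = .data$marker_id %in% highlight)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$neglog10p)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$hl), size = 0.6,
                        show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "marker index", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}
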