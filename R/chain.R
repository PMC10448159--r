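#' Ordinary least squares by QR decomposition
#'
#' Fits `response = design %*% B + error`, supporting matrix-valued responses
#' (multivariate regression). The solve goes through an orthogonal (QR)
#' decomposition; the inverse Gram matrix `(X'X)^-1`, needed by the variance
#' formulas, is recovered from the R factor. Rank deficiency is an error,
#' never a silent pseudo-inverse: the variance algebra downstream assumes a
#' full-rank design.
#'
#' @param design n x p design matrix (with unit column if an intercept is
#'   wanted).
#' @param response length-n vector or n x m matrix.
#' @param label dataset name used in error messages.
#' @return A list with `coef` (p x m), `resid_cov` (m x m residual covariance,
#'   divisor `n - p`), `gram_inv` (p x p), `df` (`n - p`) and `residuals`.
#' @export
fit_ols <- function(design, response, label = "design") {
  design <- as.matrix(design)
  response <- as.matrix(response)
  n <- nrow(design); p <- ncol(design)
  if (nrow(response) != n) {
    stop("response rows (", nrow(response), ") do not match design rows (",
         n, ") for ", label, call. = FALSE)
  }
  if (n <= p) stop("need more observations than parameters in ", label, call. = FALSE)
  qx <- qr(design)
  if (qx$rank < p) {
    stop("singular (rank-deficient) design matrix in ", label,
         ": rank ", qx$rank, " < ", p, call. = FALSE)
  }
  coef <- qr.coef(qx, response)
  resid <- response - design %*% coef
  resid_cov <- crossprod(resid) / (n - p)
  R <- qr.R(qx)
  gram_inv <- chol2inv(R)
  piv <- qx$pivot
  gram_inv[piv, piv] <- gram_inv
  gram_inv <- (gram_inv + t(gram_inv)) / 2
  dimnames(coef) <- list(colnames(design), colnames(response))
  list(coef = coef, resid_cov = resid_cov, gram_inv = gram_inv,
       df = n - p, residuals = resid)
}

#' Fit the three-step regression chain
#'
#' Fits, in order: the field model F on `(X_I, y_I)`; the multivariate model
#' G* regressing the simulated field-covariate vectors `X_II` on `Z_II`; the
#' model Q* regressing `Z_III` on `P_III`. The contracted coefficient vectors
#' are composed algebraically: `alpha_hat = A_star_hat %*% beta_hat` and
#' `gamma_hat = Gamma_star_hat %*% alpha_hat`. As a numerical cross-check the
#' sequential route -- regressing the predictions `y_hat_F = X_II beta_hat` on
#' `Z_II`, and `y_hat_G = Z_III alpha_hat` on `P_III` -- is also computed and
#' verified to agree with the composed route to 1e-10 relative tolerance
#' (the two are algebraically identical).
#'
#' @param data a `hier_data` object (responses).
#' @param designs the matching `fixed_designs` object.
#' @return An object of class `fitted_chain` with coefficient estimates,
#'   residual (co)variance estimates (`omega2_hat`, `Delta_star_hat`,
#'   `Theta_star_hat`, divisor n - p) and the three inverse Gram matrices.
#' @export
fit_chain <- function(data, designs) {
  stopifnot(inherits(data, "hier_data"), inherits(designs, "fixed_designs"))
  fit_F <- fit_ols(designs$X_I, data$y_I, "S_I (model F)")
  beta_hat <- drop(fit_F$coef)
  omega2_hat <- drop(fit_F$resid_cov)

  fit_Gs <- fit_ols(designs$Z_II, data$X_II, "S_II (model G*)")
  A_star_hat <- fit_Gs$coef
  alpha_hat <- drop(A_star_hat %*% beta_hat)

  y_hat_F <- drop(data$X_II %*% beta_hat)
  alpha_seq <- drop(fit_ols(designs$Z_II, y_hat_F, "S_II (model G)")$coef)
  check_compose(alpha_seq, alpha_hat, "alpha")

  fit_Qs <- fit_ols(designs$P_III, data$Z_III, "S_III (model Q*)")
  Gamma_star_hat <- fit_Qs$coef
  gamma_hat <- drop(Gamma_star_hat %*% alpha_hat)

  y_hat_G <- drop(data$Z_III %*% alpha_hat)
  gamma_seq <- drop(fit_ols(designs$P_III, y_hat_G, "S_III (model Q)")$coef)
  check_compose(gamma_seq, gamma_hat, "gamma")

  structure(list(
    beta_hat = beta_hat, omega2_hat = omega2_hat,
    A_star_hat = A_star_hat, Delta_star_hat = fit_Gs$resid_cov,
    alpha_hat = alpha_hat,
    Gamma_star_hat = Gamma_star_hat, Theta_star_hat = fit_Qs$resid_cov,
    gamma_hat = gamma_hat,
    xtx_inv_I = fit_F$gram_inv,
    ztz_inv_II = fit_Gs$gram_inv,
    ptp_inv_III = fit_Qs$gram_inv),
    class = "fitted_chain")
}

check_compose <- function(seq_est, composed, what) {
  rel <- max(abs(seq_est - composed)) / max(1, max(abs(composed)))
  if (!is.finite(rel) || rel > 1e-8) {
    stop("composition identity for ", what,
         " violated (relative discrepancy ", format(rel), ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.fitted_chain <- function(x, ...) {
  cat("Fitted three-step chain\n")
  cat(sprintf("  beta_hat  = (%.5g, %.5g)  omega2_hat = %.5g\n",
              x$beta_hat[1], x$beta_hat[2], x$omega2_hat))
  cat(sprintf("  alpha_hat = (%s)\n", paste(signif(x$alpha_hat, 6), collapse = ", ")))
  cat(sprintf("  gamma_hat = (%s)\n", paste(signif(x$gamma_hat, 6), collapse = ", ")))
  invisible(x)
}

#' Population-mean prediction, wall-to-wall (model-based)
#'
#' The three-phase hierarchical model-based predictor of the population mean:
#' the population mean vector of final-phase covariates (leading 1 for the
#' intercept) contracted with the composed coefficient vector,
#' `p_bar_U %*% gamma_hat`.
#'
#' @param chain a [fit_chain()] result.
#' @param p_bar_U numeric vector of population covariate means, first
#'   element 1.
#' @return The predicted population mean (scalar).
#' @export
predict_3phmb <- function(chain, p_bar_U) {
  stopifnot(inherits(chain, "fitted_chain"))
  p_bar_U <- as.numeric(p_bar_U)
  if (length(p_bar_U) != length(chain$gamma_hat)) {
    stop("p_bar_U length does not match gamma_hat", call. = FALSE)
  }
  if (p_bar_U[1] != 1) stop("first element of p_bar_U must be 1", call. = FALSE)
  sum(p_bar_U * chain$gamma_hat)
}

#' Simple random sample without replacement
#'
#' Draws a uniform random subset of `n_IV` distinct indices from `1:N`; every
#' element's inclusion probability is `n_IV / N`.
#'
#' @param N population size.
#' @param n_IV sample size, `n_IV <= N`.
#' @param seed optional integer seed (if `NULL` the current RNG state is used).
#' @return An object of class `design_sample` with `indices`,
#'   `inclusion_prob` and `seed`.
#' @export
draw_srswor <- function(N, n_IV, seed = NULL) {
  N <- as.integer(N); n_IV <- as.integer(n_IV)
  if (n_IV < 1L) stop("n_IV must be at least 1", call. = FALSE)
  if (n_IV > N) stop("n_IV (", n_IV, ") exceeds N (", N, ")", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  structure(list(indices = sample.int(N, n_IV),
                 inclusion_prob = n_IV / N,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "design_sample")
}

#' Population-mean prediction from a probability sample (hybrid)
#'
#' The three-phase hierarchical hybrid predictor: the Horvitz-Thompson
#' estimator of the population mean covariate vector,
#' `(1/N) * sum_{k in S_IV} p_k / pi_k`, contracted with `gamma_hat`. Under
#' simple random sampling without replacement (`pi = n_IV / N`) this is the
#' sample mean of the sampled covariate vectors times `gamma_hat`; with a
#' census sample it coincides exactly with [predict_3phmb()].
#'
#' @param chain a [fit_chain()] result.
#' @param P_U N x (t+1) population matrix of final-phase covariates.
#' @param sample a [draw_srswor()] result (indices into the rows of `P_U`).
#' @return The predicted population mean (scalar).
#' @export
predict_3phhy <- function(chain, P_U, sample) {
  stopifnot(inherits(chain, "fitted_chain"), inherits(sample, "design_sample"))
  P_U <- as.matrix(P_U)
  if (length(sample$indices) == 0L) stop("empty sample", call. = FALSE)
  if (max(sample$indices) > nrow(P_U)) {
    stop("sample indices exceed the population size", call. = FALSE)
  }
  if (ncol(P_U) != length(chain$gamma_hat)) {
    stop("P_U columns do not match gamma_hat", call. = FALSE)
  }
  p_bar_ht <- ht_mean(P_U, sample)
  sum(p_bar_ht * chain$gamma_hat)
}

# Horvitz-Thompson estimate of the population mean covariate vector
ht_mean <- function(P_U, sample) {
  colSums(P_U[sample$indices, , drop = FALSE] / sample$inclusion_prob) / nrow(P_U)
}
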