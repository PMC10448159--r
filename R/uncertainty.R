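#' OLS coefficient covariance block
#'
#' For a univariate fit with error variance `s2`, the coefficient covariance
#' is `s2 * gram_inv`. For a multivariate fit with coefficient matrix `M_hat`
#' and error covariance `E`, the quadratic-form contraction `Cov(M_hat v)`
#' collapses through the Kronecker structure to `(v' E v) * gram_inv`; pass
#' the contraction vector as `contract`.
#'
#' @param gram_inv p x p inverse Gram matrix of the fit (symmetric PSD).
#' @param error_cov scalar error variance, or m x m error covariance when
#'   `contract` is supplied.
#' @param contract optional length-m contraction vector.
#' @return A p x p covariance matrix.
#' @export
cov_coeff_blocks <- function(gram_inv, error_cov, contract = NULL) {
  gram_inv <- as.matrix(gram_inv)
  check_psd(gram_inv, "gram_inv")
  if (is.null(contract)) {
    if (length(error_cov) != 1L) {
      stop("matrix error_cov requires a contraction vector", call. = FALSE)
    }
    s2 <- as.numeric(error_cov)
  } else {
    E <- as.matrix(error_cov)
    check_psd(E, "error_cov")
    contract <- as.numeric(contract)
    if (length(contract) != nrow(E)) {
      stop("contraction vector does not match error covariance", call. = FALSE)
    }
    s2 <- drop(t(contract) %*% E %*% contract)
  }
  if (s2 < 0) stop("negative error variance", call. = FALSE)
  s2 * gram_inv
}

check_psd <- function(M, label) {
  if (max(abs(M - t(M))) > 1e-8 * max(1, max(abs(M)))) {
    stop(label, " must be symmetric", call. = FALSE)
  }
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(1, max(abs(ev)))) {
    stop(label, " must be positive semidefinite", call. = FALSE)
  }
  invisible(TRUE)
}

# Pull the parameter blocks needed by the covariance algebra from either the
# true chain parameters or a fitted chain (plug-in route).
par_blocks <- function(x) {
  if (inherits(x, "chain_params")) {
    list(beta = x$beta, omega2 = x$omega2,
         A_star = x$A_star, Delta_star = x$Delta_star, alpha = x$alpha,
         Gamma_star = x$Gamma_star, Theta_star = x$Theta_star)
  } else if (inherits(x, "fitted_chain")) {
    list(beta = x$beta_hat, omega2 = x$omega2_hat,
         A_star = x$A_star_hat, Delta_star = x$Delta_star_hat,
         alpha = x$alpha_hat,
         Gamma_star = x$Gamma_star_hat, Theta_star = x$Theta_star_hat)
  } else {
    stop("expected a chain_params or fitted_chain object", call. = FALSE)
  }
}

grams_of <- function(x) {
  if (inherits(x, "fixed_designs")) {
    list(G_I = solve(crossprod(x$X_I)),
         G_II = solve(crossprod(x$Z_II)),
         G_III = solve(crossprod(x$P_III)))
  } else if (inherits(x, "fitted_chain")) {
    list(G_I = x$xtx_inv_I, G_II = x$ztz_inv_II, G_III = x$ptp_inv_III)
  } else if (is.list(x) && all(c("G_I", "G_II", "G_III") %in% names(x))) {
    x
  } else {
    stop("cannot extract Gram inverses from this object", call. = FALSE)
  }
}

#' Covariance of the composed coefficient estimator
#'
#' Applies the law of total covariance twice to decompose
#' `Cov(gamma_hat) = Cov(Gamma_star_hat %*% alpha_hat)` into contributions
#' from the three fits plus two trace terms:
#' \itemize{
#'   \item final-fit term `theta2 * G_III` (with
#'     `theta2 = alpha' Theta_star alpha`),
#'   \item propagated middle-fit term
#'     `Gamma_star (delta2 * G_II) Gamma_star'`,
#'   \item propagated first-fit term
#'     `Gamma_star A_star (omega2 * G_I) A_star' Gamma_star'`,
#'   \item trace terms `Tr[Delta_star omega2 G_I] * Gamma_star G_II
#'     Gamma_star'` and `Tr[Theta_star Cov_G(alpha_hat)] * G_III`.
#' }
#' Pass true parameters (`chain_params`) for the analytic variance or a
#' `fitted_chain` for the plug-in estimator; either way the Gram inverses of
#' the three fixed designs are required.
#'
#' @param params a `chain_params` or `fitted_chain` object.
#' @param grams a `fixed_designs`, `fitted_chain`, or list with `G_I`,
#'   `G_II`, `G_III` inverse Gram matrices.
#' @return An object of class `gamma_cov` holding the term matrices
#'   (`term_Q`, `term_G`, `term_F`, `term_traces`), their sum `cov_full`, the
#'   trace-free `cov_notrace`, and the scalars `omega2`, `delta2`, `theta2`.
#' @export
cov_gamma_hat <- function(params, grams) {
  pb <- par_blocks(params)
  gr <- grams_of(grams)
  cov_F <- pb$omega2 * gr$G_I
  delta2 <- drop(t(pb$beta) %*% pb$Delta_star %*% pb$beta)
  theta2 <- drop(t(pb$alpha) %*% pb$Theta_star %*% pb$alpha)

  trace_G <- sum(diag(pb$Delta_star %*% cov_F))
  AcovFA <- pb$A_star %*% cov_F %*% t(pb$A_star)
  cov_G_alpha <- (delta2 + trace_G) * gr$G_II + AcovFA
  cov_G_alpha_nt <- delta2 * gr$G_II + AcovFA

  trace_Q <- sum(diag(pb$Theta_star %*% cov_G_alpha))

  term_Q <- theta2 * gr$G_III
  term_G <- pb$Gamma_star %*% (delta2 * gr$G_II) %*% t(pb$Gamma_star)
  term_F <- pb$Gamma_star %*% AcovFA %*% t(pb$Gamma_star)
  term_traces <- trace_G * (pb$Gamma_star %*% gr$G_II %*% t(pb$Gamma_star)) +
    trace_Q * gr$G_III

  structure(list(
    term_Q = term_Q, term_G = term_G, term_F = term_F,
    term_traces = term_traces,
    cov_full = term_Q + term_G + term_F + term_traces,
    cov_notrace = term_Q + term_G + term_F,
    cov_G_alpha = cov_G_alpha, cov_G_alpha_notrace = cov_G_alpha_nt,
    cov_F_beta = cov_F,
    gamma = drop(pb$Gamma_star %*% pb$alpha),
    omega2 = pb$omega2, delta2 = delta2, theta2 = theta2),
    class = "gamma_cov")
}

quad <- function(v, M) drop(t(v) %*% M %*% v)

new_variance_report <- function(mode, terms, includes_traces) {
  total <- sum(unlist(terms))
  structure(c(list(total = total, mode = mode,
                   includes_traces = includes_traces), terms),
            class = "variance_report")
}

#' @export
print.variance_report <- function(x, ...) {
  cat(sprintf("Variance report [%s]%s\n", x$mode,
              if (x$includes_traces) "" else " (trace terms excluded)"))
  cat(sprintf("  total        : %.6g\n", x$total))
  for (nm in setdiff(names(x),
                     c("total", "mode", "includes_traces", "trace_terms_value"))) {
    cat(sprintf("  %-13s: %.6g\n", nm, x[[nm]]))
  }
  invisible(x)
}

#' Variance of the wall-to-wall (model-based) predictor
#'
#' Contracts `Cov(gamma_hat)` with the population covariate mean vector:
#' `total = p_bar_U %*% Cov(gamma_hat) %*% p_bar_U'`. With
#' `include_traces = FALSE` the trace terms of the decomposition are dropped
#' (the three-term approximation); they are always reported separately so the
#' approximation error is visible.
#'
#' @param cov_gamma a [cov_gamma_hat()] result.
#' @param p_bar_U population covariate mean vector (first element 1).
#' @param include_traces include the trace terms in the total (default TRUE).
#' @return A `variance_report` with fields `total`, `term_Q`, `term_G`,
#'   `term_F`, `trace_terms`.
#' @export
variance_3phmb <- function(cov_gamma, p_bar_U, include_traces = TRUE) {
  stopifnot(inherits(cov_gamma, "gamma_cov"))
  p_bar_U <- as.numeric(p_bar_U)
  terms <- list(
    term_Q = quad(p_bar_U, cov_gamma$term_Q),
    term_G = quad(p_bar_U, cov_gamma$term_G),
    term_F = quad(p_bar_U, cov_gamma$term_F),
    trace_terms = if (include_traces) quad(p_bar_U, cov_gamma$term_traces) else 0)
  rep <- new_variance_report("3phmb", terms, include_traces)
  rep$trace_terms_value <- quad(p_bar_U, cov_gamma$term_traces)
  rep
}

#' Variance of the hybrid predictor
#'
#' Adds to the model component `p_bar %*% Cov(gamma_hat) %*% p_bar'` the
#' design component of estimating the population covariate mean from a
#' probability sample. Under simple random sampling without replacement the
#' design component is `(1/n_IV) (1 - n_IV/N) * gamma' Cov(P_U) gamma`, with
#' `Cov(P_U)` the finite-population covariance of the covariate columns
#' (divisor N - 1 on the analytic route; a sample covariance with divisor
#' `n_IV - 1` on the estimation route). The design-model interaction trace
#' `Tr[Cov_design Cov(gamma_hat)]` is reported separately and included in the
#' total when `include_traces = TRUE`.
#'
#' @param cov_gamma a [cov_gamma_hat()] result.
#' @param gamma coefficient vector contracted with the design covariance
#'   (true `gamma` on the analytic route, `gamma_hat` on the plug-in route).
#' @param P_U population covariate matrix, or `NULL` if `cov_PU` is given.
#' @param n_IV sample size of the probability sample.
#' @param p_bar_U covariate mean vector used in the model component.
#' @param include_traces include all trace terms in the total (default TRUE).
#' @param cov_PU optional precomputed covariance of the covariate vectors
#'   (used by the plug-in estimator, where only a sample of P is available).
#' @param N population size (required when `cov_PU` is given).
#' @return A `variance_report` with fields `total`, `design_term`, `term_Q`,
#'   `term_G`, `term_F`, `trace_terms` (model traces + design-model trace).
#' @export
variance_3phhy <- function(cov_gamma, gamma, P_U, n_IV, p_bar_U,
                           include_traces = TRUE, cov_PU = NULL, N = NULL) {
  stopifnot(inherits(cov_gamma, "gamma_cov"))
  gamma <- as.numeric(gamma)
  if (is.null(cov_PU)) {
    P_U <- as.matrix(P_U)
    if (nrow(P_U) < 2L) stop("population must have at least 2 elements", call. = FALSE)
    N <- nrow(P_U)
    cov_PU <- stats::cov(P_U)
  } else {
    if (is.null(N)) stop("N is required when cov_PU is supplied", call. = FALSE)
  }
  n_IV <- as.integer(n_IV)
  if (n_IV > N) stop("n_IV (", n_IV, ") exceeds N (", N, ")", call. = FALSE)
  fpc <- (1 / n_IV) * (1 - n_IV / N)
  cov_design <- fpc * cov_PU
  cov_model <- if (include_traces) cov_gamma$cov_full else cov_gamma$cov_notrace
  trace_design <- sum(diag(cov_design %*% cov_model))
  p_bar_U <- as.numeric(p_bar_U)
  terms <- list(
    design_term = quad(gamma, cov_design),
    term_Q = quad(p_bar_U, cov_gamma$term_Q),
    term_G = quad(p_bar_U, cov_gamma$term_G),
    term_F = quad(p_bar_U, cov_gamma$term_F),
    trace_terms = if (include_traces) {
      quad(p_bar_U, cov_gamma$term_traces) + trace_design
    } else 0)
  rep <- new_variance_report("3phhy", terms, include_traces)
  rep$trace_terms_value <- quad(p_bar_U, cov_gamma$term_traces) + trace_design
  rep$trace_design <- trace_design
  rep
}

#' Plug-in variance estimator
#'
#' Evaluates the analytic variance formulas with every unknown replaced by
#' its estimate from the fitted chain: residual (co)variances for the error
#' (co)variances, estimated coefficients for the true ones, and -- for the
#' hybrid mode -- the sample covariance of the sampled covariate vectors
#' (divisor `n_IV - 1`, same finite-population correction) for the population
#' covariance, with the Horvitz-Thompson mean standing in for the unknown
#' population covariate mean in the model component.
#'
#' @param chain a [fit_chain()] result.
#' @param mode `"3phmb"` or `"3phhy"`.
#' @param p_bar_U population covariate mean vector (3phmb mode).
#' @param P_U population covariate matrix (3phhy mode; only the sampled rows
#'   are used).
#' @param sample a [draw_srswor()] result (3phhy mode).
#' @param include_traces include trace terms in the total (default TRUE).
#' @return A `variance_report`.
#' @export
estimate_variance <- function(chain, mode = c("3phmb", "3phhy"),
                              p_bar_U = NULL, P_U = NULL, sample = NULL,
                              include_traces = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(chain, "fitted_chain"))
  cg <- cov_gamma_hat(chain, chain)
  if (mode == "3phmb") {
    if (is.null(p_bar_U)) stop("p_bar_U is required for 3phmb", call. = FALSE)
    variance_3phmb(cg, p_bar_U, include_traces)
  } else {
    if (is.null(P_U) || is.null(sample)) {
      stop("P_U and sample are required for 3phhy", call. = FALSE)
    }
    P_U <- as.matrix(P_U)
    P_s <- P_U[sample$indices, , drop = FALSE]
    p_bar_ht <- ht_mean(P_U, sample)
    variance_3phhy(cg, chain$gamma_hat, P_U = NULL,
                   n_IV = length(sample$indices), p_bar_U = p_bar_ht,
                   include_traces = include_traces,
                   cov_PU = stats::cov(P_s), N = nrow(P_U))
  }
}

#' Mean squared error under independent variability terms
#'
#' Adds to the predictor variance the population-averaging contribution of
#' the three model error terms, `(theta2 + delta2 + omega2) / N`. The result
#' assumes the variability terms of the three models are mutually independent
#' and free of spatial autocorrelation; the returned value carries the
#' attribute `independence_assumed = TRUE` as an explicit marker of that
#' assumption.
#'
#' @param variance a `variance_report` (either mode).
#' @param params a `chain_params` or `fitted_chain` supplying the error
#'   variances.
#' @param N population size.
#' @return The MSE (scalar), with attributes `addon` and
#'   `independence_assumed`.
#' @export
mse_under_independence <- function(variance, params, N) {
  stopifnot(inherits(variance, "variance_report"))
  N <- as.integer(N)
  if (N <= 0L) stop("N must be positive", call. = FALSE)
  pb <- par_blocks(params)
  delta2 <- drop(t(pb$beta) %*% pb$Delta_star %*% pb$beta)
  theta2 <- drop(t(pb$alpha) %*% pb$Theta_star %*% pb$alpha)
  addon <- (theta2 + delta2 + pb$omega2) / N
  structure(variance$total + addon, addon = addon, independence_assumed = TRUE)
}
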