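#' Superpopulation specification for a chained Y--X--Z--P world
#'
#' Defines the jointly normal superpopulation generating the finite population:
#' marginal means and standard deviations of the response Y (aboveground
#' biomass density, e.g. Mg/ha), the field covariate X (e.g. mean diameter),
#' the intermediate remote-sensing covariate Z (e.g. an ALS height metric) and
#' the final-phase covariate P (e.g. a satellite height or reflectance metric),
#' together with the chain correlations `r_YX`, `r_XZ`, `r_ZP` and the sizes of
#' the four nested datasets and the population.
#'
#' The defaults are the boreal-forest study conditions used throughout the
#' package's validation: means 62.62 / 10.94 / 7.16 / 8.28, standard deviations
#' 49.53 / 6.30 / 4.34 / 5.69, correlations 0.77 / 0.75 / 0.76, and dataset
#' sizes nI = 102, nII = 943, nIII = 1721, nIV = 5760 over a population of
#' N = 38400 grid cells. No ordering of the dataset sizes is required.
#'
#' @param mu_Y,mu_X,mu_Z,mu_P marginal superpopulation means.
#' @param sd_Y,sd_X,sd_Z,sd_P marginal standard deviations, all `> 0`
#'   (`sd = 0` covariates are tolerated by the design generator but rejected
#'   at model-fitting time as singular).
#' @param r_YX,r_XZ,r_ZP chain correlations, each strictly inside (-1, 1).
#' @param n_I,n_II,n_III,n_IV dataset sizes: field plots with measured Y
#'   (`n_I`), plots with field covariates and intermediate RS covariates
#'   (`n_II`), cells with intermediate and final-phase covariates (`n_III`),
#'   and the probability sample of final-phase covariates used by hybrid
#'   inference (`n_IV <= N`).
#' @param N number of grid cells in the population.
#'
#' @return An object of class `superpop_spec`.
#' @seealso [derive_chain_params()], [generate_designs()], [run_validation()]
#' @export
#' @examples
#' spec <- superpop_spec()
#' derive_chain_params(spec)
superpop_spec <- function(mu_Y = 62.62, mu_X = 10.94, mu_Z = 7.16, mu_P = 8.28,
                          sd_Y = 49.53, sd_X = 6.30, sd_Z = 4.34, sd_P = 5.69,
                          r_YX = 0.77, r_XZ = 0.75, r_ZP = 0.76,
                          n_I = 102L, n_II = 943L, n_III = 1721L,
                          n_IV = 5760L, N = 38400L) {
  spec <- list(
    mu_Y = as.numeric(mu_Y), mu_X = as.numeric(mu_X),
    mu_Z = as.numeric(mu_Z), mu_P = as.numeric(mu_P),
    sd_Y = as.numeric(sd_Y), sd_X = as.numeric(sd_X),
    sd_Z = as.numeric(sd_Z), sd_P = as.numeric(sd_P),
    r_YX = as.numeric(r_YX), r_XZ = as.numeric(r_XZ), r_ZP = as.numeric(r_ZP),
    n_I = as.integer(n_I), n_II = as.integer(n_II), n_III = as.integer(n_III),
    n_IV = as.integer(n_IV), N = as.integer(N)
  )
  class(spec) <- "superpop_spec"
  validate_superpop_spec(spec)
  spec
}

validate_superpop_spec <- function(spec, allow_zero_sd = FALSE) {
  stopifnot(inherits(spec, "superpop_spec"))
  num <- vapply(spec, function(v) is.numeric(v) && length(v) == 1L && is.finite(v),
                logical(1))
  if (!all(num)) {
    stop("superpop_spec fields must be finite scalars; offending: ",
         paste(names(spec)[!num], collapse = ", "), call. = FALSE)
  }
  sds <- unlist(spec[c("sd_Y", "sd_X", "sd_Z", "sd_P")])
  if (any(sds < 0) || (!allow_zero_sd && any(sds == 0))) {
    stop("all superpopulation standard deviations must be > 0", call. = FALSE)
  }
  rs <- unlist(spec[c("r_YX", "r_XZ", "r_ZP")])
  if (any(abs(rs) >= 1)) {
    stop("chain correlations must satisfy |r| < 1 ",
         "(|r| = 1 gives a degenerate conditional variance)", call. = FALSE)
  }
  ns <- unlist(spec[c("n_I", "n_II", "n_III", "n_IV", "N")])
  if (any(ns < 1)) stop("dataset sizes must be positive integers", call. = FALSE)
  if (spec$n_IV > spec$N) stop("n_IV must not exceed N", call. = FALSE)
  # univariate chain: 2 coefficients per model, need at least p + 1 rows
  if (any(unlist(spec[c("n_I", "n_II", "n_III")]) < 3L)) {
    stop("n_I, n_II, n_III must each be at least 3 ",
         "(number of model parameters + 1)", call. = FALSE)
  }
  invisible(spec)
}

#' @export
print.superpop_spec <- function(x, ...) {
  cat("Superpopulation specification (jointly normal, chained Y-X-Z-P)\n")
  cat(sprintf("  means : Y %.4g  X %.4g  Z %.4g  P %.4g\n",
              x$mu_Y, x$mu_X, x$mu_Z, x$mu_P))
  cat(sprintf("  sds   : Y %.4g  X %.4g  Z %.4g  P %.4g\n",
              x$sd_Y, x$sd_X, x$sd_Z, x$sd_P))
  cat(sprintf("  chain : r_YX %.3g  r_XZ %.3g  r_ZP %.3g\n",
              x$r_YX, x$r_XZ, x$r_ZP))
  cat(sprintf("  sizes : n_I %d  n_II %d  n_III %d  n_IV %d  N %d\n",
              x$n_I, x$n_II, x$n_III, x$n_IV, x$N))
  invisible(x)
}

#' Derive the true model-chain parameters implied by a superpopulation
#'
#' Under the jointly normal superpopulation, conditional-expectation algebra
#' yields the "true" parameters of the five models in the chain:
#' \describe{
#'   \item{F}{`Y = x beta + eps`, `eps ~ N(0, omega2)` with slope
#'     `r_YX * sd_Y / sd_X` and `omega2 = sd_Y^2 (1 - r_YX^2)`.}
#'   \item{G*}{multivariate regression of the field covariate vector
#'     `(1, x)` on `(1, z)`; the unit component regresses perfectly, so the
#'     corresponding row/column of the error covariance `Delta_star` is zero.}
#'   \item{G}{the beta-contraction of G*: `alpha = A_star %*% beta`,
#'     `delta2 = t(beta) %*% Delta_star %*% beta = sd_Y^2 r_YX^2 (1 - r_XZ^2)`.}
#'   \item{Q*}{multivariate regression of `(1, z)` on `(1, p)`.}
#'   \item{Q}{the alpha-contraction of Q*: `gamma = Gamma_star %*% alpha`,
#'     `theta2 = sd_Y^2 r_YX^2 r_XZ^2 (1 - r_ZP^2)`.}
#' }
#' The composition identities `alpha = A_star beta` and
#' `gamma = Gamma_star alpha` hold exactly by construction.
#'
#' @param spec a [superpop_spec()].
#' @return An object of class `chain_params` with fields `beta`, `omega2`,
#'   `A_star`, `Delta_star`, `alpha`, `delta2`, `Gamma_star`, `Theta_star`,
#'   `gamma`, `theta2`, and the originating `spec`.
#' @export
derive_chain_params <- function(spec) {
  validate_superpop_spec(spec)
  b1 <- spec$r_YX * spec$sd_Y / spec$sd_X
  b0 <- spec$mu_Y - b1 * spec$mu_X
  beta <- c(b0, b1)
  omega2 <- spec$sd_Y^2 * (1 - spec$r_YX^2)

  a1 <- spec$r_XZ * spec$sd_X / spec$sd_Z
  a0 <- spec$mu_X - a1 * spec$mu_Z
  # columns: unit component of (1, x), then x; rows: regressors (1, z)
  A_star <- cbind(c(1, 0), c(a0, a1))
  Delta_star <- diag(c(0, spec$sd_X^2 * (1 - spec$r_XZ^2)))

  g1 <- spec$r_ZP * spec$sd_Z / spec$sd_P
  g0 <- spec$mu_Z - g1 * spec$mu_P
  Gamma_star <- cbind(c(1, 0), c(g0, g1))
  Theta_star <- diag(c(0, spec$sd_Z^2 * (1 - spec$r_ZP^2)))

  alpha <- drop(A_star %*% beta)
  delta2 <- drop(t(beta) %*% Delta_star %*% beta)
  gamma <- drop(Gamma_star %*% alpha)
  theta2 <- drop(t(alpha) %*% Theta_star %*% alpha)

  structure(list(beta = beta, omega2 = omega2,
                 A_star = A_star, Delta_star = Delta_star,
                 alpha = alpha, delta2 = delta2,
                 Gamma_star = Gamma_star, Theta_star = Theta_star,
                 gamma = gamma, theta2 = theta2,
                 spec = spec),
            class = "chain_params")
}

#' @export
print.chain_params <- function(x, ...) {
  cat("True model-chain parameters\n")
  cat(sprintf("  F : beta  = (%.5g, %.5g)   omega2 = %.5g\n",
              x$beta[1], x$beta[2], x$omega2))
  cat(sprintf("  G : alpha = (%.5g, %.5g)   delta2 = %.5g\n",
              x$alpha[1], x$alpha[2], x$delta2))
  cat(sprintf("  Q : gamma = (%.5g, %.5g)   theta2 = %.5g\n",
              x$gamma[1], x$gamma[2], x$theta2))
  invisible(x)
}

#' Full 4x4 correlation matrix of (Y, X, Z, P)
#'
#' The chain correlations determine the off-chain entries through conditional
#' independence along the chain Y--X--Z--P: `r_YZ = r_YX r_XZ`,
#' `r_XP = r_XZ r_ZP`, `r_YP = r_YX r_XZ r_ZP`. The result is symmetric with
#' unit diagonal and must be positive definite.
#'
#' @param spec a [superpop_spec()].
#' @return A 4x4 correlation matrix with dimnames `Y, X, Z, P`.
#' @export
full_correlation_matrix <- function(spec) {
  validate_superpop_spec(spec)
  r_yx <- spec$r_YX; r_xz <- spec$r_XZ; r_zp <- spec$r_ZP
  R <- matrix(c(
    1,             r_yx,        r_yx * r_xz, r_yx * r_xz * r_zp,
    r_yx,          1,           r_xz,        r_xz * r_zp,
    r_yx * r_xz,   r_xz,        1,           r_zp,
    r_yx * r_xz * r_zp, r_xz * r_zp, r_zp,  1), 4, 4)
  dimnames(R) <- list(c("Y", "X", "Z", "P"), c("Y", "X", "Z", "P"))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("implied correlation matrix is not positive definite", call. = FALSE)
  }
  R
}

#' Variance-reduction factor of the proxy response
#'
#' Each modelling step replaces the response by its conditional expectation
#' given the next covariate, shrinking its variance by the squared correlation
#' of that step. After k steps with correlations `r_1, ..., r_k` the proxy
#' response retains the fraction `prod(r_i^2)` of the original response
#' variance.
#'
#' @param correlations numeric vector of chain correlations, each `|r| <= 1`.
#' @return The product of squared correlations (in `[0, 1]`): the multiplier
#'   of the original response variance after that many steps.
#' @export
#' @examples
#' variance_reduction_factor(0.8)        # 0.64
#' variance_reduction_factor(c(0.9, 0.9))  # 0.6561
variance_reduction_factor <- function(correlations) {
  correlations <- as.numeric(correlations)
  if (length(correlations) == 0L) return(1)
  if (any(!is.finite(correlations)) || any(abs(correlations) > 1)) {
    stop("correlations must be finite with |r| <= 1", call. = FALSE)
  }
  prod(correlations^2)
}

#' Read / write a superpopulation spec as a flat key-value config file
#'
#' The config is YAML with one key per spec field (`mu_Y`, `sd_Y`, `r_YX`,
#' `n_I`, ..., `N`). Unknown keys are rejected.
#'
#' @param path file path.
#' @return `read_superpop_config()` returns a [superpop_spec()];
#'   `write_superpop_config()` returns `path` invisibly.
#' @export
read_superpop_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(superpop_spec))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(superpop_spec, vals)
}

#' @rdname read_superpop_config
#' @param spec a [superpop_spec()] to serialize.
#' @export
write_superpop_config <- function(spec, path) {
  validate_superpop_spec(spec)
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}
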