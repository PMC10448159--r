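test_that("coefficient covariance blocks follow the OLS sandwich algebra", {
  G <- diag(2)
  expect_equal(cov_coeff_blocks(G, 0), matrix(0, 2, 2))
  expect_equal(cov_coeff_blocks(G, 3.5), 3.5 * diag(2))
  # multivariate contraction: (v' E v) * gram_inv
  E <- matrix(c(2, 0.5, 0.5, 1), 2, 2)
  v <- c(1, -2)
  expect_equal(cov_coeff_blocks(G, E, contract = v),
               drop(t(v) %*% E %*% v) * G)
  expect_error(cov_coeff_blocks(G, matrix(c(1, 2, 3, 4), 2, 2), contract = v),
               "symmetric")
  expect_error(cov_coeff_blocks(G, E), "contraction")
})

test_that("coefficient covariance matches brute-force refitting", {
  set.seed(12)
  X <- cbind(1, rnorm(15, 5, 2))
  beta <- c(2, 0.7); s2 <- 4
  fitG <- solve(crossprod(X))
  analytic <- cov_coeff_blocks(fitG, s2)
  bhats <- replicate(40000, {
    drop(fit_ols(X, drop(X %*% beta) + rnorm(15, 0, 2))$coef)
  })
  emp <- cov(t(bhats))
  # MC standard error of a variance estimate is about V sqrt(2/n)
  tol <- 4 * sqrt(2 / 40000)
  expect_lt(max(abs(emp - analytic) / max(abs(analytic))), tol * 3)
})

test_that("composed covariance vanishes without noise and collapses to the first-fit term", {
  spec <- small_spec()
  par <- derive_chain_params(spec)
  d <- generate_designs(spec, 51)

  cg0 <- cov_gamma_hat(noise_free(par), d)
  expect_equal(cg0$cov_full, matrix(0, 2, 2), tolerance = 1e-18,
               ignore_attr = TRUE)

  par_f <- noise_free(par)
  par_f$omega2 <- par$omega2   # first-fit noise only
  cg1 <- cov_gamma_hat(par_f, d)
  grams <- list(G_I = solve(crossprod(d$X_I)),
                G_II = solve(crossprod(d$Z_II)),
                G_III = solve(crossprod(d$P_III)))
  expected <- par$Gamma_star %*% par$A_star %*% (par$omega2 * grams$G_I) %*%
    t(par$A_star) %*% t(par$Gamma_star)
  expect_equal(cg1$cov_full, expected, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(cg1$term_traces, matrix(0, 2, 2), tolerance = 1e-18,
               ignore_attr = TRUE)
})

test_that("full minus trace-free decomposition equals the trace terms exactly", {
  set.seed(13)
  for (i in 1:20) {
    spec <- random_spec()
    par <- derive_chain_params(spec)
    d <- generate_designs(spec, sub_seed(13, i))
    cg <- cov_gamma_hat(par, d)
    expect_equal(cg$cov_full - cg$cov_notrace, cg$term_traces,
                 tolerance = 1e-12)
    pb <- colMeans(d$P_U)
    v_full <- variance_3phmb(cg, pb, include_traces = TRUE)
    v_nt <- variance_3phmb(cg, pb, include_traces = FALSE)
    expect_equal(v_full$total - v_nt$total, v_full$trace_terms,
                 tolerance = 1e-10 * max(1, v_full$total))
    # report invariant: total is the sum of its listed terms
    expect_equal(v_full$total,
                 v_full$term_Q + v_full$term_G + v_full$term_F +
                   v_full$trace_terms, tolerance = 1e-12 * max(1, v_full$total))
    expect_true(all(c(v_full$term_Q, v_full$term_G, v_full$term_F,
                      v_full$trace_terms) >= 0))
  }
})

test_that("hybrid variance adds a design term that vanishes for a census", {
  spec <- small_spec()
  par <- derive_chain_params(spec)
  d <- generate_designs(spec, 61)
  cg <- cov_gamma_hat(par, d)
  pb <- colMeans(d$P_U)
  v_mb <- variance_3phmb(cg, pb)
  v_hy <- variance_3phhy(cg, par$gamma, d$P_U, spec$n_IV, pb)
  expect_gt(v_hy$design_term, 0)
  expect_gt(v_hy$total, v_mb$total)
  # census: fpc = 0 collapses the design term and the totals coincide
  v_census <- variance_3phhy(cg, par$gamma, d$P_U, spec$N, pb)
  expect_equal(v_census$design_term, 0)
  expect_equal(v_census$total, v_mb$total +
                 (v_census$trace_terms - v_mb$trace_terms), tolerance = 1e-12)
  expect_equal(v_census$trace_design, 0)
  # intercept-only gamma: constant prediction, zero design variance
  v_c <- variance_3phhy(cg, c(4, 0), d$P_U, spec$n_IV, pb)
  expect_equal(v_c$design_term, 0, tolerance = 1e-12)
  expect_error(variance_3phhy(cg, par$gamma, d$P_U, nrow(d$P_U) + 1, pb),
               "exceeds")
})

test_that("plug-in estimator reproduces the analytic formula at the true values", {
  # feeding the estimator a 'fitted chain' whose entries are the true
  # parameters must give exactly the analytic variance
  spec <- small_spec()
  par <- derive_chain_params(spec)
  d <- generate_designs(spec, 71)
  grams <- list(G_I = solve(crossprod(d$X_I)),
                G_II = solve(crossprod(d$Z_II)),
                G_III = solve(crossprod(d$P_III)))
  chain_true <- structure(list(
    beta_hat = par$beta, omega2_hat = par$omega2,
    A_star_hat = par$A_star, Delta_star_hat = par$Delta_star,
    alpha_hat = par$alpha,
    Gamma_star_hat = par$Gamma_star, Theta_star_hat = par$Theta_star,
    gamma_hat = par$gamma,
    xtx_inv_I = grams$G_I, ztz_inv_II = grams$G_II,
    ptp_inv_III = grams$G_III), class = "fitted_chain")
  pb <- colMeans(d$P_U)
  est <- estimate_variance(chain_true, "3phmb", p_bar_U = pb)
  ana <- variance_3phmb(cov_gamma_hat(par, d), pb)
  expect_equal(est$total, ana$total, tolerance = 1e-12)
})

test_that("noise-free fitted chain estimates zero variance", {
  spec <- small_spec()
  par <- noise_free(derive_chain_params(spec))
  d <- generate_designs(spec, 81)
  r <- generate_responses(d, par, 82)
  chain <- fit_chain(r, d)
  pb <- colMeans(d$P_U)
  expect_lt(estimate_variance(chain, "3phmb", p_bar_U = pb)$total, 1e-12)
  s <- draw_srswor(spec$N, spec$n_IV, 83)
  v <- estimate_variance(chain, "3phhy", P_U = d$P_U, sample = s)
  # only the design term survives, driven by gamma_hat = gamma
  expect_equal(v$total, v$design_term, tolerance = 1e-10)
})

test_that("independence MSE adds the averaged error variances", {
  spec <- small_spec()
  par <- derive_chain_params(spec)
  d <- generate_designs(spec, 91)
  cg <- cov_gamma_hat(par, d)
  v <- variance_3phmb(cg, colMeans(d$P_U))
  mse <- mse_under_independence(v, par, spec$N)
  addon <- (par$theta2 + par$delta2 + par$omega2) / spec$N
  expect_equal(as.numeric(mse), v$total + addon, tolerance = 1e-12)
  expect_equal(attr(mse, "addon"), addon)
  expect_true(attr(mse, "independence_assumed"))
  # vanishing add-on for a huge population
  mse_big <- mse_under_independence(v, par, 1e9)
  expect_equal(as.numeric(mse_big), v$total, tolerance = 1e-5)
  # zero error variances: MSE equals the variance
  mse0 <- mse_under_independence(v, noise_free(par), spec$N)
  expect_equal(as.numeric(mse0), v$total)
})

test_that("MC mean squared error agrees with the independence MSE formula", {
  # small world: simulate finite populations (responses for all N cells) and
  # compare the realized squared prediction error to Eq-style variance + addon
  spec <- small_spec(N = 200L, n_IV = 40L)
  par <- derive_chain_params(spec)
  d <- generate_designs(spec, 101)
  cg <- cov_gamma_hat(par, d)
  pb <- colMeans(d$P_U)
  mse_formula <- as.numeric(mse_under_independence(variance_3phmb(cg, pb),
                                                   par, spec$N))
  set.seed(102)
  R <- 4000
  errs <- numeric(R)
  for (i in seq_len(R)) {
    data <- generate_responses(d, par, sub_seed(101, i))
    chain <- fit_chain(data, d)
    # realized finite-population mean: chain models applied to U plus noise
    e_U <- rnorm(spec$N, 0, sqrt(par$theta2))
    u_U <- rnorm(spec$N, 0, sqrt(par$delta2))
    eps_U <- rnorm(spec$N, 0, sqrt(par$omega2))
    y_U <- drop(d$P_U %*% par$gamma) + e_U + u_U + eps_U
    errs[i] <- predict_3phmb(chain, pb) - mean(y_U)
  }
  mse_mc <- mean(errs^2)
  se <- sd(errs^2) / sqrt(R)
  expect_lt(abs(mse_mc - mse_formula), 4 * se)
})
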