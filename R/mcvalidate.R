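#' Configuration for a Monte-Carlo validation run
#'
#' @param spec a [superpop_spec()]; defaults to the boreal study conditions.
#' @param n_reps number of Monte-Carlo iterations (>= 2). The default 10^4
#'   keeps a desk-scale run in seconds-to-minutes; Monte-Carlo standard
#'   errors in the report make reduced replication statistically
#'   interpretable. Full-fidelity runs simply pass a larger value.
#' @param master_seed integer master seed. The fixed designs use
#'   `sub_seed(master_seed, 0)`; iteration i uses `sub_seed(master_seed, i)`,
#'   so any single iteration is individually replayable.
#' @param include_traces include trace terms in analytic totals and
#'   estimators (default TRUE).
#' @param modes which predictors to validate, subset of
#'   `c("3phmb", "3phhy")`.
#' @param estimate_variances apply the plug-in variance estimators each
#'   iteration (default TRUE; turn off for speed when only predictions are
#'   needed).
#' @param collect_draws store per-iteration predictions and composed
#'   coefficient draws in the report (default FALSE; summaries only).
#' @param params optional `chain_params` override; by default derived from
#'   `spec`. Allows validation of hand-modified worlds (e.g. noise-free).
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(spec = superpop_spec(), n_reps = 10000L,
                      master_seed = 1L, include_traces = TRUE,
                      modes = c("3phmb", "3phhy"),
                      estimate_variances = TRUE, collect_draws = FALSE,
                      params = NULL) {
  validate_superpop_spec(spec)
  n_reps <- as.integer(n_reps)
  if (n_reps < 2L) stop("n_reps must be at least 2", call. = FALSE)
  modes <- match.arg(modes, several.ok = TRUE)
  structure(list(spec = spec, n_reps = n_reps,
                 master_seed = as.integer(master_seed),
                 include_traces = isTRUE(include_traces),
                 modes = modes,
                 estimate_variances = isTRUE(estimate_variances),
                 collect_draws = isTRUE(collect_draws),
                 params = params),
            class = "mc_config")
}

#' Run the full Monte-Carlo validation
#'
#' Executes the validation protocol end to end:
#' \enumerate{
#'   \item derive the true chain parameters from the superpopulation spec;
#'   \item generate the fixed explanatory designs once;
#'   \item compute the analytic variances of both predictors, conditional on
#'     those realized designs;
#'   \item loop `n_reps` times: regenerate all responses, fit the chain,
#'     record both predictions, draw a fresh SRSWOR sample for the hybrid
#'     predictor, and apply both plug-in variance estimators.
#' }
#' The analytic variances are conditional on the one realized set of designs,
#' so their values vary (slightly) across master seeds; the empirical and
#' estimated variances are directly comparable to them because they share the
#' same designs.
#'
#' @param config an [mc_config()].
#' @return An object of class `mc_report`: per-mode analytic variance,
#'   empirical variance of the recorded predictions, mean plug-in variance
#'   estimate, mean prediction, trace-term relative contributions (% of the
#'   analytic total), Monte-Carlo standard errors for every summary, and the
#'   echoed config (the report is re-runnable from itself).
#' @export
run_validation <- function(config) {
  stopifnot(inherits(config, "mc_config"))
  spec <- config$spec
  params <- if (is.null(config$params)) derive_chain_params(spec) else config$params
  designs <- generate_designs(spec, sub_seed(config$master_seed, 0))
  cg_true <- cov_gamma_hat(params, designs)
  p_bar_U <- colMeans(designs$P_U)

  analytic <- list()
  if ("3phmb" %in% config$modes) {
    analytic$`3phmb` <- variance_3phmb(cg_true, p_bar_U, config$include_traces)
  }
  if ("3phhy" %in% config$modes) {
    analytic$`3phhy` <- variance_3phhy(cg_true, params$gamma, designs$P_U,
                                       spec$n_IV, p_bar_U,
                                       config$include_traces)
  }

  R <- config$n_reps
  pred <- vest <- list()
  for (m in config$modes) {
    pred[[m]] <- numeric(R)
    if (config$estimate_variances) vest[[m]] <- numeric(R)
  }
  gamma_draws <- if (config$collect_draws) {
    matrix(NA_real_, R, length(params$gamma))
  } else NULL

  for (i in seq_len(R)) {
    it_seed <- sub_seed(config$master_seed, i)
    res <- tryCatch({
      data <- generate_responses(designs, params, it_seed)
      chain <- fit_chain(data, designs)
      out <- list(chain = chain)
      if ("3phhy" %in% config$modes) {
        out$s_IV <- draw_srswor(spec$N, spec$n_IV)
      }
      out
    }, error = function(e) {
      stop("Monte-Carlo iteration ", i, " (sub-seed ", it_seed, ") failed: ",
           conditionMessage(e), call. = FALSE)
    })
    chain <- res$chain
    if (!is.null(gamma_draws)) gamma_draws[i, ] <- chain$gamma_hat
    if ("3phmb" %in% config$modes) {
      pred$`3phmb`[i] <- predict_3phmb(chain, p_bar_U)
      if (config$estimate_variances) {
        vest$`3phmb`[i] <- estimate_variance(chain, "3phmb", p_bar_U = p_bar_U,
                                             include_traces = config$include_traces)$total
      }
    }
    if ("3phhy" %in% config$modes) {
      pred$`3phhy`[i] <- predict_3phhy(chain, designs$P_U, res$s_IV)
      if (config$estimate_variances) {
        vest$`3phhy`[i] <- estimate_variance(chain, "3phhy", P_U = designs$P_U,
                                             sample = res$s_IV,
                                             include_traces = config$include_traces)$total
      }
    }
  }

  summarize_mode <- function(m) {
    p <- pred[[m]]
    emp <- stats::var(p)
    out <- list(
      analytic_variance = analytic[[m]]$total,
      empirical_variance = emp,
      mean_prediction = mean(p),
      trace_relative_contribution =
        100 * analytic[[m]]$trace_terms_value / analytic[[m]]$total,
      se_mean_prediction = stats::sd(p) / sqrt(R),
      se_empirical_variance = emp * sqrt(2 / (R - 1)))
    if (config$estimate_variances) {
      v <- vest[[m]]
      out$mean_estimated_variance <- mean(v)
      out$se_mean_estimated_variance <- stats::sd(v) / sqrt(R)
    }
    out
  }
  modes_summary <- lapply(stats::setNames(config$modes, config$modes),
                          summarize_mode)

  structure(list(
    modes = modes_summary,
    analytic_reports = analytic,
    p_bar_U = p_bar_U,
    params = params,
    design_seed = designs$seed,
    config = config,
    draws = if (config$collect_draws) {
      list(predictions = pred, estimated_variances = vest,
           gamma_hat = gamma_draws)
    } else NULL),
    class = "mc_report")
}

#' @export
print.mc_report <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Monte-Carlo validation: %d reps, master seed %d%s\n",
              cfg$n_reps, cfg$master_seed,
              if (cfg$include_traces) "" else ", trace terms excluded"))
  cat("Predictor variances (analytic V conditional on the realized designs):\n")
  hdr <- sprintf("  %-7s %10s %10s %10s %12s", "mode", "V", "V_MC",
                 "mean V^", "mean pred")
  cat(hdr, "\n")
  for (m in names(x$modes)) {
    s <- x$modes[[m]]
    cat(sprintf("  %-7s %10.4f %10.4f %10s %12.4f\n", m,
                s$analytic_variance, s$empirical_variance,
                if (is.null(s$mean_estimated_variance)) "-" else
                  sprintf("%.4f", s$mean_estimated_variance),
                s$mean_prediction))
  }
  cat("Trace-term contribution to the analytic variance:\n")
  for (m in names(x$modes)) {
    s <- x$modes[[m]]
    cat(sprintf("  %-7s %10.2e %%\n", m, s$trace_relative_contribution))
  }
  invisible(x)
}

#' Bias summary of a Monte-Carlo report
#'
#' For each validated mode, reports the prediction bias relative to the
#' superpopulation mean of the response with its Monte-Carlo standard error
#' and standardized (z) value, and the relative bias of the plug-in variance
#' estimator against the empirical variance with a z value combining both
#' Monte-Carlo uncertainties.
#'
#' @param report an [run_validation()] result.
#' @param params optional `chain_params`; defaults to the report's.
#' @return A data.frame with one row per mode.
#' @export
summarize_bias <- function(report, params = NULL) {
  stopifnot(inherits(report, "mc_report"))
  mu_Y <- report$config$spec$mu_Y
  rows <- lapply(names(report$modes), function(m) {
    s <- report$modes[[m]]
    bias <- s$mean_prediction - mu_Y
    z <- bias / s$se_mean_prediction
    if (!is.null(s$mean_estimated_variance)) {
      vrb <- (s$mean_estimated_variance - s$empirical_variance) /
        s$empirical_variance
      vz <- (s$mean_estimated_variance - s$empirical_variance) /
        sqrt(s$se_mean_estimated_variance^2 + s$se_empirical_variance^2)
    } else {
      vrb <- NA_real_; vz <- NA_real_
    }
    data.frame(mode = m, mean_prediction = s$mean_prediction,
               prediction_bias = bias, se = s$se_mean_prediction,
               z = z, empirical_variance = s$empirical_variance,
               mean_estimated_variance =
                 if (is.null(s$mean_estimated_variance)) NA_real_
                 else s$mean_estimated_variance,
               variance_relative_bias = vrb, variance_z = vz)
  })
  do.call(rbind, rows)
}
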