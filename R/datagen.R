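#' Deterministic sub-seed derivation
#'
#' Counter-based scheme used everywhere the package needs several independent
#' random streams from one master seed: `sub_seed(master, k)` hashes the
#' (master, counter) pair into a 31-bit seed by modular multiplication with
#' two large primes. Counter 0 is reserved for the fixed designs; Monte-Carlo
#' iteration i uses counter i.
#'
#' @param master integer master seed.
#' @param counter nonnegative integer counter.
#' @return An integer usable with [set.seed()].
#' @export
sub_seed <- function(master, counter) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- (as.numeric(master) %% m) * 48271 %% m
  s <- (s + (as.numeric(counter) %% m) * 16807) %% m
  as.integer((s * 69621) %% m)
}

#' Generate the fixed explanatory designs
#'
#' Draws the four design matrices once, from the spec's marginal normal
#' distributions: `X_I` (field covariate over the field dataset), `Z_II`
#' (intermediate RS covariate over the second dataset), `P_III` (final-phase
#' covariate over the third dataset) and `P_U` (final-phase covariate over the
#' whole population). Each matrix carries a leading unit column for the
#' intercept. The designs are held fixed across Monte-Carlo iterations; only
#' the responses are regenerated per iteration (see [generate_responses()]).
#' Covariate columns across datasets are drawn independently.
#'
#' @param spec a [superpop_spec()].
#' @param seed integer seed; the draw is deterministic given `(spec, seed)`.
#' @return An object of class `fixed_designs` with matrices `X_I`, `Z_II`,
#'   `P_III`, `P_U`, the originating `spec` and `seed`.
#' @export
generate_designs <- function(spec, seed) {
  # sd = 0 covariates are legal here (degenerate constant columns); the
  # resulting singular designs are rejected downstream at fit time
  validate_superpop_spec(spec, allow_zero_sd = TRUE)
  set.seed(as.integer(seed))
  X_I   <- cbind(`(Intercept)` = 1, x = stats::rnorm(spec$n_I,   spec$mu_X, spec$sd_X))
  Z_II  <- cbind(`(Intercept)` = 1, z = stats::rnorm(spec$n_II,  spec$mu_Z, spec$sd_Z))
  P_III <- cbind(`(Intercept)` = 1, p = stats::rnorm(spec$n_III, spec$mu_P, spec$sd_P))
  P_U   <- cbind(`(Intercept)` = 1, p = stats::rnorm(spec$N,     spec$mu_P, spec$sd_P))
  structure(list(X_I = X_I, Z_II = Z_II, P_III = P_III, P_U = P_U,
                 spec = spec, seed = as.integer(seed)),
            class = "fixed_designs")
}

#' @export
print.fixed_designs <- function(x, ...) {
  cat("Fixed designs: X_I", nrow(x$X_I), "x", ncol(x$X_I),
      "| Z_II", nrow(x$Z_II), "x", ncol(x$Z_II),
      "| P_III", nrow(x$P_III), "x", ncol(x$P_III),
      "| P_U", nrow(x$P_U), "x", ncol(x$P_U),
      "(seed", x$seed, ")\n")
  invisible(x)
}

# rows ~ N(0, Sigma) with possibly singular Sigma (zero-variance unit
# component). Eigen-based square root; negative eigenvalues from round-off
# are clipped at zero.
mvn_rows <- function(n, Sigma) {
  m <- nrow(Sigma)
  if (all(Sigma == 0)) return(matrix(0, n, m))
  E <- eigen(Sigma, symmetric = TRUE)
  vals <- pmax(E$values, 0)
  L <- E$vectors %*% (sqrt(vals) * t(E$vectors))
  matrix(stats::rnorm(n * m), n, m) %*% L
}

#' Generate the hierarchical responses for one Monte-Carlo iteration
#'
#' Given the fixed designs and the true chain parameters, draws fresh
#' variability terms and builds the responses of the three training datasets:
#' `y_I = X_I beta + eps` with `eps ~ N(0, omega2)`, the multivariate field
#' covariate responses `X_II = Z_II A_star + noise` with rows
#' `~ N(0, Delta_star)`, and `Z_III = P_III Gamma_star + noise` with rows
#' `~ N(0, Theta_star)`. Unit columns of `X_II` and `Z_III` are exactly 1
#' because the corresponding error-covariance rows/columns are zero.
#'
#' @param designs a [generate_designs()] result.
#' @param params a [derive_chain_params()] result from the same spec.
#' @param seed integer iteration seed.
#' @return An object of class `hier_data` with `y_I`, `X_II`, `Z_III` and
#'   `iteration_seed`.
#' @export
generate_responses <- function(designs, params, seed) {
  stopifnot(inherits(designs, "fixed_designs"), inherits(params, "chain_params"))
  if (ncol(designs$X_I) != length(params$beta) ||
      ncol(designs$Z_II) != nrow(params$A_star) ||
      ncol(designs$P_III) != nrow(params$Gamma_star)) {
    stop("designs and params have inconsistent dimensions", call. = FALSE)
  }
  set.seed(as.integer(seed))
  y_I <- drop(designs$X_I %*% params$beta) +
    stats::rnorm(nrow(designs$X_I), 0, sqrt(params$omega2))
  X_II <- designs$Z_II %*% params$A_star +
    mvn_rows(nrow(designs$Z_II), params$Delta_star)
  Z_III <- designs$P_III %*% params$Gamma_star +
    mvn_rows(nrow(designs$P_III), params$Theta_star)
  colnames(X_II) <- colnames(designs$X_I)
  colnames(Z_III) <- colnames(designs$Z_II)
  structure(list(y_I = y_I, X_II = X_II, Z_III = Z_III,
                 iteration_seed = as.integer(seed)),
            class = "hier_data")
}

#' Write / load the four datasets as headed CSV files
#'
#' On disk the unit columns are omitted and re-added on load. Files and
#' schemas: `s1.csv` (`y`, `x`), `s2.csv` (`x`, `z`), `s3.csv` (`z`, `p`),
#' `u.csv` (`p`), plus `config.yml` echoing the spec. `load_datasets()`
#' validates headers and numeric content and reconstructs both the
#' `fixed_designs` and the `hier_data` objects.
#'
#' @param designs a `fixed_designs` object.
#' @param responses a `hier_data` object from the same designs.
#' @param dir output directory (created if missing).
#' @return `write_datasets()` returns `dir` invisibly; `load_datasets()`
#'   returns `list(designs = , responses = , spec = )`.
#' @export
write_datasets <- function(designs, responses, dir) {
  stopifnot(inherits(designs, "fixed_designs"), inherits(responses, "hier_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(y = responses$y_I, x = designs$X_I[, 2]),
                   file.path(dir, "s1.csv"), row.names = FALSE)
  utils::write.csv(data.frame(x = responses$X_II[, 2], z = designs$Z_II[, 2]),
                   file.path(dir, "s2.csv"), row.names = FALSE)
  utils::write.csv(data.frame(z = responses$Z_III[, 2], p = designs$P_III[, 2]),
                   file.path(dir, "s3.csv"), row.names = FALSE)
  utils::write.csv(data.frame(p = designs$P_U[, 2]),
                   file.path(dir, "u.csv"), row.names = FALSE)
  write_superpop_config(designs$spec, file.path(dir, "config.yml"))
  invisible(dir)
}

read_dataset_csv <- function(path, cols) {
  if (!file.exists(path)) stop("dataset file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (nrow(df) == 0L) stop("empty dataset file: ", path, call. = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (cn in cols) {
    v <- df[[cn]]
    if (!is.numeric(v) || anyNA(v)) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))))[1]
      stop("non-numeric value in file ", path, ", column '", cn,
           "', row ", ifelse(is.na(bad), "?", bad), call. = FALSE)
    }
  }
  df[cols]
}

#' @rdname write_datasets
#' @export
load_datasets <- function(dir) {
  s1 <- read_dataset_csv(file.path(dir, "s1.csv"), c("y", "x"))
  s2 <- read_dataset_csv(file.path(dir, "s2.csv"), c("x", "z"))
  s3 <- read_dataset_csv(file.path(dir, "s3.csv"), c("z", "p"))
  u  <- read_dataset_csv(file.path(dir, "u.csv"),  "p")
  cfg <- file.path(dir, "config.yml")
  spec <- if (file.exists(cfg)) read_superpop_config(cfg) else NULL
  if (!is.null(spec)) {
    sizes <- c(n_I = nrow(s1), n_II = nrow(s2), n_III = nrow(s3), N = nrow(u))
    want <- unlist(spec[c("n_I", "n_II", "n_III", "N")])
    if (any(sizes != want)) {
      stop("dataset row counts disagree with config sizes: got ",
           paste(sizes, collapse = "/"), ", expected ",
           paste(want, collapse = "/"), call. = FALSE)
    }
  }
  unit <- function(v) cbind(`(Intercept)` = 1, v)
  designs <- structure(list(
    X_I = {m <- unit(s1$x); colnames(m)[2] <- "x"; m},
    Z_II = {m <- unit(s2$z); colnames(m)[2] <- "z"; m},
    P_III = {m <- unit(s3$p); colnames(m)[2] <- "p"; m},
    P_U = {m <- unit(u$p); colnames(m)[2] <- "p"; m},
    spec = spec, seed = NA_integer_), class = "fixed_designs")
  responses <- structure(list(
    y_I = s1$y,
    X_II = {m <- unit(s2$x); colnames(m)[2] <- "x"; m},
    Z_III = {m <- unit(s3$z); colnames(m)[2] <- "z"; m},
    iteration_seed = NA_integer_), class = "hier_data")
  list(designs = designs, responses = responses, spec = spec)
}
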