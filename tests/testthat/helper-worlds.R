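# Shared fixture builders: all data are generated in code.

# the boreal study conditions (package defaults)
boreal_spec <- function() superpop_spec()

# a small world for fast brute-force / oracle work
small_spec <- function(n_I = 30L, n_II = 50L, n_III = 80L,
                       n_IV = 50L, N = 400L) {
  superpop_spec(n_I = n_I, n_II = n_II, n_III = n_III, n_IV = n_IV, N = N)
}

# a random valid spec (means/sds/correlations drawn uniformly)
random_spec <- function() {
  superpop_spec(
    mu_Y = runif(1, -50, 100), mu_X = runif(1, -10, 20),
    mu_Z = runif(1, -10, 20), mu_P = runif(1, -10, 20),
    sd_Y = runif(1, 0.5, 60), sd_X = runif(1, 0.5, 10),
    sd_Z = runif(1, 0.5, 10), sd_P = runif(1, 0.5, 10),
    r_YX = runif(1, -0.95, 0.95), r_XZ = runif(1, -0.95, 0.95),
    r_ZP = runif(1, -0.95, 0.95),
    n_I = 20L, n_II = 25L, n_III = 30L, n_IV = 10L, N = 100L)
}

# zero out every error (co)variance: the chain becomes deterministic
noise_free <- function(params) {
  params$omega2 <- 0
  params$Delta_star[] <- 0
  params$Theta_star[] <- 0
  params$delta2 <- 0
  params$theta2 <- 0
  params
}

# one simulated world, fitted
fitted_world <- function(spec = small_spec(), seed = 1L) {
  params <- derive_chain_params(spec)
  designs <- generate_designs(spec, sub_seed(seed, 0))
  data <- generate_responses(designs, params, sub_seed(seed, 1))
  list(spec = spec, params = params, designs = designs, data = data,
       chain = fit_chain(data, designs))
}
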