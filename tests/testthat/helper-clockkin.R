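# Canonical order-one parameter sets used throughout (the arbitrary
# simulation values of the regime comparisons).
par_mhp <- function(eps = 1e-2)
  nondim_params(eps, beta = 0.6, gamma = 0.7, sigma = 0.8, phi = 0.2, rho = 2)
par_hhp <- function(eps = 1e-2)
  nondim_params(eps, beta = 0.6, gamma = 0.7, sigma = 0.8, phi = 0.2,
                rho_hat = 0.9)

# Bench-scale generating truth used by the synthetic presets.
TRUTH <- c(phi = 0.158, k2 = 0.0663)

# Random admissible dimensional state.
rand_state <- function() {
  s <- stats::runif(5, 0, 1e-2)
  names(s) <- c("D", "P", "Q", "C", "I")
  s
}

# Fourth-order central difference (5-point stencil).
num_deriv <- function(f, x, h = 1e-3) {
  (-f(x + 2 * h) + 8 * f(x + h) - 8 * f(x - h) + f(x - 2 * h)) / (12 * h)
}
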