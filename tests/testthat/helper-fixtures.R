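# shared fixtures: representative parameter sets on both sides of the
# tipping point for each family

p3_above <- function(N = 100)
  params_3d(beta = 2, delta = 0.5, sigma = 0.5, rho_x = 1, rho_c = 0.5, N = N)

p3_below <- function(N = 100)
  params_3d(beta = 0.4, delta = 0.5, sigma = 0.5, rho_x = 1, rho_c = 0.5, N = N)

p5_above <- function(N = 120, nu_c = 0, eps = 0)
  params_5d(beta = 1, delta1 = 0.3, sigma1 = 0.4, rho = 1, nu_p = 0.2,
            nu_c = nu_c, delta2 = 0.2, sigma2 = 0.5, phi = 0.3,
            eps = eps, N = N)

p5_below <- function(N = 120, nu_c = 0, eps = 0)
  params_5d(beta = 0.25, delta1 = 0.3, sigma1 = 0.4, rho = 1, nu_p = 0.2,
            nu_c = nu_c, delta2 = 0.2, sigma2 = 0.5, phi = 0.3,
            eps = eps, N = N)

p9_base <- function(beta = 2, rho3 = 1, eps = 0, N = 100, nu_c1 = 0, nu_c2 = 0)
  params_9d(beta = beta, delta1 = 0.5, sigma1 = 0.5, rho1 = 1,
            nu_p1 = 0.2, nu_c1 = nu_c1, phi1 = 0.3,
            delta2 = 0.2, sigma2 = 0.5, rho2 = 1,
            nu_p2 = 0.2, nu_c2 = nu_c2, phi2 = 0.3,
            delta3 = 0.2, sigma3 = 0.5, rho3 = rho3, eps = eps, N = N)

p_no_parole <- function(beta = 2, delta = 0.5, sigma = 0.5, eps = 0, N = 120)
  params_3d(beta = beta, delta = delta, sigma = sigma, rho_x = 0, rho_c = 0,
            eps = eps, N = N)

random_state <- function(model, N = 100) {
  k <- length(compartments(model))
  e <- stats::rexp(k)
  stats::setNames(e / sum(e) * N, compartments(model))
}
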