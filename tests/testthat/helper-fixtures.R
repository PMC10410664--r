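# Shared fixtures and independent numeric oracles.  Everything is built in
# code (no binary fixtures); expensive objects are memoized per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

fixture_roster <- function() memo("roster", make_fixture_components(1))

# noise-free study with reduced AAPS settings to stay inside the time budget
fixture_study_noisefree <- function() memo("study0", generate_screening_study(
  config = list(noise_cv = 0, aaps_step = 25, grid_n = 121), seed = 1))

toy_api <- function(u = 320, eps = 1200, M = 250, m_over_M = 0.03,
                    sigma = 3.5, kappa = 0.02, nd = 2, na = 2,
                    Tm = 420, dH = 30, cp = 100, name = "TAPI") {
  saft_component(name, M, segment_params(m_over_M, sigma, u, eps, kappa, nd, na),
                 role = "API", fusion = fusion_properties(Tm, dH, cp))
}

toy_polymer <- function(u = 260, M = 2000, m_over_M = 0.03, sigma = 3.8,
                        eps = 0, kappa = 0, nd = 0, na = 0, name = "TPOLY") {
  saft_component(name, M, segment_params(m_over_M, sigma, u, eps, kappa, nd, na),
                 role = "polymer")
}

# ---- independent finite-difference oracles on the reduced residual
# Helmholtz energy (central differences; the analytic path in the package
# never uses these formulas)

ares_of <- function(mix, T, rho, x)
  saftscreen:::cpp_eval(mix$model, T, rho, x, FALSE)$a_res

fd_Z <- function(mix, T, rho, x, h = 1e-6) {
  hh <- h * rho
  ap <- ares_of(mix, T, rho + hh, x)
  am <- ares_of(mix, T, rho - hh, x)
  1 + rho * (ap - am) / (2 * hh)
}

# residual chemical potentials from the total Helmholtz energy A_res/(kT) =
# n_tot * a_res(rho = n_tot/V, x), differentiated w.r.t. mole numbers at
# fixed T and V (the density varies with n_tot, so the pressure-related
# Z - 1 piece arises from the differentiation itself);
# ln phi_i = mu_i_res/(kT) - ln Z
fd_lnphi <- function(mix, T, rho, x, h = 1e-7) {
  V <- sum(x) / rho
  Ftot <- function(n) {
    ntot <- sum(n)
    ntot * ares_of(mix, T, ntot / V, n / ntot)
  }
  Z <- saftscreen:::cpp_eval(mix$model, T, rho, x, FALSE)$Z
  vapply(seq_along(x), function(i) {
    np <- x; nm <- x
    np[i] <- x[i] + h; nm[i] <- x[i] - h
    (Ftot(np) - Ftot(nm)) / (2 * h) - log(Z)
  }, 0)
}

# brute-force binodal: lower convex hull of the Gibbs-of-mixing curve on a
# dense grid; returns the x endpoints of the tie line (or NULL)
hull_binodal <- function(api, poly, T, kij = 0, n = 4000) {
  xg <- sort(unique(c(10^seq(-8, -1.3, length.out = 500),
                      seq(0.05, 0.95, length.out = n),
                      1 - 10^seq(-1.3, -8, length.out = 500))))
  gc <- mixing_gibbs_curve(api, poly, T, x = xg, kij = kij)
  h <- saftscreen:::lower_hull(gc$x, gc$g_mix)
  gaps <- diff(h)
  k <- which.max(gaps)
  if (gaps[k] <= 1) return(NULL)
  c(gc$x[h[k]], gc$x[h[k + 1]])
}

# seeded random toy state (binary mixture of nonpolymeric associating
# chains) for the oracle-equivalence sweeps
random_toy_state <- function() {
  a <- saft_component("RA", runif(1, 100, 400),
                      segment_params(runif(1, 0.01, 0.05), runif(1, 2.9, 4.5),
                                     runif(1, 220, 480),
                                     eps_hb = runif(1, 500, 2000),
                                     kappa_hb = runif(1, 0.01, 0.03),
                                     n_donor = sample(0:2, 1),
                                     n_acceptor = sample(1:2, 1)))
  b <- saft_component("RB", runif(1, 100, 2000),
                      segment_params(runif(1, 0.01, 0.05), runif(1, 2.9, 4.5),
                                     runif(1, 220, 480),
                                     eps_hb = if (runif(1) < 0.5) runif(1, 500, 2000) else 0,
                                     kappa_hb = 0.02,
                                     n_donor = sample(0:1, 1),
                                     n_acceptor = sample(0:2, 1)))
  x1 <- runif(1, 0.05, 0.95)
  mix <- mixture(list(a, b), x = c(x1, 1 - x1))
  # keep the packing fraction inside the liquid-like range, and reject
  # states with Z <= 0 (inside the mechanical instability ln(phi) is
  # undefined for both the analytic path and the oracle)
  T <- runif(1, 300, 500)
  s3 <- sum(vapply(seq_along(mix$model$mseg), function(t) {
    d <- mix$model$sigma[t] * (1 - 0.12 * exp(-3 * mix$model$u[t] / T))
    mix$x[mix$model$comp[t]] * mix$model$mseg[t] * d^3
  }, 0)) * pi / 6
  for (i in 1:50) {
    eta <- runif(1, 0.15, 0.45)
    if (saftscreen:::cpp_eval(mix$model, T, eta / s3, mix$x, FALSE)$Z > 0.05)
      return(list(mix = mix, T = T, rho = eta / s3))
  }
  random_toy_state()
}
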