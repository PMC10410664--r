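# EOS core: combining rules, limits, breakdown, analytic-vs-FD oracles,
# association, density solving, activity coefficients.

test_that("cross parameters follow the combining rules", {
  si <- segment_params(0.03, 3.2, 100, 1000, 0.02, 1, 1)
  sj <- segment_params(0.03, 3.8, 400, 500, 0.03, 1, 1)
  # identity
  ii <- cross_parameters(si, si, 0)
  expect_equal(ii$u_ij, si$u)
  expect_equal(ii$sigma_ij, si$sigma)
  expect_equal(ii$eps_hb_ij, si$eps_hb)
  expect_equal(ii$kappa_hb_ij, si$kappa_hb)
  # geometric mean and kij correction
  expect_equal(cross_parameters(si, sj, 0)$u_ij, 200)
  expect_equal(cross_parameters(si, sj, 0.1)$u_ij, 180)
  expect_equal(cross_parameters(si, sj)$sigma_ij, 3.5)
  # induced cross association: partner with eps_hb = 0 gets half the energy
  sk <- segment_params(0.03, 3.2, 250, 0, 0.02, 0, 1)
  expect_equal(cross_parameters(si, sk)$eps_hb_ij, si$eps_hb / 2)
  expect_gt(cross_parameters(si, sk)$kappa_hb_ij, 0)
  expect_error(cross_parameters(si, sj, 3), "negative")
})

test_that("ideal-gas limit: a_res, Z - 1 and ln phi vanish as rho -> 0", {
  ros <- fixture_roster()
  for (pair in list(list(ros$apis$API1, ros$polymers$PSELF),
                    list(ros$apis$API2, ros$polymers$PNON),
                    list(ros$apis$API3, ros$polymers$PCOPO))) {
    mix <- mixture(pair, x = c(0.3, 0.7))
    liq <- solve_density(mix, 400, 1e5, "liquid")
    st <- residual_state(mix, 400, liq$rho * 1e-12)
    expect_lt(abs(st$a_res), 1e-6)
    expect_lt(abs(st$Z - 1), 1e-6)
    expect_lt(max(abs(st$lnphi)), 1e-5)
  }
})

test_that("contribution breakdown sums to the total at every state", {
  set.seed(42)
  for (i in 1:12) {
    ts <- random_toy_state()
    st <- residual_state(ts$mix, ts$T, ts$rho)
    expect_lt(abs(st$a_hc + st$a_disp + st$a_assoc - st$a_res),
              1e-10 * max(1, abs(st$a_res)))
  }
})

test_that("analytic Z and ln phi match finite-difference oracles (20 states)", {
  set.seed(7)
  for (i in 1:20) {
    ts <- random_toy_state()
    st <- residual_state(ts$mix, ts$T, ts$rho)
    Zfd <- fd_Z(ts$mix, ts$T, ts$rho, ts$mix$x)
    expect_lt(abs(st$Z - Zfd) / abs(Zfd), 1e-6)
    lnfd <- fd_lnphi(ts$mix, ts$T, ts$rho, ts$mix$x)
    expect_lt(max(abs(st$lnphi - lnfd) / pmax(1, abs(lnfd))), 1e-6)
  }
})

test_that("association: no sites, vanishing energy, quadratic closed form", {
  # no component has sites -> empty table, zero contribution
  mix0 <- mixture(list(toy_api(eps = 0, kappa = 0, nd = 0, na = 0),
                       toy_polymer()), x = c(0.5, 0.5))
  st0 <- residual_state(mix0, 400, 1e-4)
  expect_equal(st0$a_assoc, 0)
  expect_equal(nrow(association_site_fractions(mix0, 400, 1e-4)), 0)

  # symmetric 2-site scheme: X solves rho*Delta*X^2 + X - 1 = 0
  a2 <- saft_component("A2", 200, segment_params(0.02, 3.5, 300, 1500, 0.02, 1, 1))
  mix <- mixture(list(a2), x = 1)
  T <- 350; rho <- 2e-3
  sf <- association_site_fractions(mix, T, rho)
  expect_equal(nrow(sf), 2)
  # independent closed form with Delta recomputed from its definition
  st <- residual_state(mix, T, rho)
  d <- 3.5 * (1 - 0.12 * exp(-3 * 300 / T))
  zeta2 <- pi / 6 * rho * (0.02 * 200) * d^2
  zeta3 <- pi / 6 * rho * (0.02 * 200) * d^3
  dts <- d / 2
  g <- 1 / (1 - zeta3) + dts * 3 * zeta2 / (1 - zeta3)^2 +
    dts^2 * 2 * zeta2^2 / (1 - zeta3)^3
  Delta <- 3.5^3 * g * 0.02 * expm1(1500 / T)
  Xclosed <- (-1 + sqrt(1 + 4 * rho * Delta)) / (2 * rho * Delta)
  expect_equal(sf$X, rep(Xclosed, 2), tolerance = 1e-9)

  # eps -> 0 with kappa > 0: all X -> 1 (kappa>0 alone needs sites+partner)
  aeps <- saft_component("AE", 200, segment_params(0.02, 3.5, 300, 1e-8, 0.02, 1, 1))
  sfe <- association_site_fractions(mixture(list(aeps), x = 1), T, rho)
  expect_true(all(abs(sfe$X - 1) < 1e-6))

  # bounds and sign of the association contribution
  expect_true(all(sf$X > 0 & sf$X <= 1))
  expect_lt(st$a_assoc, 0)
})

test_that("hard-chain term reduces to Carnahan-Starling for m = 1 spheres", {
  # single nonassociating spherical segment: a_hc == a_hs (chain term absent)
  M <- 100
  sph <- saft_component("SPH", M, segment_params(1 / M, 3.5, 250))
  expect_equal(sph$m_total, 1)
  mix <- mixture(list(sph), x = 1)
  T <- 300; rho <- 2e-3
  st <- residual_state(mix, T, rho)
  d <- 3.5 * (1 - 0.12 * exp(-3 * 250 / T))
  eta <- pi / 6 * rho * d^3
  a_cs <- (4 * eta - 3 * eta^2) / (1 - eta)^2
  expect_equal(st$a_hc, a_cs, tolerance = 1e-12)
  expect_equal(st$a_hc, st$a_hs, tolerance = 1e-12)
})

test_that("one-segment-type copolymer path equals the homopolymer path", {
  seg <- segment_params(0.03, 3.8, 260, 1500, 0.02)
  homo <- saft_component("H", 5000, seg, scheme = c(10, 10), role = "polymer")
  copo <- saft_component("C", 5000, list(a = seg, b = seg),
                         mass_fractions = c(0.55, 0.45), scheme = c(10, 10),
                         role = "polymer")
  api <- toy_api()
  mh <- mixture(list(api, homo), x = c(0.4, 0.6))
  mc <- mixture(list(api, copo), x = c(0.4, 0.6))
  for (rho in c(2e-4, 2.4e-4)) {   # liquid-like states with Z > 0
    sh <- residual_state(mh, 380, rho)
    sc <- residual_state(mc, 380, rho)
    expect_lt(abs(sh$a_res - sc$a_res) / abs(sh$a_res), 1e-12)
    expect_lt(max(abs(sh$lnphi - sc$lnphi) / pmax(1, abs(sh$lnphi))), 1e-12)
  }
})

test_that("component reordering permutes ln phi and gamma identically", {
  a <- toy_api(); b <- toy_polymer(M = 800)
  m12 <- mixture(list(a, b), x = c(0.3, 0.7))
  m21 <- mixture(list(b, a), x = c(0.7, 0.3))
  l12 <- ln_fugacity_coefficients(m12, 390, 1e5)
  l21 <- ln_fugacity_coefficients(m21, 390, 1e5)
  expect_equal(unname(l12), unname(rev(l21)), tolerance = 1e-12)
  g12 <- activity_coefficients(m12, 390, 1e5)
  g21 <- activity_coefficients(m21, 390, 1e5)
  expect_equal(unname(g12), unname(rev(g21)), tolerance = 1e-10)
})

test_that("density solver: round trip, branch hints, ideal-gas vapor", {
  mix <- mixture(list(toy_api(), toy_polymer()), x = c(0.5, 0.5))
  T <- 400
  liq <- solve_density(mix, T, 1e5, "liquid")
  expect_gt(liq$eta, 0); expect_lt(liq$eta, 0.7404)
  st <- residual_state(mix, T, liq$rho)
  expect_lt(abs(st$p - 1e5) / 1e5, 1e-9)

  # very low pressure vapor root is the ideal-gas density
  sm <- mixture(list(saft_component("S", 100, segment_params(0.02, 3.5, 250))), x = 1)
  pv <- 1
  vap <- solve_density(sm, T, pv, "vapor")
  rho_ig <- pv / (1.380649e-23 * T) * 1e-30
  expect_equal(vap$rho, rho_ig, tolerance = 1e-4)

  # Z continuous and increasing in rho around the liquid root
  rhos <- liq$rho * seq(0.98, 1.02, length.out = 9)
  Zs <- vapply(rhos, function(r) residual_state(mix, T, r)$Z, 0)
  expect_true(all(diff(Zs) > 0))
})

test_that("activity coefficients: pure limit, indistinguishable species, Gibbs-Duhem", {
  a <- toy_api()
  b <- toy_polymer(M = 1500)
  mix <- mixture(list(a, b))
  expect_equal(unname(activity_coefficients(mix, 400, 1e5, x = c(1, 0))[1]), 1,
               tolerance = 1e-10)

  # two components with identical parameters: gamma = 1 at all compositions
  a2 <- saft_component("Acopy", a$molar_mass, a$segments[[1]])
  mixid <- mixture(list(a, a2))
  for (x1 in c(0.1, 0.5, 0.9)) {
    g <- activity_coefficients(mixid, 400, 1e5, x = c(x1, 1 - x1))
    expect_equal(unname(g), c(1, 1), tolerance = 1e-8)
  }

  # Gibbs-Duhem: sum_i x_i dln(gamma_i)/dx = 0 along composition
  h <- 1e-5
  for (x1 in c(0.2, 0.5, 0.8)) {
    gp <- log(activity_coefficients(mix, 400, 1e5, x = c(x1 + h, 1 - x1 - h)))
    gm <- log(activity_coefficients(mix, 400, 1e5, x = c(x1 - h, 1 - x1 + h)))
    resid <- x1 * (gp[1] - gm[1]) / (2 * h) +
      (1 - x1) * (gp[2] - gm[2]) / (2 * h)
    expect_lt(abs(resid), 1e-5)
  }
})

test_that("liquid density of n-hexane from literature parameters is physical", {
  # m = 3.0576, sigma = 3.7983 A, u/kB = 236.77 K; experimental liquid
  # density at 298.15 K is about 0.655 g/cm3 -- the EOS should land close
  M <- 86.177
  hex <- saft_component("hexane", M, segment_params(3.0576 / M, 3.7983, 236.77))
  mix <- mixture(list(hex), x = 1)
  liq <- solve_density(mix, 298.15, 101325, "liquid")
  rho_g_cm3 <- liq$rho / 6.02214076e23 * M * 1e24
  expect_equal(rho_g_cm3, 0.655, tolerance = 0.05)
})
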