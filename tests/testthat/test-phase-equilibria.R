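# SLE points/curves, LLE binodals (alternating tangents vs brute force),
# AAPS scans, phase-diagram assembly.

test_that("SLE point: melting-point limit, ideal closed form, self-consistency", {
  lib <- parameter_library()
  npx <- build_component(lib, "NPX")
  poly <- toy_polymer(M = 3000)

  # T = T_m: dG_fus = 0, gamma(1) = 1, so x = 1
  s <- solve_sle_point(npx, poly, npx$fusion$T_m)
  expect_equal(s$x, 1, tolerance = 1e-12)
  expect_equal(s$w, 1, tolerance = 1e-12)

  # ideal mode: x = exp(-dG_fus/(RT)) in closed form
  sid <- solve_sle_point(npx, poly, 400, ideal = TRUE)
  R <- 8.31446261815324
  expect_equal(sid$x,
               exp(-fusion_gibbs_energy(npx$fusion, 400) / (R * 400)),
               tolerance = 1e-12)

  # full model: the stored point re-satisfies the SLE equation when gamma is
  # recomputed from scratch at the stored composition
  s <- solve_sle_point(npx, poly, 390)
  mix <- mixture(list(npx, poly))
  g <- activity_coefficients(mix, 390, 1e5, x = c(s$x, 1 - s$x))[[1]]
  resid <- log(s$x * g) + fusion_gibbs_energy(npx$fusion, 390) / (R * 390)
  expect_lt(abs(resid), 1e-10)

  expect_error(solve_sle_point(npx, poly, npx$fusion$T_m + 5), "melting point")
})

test_that("cross-association and kij shift the predicted solubility as expected", {
  api <- toy_api(eps = 1500)
  pol_assoc <- saft_component("PA", 2000,
                              segment_params(0.03, 3.8, 260, 0, 0.02, 0, 20),
                              role = "polymer")
  pol_plain <- toy_polymer(M = 2000)
  # induced cross-association (acceptor sites on the polymer) raises x
  xa <- solve_sle_point(api, pol_assoc, 370)$x
  xp <- solve_sle_point(api, pol_plain, 370)$x
  expect_gt(xa, xp)
  # increasing kij (weaker cross attraction) never increases x
  xs <- vapply(c(-0.02, 0, 0.02, 0.05), function(k)
    solve_sle_point(api, pol_plain, 370, kij = k)$x, 0)
  expect_true(all(diff(xs) < 0))
})

test_that("solubility curve: grids, monotonicity, warm starts, defaults", {
  api <- toy_api()
  poly <- toy_polymer(M = 2000)
  # single-point grid at T_m
  sc1 <- solubility_curve(api, poly, T_grid = api$fusion$T_m)
  expect_equal(nrow(sc1), 1)
  expect_equal(sc1$x_api, 1, tolerance = 1e-12)
  # ideal mode is monotonically decreasing as T decreases
  sci <- solubility_curve(api, poly, T_grid = seq(320, 420, 10), ideal = TRUE)
  expect_true(all(diff(sci$x_api) > 0))
  # full model curve solves every point and re-satisfies the SLE equation
  sc <- solubility_curve(api, poly, T_grid = seq(340, 420, 10))
  expect_false(any(is.na(sc$x_api)))
  expect_length(attr(sc, "failures"), 0)
  R <- 8.31446261815324
  mix <- mixture(list(api, poly))
  for (i in c(1, 4, 9)) {
    g <- activity_coefficients(mix, sc$T_K[i], 1e5,
                               x = c(sc$x_api[i], 1 - sc$x_api[i]))[[1]]
    resid <- log(sc$x_api[i] * g) +
      fusion_gibbs_energy(api$fusion, sc$T_K[i]) / (R * sc$T_K[i])
    expect_lt(abs(resid), 1e-10)
  }
  # default pressure is 0.1 MPa
  expect_equal(attr(sc, "p"), 1e5)
  expect_equal(solve_sle_point(api, poly, 400)$p, 1e5)
})

test_that("LLE: identical components never split; convex curves never split", {
  a <- toy_api()
  a2 <- saft_component("Acopy", a$molar_mass, a$segments[[1]])
  r <- solve_lle_point(a, a2, 350)
  expect_false(r$split)

  # no-split verdicts agree with a dense convexity scan of g_mix
  poly <- toy_polymer(M = 2000, u = 320)
  r2 <- solve_lle_point(a, poly, 400)   # favorable interactions: miscible
  xg <- seq(1e-4, 1 - 1e-4, length.out = 1000)
  gc <- mixing_gibbs_curve(a, poly, 400, x = xg)
  curv <- saftscreen:::second_diff(gc$x, gc$g_mix)
  expect_false(r2$split)
  expect_true(all(curv[!is.na(curv)] > 0))
})

test_that("alternating tangents agree with the convex-hull oracle on 5 toys", {
  toys <- list(
    list(api = toy_api(u = 400), poly = toy_polymer(M = 2000), T = 350, kij = 0.04),
    list(api = toy_api(u = 420), poly = toy_polymer(M = 1500, m_over_M = 0.028,
                                                    sigma = 3.7, u = 280),
         T = 330, kij = 0.03),
    list(api = toy_api(u = 380, eps = 800),
         poly = toy_polymer(M = 3000, m_over_M = 0.032, sigma = 4.0, u = 250),
         T = 370, kij = 0.05),
    list(api = toy_api(u = 440), poly = toy_polymer(M = 1000, m_over_M = 0.025,
                                                    sigma = 3.6, u = 300),
         T = 340, kij = 0.05),
    list(api = toy_api(u = 350, eps = 600),
         poly = toy_polymer(M = 5000, m_over_M = 0.03, sigma = 3.9, u = 240),
         T = 360, kij = 0.04))
  for (tt in toys) {
    alt <- solve_lle_point(tt$api, tt$poly, tt$T, kij = tt$kij)
    orc <- hull_binodal(tt$api, tt$poly, tt$T, kij = tt$kij)
    expect_true(alt$split)
    expect_false(is.null(orc))
    expect_lt(abs(alt$x1 - orc[1]), 1e-3)
    expect_lt(abs(alt$x2 - orc[2]), 1e-3)
    # equal-activity condition recomputed independently from fresh states
    mix <- mixture(list(tt$api, tt$poly), kij = tt$kij)
    a1 <- log(c(alt$x1, 1 - alt$x1)) +
      log(activity_coefficients(mix, tt$T, 1e5, x = c(alt$x1, 1 - alt$x1)))
    a2 <- log(c(1 - alt$x2_poly, alt$x2_poly)) +
      log(activity_coefficients(mix, tt$T, 1e5,
                                x = c(1 - alt$x2_poly, alt$x2_poly)))
    expect_lt(max(abs(a1 - a2)), 1e-8)
  }
})

test_that("AAPS scan: empty for miscible pairs, contiguous and narrowing near UCST", {
  a <- toy_api()
  a2 <- saft_component("Acopy", a$molar_mass, a$segments[[1]])
  bc0 <- aaps_scan(a, a2, T_range = c(300, 400), step = 50)
  expect_equal(nrow(bc0), 0)
  expect_false(has_aaps(bc0))

  # demixing toy pair: nonempty contiguous span, consistent with the
  # per-point solver
  api <- toy_api(u = 400); poly <- toy_polymer(M = 2000)
  bc <- aaps_scan(api, poly, T_range = c(300, 400), step = 20, kij = 0.04)
  expect_true(has_aaps(bc))
  expect_equal(bc$T_K, seq(min(bc$T_K), max(bc$T_K), by = 20))
  pt <- solve_lle_point(api, poly, bc$T_K[1], kij = 0.04)
  expect_equal(pt$x1, bc$x_L1[1], tolerance = 1e-9)

  # small-molecule UCST pair: the split narrows toward the last split T
  s1 <- saft_component("S1", 100, segment_params(0.025, 3.5, 280))
  s2 <- saft_component("S2", 120, segment_params(0.025, 3.6, 300))
  bcu <- aaps_scan(s1, s2, T_range = c(250, 400), step = 25, kij = 0.08)
  expect_true(has_aaps(bcu))
  width <- bcu$x_L2 - bcu$x_L1
  expect_true(all(diff(width) < 0))
  expect_lt(max(bcu$T_K), 400)   # closes before the top of the range
})

test_that("SLE roots reported inside a demixing window avoid the unstable region", {
  api <- toy_api(u = 400)
  poly <- toy_polymer(M = 2000)
  for (T in c(340, 360, 380)) {
    l <- solve_lle_point(api, poly, T, kij = 0.04)
    s <- solve_sle_point(api, poly, T, kij = 0.04, all_roots = TRUE)
    expect_true(l$split)
    expect_true(s$x <= l$spinodal[1] || s$x >= l$spinodal[2])
    # binodal straddles the solubility composition; root is the smallest
    expect_equal(s$x, min(s$roots))
  }
})

test_that("phase diagram bundles both curves and serializes round-trip", {
  api <- toy_api(u = 400)
  poly <- toy_polymer(M = 2000)
  pd <- build_phase_diagram(api, poly, kij = 0.04,
                            T_grid = seq(340, 420, 20),
                            aaps_range = c(300, 400), aaps_step = 25,
                            grid_n = 121)
  expect_s3_class(pd, "phase_diagram")
  expect_gt(nrow(pd$sle), 0)
  expect_true(has_aaps(pd$aaps))

  # miscible system: empty binodal, diagram still builds
  pd0 <- build_phase_diagram(toy_api(), toy_polymer(M = 2000, u = 320),
                             T_grid = seq(340, 420, 40),
                             aaps_range = c(340, 400), aaps_step = 30,
                             grid_n = 121)
  expect_false(has_aaps(pd0$aaps))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_phase_diagram(pd, path)
  rt <- read_phase_diagram(path)
  expect_setequal(unique(rt$branch), c("SLE", "AAPS_L1", "AAPS_L2"))
  sle_rt <- rt[rt$branch == "SLE", ]
  expect_equal(sle_rt$x_api, pd$sle$x_api, tolerance = 1e-9)
  expect_equal(rt[rt$branch == "AAPS_L1", "x_api"], pd$aaps$x_L1,
               tolerance = 1e-9)
  # byte-stable rewrite
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_phase_diagram(pd, path2)
  expect_identical(readLines(path), readLines(path2))
})
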