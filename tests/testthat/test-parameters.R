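# Parameter library, built-in tables, fusion thermodynamics.

test_that("built-in library has 7 REF APIs and 4 ALT sets", {
  lib <- parameter_library()
  expect_equal(sum(lib$apis$strategy == "REF"), 7)
  expect_equal(sum(lib$apis$strategy == "ALT"), 4)
  expect_setequal(lib$apis$api[lib$apis$strategy == "ALT"],
                  c("IBP", "IMC", "NPX", "PCM"))
  for (a in unique(lib$apis$api))
    expect_s3_class(build_component(lib, a, "REF"), "saft_component")
})

test_that("built-in constants match the packaged copy of the printed tables", {
  ref <- read.delim(system.file("extdata", "api_parameters.tsv",
                                package = "saftscreen"),
                    stringsAsFactors = FALSE)
  tab <- api_parameter_table()
  tab <- tab[order(tab$api, tab$strategy), ]
  ref <- ref[order(ref$api, ref$strategy), ]
  for (f in c("m_over_M", "sigma", "u", "eps_hb", "kappa_hb"))
    expect_identical(unname(tab[[f]]), unname(ref[[f]]))
  expect_identical(tab$scheme, ref$scheme)

  fref <- read.delim(system.file("extdata", "api_fusion.tsv",
                                 package = "saftscreen"),
                     stringsAsFactors = FALSE)
  ftab <- merge(api_fusion_table(), molar_mass_table()$api, by = "api")
  ftab <- ftab[order(ftab$api), ]; fref <- fref[order(fref$api), ]
  for (f in c("T_m", "dH_fus", "dCp_a", "dCp_b", "M"))
    expect_identical(unname(ftab[[f]]), unname(fref[[f]]))
})

test_that("build_component computes m = (m/M) * M and attaches fusion data", {
  lib <- parameter_library()
  sim <- build_component(lib, "SIM")
  expect_equal(sim$m_total, 0.010695 * 418.60, tolerance = 1e-12)
  expect_equal(round(sim$m_total, 3), 4.477)
  expect_equal(sim$segments[[1]]$n_donor, 3)
  expect_equal(sim$segments[[1]]$n_acceptor, 3)
  expect_equal(sim$fusion$T_m, 412.45)
  # no ALT set exists for NIF
  expect_error(build_component(lib, "NIF", "ALT"), "ALT")
  expect_error(build_component(lib, "NOSUCH"), "unknown component")
})

test_that("parameter file: overrides, schema validation, copolymers, round trip", {
  path <- withr::local_tempfile(fileext = ".dcf")
  writeLines(c(
    "type: segment", "name: segLA", "m_over_M: 0.025", "sigma: 3.7",
    "u: 280", "",
    "type: segment", "name: segGA", "m_over_M: 0.030", "sigma: 3.5",
    "u: 260", "",
    "type: polymer", "name: PLGAtoy", "M: 9877",
    "segments: segLA=0.554,segGA=0.446", "",
    "type: solvent", "name: ethanolish", "M: 46.07", "m_over_M: 0.0517",
    "sigma: 3.18", "u: 198.2", "eps_hb: 2653.4", "kappa_hb: 0.032",
    "scheme: 2 (1, 1)", ""), path)
  expect_silent(lib <- parameter_library(path))
  # copolymer expands to two segment types with the stated mass fractions
  plga <- build_component(lib, "PLGAtoy")
  expect_length(plga$segments, 2)
  expect_equal(plga$mass_fractions, c(0.554, 0.446))
  expect_equal(plga$m_total, (0.025 * 0.554 + 0.030 * 0.446) * 9877)
  expect_s3_class(build_component(lib, "ethanolish"), "saft_component")

  # override with warning
  path2 <- withr::local_tempfile(fileext = ".dcf")
  writeLines(c("type: api", "name: GSF", "strategy: REF",
               "m_over_M: 0.040179", "sigma: 9.9", "u: 221.26",
               "eps_hb: 1985.49", "kappa_hb: 0.02", "scheme: 4 (2, 2)", ""),
             path2)
  expect_warning(lib2 <- parameter_library(path2), "overrides")
  expect_equal(build_component(lib2, "GSF")$segments[[1]]$sigma, 9.9)

  # kappa_hb > 0 with eps_hb = 0 and no sites is a schema error
  path3 <- withr::local_tempfile(fileext = ".dcf")
  writeLines(c("type: solvent", "name: bad", "M: 100", "m_over_M: 0.03",
               "sigma: 3.5", "u: 250", "kappa_hb: 0.02", ""), path3)
  expect_error(parameter_library(path3), "association sites")

  # a polymer without M is rejected
  path4 <- withr::local_tempfile(fileext = ".dcf")
  writeLines(c("type: polymer", "name: noM", "segments: segLA", ""), path4)
  expect_error(parameter_library(path4), "missing field 'M'")

  # round trip: write -> read -> identical records
  out <- withr::local_tempfile(fileext = ".dcf")
  write_parameter_library(lib, out)
  lib_rt <- parameter_library(out)
  expect_equal(lib_rt$segments, lib$segments)
  expect_equal(lib_rt$polymers[order(names(lib_rt$polymers))],
               lib$polymers[order(names(lib$polymers))])
  expect_equal(lib_rt$solvents, lib$solvents)
})

test_that("fusion Gibbs energy: closed form vs numerical-integration oracle", {
  lib <- parameter_library()
  # NPX (constant dCp) at 400 K
  npx <- build_component(lib, "NPX")$fusion
  oracle <- function(fus, T) {
    dH <- fus$dH_fus * 1000
    i1 <- integrate(function(t) fus$dCp_a + fus$dCp_b * t, T, fus$T_m,
                    rel.tol = 1e-12)$value
    i2 <- integrate(function(t) (fus$dCp_a + fus$dCp_b * t) / t, T, fus$T_m,
                    rel.tol = 1e-12)$value
    dH * (1 - T / fus$T_m) - i1 + T * i2
  }
  expect_equal(fusion_gibbs_energy(npx, 400), oracle(npx, 400),
               tolerance = 1e-10)
  # IBP has a T-dependent dCp: the analytic path must track the full
  # integral, which differs from the constant-dCp shortcut
  ibp <- build_component(lib, "IBP")$fusion
  expect_equal(fusion_gibbs_energy(ibp, 310), oracle(ibp, 310),
               tolerance = 1e-10)
  shortcut <- ibp; shortcut$dCp_b <- 0
  expect_gt(abs(fusion_gibbs_energy(ibp, 310) -
                  fusion_gibbs_energy(shortcut, 310)), 1)
  # out of range
  expect_error(fusion_gibbs_energy(npx, 500), "out of range")
})

test_that("dG_fus is zero at T_m, positive and increasing below, for all APIs", {
  lib <- parameter_library()
  for (a in unique(lib$apis$api)) {
    fus <- build_component(lib, a)$fusion
    expect_equal(fusion_gibbs_energy(fus, fus$T_m), 0, tolerance = 1e-9)
    Ts <- seq(298, fus$T_m, length.out = 40)
    dG <- fusion_gibbs_energy(fus, Ts)
    expect_true(all(dG >= -1e-9))
    expect_true(all(diff(dG) < 0))   # decreasing toward zero at T_m
  }
})

test_that("mole/weight conversion identities and the GSF-in-EUD example", {
  expect_equal(x_to_w(1, 352.77, 212000), 1)
  expect_equal(x_to_w(0.5, 100, 100), 0.5)
  expect_equal(x_to_w(0.5, 352.77, 212000), 352.77 / (352.77 + 212000))
  expect_equal(signif(x_to_w(0.5, 352.77, 212000), 4), 1.661e-3)
  # exact round trip
  set.seed(1)
  xs <- runif(50)
  expect_equal(w_to_x(x_to_w(xs, 230.26, 25700), 230.26, 25700), xs,
               tolerance = 1e-14)
})

test_that("segment and component validation enforces the invariants", {
  expect_error(segment_params(0.03, -1, 250), "sigma")
  expect_error(segment_params(0.03, 3.5, 250, eps_hb = 100, kappa_hb = 0),
               "kappa_hb")
  seg <- segment_params(0.03, 3.5, 250)
  expect_error(saft_component("x", 100, list(seg, seg),
                              mass_fractions = c(0.6, 0.6)), "sum to 1")
  expect_error(mixture(list(toy_api(), toy_polymer()), x = c(0.5, 0.4)),
               "sum to 1")
  expect_error(mixture(list(toy_api(), toy_polymer()), x = c(-0.1, 1.1)),
               "nonnegative")
})
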