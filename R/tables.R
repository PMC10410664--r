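# Built-in parameter tables for the seven reference APIs.
#
# Values are stored exactly as printed in the primary literature compilation
# this package ships with: molar masses, fusion properties (melting point,
# enthalpy of fusion, linear liquid-crystal heat-capacity difference) and the
# two PC-SAFT parametrization strategies, REF (solubility-data-based) and ALT
# (additionally trained on pure-liquid densities and vapor pressures; only
# available for IBP, IMC, NPX and PCM).  Polymer PC-SAFT parameters are not
# built in: they are supplied by the user through a parameter library file or
# generated as fixtures (see make_fixture_components()).

.builtin_api_M <- function() {
  data.frame(
    api = c("GSF", "IBP", "IMC", "NPX", "NIF", "PCM", "SIM"),
    M = c(352.77, 206.28, 357.79, 230.26, 346.34, 151.16, 418.60),
    stringsAsFactors = FALSE)
}

.builtin_polymer_M <- function() {
  data.frame(
    polymer = c("EUD", "HPMCAS", "PDL", "PLGA50", "PLGA75", "PVA",
                "PVPK12", "PVPK25", "PVPK30", "PVPVAc64", "SOL"),
    M = c(212000, 120000, 16400, 9877, 12900, 32000,
          2500, 25700, 49000, 65000, 118000),
    stringsAsFactors = FALSE)
}

.builtin_fusion <- function() {
  data.frame(
    api = c("GSF", "IBP", "IMC", "NPX", "NIF", "PCM", "SIM"),
    polymorph = c("I", "I", "gamma", "I", "alpha", "I", "I"),
    T_m = c(491.85, 348.55, 433.35, 429.25, 445.75, 442.55, 412.45),
    dH_fus = c(37.90, 26.40, 38.10, 32.40, 39.30, 28.00, 27.75),
    dCp_a = c(93.84, 176.16440, 238.18385, 99.30, 121.22, 99.80, 278.77100),
    dCp_b = c(0, -0.3449480, -0.2785901, 0, 0, 0, -0.331300),
    stringsAsFactors = FALSE)
}

.builtin_api_params <- function() {
  data.frame(
    api = c("GSF", "IBP", "IBP", "IMC", "IMC", "NPX", "NPX", "NIF",
            "PCM", "PCM", "SIM"),
    strategy = c("REF", "REF", "ALT", "REF", "ALT", "REF", "ALT", "REF",
                 "REF", "ALT", "REF"),
    m_over_M = c(0.040179, 0.012226, 0.026365, 0.039920, 0.022072,
                 0.035200, 0.019162, 0.023470, 0.049775, 0.021406, 0.010695),
    sigma = c(3.3720, 4.4320, 4.0179, 3.5350, 3.8225, 2.9390, 4.1142,
              3.5810, 3.5080, 3.9819, 3.0711),
    u = c(221.26, 374.65, 309.40, 262.79, 374.51, 229.45, 470.92,
          309.44, 398.28, 432.09, 296.07),
    eps_hb = c(1985.49, 879.42, 516.47, 886.40, 1295.43, 934.20, 1202.65,
               1221.58, 1994.23, 1635.92, 1449.58),
    kappa_hb = c(0.02, 0.03, 0.089457, 0.02, 0.011350, 0.02, 0.009524,
                 0.02, 0.01, 0.054320, 0.01),
    scheme = c("4 (2, 2)", "4 (2, 2)", "4 (2, 2)", "6 (3, 3)", "6 (3, 3)",
               "4 (2, 2)", "4 (2, 2)", "4 (2, 2)", "4 (2, 2)", "4 (2, 2)",
               "6 (3, 3)"),
    stringsAsFactors = FALSE)
}

#' Built-in API tables
#'
#' Accessors for the packaged API data: PC-SAFT parameter sets (strategies
#' REF and ALT), fusion properties and molar masses.
#'
#' @return data.frames; see the parameter library vignette for the column
#'   meanings and units (m/M in mol/g, sigma in Angstrom, u/kB and eps_hb/kB
#'   in K, T_m in K, dH_fus in kJ/mol, dCp in J/(K mol)).
#' @export
api_parameter_table <- function() .builtin_api_params()

#' @rdname api_parameter_table
#' @export
api_fusion_table <- function() .builtin_fusion()

#' @rdname api_parameter_table
#' @export
molar_mass_table <- function() {
  list(api = .builtin_api_M(), polymer = .builtin_polymer_M())
}
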