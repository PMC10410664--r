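#' Fusion properties of a crystalline API
#'
#' Melting temperature, molar enthalpy of fusion at the melting point and the
#' (possibly temperature-dependent) difference between liquid and crystal
#' isobaric heat capacities, `dCp(T) = dCp_a + dCp_b * T` in J/(K mol).
#'
#' @param T_m melting temperature, K.
#' @param dH_fus molar enthalpy of fusion at `T_m`, kJ/mol (as tabulated).
#' @param dCp_a,dCp_b coefficients of the linear heat-capacity difference,
#'   J/(K mol) and J/(K^2 mol); `dCp_b = 0` for a constant difference.
#' @param polymorph optional polymorph label.
#' @return An object of class `"fusion_properties"`.
#' @export
fusion_properties <- function(T_m, dH_fus, dCp_a, dCp_b = 0, polymorph = NA) {
  stopifnot(T_m > 0, dH_fus > 0)
  Tchk <- seq(250, T_m, length.out = 50)
  if (any(dCp_a + dCp_b * Tchk <= 0))
    stop("dCp(T) must be positive over [250 K, T_m]")
  structure(list(T_m = T_m, dH_fus = dH_fus, dCp_a = dCp_a, dCp_b = dCp_b,
                 polymorph = polymorph),
            class = "fusion_properties")
}

#' @export
print.fusion_properties <- function(x, ...) {
  cat(sprintf("fusion: T_m = %g K, dH_fus = %g kJ/mol, dCp = %g %s J/(K mol)\n",
              x$T_m, x$dH_fus, x$dCp_a,
              if (x$dCp_b != 0) sprintf("%+g T", x$dCp_b) else ""))
  invisible(x)
}

#' Gibbs energy difference between supercooled liquid and crystal
#'
#' `dG_fus(T) = dH_fus (1 - T/T_m) - int_T^Tm dCp dT + T int_T^Tm dCp/T dT`,
#' with the linear `dCp(T)` integrated in closed form.  Positive below the
#' melting point, zero at `T = T_m`.
#'
#' @param fusion a [fusion_properties()] object.
#' @param T temperature(s), K; must satisfy `0 < T <= T_m`.
#' @return Gibbs energy difference in J/mol (vectorized over `T`).
#' @export
fusion_gibbs_energy <- function(fusion, T) {
  stopifnot(inherits(fusion, "fusion_properties"))
  if (any(T <= 0) || any(T > fusion$T_m + 1e-9))
    stop("T out of range: fusion_gibbs_energy requires 0 < T <= T_m")
  Tm <- fusion$T_m; a <- fusion$dCp_a; b <- fusion$dCp_b
  dH <- fusion$dH_fus * 1000              # kJ/mol -> J/mol
  intCp <- a * (Tm - T) + b / 2 * (Tm^2 - T^2)       # int_T^Tm dCp dT
  intCpT <- a * log(Tm / T) + b * (Tm - T)           # int_T^Tm dCp/T dT
  dH * (1 - T / Tm) - intCp + T * intCpT
}
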