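#' Define a mixture of PC-SAFT components
#'
#' @param components list of [saft_component()] objects.
#' @param x mole fractions (default equimolar).  Must be nonnegative and sum
#'   to 1 within 1e-12.
#' @param kij binary interaction matrix (symmetric, zero diagonal) or a single
#'   number applied to every unlike pair.  Default 0: pure prediction.
#' @return An object of class `"saft_mixture"`.
#' @export
mixture <- function(components, x = NULL, kij = 0) {
  if (inherits(components, "saft_component")) components <- list(components)
  stopifnot(length(components) >= 1,
            all(vapply(components, inherits, TRUE, "saft_component")))
  nc <- length(components)
  if (is.null(x)) x <- rep(1 / nc, nc)
  check_molefrac(x, nc)
  if (length(kij) == 1L) {
    k <- matrix(kij, nc, nc); diag(k) <- 0
  } else {
    k <- as.matrix(kij)
    stopifnot(nrow(k) == nc, ncol(k) == nc)
    if (max(abs(k - t(k))) > 1e-14) stop("kij matrix must be symmetric")
    if (any(diag(k) != 0)) stop("kij matrix must have a zero diagonal")
  }
  structure(list(components = components, x = x, kij = k,
                 model = compile_model(components, k)),
            class = "saft_mixture")
}

check_molefrac <- function(x, nc) {
  stopifnot(is.numeric(x), length(x) == nc)
  if (any(x < 0)) stop("mole fractions must be nonnegative")
  if (abs(sum(x) - 1) > 1e-12) stop("mole fractions must sum to 1 within 1e-12")
  invisible(TRUE)
}

# Flatten a component list into the arrays consumed by the C++ core.
compile_model <- function(components, kij) {
  comp <- integer(0); mseg <- sigma <- u <- eps <- kap <- nd <- na <- numeric(0)
  b1 <- b2 <- integer(0); bfrac <- numeric(0)
  mcomp <- numeric(length(components))
  off <- 0L
  for (i in seq_along(components)) {
    cm <- components[[i]]
    ns <- length(cm$segments)
    for (s in seq_len(ns)) {
      sp <- cm$segments[[s]]
      comp <- c(comp, i)
      mseg <- c(mseg, cm$m_alpha[s])
      sigma <- c(sigma, sp$sigma); u <- c(u, sp$u)
      eps <- c(eps, sp$eps_hb); kap <- c(kap, sp$kappa_hb)
      nd <- c(nd, sp$n_donor); na <- c(na, sp$n_acceptor)
    }
    b1 <- c(b1, off + cm$bonds$t1)
    b2 <- c(b2, off + cm$bonds$t2)
    bfrac <- c(bfrac, cm$bonds$frac)
    mcomp[i] <- cm$m_total
    off <- off + ns
  }
  list(comp = comp, mseg = mseg, sigma = sigma, u = u, eps_hb = eps,
       kappa_hb = kap, n_donor = nd, n_acceptor = na, kij = kij,
       bond_t1 = b1, bond_t2 = b2, bond_frac = bfrac, mcomp = mcomp)
}

#' @export
print.saft_mixture <- function(x, ...) {
  cat(sprintf("<saft_mixture> %d components: %s\n", length(x$components),
              paste(vapply(x$components, `[[`, "", "name"), collapse = ", ")))
  cat("  x =", paste(signif(x$x, 6), collapse = ", "), "\n")
  if (any(x$kij != 0)) cat("  nonzero kij present\n")
  invisible(x)
}

phase_hint_code <- function(phase) {
  switch(match.arg(phase, c("liquid", "vapor", "auto")),
         liquid = 1L, vapor = 2L, auto = 0L)
}

#' Residual thermodynamic state at given temperature and density
#'
#' Evaluates the reduced residual Helmholtz energy `a_res = A_res/(N kB T)`
#' with its hard-chain, dispersion and association breakdown, the
#' compressibility factor `Z = 1 + rho (d a_res / d rho)`, the pressure and
#' the fugacity-coefficient logs.
#'
#' @param mix a [mixture()].
#' @param T temperature, K.
#' @param rho number density, molecules per cubic Angstrom.
#' @param x optional mole-fraction override.
#' @return list with elements `rho`, `eta`, `a_hc`, `a_disp`, `a_assoc`,
#'   `a_res`, `Z`, `p` (Pa), `lnphi`, and association site fractions.
#' @export
residual_state <- function(mix, T, rho, x = mix$x) {
  stopifnot(inherits(mix, "saft_mixture"), T > 0, rho > 0)
  check_molefrac(x, length(mix$components))
  cpp_eval(mix$model, T, rho, x, TRUE)
}

#' Compressibility factor at given temperature and density
#'
#' `Z = 1 + rho (d a_res / d rho)` at fixed temperature and composition,
#' from the analytic density derivative of the residual Helmholtz energy.
#'
#' @inheritParams residual_state
#' @return scalar Z.
#' @export
compressibility_factor <- function(mix, T, rho, x = mix$x) {
  residual_state(mix, T, rho, x)$Z
}

#' Solve for the density at given temperature and pressure
#'
#' Safeguarded root search on the packing fraction eta in (0, 0.7404).  With
#' `phase = "auto"` and multiple density roots, the root with the lowest
#' Gibbs energy is returned.
#'
#' @inheritParams residual_state
#' @param p pressure, Pa.
#' @param phase `"liquid"`, `"vapor"` or `"auto"`.
#' @return list with `rho` (molecules/A^3) and `eta`.
#' @export
solve_density <- function(mix, T, p, phase = "liquid", x = mix$x) {
  stopifnot(inherits(mix, "saft_mixture"), T > 0, p > 0)
  check_molefrac(x, length(mix$components))
  cpp_density(mix$model, T, p, x, phase_hint_code(phase))
}

#' Fugacity-coefficient logs at given temperature and pressure
#'
#' @inheritParams solve_density
#' @return named numeric vector of ln(phi_i).
#' @export
ln_fugacity_coefficients <- function(mix, T, p, phase = "liquid", x = mix$x) {
  st <- saft_state_tp(mix, T, p, phase, x)
  setNames(st$lnphi, vapply(mix$components, `[[`, "", "name"))
}

# density solve + full evaluation in one call
saft_state_tp <- function(mix, T, p, phase = "liquid", x = mix$x) {
  stopifnot(inherits(mix, "saft_mixture"), T > 0, p > 0)
  check_molefrac(x, length(mix$components))
  cpp_state_tp(mix$model, T, p, x, phase_hint_code(phase))
}

#' Activity coefficients in the liquid mixture
#'
#' `gamma_i = phi_i(T, p, x) / phi_i^pure(T, p)`, both on the liquid branch.
#' Pure-component reference states that fail to yield a liquid density root
#' are reported distinctly from mixture failures.
#'
#' @inheritParams solve_density
#' @return named vector of activity coefficients.
#' @export
activity_coefficients <- function(mix, T, p = 1e5, x = mix$x) {
  nc <- length(mix$components)
  st <- tryCatch(saft_state_tp(mix, T, p, "liquid", x),
                 error = function(e) stop("mixture state failed: ",
                                          conditionMessage(e), call. = FALSE))
  lnph_pure <- numeric(nc)
  for (i in seq_len(nc)) {
    xi <- rep(0, nc); xi[i] <- 1
    sti <- tryCatch(saft_state_tp(mix, T, p, "liquid", xi),
                    error = function(e) stop("pure liquid state of component ",
                                             i, " failed: ", conditionMessage(e),
                                             call. = FALSE))
    lnph_pure[i] <- sti$lnphi[i]
  }
  setNames(exp(st$lnphi - lnph_pure),
           vapply(mix$components, `[[`, "", "name"))
}

#' @rdname activity_coefficients
#' @param i component index.
#' @export
activity_coefficient <- function(mix, i, T, p = 1e5, x = mix$x) {
  activity_coefficients(mix, T, p, x)[[i]]
}

#' Association site fractions
#'
#' Fraction of hydrogen-bonding sites of each class (component, segment type,
#' donor/acceptor) not bonded, from the mass-action equations solved by damped
#' successive substitution (tolerance 1e-12).
#'
#' @inheritParams residual_state
#' @return data.frame with columns `component`, `segment`, `site`, `n`, `X`.
#'   Zero rows when no component carries sites.
#' @export
association_site_fractions <- function(mix, T, rho, x = mix$x) {
  st <- residual_state(mix, T, rho, x)
  m <- mix$model
  don <- which(m$n_donor > 0); acc <- which(m$n_acceptor > 0)
  nm <- vapply(mix$components, `[[`, "", "name")
  out <- data.frame(
    component = nm[m$comp[c(don, acc)]],
    segment = c(don, acc),
    site = rep(c("donor", "acceptor"), c(length(don), length(acc))),
    n = c(m$n_donor[don], m$n_acceptor[acc]),
    X = c(st$XD, st$XA))
  rownames(out) <- NULL
  out
}

#' Convert between mole and weight fraction of the API in a binary
#'
#' `w = x M_API / (x M_API + (1 - x) M_poly)`; the inverse is exact.
#'
#' @param value mole fraction (direction `"x_to_w"`) or weight fraction
#'   (direction `"w_to_x"`), in `[0, 1]`; vectorized.
#' @param M_api,M_poly molar masses, g/mol.
#' @param direction conversion direction.
#' @return converted fraction(s).
#' @export
mole_weight_convert <- function(value, M_api, M_poly,
                                direction = c("x_to_w", "w_to_x")) {
  direction <- match.arg(direction)
  stopifnot(all(value >= 0 & value <= 1), M_api > 0, M_poly > 0)
  if (direction == "x_to_w") {
    value * M_api / (value * M_api + (1 - value) * M_poly)
  } else {
    (value / M_api) / (value / M_api + (1 - value) / M_poly)
  }
}

#' @rdname mole_weight_convert
#' @param x,w fractions to convert.
#' @export
x_to_w <- function(x, M_api, M_poly) mole_weight_convert(x, M_api, M_poly, "x_to_w")

#' @rdname mole_weight_convert
#' @export
w_to_x <- function(w, M_api, M_poly) mole_weight_convert(w, M_api, M_poly, "w_to_x")
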