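# Solid-liquid equilibrium: solubility of a crystalline API in an amorphous
# polymer (or a low-M solvent).  The equilibrium composition satisfies
#   ln(x_API * gamma_API(T, p, x)) = -dG_fus(T) / (R T),
# with gamma from PC-SAFT and dG_fus from the fusion properties.

# gamma evaluator for the API (component 1) in a binary; caches the pure
# reference states per temperature.
make_lngamma_api <- function(mix, T, p) {
  pure_api <- saft_state_tp(mix, T, p, "liquid", c(1, 0))$lnphi[1]
  function(x) {
    st <- saft_state_tp(mix, T, p, "liquid", c(x, 1 - x))
    st$lnphi[1] - pure_api
  }
}

#' Solve one solubility (SLE) point
#'
#' Damped successive substitution on
#' `x <- exp(-dG_fus/(RT)) / gamma_API(x)` with a bracketed root-finding
#' fallback on `f(x) = ln x + ln gamma_API(x) + dG_fus/(RT)`.  When several
#' roots exist (possible inside a demixing region), the smallest root in
#' (0, 1] is returned and all roots are reported via `all_roots = TRUE`.
#'
#' @param api API [saft_component()] carrying [fusion_properties()] (or pass
#'   `fusion` explicitly).
#' @param polymer polymer or solvent [saft_component()].
#' @param T temperature, K (must not exceed the melting point).
#' @param kij binary interaction parameter (default 0, pure prediction).
#' @param p pressure, Pa (default 0.1 MPa).
#' @param fusion optional [fusion_properties()] override.
#' @param x_init optional starting mole fraction (warm start).
#' @param ideal if `TRUE`, force `gamma = 1` (ideal-solubility closed form).
#' @param all_roots also scan for and report every root.
#' @param tol residual tolerance on `f(x)`.
#' @return list with `T`, `x` (mole fraction), `w` (weight fraction),
#'   `gamma`, `residual`, `converged`, and optionally `roots`.
#' @export
solve_sle_point <- function(api, polymer, T, kij = 0, p = 1e5, fusion = NULL,
                            x_init = NULL, ideal = FALSE, all_roots = FALSE,
                            tol = 1e-10) {
  fus <- fusion %||% api$fusion
  if (is.null(fus)) stop("API component has no fusion properties")
  if (T > fus$T_m + 1e-9) stop("T exceeds the melting point T_m = ", fus$T_m, " K")
  rhs <- -fusion_gibbs_energy(fus, T) / (.R_GAS * T)   # = ln(x gamma), <= 0

  mix <- mixture(list(api, polymer), kij = kij)
  lngamma <- if (ideal) function(x) 0 else make_lngamma_api(mix, T, p)
  f <- function(x) log(x) + lngamma(x) - rhs

  x <- x_init %||% min(1, exp(rhs))
  converged <- FALSE
  lam <- 0.7
  lng <- lngamma(x)
  for (it in seq_len(50)) {
    res <- log(x) + lng - rhs
    if (abs(res) < tol) { converged <- TRUE; break }
    lnx <- (1 - lam) * log(x) + lam * (rhs - lng)
    x <- exp(min(lnx, 0))
    lng <- lngamma(x)
  }
  if (!converged) {
    sol <- tryCatch(
      uniroot(f, c(1e-12, 1), tol = 1e-14, maxiter = 200),
      error = function(e) stop("SLE iteration failed to converge at T = ", T,
                               " K: ", conditionMessage(e), call. = FALSE))
    x <- sol$root
    lng <- lngamma(x)
    converged <- abs(f(x)) < 1e-8
  }

  roots <- NULL
  if (all_roots) {
    lnxg <- seq(log(1e-8), 0, length.out = 240)
    fg <- vapply(lnxg, function(l) f(exp(l)), 0)
    sgn <- sign(fg)
    roots <- numeric(0)
    for (i in seq_len(length(lnxg) - 1)) {
      if (is.na(sgn[i]) || is.na(sgn[i + 1])) next
      if (sgn[i] != sgn[i + 1]) {
        r <- uniroot(function(l) f(exp(l)), c(lnxg[i], lnxg[i + 1]),
                     tol = 1e-13)$root
        roots <- c(roots, exp(r))
      }
    }
    if (abs(fg[length(fg)]) < tol) roots <- c(roots, 1)
    roots <- sort(unique(roots))
    if (length(roots) > 0) x <- roots[1]
  }

  list(T = T, x = x,
       w = x_to_w(x, api$molar_mass, polymer$molar_mass),
       gamma = exp(lngamma(x)), residual = f(x), converged = converged,
       roots = roots, kij = kij, p = p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Solubility curve of an API in a polymer
#'
#' One SLE point per grid temperature, solved from the melting point
#' downward with warm starts from the neighboring solution.  Failed points
#' are recorded (with a message) rather than aborting the curve.
#'
#' @inheritParams solve_sle_point
#' @param T_grid sorted temperature grid, K; defaults to 1 K steps from
#'   298 K up to and including `T_m`.
#' @return data.frame of class `"solubility_curve"` with columns `T_K`,
#'   `x_api`, `w_api`; attributes `api`, `polymer`, `kij`, `p`, `failures`.
#' @export
solubility_curve <- function(api, polymer, T_grid = NULL, kij = 0, p = 1e5,
                             fusion = NULL, ideal = FALSE) {
  fus <- fusion %||% api$fusion
  if (is.null(fus)) stop("API component has no fusion properties")
  if (is.null(T_grid)) T_grid <- unique(c(seq(298, fus$T_m, by = 1), fus$T_m))
  T_grid <- sort(T_grid)
  if (max(T_grid) > fus$T_m + 1e-9) stop("T_grid exceeds T_m")

  n <- length(T_grid)
  xs <- ws <- rep(NA_real_, n)
  failures <- character(0)
  x_prev <- NULL
  for (i in rev(seq_len(n))) {
    res <- tryCatch(
      solve_sle_point(api, polymer, T_grid[i], kij = kij, p = p, fusion = fus,
                      x_init = x_prev, ideal = ideal),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("T = %.2f K: %s", T_grid[i],
                                      conditionMessage(res)))
    } else {
      xs[i] <- res$x; ws[i] <- res$w
      x_prev <- res$x
    }
  }
  if (all(is.na(xs)))
    stop("solubility curve failed at every grid temperature; first error: ",
         failures[1])
  out <- data.frame(T_K = T_grid, x_api = xs, w_api = ws)
  structure(out,
            class = c("solubility_curve", "data.frame"),
            api = api$name, polymer = polymer$name, kij = kij, p = p,
            strategy = attr(api, "strategy"), failures = failures)
}
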