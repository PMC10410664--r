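# Liquid-liquid equilibrium (amorphous-amorphous phase separation, AAPS).
#
# Binodal points are located with an alternating-tangent construction on the
# reduced Gibbs energy of mixing
#   G(x)/RT = x ln a_API(x) + (1 - x) ln a_poly(x),    a_i = x_i gamma_i,
# searching for the composition of one phase at a time: the API activity
# equation is solved for the dilute phase at fixed concentrated-phase
# composition, then the polymer activity equation for the concentrated phase,
# until both activities match across the phases.  Starting compositions come
# from a spinodal pre-check (sign changes of the second composition
# derivative of G on a coarse grid) plus a convex-hull bridge of the grid.

# Evaluate ln(activity) of both components over an x grid (API mole
# fraction) in one compiled call; rows for the two pure liquids included.
binary_lnactivity_grid <- function(mix, T, p, xg) {
  xmat <- rbind(cbind(xg, 1 - xg), c(1, 0), c(0, 1))
  out <- cpp_lnphi_grid(mix$model, T, p, xmat, 1L)
  n <- length(xg)
  lnphi <- out$lnphi
  pureA <- lnphi[n + 1, 1]
  pureP <- lnphi[n + 2, 2]
  list(lnaA = log(xg) + lnphi[seq_len(n), 1] - pureA,
       lnaP = log1p(-xg) + lnphi[seq_len(n), 2] - pureP,
       pureA = pureA, pureP = pureP)
}

#' Reduced Gibbs energy of mixing curve for an API-polymer binary
#'
#' @inheritParams solve_sle_point
#' @param x grid of API mole fractions in (0, 1).
#' @return data.frame with `x`, `lna_api`, `lna_poly` and `g_mix`
#'   (= `G_mix/(RT)` per mole of molecules).
#' @export
mixing_gibbs_curve <- function(api, polymer, T, x = NULL, kij = 0, p = 1e5) {
  if (is.null(x)) x <- lle_default_grid(201)
  stopifnot(all(x > 0 & x < 1))
  mix <- mixture(list(api, polymer), kij = kij)
  g <- binary_lnactivity_grid(mix, T, p, x)
  data.frame(x = x, lna_api = g$lnaA, lna_poly = g$lnaP,
             g_mix = x * g$lnaA + (1 - x) * g$lnaP)
}

lle_default_grid <- function(n) {
  sort(unique(c(10^seq(-8, -2, length.out = 25),
                seq(0.005, 0.995, length.out = n),
                1 - 10^seq(-2, -8, length.out = 25))))
}

# second derivative on a nonuniform grid (central three-point formula)
second_diff <- function(x, y) {
  n <- length(x)
  i <- 2:(n - 1)
  hm <- x[i] - x[i - 1]; hp <- x[i + 1] - x[i]
  d2 <- 2 * (y[i - 1] / (hm * (hm + hp)) - y[i] / (hm * hp) +
               y[i + 1] / (hp * (hm + hp)))
  c(NA, d2, NA)
}

# indices of the lower convex hull of (x, y), x ascending
lower_hull <- function(x, y) {
  keep <- integer(0)
  for (i in seq_along(x)) {
    while (length(keep) >= 2) {
      a <- keep[length(keep) - 1]; b <- keep[length(keep)]
      # pop b if it lies above chord a--i
      if ((x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a]) < 0)
        keep <- keep[-length(keep)]
      else break
    }
    keep <- c(keep, i)
  }
  keep
}

#' Solve one liquid-liquid (AAPS binodal) point
#'
#' @inheritParams solve_sle_point
#' @param grid_n resolution of the composition grid used for the spinodal
#'   pre-check and the starting values.
#' @param tol convergence tolerance on the ln-activity match across phases.
#' @param max_iter maximum alternating iterations.
#' @return list with `split` (logical), and when a split exists `x1 < x2`
#'   (API mole fractions of the API-lean and API-rich phase), weight-fraction
#'   counterparts `w1`, `w2`, the equal-activity `residual`, and the spinodal
#'   interval.  A detected spinodal whose tangent iteration fails raises an
#'   error (distinct from the clean no-split return).
#' @export
solve_lle_point <- function(api, polymer, T, kij = 0, p = 1e5, grid_n = 201,
                            tol = 1e-8, max_iter = 100) {
  mix <- mixture(list(api, polymer), kij = kij)
  xg <- lle_default_grid(grid_n)
  gg <- binary_lnactivity_grid(mix, T, p, xg)
  G <- xg * gg$lnaA + (1 - xg) * gg$lnaP
  curv <- second_diff(xg, G)
  unstable <- which(!is.na(curv) & curv < 0)
  if (length(unstable) == 0)
    return(list(split = FALSE, T = T))
  s1 <- xg[min(unstable)]; s2 <- xg[max(unstable)]

  # hull edge bridging the unstable window provides starting phases
  hull <- lower_hull(xg, G)
  x1 <- NA_real_; x2 <- NA_real_
  for (k in seq_len(length(hull) - 1)) {
    if (xg[hull[k]] <= s1 && xg[hull[k + 1]] >= s2) {
      x1 <- xg[hull[k]]; x2 <- xg[hull[k + 1]]
      break
    }
  }
  if (is.na(x1)) { x1 <- max(min(xg), s1 / 2); x2 <- min(max(xg), (s2 + 1) / 2) }

  # Phase variables in log space: u = ln(x_API) for the API-lean phase L1,
  # v = ln(x_poly) for the API-rich phase L2.  Log space keeps extreme
  # partitioning representable (the polymer content of the rich phase can be
  # below double-precision resolution of 1 - x).
  cache <- new.env(parent = emptyenv())
  lna_lean <- function(u) {    # c(ln a_API, ln a_poly) at x_API = exp(u)
    key <- sprintf("L%.17g", u)
    if (!is.null(cache[[key]])) return(cache[[key]])
    xA <- exp(u)
    st <- saft_state_tp(mix, T, p, "liquid", c(xA, 1 - xA))
    val <- c(u + st$lnphi[1] - gg$pureA,
             log1p(-xA) + st$lnphi[2] - gg$pureP)
    cache[[key]] <- val
    val
  }
  lna_rich <- function(v) {    # c(ln a_API, ln a_poly) at x_poly = exp(v)
    key <- sprintf("R%.17g", v)
    if (!is.null(cache[[key]])) return(cache[[key]])
    xP <- exp(v)
    st <- saft_state_tp(mix, T, p, "liquid", c(1 - xP, xP))
    val <- c(log1p(-xP) + st$lnphi[1] - gg$pureA,
             v + st$lnphi[2] - gg$pureP)
    cache[[key]] <- val
    val
  }

  u <- log(x1)
  v <- log(max(1 - x2, 1e-12))
  u_min <- log(1e-300); v_min <- log(1e-300)
  u_max <- log(min(s1, 0.9999999)); v_max <- log(max(1 - s2, 1e-12))
  converged <- FALSE
  resid <- c(NA_real_, NA_real_)
  for (it in seq_len(max_iter)) {
    # API-lean phase from the API activity match (one phase at a time)
    tA <- lna_rich(v)[1]
    f1 <- function(uu) lna_lean(uu)[1] - tA
    f1lo <- f1(u_min); f1hi <- f1(u_max)
    u <- if (f1lo * f1hi <= 0)
      uniroot(f1, c(u_min, u_max), f.lower = f1lo, f.upper = f1hi,
              tol = 1e-13)$root
    else if (abs(f1lo) < abs(f1hi)) u_min else u_max
    # API-rich phase from the polymer activity match
    tP <- lna_lean(u)[2]
    f2 <- function(vv) lna_rich(vv)[2] - tP
    f2lo <- f2(v_min); f2hi <- f2(v_max)
    v <- if (f2lo * f2hi <= 0)
      uniroot(f2, c(v_min, v_max), f.lower = f2lo, f.upper = f2hi,
              tol = 1e-13)$root
    else if (abs(f2lo) < abs(f2hi)) v_min else v_max
    resid <- abs(lna_lean(u) - lna_rich(v))
    if (max(resid) < tol) { converged <- TRUE; break }
  }
  x1 <- exp(u)
  xp2 <- exp(v)
  x2 <- 1 - xp2
  if (x2 - x1 < 1e-5)   # trivial root: treat as no split (near-critical)
    return(list(split = FALSE, T = T, near_critical = TRUE))
  if (!converged)
    stop(sprintf(paste0("alternating-tangent iteration did not converge at ",
                        "T = %.2f K (spinodal [%.4g, %.4g] present; ",
                        "residual %.3g)"), T, s1, s2, max(resid)))
  MA <- api$molar_mass; MP <- polymer$molar_mass
  list(split = TRUE, T = T, x1 = x1, x2 = x2, x2_poly = xp2,
       w1 = x_to_w(x1, MA, MP),
       w2 = MA / (MA + xp2 / (1 - xp2) * MP),
       residual = resid, spinodal = c(s1, s2))
}

#' Temperature scan for amorphous-amorphous phase separation
#'
#' Runs [solve_lle_point()] over a temperature range (default 200-600 K) and
#' collects the binodal points.  Per-temperature failures are logged in the
#' `failures` attribute and do not abort the scan; an empty curve means no
#' AAPS is predicted.
#'
#' @inheritParams solve_lle_point
#' @param T_range scan bounds, K.
#' @param step scan step, K.
#' @return data.frame of class `"binodal_curve"` with columns `T_K`, `x_L1`,
#'   `x_L2`, `w_L1`, `w_L2`; attributes `aaps` (logical flag) and `failures`.
#' @export
aaps_scan <- function(api, polymer, T_range = c(200, 600), step = 2, kij = 0,
                      p = 1e5, grid_n = 201) {
  Ts <- seq(T_range[1], T_range[2], by = step)
  rows <- list(); failures <- character(0)
  for (T in Ts) {
    res <- tryCatch(
      solve_lle_point(api, polymer, T, kij = kij, p = p, grid_n = grid_n),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("T = %.1f K: %s", T, conditionMessage(res)))
    } else if (isTRUE(res$split)) {
      rows[[length(rows) + 1]] <- data.frame(
        T_K = T, x_L1 = res$x1, x_L2 = res$x2, w_L1 = res$w1, w_L2 = res$w2)
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(T_K = numeric(0), x_L1 = numeric(0), x_L2 = numeric(0),
               w_L1 = numeric(0), w_L2 = numeric(0))
  structure(out, class = c("binodal_curve", "data.frame"),
            api = api$name, polymer = polymer$name, kij = kij, p = p,
            aaps = nrow(out) > 0, failures = failures)
}

#' @rdname aaps_scan
#' @param binodal a `"binodal_curve"`.
#' @export
has_aaps <- function(binodal) isTRUE(attr(binodal, "aaps"))
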