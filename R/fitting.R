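# Simulated-annealing estimation of API PC-SAFT parameters from solubility
# data in low-M solvents, mirroring the routine parametrization strategy:
# kappa_hb is held fixed (0.01 by default) and the four parameters m, sigma,
# u/kB and eps_hb/kB are regressed.

#' Configuration for an API parameter fit
#'
#' @param bounds named list of `c(lower, upper)` bounds for `m` (total
#'   segment number), `sigma` (A), `u` (K) and `eps_hb` (K).
#' @param kappa_hb fixed association volume (freed only by adding it to
#'   `bounds`; default fixed at 0.01 as routinely done for APIs).
#' @param scheme association scheme, `c(donor, acceptor)` or `"Z (X, Y)"`
#'   (default the symmetric six-site scheme `6 (3, 3)`).
#' @param t_init,t_final,cooling,moves_per_level annealing schedule: initial
#'   and final Metropolis temperatures (loss units), geometric cooling
#'   factor, moves per temperature level.
#' @param proposal_frac Gaussian proposal s.d. as a fraction of each bound
#'   width.
#' @param loss `"lnx"` (default): mean squared deviation in `ln x_API` from
#'   fully solved SLE points; `"residual"`: mean squared SLE-equation
#'   residual evaluated at the data (cheaper, no inner solve).
#' @param polish run a deterministic Nelder-Mead refinement from the best
#'   annealing state (default `TRUE`).
#' @param seed RNG seed (fit is bit-reproducible under a fixed seed).
#' @return list of class `"fit_config"`.
#' @export
fit_config <- function(bounds = list(m = c(1.5, 25), sigma = c(2.5, 4.8),
                                     u = c(150, 550), eps_hb = c(200, 4000)),
                       kappa_hb = 0.01, scheme = c(3, 3),
                       t_init = 1.0, t_final = 0.01, cooling = 0.95,
                       moves_per_level = 50, proposal_frac = 0.02,
                       loss = c("lnx", "residual"), polish = TRUE, seed = 1) {
  loss <- match.arg(loss)
  stopifnot(all(vapply(bounds, function(b)
    length(b) == 2 && all(is.finite(b)) && b[1] < b[2], TRUE)))
  stopifnot(t_init > t_final, t_final > 0, cooling > 0, cooling < 1,
            moves_per_level >= 1)
  structure(list(bounds = bounds, kappa_hb = kappa_hb,
                 scheme = parse_scheme(scheme), t_init = t_init,
                 t_final = t_final, cooling = cooling,
                 moves_per_level = moves_per_level,
                 proposal_frac = proposal_frac, loss = loss,
                 polish = polish, seed = seed),
            class = "fit_config")
}

# API component from a candidate parameter vector
api_from_params <- function(par, api_M, scheme, kappa_hb, fusion) {
  saft_component("fit_candidate", api_M,
                 segment_params(par[["m"]] / api_M, par[["sigma"]], par[["u"]],
                                eps_hb = par[["eps_hb"]],
                                kappa_hb = if ("kappa_hb" %in% names(par))
                                  par[["kappa_hb"]] else kappa_hb,
                                n_donor = scheme[["donor"]],
                                n_acceptor = scheme[["acceptor"]]),
                 role = "API", fusion = fusion)
}

# fast inline SLE solve (mole fraction in a solvent) reusing a prebuilt
# mixture and a cached pure-API reference state
sle_x_fast <- function(mix, rhs, T, p, x_init = NULL, pureA = NULL) {
  if (is.null(pureA)) pureA <- saft_state_tp(mix, T, p, "liquid", c(1, 0))$lnphi[1]
  lng <- function(x) saft_state_tp(mix, T, p, "liquid", c(x, 1 - x))$lnphi[1] - pureA
  x <- x_init %||% min(1, exp(rhs))
  g <- lng(x)
  for (it in seq_len(40)) {
    res <- log(x) + g - rhs
    if (abs(res) < 1e-9) return(x)
    x <- exp(min(0.3 * log(x) + 0.7 * (rhs - g), 0))
    g <- lng(x)
  }
  uniroot(function(xx) log(xx) + lng(xx) - rhs, c(1e-12, 1), tol = 1e-12)$root
}

#' Loss of a candidate API parameter set against solvent solubility data
#'
#' Default loss: mean squared deviation in `ln x_API` over all (solvent, T)
#' points, with the model solubility obtained by solving the SLE equation at
#' each datum.  Candidate sets for which the solver fails (or that fall
#' outside the bounds) receive a large penalty value.
#'
#' @param par named vector with `m`, `sigma`, `u`, `eps_hb` (optionally
#'   `kappa_hb`).
#' @param data data.frame with columns `solvent`, `T_K`, `x_api`.
#' @param solvents named list of solvent [saft_component()]s.
#' @param api_M API molar mass, g/mol.
#' @param fusion API [fusion_properties()].
#' @param config a [fit_config()].
#' @param penalty loss value assigned to infeasible candidates.
#' @return scalar loss, with attribute `residuals` (per-datum `ln x` errors)
#'   when finite.
#' @export
fit_objective <- function(par, data, solvents, api_M, fusion, config,
                          penalty = 1e6) {
  stopifnot(inherits(config, "fit_config"))
  for (nm in names(config$bounds)) {
    b <- config$bounds[[nm]]
    if (par[[nm]] < b[1] || par[[nm]] > b[2]) return(penalty)
  }
  api <- tryCatch(api_from_params(par, api_M, config$scheme, config$kappa_hb,
                                  fusion),
                  error = function(e) NULL)
  if (is.null(api)) return(penalty)
  p <- 1e5
  # the pure-API liquid reference depends on T only: solve once per T
  uT <- unique(data$T_K)
  mix0 <- mixture(list(api, solvents[[data$solvent[1]]]))
  pureA <- tryCatch(
    vapply(uT, function(T)
      saft_state_tp(mix0, T, p, "liquid", c(1, 0))$lnphi[1], 0),
    error = function(e) NULL)
  if (is.null(pureA)) return(penalty)
  names(pureA) <- sprintf("%.10g", uT)
  resids <- numeric(nrow(data))
  for (sv in unique(data$solvent)) {
    idx <- which(data$solvent == sv)
    idx <- idx[order(-data$T_K[idx])]
    mix <- mixture(list(api, solvents[[sv]]))
    x_prev <- NULL
    for (i in idx) {
      T <- data$T_K[i]
      pA <- pureA[[sprintf("%.10g", T)]]
      rhs <- -fusion_gibbs_energy(fusion, T) / (.R_GAS * T)
      if (config$loss == "lnx") {
        xc <- tryCatch(sle_x_fast(mix, rhs, T, p, x_prev, pureA = pA),
                       error = function(e) NA_real_)
        if (!is.finite(xc) || xc <= 0) return(penalty)
        resids[i] <- log(xc) - log(data$x_api[i])
        x_prev <- xc
      } else {
        xe <- data$x_api[i]
        st <- tryCatch(
          saft_state_tp(mix, T, p, "liquid", c(xe, 1 - xe))$lnphi[1] - pA,
          error = function(e) NA_real_)
        if (!is.finite(st)) return(penalty)
        resids[i] <- log(xe) + st - rhs
      }
    }
  }
  structure(mean(resids^2), residuals = resids)
}

#' Fit API PC-SAFT parameters by simulated annealing
#'
#' Metropolis-accepted random walk over the free parameters with a geometric
#' cooling schedule, followed (by default) by a deterministic local
#' refinement of the best state found.  Returns the best-ever state, not the
#' final one.  Bit-reproducible under a fixed seed.
#'
#' @inheritParams fit_objective
#' @param start optional named start vector (defaults to the bound
#'   midpoints).
#' @return list of class `"saft_fit"`: `par` (best parameters), `m_over_M`,
#'   `objective`, `start_objective`, `trajectory` (per-level data.frame),
#'   `residuals`, `n_eval`, `annealing_par`/`annealing_objective` (pre-polish
#'   best), and `config`.
#' @export
fit_api_parameters <- function(config, data, solvents, api_M, fusion,
                               start = NULL) {
  stopifnot(inherits(config, "fit_config"))
  set.seed(config$seed)
  free <- names(config$bounds)
  lo <- vapply(config$bounds, `[`, 0, 1)
  hi <- vapply(config$bounds, `[`, 0, 2)
  width <- hi - lo
  par <- if (is.null(start)) setNames((lo + hi) / 2, free) else start[free]

  obj <- function(p) as.numeric(fit_objective(p, data, solvents, api_M,
                                              fusion, config))
  cur <- obj(par)
  n_eval <- 1L
  best <- par; best_f <- cur; start_f <- cur
  n_level <- max(1L, ceiling(log(config$t_final / config$t_init) /
                               log(config$cooling)))
  traj <- data.frame(level = seq_len(n_level), temp = NA_real_,
                     current = NA_real_, best = NA_real_, accepted = NA_real_)
  temp <- config$t_init
  for (lv in seq_len(n_level)) {
    acc <- 0L
    for (mv in seq_len(config$moves_per_level)) {
      prop <- par + rnorm(length(free), 0, config$proposal_frac * width)
      # reflect into bounds
      for (j in seq_along(free)) {
        if (prop[j] < lo[j]) prop[j] <- min(hi[j], 2 * lo[j] - prop[j])
        if (prop[j] > hi[j]) prop[j] <- max(lo[j], 2 * hi[j] - prop[j])
      }
      f <- obj(prop)
      n_eval <- n_eval + 1L
      if (f <= cur || runif(1) < exp(-(f - cur) / temp)) {
        par <- prop; cur <- f; acc <- acc + 1L
        if (f < best_f) { best <- par; best_f <- f }
      }
    }
    traj$temp[lv] <- temp
    traj$current[lv] <- cur
    traj$best[lv] <- best_f
    traj$accepted[lv] <- acc / config$moves_per_level
    temp <- temp * config$cooling
  }
  ann_par <- best; ann_f <- best_f

  if (isTRUE(config$polish)) {
    res <- optim(best, obj, method = "Nelder-Mead",
                 control = list(maxit = 400, reltol = 1e-12))
    n_eval <- n_eval + res$counts[["function"]]
    if (res$value < best_f) { best <- res$par; best_f <- res$value }
  }

  full <- fit_objective(best, data, solvents, api_M, fusion, config)
  structure(list(par = setNames(as.numeric(best), free),
                 m_over_M = best[["m"]] / api_M,
                 objective = best_f, start_objective = start_f,
                 annealing_par = setNames(as.numeric(ann_par), free),
                 annealing_objective = ann_f,
                 trajectory = traj, residuals = attr(full, "residuals"),
                 n_eval = n_eval, config = config),
            class = "saft_fit")
}

#' @export
print.saft_fit <- function(x, ...) {
  cat("<saft_fit> best loss", signif(x$objective, 6), "after", x$n_eval,
      "evaluations\n")
  print(signif(x$par, 6))
  invisible(x)
}
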