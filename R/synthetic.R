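# Seeded generators for fixture components and synthetic "experimental"
# datasets with the structure of sparse DSC-derived solubility data: few
# points per system, clustered at high temperature below the melting point,
# multiplicative (lognormal) noise on the weight fraction.

runif1 <- function(lo, hi) runif(1, lo, hi)

#' Generate a deterministic roster of fixture components
#'
#' Three toy APIs (association schemes 2-, 4- and 6-site) and four toy
#' polymers covering the association archetypes seen in real carriers: one
#' self-associating, one purely induced-cross-associating (acceptor sites,
#' zero self-association energy), one completely nonassociating, and one
#' two-monomer copolymer.  Four small solvents (two alcohol-like
#' self-associating, one acceptor-only, one inert) support parameter-fitting
#' tests.  All parameters are drawn inside the ranges spanned by the built-in
#' API table (m/M in 0.01-0.05 mol/g, sigma in 2.9-4.5 A, u/kB in 220-480 K,
#' eps_hb/kB in 500-2000 K); fusion properties lie inside the built-in
#' fusion table ranges (T_m 348-492 K, dH_fus 26-40 kJ/mol).
#'
#' @param seed RNG seed; the roster is bit-reproducible.
#' @return list of class `"fixture_roster"` with `apis`, `polymers`,
#'   `solvents` (named lists of [saft_component()]) and `seed`.
#' @export
make_fixture_components <- function(seed = 1) {
  set.seed(seed)
  schemes <- list(c(1, 1), c(2, 2), c(3, 3))
  apis <- list()
  for (i in 1:3) {
    M <- runif1(150, 420)
    dCp_b <- if (i == 3) -0.3 else 0
    dCp_a <- if (i == 3) runif1(250, 280) else runif1(90, 200)
    fus <- fusion_properties(T_m = runif1(348, 492), dH_fus = runif1(26, 40),
                             dCp_a = dCp_a, dCp_b = dCp_b)
    nm <- paste0("API", i)
    apis[[nm]] <- saft_component(
      nm, M,
      segment_params(runif1(0.01, 0.05), runif1(2.9, 4.5), runif1(220, 480),
                     eps_hb = runif1(500, 2000), kappa_hb = runif1(0.01, 0.03),
                     n_donor = schemes[[i]][1], n_acceptor = schemes[[i]][2]),
      role = "API", fusion = fus)
  }

  polymers <- list()
  # self-associating carrier (donor + acceptor per monomer unit)
  {
    M <- 15000; units <- M / 100
    polymers$PSELF <- saft_component(
      "PSELF", M,
      segment_params(runif1(0.02, 0.04), runif1(2.9, 4.5), runif1(220, 480),
                     eps_hb = runif1(1500, 2000), kappa_hb = 0.02,
                     n_donor = units, n_acceptor = units),
      role = "polymer")
  }
  # induced cross-association only: acceptor sites, eps_hb = 0
  {
    M <- 25000; units <- M / 100
    polymers$PIND <- saft_component(
      "PIND", M,
      segment_params(runif1(0.02, 0.04), runif1(2.9, 4.5), runif1(220, 480),
                     eps_hb = 0, kappa_hb = 0.02, n_acceptor = units),
      role = "polymer")
  }
  # completely nonassociating
  polymers$PNON <- saft_component(
    "PNON", 10000,
    segment_params(runif1(0.02, 0.04), runif1(2.9, 4.5), runif1(220, 480)),
    role = "polymer")
  # copolymer: acceptor-bearing monomer A (60 wt%) + inert monomer B
  {
    M <- 20000
    segA <- segment_params(runif1(0.02, 0.04), runif1(2.9, 4.5),
                           runif1(220, 480), eps_hb = 0, kappa_hb = 0.02)
    segB <- segment_params(runif1(0.02, 0.04), runif1(2.9, 4.5),
                           runif1(220, 480))
    polymers$PCOPO <- saft_component(
      "PCOPO", M, list(A = segA, B = segB), mass_fractions = c(0.6, 0.4),
      scheme = c(0, 0.6 * M / 100), role = "polymer")
  }

  solvents <- list()
  for (i in 1:4) {
    nm <- paste0("SOLV", i)
    M <- runif1(40, 120)
    solvents[[nm]] <- switch(
      i,
      saft_component(nm, M, segment_params(runif1(0.03, 0.05), runif1(3.0, 3.6),
                                           runif1(200, 280), eps_hb = runif1(2000, 2600),
                                           kappa_hb = 0.032, n_donor = 1,
                                           n_acceptor = 1), role = "solvent"),
      saft_component(nm, M, segment_params(runif1(0.03, 0.05), runif1(3.2, 3.8),
                                           runif1(220, 300), eps_hb = runif1(1800, 2400),
                                           kappa_hb = 0.02, n_donor = 1,
                                           n_acceptor = 1), role = "solvent"),
      saft_component(nm, M, segment_params(runif1(0.03, 0.05), runif1(3.2, 3.8),
                                           runif1(250, 330), eps_hb = 0,
                                           kappa_hb = 0.02, n_acceptor = 2),
                     role = "solvent"),
      saft_component(nm, M, segment_params(runif1(0.03, 0.05), runif1(3.4, 4.0),
                                           runif1(230, 300)), role = "solvent"))
  }
  structure(list(apis = apis, polymers = polymers, solvents = solvents,
                 seed = seed), class = "fixture_roster")
}

#' Look up a roster component by name
#' @param roster a [make_fixture_components()] roster.
#' @param name component name.
#' @export
roster_component <- function(roster, name) {
  for (group in c("apis", "polymers", "solvents"))
    if (name %in% names(roster[[group]])) return(roster[[group]][[name]])
  stop("unknown roster component '", name, "'")
}

#' Synthetic API-in-polymer solubility dataset
#'
#' Emulates sparse DSC-derived data: `n_points` temperatures inside
#' `[T_m - T_window, T_m)`, weight fractions from the forward SLE model with
#' multiplicative lognormal noise `w_obs = w exp(eps)`,
#' `eps ~ N(0, noise_cv^2)`, truncated into (0, 1) (truncations are counted
#' in the `truncated` attribute).  The noise-free model curve is retained in
#' the `ground_truth` attribute.
#'
#' @inheritParams solve_sle_point
#' @param n_points number of temperatures (default 4, mirroring the sparsity
#'   of calorimetric solubility data).
#' @param T_window width of the temperature window below T_m, K (default 60).
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed RNG seed.
#' @return an `"experimental_data"` data.frame (columns `system_id`, `api`,
#'   `polymer`, `T_K`, `w_api_exp`).
#' @export
generate_polymer_solubility_data <- function(api, polymer, n_points = 4,
                                             T_window = 60, noise_cv = 0.05,
                                             seed = 1, kij = 0, p = 1e5) {
  set.seed(seed)
  Tm <- api$fusion$T_m
  Ts <- seq(Tm - T_window, Tm - 5, length.out = n_points)
  # each point solved fresh (no warm start) so the ground truth is exactly
  # what an independent solve_sle_point() call reproduces, including the
  # documented smallest-root tie-break in demixing regions
  w_model <- vapply(Ts, function(T)
    solve_sle_point(api, polymer, T, kij = kij, p = p)$w, 0)
  eps <- rnorm(n_points, 0, noise_cv)
  w_obs <- w_model * exp(eps)
  # multiplicative noise keeps w > 0; only the upper bound can be violated
  ntrunc <- sum(w_obs >= 1)
  w_obs <- pmin(w_obs, 1 - 1e-9)
  out <- data.frame(
    system_id = paste(api$name, polymer$name, sep = "-"),
    api = api$name, polymer = polymer$name, T_K = Ts, w_api_exp = w_obs)
  structure(out, class = c("experimental_data", "data.frame"),
            ground_truth = data.frame(T_K = Ts, w_model = w_model),
            kij = kij, noise_cv = noise_cv, seed = seed, truncated = ntrunc)
}

#' Synthetic API-in-solvent solubility datasets for parameter fitting
#'
#' @inheritParams generate_polymer_solubility_data
#' @param solvents named list of solvent [saft_component()]s.
#' @param T_grid temperatures, K (default 6 points, 280-330 K).
#' @return data.frame with columns `solvent`, `T_K`, `x_api`; ground truth
#'   in the `ground_truth` attribute.
#' @export
generate_solvent_solubility_data <- function(api, solvents,
                                             T_grid = seq(280, 330,
                                                          length.out = 6),
                                             noise_cv = 0, seed = 1, p = 1e5) {
  set.seed(seed)
  rows <- list()
  for (sv in names(solvents)) {
    x_prev <- NULL
    xs <- rep(NA_real_, length(T_grid))
    ord <- order(-T_grid)
    for (i in ord) {
      sol <- solve_sle_point(api, solvents[[sv]], T_grid[i], p = p,
                             x_init = x_prev)
      xs[i] <- sol$x
      x_prev <- sol$x
    }
    rows[[sv]] <- data.frame(solvent = sv, T_K = T_grid, x_api = xs)
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  out <- truth
  out$x_api <- out$x_api * exp(rnorm(nrow(out), 0, noise_cv))
  structure(out, ground_truth = truth, noise_cv = noise_cv, seed = seed)
}

#' Generate a full synthetic screening study
#'
#' Crosses the fixture roster (3 APIs x 4 polymers) into synthetic datasets,
#' scans every system for AAPS, and records the ground-truth polymer order
#' per API (noise-free forward model at the ranking temperature, AAPS
#' penalty applied).
#'
#' @param config named list overriding defaults: `n_points` (4), `T_window`
#'   (60 K), `noise_cv` (0.05), `kij` (0), `p` (0.1 MPa), `aaps` (TRUE),
#'   `aaps_range` (c(200, 600) K), `aaps_step` (10 K), `grid_n` (161),
#'   `penalty` (TRUE).
#' @param seed RNG seed; the study regenerates bit-exactly.
#' @return list of class `"synthetic_study"`: `roster`, `data` (pooled
#'   experimental-format data.frame), `aaps` (per-system flag data.frame),
#'   `truth` (per-API ranking tables and noise-free `w`), `config`, `seed`.
#' @export
generate_screening_study <- function(config = list(), seed = 1) {
  cfg <- modifyList(list(n_points = 4, T_window = 60, noise_cv = 0.05,
                         kij = 0, p = 1e5, aaps = TRUE,
                         aaps_range = c(200, 600), aaps_step = 10,
                         grid_n = 161, penalty = TRUE), config)
  roster <- make_fixture_components(seed)
  datasets <- list(); flags <- list()
  isys <- 0L
  for (ap in names(roster$apis)) for (pl in names(roster$polymers)) {
    isys <- isys + 1L
    api <- roster$apis[[ap]]; poly <- roster$polymers[[pl]]
    ds <- generate_polymer_solubility_data(
      api, poly, n_points = cfg$n_points, T_window = cfg$T_window,
      noise_cv = cfg$noise_cv, seed = seed * 1000L + isys, kij = cfg$kij,
      p = cfg$p)
    datasets[[isys]] <- ds
    aaps_flag <- FALSE
    if (isTRUE(cfg$aaps)) {
      bc <- aaps_scan(api, poly, T_range = cfg$aaps_range,
                      step = cfg$aaps_step, kij = cfg$kij, p = cfg$p,
                      grid_n = cfg$grid_n)
      aaps_flag <- has_aaps(bc)
    }
    flags[[isys]] <- data.frame(api = ap, polymer = pl, aaps = aaps_flag)
  }
  data <- do.call(rbind, datasets)
  class(data) <- c("experimental_data", "data.frame")
  aaps <- do.call(rbind, flags)

  truth <- list()
  for (ap in names(roster$apis)) {
    api <- roster$apis[[ap]]
    T_rank <- select_ranking_temperature(data, ap)
    w_true <- vapply(names(roster$polymers), function(pl)
      solve_sle_point(api, roster$polymers[[pl]], T_rank, kij = cfg$kij,
                      p = cfg$p)$w, 0)
    fl <- aaps$aaps[aaps$api == ap][match(names(w_true),
                                          aaps$polymer[aaps$api == ap])]
    truth[[ap]] <- list(T_rank = T_rank, w = w_true,
                        ranking = rank_polymers(w_true, fl,
                                                penalty = cfg$penalty))
  }
  structure(list(roster = roster, data = data, aaps = aaps, truth = truth,
                 config = cfg, seed = seed), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> seed %d: %d APIs x %d polymers, %d points, noise_cv = %g\n",
              x$seed, length(x$roster$apis), length(x$roster$polymers),
              nrow(x$data), x$config$noise_cv))
  invisible(x)
}
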