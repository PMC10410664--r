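# Workflow entry points binding the modules into the screening pipeline
# (predict -> diagram -> score -> rank), plus a minimal CLI dispatcher.
# Configuration is JSON; every run writes a manifest with the resolved
# configuration and a content hash so reruns can be verified bit-identical.

#' Read a run configuration
#'
#' @param config a JSON file path or a named list.
#' @return normalized configuration list with defaults filled in.
#' @export
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  modifyList(list(seed = 1, out_dir = "saftscreen_out", pressure = 1e5,
                  strategy = "REF", kij = 0, parameter_file = NULL,
                  fixture_seed = NULL, sle_step = 1,
                  aaps_range = c(200, 600), aaps_step = 2, grid_n = 201,
                  penalty = TRUE, verbosity = 1), config)
}

# small polynomial hash of a string (reproducibility fingerprint)
config_hash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

write_manifest <- function(cfg, dir, extra = list()) {
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  manifest <- c(list(package = "saftscreen",
                     version = as.character(packageVersion("saftscreen")),
                     seed = cfg$seed, config = cfg,
                     config_hash = config_hash(as.character(cfg_json))), extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# resolve components either from a parameter library or the fixture roster
resolver <- function(cfg) {
  if (!is.null(cfg$fixture_seed)) {
    roster <- make_fixture_components(cfg$fixture_seed)
    function(name, strategy = NULL) roster_component(roster, name)
  } else {
    lib <- parameter_library(cfg$parameter_file)
    function(name, strategy = cfg$strategy) build_component(lib, name, strategy)
  }
}

#' Predict phase diagrams for the configured systems
#'
#' Writes one phase-diagram file per system plus a run manifest.  Config
#' keys: `systems` (list of `{api, polymer}`), `strategy`, `kij`,
#' `pressure`, `sle_step`, `aaps_range`, `aaps_step`, `parameter_file` or
#' `fixture_seed`, `out_dir`.  Per-system failures are collected in the
#' manifest; the call errors only when every system fails.
#'
#' @param config JSON path or list (see [read_run_config()]).
#' @return invisibly, list with `outputs` and `failures`.
#' @export
run_predict <- function(config) {
  cfg <- read_run_config(config)
  if (is.null(cfg$systems) || length(cfg$systems) == 0)
    stop("config has no systems to predict")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  resolve <- resolver(cfg)
  systems <- cfg$systems
  if (is.data.frame(systems))
    systems <- lapply(seq_len(nrow(systems)), function(i) as.list(systems[i, ]))
  outputs <- character(0); failures <- list()
  for (sys in systems) {
    tag <- paste(sys$api, sys$polymer, sep = "_")
    res <- tryCatch({
      api <- resolve(sys$api, cfg$strategy)
      poly <- resolve(sys$polymer)
      Tm <- api$fusion$T_m
      pd <- build_phase_diagram(
        api, poly, kij = cfg$kij, p = cfg$pressure,
        T_grid = unique(c(seq(298, Tm, by = cfg$sle_step), Tm)),
        aaps_range = cfg$aaps_range, aaps_step = cfg$aaps_step,
        grid_n = cfg$grid_n)
      path <- file.path(cfg$out_dir, paste0(tag, "_diagram.tsv"))
      write_phase_diagram(pd, path)
      path
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[tag]] <- conditionMessage(res)
    } else {
      outputs <- c(outputs, res)
    }
  }
  write_manifest(cfg, cfg$out_dir,
                 list(command = "predict", outputs = basename(outputs),
                      failures = failures))
  if (length(outputs) == 0)
    stop("all systems failed; first failure: ", failures[[1]])
  invisible(list(outputs = outputs, failures = failures))
}

#' Score predictions against experimental data and rank polymers
#'
#' Reads an experimental dataset (`data_file`, format of
#' [read_experimental_data()]), computes the pure-prediction solubility at
#' every experimental point, writes AARD/ARD grids with ALL margins and a
#' per-API ranking table (AAPS flags from a scan unless `ranking = FALSE`).
#' Systems whose components cannot be resolved (e.g. ALT requested for an
#' API that only has a REF set) are skipped with a notice in the manifest.
#'
#' @inheritParams run_predict
#' @return invisibly, list with `errors` (an [aggregate_errors()] summary),
#'   `rankings`, `skipped`.
#' @export
run_screen <- function(config) {
  cfg <- read_run_config(config)
  if (is.null(cfg$data_file)) stop("config needs 'data_file'")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  dat <- read_experimental_data(cfg$data_file)
  resolve <- resolver(cfg)

  skipped <- list(); rows <- list()
  for (sid in unique(dat$system_id)) {
    d <- dat[dat$system_id == sid, ]
    comps <- tryCatch(
      list(api = resolve(d$api[1], cfg$strategy), poly = resolve(d$polymer[1])),
      error = function(e) e)
    if (inherits(comps, "error")) {
      skipped[[sid]] <- conditionMessage(comps)
      next
    }
    w_calc <- rep(NA_real_, nrow(d))
    for (i in order(-d$T_K)) {
      res <- tryCatch(
        solve_sle_point(comps$api, comps$poly, d$T_K[i], kij = cfg$kij,
                        p = cfg$pressure),
        error = function(e) e)
      if (inherits(res, "error")) {
        skipped[[paste0(sid, "@", d$T_K[i])]] <- conditionMessage(res)
      } else w_calc[i] <- res$w
    }
    keep <- !is.na(w_calc)
    if (any(keep))
      rows[[sid]] <- data.frame(api = d$api[keep], polymer = d$polymer[keep],
                                T_K = d$T_K[keep], w_exp = d$w_api_exp[keep],
                                w_calc = w_calc[keep])
  }
  if (length(rows) == 0) stop("no system could be scored")
  scored <- do.call(rbind, rows)
  errs <- aggregate_errors(scored)
  write.table(format(errs$aard, digits = 8), file.path(cfg$out_dir, "aard_grid.tsv"),
              sep = "\t", quote = FALSE, col.names = NA)
  write.table(format(errs$ard, digits = 8), file.path(cfg$out_dir, "ard_grid.tsv"),
              sep = "\t", quote = FALSE, col.names = NA)

  rankings <- list()
  if (!identical(cfg$ranking, FALSE)) {
    for (ap in unique(scored$api)) {
      T_rank <- select_ranking_temperature(dat, ap)
      polys <- unique(scored$polymer[scored$api == ap])
      api_cm <- resolve(ap, cfg$strategy)
      w_pred <- vapply(polys, function(pl)
        solve_sle_point(api_cm, resolve(pl), T_rank, kij = cfg$kij,
                        p = cfg$pressure)$w, 0)
      flags <- vapply(polys, function(pl)
        has_aaps(aaps_scan(api_cm, resolve(pl), T_range = cfg$aaps_range,
                           step = cfg$aaps_step, kij = cfg$kij,
                           p = cfg$pressure, grid_n = cfg$grid_n)), TRUE)
      rk <- rank_polymers(setNames(w_pred, polys), flags,
                          penalty = !identical(cfg$penalty, FALSE))
      rankings[[ap]] <- rk
      write.table(rk, file.path(cfg$out_dir, paste0("ranking_", ap, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  write_manifest(cfg, cfg$out_dir,
                 list(command = "screen", skipped = skipped,
                      n_points_scored = nrow(scored)))
  invisible(list(errors = errs, rankings = rankings, skipped = skipped))
}

#' Generate a synthetic study on disk
#'
#' @inheritParams run_predict
#' @return invisibly, the [generate_screening_study()] object.
#' @export
run_synth <- function(config) {
  cfg <- read_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  study <- generate_screening_study(cfg$synth %||% list(), seed = cfg$seed)
  write_experimental_data(study$data, file.path(cfg$out_dir, "synthetic_data.tsv"))
  write.table(study$aaps, file.path(cfg$out_dir, "aaps_flags.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(cfg, cfg$out_dir, list(command = "synth"))
  invisible(study)
}

#' Fit API parameters from a config file
#'
#' Config keys: `fit` (a list accepted by [fit_config()]), `fit_data`
#' (solvent-solubility TSV with columns `solvent`, `T_K`, `x_api`),
#' `api_M`, `fusion` (list with `T_m`, `dH_fus`, `dCp_a`, optional `dCp_b`),
#' and either `parameter_file` (solvent records) or `fixture_seed`.
#'
#' @inheritParams run_predict
#' @return invisibly, the [fit_api_parameters()] result.
#' @export
run_fit <- function(config) {
  cfg <- read_run_config(config)
  stopifnot(!is.null(cfg$fit_data), !is.null(cfg$api_M), !is.null(cfg$fusion))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  dat <- read.delim(cfg$fit_data, stringsAsFactors = FALSE)
  stopifnot(all(c("solvent", "T_K", "x_api") %in% names(dat)))
  resolve <- resolver(cfg)
  solvents <- setNames(lapply(unique(dat$solvent), resolve), unique(dat$solvent))
  fus <- do.call(fusion_properties, cfg$fusion)
  fc_args <- cfg$fit %||% list()
  fc_args$seed <- fc_args$seed %||% cfg$seed
  fc <- do.call(fit_config, fc_args)
  fit <- fit_api_parameters(fc, dat, solvents, cfg$api_M, fus)
  write.table(fit$trajectory, file.path(cfg$out_dir, "fit_trajectory.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(par = as.list(fit$par), m_over_M = fit$m_over_M,
         objective = fit$objective, n_eval = fit$n_eval),
    file.path(cfg$out_dir, "fit_result.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(cfg, cfg$out_dir, list(command = "fit"))
  invisible(fit)
}

#' Command-line dispatcher
#'
#' Usage (e.g. from `Rscript`):
#' `Rscript -e 'saftscreen::saftscreen_cli()' predict --config cfg.json`.
#' Subcommands: `predict`, `screen`, `synth`, `fit`.
#'
#' @param args character vector (default: command-line arguments).
#' @return exit status, invisibly (0 on success).
#' @export
saftscreen_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1) {
    message("usage: saftscreen <predict|screen|synth|fit> --config <file>")
    return(invisible(2L))
  }
  cmd <- args[1]
  ci <- which(args == "--config")
  if (length(ci) != 1 || ci + 1 > length(args)) {
    message("missing --config <file>")
    return(invisible(2L))
  }
  cfgfile <- args[ci + 1]
  fn <- switch(cmd, predict = run_predict, screen = run_screen,
               synth = run_synth, fit = run_fit, NULL)
  if (is.null(fn)) {
    message("unknown subcommand '", cmd, "'")
    return(invisible(2L))
  }
  res <- tryCatch({ fn(cfgfile); 0L }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(res)
}
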