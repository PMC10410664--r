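#' Parameter library: built-ins plus user-supplied records
#'
#' The library resolves component names to PC-SAFT models.  API parameters,
#' fusion properties and molar masses for the seven reference APIs are built
#' in; polymer and solvent parameters are supplied through a parameter file
#' (or programmatically).  User records override built-ins on key collision,
#' with a warning.
#'
#' @section File format:
#' Debian-control-style text (blank-line-separated `field: value` records,
#' read with [read.dcf()]).  Every record needs a `type` field:
#' \describe{
#'   \item{`segment`}{`name`, `m_over_M` (mol/g), `sigma` (A), `u` (K),
#'     `eps_hb` (K, optional), `kappa_hb` (optional).}
#'   \item{`polymer`}{`name`, `M` (g/mol), `segments` (either a segment name,
#'     or `"segA=0.6,segB=0.4"` mass fractions), optional `scheme`
#'     (`"Z (X, Y)"` association sites per molecule, distributed uniformly
#'     over segment types with `kappa_hb > 0`), optional `bond_mode`
#'     (`random`/`alternating`).}
#'   \item{`api`}{`name`, `strategy` (REF/ALT), `m_over_M`, `sigma`, `u`,
#'     `eps_hb`, `kappa_hb`, `scheme`, optional `M` (required for APIs not
#'     built in).}
#'   \item{`solvent`}{`name`, `M`, `m_over_M`, `sigma`, `u`, optional
#'     `eps_hb`, `kappa_hb`, `scheme`.}
#'   \item{`fusion`}{`api`, `T_m` (K), `dH_fus` (kJ/mol), `dCp_a`
#'     (J/(K mol)), optional `dCp_b`, `polymorph`.}
#' }
#'
#' @param path optional path to a parameter file.
#' @return An object of class `"parameter_library"`.
#' @export
parameter_library <- function(path = NULL) {
  lib <- structure(list(
    apis = .builtin_api_params(),
    fusion = .builtin_fusion(),
    api_M = .builtin_api_M(),
    polymer_M = .builtin_polymer_M(),
    segments = list(),
    polymers = list(),
    solvents = list()), class = "parameter_library")
  if (!is.null(path)) lib <- merge_parameter_file(lib, path)
  lib
}

#' @rdname parameter_library
#' @export
load_parameter_library <- parameter_library

num_field <- function(rec, field, irec, required = TRUE, default = NA_real_) {
  v <- rec[[field]]
  if (is.null(v) || is.na(v)) {
    if (required)
      stop(sprintf("parameter file record %d: missing field '%s'", irec, field))
    return(default)
  }
  out <- suppressWarnings(as.numeric(v))
  if (is.na(out))
    stop(sprintf("parameter file record %d: field '%s' is not numeric ('%s')",
                 irec, field, v))
  out
}

chr_field <- function(rec, field, irec, required = TRUE, default = NA_character_) {
  v <- rec[[field]]
  if (is.null(v) || is.na(v)) {
    if (required)
      stop(sprintf("parameter file record %d: missing field '%s'", irec, field))
    return(default)
  }
  v
}

merge_parameter_file <- function(lib, path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  mat <- read.dcf(path)
  if (nrow(mat) == 0) return(lib)
  for (irec in seq_len(nrow(mat))) {
    rec <- as.list(mat[irec, ])
    rec <- rec[!is.na(rec)]
    type <- chr_field(rec, "type", irec)
    switch(type,
      segment = {
        nm <- chr_field(rec, "name", irec)
        sp <- segment_params(
          m_over_M = num_field(rec, "m_over_M", irec),
          sigma = num_field(rec, "sigma", irec),
          u = num_field(rec, "u", irec),
          eps_hb = num_field(rec, "eps_hb", irec, FALSE, 0),
          kappa_hb = num_field(rec, "kappa_hb", irec, FALSE, 0))
        if (nm %in% names(lib$segments))
          warning("parameter file overrides segment '", nm, "'")
        lib$segments[[nm]] <- sp
      },
      polymer = {
        nm <- chr_field(rec, "name", irec)
        M <- num_field(rec, "M", irec)   # missing M -> rejection
        segspec <- chr_field(rec, "segments", irec)
        parts <- strsplit(segspec, ",", fixed = TRUE)[[1]]
        segs <- list(); wfr <- numeric(0)
        for (pp in parts) {
          kv <- strsplit(trimws(pp), "=", fixed = TRUE)[[1]]
          segs <- c(segs, trimws(kv[1]))
          wfr <- c(wfr, if (length(kv) > 1) as.numeric(kv[2]) else 1)
        }
        if (abs(sum(wfr) - 1) > 1e-10)
          stop(sprintf("parameter file record %d: segment mass fractions of '%s' must sum to 1",
                       irec, nm))
        if (nm %in% names(lib$polymers))
          warning("parameter file overrides polymer '", nm, "'")
        lib$polymers[[nm]] <- list(
          M = M, segments = unlist(segs), mass_fractions = wfr,
          scheme = chr_field(rec, "scheme", irec, FALSE),
          bond_mode = chr_field(rec, "bond_mode", irec, FALSE, "random"))
        lib$polymer_M <- upsert(lib$polymer_M, "polymer", nm, list(M = M))
      },
      api = {
        nm <- chr_field(rec, "name", irec)
        strategy <- chr_field(rec, "strategy", irec, FALSE, "REF")
        row <- list(
          api = nm, strategy = strategy,
          m_over_M = num_field(rec, "m_over_M", irec),
          sigma = num_field(rec, "sigma", irec),
          u = num_field(rec, "u", irec),
          eps_hb = num_field(rec, "eps_hb", irec, FALSE, 0),
          kappa_hb = num_field(rec, "kappa_hb", irec, FALSE, 0),
          scheme = chr_field(rec, "scheme", irec, FALSE, "0 (0, 0)"))
        check_assoc_record(row, irec)
        hit <- lib$apis$api == nm & lib$apis$strategy == strategy
        if (any(hit)) {
          warning("parameter file overrides API '", nm, "' (", strategy, ")")
          for (f in names(row)) lib$apis[hit, f] <- row[[f]]
        } else {
          lib$apis <- rbind(lib$apis, as.data.frame(row, stringsAsFactors = FALSE))
        }
        M <- num_field(rec, "M", irec, FALSE)
        if (!is.na(M)) lib$api_M <- upsert(lib$api_M, "api", nm, list(M = M))
      },
      solvent = {
        nm <- chr_field(rec, "name", irec)
        row <- list(
          M = num_field(rec, "M", irec),
          m_over_M = num_field(rec, "m_over_M", irec),
          sigma = num_field(rec, "sigma", irec),
          u = num_field(rec, "u", irec),
          eps_hb = num_field(rec, "eps_hb", irec, FALSE, 0),
          kappa_hb = num_field(rec, "kappa_hb", irec, FALSE, 0),
          scheme = chr_field(rec, "scheme", irec, FALSE, "0 (0, 0)"))
        check_assoc_record(c(row, name = nm), irec)
        if (nm %in% names(lib$solvents))
          warning("parameter file overrides solvent '", nm, "'")
        lib$solvents[[nm]] <- row
      },
      fusion = {
        nm <- chr_field(rec, "api", irec)
        row <- list(
          api = nm,
          polymorph = chr_field(rec, "polymorph", irec, FALSE),
          T_m = num_field(rec, "T_m", irec),
          dH_fus = num_field(rec, "dH_fus", irec),
          dCp_a = num_field(rec, "dCp_a", irec),
          dCp_b = num_field(rec, "dCp_b", irec, FALSE, 0))
        hit <- lib$fusion$api == nm
        if (any(hit)) {
          warning("parameter file overrides fusion properties of '", nm, "'")
          for (f in names(row)) lib$fusion[hit, f] <- row[[f]]
        } else {
          lib$fusion <- rbind(lib$fusion,
                              as.data.frame(row, stringsAsFactors = FALSE))
        }
      },
      stop(sprintf("parameter file record %d: unknown type '%s'", irec, type)))
  }
  lib
}

check_assoc_record <- function(row, irec) {
  sc <- parse_scheme(row$scheme)
  if (row$kappa_hb > 0 && row$eps_hb == 0 && sum(sc) == 0)
    stop(sprintf(
      "parameter file record %d ('%s'): kappa_hb > 0 with eps_hb = 0 requires association sites",
      irec, row$name))
  if (row$eps_hb > 0 && sum(sc) == 0)
    stop(sprintf(
      "parameter file record %d ('%s'): eps_hb > 0 requires association sites",
      irec, row$name))
  invisible(TRUE)
}

upsert <- function(df, keycol, key, values) {
  hit <- df[[keycol]] == key
  if (any(hit)) {
    for (f in names(values)) df[hit, f] <- values[[f]]
  } else {
    row <- c(setNames(list(key), keycol), values)
    df <- rbind(df, as.data.frame(row, stringsAsFactors = FALSE))
  }
  df
}

#' @export
print.parameter_library <- function(x, ...) {
  cat(sprintf("<parameter_library> %d API sets (%d APIs), %d polymers, %d solvents, %d segments\n",
              nrow(x$apis), length(unique(x$apis$api)), length(x$polymers),
              length(x$solvents), length(x$segments)))
  invisible(x)
}

#' Resolve a library entry to a component model
#'
#' @param lib a [parameter_library()].
#' @param name API, polymer or solvent name.
#' @param strategy API parametrization strategy, `"REF"` or `"ALT"` (ignored
#'   for polymers and solvents).
#' @return A [saft_component()]; APIs carry their fusion properties.
#' @examples
#' lib <- parameter_library()
#' sim <- build_component(lib, "SIM")      # m = 0.010695 * 418.60
#' @export
build_component <- function(lib, name, strategy = "REF") {
  stopifnot(inherits(lib, "parameter_library"))
  if (name %in% lib$apis$api) {
    hit <- lib$apis$api == name & lib$apis$strategy == strategy
    if (!any(hit))
      stop("no ", strategy, " parameter set exists for API '", name, "'")
    row <- lib$apis[hit, ][1, ]
    Mrow <- lib$api_M[lib$api_M$api == name, ]
    if (nrow(Mrow) == 0) stop("no molar mass known for API '", name, "'")
    sc <- parse_scheme(row$scheme)
    seg <- segment_params(row$m_over_M, row$sigma, row$u, row$eps_hb,
                          row$kappa_hb, sc[["donor"]], sc[["acceptor"]])
    fus <- NULL
    frow <- lib$fusion[lib$fusion$api == name, ]
    if (nrow(frow) > 0)
      fus <- fusion_properties(frow$T_m[1], frow$dH_fus[1], frow$dCp_a[1],
                               frow$dCp_b[1], frow$polymorph[1])
    return(saft_component(name, Mrow$M[1], seg, role = "API", fusion = fus))
  }
  if (name %in% names(lib$polymers)) {
    sp <- lib$polymers[[name]]
    missing <- setdiff(sp$segments, names(lib$segments))
    if (length(missing) > 0)
      stop("polymer '", name, "' references unknown segment(s): ",
           paste(missing, collapse = ", "))
    segs <- lib$segments[sp$segments]
    cm <- saft_component(name, sp$M, segs, sp$mass_fractions,
                         scheme = if (is.na(sp$scheme)) NULL else sp$scheme,
                         bond_mode = sp$bond_mode, role = "polymer")
    for (s in cm$segments)
      if (s$kappa_hb > 0 && s$eps_hb == 0 && s$n_donor + s$n_acceptor == 0)
        stop("polymer '", name,
             "': segment with kappa_hb > 0 and eps_hb = 0 has no association sites")
    return(cm)
  }
  if (name %in% names(lib$solvents)) {
    sv <- lib$solvents[[name]]
    sc <- parse_scheme(sv$scheme)
    seg <- segment_params(sv$m_over_M, sv$sigma, sv$u, sv$eps_hb,
                          sv$kappa_hb, sc[["donor"]], sc[["acceptor"]])
    return(saft_component(name, sv$M, seg, role = "solvent"))
  }
  stop("unknown component '", name, "'")
}

#' Write the user-definable part of a parameter library to a file
#'
#' Round-trips with [parameter_library()]: segments, polymers, solvents, and
#' any API/fusion records that differ from the built-ins.
#'
#' @param lib a [parameter_library()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_parameter_library <- function(lib, path) {
  stopifnot(inherits(lib, "parameter_library"))
  recs <- list()
  fmt <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
  for (nm in names(lib$segments)) {
    s <- lib$segments[[nm]]
    recs <- c(recs, list(c(type = "segment", name = nm,
                           m_over_M = fmt(s$m_over_M), sigma = fmt(s$sigma),
                           u = fmt(s$u), eps_hb = fmt(s$eps_hb),
                           kappa_hb = fmt(s$kappa_hb))))
  }
  for (nm in names(lib$polymers)) {
    p <- lib$polymers[[nm]]
    segspec <- paste(sprintf("%s=%s", p$segments, fmt(p$mass_fractions)),
                     collapse = ",")
    rec <- c(type = "polymer", name = nm, M = fmt(p$M), segments = segspec,
             bond_mode = p$bond_mode)
    if (!is.na(p$scheme)) rec <- c(rec, scheme = p$scheme)
    recs <- c(recs, list(rec))
  }
  for (nm in names(lib$solvents)) {
    s <- lib$solvents[[nm]]
    recs <- c(recs, list(c(type = "solvent", name = nm, M = fmt(s$M),
                           m_over_M = fmt(s$m_over_M), sigma = fmt(s$sigma),
                           u = fmt(s$u), eps_hb = fmt(s$eps_hb),
                           kappa_hb = fmt(s$kappa_hb), scheme = s$scheme)))
  }
  builtin <- .builtin_api_params()
  for (i in seq_len(nrow(lib$apis))) {
    row <- lib$apis[i, ]
    match <- builtin[builtin$api == row$api & builtin$strategy == row$strategy, ]
    if (nrow(match) == 1 && isTRUE(all.equal(as.list(match), as.list(row),
                                             check.attributes = FALSE)))
      next
    Mrow <- lib$api_M[lib$api_M$api == row$api, ]
    recs <- c(recs, list(c(type = "api", name = row$api, strategy = row$strategy,
                           m_over_M = fmt(row$m_over_M), sigma = fmt(row$sigma),
                           u = fmt(row$u), eps_hb = fmt(row$eps_hb),
                           kappa_hb = fmt(row$kappa_hb), scheme = row$scheme,
                           M = fmt(Mrow$M[1]))))
  }
  fields <- unique(unlist(lapply(recs, names)))
  mat <- matrix(NA_character_, length(recs), length(fields),
                dimnames = list(NULL, fields))
  for (i in seq_along(recs)) mat[i, names(recs[[i]])] <- recs[[i]]
  write.dcf(mat, path)
  invisible(path)
}
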