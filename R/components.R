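#' PC-SAFT parameters of one segment type
#'
#' A segment type is the basic building block of a PC-SAFT chain.  Small
#' molecules and homopolymers consist of a single segment type; copolymers
#' combine several, each parametrized from the corresponding homopolymer.
#'
#' @param m_over_M segment number per unit molar mass, mol/g.  The segment
#'   number contributed to a chain of molar mass `M` is `m = m_over_M * M`
#'   (times the mass fraction of the chain made of this type).
#' @param sigma segment diameter, Angstrom.
#' @param u dispersion energy over the Boltzmann constant, K.
#' @param eps_hb association (hydrogen-bond) energy over k_B, K.  Zero for
#'   non-self-associating types.
#' @param kappa_hb dimensionless association volume.  A type with
#'   `eps_hb = 0` but `kappa_hb > 0` and acceptor sites models induced
#'   cross-association with self-associating partners.
#' @param n_donor,n_acceptor hydrogen-bond donor/acceptor site counts carried
#'   by this type (per molecule for single-type components; see
#'   [saft_component()] for how a component-level scheme overrides these).
#' @return An object of class `"segment_params"`.
#' @examples
#' segment_params(0.0352, 2.939, 229.45, eps_hb = 934.2, kappa_hb = 0.02,
#'                n_donor = 2, n_acceptor = 2)
#' @export
segment_params <- function(m_over_M, sigma, u, eps_hb = 0, kappa_hb = 0,
                           n_donor = 0, n_acceptor = 0) {
  stopifnot(is.numeric(m_over_M), m_over_M > 0,
            is.numeric(sigma), sigma > 0,
            is.numeric(u), u > 0,
            eps_hb >= 0, kappa_hb >= 0,
            n_donor >= 0, n_acceptor >= 0)
  if (eps_hb > 0 && kappa_hb <= 0)
    stop("a segment with eps_hb > 0 must have kappa_hb > 0")
  structure(list(m_over_M = m_over_M, sigma = sigma, u = u,
                 eps_hb = eps_hb, kappa_hb = kappa_hb,
                 n_donor = n_donor, n_acceptor = n_acceptor),
            class = "segment_params")
}

#' @export
print.segment_params <- function(x, ...) {
  cat(sprintf("PC-SAFT segment: m/M = %g mol/g, sigma = %g A, u/kB = %g K\n",
              x$m_over_M, x$sigma, x$u))
  if (x$kappa_hb > 0 || x$n_donor + x$n_acceptor > 0)
    cat(sprintf("  association: eps/kB = %g K, kappa = %g, sites %g (%g, %g)\n",
                x$eps_hb, x$kappa_hb, x$n_donor + x$n_acceptor,
                x$n_donor, x$n_acceptor))
  invisible(x)
}

#' Parse an association scheme string such as "4 (2, 2)"
#'
#' The convention is `Z (X, Y)`: `Z` sites in total, `X` donors, `Y`
#' acceptors per molecule.
#' @param scheme character scalar, or a numeric vector `c(donor, acceptor)`.
#' @return numeric `c(donor, acceptor)`.
#' @export
parse_scheme <- function(scheme) {
  if (is.numeric(scheme)) {
    stopifnot(length(scheme) == 2, all(scheme >= 0))
    return(c(donor = scheme[[1]], acceptor = scheme[[2]]))
  }
  m <- regmatches(scheme, regexec(
    "^\\s*([0-9.]+)\\s*\\(\\s*([0-9.]+)\\s*,\\s*([0-9.]+)\\s*\\)\\s*$", scheme))[[1]]
  if (length(m) != 4)
    stop("cannot parse association scheme '", scheme, "' (expected 'Z (X, Y)')")
  z <- as.numeric(m[2]); xd <- as.numeric(m[3]); ya <- as.numeric(m[4])
  if (abs(xd + ya - z) > 1e-9)
    stop("association scheme '", scheme, "': donor + acceptor != total")
  c(donor = xd, acceptor = ya)
}

#' Build a PC-SAFT component model
#'
#' A component is a chain of one or more segment types with a molar mass, an
#' association-site scheme and a role.  The total segment number is
#' `m = sum_alpha (m/M)_alpha * w_alpha * M`, where `w_alpha` is the mass
#' fraction of the chain belonging to type `alpha`.  Bond fractions between
#' segment types default to the random (composition-proportional) convention;
#' strictly alternating two-type chains are available via `bond_mode`.
#'
#' @param name component identifier.
#' @param molar_mass molar mass, g/mol.
#' @param segments a [segment_params()] object, or a named list of them for
#'   copolymers.
#' @param mass_fractions mass fraction of the chain made of each segment type
#'   (same length/order as `segments`, must sum to 1).
#' @param scheme optional component-level association scheme (string
#'   `"Z (X, Y)"` or numeric `c(donor, acceptor)`).  When given, the donor and
#'   acceptor counts are distributed uniformly over the associating segment
#'   types (those with `kappa_hb > 0`), overriding per-segment counts.
#' @param bond_mode `"random"` (default) or `"alternating"` (two types only).
#' @param role one of `"API"`, `"polymer"`, `"solvent"`.
#' @param fusion optional [fusion_properties()] for crystalline APIs.
#' @return An object of class `"saft_component"`.
#' @examples
#' npx <- saft_component("NPX", 230.26,
#'   segment_params(0.0352, 2.939, 229.45, 934.2, 0.02, 2, 2), role = "API")
#' npx
#' @export
saft_component <- function(name, molar_mass, segments, mass_fractions = NULL,
                           scheme = NULL,
                           bond_mode = c("random", "alternating"),
                           role = c("API", "polymer", "solvent"),
                           fusion = NULL) {
  role <- match.arg(role)
  bond_mode <- match.arg(bond_mode)
  if (inherits(segments, "segment_params")) segments <- list(segments)
  stopifnot(length(segments) >= 1,
            all(vapply(segments, inherits, TRUE, "segment_params")))
  ns <- length(segments)
  if (is.null(mass_fractions)) {
    if (ns > 1) stop("mass_fractions must be given for multi-segment components")
    mass_fractions <- 1
  }
  stopifnot(length(mass_fractions) == ns, all(mass_fractions > 0))
  if (abs(sum(mass_fractions) - 1) > 1e-10)
    stop("mass_fractions must sum to 1")
  stopifnot(molar_mass > 0)

  m_alpha <- vapply(seq_len(ns), function(i)
    segments[[i]]$m_over_M * mass_fractions[i] * molar_mass, 0)
  m_total <- sum(m_alpha)
  if (m_total <= 0) stop("total segment number must be positive")

  if (!is.null(scheme)) {
    sc <- parse_scheme(scheme)
    assoc <- which(vapply(segments, function(s) s$kappa_hb > 0, TRUE))
    if (length(assoc) == 0L) {
      if (sum(sc) > 0)
        stop("component-level scheme given but no segment type has kappa_hb > 0")
    } else {
      for (i in seq_len(ns)) {
        segments[[i]]$n_donor <- 0
        segments[[i]]$n_acceptor <- 0
      }
      for (i in assoc) {
        segments[[i]]$n_donor <- sc[["donor"]] / length(assoc)
        segments[[i]]$n_acceptor <- sc[["acceptor"]] / length(assoc)
      }
    }
  }

  z <- m_alpha / m_total   # segment number fractions
  if (ns == 1L) {
    bonds <- data.frame(t1 = 1L, t2 = 1L, frac = 1)
  } else if (bond_mode == "alternating") {
    if (ns != 2L) stop("alternating bonding requires exactly two segment types")
    bonds <- data.frame(t1 = 1L, t2 = 2L, frac = 1)
  } else {
    t1 <- integer(0); t2 <- integer(0); fr <- numeric(0)
    for (i in seq_len(ns)) for (j in i:ns) {
      t1 <- c(t1, i); t2 <- c(t2, j)
      fr <- c(fr, if (i == j) z[i]^2 else 2 * z[i] * z[j])
    }
    bonds <- data.frame(t1 = t1, t2 = t2, frac = fr / sum(fr))
  }

  if (!is.null(fusion)) stopifnot(inherits(fusion, "fusion_properties"))
  structure(list(name = name, molar_mass = molar_mass, segments = segments,
                 mass_fractions = mass_fractions, m_alpha = m_alpha,
                 m_total = m_total, bonds = bonds, bond_mode = bond_mode,
                 role = role, fusion = fusion),
            class = "saft_component")
}

#' @export
print.saft_component <- function(x, ...) {
  cat(sprintf("<saft_component> %s (%s), M = %g g/mol, m = %.4f (%d segment type%s)\n",
              x$name, x$role, x$molar_mass, x$m_total,
              length(x$segments), if (length(x$segments) > 1) "s" else ""))
  nd <- sum(vapply(x$segments, `[[`, 0, "n_donor"))
  na <- sum(vapply(x$segments, `[[`, 0, "n_acceptor"))
  if (nd + na > 0)
    cat(sprintf("  association sites per molecule: %g donors, %g acceptors\n", nd, na))
  if (!is.null(x$fusion))
    cat(sprintf("  fusion: T_m = %g K, dH_fus = %g kJ/mol\n",
                x$fusion$T_m, x$fusion$dH_fus))
  invisible(x)
}

#' Cross parameters between two segment types
#'
#' Conventional combining rules: arithmetic mean for the diameter, geometric
#' mean corrected by `(1 - kij)` for the dispersion energy, and for
#' association the arithmetic mean of the energies with a Wolbach-Sandler
#' volume term.  A partner with `eps_hb = 0` but `kappa_hb > 0` therefore
#' picks up half the association energy of a self-associating partner
#' (induced cross-association).
#'
#' @param seg_i,seg_j [segment_params()] objects.
#' @param kij dimensionless binary interaction parameter (default 0; pure
#'   prediction).
#' @return list with `sigma_ij`, `u_ij`, `eps_hb_ij`, `kappa_hb_ij`.
#' @export
cross_parameters <- function(seg_i, seg_j, kij = 0) {
  stopifnot(inherits(seg_i, "segment_params"), inherits(seg_j, "segment_params"))
  if (abs(kij) > 1 && sqrt(seg_i$u * seg_j$u) * (1 - kij) < 0)
    stop("invalid parameters: cross-dispersion energy would be negative (|kij| > 1)")
  sigma_ij <- (seg_i$sigma + seg_j$sigma) / 2
  u_ij <- sqrt(seg_i$u * seg_j$u) * (1 - kij)
  if (u_ij < 0) stop("invalid parameters: negative cross-dispersion energy")
  eps_ij <- (seg_i$eps_hb + seg_j$eps_hb) / 2
  kap_ij <- sqrt(seg_i$kappa_hb * seg_j$kappa_hb) *
    (sqrt(seg_i$sigma * seg_j$sigma) / sigma_ij)^3
  list(sigma_ij = sigma_ij, u_ij = u_ij,
       eps_hb_ij = eps_ij, kappa_hb_ij = kap_ij)
}
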