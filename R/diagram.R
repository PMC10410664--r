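# Phase-diagram assembly and serialization.

#' Build an API-polymer phase diagram (SLE + AAPS curves)
#'
#' Computes the solubility curve and the AAPS binodal with shared settings.
#'
#' @inheritParams solve_sle_point
#' @param T_grid SLE temperature grid (default 1 K steps from 298 K to T_m).
#' @param aaps_range,aaps_step AAPS scan range and step, K.
#' @param grid_n LLE composition-grid resolution.
#' @return list of class `"phase_diagram"` with elements `sle`
#'   (a [solubility_curve()]) and `aaps` (an [aaps_scan()] result).
#' @export
build_phase_diagram <- function(api, polymer, kij = 0, p = 1e5, T_grid = NULL,
                                aaps_range = c(200, 600), aaps_step = 2,
                                grid_n = 201, fusion = NULL) {
  sle <- solubility_curve(api, polymer, T_grid = T_grid, kij = kij, p = p,
                          fusion = fusion)
  aaps <- aaps_scan(api, polymer, T_range = aaps_range, step = aaps_step,
                    kij = kij, p = p, grid_n = grid_n)
  structure(list(sle = sle, aaps = aaps, api = api$name,
                 polymer = polymer$name, kij = kij, p = p),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("<phase_diagram> %s in %s (kij = %g, p = %g Pa)\n",
              x$api, x$polymer, x$kij, x$p))
  cat(sprintf("  SLE: %d points; AAPS: %s\n", nrow(x$sle),
              if (has_aaps(x$aaps)) sprintf("%d binodal points", nrow(x$aaps))
              else "none predicted"))
  invisible(x)
}

#' Serialize / deserialize a phase diagram
#'
#' Tab-separated long format with columns `T_K`, `x_api`, `w_api`, `branch`
#' (`SLE`, `AAPS_L1`, `AAPS_L2`), written at fixed precision so reruns
#' diff cleanly.
#'
#' @param pd a `"phase_diagram"`.
#' @param path output path.
#' @export
write_phase_diagram <- function(pd, path) {
  stopifnot(inherits(pd, "phase_diagram"))
  sle <- pd$sle[!is.na(pd$sle$x_api), ]
  long <- data.frame(
    T_K = c(sle$T_K, pd$aaps$T_K, pd$aaps$T_K),
    x_api = c(sle$x_api, pd$aaps$x_L1, pd$aaps$x_L2),
    w_api = c(sle$w_api, pd$aaps$w_L1, pd$aaps$w_L2),
    branch = c(rep("SLE", nrow(sle)), rep("AAPS_L1", nrow(pd$aaps)),
               rep("AAPS_L2", nrow(pd$aaps))))
  long$T_K <- formatC(long$T_K, format = "f", digits = 4)
  long$x_api <- formatC(long$x_api, format = "e", digits = 10)
  long$w_api <- formatC(long$w_api, format = "e", digits = 10)
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phase_diagram
#' @return `read_phase_diagram()` returns the long-format data.frame.
#' @export
read_phase_diagram <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("T_K", "x_api", "w_api", "branch")
  if (!all(need %in% names(df)))
    stop("phase diagram file missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df
}
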