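# Prediction-error statistics, aggregation, kij fitting and polymer ranking.

#' Average absolute relative deviation, percent
#'
#' `AARD = 100/N * sum |w_calc - w_exp| / w_exp`.
#'
#' @param exp experimental values (> 0).
#' @param calc calculated values (same length).
#' @return percent AARD.
#' @export
aard <- function(exp, calc) {
  stopifnot(length(exp) == length(calc), length(exp) >= 1)
  if (any(exp <= 0)) stop("experimental values must be positive")
  100 * mean(abs(calc - exp) / exp)
}

#' Average (signed) relative deviation, percent
#'
#' `ARD = 100/N * sum (w_calc - w_exp) / w_exp`; negative values indicate
#' systematic underestimation by the model.
#'
#' @inheritParams aard
#' @return percent ARD.
#' @export
ard <- function(exp, calc) {
  stopifnot(length(exp) == length(calc), length(exp) >= 1)
  if (any(exp <= 0)) stop("experimental values must be positive")
  100 * mean((calc - exp) / exp)
}

#' Coefficient of determination of an ordinary least-squares line
#'
#' @param x descriptor values (>= 3, nonzero variance).
#' @param y response values.
#' @return R-squared of the linear fit of `y` on `x`.
#' @export
correlate_r2 <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0) stop("descriptor has zero variance")
  fit <- stats::lm.fit(cbind(1, x), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' Aggregate per-point deviations into an AARD/ARD grid with ALL margins
#'
#' Builds the polymer-by-API error grids.  The `ALL` row/column (and the
#' overall corner) pool the underlying per-point deviations of the group by
#' default (`mode = "pooled"`); `mode = "system_mean"` instead averages the
#' per-system statistics, the alternative convention.
#'
#' @param data data.frame with columns `api`, `polymer`, `w_exp`, `w_calc`
#'   (one row per experimental point).
#' @param mode pooling convention for the ALL margins.
#' @return list of class `"error_summary"`: `aard` and `ard` matrices
#'   (polymers x APIs with ALL margins), `per_system` data.frame, `mode`.
#' @export
aggregate_errors <- function(data, mode = c("pooled", "system_mean")) {
  mode <- match.arg(mode)
  stopifnot(all(c("api", "polymer", "w_exp", "w_calc") %in% names(data)))
  if (nrow(data) == 0) stop("no data to aggregate")
  data$rd <- (data$w_calc - data$w_exp) / data$w_exp * 100

  apis <- sort(unique(data$api)); polys <- sort(unique(data$polymer))
  per_system <- do.call(rbind, lapply(
    split(data, list(data$api, data$polymer), drop = TRUE), function(d)
      data.frame(api = d$api[1], polymer = d$polymer[1], n = nrow(d),
                 aard = mean(abs(d$rd)), ard = mean(d$rd))))
  rownames(per_system) <- NULL

  cellfun <- function(d, stat) {
    if (nrow(d) == 0) return(NA_real_)
    if (mode == "pooled") {
      if (stat == "aard") mean(abs(d$rd)) else mean(d$rd)
    } else {
      ps <- vapply(split(d, paste(d$api, d$polymer)), function(s)
        if (stat == "aard") mean(abs(s$rd)) else mean(s$rd), 0)
      mean(ps)
    }
  }
  dims <- list(c(polys, "ALL"), c(apis, "ALL"))
  aardm <- ardm <- matrix(NA_real_, length(polys) + 1, length(apis) + 1,
                          dimnames = dims)
  for (pl in c(polys, "ALL")) for (ap in c(apis, "ALL")) {
    d <- data[(pl == "ALL" | data$polymer == pl) &
                (ap == "ALL" | data$api == ap), ]
    aardm[pl, ap] <- cellfun(d, "aard")
    ardm[pl, ap] <- cellfun(d, "ard")
  }
  structure(list(aard = aardm, ard = ardm, per_system = per_system,
                 mode = mode), class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat("AARD(w_api) grid, % (mode:", x$mode, ")\n")
  print(round(x$aard, 1))
  invisible(x)
}

#' Fit a temperature-independent kij to a single experimental point
#'
#' One-dimensional bracketed root-finding on the predicted weight-fraction
#' solubility so that the model reproduces `w_exp` at `T_exp`.  Increasing
#' kij weakens the cross attraction and lowers the predicted solubility.
#'
#' @inheritParams solve_sle_point
#' @param T_exp,w_exp the experimental point.
#' @param interval kij search bracket.
#' @return fitted kij (scalar), with attribute `w_check`.
#' @export
fit_kij_to_point <- function(api, polymer, T_exp, w_exp,
                             interval = c(-0.2, 0.2), p = 1e5, fusion = NULL) {
  wpred <- function(k)
    solve_sle_point(api, polymer, T_exp, kij = k, p = p, fusion = fusion)$w
  f <- function(k) wpred(k) - w_exp
  f0 <- f(0)
  if (abs(f0) < 1e-10) return(structure(0, w_check = w_exp + f0))
  flo <- f(interval[1]); fhi <- f(interval[2])
  if (sign(flo) == sign(fhi))
    stop("no kij in [", interval[1], ", ", interval[2],
         "] reproduces w_exp = ", w_exp, " at T = ", T_exp, " K")
  k <- uniroot(f, interval, f.lower = flo, f.upper = fhi, tol = 1e-10)$root
  wk <- wpred(k)
  if (abs(wk - w_exp) > 1e-6)
    warning("kij fit residual |w - w_exp| = ", signif(abs(wk - w_exp), 3))
  structure(k, w_check = wk)
}

#' Rank polymers by predicted compatibility with an API
#'
#' Polymers are ordered by predicted weight-fraction solubility at the
#' ranking temperature (descending; rank 1 = most compatible).  Every
#' AAPS-flagged polymer is then demoted exactly one position below its
#' unpenalized slot; unflagged polymers fill the remaining slots in
#' predicted order.  Demotion past the list end is clamped, so a flagged
#' polymer already in last place stays there.
#'
#' @param w_pred named numeric vector of predicted `w_api` per polymer, or a
#'   data.frame with columns `polymer`, `w_pred` and optionally `aaps`.
#' @param aaps logical vector of AAPS flags (default all `FALSE`).
#' @param penalty apply the AAPS penalty (default `TRUE`).
#' @return data.frame of class `"ranking_table"` with columns `polymer`,
#'   `w_pred`, `aaps`, `rank_unpenalized`, `rank`, ordered by `rank`.
#' @export
rank_polymers <- function(w_pred, aaps = NULL, penalty = TRUE) {
  if (is.data.frame(w_pred)) {
    df <- w_pred
    stopifnot(all(c("polymer", "w_pred") %in% names(df)))
    if (is.null(aaps)) aaps <- if ("aaps" %in% names(df)) df$aaps else NULL
    w <- setNames(df$w_pred, df$polymer)
  } else {
    w <- w_pred
    if (is.null(names(w))) names(w) <- paste0("polymer", seq_along(w))
  }
  n <- length(w)
  if (is.null(aaps)) aaps <- rep(FALSE, n)
  stopifnot(length(aaps) == n)

  ord <- order(-w)
  base_rank <- integer(n); base_rank[ord] <- seq_len(n)
  # place each flagged polymer at base rank + 1 (clamped to the list end;
  # if that slot is taken by a deeper flagged entry, it backs up to the
  # nearest free slot above -- entries already last cannot be demoted);
  # unflagged polymers fill the remaining slots in base order
  slot <- rep(NA_integer_, n)            # position -> component index
  if (penalty && any(aaps)) {
    flagged <- which(aaps)[order(-base_rank[which(aaps)])]
    for (i in flagged) {
      pos <- min(base_rank[i] + 1L, n)
      while (pos >= 1L && !is.na(slot[pos])) pos <- pos - 1L
      slot[pos] <- i
    }
    rest <- setdiff(seq_len(n)[order(base_rank)], which(aaps))
    slot[is.na(slot)] <- rest
  } else {
    slot <- ord
  }
  out <- data.frame(polymer = names(w)[slot], w_pred = unname(w)[slot],
                    aaps = aaps[slot],
                    rank_unpenalized = base_rank[slot],
                    rank = seq_len(n))
  class(out) <- c("ranking_table", "data.frame")
  out
}

#' Ranking temperature for an API test set
#'
#' The lowest experimental temperature common to all systems of the API:
#' the maximum over systems of each system's minimum measured temperature.
#'
#' @param data experimental data.frame (columns `api`, `polymer`, `T_K`).
#' @param api API name.
#' @return temperature, K.
#' @export
select_ranking_temperature <- function(data, api) {
  d <- data[data$api == api, ]
  if (nrow(d) == 0) stop("no experimental systems for API '", api, "'")
  max(vapply(split(d$T_K, d$polymer), min, 0))
}

#' Experimental solubility at the ranking temperature
#'
#' Returns the measured `w` when a point exists at `T_rank` (within `T_tol`);
#' otherwise adjusts a temperature-independent kij to the system's lowest-T
#' point ([fit_kij_to_point()]) and extrapolates the model to `T_rank` --
#' the treatment used for systems with a single experimental point.
#'
#' @inheritParams fit_kij_to_point
#' @param points data.frame with `T_K`, `w_api_exp` for one system.
#' @param T_rank ranking temperature, K.
#' @param T_tol match tolerance, K.
#' @return list with `w`, `method` ("direct" or "kij_extrapolation"), `kij`.
#' @export
experimental_w_at <- function(api, polymer, points, T_rank, T_tol = 0.5,
                              p = 1e5, fusion = NULL) {
  stopifnot(all(c("T_K", "w_api_exp") %in% names(points)), nrow(points) >= 1)
  hit <- which(abs(points$T_K - T_rank) <= T_tol)
  if (length(hit) > 0) {
    i <- hit[which.min(abs(points$T_K[hit] - T_rank))]
    return(list(w = points$w_api_exp[i], method = "direct", kij = NA_real_))
  }
  i <- which.min(points$T_K)
  k <- fit_kij_to_point(api, polymer, points$T_K[i], points$w_api_exp[i],
                        p = p, fusion = fusion)
  w <- solve_sle_point(api, polymer, T_rank, kij = as.numeric(k), p = p,
                       fusion = fusion)$w
  list(w = w, method = "kij_extrapolation", kij = as.numeric(k))
}
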