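# Delimited-text readers/writers shared by the screening and synthetic-data
# modules.  Experimental solubility tables carry one row per (system, T)
# point: system_id, api, polymer, T_K, w_api_exp.

#' Read / write experimental solubility datasets
#'
#' Tab-separated text with columns `system_id`, `api`, `polymer`, `T_K`,
#' `w_api_exp` (weight-fraction solubility of the API in the polymer).
#'
#' @param path file path.
#' @return data.frame of class `"experimental_data"`.
#' @export
read_experimental_data <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("system_id", "api", "polymer", "T_K", "w_api_exp")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("experimental data file missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) < 1) stop("experimental data file has no rows")
  if (any(df$w_api_exp <= 0 | df$w_api_exp >= 1))
    stop("w_api_exp must lie strictly in (0, 1)")
  class(df) <- c("experimental_data", "data.frame")
  df
}

#' @rdname read_experimental_data
#' @param data data.frame with the columns above.
#' @export
write_experimental_data <- function(data, path) {
  need <- c("system_id", "api", "polymer", "T_K", "w_api_exp")
  stopifnot(all(need %in% names(data)))
  out <- as.data.frame(data)[, need]
  out$T_K <- formatC(out$T_K, format = "f", digits = 8)
  out$w_api_exp <- formatC(out$w_api_exp, format = "e", digits = 12)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
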