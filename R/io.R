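# CSV round-tripping for populations and result tables.

#' Read or write population files
#'
#' Populations are stored as plain CSV: `id,u,z` for covariates only, or
#' `id,u,z,t,delta` once events have been simulated. Doubles keep full
#' precision.
#'
#' @param pop A population tibble.
#' @param path File path.
#' @return `write_population()` returns `pop` invisibly;
#'   `read_population()` returns a tibble.
#' @export
write_population <- function(pop, path) {
  stopifnot(all(c("id", "u", "z") %in% names(pop)))
  readr::write_csv(pop, path)
  invisible(pop)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  cols <- readr::cols(
    id = readr::col_integer(),
    u = readr::col_double(),
    z = readr::col_integer(),
    .default = readr::col_double()
  )
  out <- readr::read_csv(path, col_types = cols, progress = FALSE)
  if ("delta" %in% names(out)) out$delta <- as.integer(out$delta)
  out
}

#' Write a long-format bias table
#'
#' @param result A `"scenario_result"` from [run_scenario()] or a
#'   `"bias_table"` from [compute_bias_measures()].
#' @param path File path for the CSV.
#' @return `result`, invisibly.
#' @export
write_bias_table <- function(result, path) {
  readr::write_csv(as_tibble(result), path)
  invisible(result)
}
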