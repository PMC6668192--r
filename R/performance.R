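#' Bias measures across simulation repetitions
#'
#' Pools per-repetition estimates into the study's three bias measures for
#' each event, with normal-approximation 95% confidence intervals based on
#' the Monte-Carlo standard error of the mean:
#' \describe{
#'   \item{`theta_RCT`}{mean of \eqn{\hat\Gamma_i - \hat\Gamma_{i0}} — the
#'     gap between the subdistribution estimate and the estimate from a
#'     paired hypothetical randomised trial (`rho = 0`, `pi = 0.5`).}
#'   \item{`theta_Exp`}{mean of \eqn{\hat\Gamma_i - \Gamma_i} — bias relative
#'     to the explicitly computed least-false subdistribution effect at the
#'     current `rho`.}
#'   \item{`theta_CSH`}{mean of \eqn{\hat\gamma_i - \gamma_i} — bias of the
#'     cause-specific estimate relative to the prescribed effect.}
#' }
#'
#' @param records A data frame with one row per (repetition, event):
#'   columns `rep`, `event`, `gamma_hat`, `Gamma_hat`, `Gamma_hat_rct`.
#' @param truths A [true_effects()] object computed at the same `rho` and
#'   parameters as the records. If the records carry a `rho` attribute (as
#'   those from [run_cell()] do), a mismatch is an error.
#' @return A tibble of class `"bias_table"` with columns `event`, `measure`,
#'   `estimate`, `ci_low`, `ci_high`, `n_reps`.
#' @export
compute_bias_measures <- function(records, truths) {
  stopifnot(inherits(truths, "true_effects"))
  req <- c("rep", "event", "gamma_hat", "Gamma_hat", "Gamma_hat_rct")
  if (!is.data.frame(records) || !all(req %in% names(records))) {
    abort(paste("`records` must contain columns",
                paste0("`", req, "`", collapse = ", "), "."),
          class = "crconfound_invalid_parameter")
  }
  rec_rho <- attr(records, "rho")
  if (!is.null(rec_rho) && abs(rec_rho - truths$rho) > 1e-12) {
    abort(sprintf(
      "`records` were generated at rho = %g but `truths` were computed at rho = %g.",
      rec_rho, truths$rho
    ), class = "crconfound_consistency")
  }
  if (min(table(records$event)) < 2L) {
    abort("At least 2 repetitions per event are required.",
          class = "crconfound_insufficient_replication")
  }
  truth_tbl <- tibble(
    event = c(1L, 2L),
    gamma = c(truths$gamma1, truths$gamma2),
    Gamma = c(truths$Gamma1, truths$Gamma2)
  )
  out <- records |>
    as_tibble() |>
    dplyr::inner_join(truth_tbl, by = "event") |>
    dplyr::mutate(
      theta_RCT = .data$Gamma_hat - .data$Gamma_hat_rct,
      theta_Exp = .data$Gamma_hat - .data$Gamma,
      theta_CSH = .data$gamma_hat - .data$gamma
    ) |>
    tidyr::pivot_longer(dplyr::all_of(c("theta_RCT", "theta_Exp", "theta_CSH")),
                        names_to = "measure", values_to = "diff") |>
    dplyr::group_by(.data$event, .data$measure) |>
    dplyr::summarise(
      estimate = mean(.data$diff),
      mc_se = sd(.data$diff) / sqrt(dplyr::n()),
      n_reps = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      ci_low = .data$estimate - 1.96 * .data$mc_se,
      ci_high = .data$estimate + 1.96 * .data$mc_se,
      measure = factor(.data$measure,
                       levels = c("theta_RCT", "theta_Exp", "theta_CSH"))
    ) |>
    dplyr::arrange(.data$event, .data$measure) |>
    dplyr::select("event", "measure", "estimate", "ci_low", "ci_high",
                  "mc_se", "n_reps")
  class(out) <- c("bias_table", class(out))
  out
}
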