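# Single-binary-covariate partial likelihood machinery shared by the
# cause-specific and subdistribution fitters. With covariate z in {0,1},
# everything reduces to per-event-time at-risk counts (n0_j, n1_j) and tied
# event counts (d0_j, d1_j) per arm; Breslow handling of ties.

#' @keywords internal
#' @noRd
risk_counts <- function(t, delta, z, event, model) {
  te_all <- t[delta == event]
  if (length(te_all) == 0L) {
    abort("No events of the requested type in the data.",
          class = "crconfound_degenerate_data")
  }
  te <- sort(unique(te_all))
  n1_tot <- sum(z == 1)
  n0_tot <- sum(z == 0)
  # events per arm at each (tied) event time
  d1 <- tabulate(match(t[delta == event & z == 1], te), length(te))
  d0 <- tabulate(match(t[delta == event & z == 0], te), length(te))
  if (model == "cause_specific") {
    # risk set at time s: all subjects with T >= s
    s1 <- sort(t[z == 1])
    s0 <- sort(t[z == 0])
  } else {
    # subdistribution risk set for `event`: subjects leave only at their own
    # event of this type; competing-event subjects stay at risk forever.
    # With no censoring the IPCW weights are identically 1, so at-risk count
    # at s is n_total minus prior events of the modelled type.
    s1 <- sort(t[z == 1 & delta == event])
    s0 <- sort(t[z == 0 & delta == event])
  }
  n1 <- n1_tot - findInterval(te, s1, left.open = TRUE)
  n0 <- n0_tot - findInterval(te, s0, left.open = TRUE)
  list(n0 = n0, n1 = n1, d0 = d0, d1 = d1)
}

#' @keywords internal
#' @noRd
fit_binary_ph <- function(t, delta, z, event, model,
                          tol_score = 1e-9, tol_step = 1e-10, max_iter = 50L) {
  if (length(unique(z)) < 2L) {
    abort("Treatment indicator is constant: effect is non-identifiable.",
          class = "crconfound_non_identifiable")
  }
  rc <- risk_counts(t, delta, z, event, model)
  d <- rc$d0 + rc$d1
  s1_events <- sum(rc$d1)

  score_info <- function(b) {
    eb <- exp(b)
    denom <- rc$n0 + rc$n1 * eb
    mu <- rc$n1 * eb / denom
    list(
      score = s1_events - sum(d * mu),
      info = sum(d * mu * (1 - mu)),
      loglik = s1_events * b - sum(d * log(denom))
    )
  }

  b <- 0
  converged <- FALSE
  iter <- 0L
  si <- score_info(b)
  while (iter < max_iter) {
    iter <- iter + 1L
    if (si$info <= 0) break
    step <- si$score / si$info
    # step-halving safeguard: accept only steps that do not blow up
    new_b <- b + step
    si_new <- score_info(new_b)
    halvings <- 0L
    while (halvings < 30L &&
           (!is.finite(si_new$loglik) || si_new$loglik < si$loglik - 1e-12)) {
      step <- step / 2
      new_b <- b + step
      si_new <- score_info(new_b)
      halvings <- halvings + 1L
    }
    b <- new_b
    si <- si_new
    if (abs(si$score) < tol_score || abs(step) < tol_step) {
      converged <- TRUE
      break
    }
  }
  se <- if (si$info > 0) 1 / sqrt(si$info) else NA_real_
  structure(
    list(
      model = model,
      event = as.integer(event),
      coef = b,
      se = se,
      loglik = si$loglik,
      n = length(t),
      n_events = sum(d),
      converged = converged && is.finite(b),
      iterations = iter
    ),
    class = "cr_fit"
  )
}

check_sample <- function(data, event) {
  req <- c("t", "delta", "z")
  if (!is.data.frame(data) || !all(req %in% names(data))) {
    abort("`data` must contain columns `t`, `delta` and `z`.",
          class = "crconfound_invalid_parameter")
  }
  if (anyNA(data[req])) {
    abort("`t`, `delta`, `z` must not contain missing values.",
          class = "crconfound_invalid_parameter")
  }
  if (!all(data$delta %in% c(1, 2))) {
    abort("`delta` must only take values 1 and 2.",
          class = "crconfound_invalid_parameter")
  }
  if (!all(data$z %in% c(0, 1))) {
    abort("`z` must be a 0/1 treatment indicator.",
          class = "crconfound_invalid_parameter")
  }
  if (!event %in% c(1, 2)) {
    abort("`event` must be 1 or 2.", class = "crconfound_invalid_parameter")
  }
}

#' Cause-specific Cox model for a binary treatment
#'
#' Maximises the Cox partial likelihood for the single indicator covariate
#' `z`, treating the competing event as censoring at its time: the risk set
#' at an event time `s` is every subject with `T >= s`. Fitting is
#' Newton-Raphson from 0 with step-halving, Breslow handling of ties, and a
#' model-based standard error from the observed information.
#'
#' @param data Data frame with columns `t` (event time), `delta` (1 or 2)
#'   and `z` (0/1 treatment); extra columns such as the unmeasured
#'   confounder `u` are ignored — the analysis model deliberately omits it.
#' @param event Which event to model: 1 (event-of-interest) or 2
#'   (competing event).
#' @return An object of class `"cr_fit"`; see [tidy.cr_fit()] and
#'   [glance.cr_fit()].
#' @examples
#' pop <- generate_confounded_covariates(2000, rho = 0.4, pi = 0.5, seed = 1)
#' sim <- simulate_events(pop, hazard_params(beta1 = -1, gamma1 = -1), seed = 2)
#' tidy(cox_cause_specific(sim, event = 1))
#' @seealso [fine_gray()]
#' @export
cox_cause_specific <- function(data, event = 1) {
  check_sample(data, event)
  fit_binary_ph(data$t, data$delta, data$z, event, "cause_specific")
}

#' Fine-Gray subdistribution model for a binary treatment
#'
#' Maximises the subdistribution partial likelihood for the indicator
#' covariate `z`: the risk set at an event time `s` keeps subjects who
#' already had the competing event "forever", so it is everyone except
#' prior events of the modelled type. Because the design has no censoring,
#' all inverse-probability-of-censoring weights equal 1 and the fit is an
#' exact partial likelihood, not a weighted approximation. Optimiser, tie
#' handling and standard errors are as in [cox_cause_specific()].
#'
#' @inheritParams cox_cause_specific
#' @return An object of class `"cr_fit"`.
#' @export
fine_gray <- function(data, event = 1) {
  check_sample(data, event)
  fit_binary_ph(data$t, data$delta, data$z, event, "subdistribution")
}

#' @export
print.cr_fit <- function(x, ...) {
  cat(sprintf(
    "<cr_fit: %s, event %d> coef = %.5f (se %.5f), %d/%d events, %s in %d iter\n",
    x$model, x$event, x$coef, x$se, x$n_events, x$n,
    if (x$converged) "converged" else "NOT converged", x$iterations
  ))
  invisible(x)
}

#' Tidy a competing-risks fit
#'
#' @param x A `"cr_fit"` from [cox_cause_specific()] or [fine_gray()].
#' @param ... Unused.
#' @return A one-row tibble with `term`, `estimate` (log hazard ratio),
#'   `std.error`, `statistic` and `p.value`.
#' @method tidy cr_fit
#' @export
tidy.cr_fit <- function(x, ...) {
  stat <- x$coef / x$se
  tibble(
    term = "z",
    estimate = x$coef,
    std.error = x$se,
    statistic = stat,
    p.value = 2 * pnorm(-abs(stat))
  )
}

#' Glance at a competing-risks fit
#'
#' @inheritParams tidy.cr_fit
#' @return A one-row tibble with `model`, `event`, `n`, `n_events`,
#'   `logLik`, `converged` and `iterations`.
#' @method glance cr_fit
#' @export
glance.cr_fit <- function(x, ...) {
  tibble(
    model = x$model,
    event = x$event,
    n = x$n,
    n_events = x$n_events,
    logLik = x$loglik,
    converged = x$converged,
    iterations = x$iterations
  )
}
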