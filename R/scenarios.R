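# Scenario grid: eight built-in designs, each crossing 5 correlation values
# with 3 values of one varied parameter, at 100 repetitions of n = 10,000 by
# default (1,500 simulation runs per scenario).

RHO_GRID_MAIN <- c(0, 0.2, 0.4, 0.6, 0.797)
RHO_GRID_UNEVEN <- c(0, 0.14, 0.29, 0.42, 0.57)

#' Define a simulation scenario
#'
#' @param id Integer scenario identifier.
#' @param name Short descriptive label.
#' @param varied_param Which parameter the scenario varies:
#'   `"beta1"`, `"beta2"`, `"pi"` or `"k"`.
#' @param varied_values The (usually 3) values it takes.
#' @param rho_grid The (usually 5) confounder-treatment correlations.
#' @param gamma1,gamma2,beta1,beta2,k,baseline,pi Fixed parameter values
#'   (the varied one is overridden cell by cell).
#' @param n Subjects per simulated population.
#' @param reps Repetitions per cell.
#' @return A list of class `"scenario_spec"`.
#' @export
scenario_spec <- function(id, name, varied_param, varied_values,
                          rho_grid = RHO_GRID_MAIN,
                          gamma1 = 0, gamma2 = 0, beta1 = 0, beta2 = 0,
                          k = 1, baseline = "constant", pi = 0.5,
                          n = 10000L, reps = 100L) {
  varied_param <- match.arg(varied_param, c("beta1", "beta2", "pi", "k"))
  spec <- structure(
    list(id = as.integer(id), name = name, varied_param = varied_param,
         varied_values = varied_values, rho_grid = rho_grid,
         gamma1 = gamma1, gamma2 = gamma2, beta1 = beta1, beta2 = beta2,
         k = k, baseline = baseline, pi = pi,
         n = as.integer(n), reps = as.integer(reps)),
    class = "scenario_spec"
  )
  # every (rho, pi) cell must be feasible before any simulation runs
  for (v in varied_values) {
    pv <- if (varied_param == "pi") v else pi
    for (r in rho_grid) latent_correlation(r, pv)
  }
  spec
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "<scenario_spec %d: %s>\n  varies %s over {%s}; rho in {%s}\n  fixed: gamma1=%g gamma2=%g beta1=%g beta2=%g k=%g pi=%g baseline=%s\n  %d reps of n=%d per cell (%d runs)\n",
    x$id, x$name, x$varied_param,
    paste(signif(x$varied_values, 3), collapse = ", "),
    paste(signif(x$rho_grid, 3), collapse = ", "),
    x$gamma1, x$gamma2, x$beta1, x$beta2, x$k, x$pi, x$baseline,
    x$reps, x$n, length(x$rho_grid) * length(x$varied_values) * x$reps
  ))
  invisible(x)
}

#' The eight built-in scenarios
#'
#' Returns the study's scenario grid. Scenarios 1-4 and 6-8 cross
#' `rho` in `{0, 0.2, 0.4, 0.6, 0.797}` (0.797 being the feasibility bound
#' at `pi = 0.5`) with three values of one varied parameter; Scenario 5
#' varies the prevalence `pi` itself and uses the tighter grid
#' `{0, 0.14, 0.29, 0.42, 0.57}`. At the default 100 repetitions each
#' scenario comprises 5 x 3 x 100 = 1,500 simulation runs.
#'
#' \enumerate{
#'   \item No effect: `gamma1 = gamma2 = 0`, `beta1` varied in -1, 0, 1.
#'   \item Positive effect: treatment benefits both events
#'     (`gamma1 = gamma2 = -1`), `beta1` varied.
#'   \item Differential effect: `gamma1 = -1`, `gamma2 = 1`, `beta1` varied.
#'   \item Competing confounder: null treatment, confounder acts on the
#'     competing event only (`beta2` varied).
#'   \item Uneven arms: `gamma1 = -1`, `beta1 = 1`, `pi` varied in
#'     0.1, 0.5, 0.9.
#'   \item Uneven events: null treatment, `beta1 = 1`, `k` varied in
#'     0.5, 1, 2.
#'   \item Weibull baseline: Scenario 1 with `lambda0(t) = 2t`.
#'   \item Plausible baseline: Scenario 1 with the biologically plausible
#'     baseline.
#' }
#'
#' @param n,reps Population size and repetitions per cell, applied to all
#'   scenarios (defaults 10,000 and 100).
#' @return A named list of 8 [scenario_spec()] objects.
#' @export
builtin_scenarios <- function(n = 10000L, reps = 100L) {
  b1 <- c(-1, 0, 1)
  list(
    s1 = scenario_spec(1, "No Effect", "beta1", b1, n = n, reps = reps),
    s2 = scenario_spec(2, "Positive Effect", "beta1", b1,
                       gamma1 = -1, gamma2 = -1, n = n, reps = reps),
    s3 = scenario_spec(3, "Differential Effect", "beta1", b1,
                       gamma1 = -1, gamma2 = 1, n = n, reps = reps),
    s4 = scenario_spec(4, "Competing Confounder", "beta2", b1,
                       n = n, reps = reps),
    s5 = scenario_spec(5, "Uneven Arms", "pi", c(0.1, 0.5, 0.9),
                       rho_grid = RHO_GRID_UNEVEN,
                       gamma1 = -1, gamma2 = 0, beta1 = 1,
                       n = n, reps = reps),
    s6 = scenario_spec(6, "Uneven Events", "k", c(0.5, 1, 2),
                       beta1 = 1, n = n, reps = reps),
    s7 = scenario_spec(7, "Weibull Distribution", "beta1", b1,
                       baseline = "weibull", n = n, reps = reps),
    s8 = scenario_spec(8, "Plausible Distribution", "beta1", b1,
                       baseline = "plausible", n = n, reps = reps)
  )
}

cell_params <- function(spec, varied_value) {
  pi <- spec$pi
  hp_args <- list(beta1 = spec$beta1, beta2 = spec$beta2,
                  gamma1 = spec$gamma1, gamma2 = spec$gamma2,
                  k = spec$k, baseline = spec$baseline)
  if (spec$varied_param == "pi") {
    pi <- varied_value
  } else {
    hp_args[[spec$varied_param]] <- varied_value
  }
  list(hp = do.call(hazard_params, hp_args), pi = pi)
}

#' Run one simulation cell
#'
#' Executes `reps` repetitions at a single (`rho`, parameter) combination.
#' Each repetition generates a confounded population and an independent
#' paired hypothetical-RCT population (`rho = 0`, `pi = 0.5`, same size and
#' hazard parameters), simulates competing event times for both, fits the
#' cause-specific and subdistribution models for both events on the
#' confounded data and the subdistribution models on the RCT data, and
#' records the estimates. Non-converged fits are dropped with a warning;
#' more than 5% exclusions aborts the cell.
#'
#' @param hp A [hazard_params()] object.
#' @param rho,pi Generating correlation and prevalence.
#' @param n Subjects per population.
#' @param reps Number of repetitions (>= 2).
#' @param seed Master seed for the cell; per-repetition substreams are
#'   derived from it up front, so results do not depend on execution order.
#' @param truths Optional precomputed [true_effects()]; computed via the
#'   expected-score method if omitted.
#' @return A list with `records` (per-rep tibble), `bias`
#'   (a [compute_bias_measures()] table) and `truths`.
#' @export
run_cell <- function(hp, rho, pi = 0.5, n = 10000L, reps = 100L, seed = 1L,
                     truths = NULL) {
  stopifnot(inherits(hp, "hazard_params"), reps >= 2L)
  if (is.null(truths)) {
    truths <- true_effects(hp, rho, pi, method = "expected_score")
  }
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, 4L * reps), nrow = reps)
  records <- purrr::map_dfr(seq_len(reps), function(rep_i) {
    sim <- simulate_events(
      generate_confounded_covariates(n, rho = rho, pi = pi,
                                     seed = seeds[rep_i, 1L]),
      hp, seed = seeds[rep_i, 2L]
    )
    rct <- simulate_events(
      generate_confounded_covariates(n, rho = 0, pi = 0.5,
                                     seed = seeds[rep_i, 3L]),
      hp, seed = seeds[rep_i, 4L]
    )
    purrr::map_dfr(1:2, function(ev) {
      cs <- cox_cause_specific(sim, event = ev)
      fg <- fine_gray(sim, event = ev)
      fg0 <- fine_gray(rct, event = ev)
      tibble(
        rep = rep_i, event = ev,
        gamma_hat = cs$coef, Gamma_hat = fg$coef, Gamma_hat_rct = fg0$coef,
        converged = cs$converged && fg$converged && fg0$converged
      )
    })
  })
  n_bad <- sum(!records$converged)
  if (n_bad > 0) {
    if (n_bad / nrow(records) > 0.05) {
      abort(sprintf("%d of %d fits failed to converge (> 5%%).",
                    n_bad, nrow(records)),
            class = "crconfound_convergence")
    }
    warning(sprintf("Excluding %d non-converged repetition records.", n_bad))
    records <- records[records$converged, ]
  }
  records$converged <- NULL
  attr(records, "rho") <- rho
  list(records = records, bias = compute_bias_measures(records, truths),
       truths = truths)
}

#' Run a full scenario grid
#'
#' Executes every (`rho`, varied value) cell of a [scenario_spec()],
#' computing the least-false effects once per cell and pooling bias
#' measures over repetitions. Deterministic for a given `master_seed`
#' regardless of execution order: each cell's seed is derived up front.
#'
#' @param spec A [scenario_spec()].
#' @param master_seed Integer seed governing the whole grid.
#' @param workers Number of parallel workers for cells (forked via
#'   `parallel::mclapply`; 1 = sequential). Results are identical for any
#'   worker count.
#' @param gamma_method Method for the least-false effects
#'   (see [true_effects()]).
#' @return A tibble of class `"scenario_result"`: one row per (cell, event,
#'   measure) with columns `scenario`, `name`, `rho`, `varied_param`,
#'   `varied_value`, `event`, `measure`, `estimate`, `ci_low`, `ci_high`,
#'   `mc_se`, `n_reps`, plus the per-cell `Gamma` truth used.
#' @export
run_scenario <- function(spec, master_seed = 1L, workers = 1L,
                         gamma_method = "expected_score") {
  stopifnot(inherits(spec, "scenario_spec"))
  cells <- tidyr::expand_grid(rho = spec$rho_grid,
                              varied_value = spec$varied_values)
  set.seed(master_seed)
  cell_seeds <- sample.int(.Machine$integer.max - 1L, nrow(cells))
  run_one <- function(i) {
    cp <- cell_params(spec, cells$varied_value[i])
    truths <- true_effects(cp$hp, cells$rho[i], cp$pi, method = gamma_method,
                           seed = cell_seeds[i])
    res <- run_cell(cp$hp, cells$rho[i], cp$pi, n = spec$n, reps = spec$reps,
                    seed = cell_seeds[i], truths = truths)
    dplyr::mutate(
      as_tibble(res$bias),
      scenario = spec$id, name = spec$name,
      rho = cells$rho[i],
      varied_param = spec$varied_param,
      varied_value = cells$varied_value[i],
      Gamma = ifelse(.data$event == 1, truths$Gamma1, truths$Gamma2),
      .before = 1
    )
  }
  out <- if (workers > 1L) {
    dplyr::bind_rows(parallel::mclapply(seq_len(nrow(cells)), run_one,
                                        mc.cores = workers))
  } else {
    dplyr::bind_rows(lapply(seq_len(nrow(cells)), run_one))
  }
  class(out) <- c("scenario_result", class(out))
  out
}
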