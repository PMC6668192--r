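#' Maximum achievable |Corr(U, Z)| for a given treatment prevalence
#'
#' A standard-normal confounder `U` and a binary treatment `Z` with
#' `P(Z = 1) = pi` cannot be arbitrarily strongly correlated. Under the
#' latent-threshold construction used by [generate_confounded_covariates()]
#' (`Z = 1` when a latent normal exceeds the `1 - pi` quantile), the Pearson
#' correlation is bounded by
#' \deqn{\frac{\phi(c)}{\sqrt{\pi(1-\pi)}}, \quad c = \Phi^{-1}(1-\pi),}
#' attained when the latent variable equals `U` itself. At `pi = 0.5` the
#' bound is 0.7979; it shrinks towards 0 as the arms become more uneven.
#'
#' @param pi Treatment prevalence, a number (or vector) strictly between 0
#'   and 1.
#' @return The supremum of `|Corr(U, Z)|`, same length as `pi`.
#' @examples
#' max_abs_correlation(0.5) # 0.7979
#' max_abs_correlation(0.1) # 0.5847; symmetric in pi <-> 1 - pi
#' @export
max_abs_correlation <- function(pi) {
  if (!is.numeric(pi) || any(!is.finite(pi)) || any(pi <= 0) || any(pi >= 1)) {
    abort("`pi` must lie strictly between 0 and 1.",
          class = "crconfound_invalid_parameter")
  }
  dnorm(qnorm(1 - pi)) / sqrt(pi * (1 - pi))
}

#' Latent bivariate-normal correlation needed to hit a target Corr(U, Z)
#'
#' Inverse of the dichotomised-bivariate-normal correlation map: returns the
#' correlation `r` such that if `(U, V)` is standard bivariate normal with
#' correlation `r` and `Z = 1{V > c}` with `c` the `(1 - pi)` quantile, then
#' `Corr(U, Z) = rho`. Because `Cov(U, Z) = r * phi(c)` in that construction,
#' the inverse is linear: `r = rho * sqrt(pi (1 - pi)) / phi(c)`.
#'
#' @param rho Target Pearson correlation between `U` and `Z`.
#' @param pi Treatment prevalence in (0, 1).
#' @return The latent correlation, in \eqn{[-1, 1]}.
#' @export
latent_correlation <- function(rho, pi) {
  bound <- max_abs_correlation(pi)
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho)) {
    abort("`rho` must be a single finite number.",
          class = "crconfound_invalid_parameter")
  }
  if (abs(rho) > bound + 1e-12) {
    abort(
      sprintf(
        "Corr(U, Z) = %.4g is infeasible at pi = %.4g: |rho| must be <= %.4f.",
        rho, pi, bound
      ),
      class = "crconfound_infeasible_correlation"
    )
  }
  r <- rho * sqrt(pi * (1 - pi)) / dnorm(qnorm(1 - pi))
  min(max(r, -1), 1)
}

#' Parameters for a confounded population
#'
#' Bundles the population size, target correlation, treatment prevalence and
#' RNG seed, validating feasibility up front so scenario grids cannot
#' silently run at an unattainable correlation.
#'
#' @param n Number of subjects (>= 2).
#' @param rho Target `Corr(U, Z)`; must satisfy
#'   `|rho| <= max_abs_correlation(pi)`.
#' @param pi Treatment prevalence `P(Z = 1)`, in (0, 1).
#' @param seed Integer RNG seed.
#' @return A list of class `"population_params"`.
#' @export
population_params <- function(n, rho, pi, seed) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n)) {
    abort("`n` must be a single integer >= 2.",
          class = "crconfound_invalid_parameter")
  }
  latent_correlation(rho, pi) # validates rho, pi jointly
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single integer.",
          class = "crconfound_invalid_parameter")
  }
  structure(
    list(n = as.integer(n), rho = rho, pi = pi, seed = as.integer(seed)),
    class = "population_params"
  )
}

#' Generate a confounded population
#'
#' Draws `n` subjects with an unmeasured confounder `U ~ N(0, 1)` and a
#' binary treatment `Z` such that `P(Z = 1) = pi` and `Corr(U, Z) = rho`.
#' `(U, V)` is drawn bivariate standard normal with correlation
#' [latent_correlation()]`(rho, pi)` and `Z = 1{V > c}` with
#' `c = qnorm(1 - pi)`, so larger latent values mean treated and the sign of
#' `rho` carries through to the population.
#'
#' @param params A [population_params()] object, or `n` if the remaining
#'   arguments are given directly.
#' @param rho,pi,seed Used when `params` is a plain population size.
#' @return A tibble with columns `id` (0-based), `u` and `z`.
#' @examples
#' pop <- generate_confounded_covariates(1000, rho = 0.4, pi = 0.5, seed = 1)
#' cor(pop$u, pop$z)
#' @export
generate_confounded_covariates <- function(params, rho = NULL, pi = NULL,
                                           seed = NULL) {
  if (!inherits(params, "population_params")) {
    params <- population_params(params, rho, pi, seed)
  }
  r <- latent_correlation(params$rho, params$pi)
  cc <- qnorm(1 - params$pi)
  set.seed(params$seed)
  u <- rnorm(params$n)
  v <- r * u + sqrt(max(0, 1 - r^2)) * rnorm(params$n)
  tibble(
    id = seq_len(params$n) - 1L,
    u = u,
    z = as.integer(v > cc)
  )
}
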