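#' Nutrient-dependent host and phage physiology
#'
#' Parameters of the shared nutrient-response model: Monod growth of the
#' host, and the latency/burst-size dependence of the phage on host
#' physiology. These functions are common to every model in the package.
#'
#' The latent period is modelled as an Erlang chain of `N_stages`
#' sequential sub-states, so that the time from infection to burst has
#' mean `tau(n)` and relative standard deviation `1/sqrt(N_stages)`.
#' `tau0` is the *total* minimum latency (the mean latent period at the
#' reference nutrient level); per-sub-state rates are always derived as
#' `N_stages / tau(n)`.
#'
#' @param g_max maximum host growth rate (1/min).
#' @param K_n Monod constant: nutrient level at half-maximum growth
#'   (same units as the nutrient field, per mL or per um^2).
#' @param beta0 maximum burst size (phages released per lysing cell).
#' @param tau0 total minimum latent period (min) at the reference
#'   nutrient level.
#' @param r_l ratio of minimum to maximum latency-time dependence, in
#'   \[0, 1\]. `r_l = 0` makes the latency diverge as nutrient runs out
#'   (lysis arrest under starvation).
#' @param r_b ratio of minimum to maximum burst size, in \[0, 1\].
#' @param n_ref reference (initial) nutrient level used to normalize the
#'   growth-rate dependence.
#' @param N_stages number of sequential infection sub-states (Erlang
#'   shape parameter).
#'
#' @return An object of class `nutrient_response`.
#' @export
#' @examples
#' p <- nutrient_response()
#' growth_rate(1e9, p)       # Monod growth at the reference nutrient
#' burst_size(0, p)          # starvation burst size = r_b * beta0
#' stage_rate(1e9, p)        # per-sub-state progression rate, 1/min
nutrient_response <- function(g_max = 0.034, K_n = 2e8, beta0 = 150,
                              tau0 = 20, r_l = 0.5, r_b = 0.1,
                              n_ref = 1e9, N_stages = 10L) {
  stopifnot(
    "g_max must be > 0" = is.numeric(g_max) && g_max > 0,
    "K_n must be > 0" = is.numeric(K_n) && K_n > 0,
    "beta0 must be > 0" = is.numeric(beta0) && beta0 > 0,
    "tau0 must be > 0" = is.numeric(tau0) && tau0 > 0,
    "r_l must be in [0, 1]" = is.numeric(r_l) && r_l >= 0 && r_l <= 1,
    "r_b must be in [0, 1]" = is.numeric(r_b) && r_b >= 0 && r_b <= 1,
    "n_ref must be > 0" = is.numeric(n_ref) && n_ref > 0,
    "N_stages must be a positive integer" =
      is.numeric(N_stages) && N_stages >= 1 && N_stages == round(N_stages)
  )
  structure(
    list(g_max = g_max, K_n = K_n, beta0 = beta0, tau0 = tau0,
         r_l = r_l, r_b = r_b, n_ref = n_ref, N_stages = as.integer(N_stages)),
    class = "nutrient_response"
  )
}

#' @export
print.nutrient_response <- function(x, ...) {
  cat("Nutrient response parameters\n")
  cat(sprintf("  g_max = %g /min, K_n = %g, n_ref = %g\n", x$g_max, x$K_n, x$n_ref))
  cat(sprintf("  beta0 = %g, r_b = %g; tau0 = %g min (total), r_l = %g; N = %d stages\n",
              x$beta0, x$r_b, x$tau0, x$r_l, x$N_stages))
  invisible(x)
}

#' Monod growth rate
#'
#' `g(n) = g_max * n / (K_n + n)`: zero at `n = 0`, half-maximal at
#' `n = K_n`, saturating at `g_max`.
#'
#' @param n nutrient level (>= 0); vectorized.
#' @param p a [nutrient_response()] object.
#' @return growth rate (1/min).
#' @export
growth_rate <- function(n, p) {
  if (any(n < 0)) stop("nutrient level must be nonnegative")
  p$g_max * n / (p$K_n + n)
}

#' Nutrient-dependent burst size
#'
#' `beta(n) = beta0 * (r_b + (1 - r_b) * g(n)/g(n_ref))`: equals `beta0`
#' at the reference nutrient and `r_b * beta0` under starvation.
#'
#' @inheritParams growth_rate
#' @return burst size (phages per lysing cell).
#' @export
burst_size <- function(n, p) {
  g_ref <- growth_rate(p$n_ref, p)
  if (g_ref <= 0) stop("reference nutrient level must give positive growth")
  p$beta0 * (p$r_b + (1 - p$r_b) * growth_rate(n, p) / g_ref)
}

#' Per-sub-state latency progression rate
#'
#' The latency chain advances through `N_stages` sub-states at rate
#' `N_stages / (f_tau * tau(n))` each, where
#' `tau(n) = tau0 / (r_l + (1 - r_l) * g(n)/g(n_ref))` is the mean latent
#' period. The rate form is used throughout so that `r_l = 0, n = 0`
#' gives rate 0 exactly (lysis arrest, not division by zero). `f_tau`
#' scales the whole chain uniformly, as in the lysis-inhibited state.
#'
#' @inheritParams growth_rate
#' @param f_tau latency fold-extension factor (>= 1); 1 for the normal
#'   infection chain, `f_tau` for the LIN chain.
#' @return per-sub-state progression rate (1/min).
#' @export
stage_rate <- function(n, p, f_tau = 1) {
  if (any(f_tau < 1)) stop("f_tau must be >= 1")
  g_ref <- growth_rate(p$n_ref, p)
  (p$N_stages / (f_tau * p$tau0)) *
    (p$r_l + (1 - p$r_l) * growth_rate(n, p) / g_ref)
}

#' Mean latent period at a given nutrient level
#'
#' `tau(n) = tau0 / (r_l + (1 - r_l) * g(n)/g(n_ref))`; `Inf` when the
#' denominator vanishes (`r_l = 0` and `n = 0`).
#'
#' @inheritParams stage_rate
#' @return mean latent period (min), possibly `Inf`.
#' @export
latency_time <- function(n, p, f_tau = 1) {
  r <- stage_rate(n, p, f_tau)
  ifelse(r > 0, p$N_stages / r, Inf)
}
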