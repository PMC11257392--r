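#' Time at which free phage overtakes uninfected bacteria
#'
#' Earliest time with total free phage (`R + P`) at least equal to the
#' uninfected bacteria concentration, located by linear interpolation
#' between samples. Around this time secondary adsorptions start to
#' dominate the dynamics.
#'
#' @param ts a `lin_timeseries` from [simulate_batch()].
#' @return time in minutes, or `NA` if the phage never catches up.
#' @export
phage_crossing_time <- function(ts) {
  d <- ts$R + ts$P - ts$B
  idx <- which(d >= 0)
  if (length(idx) == 0) return(NA_real_)
  i <- idx[1]
  if (i == 1) return(ts$time_min[1])
  t0 <- ts$time_min[i - 1]; t1 <- ts$time_min[i]
  d0 <- d[i - 1]; d1 <- d[i]
  t0 + (t1 - t0) * (-d0) / (d1 - d0)
}

#' Relative decline of free phage from its peak
#'
#' `(max_t X(t) - X(t_end)) / max_t X(t)` for a free-phage column, using
#' the global maximum over the sampled grid (earliest time on ties).
#' Returns 0 when the trajectory is nondecreasing to the end.
#'
#' @param ts a `lin_timeseries`.
#' @param strain `"R"` or `"P"`.
#' @return dimensionless decline in \[0, 1\].
#' @export
peak_decline <- function(ts, strain = "R") {
  x <- ts[[strain]]
  pk <- max(x)
  if (pk <= 0) return(0)
  max(0, (pk - x[length(x)]) / pk)
}

#' Final phage ratio in separate cultures
#'
#' Runs the LIN phage (M1) and the r-mutant (M0) in *separate* cultures
#' from identical initial conditions and returns the ratio of free phage
#' concentrations `P(t_end) / R(t_end)`.
#'
#' @param f_tau,f_beta LIN fold factors (>= 1).
#' @param response a [nutrient_response()].
#' @param eta adsorption rate (mL/min).
#' @param B0,n0,phage0 initial bacteria, nutrient and phage (/mL); the
#'   same `phage0` seeds `R` in M0 and `P` in M1.
#' @param t_end end time (min).
#' @param ... passed to [simulate_batch()].
#' @return list with `ratio` (`Inf` when `R(t_end) = 0`), `P_end`,
#'   `R_end`.
#' @export
final_phage_ratio_separate <- function(f_tau, f_beta,
                                       response = nutrient_response(),
                                       eta = 5e-10,
                                       B0 = 1e6, n0 = 1e9, phage0 = 1e3,
                                       t_end = 1200, ...) {
  pm0 <- well_mixed_params(response, eta, model_id = "M0")
  pm1 <- well_mixed_params(response, eta, f_tau = f_tau, f_beta = f_beta,
                           model_id = "M1")
  ts0 <- simulate_batch(pm0, batch_init(pm0, B0, n0, R0 = phage0),
                        t_end = t_end, ...)
  ts1 <- simulate_batch(pm1, batch_init(pm1, B0, n0, P0 = phage0),
                        t_end = t_end, ...)
  R_end <- ts0$R[nrow(ts0)]; P_end <- ts1$P[nrow(ts1)]
  list(ratio = if (R_end > 0) P_end / R_end else Inf,
       P_end = P_end, R_end = R_end)
}

#' Outcome of a mixed-culture competition (MC1)
#'
#' Integrates the competition model and summarizes it by (a) the final
#' free-phage ratio `P/R`, (b) the relative decline of free r-mutant
#' phage from its peak (caused by adsorption onto long-lived LIN-state
#' cells), and (c) the time at which total free phage overtakes the
#' uninfected bacteria.
#'
#' @inheritParams final_phage_ratio_separate
#' @param trigger_mode see [well_mixed_params()].
#' @param R0,P0 initial free phage of each strain (/mL).
#' @return list with `ratio` (`Inf` if `R(t_end) = 0`), `peak_decline_R`
#'   (fraction), `crossing_time_min`, and the full `timeseries`.
#' @export
competition_outcome <- function(f_tau, f_beta,
                                response = nutrient_response(),
                                eta = 5e-10,
                                B0 = 1e6, n0 = 1e9, R0 = 1e3, P0 = 1e3,
                                t_end = 1200,
                                trigger_mode = "any_phage", ...) {
  pm <- well_mixed_params(response, eta, f_tau = f_tau, f_beta = f_beta,
                          trigger_mode = trigger_mode, model_id = "MC1")
  ts <- simulate_batch(pm, batch_init(pm, B0, n0, R0 = R0, P0 = P0),
                       t_end = t_end, ...)
  R_end <- ts$R[nrow(ts)]; P_end <- ts$P[nrow(ts)]
  list(ratio = if (R_end > 0) P_end / R_end else Inf,
       peak_decline_R = peak_decline(ts, "R"),
       crossing_time_min = phage_crossing_time(ts),
       timeseries = ts)
}

#' Sweep the LIN fold factors
#'
#' Computes the log10 final phage ratio `P/R` over an `(f_tau, f_beta)`
#' grid, either with the two phages in separate cultures
#' (`mode = "separate"`: M1 vs a single shared M0 reference) or competing
#' in a mixed culture (`mode = "competition"`: MC1). The ratio-one
#' contour is extracted from the log10 matrix by interpolation.
#'
#' @param mode `"separate"` or `"competition"`.
#' @param f_tau_grid,f_beta_grid numeric grids (all values >= 1).
#' @param response,eta,B0,n0,phage0,t_end,trigger_mode as in the
#'   single-point operations; `phage0` seeds each strain present.
#' @param ... passed to [simulate_batch()].
#' @return An object of class `lin_sweep`: list with `log10_ratio`
#'   matrix (rows `f_tau`, columns `f_beta`), the grids, `mode`,
#'   `contour_one` (data.frame polyline, possibly empty) and `errors`
#'   (per-cell messages, `NA` where the cell succeeded).
#' @export
sweep_lin_grid <- function(mode = c("separate", "competition"),
                           f_tau_grid, f_beta_grid,
                           response = nutrient_response(), eta = 5e-10,
                           B0 = 1e6, n0 = 1e9, phage0 = 1e3, t_end = 1200,
                           trigger_mode = "any_phage", ...) {
  mode <- match.arg(mode)
  stopifnot(length(f_tau_grid) > 0, length(f_beta_grid) > 0,
            all(f_tau_grid >= 1), all(f_beta_grid >= 1))
  nt <- length(f_tau_grid); nb <- length(f_beta_grid)
  ratio <- matrix(NA_real_, nt, nb,
                  dimnames = list(paste0("f_tau=", f_tau_grid),
                                  paste0("f_beta=", f_beta_grid)))
  errors <- matrix(NA_character_, nt, nb)
  R_ref <- NULL
  if (mode == "separate") {
    pm0 <- well_mixed_params(response, eta, model_id = "M0")
    ts0 <- simulate_batch(pm0, batch_init(pm0, B0, n0, R0 = phage0),
                          t_end = t_end, ...)
    R_ref <- ts0$R[nrow(ts0)]
  }
  for (i in seq_len(nt)) for (j in seq_len(nb)) {
    res <- tryCatch({
      if (mode == "separate") {
        pm1 <- well_mixed_params(response, eta, f_tau = f_tau_grid[i],
                                 f_beta = f_beta_grid[j], model_id = "M1")
        ts1 <- simulate_batch(pm1, batch_init(pm1, B0, n0, P0 = phage0),
                              t_end = t_end, ...)
        if (R_ref > 0) ts1$P[nrow(ts1)] / R_ref else Inf
      } else {
        competition_outcome(f_tau_grid[i], f_beta_grid[j], response, eta,
                            B0, n0, R0 = phage0, P0 = phage0,
                            t_end = t_end, trigger_mode = trigger_mode,
                            ...)$ratio
      }
    }, error = function(e) e)
    if (inherits(res, "error")) errors[i, j] <- conditionMessage(res)
    else ratio[i, j] <- res
  }
  lg <- log10(ratio)
  contour_one <- data.frame(f_tau = numeric(0), f_beta = numeric(0))
  if (nt > 1 && nb > 1 && all(is.finite(lg))) {
    cl <- grDevices::contourLines(x = f_tau_grid, y = f_beta_grid, z = lg,
                                  levels = 0)
    if (length(cl) > 0)
      contour_one <- data.frame(f_tau = cl[[1]]$x, f_beta = cl[[1]]$y)
  }
  structure(list(log10_ratio = lg, f_tau_grid = f_tau_grid,
                 f_beta_grid = f_beta_grid, mode = mode,
                 contour_one = contour_one, errors = errors),
            class = "lin_sweep")
}

#' @export
print.lin_sweep <- function(x, digits = 3, ...) {
  cat(sprintf("LIN sweep (%s mode), log10(P/R):\n", x$mode))
  print(round(x$log10_ratio, digits))
  if (any(!is.na(x$errors)))
    cat(sprintf("  %d cell(s) failed\n", sum(!is.na(x$errors))))
  invisible(x)
}
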