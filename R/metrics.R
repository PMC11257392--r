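# Front-radius metrics of plaque morphology.

# Outermost sign change of f(r) along the radial grid, located by linear
# interpolation between adjacent cell centers. Scans from the outer
# boundary inward so the first bracket found is the outermost; NA when f
# never changes sign ("absent").
.outermost_crossing <- function(r, f) {
  M <- length(f)
  if (M < 2) return(NA_real_)
  prod <- f[-M] * f[-1]
  idx <- which(prod <= 0 & (f[-M] != 0 | f[-1] != 0))
  if (length(idx) == 0) return(NA_real_)
  j <- max(idx)
  r[j] + (r[j + 1] - r[j]) * f[j] / (f[j] - f[j + 1])
}

#' Front radii of a plaque snapshot
#'
#' Extracts the four radii that characterize the expanding infection,
#' each as the *outermost* crossing of its defining difference function,
#' interpolated linearly between cell centers:
#' \describe{
#'   \item{r_PB0}{largest r where the free phage density equals the
#'     initial lawn density `B0` (about one phage per microcolony: the
#'     furthest reach of likely infection).}
#'   \item{r_super}{largest r where free phage equals the total bacteria
#'     density; inside it secondary adsorptions dominate and LIN is
#'     likely induced.}
#'   \item{r_half}{largest r where total bacteria falls to half its
#'     value at the domain edge: the visible plaque radius.}
#'   \item{r_ZOI}{largest r where *uninfected* bacteria falls to half
#'     its edge value: the zone of infection.}
#' }
#' The half-value references are taken from the outermost grid cell of
#' the same snapshot (the undisturbed lawn), so lawn growth over time is
#' accounted for automatically. A radius with no crossing is reported as
#' `NA` ("absent").
#'
#' @param snapshot a `radial_field`.
#' @param B0 initial lawn density (/um^2) used for `r_PB0`.
#' @param half_fraction lawn-density fraction defining the visible
#'   clearing (default 0.5); lower values emulate a stricter clearing
#'   threshold.
#' @return An object of class `plaque_metrics`: list with `r_PB0`,
#'   `r_super`, `r_half`, `r_ZOI` (um or `NA`) and `time`.
#' @export
front_radii <- function(snapshot, B0, half_fraction = 0.5) {
  stopifnot(inherits(snapshot, "radial_field"),
            half_fraction > 0, half_fraction < 1)
  r <- snapshot$grid$r
  M <- snapshot$grid$M
  B_tot <- total_bacteria(snapshot)
  ph <- snapshot$phage
  structure(list(
    r_PB0 = .outermost_crossing(r, ph - B0),
    r_super = .outermost_crossing(r, ph - B_tot),
    r_half = .outermost_crossing(r, B_tot - half_fraction * B_tot[M]),
    r_ZOI = .outermost_crossing(r, snapshot$B - half_fraction * snapshot$B[M]),
    time = snapshot$time
  ), class = "plaque_metrics")
}

#' @export
print.plaque_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "absent" else sprintf("%.1f um", v)
  cat(sprintf("Front radii at t = %g min: r_PB0 = %s, r_super = %s, r_half = %s, r_ZOI = %s\n",
              x$time, fmt(x$r_PB0), fmt(x$r_super), fmt(x$r_half), fmt(x$r_ZOI)))
  invisible(x)
}

#' Time at which a front metric settles to its final value
#'
#' Earliest sampled time after which the metric stays within
#' `rel_tol` (relative) of its value at the last sample: the arrest time
#' of plaque expansion.
#'
#' @param metrics the `metrics` data.frame of a `plaque_sim`.
#' @param metric column name, e.g. `"r_half"` or `"r_ZOI"`.
#' @param rel_tol relative settling tolerance (default 1 percent).
#' @return time (min), or `NA` if the metric is absent at the end.
#' @export
settling_time <- function(metrics, metric = "r_half", rel_tol = 0.01) {
  m <- metrics[[metric]]
  t <- metrics$time_min
  final <- m[length(m)]
  if (is.na(final) || final <= 0) return(NA_real_)
  ok <- !is.na(m) & abs(m - final) / final < rel_tol
  # earliest index from which every later sample (inclusive) is settled
  settled <- rev(cumprod(rev(ok))) > 0
  t[which(settled)[1]]
}

#' Plaque-morphology ratios over the LIN parameter grid
#'
#' Runs the r-mutant plaque (MP0) once as the reference and the LIN
#' plaque (MP1) for every `(f_tau, f_beta)` grid cell, and returns the
#' ratios of the visible plaque radius `r_half` and of the zone of
#' infection `r_ZOI` (LIN / r-mutant), evaluated at `t_eval`.
#'
#' @param f_tau_grid,f_beta_grid numeric grids (>= 1).
#' @param params a [plaque_params()]; its `f_tau`/`f_beta` are
#'   overridden per cell.
#' @param t_eval evaluation time (min), default 300.
#' @param reference optional precomputed MP0 `plaque_sim` to reuse.
#' @return An object of class `plaque_sweep`: list with matrices
#'   `r_half_ratio` and `r_ZOI_ratio` (rows `f_tau`, columns `f_beta`),
#'   the grids, `t_eval`, the reference radii, and per-cell `errors`
#'   (`NA` where the cell succeeded; failed cells hold `NA` ratios).
#' @export
plaque_ratio_sweep <- function(f_tau_grid, f_beta_grid, params = plaque_params(),
                               t_eval = 300, reference = NULL) {
  stopifnot(all(f_tau_grid >= 1), all(f_beta_grid >= 1))
  if (is.null(reference))
    reference <- simulate_plaque(params, "r_mutant",
                                 sample_times = seq(0, t_eval, by = 10))
  mref <- reference$metrics
  ref_half <- stats::approx(mref$time_min, mref$r_half, t_eval)$y
  ref_zoi <- stats::approx(mref$time_min, mref$r_ZOI, t_eval)$y
  nt <- length(f_tau_grid); nb <- length(f_beta_grid)
  dn <- list(paste0("f_tau=", f_tau_grid), paste0("f_beta=", f_beta_grid))
  r_half_ratio <- matrix(NA_real_, nt, nb, dimnames = dn)
  r_ZOI_ratio <- matrix(NA_real_, nt, nb, dimnames = dn)
  errors <- matrix(NA_character_, nt, nb)
  for (i in seq_len(nt)) for (j in seq_len(nb)) {
    res <- tryCatch({
      p <- params
      p$f_tau <- f_tau_grid[i]; p$f_beta <- f_beta_grid[j]
      sim <- simulate_plaque(p, "lin_phage",
                             sample_times = seq(0, t_eval, by = 10))
      m <- sim$metrics
      c(stats::approx(m$time_min, m$r_half, t_eval)$y / ref_half,
        stats::approx(m$time_min, m$r_ZOI, t_eval)$y / ref_zoi)
    }, error = function(e) e)
    if (inherits(res, "error")) errors[i, j] <- conditionMessage(res)
    else { r_half_ratio[i, j] <- res[1]; r_ZOI_ratio[i, j] <- res[2] }
  }
  structure(list(r_half_ratio = r_half_ratio, r_ZOI_ratio = r_ZOI_ratio,
                 f_tau_grid = f_tau_grid, f_beta_grid = f_beta_grid,
                 t_eval = t_eval, ref_r_half = ref_half, ref_r_ZOI = ref_zoi,
                 errors = errors),
            class = "plaque_sweep")
}

#' @export
print.plaque_sweep <- function(x, digits = 3, ...) {
  cat(sprintf("Plaque morphology sweep at t = %g min (LIN / r-mutant):\n",
              x$t_eval))
  cat("r_half ratio:\n"); print(round(x$r_half_ratio, digits))
  cat("r_ZOI ratio:\n"); print(round(x$r_ZOI_ratio, digits))
  invisible(x)
}
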