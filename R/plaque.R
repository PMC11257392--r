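#' Annular finite-volume grid for radially symmetric fields
#'
#' Cell centers at `r_j = (j - 1/2) dr`, `j = 1..M`, with `M = R_max/dr`
#' rounded to the nearest integer; annulus areas
#' `A_j = pi ((r_j + dr/2)^2 - (r_j - dr/2)^2)`. The first center sits at
#' `dr/2`, so the `1/r` coordinate singularity is never evaluated, and
#' the areas sum to `pi R_max^2` exactly.
#'
#' @param R_max domain radius (um).
#' @param dr grid spacing (um).
#' @return An object of class `radial_grid` with components `r`
#'   (centers), `r_face` (interior face radii), `A` (areas), `dr`, `M`,
#'   `R_max`.
#' @export
radial_grid <- function(R_max = 10000, dr = 20) {
  stopifnot(R_max > dr, dr > 0)
  M <- round(R_max / dr)
  r <- (seq_len(M) - 0.5) * dr
  structure(list(r = r,
                 r_face = seq_len(M - 1) * dr,
                 A = pi * (((r + dr / 2)^2) - ((r - dr / 2)^2)),
                 dr = dr, M = M, R_max = M * dr),
            class = "radial_grid")
}

#' @export
print.radial_grid <- function(x, ...) {
  cat(sprintf("Radial grid: %d annuli, dr = %g um, R_max = %g um\n",
              x$M, x$dr, x$R_max))
  invisible(x)
}

#' Conservative radial diffusion operator
#'
#' Finite-volume Laplacian in polar symmetry for a per-area density:
#' the flux across the face at radius `r` is
#' `-D * 2 pi r * du/dr`, with zero flux at the origin (symmetry) and at
#' `R_max` (reflecting boundary). The operator conserves
#' `sum_j A_j u_j` exactly.
#'
#' @param u per-area density at the cell centers (length `M`), or a
#'   matrix with `M` columns (one row per species/stage).
#' @param D diffusivity (um^2/min, >= 0).
#' @param grid a [radial_grid()].
#' @return rate of change of `u` (same shape).
#' @export
radial_diffusion <- function(u, D, grid) {
  if (D < 0) stop("diffusivity must be nonnegative")
  if (is.matrix(u)) return(t(apply(u, 1, radial_diffusion, D = D, grid = grid)))
  stopifnot(length(u) == grid$M)
  flux <- 2 * pi * grid$r_face * D * diff(u) / grid$dr
  (c(flux, 0) - c(0, flux)) / grid$A
}

#' Plaque-formation model parameters
#'
#' Radially symmetric reaction-diffusion versions of the batch models:
#' MP0 (r-mutant) and MP1 (LIN phage). All densities are per-area
#' (per um^2), obtained by integrating over the soft-agar thickness
#' `delta_a`; accordingly the volumetric adsorption rate `eta` (mL/min)
#' is converted to a per-area rate `eta * 1e12 / delta_a` (um^2/min,
#' using 1 mL = 1e12 um^3). Only phage and nutrient diffuse; bacteria
#' are immobile in the soft agar. The latency ratio `r_l` is 0 so that
#' the latent period diverges when the nutrient runs out, arresting
#' plaque expansion.
#'
#' @param g_max,beta0,tau0,r_b,N_stages as in [nutrient_response()].
#' @param r_l latency ratio; default 0 (starvation arrest).
#' @param k_n per-area Monod constant (/um^2), default `n0/5`.
#' @param eta volumetric adsorption rate (mL/min) before division by the
#'   agar thickness.
#' @param f_tau,f_beta,trigger_mode LIN parameters (used by MP1).
#' @param delta_a soft-agar thickness (um).
#' @param D_p,D_n phage and nutrient diffusivities (um^2/min).
#' @param B0,n0 initial lawn bacteria and nutrient (/um^2).
#' @param R_max,dr domain radius and grid spacing (um).
#' @param t_end integration end time (min).
#' @return An object of class `plaque_params`.
#' @export
plaque_params <- function(g_max = 0.034, k_n = 0.1, beta0 = 150, tau0 = 20,
                          r_l = 0, r_b = 0.1, N_stages = 10L,
                          eta = 5e-10, f_tau = 1, f_beta = 1,
                          trigger_mode = "any_phage",
                          delta_a = 500, D_p = 240, D_n = 5e4,
                          B0 = 1 / 400, n0 = 0.5,
                          R_max = 10000, dr = 20, t_end = 400) {
  stopifnot("delta_a must be > 0" = delta_a > 0,
            "diffusivities must be >= 0" = D_p >= 0 && D_n >= 0,
            "need R_max > dr > 0" = R_max > dr && dr > 0,
            "B0, n0 must be > 0" = B0 > 0 && n0 > 0)
  response <- nutrient_response(g_max = g_max, K_n = k_n, beta0 = beta0,
                                tau0 = tau0, r_l = r_l, r_b = r_b,
                                n_ref = n0, N_stages = N_stages)
  eta_area <- eta * 1e12 / delta_a  # mL/min -> um^3/min, / agar depth
  structure(list(response = response, eta = eta, eta_area = eta_area,
                 f_tau = f_tau, f_beta = f_beta, trigger_mode = trigger_mode,
                 delta_a = delta_a, D_p = D_p, D_n = D_n,
                 B0 = B0, n0 = n0, grid = radial_grid(R_max, dr),
                 t_end = t_end),
            class = "plaque_params")
}

#' @export
print.plaque_params <- function(x, ...) {
  cat(sprintf(
    "Plaque model: eta/delta_a = %g um^2/min, D_p = %g, D_n = %g um^2/min\n",
    x$eta_area, x$D_p, x$D_n))
  cat(sprintf("  lawn B0 = %g /um^2, n0 = %g /um^2, f_tau = %g, f_beta = %g\n",
              x$B0, x$n0, x$f_tau, x$f_beta))
  print(x$grid)
  invisible(x)
}

# Internal: well_mixed_params view of a plaque_params in per-area units.
.plaque_wm <- function(params, strain) {
  well_mixed_params(response = params$response, eta = params$eta_area,
                    f_tau = params$f_tau, f_beta = params$f_beta,
                    trigger_mode = params$trigger_mode,
                    model_id = if (strain == "r_mutant") "M0" else "M1")
}

#' Initial field for a single-plaque simulation
#'
#' A uniform lawn (`B = B0`, `n = n0` everywhere), no free phage, and a
#' discrete Dirac delta of freshly infected cells: stage-1 infected
#' density `1/A_1` in the innermost annulus, i.e. exactly one infected
#' bacterium in the whole domain.
#'
#' @param params a [plaque_params()].
#' @param strain `"r_mutant"` (MP0) or `"lin_phage"` (MP1).
#' @return An object of class `radial_field`: list with `grid`, `time`,
#'   `strain`, and per-area fields `B`, `n`, `phage`, `I` (stages x
#'   cells) and `L` (stages x cells; all zero for the r-mutant).
#' @export
initial_plaque_state <- function(params, strain = c("r_mutant", "lin_phage")) {
  strain <- match.arg(strain)
  g <- params$grid
  N <- params$response$N_stages
  I <- matrix(0, N, g$M)
  I[1, 1] <- 1 / g$A[1]
  structure(list(grid = g, time = 0, strain = strain,
                 B = rep(params$B0, g$M), n = rep(params$n0, g$M),
                 phage = rep(0, g$M), I = I, L = matrix(0, N, g$M)),
            class = "radial_field")
}

#' @export
print.radial_field <- function(x, ...) {
  cat(sprintf("Radial field (%s) at t = %g min on %d annuli\n",
              x$strain, x$time, x$grid$M))
  cat(sprintf("  total B = %g, nutrient = %g, free phage = %g\n",
              sum(x$B * x$grid$A), sum(x$n * x$grid$A),
              sum(x$phage * x$grid$A)))
  invisible(x)
}

#' Total (uninfected + infected + LIN) bacteria profile of a field
#'
#' @param field a `radial_field`.
#' @return per-area density vector, length `M`.
#' @export
total_bacteria <- function(field) {
  field$B + colSums(field$I) + colSums(field$L)
}

# Internal pack/unpack: species-major layout for deSolve::ode.1D.
.pl_pack <- function(field) {
  c(field$B, field$n, field$phage,
    as.vector(t(field$I)),
    if (field$strain == "lin_phage") as.vector(t(field$L)))
}

.pl_unpack <- function(y, params, strain, time) {
  M <- params$grid$M; N <- params$response$N_stages
  Y <- matrix(pmax(y, 0), nrow = M)
  I <- t(Y[, 3 + seq_len(N), drop = FALSE])
  L <- if (strain == "lin_phage") t(Y[, 3 + N + seq_len(N), drop = FALSE])
       else matrix(0, N, M)
  structure(list(grid = params$grid, time = time, strain = strain,
                 B = Y[, 1], n = Y[, 2], phage = Y[, 3], I = I, L = L),
            class = "radial_field")
}

#' Simulate plaque formation (MP0 / MP1)
#'
#' Method-of-lines integration of the radially symmetric
#' reaction-diffusion model: the batch reaction terms evaluated
#' pointwise with the local nutrient density (normalized by the growth
#' rate at the initial per-area nutrient `n0`), plus conservative radial
#' diffusion of the free phage (`D_p`) and the nutrient (`D_n`).
#' Bacteria do not move. Integration uses the banded-Jacobian stiff
#' solver of [deSolve::ode.1D()].
#'
#' @param params a [plaque_params()].
#' @param strain `"r_mutant"` (MP0) or `"lin_phage"` (MP1).
#' @param sample_times times (min) at which fields are recorded; default
#'   every 10 min up to `params$t_end`.
#' @param init optional initial `radial_field`; default
#'   [initial_plaque_state()].
#' @param rtol,atol integration tolerances (`atol` in /um^2).
#' @return An object of class `plaque_sim`: list with `fields` (one
#'   `radial_field` per sample time), `metrics` (data.frame `time_min,
#'   r_PB0, r_super, r_half, r_ZOI` from [front_radii()]), `params`,
#'   `strain`.
#' @export
simulate_plaque <- function(params, strain = c("r_mutant", "lin_phage"),
                            sample_times = NULL, init = NULL,
                            rtol = 1e-6, atol = 1e-12) {
  strain <- match.arg(strain)
  if (is.null(sample_times))
    sample_times <- seq(0, params$t_end, by = 10)
  stopifnot(params$t_end >= max(sample_times))
  if (is.null(init)) init <- initial_plaque_state(params, strain)
  g <- params$grid
  N <- params$response$N_stages
  M <- g$M
  pm <- .plaque_wm(params, strain)
  nspec <- 3 + N + if (strain == "lin_phage") N else 0

  dif <- function(u, D) {
    flux <- 2 * pi * g$r_face * D * diff(u) / g$dr
    (c(flux, 0) - c(0, flux)) / g$A
  }

  func <- function(t, y, p) {
    Y <- matrix(pmax(y, 0), nrow = M)
    B <- Y[, 1]; n <- Y[, 2]; phage <- Y[, 3]
    I <- t(Y[, 3 + seq_len(N), drop = FALSE])
    if (strain == "lin_phage") {
      L <- t(Y[, 3 + N + seq_len(N), drop = FALSE])
      d <- .wm_rhs(B, n, R = B * 0, P = phage, I_R = matrix(0, 1, M),
                   I_P = I, L = L, pm = pm)
      dphage <- d$dP + dif(phage, params$D_p)
      dn <- d$dn + dif(n, params$D_n)
      list(c(d$dB, dn, dphage, as.vector(t(d$dI_P)), as.vector(t(d$dL))))
    } else {
      d <- .wm_rhs(B, n, R = phage, P = B * 0, I_R = I,
                   I_P = matrix(0, 1, M), L = matrix(0, 1, M), pm = pm)
      dphage <- d$dR + dif(phage, params$D_p)
      dn <- d$dn + dif(n, params$D_n)
      list(c(d$dB, dn, dphage, as.vector(t(d$dI_R))))
    }
  }

  times <- sort(unique(c(0, sample_times)))
  out <- deSolve::ode.1D(y = .pl_pack(init), times = times, func = func,
                         parms = NULL, nspec = nspec, dimens = M,
                         method = "lsoda", rtol = rtol, atol = atol,
                         maxsteps = 100000)
  if (attr(out, "istate")[1] < 0)
    stop(sprintf("plaque integrator failed at t = %g min", max(out[, 1])))
  fields <- lapply(seq_len(nrow(out)), function(i)
    .pl_unpack(out[i, -1], params, strain, out[i, 1]))
  names(fields) <- paste0("t", out[, 1])
  metrics <- do.call(rbind, lapply(fields, function(f) {
    fr <- front_radii(f, params$B0)
    data.frame(time_min = f$time, r_PB0 = fr$r_PB0, r_super = fr$r_super,
               r_half = fr$r_half, r_ZOI = fr$r_ZOI)
  }))
  rownames(metrics) <- NULL
  structure(list(fields = fields, metrics = metrics, params = params,
                 strain = strain),
            class = "plaque_sim")
}

#' @export
print.plaque_sim <- function(x, ...) {
  cat(sprintf("Plaque simulation (%s), %d snapshots to %g min\n",
              x$strain, length(x$fields), max(x$metrics$time_min)))
  print(utils::tail(x$metrics, 3))
  invisible(x)
}
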