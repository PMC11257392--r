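#' Well-mixed batch model parameters
#'
#' Parameters for the three well-mixed batch models:
#' \describe{
#'   \item{M0}{r-mutant (rapid lysis) phage `R` alone: Lotka-Volterra
#'     adsorption, Erlang-staged latency, no lysis inhibition.}
#'   \item{M1}{LIN-capable phage `P` alone: a secondary adsorption on an
#'     infected cell moves it into the lysis-inhibited chain `L`, whose
#'     total latency is `f_tau * tau(n)` and whose burst size is
#'     `f_beta * beta(n)`. Cells in the LIN state keep adsorbing (and so
#'     inactivating) free phage without changing state.}
#'   \item{MC1}{direct competition of `R` and `P` in one culture. The
#'     primary infection fixes the progeny strain (superinfection
#'     exclusion); secondary adsorption of either strain triggers LIN on
#'     a P-infected cell when `trigger_mode = "any_phage"`, or only a P
#'     adsorption when `trigger_mode = "lin_phage_only"`.}
#' }
#'
#' @param response a [nutrient_response()] object.
#' @param eta adsorption rate constant (mL/min in batch units; per-area
#'   units in the plaque models).
#' @param f_tau LIN latency fold-extension (>= 1).
#' @param f_beta LIN burst-size fold-increase (>= 1).
#' @param trigger_mode which strains trigger LIN on a P-infected cell:
#'   `"any_phage"` (default), `"lin_phage_only"`, or `"none"` (a
#'   diagnostic mode that disables the secondary-adsorption transition
#'   entirely, reducing M1 to M0 when `f_tau = f_beta = 1`).
#' @param model_id one of `"M0"`, `"M1"`, `"MC1"`.
#' @return An object of class `well_mixed_params`.
#' @export
well_mixed_params <- function(response = nutrient_response(),
                              eta = 5e-10, f_tau = 1, f_beta = 1,
                              trigger_mode = c("any_phage", "lin_phage_only",
                                               "none"),
                              model_id = c("M0", "M1", "MC1")) {
  trigger_mode <- match.arg(trigger_mode)
  model_id <- match.arg(model_id)
  stopifnot(
    inherits(response, "nutrient_response"),
    "eta must be > 0" = is.numeric(eta) && eta > 0,
    "f_tau must be >= 1" = is.numeric(f_tau) && f_tau >= 1,
    "f_beta must be >= 1" = is.numeric(f_beta) && f_beta >= 1
  )
  structure(
    list(response = response, eta = eta, f_tau = f_tau, f_beta = f_beta,
         trigger_mode = trigger_mode, model_id = model_id),
    class = "well_mixed_params"
  )
}

#' @export
print.well_mixed_params <- function(x, ...) {
  cat(sprintf("Well-mixed model %s: eta = %g, f_tau = %g, f_beta = %g, trigger = %s\n",
              x$model_id, x$eta, x$f_tau, x$f_beta, x$trigger_mode))
  print(x$response)
  invisible(x)
}

#' Well-mixed state
#'
#' Concentrations per mL of every compartment: uninfected bacteria `B`,
#' nutrient `n` (in cell-equivalents), free phages `R` (r-mutant) and `P`
#' (LIN phage), and the staged infected chains `I_R`, `I_P` and the
#' lysis-inhibited chain `L`, each a vector of length `N_stages`.
#' Compartments not used by a model (e.g. `P`, `I_P`, `L` in M0) must be
#' identically zero.
#'
#' @param B,n,R,P scalar concentrations (>= 0).
#' @param I_R,I_P,L stage-resolved concentrations, length `N_stages`
#'   each (scalars are recycled).
#' @param N_stages chain length.
#' @return An object of class `well_mixed_state`.
#' @export
well_mixed_state <- function(B = 0, n = 0, R = 0, P = 0,
                             I_R = 0, I_P = 0, L = 0, N_stages = 10L) {
  N <- as.integer(N_stages)
  I_R <- rep_len(I_R, N); I_P <- rep_len(I_P, N); L <- rep_len(L, N)
  s <- list(B = B, n = n, R = R, P = P, I_R = I_R, I_P = I_P, L = L)
  if (any(unlist(s) < 0)) stop("state components must be nonnegative")
  structure(c(s, list(N_stages = N)), class = "well_mixed_state")
}

#' @export
print.well_mixed_state <- function(x, ...) {
  cat(sprintf("Well-mixed state (N = %d stages):\n", x$N_stages))
  cat(sprintf("  B = %g, n = %g, R = %g, P = %g\n", x$B, x$n, x$R, x$P))
  cat(sprintf("  sum(I_R) = %g, sum(I_P) = %g, sum(L) = %g\n",
              sum(x$I_R), sum(x$I_P), sum(x$L)))
  invisible(x)
}

# --- packing --------------------------------------------------------------
# Internal flat layout: B, n, R, P, I_R[1..N], I_P[1..N], L[1..N], then four
# bookkeeping integrals: cumulative phages produced and adsorbed per strain.

.wm_pack <- function(state) {
  c(B = state$B, n = state$n, R = state$R, P = state$P,
    state$I_R, state$I_P, state$L,
    prod_R = 0, ads_R = 0, prod_P = 0, ads_P = 0)
}

.wm_unpack <- function(y, N) {
  well_mixed_state(B = max(y[1], 0), n = max(y[2], 0),
                   R = max(y[3], 0), P = max(y[4], 0),
                   I_R = pmax(y[5:(4 + N)], 0),
                   I_P = pmax(y[(5 + N):(4 + 2 * N)], 0),
                   L = pmax(y[(5 + 2 * N):(4 + 3 * N)], 0),
                   N_stages = N)
}

# Flat-vector right-hand side shared by all three models; also used by the
# plaque module, vectorized over grid cells (each argument a vector).
# Returns a list of component derivatives plus the phage source/sink fluxes.
.wm_rhs <- function(B, n, R, P, I_R, I_P, L, pm) {
  rp <- pm$response
  g <- growth_rate(n, rp)
  beta <- burst_size(n, rp)
  k <- stage_rate(n, rp, 1)            # per-sub-state rate, normal chain
  kL <- k / pm$f_tau                   # LIN chain: uniform slow-down
  N <- rp$N_stages
  eta <- pm$eta

  nr <- NROW(I_R)                      # stages are rows when vectorized
  zero <- B * 0
  dB <- g * B
  dn <- -g * B
  dI_R <- I_R * 0; dI_P <- I_P * 0; dL <- L * 0
  dR <- zero; dP <- zero
  prod_R <- zero; ads_R <- zero; prod_P <- zero; ads_P <- zero

  sumI_R <- if (is.matrix(I_R)) colSums(I_R) else sum(I_R)
  sumI_P <- if (is.matrix(I_P)) colSums(I_P) else sum(I_P)
  sumL <- if (is.matrix(L)) colSums(L) else sum(L)

  row <- function(M, i) if (is.matrix(M)) M[i, ] else M[i]
  setrow <- function(M, i, v) { if (is.matrix(M)) M[i, ] <- v else M[i] <- v; M }

  if (pm$model_id %in% c("M0", "MC1")) {
    B_tot <- B + sumI_R + if (pm$model_id == "MC1") sumI_P + sumL else 0
    dB <- dB - eta * R * B
    dI_R <- setrow(dI_R, 1, eta * R * B - row(I_R, 1) * k)
    if (N > 1) for (i in 2:N)
      dI_R <- setrow(dI_R, i, (row(I_R, i - 1) - row(I_R, i)) * k)
    prod_R <- beta * row(I_R, N) * k
    ads_R <- eta * R * B_tot
    dR <- prod_R - ads_R
  }
  if (pm$model_id %in% c("M1", "MC1")) {
    phi <- if (pm$model_id == "MC1") R + P else P          # superinfecting phage
    phi_trig <- switch(pm$trigger_mode,
                       any_phage = phi, lin_phage_only = P, none = 0)
    B_tot <- B + sumI_P + sumL + if (pm$model_id == "MC1") sumI_R else 0
    dB <- dB - eta * P * B
    dI_P <- setrow(dI_P, 1,
                   eta * P * B - eta * phi_trig * row(I_P, 1) - row(I_P, 1) * k)
    if (N > 1) for (i in 2:N)
      dI_P <- setrow(dI_P, i,
                     (row(I_P, i - 1) - row(I_P, i)) * k -
                       eta * phi_trig * row(I_P, i))
    dL <- setrow(dL, 1, eta * phi_trig * sumI_P - row(L, 1) * kL)
    if (N > 1) for (i in 2:N)
      dL <- setrow(dL, i, (row(L, i - 1) - row(L, i)) * kL)
    prod_P <- beta * row(I_P, N) * k + pm$f_beta * beta * row(L, N) * kL
    ads_P <- eta * P * B_tot
    dP <- prod_P - ads_P
  }
  list(dB = dB, dn = dn, dR = dR, dP = dP,
       dI_R = dI_R, dI_P = dI_P, dL = dL,
       prod_R = prod_R, ads_R = ads_R, prod_P = prod_P, ads_P = ads_P)
}

#' Time derivative of a well-mixed state
#'
#' Evaluates the right-hand side of the selected batch model (M0, M1 or
#' MC1) at a given state: Monod cell division `g(n)B`, Lotka-Volterra
#' infection `eta * phage * B`, Erlang stage progression, lysis flux
#' `beta(n) * I_N * N/tau(n)` (and `f_beta * beta(n) * L_N * N/(f_tau
#' tau(n))` for the LIN chain), free-phage loss by adsorption to all
#' cells, and nutrient consumption equal to the division flux.
#'
#' @param state a [well_mixed_state()].
#' @param params a [well_mixed_params()]; `params$model_id` selects the
#'   model.
#' @return A `well_mixed_state`-shaped list of rates (class
#'   `well_mixed_rate`; components may be negative).
#' @export
well_mixed_derivative <- function(state, params) {
  stopifnot(inherits(state, "well_mixed_state"),
            inherits(params, "well_mixed_params"))
  if (state$N_stages != params$response$N_stages)
    stop("state and params disagree on N_stages")
  v <- unlist(state[c("B", "n", "R", "P", "I_R", "I_P", "L")])
  if (any(is.na(v))) stop("NaN/NA in state")
  if (any(v < 0)) stop("state components must be nonnegative")
  d <- .wm_rhs(state$B, state$n, state$R, state$P,
               state$I_R, state$I_P, state$L, params)
  structure(list(B = d$dB, n = d$dn, R = d$dR, P = d$dP,
                 I_R = d$dI_R, I_P = d$dI_P, L = d$dL,
                 N_stages = state$N_stages),
            class = c("well_mixed_rate"))
}

#' Default batch initial condition
#'
#' Uninfected bacteria at `B0`, nutrient at `n0`, and free phage of the
#' strain(s) the model uses: `R0` for M0, `P0` for M1, both for MC1.
#'
#' @param params a [well_mixed_params()].
#' @param B0,n0 initial bacteria and nutrient (/mL).
#' @param R0,P0 initial free phage (/mL); ignored for models that do not
#'   carry the strain.
#' @return a [well_mixed_state()].
#' @export
batch_init <- function(params, B0 = 1e6, n0 = 1e9, R0 = 1e3, P0 = 1e3) {
  N <- params$response$N_stages
  well_mixed_state(
    B = B0, n = n0,
    R = if (params$model_id %in% c("M0", "MC1")) R0 else 0,
    P = if (params$model_id %in% c("M1", "MC1")) P0 else 0,
    N_stages = N
  )
}

#' Integrate a well-mixed batch model
#'
#' Adaptive stiff-capable integration (deSolve `lsoda`) of the selected
#' model, sampled on a regular time grid. Sampled components in
#' `[-atol, 0)` are clipped to zero; values far below `-atol` abort with
#' a diagnostic.
#'
#' @param params a [well_mixed_params()].
#' @param init a [well_mixed_state()]; defaults to [batch_init()].
#' @param t_end end time (min).
#' @param sample_dt output sampling interval (min).
#' @param rtol,atol integration tolerances.
#' @return A data.frame of class `lin_timeseries` with columns
#'   `time_min, B, n, R, P, I_R_total, I_P_total, L_total, B_tot` and the
#'   cumulative phage production/adsorption integrals `prod_R, ads_R,
#'   prod_P, ads_P`. The full staged trajectory is kept in
#'   `attr(, "stages")`; the parameters in `attr(, "params")`.
#' @export
#' @examples
#' pm <- well_mixed_params(model_id = "M0")
#' ts <- simulate_batch(pm, t_end = 600)
#' tail(ts[, c("time_min", "B", "R")])
simulate_batch <- function(params, init = batch_init(params), t_end = 1200,
                           sample_dt = 1, rtol = 1e-8, atol = 1e-6) {
  stopifnot(t_end > 0)
  N <- params$response$N_stages
  y0 <- .wm_pack(init)
  func <- function(t, y, pm) {
    N <- pm$response$N_stages
    y <- pmax(y, 0)
    d <- .wm_rhs(y[1], y[2], y[3], y[4], y[5:(4 + N)],
                 y[(5 + N):(4 + 2 * N)], y[(5 + 2 * N):(4 + 3 * N)], pm)
    list(c(d$dB, d$dn, d$dR, d$dP, d$dI_R, d$dI_P, d$dL,
           d$prod_R, d$ads_R, d$prod_P, d$ads_P))
  }
  times <- seq(0, t_end, by = sample_dt)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  out <- deSolve::ode(y = y0, times = times, func = func, parms = params,
                      method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 50000)
  if (attr(out, "istate")[1] < 0)
    stop(sprintf("integrator failed at t = %g min", max(out[, 1])))
  ycols <- out[, -1, drop = FALSE]
  if (min(ycols) < -1000 * atol)
    stop(sprintf("state fell below -1000*atol (min = %g); integration unreliable",
                 min(ycols)))
  ycols[ycols < 0] <- 0
  I_R <- ycols[, 5:(4 + N), drop = FALSE]
  I_P <- ycols[, (5 + N):(4 + 2 * N), drop = FALSE]
  L <- ycols[, (5 + 2 * N):(4 + 3 * N), drop = FALSE]
  ts <- data.frame(
    time_min = out[, 1],
    B = ycols[, 1], n = ycols[, 2], R = ycols[, 3], P = ycols[, 4],
    I_R_total = rowSums(I_R), I_P_total = rowSums(I_P), L_total = rowSums(L)
  )
  ts$B_tot <- ts$B + ts$I_R_total + ts$I_P_total + ts$L_total
  ts$prod_R <- ycols[, 4 + 3 * N + 1]; ts$ads_R <- ycols[, 4 + 3 * N + 2]
  ts$prod_P <- ycols[, 4 + 3 * N + 3]; ts$ads_P <- ycols[, 4 + 3 * N + 4]
  attr(ts, "stages") <- list(I_R = I_R, I_P = I_P, L = L)
  attr(ts, "params") <- params
  class(ts) <- c("lin_timeseries", "data.frame")
  ts
}

#' @export
print.lin_timeseries <- function(x, ...) {
  pm <- attr(x, "params")
  cat(sprintf("Batch time series (%s), %d samples over %g min\n",
              if (is.null(pm)) "?" else pm$model_id,
              nrow(x), max(x$time_min)))
  print.data.frame(utils::tail(as.data.frame(
    x[, c("time_min", "B", "n", "R", "P", "L_total", "B_tot")]), 3))
  invisible(x)
}

#' @export
plot.lin_timeseries <- function(x, log = "y", floor = 1, ...) {
  cols <- c(B = "black", R = "red3", P = "blue3",
            I_R_total = "orange3", I_P_total = "purple3", L_total = "green4")
  keep <- names(cols)[vapply(names(cols), function(v) any(x[[v]] > 0), TRUE)]
  yl <- range(unlist(lapply(keep, function(v) pmax(x[[v]], floor))))
  graphics::plot(NA, xlim = range(x$time_min / 60), ylim = yl, log = log,
                 xlab = "time (h)", ylab = "concentration (/mL)", ...)
  for (v in keep)
    graphics::lines(x$time_min / 60, pmax(x[[v]], floor), col = cols[[v]])
  graphics::legend("bottomright", legend = keep, col = cols[keep], lty = 1,
                   bty = "n", cex = 0.8)
  invisible(x)
}
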