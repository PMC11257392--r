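#' Integer count state for the event-driven simulator
#'
#' Exact integer counterpart of a [well_mixed_state()] in a volume `V`
#' (mL). The nutrient is an integer pool of cell-equivalents so that
#' conservation is exact: one unit is consumed per division.
#'
#' @param B,n,R,P nonnegative integer counts (`n` in cell-equivalents).
#' @param I_R,I_P,L stage-resolved integer counts (length `N_stages`).
#' @param V volume (mL, > 0).
#' @param N_stages chain length.
#' @return An object of class `count_state`.
#' @export
count_state <- function(B = 0, n = 0, R = 0, P = 0,
                        I_R = 0, I_P = 0, L = 0, V = 1e-3, N_stages = 10L) {
  N <- as.integer(N_stages)
  s <- list(B = B, n = n, R = R, P = P,
            I_R = rep_len(I_R, N), I_P = rep_len(I_P, N), L = rep_len(L, N))
  v <- unlist(s)
  if (any(v < 0) || any(v != round(v))) stop("counts must be nonnegative integers")
  if (V <= 0) stop("V must be > 0")
  structure(c(s, list(V = V, N_stages = N)), class = "count_state")
}

#' Exact event-driven simulation of the well-mixed models
#'
#' Statistically exact (Gillespie direct method) counterpart of the
#' batch ODE models for integer populations in a volume `V`. The
#' reaction set mirrors the ODE terms: division (consuming one nutrient
#' unit), adsorption of each free phage type to each cell class
#' (infection on uninfected cells, LIN triggering on once-infected
#' P-cells when the adsorbing strain can trigger, pure inactivation
#' otherwise), Erlang stage progression, and lysis releasing `beta(n)`
#' (or `f_beta * beta(n)` from the LIN chain) phages. Real-valued burst
#' sizes are rounded stochastically (floor plus a Bernoulli remainder)
#' so the mean burst is exact. Bimolecular propensities scale as
#' `eta / V`.
#'
#' @param params a [well_mixed_params()]; `model_id` selects which
#'   strains/channels exist.
#' @param init a [count_state()].
#' @param seed integer RNG seed; identical seed, parameters and initial
#'   counts give an identical event sequence.
#' @param t_end end time (min).
#' @param sample_times times at which the state is recorded (default 61
#'   evenly spaced points).
#' @param max_events cap on the number of events; if reached the run
#'   stops early and is flagged `capped`.
#' @param record_events keep the per-event log (time, type); only
#'   sensible for small runs.
#' @return An object of class `lin_events`: list with `timeseries` (a
#'   data.frame `time_min, B, n, R, P, I_R_total, I_P_total, L_total,
#'   B_tot`), `final` (`count_state`), bookkeeping `counts` (adsorbed
#'   and released totals per strain, event total), `capped`, and
#'   optionally `events`.
#' @export
simulate_events <- function(params, init, seed, t_end,
                            sample_times = seq(0, t_end, length.out = 61),
                            max_events = 5e6, record_events = FALSE) {
  stopifnot(inherits(params, "well_mixed_params"),
            inherits(init, "count_state"), t_end > 0)
  rp <- params$response
  N <- rp$N_stages
  if (init$N_stages != N) stop("init and params disagree on N_stages")
  set.seed(as.integer(seed))

  V <- init$V
  etaV <- params$eta / V
  has_R <- params$model_id %in% c("M0", "MC1")
  has_P <- params$model_id %in% c("M1", "MC1")
  trig_any <- params$trigger_mode == "any_phage"

  B <- init$B; nn <- init$n; R <- init$R; P <- init$P
  IR <- init$I_R; IP <- init$I_P; LL <- init$L

  ads_R <- 0; ads_P <- 0; rel_R <- 0; rel_P <- 0; n_events <- 0
  capped <- FALSE
  t <- 0

  sample_times <- sort(unique(pmin(sample_times, t_end)))
  ns <- length(sample_times)
  rec <- matrix(0, ns, 8)
  si <- 1
  record <- function(upto) {
    while (si <= ns && sample_times[si] <= upto) {
      rec[si, ] <<- c(sample_times[si], B, nn, R, P, sum(IR), sum(IP), sum(LL))
      si <<- si + 1
    }
  }
  ev_t <- numeric(0); ev_type <- character(0)
  log_ev <- function(type) {
    if (record_events) { ev_t <<- c(ev_t, t); ev_type <<- c(ev_type, type) }
  }
  draw_burst <- function(b) floor(b) + (stats::runif(1) < (b - floor(b)))

  # channel layout:
  # 1 division; 2 R->B; 3 P->B; 4 R->I_R; 5 P->I_R; 6 R->I_P; 7 P->I_P;
  # 8 R->L; 9 P->L; 10..(9+N) I_R stage i; (10+N)..(9+2N) I_P stage i;
  # (10+2N)..(9+3N) L stage i (last stage of each chain = lysis)
  repeat {
    nc <- nn / V
    g <- rp$g_max * nc / (rp$K_n + nc)
    k <- stage_rate(nc, rp, 1)
    kL <- k / params$f_tau
    sIR <- sum(IR); sIP <- sum(IP); sL <- sum(LL)
    a <- c(g * B,
           if (has_R) etaV * R * B else 0,
           if (has_P) etaV * P * B else 0,
           if (has_R) etaV * R * sIR else 0,
           if (has_P) etaV * P * sIR else 0,
           if (has_R) etaV * R * sIP else 0,
           if (has_P) etaV * P * sIP else 0,
           if (has_R) etaV * R * sL else 0,
           if (has_P) etaV * P * sL else 0,
           k * IR, k * IP, kL * LL)
    a0 <- sum(a)
    if (a0 <= 0) { t <- t_end; break }
    t_new <- t + stats::rexp(1, a0)
    if (t_new > t_end) { t <- t_end; break }
    record(t_new)        # samples strictly before the event keep old state
    t <- t_new
    ch <- findInterval(stats::runif(1) * a0, cumsum(a)) + 1
    if (ch == 1) { B <- B + 1; nn <- nn - 1; log_ev("division") }
    else if (ch == 2) { R <- R - 1; B <- B - 1; IR[1] <- IR[1] + 1
                        ads_R <- ads_R + 1; log_ev("infect_R") }
    else if (ch == 3) { P <- P - 1; B <- B - 1; IP[1] <- IP[1] + 1
                        ads_P <- ads_P + 1; log_ev("infect_P") }
    else if (ch == 4) { R <- R - 1; ads_R <- ads_R + 1; log_ev("inactivate_R") }
    else if (ch == 5) { P <- P - 1; ads_P <- ads_P + 1; log_ev("inactivate_P") }
    else if (ch %in% c(6, 7)) {
      trig <- if (params$trigger_mode == "none") FALSE
              else (ch == 7) || trig_any
      if (ch == 6) { R <- R - 1; ads_R <- ads_R + 1 }
      else { P <- P - 1; ads_P <- ads_P + 1 }
      if (trig) {
        i <- sample.int(N, 1, prob = IP)
        IP[i] <- IP[i] - 1; LL[1] <- LL[1] + 1
        log_ev("lin_trigger")
      } else log_ev("inactivate_R")
    }
    else if (ch == 8) { R <- R - 1; ads_R <- ads_R + 1; log_ev("inactivate_R") }
    else if (ch == 9) { P <- P - 1; ads_P <- ads_P + 1; log_ev("inactivate_P") }
    else {
      i <- ch - 9
      beta <- burst_size(nc, rp)
      if (i <= N) {                     # I_R chain
        IR[i] <- IR[i] - 1
        if (i < N) { IR[i + 1] <- IR[i + 1] + 1; log_ev("stage_R") }
        else { b <- draw_burst(beta); R <- R + b; rel_R <- rel_R + b
               log_ev("lysis_R") }
      } else if (i <= 2 * N) {          # I_P chain
        i <- i - N
        IP[i] <- IP[i] - 1
        if (i < N) { IP[i + 1] <- IP[i + 1] + 1; log_ev("stage_P") }
        else { b <- draw_burst(beta); P <- P + b; rel_P <- rel_P + b
               log_ev("lysis_P") }
      } else {                          # LIN chain
        i <- i - 2 * N
        LL[i] <- LL[i] - 1
        if (i < N) { LL[i + 1] <- LL[i + 1] + 1; log_ev("stage_L") }
        else { b <- draw_burst(params$f_beta * beta); P <- P + b
               rel_P <- rel_P + b; log_ev("lysis_L") }
      }
    }
    n_events <- n_events + 1
    if (n_events >= max_events) { capped <- TRUE; break }
  }
  record(t)
  if (si <= ns && !capped) record(t_end)
  ts <- data.frame(time_min = rec[seq_len(si - 1), 1],
                   B = rec[seq_len(si - 1), 2], n = rec[seq_len(si - 1), 3],
                   R = rec[seq_len(si - 1), 4], P = rec[seq_len(si - 1), 5],
                   I_R_total = rec[seq_len(si - 1), 6],
                   I_P_total = rec[seq_len(si - 1), 7],
                   L_total = rec[seq_len(si - 1), 8])
  ts$B_tot <- ts$B + ts$I_R_total + ts$I_P_total + ts$L_total
  out <- list(
    timeseries = ts,
    final = count_state(B, nn, R, P, IR, IP, LL, V = V, N_stages = N),
    counts = list(ads_R = ads_R, ads_P = ads_P,
                  released_R = rel_R, released_P = rel_P,
                  n_events = n_events),
    capped = capped
  )
  if (record_events) out$events <- data.frame(time_min = ev_t, type = ev_type)
  structure(out, class = "lin_events")
}

#' @export
print.lin_events <- function(x, ...) {
  cat(sprintf("Event-driven run: %d events%s\n", x$counts$n_events,
              if (x$capped) " (capped)" else ""))
  print(utils::tail(x$timeseries, 3))
  invisible(x)
}
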