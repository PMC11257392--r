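test_that("derivative matches hand-evaluated fluxes and trivial limits", {
  pm <- well_mixed_params(model_id = "M0")
  N <- pm$response$N_stages
  # all-zero state -> all-zero derivative
  d0 <- well_mixed_derivative(well_mixed_state(N_stages = N), pm)
  expect_equal(unlist(d0[c("B", "n", "R", "P")]), c(B = 0, n = 0, R = 0, P = 0))
  expect_true(all(unlist(d0[c("I_R", "I_P", "L")]) == 0))
  # uncoupled growth when no phage
  st <- well_mixed_state(B = 1e6, n = 1e9, N_stages = N)
  d <- well_mixed_derivative(st, pm)
  g <- growth_rate(1e9, pm$response)
  expect_equal(d$B, g * 1e6)
  expect_equal(d$n, -g * 1e6)
  expect_equal(d$R, 0)
  # direct evaluation with free phage present
  st2 <- well_mixed_state(B = 1e6, n = 1e9, R = 1e3, N_stages = N)
  d2 <- well_mixed_derivative(st2, pm)
  expect_equal(d2$B, g * 1e6 - 5e-10 * 1e3 * 1e6)   # = 28332.83 /mL/min
  expect_equal(d2$I_R[1], 5e-10 * 1e3 * 1e6)
  expect_equal(d2$R, -5e-10 * 1e3 * 1e6)            # adsorption only, no lysis yet
  expect_error(well_mixed_derivative(
    well_mixed_state(B = 1, N_stages = 5), pm), "N_stages")
})

test_that("batch growth without phage consumes all nutrient into cells", {
  pm <- well_mixed_params(model_id = "M0")
  ts <- simulate_batch(pm, batch_init(pm, R0 = 0), t_end = 1200)
  expect_equal(ts$B[nrow(ts)], 1.001e9, tolerance = 1e-4)
  # conservation of B + n along the whole trajectory
  expect_equal(ts$B + ts$n, rep(1.001e9, nrow(ts)), tolerance = 1e-6)
  # nonnegativity after clipping
  expect_true(all(as.matrix(ts[, c("B", "n", "R", "P", "B_tot")]) >= 0))
})

test_that("Erlang chain releases beta(n) phages per infected cell", {
  # B = 0 so the nutrient stays at n0; negligible eta isolates the chain
  pm <- well_mixed_params(model_id = "M1", eta = 1e-30)
  st <- well_mixed_state(B = 0, n = 1e9, I_P = c(100, rep(0, 9)))
  ts <- simulate_batch(pm, st, t_end = 400)
  expect_equal(ts$P[nrow(ts)], 150 * 100, tolerance = 1e-6)
})

test_that("lysis-flux-weighted mean burst time equals tau(n), f_tau*tau(n) for LIN", {
  rp <- nutrient_response()
  k <- stage_rate(1e9, rp)
  # normal chain: pulse of stage-1 infected cells at fixed nutrient
  pm <- well_mixed_params(model_id = "M0", eta = 1e-30)
  ts <- simulate_batch(pm, well_mixed_state(B = 0, n = 1e9,
                                            I_R = c(100, rep(0, 9))),
                       t_end = 200, sample_dt = 0.05)
  flux <- attr(ts, "stages")$I_R[, 10] * k
  expect_equal(sum(ts$time_min * flux) / sum(flux), 20, tolerance = 1e-3)
  # LIN chain: pulse of L_1, per-sub-state rate k / f_tau
  pm5 <- well_mixed_params(model_id = "M1", eta = 1e-30, f_tau = 5)
  ts5 <- simulate_batch(pm5, well_mixed_state(B = 0, n = 1e9,
                                              L = c(100, rep(0, 9))),
                        t_end = 600, sample_dt = 0.1)
  flux5 <- attr(ts5, "stages")$L[, 10] * k / 5
  expect_equal(sum(ts5$time_min * flux5) / sum(flux5), 100, tolerance = 1e-3)
})

test_that("MC1 embeds M0 and M1 as single-strain limits", {
  resp <- nutrient_response()
  pmc <- well_mixed_params(resp, model_id = "MC1")
  rel <- function(a, b) max(abs(a - b) / (abs(b) + 1))
  # P0 = 0 reproduces M0
  tc <- simulate_batch(pmc, batch_init(pmc, P0 = 0), t_end = 1200)
  t0 <- cache_m0()
  for (col in c("B", "n", "R", "B_tot"))
    expect_lt(rel(tc[[col]], t0[[col]]), 1e-5)
  expect_true(all(tc$P == 0) && all(tc$I_P_total == 0) && all(tc$L_total == 0))
  # R0 = 0 reproduces M1
  pm1 <- well_mixed_params(resp, f_tau = 5, f_beta = 5, model_id = "M1")
  t1 <- simulate_batch(pm1, batch_init(pm1), t_end = 1200)
  pmc5 <- well_mixed_params(resp, f_tau = 5, f_beta = 5, model_id = "MC1")
  tc5 <- simulate_batch(pmc5, batch_init(pmc5, R0 = 0), t_end = 1200)
  for (col in c("B", "n", "P", "L_total", "B_tot"))
    expect_lt(rel(tc5[[col]], t1[[col]]), 1e-5)
})

test_that("phage bookkeeping balances production against adsorption", {
  out <- cache_mc1()
  ts <- out$timeseries
  nR <- ts$prod_R - ts$ads_R - (ts$R - ts$R[1])
  nP <- ts$prod_P - ts$ads_P - (ts$P - ts$P[1])
  expect_lt(max(abs(nR)) / max(ts$R), 1e-6)
  expect_lt(max(abs(nP)) / max(ts$P), 1e-6)
})

test_that("all three models keep sampled states nonnegative", {
  for (id in c("M0", "M1", "MC1")) {
    pm <- well_mixed_params(model_id = id, f_tau = 5, f_beta = 5)
    ts <- simulate_batch(pm, batch_init(pm), t_end = 1200, sample_dt = 5)
    expect_true(all(as.matrix(ts[, c("B", "n", "R", "P", "I_R_total",
                                     "I_P_total", "L_total")]) >= 0),
                info = id)
  }
})
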