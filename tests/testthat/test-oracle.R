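test_that("nothing happens without phage and nutrient", {
  pm <- well_mixed_params(model_id = "M0")
  ev <- simulate_events(pm, count_state(B = 50, V = 1e-3), seed = 1,
                        t_end = 100)
  expect_true(all(ev$timeseries$B == 50))
  expect_equal(ev$counts$n_events, 0)
})

test_that("identical seeds give identical event sequences", {
  pm <- well_mixed_params(model_id = "M1", f_tau = 2, f_beta = 2)
  ini <- count_state(B = 100, n = 500, P = 20, V = 1e-6)
  e1 <- simulate_events(pm, ini, seed = 11, t_end = 40, record_events = TRUE)
  e2 <- simulate_events(pm, ini, seed = 11, t_end = 40, record_events = TRUE)
  e3 <- simulate_events(pm, ini, seed = 12, t_end = 40, record_events = TRUE)
  expect_identical(e1$events, e2$events)
  expect_identical(e1$timeseries, e2$timeseries)
  expect_false(identical(e1$events, e3$events))
})

test_that("phage counts balance adsorptions against releases exactly", {
  pm <- well_mixed_params(model_id = "MC1", f_tau = 3, f_beta = 3)
  ini <- count_state(B = 150, n = 800, R = 15, P = 15, V = 1e-6)
  ev <- simulate_events(pm, ini, seed = 3, t_end = 50)
  fin <- ev$final
  expect_identical(fin$R, 15 - ev$counts$ads_R + ev$counts$released_R)
  expect_identical(fin$P, 15 - ev$counts$ads_P + ev$counts$released_P)
  expect_true(all(unlist(fin[c("B", "n", "R", "P", "I_R", "I_P", "L")]) >= 0))
})

test_that("single-cell lysis times follow the Erlang latency distribution", {
  # one infected cell, B = 0 keeps the nutrient pinned at n_ref;
  # Erlang(N = 10, mean 20 min): SD = 20/sqrt(10)
  pm <- well_mixed_params(model_id = "M0")
  reps <- 1500
  lt <- vapply(seq_len(reps), function(i) {
    ev <- simulate_events(pm, count_state(n = 1e6, I_R = c(1, rep(0, 9)),
                                          V = 1e-3),
                          seed = 1000 + i, t_end = 500,
                          sample_times = c(0, 500), record_events = TRUE)
    ev$events$time_min[ev$events$type == "lysis_R"]
  }, 1)
  sd_true <- 20 / sqrt(10)
  se <- sd_true / sqrt(reps)
  expect_lt(abs(mean(lt) - 20), 3 * se)
  expect_equal(sd(lt), sd_true, tolerance = 0.1)
  # LIN chain: whole chain slowed by f_tau = 5
  pm5 <- well_mixed_params(model_id = "M1", f_tau = 5)
  lt5 <- vapply(seq_len(400), function(i) {
    ev <- simulate_events(pm5, count_state(n = 1e6, L = c(1, rep(0, 9)),
                                           V = 1e-3),
                          seed = 5000 + i, t_end = 2000,
                          sample_times = c(0, 2000), record_events = TRUE)
    ev$events$time_min[ev$events$type == "lysis_L"]
  }, 1)
  expect_lt(abs(mean(lt5) - 100), 3 * 5 * sd_true / sqrt(400))
})

test_that("stochastic trajectory means track the ODE solution at large volume", {
  # 1000 cells: large enough that demographic correlations (an O(1/size)
  # effect on the means) sit well below the Monte-Carlo standard error
  pm <- well_mixed_params(model_id = "M1", f_tau = 2, f_beta = 2)
  V <- 5e-6
  ini <- count_state(B = 1000, n = 5000, P = 200, V = V)
  checkpoints <- c(15, 30, 40)
  reps <- 16
  runs <- lapply(seq_len(reps), function(i)
    simulate_events(pm, ini, seed = 200 + i, t_end = 40,
                    sample_times = c(0, checkpoints))$timeseries)
  ode <- simulate_batch(pm, well_mixed_state(B = 1000 / V, n = 5000 / V,
                                             P = 200 / V),
                        t_end = 40, sample_dt = 1)
  for (col in c("P", "B_tot", "L_total")) {
    mc <- sapply(runs, function(r) r[[col]][match(checkpoints, r$time_min)])
    mc <- matrix(mc, nrow = length(checkpoints)) / V   # counts -> conc
    m <- rowMeans(mc)
    se <- apply(mc, 1, sd) / sqrt(reps)
    ref <- ode[[col]][match(checkpoints, ode$time_min)]
    expect_true(all(abs(m - ref) <= 3 * se), info = col)
  }
})

test_that("the event cap stops runaway simulations gracefully", {
  pm <- well_mixed_params(model_id = "M0")
  ini <- count_state(B = 100, n = 10000, R = 10, V = 1e-6)
  ev <- simulate_events(pm, ini, seed = 1, t_end = 300, max_events = 50)
  expect_true(ev$capped)
  expect_equal(ev$counts$n_events, 50)
})
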