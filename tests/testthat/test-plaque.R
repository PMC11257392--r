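test_that("annular grid tiles the disc exactly", {
  g <- radial_grid(10000, 20)
  expect_equal(g$M, 500)
  expect_equal(g$r[1], 10)                       # first center at dr/2
  expect_equal(sum(g$A), pi * 10000^2, tolerance = 1e-12)
})

test_that("radial diffusion is conservative and kills uniform fields", {
  g <- radial_grid(2000, 20)
  expect_equal(radial_diffusion(rep(3.7, g$M), 240, g), rep(0, g$M))
  set.seed(42)
  u <- runif(g$M)
  rate <- radial_diffusion(u, 240, g)
  expect_equal(sum(g$A * rate), 0, tolerance = 1e-12 * sum(abs(g$A * rate)))
  expect_error(radial_diffusion(u, -1, g), "nonnegative")
})

test_that("free spreading follows the 2-D heat kernel", {
  g <- radial_grid(4000, 20)
  D <- 240; t0 <- 50; t1 <- 150
  f <- make_fixture("gaussian_profile", grid = g, D = D, t0 = t0)
  out <- deSolve::ode(f$phage, c(0, t1 - t0),
                      function(t, y, p) list(radial_diffusion(y, D, g)),
                      NULL, method = "lsoda", rtol = 1e-10, atol = 1e-16)
  num <- out[2, -1]
  ana <- 1 / (4 * pi * D * t1) * exp(-g$r^2 / (4 * D * t1))
  sel <- ana > max(ana) * 1e-3
  expect_lt(max(abs(num[sel] - ana[sel]) / ana[sel]), 0.02)
})

test_that("the initial plaque seed is exactly one infected bacterium", {
  pp <- plaque_params()
  f <- initial_plaque_state(pp, "lin_phage")
  g <- pp$grid
  expect_equal(sum(g$A * colSums(f$I)), 1)               # discrete Dirac delta
  expect_equal(sum(g$A * f$B), pp$B0 * pi * g$R_max^2)
  expect_equal(sum(g$A * f$n), pp$n0 * pi * g$R_max^2)
  expect_true(all(f$phage == 0))
})

test_that("without phage the lawn grows uniformly to B0 + n0 per area", {
  pp <- plaque_params(R_max = 1000, dr = 20, t_end = 400)
  init <- initial_plaque_state(pp, "r_mutant")
  init$I[] <- 0                                          # no seed
  sim <- simulate_plaque(pp, "r_mutant", sample_times = c(0, 400),
                         init = init)
  fin <- sim$fields[[2]]
  expect_equal(fin$B, rep(pp$B0 + pp$n0, pp$grid$M), tolerance = 1e-4)
  expect_true(all(fin$phage == 0))
  expect_true(all(is.na(unlist(sim$metrics[, -1]))))     # no fronts at all
})

test_that("plaque fields stay nonnegative and nutrient only decreases", {
  sim <- cache_mp1()
  A <- sim$params$grid$A
  tot_n <- vapply(sim$fields, function(f) sum(A * f$n), 1)
  expect_true(all(diff(tot_n) < 0))
  for (f in sim$fields[c(1, 11, 21, 41)]) {
    expect_true(all(f$B >= 0) && all(f$n >= 0) && all(f$phage >= 0))
    expect_true(all(f$I >= 0) && all(f$L >= 0))
  }
})

test_that("bacterial bookkeeping: lawn bacteria change only by growth and lysis", {
  # nutrient + total bacteria is conserved up to the lysis sink:
  # divisions convert nutrient one-to-one into cells, so
  # total(B_tot) + total(n) decreases only by lysed cells.
  sim <- cache_mp0()
  A <- sim$params$grid$A
  tot <- vapply(sim$fields, function(f) sum(A * (total_bacteria(f) + f$n)), 1)
  expect_true(all(diff(tot) <= 1e-8 * tot[1]))
})

test_that("r_super stays inside r_PB0 throughout the expansion", {
  for (sim in list(cache_mp0(), cache_mp1())) {
    m <- sim$metrics
    ok <- !is.na(m$r_super) & !is.na(m$r_PB0)
    expect_true(any(ok))
    expect_true(all(m$r_super[ok] < m$r_PB0[ok]))
  }
})

test_that("front positions expand at a common speed before nutrient arrest", {
  m <- cache_mp0()$metrics
  win <- m$time_min >= 100 & m$time_min <= 200      # linear expansion window
  speed <- function(col) stats::coef(stats::lm(m[[col]][win] ~ m$time_min[win]))[2]
  v <- c(speed("r_PB0"), speed("r_half"), speed("r_ZOI"))
  expect_lt((max(v) - min(v)) / mean(v), 0.10)
})

test_that("MP1 without secondary adsorption collapses onto MP0", {
  pp0 <- plaque_params(R_max = 2000, dr = 20, t_end = 150)
  pp1 <- plaque_params(R_max = 2000, dr = 20, t_end = 150,
                       trigger_mode = "none")   # f_tau = f_beta = 1
  s0 <- simulate_plaque(pp0, "r_mutant", sample_times = c(0, 75, 150))
  s1 <- simulate_plaque(pp1, "lin_phage", sample_times = c(0, 75, 150))
  for (i in 2:3) {
    f0 <- s0$fields[[i]]; f1 <- s1$fields[[i]]
    expect_equal(f1$B, f0$B, tolerance = 1e-4)
    expect_equal(f1$phage, f0$phage, tolerance = 1e-3)
    expect_lt(max(f1$L), 1e-20)     # roundoff from the implicit solver only
  }
})

test_that("halving the grid spacing barely moves the plaque radius", {
  sims <- lapply(c(20, 10), function(dr) {
    pp <- plaque_params(R_max = 3000, dr = dr, t_end = 150)
    simulate_plaque(pp, "r_mutant", sample_times = c(0, 150))
  })
  r1 <- sims[[1]]$metrics$r_half[2]
  r2 <- sims[[2]]$metrics$r_half[2]
  expect_lt(abs(r1 - r2) / r2, 0.02)
})
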