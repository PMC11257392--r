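test_that("a uniform uninfected lawn has no front radii", {
  g <- radial_grid(2000, 20)
  f <- make_fixture("step_profile", grid = g, crossing = 3000)  # beyond R_max
  f$B <- rep(1 / 400, g$M); f$phage <- rep(0, g$M)
  fr <- front_radii(f, 1 / 400)
  expect_true(all(is.na(unlist(fr[c("r_PB0", "r_super", "r_half", "r_ZOI")]))))
})

test_that("step-profile fixture recovers the constructed crossing radius", {
  g <- radial_grid(10000, 20)
  f <- make_fixture("step_profile", grid = g, crossing = 3000)
  fr <- front_radii(f, 1 / 400)
  for (m in c("r_PB0", "r_super", "r_half", "r_ZOI"))
    expect_equal(fr[[m]], 3000, tolerance = g$dr / 3000, info = m)
  # interpolated radius lies between the bracketing cell centers
  expect_gt(fr$r_PB0, 3000 - g$dr / 2)
  expect_lt(fr$r_PB0, 3000 + g$dr / 2)
})

test_that("half-threshold crossings ignore a uniform density rescaling", {
  g <- radial_grid(10000, 20)
  f <- make_fixture("step_profile", grid = g, crossing = 1500)
  fr1 <- front_radii(f, 1 / 400)
  f2 <- f
  f2$B <- 7.3 * f$B; f2$phage <- 7.3 * f$phage
  fr2 <- front_radii(f2, 7.3 / 400)   # reference rescaled alongside
  expect_equal(fr2$r_half, fr1$r_half)
  expect_equal(fr2$r_ZOI, fr1$r_ZOI)
})

test_that("the outermost crossing is reported for double-peaked profiles", {
  g <- radial_grid(1000, 20)
  B0 <- 1 / 400
  f <- make_fixture("step_profile", grid = g, crossing = 400)
  # second phage bump further out: crossings at 400 and in [700, 760]
  f$phage <- ifelse(g$r < 400, 2 * B0, 0) +
    ifelse(g$r >= 700 & g$r < 760, 2 * B0, 0)
  fr <- front_radii(f, B0)
  expect_equal(fr$r_PB0, 760, tolerance = g$dr / 760)
})

test_that("r_ZOI bounds r_half from above on simulated LIN plaques", {
  m <- cache_mp1()$metrics
  ok <- !is.na(m$r_half) & !is.na(m$r_ZOI)
  expect_true(any(ok))
  expect_true(all(m$r_ZOI[ok] >= m$r_half[ok] - 1e-9))
})

test_that("settling time detects when a front stops moving", {
  m <- data.frame(time_min = seq(0, 100, 10),
                  r_half = c(0, 10, 30, 60, 90, 99.5, 100, 100, 100, 100, 100))
  expect_equal(settling_time(m, "r_half"), 50)
  m$r_half <- NA
  expect_true(is.na(settling_time(m, "r_half")))
})

test_that("morphology sweep runs clean and reuses the MP0 reference", {
  sw <- cache_plaque_sweep()
  expect_equal(sw$ref_r_half, metric_at(cache_mp0(), "r_half", 300))
  expect_true(all(is.na(sw$errors)))
  expect_true(all(sw$r_half_ratio > 0 & sw$r_half_ratio < 1))
  expect_true(all(abs(sw$r_ZOI_ratio - 1) < 0.1))
})
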