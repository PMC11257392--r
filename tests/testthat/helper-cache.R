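# Memoized expensive simulations shared across test files. Everything is
# computed at most once per test run, at the package's default study
# conditions.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache))
    assign(key, force(expr), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# r-mutant plaque (MP0), default parameters, to 400 min
cache_mp0 <- function() cached("mp0", simulate_plaque(plaque_params(), "r_mutant"))

# LIN plaque (MP1) at given fold factors, default parameters, to 400 min
cache_mp1 <- function(f_tau = 5, f_beta = 5) {
  cached(sprintf("mp1_%g_%g", f_tau, f_beta),
         simulate_plaque(plaque_params(f_tau = f_tau, f_beta = f_beta),
                         "lin_phage"))
}

# Fig-5 style morphology sweep over the LIN plateau, reusing cache_mp0()
cache_plaque_sweep <- function() {
  cached("plaque_sweep",
         plaque_ratio_sweep(c(3, 4, 5), c(1, 3, 5), plaque_params(),
                            t_eval = 300, reference = cache_mp0()))
}

# mixed-culture competition at f_tau = f_beta = 5, defaults, 20 h
cache_mc1 <- function() cached("mc1", competition_outcome(5, 5))

# r-mutant alone (M0), defaults, 20 h
cache_m0 <- function() {
  cached("m0", {
    pm <- well_mixed_params(model_id = "M0")
    simulate_batch(pm, batch_init(pm), t_end = 1200)
  })
}

# separate-culture sweep on a 3x3 grid, defaults
cache_sep_sweep <- function() {
  cached("sep_sweep",
         sweep_lin_grid("separate", c(1, 3, 5), c(1, 3, 5)))
}

# interpolate a metric column of a plaque_sim at time t
metric_at <- function(sim, col, t) {
  stats::approx(sim$metrics$time_min, sim$metrics[[col]], t)$y
}
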