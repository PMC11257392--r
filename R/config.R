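# Run configuration: flat key-value document, keys named after the
# conventional model symbols. Defaults reproduce the package's standard
# batch and plaque parameter tables.

.batch_defaults <- function() list(
  model = "M0", g_max = 0.034, K_n = 2e8, eta = 5e-10, tau0 = 20,
  beta0 = 150, r_l = 0.5, r_b = 0.1, N = 10L, f_tau = 1, f_beta = 1,
  trigger_mode = "any_phage", B0 = 1e6, R0 = 1e3, P0 = 1e3, n0 = 1e9,
  t_end = 1200, sample_dt = 1, seed = 1L
)

.plaque_defaults <- function() list(
  model = "MP0", g_max = 0.034, k_n = 0.1, eta = 5e-10, tau0 = 20,
  beta0 = 150, r_l = 0, r_b = 0.1, N = 10L, f_tau = 1, f_beta = 1,
  trigger_mode = "any_phage", B0 = 1 / 400, n0 = 0.5,
  delta_a = 500, D_p = 240, D_n = 5e4, R_max = 10000, dr = 20,
  t_end = 400, sample_dt = 10, seed = 1L
)

.sweep_defaults <- function() c(
  .batch_defaults()[setdiff(names(.batch_defaults()), "model")],
  list(model = "sweep", sweep_mode = "separate",
       f_tau_grid = c(1, 3, 5), f_beta_grid = c(1, 3, 5))
)

.oracle_defaults <- function() c(
  .batch_defaults(),
  list(V = 1e-3, max_events = 5e6)
)

#' Default run configuration
#'
#' The flat key-value configuration understood by [run_command()]. Keys
#' are named after the conventional symbols (`g_max`, `K_n`/`k_n`,
#' `eta`, `tau0`, `beta0`, `r_l`, `r_b`, `N`, `f_tau`, `f_beta`, ...).
#' Defaults reproduce the standard batch (M0/M1/MC1) or plaque
#' (MP0/MP1) parameter set of the package.
#'
#' @param command one of `"batch"`, `"compete"`, `"plaque"`, `"sweep"`,
#'   `"oracle"`, `"fixtures"`.
#' @return named list of class `lin_config`.
#' @export
default_config <- function(command = c("batch", "compete", "plaque",
                                       "sweep", "oracle", "fixtures")) {
  command <- match.arg(command)
  cfg <- switch(command,
    batch = .batch_defaults(),
    compete = c(.batch_defaults()[setdiff(names(.batch_defaults()), "model")],
                list(model = "MC1")),
    plaque = .plaque_defaults(),
    sweep = .sweep_defaults(),
    oracle = .oracle_defaults(),
    fixtures = list(kind = "step_profile", crossing = 3000, R_max = 10000,
                    dr = 20, seed = 1L)
  )
  structure(cfg, class = "lin_config", command = command,
            overridden = character(0))
}

#' Validate and merge configuration overrides
#'
#' Unknown keys are errors (not warnings); values are checked against
#' the model constraints (`f_tau >= 1`, `f_beta >= 1`, positive rates,
#' grids, concentrations). Overridden keys are tracked for provenance
#' logging.
#'
#' @param command subcommand name (see [default_config()]).
#' @param overrides named list of key overrides (e.g. from a YAML file
#'   or CLI flags).
#' @return validated `lin_config`.
#' @export
build_config <- function(command, overrides = list()) {
  cfg <- default_config(command)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad))
      stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
    cfg[names(overrides)] <- overrides
    attr(cfg, "overridden") <- names(overrides)
  }
  validate_config(cfg)
  cfg
}

#' @rdname build_config
#' @param cfg a `lin_config`.
#' @export
validate_config <- function(cfg) {
  chk <- function(cond, msg, key) if (!is.null(cfg[[key]]) && !cond)
    stop(sprintf("invalid config key '%s': %s", key, msg))
  num <- function(key) cfg[[key]]
  for (key in c("g_max", "K_n", "k_n", "eta", "tau0", "beta0", "n0", "B0",
                "delta_a", "D_p", "D_n", "V"))
    chk(is.numeric(num(key)) && all(num(key) > 0), "must be > 0", key)
  for (key in c("r_l", "r_b"))
    chk(is.numeric(num(key)) && num(key) >= 0 && num(key) <= 1,
        "must be in [0, 1]", key)
  for (key in c("f_tau", "f_beta"))
    chk(is.numeric(num(key)) && all(num(key) >= 1), "must be >= 1", key)
  for (key in c("f_tau_grid", "f_beta_grid"))
    chk(is.numeric(num(key)) && length(num(key)) > 0 && all(num(key) >= 1),
        "must be a nonempty grid of values >= 1", key)
  for (key in c("R0", "P0"))
    chk(is.numeric(num(key)) && all(num(key) >= 0), "must be >= 0", key)
  chk(is.numeric(cfg$N) && cfg$N >= 1 && cfg$N == round(cfg$N),
      "must be a positive integer", "N")
  chk(is.numeric(cfg$t_end) && cfg$t_end > 0, "must be > 0", "t_end")
  if (!is.null(cfg$R_max) && !is.null(cfg$dr))
    chk(cfg$R_max > cfg$dr && cfg$dr > 0, "need R_max > dr > 0", "dr")
  chk(cfg$trigger_mode %in% c("any_phage", "lin_phage_only", "none"),
      "must be 'any_phage', 'lin_phage_only' or 'none'", "trigger_mode")
  invisible(cfg)
}

#' Load a configuration file
#'
#' Reads a flat YAML key-value document and merges it over the defaults
#' for the given subcommand. Unknown keys are errors.
#'
#' @param path YAML file path.
#' @param command subcommand the config is for.
#' @return validated `lin_config`.
#' @export
load_config <- function(path, command = "batch") {
  overrides <- yaml::read_yaml(path)
  if (is.null(overrides)) overrides <- list()
  build_config(command, overrides)
}

#' @export
print.lin_config <- function(x, ...) {
  cat(sprintf("Run configuration (%s):\n", attr(x, "command")))
  ov <- attr(x, "overridden")
  for (k in names(x))
    cat(sprintf("  %s = %s%s\n", k, paste(format(x[[k]]), collapse = ", "),
                if (k %in% ov) "  [override]" else ""))
  invisible(x)
}

# config -> parameter objects -------------------------------------------

.cfg_response <- function(cfg) {
  nutrient_response(g_max = cfg$g_max, K_n = cfg$K_n, beta0 = cfg$beta0,
                    tau0 = cfg$tau0, r_l = cfg$r_l, r_b = cfg$r_b,
                    n_ref = cfg$n0, N_stages = cfg$N)
}

.cfg_wm_params <- function(cfg, model_id = cfg$model) {
  well_mixed_params(response = .cfg_response(cfg), eta = cfg$eta,
                    f_tau = cfg$f_tau, f_beta = cfg$f_beta,
                    trigger_mode = cfg$trigger_mode, model_id = model_id)
}

.cfg_plaque_params <- function(cfg) {
  plaque_params(g_max = cfg$g_max, k_n = cfg$k_n, beta0 = cfg$beta0,
                tau0 = cfg$tau0, r_l = cfg$r_l, r_b = cfg$r_b,
                N_stages = cfg$N, eta = cfg$eta, f_tau = cfg$f_tau,
                f_beta = cfg$f_beta, trigger_mode = cfg$trigger_mode,
                delta_a = cfg$delta_a, D_p = cfg$D_p, D_n = cfg$D_n,
                B0 = cfg$B0, n0 = cfg$n0, R_max = cfg$R_max, dr = cfg$dr,
                t_end = cfg$t_end)
}
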