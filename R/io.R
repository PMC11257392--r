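# Output writers and the synthetic-fixture generator.

#' Write a batch time series as CSV
#'
#' Comma-separated, header row, '.' decimal; values round-trip through
#' [read.csv()] to 15 significant digits.
#'
#' @param ts a `lin_timeseries` (or the data.frame of a `lin_events`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(ts, path) {
  cols <- intersect(c("time_min", "B", "n", "R", "P", "I_R_total",
                      "I_P_total", "L_total", "B_tot"), names(ts))
  utils::write.csv(format(as.data.frame(ts)[, cols], digits = 15,
                          scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write radial field snapshots as long-format CSV
#'
#' Columns `time_min, r_um, variable, value`, one row per grid cell and
#' state variable (`B`, `n`, `phage`, `I_total`, `L_total`, `B_tot`).
#'
#' @param fields list of `radial_field` snapshots (e.g.
#'   `plaque_sim$fields`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fields_csv <- function(fields, path) {
  long <- do.call(rbind, lapply(fields, function(f) {
    vars <- list(B = f$B, n = f$n, phage = f$phage,
                 I_total = colSums(f$I), L_total = colSums(f$L),
                 B_tot = total_bacteria(f))
    do.call(rbind, lapply(names(vars), function(v)
      data.frame(time_min = f$time, r_um = f$grid$r, variable = v,
                 value = vars[[v]])))
  }))
  utils::write.csv(format(long, digits = 15, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a front-metric trajectory as CSV
#'
#' @param metrics the `metrics` data.frame of a `plaque_sim`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  utils::write.csv(format(metrics, digits = 15, scientific = FALSE,
                          trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a sweep result as CSV matrix plus JSON metadata
#'
#' @param sweep a `lin_sweep` or `plaque_sweep`.
#' @param csv_path,json_path output files (for a `plaque_sweep` two CSVs
#'   are written, with suffixes `_r_half` and `_r_ZOI` inserted before
#'   the extension of `csv_path`).
#' @return list of written paths, invisibly.
#' @export
write_sweep_csv <- function(sweep, csv_path, json_path) {
  write_mat <- function(m, p) {
    df <- cbind(data.frame(f_tau = sweep$f_tau_grid), as.data.frame(m))
    utils::write.csv(format(df, digits = 15, trim = TRUE), p,
                     row.names = FALSE, quote = FALSE)
    p
  }
  meta <- list(schema_version = 1L, f_tau_grid = sweep$f_tau_grid,
               f_beta_grid = sweep$f_beta_grid,
               n_failed_cells = sum(!is.na(sweep$errors)))
  if (inherits(sweep, "lin_sweep")) {
    paths <- write_mat(sweep$log10_ratio, csv_path)
    meta$mode <- sweep$mode
    meta$contour_one <- sweep$contour_one
  } else {
    stub <- sub("\\.[^.]*$", "", csv_path)
    ext <- substring(csv_path, nchar(stub) + 1)
    paths <- c(write_mat(sweep$r_half_ratio, paste0(stub, "_r_half", ext)),
               write_mat(sweep$r_ZOI_ratio, paste0(stub, "_r_ZOI", ext)))
    meta$t_eval <- sweep$t_eval
    meta$ref_r_half <- sweep$ref_r_half
    meta$ref_r_ZOI <- sweep$ref_r_ZOI
  }
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(list(csv = paths, json = json_path))
}

#' Generate a synthetic test fixture
#'
#' Deterministic synthetic inputs with known structure, used to exercise
#' the metric extraction and the diffusion operator independently of the
#' full simulations:
#' \describe{
#'   \item{step_profile}{a radial field whose phage density is `2 B0`
#'     inside `crossing` and 0 outside, and whose bacterial lawn is 0
#'     inside and `lawn` outside, so every front radius crosses at
#'     `crossing` (a face radius) exactly.}
#'   \item{gaussian_profile}{a radial field whose phage density is the
#'     2-D heat kernel `amp/(4 pi D t0) exp(-r^2/(4 D t0))`, whose free
#'     spreading has the closed-form solution with `t0 -> t0 + t`.}
#'   \item{batch_snapshot}{a [well_mixed_state()] built from the
#'     supplied values.}
#' }
#'
#' @param kind fixture kind (see above).
#' @param grid a [radial_grid()] (radial kinds).
#' @param crossing step radius (um), ideally a multiple of `grid$dr`.
#' @param B0,lawn phage reference and lawn density (/um^2).
#' @param D,t0,amp heat-kernel diffusivity (um^2/min), elapsed time
#'   (min) and integrated mass.
#' @param values named list for `batch_snapshot`, passed to
#'   [well_mixed_state()].
#' @param seed unused by the deterministic kinds; kept so all fixture
#'   calls are seedable uniformly.
#' @return a `radial_field` or `well_mixed_state`.
#' @export
make_fixture <- function(kind = c("step_profile", "gaussian_profile",
                                  "batch_snapshot"),
                         grid = radial_grid(10000, 20), crossing = 3000,
                         B0 = 1 / 400, lawn = 1 / 400,
                         D = 240, t0 = 50, amp = 1,
                         values = list(), seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "batch_snapshot")
    return(do.call(well_mixed_state, values))
  N <- 10L
  f <- structure(list(grid = grid, time = 0, strain = "r_mutant",
                      B = rep(0, grid$M), n = rep(0, grid$M),
                      phage = rep(0, grid$M),
                      I = matrix(0, N, grid$M), L = matrix(0, N, grid$M)),
                 class = "radial_field")
  if (kind == "step_profile") {
    inside <- grid$r < crossing
    f$phage <- ifelse(inside, 2 * B0, 0)
    f$B <- ifelse(inside, 0, lawn)
  } else {
    f$phage <- amp / (4 * pi * D * t0) * exp(-grid$r^2 / (4 * D * t0))
  }
  f
}
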