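#' Default sweep configuration
#'
#' The configuration object consumed by [run_sweep()]. The defaults encode
#' the reference study conditions: basal species are 20% of the richness,
#' `n_E = 2 n_P` edges, 5 spatial modules, distance exponent `x = 2`,
#' 6 simulated years, and asynchrony levels `A_L = 0`, `A_H = 0.5`. Grid
#' values and replicate counts are deliberately small here; widen them per
#' experiment.
#'
#' @param ... named overrides of any field.
#' @return a list of class `sweep_config`.
#' @export
sweep_config <- function(...) {
  cfg <- list(
    temperature_values = c(0.2, 0.8),
    lam_values = c(0.47, 0.8),
    a_values = c(30, 3000),
    A_low = 0, A_high = 0.5,
    replicates = 3L,
    years = 6L,
    n_s = 30L, connectance = 0.2,
    n_p = 25L, n_c = 5L, f = 50, x = 2,
    distance_scale = 1000,
    power = 1,
    count_empty_as_zero = FALSE,
    seed = 1L)
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  cfg$n_b <- cfg$n_b %||% as.integer(round(0.2 * cfg$n_s))
  cfg$n_l <- cfg$n_l %||% links_for_connectance(cfg$n_s, cfg$n_b,
                                                cfg$connectance)
  cfg$n_e <- cfg$n_e %||% 2L * cfg$n_p
  structure(cfg, class = "sweep_config")
}

#' Run an asynchrony-sensitivity parameter sweep
#'
#' For every cell of the `(temperature, lam, a)` grid and every replicate:
#' generate a feasible stable regional community and a landscape, sample a
#' *paired* pair of activation schedules at `A_low` and `A_high` (sharing
#' the per-site nominal window lengths `w_p` and differing only in the
#' start-time jitters), simulate both runs, summarize them, and record the
#' asynchrony sensitivity of each response. Replicate seeds are derived from
#' the root seed, and the community, landscape and window lengths of a
#' replicate are shared across the dispersal grid, so contrasts in `a` are
#' paired as well.
#'
#' @param config a [sweep_config()].
#' @param progress print one line per grid cell.
#' @return a list of class `sweep_result`: `sensitivities` (one row per
#'   cell x replicate x response: `temperature`, `lam`, `a`, `ahat`,
#'   `replicate`, `response`, `x_low`, `x_high`, `S`), `responses` (one row
#'   per run), and `config`.
#' @export
run_sweep <- function(config = sweep_config(), progress = FALSE) {
  stopifnot(inherits(config, "sweep_config"))
  cfg <- config
  resp_names <- c("P_alpha", "P_gamma", "P_beta", "B_gamma", "B_beta")
  grid <- expand.grid(ti = seq_along(cfg$temperature_values),
                      li = seq_along(cfg$lam_values),
                      ai = seq_along(cfg$a_values))
  # derived, reproducible sub-seeds: 4 per (T, lam) cell per replicate, plus
  # a landscape seed and a window-length seed shared across cells
  n_cells_tl <- length(cfg$temperature_values) * length(cfg$lam_values)
  seeds <- with_seed(cfg$seed, matrix(
    child_seeds(cfg$replicates * (4L * n_cells_tl + 2L)),
    nrow = cfg$replicates))
  sens_rows <- list(); resp_rows <- list()
  for (g in seq_len(nrow(grid))) {
    ti <- grid$ti[g]; li <- grid$li[g]; ai <- grid$ai[g]
    temperature <- cfg$temperature_values[ti]
    lam <- cfg$lam_values[li]
    a <- cfg$a_values[ai]
    if (progress)
      cat(sprintf("cell T=%g lam=%g a=%g\n", temperature, lam, a))
    for (rep_i in seq_len(cfg$replicates)) {
      scol <- 4L * ((ti - 1L) * length(cfg$lam_values) + (li - 1L))
      comm_seed <- seeds[rep_i, scol + 1L]
      land_seed <- seeds[rep_i, 4L * n_cells_tl + 1L]  # shared across cells
      w_seed <- seeds[rep_i, 4L * n_cells_tl + 2L]
      comm <- generate_stable_regional_community(
        cfg$n_s, cfg$n_b, cfg$n_l, temperature, lam, seed = comm_seed)
      L <- generate_landscape(cfg$n_p, cfg$n_e, cfg$n_c, cfg$f, cfg$x,
                              seed = land_seed)
      w <- with_seed(w_seed, stats::runif(cfg$n_p, 0.2, 0.3))
      for (Ai in 1:2) {
        A <- if (Ai == 1L) cfg$A_low else cfg$A_high
        sched_seed <- seeds[rep_i, scol + 1L + Ai]
        run_seed <- (seeds[rep_i, scol + 4L] + 7919L * Ai + 104729L * ai) %%
          (.Machine$integer.max - 1L) + 1L
        sched <- sample_activation_schedule(L, A, cfg$years,
                                            seed = sched_seed, w = w)
        traj <- simulate_run(L, sched, comm$web, comm$dyn, a,
                             horizon = cfg$years, seed = run_seed,
                             distance_scale = cfg$distance_scale)
        rs <- summarize_run(traj, p = cfg$power,
                            count_empty_as_zero = cfg$count_empty_as_zero)
        resp_rows[[length(resp_rows) + 1L]] <- data.frame(
          temperature = temperature, lam = lam, a = a, ahat = log10(a),
          A = A, replicate = rep_i,
          P_alpha = rs$P_alpha, P_gamma = rs$P_gamma, P_beta = rs$P_beta,
          B_gamma = rs$B_gamma, B_beta = rs$B_beta)
        if (Ai == 1L) low <- rs else high <- rs
      }
      for (nm in resp_names) {
        sens_rows[[length(sens_rows) + 1L]] <- data.frame(
          temperature = temperature, lam = lam, a = a, ahat = log10(a),
          replicate = rep_i, response = nm,
          x_low = low[[nm]], x_high = high[[nm]],
          S = if (is.na(low[[nm]]) || is.na(high[[nm]])) NA_real_ else
            sensitivity(low[[nm]], high[[nm]], cfg$A_low, cfg$A_high))
      }
    }
  }
  structure(list(sensitivities = do.call(rbind, sens_rows),
                 responses = do.call(rbind, resp_rows),
                 config = cfg),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("sweep: %d x %d x %d grid (T x lam x a), %d replicate(s), %d year(s)\n",
              length(cfg$temperature_values), length(cfg$lam_values),
              length(cfg$a_values), cfg$replicates, cfg$years))
  agg <- stats::aggregate(S ~ response + a, data = x$sensitivities, FUN = mean,
                          na.rm = TRUE)
  cat("mean asynchrony sensitivities by dispersal ability:\n")
  print(agg, digits = 3)
  invisible(x)
}

#' Effect-size tables for every response in a sweep
#'
#' Convenience wrapper: splits a sweep's sensitivity rows by response and
#' fits [effect_sizes()] to each (one row per replicate; no cell averaging).
#'
#' @param sweep a `sweep_result`.
#' @return a named list of `effect_size_table`s.
#' @export
sweep_effect_sizes <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  out <- lapply(split(sweep$sensitivities, sweep$sensitivities$response),
                function(d) effect_sizes(d, response = "S"))
  out
}
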