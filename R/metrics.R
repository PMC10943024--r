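#' Instantaneous alpha / gamma persistence
#'
#' Persistence at an instant is species richness relative to the regional
#' pool. `scope = "alpha"` averages `richness / n_s` over the active
#' non-mainland sites; `scope = "gamma"` is the richness of the union of
#' species over all non-mainland sites, divided by `n_s`. The mainland holds
#' the full pool by construction and is excluded from both. Alpha is `NA`
#' when no non-mainland site is active.
#'
#' @param state a [metacommunity_state()].
#' @param n_s regional pool size.
#' @param scope `"alpha"` or `"gamma"`.
#' @return a scalar in `[0, 1]`, or `NA` (alpha with no active site).
#' @export
instantaneous_persistence <- function(state, n_s,
                                      scope = c("alpha", "gamma")) {
  scope <- match.arg(scope)
  ml <- state$mainland
  if (scope == "alpha") {
    act <- setdiff(which(state$active), ml)
    if (!length(act)) return(NA_real_)
    mean(rowSums(state$present[act, , drop = FALSE]) / n_s)
  } else {
    sum(colSums(state$present[-ml, , drop = FALSE]) > 0L) / n_s
  }
}

#' Instantaneous gamma / beta biomass
#'
#' `scope = "gamma"` is total community biomass summed over the non-mainland
#' sites. `scope = "beta"` is the coefficient of variation (population
#' standard deviation over mean) of per-site total biomass across the active
#' non-mainland sites; it is `NA` with fewer than two active sites or a zero
#' mean.
#'
#' @param state a [metacommunity_state()].
#' @param scope `"gamma"` or `"beta"`.
#' @return a nonnegative scalar, or `NA`.
#' @export
instantaneous_biomass <- function(state, scope = c("gamma", "beta")) {
  scope <- match.arg(scope)
  ml <- state$mainland
  if (scope == "gamma") {
    sum(state$biomass[-ml, , drop = FALSE])
  } else {
    act <- setdiff(which(state$active), ml)
    if (length(act) < 2L) return(NA_real_)
    tot <- rowSums(state$biomass[act, , drop = FALSE])
    m <- mean(tot)
    if (m == 0) return(NA_real_)
    sqrt(mean((tot - m)^2)) / m
  }
}

#' Continuous power mean of a piecewise-constant series
#'
#' `M_p = ((1/W) * sum(width_i * value_i^p))^(1/p)` over the intervals with
#' non-missing values, of total width `W`. `p = 1` is the time average,
#' `p = -1` the harmonic mean, and `p = 0` is handled as the geometric-mean
#' limit. Intervals with `NA` values are excluded from the measure.
#'
#' @param values per-interval values of the series.
#' @param widths per-interval durations (same length, >= 0).
#' @param p power-mean exponent (default 1).
#' @return the power mean, or `NA` if no non-missing measure remains.
#' @examples
#' power_mean(c(2, 4), c(3, 3))       # arithmetic: 3
#' power_mean(c(2, 4), c(3, 3), -1)   # harmonic: 8/3
#' @export
power_mean <- function(values, widths, p = 1) {
  stopifnot(length(values) == length(widths), all(widths >= 0))
  ok <- !is.na(values) & widths > 0
  W <- sum(widths[ok])
  if (W == 0) return(NA_real_)
  v <- values[ok]; w <- widths[ok] / W
  if (p == 0) exp(sum(w * log(v)))
  else sum(w * v^p)^(1 / p)
}

#' Summarize a trajectory into the response set
#'
#' Applies the instantaneous persistence/biomass definitions to every state
#' interval of a trajectory and time-averages them with the continuous power
#' mean: `P_alpha`, `P_gamma`, `B_gamma`, `B_beta`, and the derived beta
#' persistence `P_beta = P_gamma / P_alpha` (the average number of distinct
#' local communities the regional pool is spread across; `NA` when
#' `P_alpha = 0`). Intervals where alpha (or the biomass CV) is undefined
#' are excluded from the respective time average, measure-weighted, unless
#' `count_empty_as_zero`.
#'
#' @param traj a [metacom_trajectory][simulate_run].
#' @param p power-mean exponent (default 1, the time average).
#' @param count_empty_as_zero treat intervals with no active non-mainland
#'   site as alpha = 0 (and CV intervals below 2 active sites as 0) instead
#'   of excluding them.
#' @return an object of class `response_set`: list with `P_alpha`,
#'   `P_gamma`, `P_beta`, `B_gamma`, `B_beta` and the run's provenance.
#' @export
summarize_run <- function(traj, p = 1, count_empty_as_zero = FALSE) {
  stopifnot(inherits(traj, "metacom_trajectory"))
  widths <- traj$intervals$t1 - traj$intervals$t0
  ml <- traj$mainland
  n_act <- rowSums(traj$active[, -ml, drop = FALSE])
  rich_sum <- rowSums(traj$richness[, -ml, drop = FALSE])
  alpha <- ifelse(n_act > 0, rich_sum / pmax(n_act, 1L) / traj$n_s, NA_real_)
  gamma <- traj$union_count / traj$n_s
  b_gamma <- rowSums(traj$biomass[, -ml, drop = FALSE])
  nm_biom <- traj$biomass[, -ml, drop = FALSE]
  nm_act <- traj$active[, -ml, drop = FALSE]
  b_beta <- vapply(seq_len(nrow(traj$intervals)), function(i) {
    tot <- nm_biom[i, nm_act[i, ]]
    if (length(tot) < 2L) return(NA_real_)
    m <- mean(tot)
    if (m == 0) return(NA_real_)
    sqrt(mean((tot - m)^2)) / m
  }, numeric(1))
  if (count_empty_as_zero) {
    alpha[is.na(alpha)] <- 0
    b_beta[is.na(b_beta)] <- 0
  }
  P_alpha <- power_mean(alpha, widths, p)
  P_gamma <- power_mean(gamma, widths, p)
  structure(list(
    P_alpha = P_alpha, P_gamma = P_gamma,
    P_beta = if (!is.na(P_alpha) && P_alpha > 0) P_gamma / P_alpha else NA_real_,
    B_gamma = power_mean(b_gamma, widths, p),
    B_beta = power_mean(b_beta, widths, p),
    provenance = list(horizon = traj$horizon, n_p = traj$n_p,
                      n_s = traj$n_s, a = traj$a, p = p,
                      count_empty_as_zero = count_empty_as_zero)),
    class = "response_set")
}

#' @export
print.response_set <- function(x, ...) {
  cat(sprintf("responses: P_alpha = %.4f, P_gamma = %.4f, P_beta = %s, B_gamma = %.4g, B_beta = %s\n",
              x$P_alpha, x$P_gamma,
              if (is.na(x$P_beta)) "NA" else sprintf("%.4f", x$P_beta),
              x$B_gamma,
              if (is.na(x$B_beta)) "NA" else sprintf("%.4f", x$B_beta)))
  invisible(x)
}

#' Sensitivity of a response to landscape asynchrony
#'
#' The finite-difference sensitivity `S[x] = (x_H - x_L) / (A_H - A_L)`
#' between a low and a high asynchrony level. The referential levels used
#' throughout are `A_L = 0` and `A_H = 0.5`, so `S = 2 * (x_H - x_L)`.
#'
#' @param x_low,x_high response values at the low/high asynchrony.
#' @param a_low,a_high the asynchrony levels (defaults 0 and 0.5).
#' @return the sensitivity (sign = sign of `x_high - x_low`).
#' @export
sensitivity <- function(x_low, x_high, a_low = 0, a_high = 0.5) {
  if (a_high <= a_low) stop("a_high must exceed a_low")
  (x_high - x_low) / (a_high - a_low)
}
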