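#' Sample a stochastic activation schedule for a landscape
#'
#' Each non-mainland site `p` is active during one short window per year. The
#' nominal window length is drawn once per site, `w_p ~ U(0.2, 0.3)` (year
#' units), and the window of year `k` (k = 0, ..., years-1) starts at
#' `k + z_{p,k}` with jitter `z_{p,k} ~ U(-A, +A)`; `A >= 0` is the landscape
#' asynchrony. Starts below 0 are clipped to 0. The activity set of a site is
#' the union of its yearly closed intervals, with overlapping intervals
#' merged. The mainland is always active.
#'
#' @param L a [landscape][generate_landscape].
#' @param A asynchrony magnitude (>= 0); `A = 0` gives perfectly synchronized
#'   integer-time starts.
#' @param years integer horizon (>= 1); one activation window per year.
#' @param seed optional integer seed.
#' @param w optional per-site vector of nominal window lengths, overriding the
#'   `U(0.2, 0.3)` draw. Used to pair schedules that differ only in jitter
#'   (variance reduction when comparing asynchrony levels).
#' @return an object of class `activation_schedule`: list with `w`,
#'   `intervals` (per site, a k x 2 matrix of merged `[start, end]` rows),
#'   `A`, `years`, `mainland`.
#' @examples
#' L <- generate_star_landscape(3, 0.2)
#' S <- sample_activation_schedule(L, A = 0.5, years = 6, seed = 1)
#' is_active(S, 2, 0.1)
#' @export
sample_activation_schedule <- function(L, A, years, seed = NULL, w = NULL) {
  stopifnot(inherits(L, "landscape"), A >= 0, years >= 1)
  n_p <- n_sites(L)
  with_seed(seed, {
    if (is.null(w)) w <- stats::runif(n_p, 0.2, 0.3)
    stopifnot(length(w) == n_p)
    intervals <- vector("list", n_p)
    for (p in seq_len(n_p)) {
      starts <- (seq_len(years) - 1) + stats::runif(years, -A, A)
      starts <- pmax(starts, 0)
      intervals[[p]] <- merge_intervals(cbind(starts, starts + w[p]))
    }
    structure(list(w = w, intervals = intervals, A = A, years = years,
                   mainland = L$mainland, n_p = n_p),
              class = "activation_schedule")
  })
}

# merge overlapping/touching closed intervals; rows sorted by start
merge_intervals <- function(m) {
  m <- m[order(m[, 1L]), , drop = FALSE]
  out <- m[1L, , drop = FALSE]
  if (nrow(m) > 1L) for (i in 2L:nrow(m)) {
    j <- nrow(out)
    if (m[i, 1L] <= out[j, 2L]) {
      out[j, 2L] <- max(out[j, 2L], m[i, 2L])
    } else out <- rbind(out, m[i, , drop = FALSE])
  }
  dimnames(out) <- list(NULL, c("start", "end"))
  out
}

#' Is a site active at time t?
#'
#' Intervals are closed: a site is active at both its activation and its
#' deactivation instant. The mainland is always active.
#'
#' @param S an [activation_schedule][sample_activation_schedule].
#' @param p site index.
#' @param t time (>= 0), vectorized.
#' @return logical vector, same length as `t`.
#' @export
is_active <- function(S, p, t) {
  stopifnot(inherits(S, "activation_schedule"), all(t >= 0))
  if (length(p) != 1L || is.na(p) || p < 1L || p > S$n_p)
    stop("unknown site index: ", p)
  if (p == S$mainland) return(rep(TRUE, length(t)))
  iv <- S$intervals[[p]]
  vapply(t, function(ti) any(iv[, 1L] <= ti & ti <= iv[, 2L]), logical(1L))
}

#' @export
print.activation_schedule <- function(x, ...) {
  cat(sprintf(
    "activation schedule: %d sites, %d year(s), asynchrony A = %g\n",
    x$n_p, x$years, x$A))
  cat(sprintf("  nominal active length w: mean %.3f [%.3f, %.3f]; mainland site %d always active\n",
              mean(x$w), min(x$w), max(x$w), x$mainland))
  invisible(x)
}

#' Export an activation schedule to CSV
#'
#' One row per merged interval, columns `site`, `interval_index`, `start`,
#' `end`.
#'
#' @param S an `activation_schedule`.
#' @param file path to write.
#' @return the written data frame, invisibly.
#' @export
write_schedule <- function(S, file) {
  rows <- do.call(rbind, lapply(seq_len(S$n_p), function(p) {
    iv <- S$intervals[[p]]
    data.frame(site = p, interval_index = seq_len(nrow(iv)),
               start = iv[, 1L], end = iv[, 2L])
  }))
  utils::write.csv(rows, file, row.names = FALSE)
  invisible(rows)
}
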