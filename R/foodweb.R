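#' Generate a food web with controlled trophic coherence
#'
#' Builds a directed acyclic predation network (links point prey -> predator)
#' from target species richness `n_s`, basal count `n_b`, link count `n_l`
#' and temperature `temperature`, a surrogate for trophic (in)coherence:
#' small temperatures force every link to span almost exactly one trophic
#' level (coherent web, near-integer levels, no omnivory); large temperatures
#' admit links across wide level gaps (incoherent, omnivorous webs).
#'
#' Construction (a generalized preferential-preying scheme): species are
#' ordered with the `n_b` basal species first. Each consumer receives a first
#' prey drawn uniformly from the species ordered before it, which assigns it
#' a provisional trophic level (prey level + 1). The remaining
#' `n_l - (n_s - n_b)` links are then sampled without replacement from all
#' remaining (earlier species, consumer) pairs with probability proportional
#' to `exp(-(gap - 1)^2 / (2 * max(temperature, 1e-6)^2))` where `gap` is the
#' provisional level difference, so at `temperature = 0` only gap-1 links are
#' admissible. If a draw cannot place all links, the first-prey assignment is
#' resampled (`max_tries` attempts) before failing. Final trophic levels are
#' recomputed from the realized adjacency (see [trophic_levels()]).
#'
#' @param n_s species richness.
#' @param n_b number of basal species (`1 <= n_b < n_s`).
#' @param n_l number of predation links; must lie in
#'   `[n_s - n_b, n_s*(n_s - n_b - 1) + n_b]`.
#' @param temperature food-web temperature, >= 0.
#' @param seed optional integer seed.
#' @param max_tries attempts at placing all links before erroring.
#' @return an object of class `foodweb`: list with `n_s`, `n_b`, `n_l`,
#'   `temperature`, `basal` (indices `1:n_b`), `links` (n_l x 2 matrix,
#'   columns `prey`, `predator`), `tl` (prey-averaged trophic levels),
#'   `q` (incoherence) and `C` (connectance).
#' @examples
#' W <- generate_foodweb(10, 2, 14, temperature = 0.01, seed = 3)
#' W
#' @export
generate_foodweb <- function(n_s, n_b, n_l, temperature, seed = NULL,
                             max_tries = 200L) {
  stopifnot(n_b >= 1, n_s > n_b, temperature >= 0)
  max_links <- n_s * (n_s - n_b - 1) + n_b
  if (n_l < n_s - n_b || n_l > max_links)
    stop(sprintf("link budget n_l must lie in [%d, %d]", n_s - n_b, max_links))
  with_seed(seed, {
    consumers <- (n_b + 1L):n_s
    n_extra <- n_l - length(consumers)
    tmax <- max(temperature, 1e-6)
    for (try in seq_len(max_tries)) {
      # provisional levels from a uniformly chosen first prey
      lev <- c(rep(1, n_b), rep(NA_real_, n_s - n_b))
      first_prey <- integer(n_s)
      for (j in consumers) {
        first_prey[j] <- resample(seq_len(j - 1L))
        lev[j] <- lev[first_prey[j]] + 1
      }
      links <- cbind(prey = first_prey[consumers], predator = consumers)
      if (n_extra > 0L) {
        # all remaining (earlier prey i, consumer j) pairs
        cand <- do.call(rbind, lapply(consumers, function(j) {
          i <- setdiff(seq_len(j - 1L), first_prey[j])
          if (length(i)) cbind(i, j) else NULL
        }))
        w <- exp(-(lev[cand[, 2L]] - lev[cand[, 1L]] - 1)^2 / (2 * tmax^2))
        ok <- w > 0
        if (sum(ok) < n_extra) next  # level structure cannot host the budget
        pick <- sample.int(nrow(cand), n_extra, prob = w) # zero-weight rows never drawn
        links <- rbind(links, cand[pick, , drop = FALSE])
      }
      colnames(links) <- c("prey", "predator")
      return(new_foodweb(n_s, n_b, links, temperature))
    }
    stop("food-web generation failed: could not place all links in ",
         max_tries, " tries (retry with another seed or smaller n_l)")
  })
}

new_foodweb <- function(n_s, n_b, links, temperature) {
  W <- structure(list(n_s = as.integer(n_s), n_b = as.integer(n_b),
                      n_l = nrow(links), temperature = temperature,
                      basal = seq_len(n_b),
                      links = matrix(as.integer(links), ncol = 2L,
                                     dimnames = list(NULL, c("prey", "predator")))),
                 class = "foodweb")
  if (any(W$links[, 1L] == W$links[, 2L])) stop("cannibal links are not allowed")
  if (any(W$links[, 2L] <= n_b)) stop("basal species cannot be predators")
  W$tl <- trophic_levels(W)
  W$q <- incoherence(W)
  W$C <- connectance(n_s, n_b, W$n_l)
  W
}

#' Prey-averaged trophic levels
#'
#' Solves the linear system `s_i = 1` for basal species and
#' `s_j = 1 + mean(s over prey of j)` for consumers. The solution is unique
#' because every consumer chain grounds in the basal set.
#'
#' @param W a `foodweb`.
#' @return numeric vector of length `n_s`.
#' @export
trophic_levels <- function(W) {
  stopifnot(inherits(W, "foodweb"))
  n <- W$n_s
  A <- diag(n)
  b <- rep(1, n)
  npre <- tabulate(W$links[, 2L], n)
  if (any(npre[-W$basal] == 0L)) stop("consumer with no prey")
  for (k in seq_len(nrow(W$links))) {
    i <- W$links[k, 1L]; j <- W$links[k, 2L]
    A[j, i] <- A[j, i] - 1 / npre[j]
  }
  as.numeric(solve(A, b))
}

#' Trophic incoherence q
#'
#' The standard deviation of the trophic-level gap `s_predator - s_prey` over
#' all links. `q = 0` iff every link spans exactly one level (a maximally
#' coherent web); large `q` indicates omnivory.
#'
#' @param W a `foodweb`.
#' @param sample if `TRUE`, use the sample (n-1) standard deviation; the
#'   default is the population convention (divide by the number of links).
#' @return nonnegative scalar.
#' @export
incoherence <- function(W, sample = FALSE) {
  stopifnot(inherits(W, "foodweb"), nrow(W$links) >= 1L)
  tl <- W$tl %||% trophic_levels(W)
  gaps <- tl[W$links[, 2L]] - tl[W$links[, 1L]]
  if (sample) stats::sd(gaps)
  else sqrt(mean((gaps - mean(gaps))^2))
}

#' Food-web connectance
#'
#' `C = n_l / (n_s * (n_s - n_b - 1) + n_b)`: realized links over the maximum
#' possible in a web with `n_b` basal species and no cannibals.
#'
#' @param n_s species richness.
#' @param n_b basal species count.
#' @param n_l link count.
#' @return connectance in `[0, 1]`.
#' @export
connectance <- function(n_s, n_b, n_l) {
  den <- n_s * (n_s - n_b - 1) + n_b
  stopifnot(den > 0)
  n_l / den
}

#' Link count for a target connectance
#'
#' Inverts [connectance()] and rounds to the nearest feasible integer.
#'
#' @inheritParams connectance
#' @param C target connectance.
#' @return integer link count.
#' @export
links_for_connectance <- function(n_s, n_b, C) {
  n_l <- round(C * (n_s * (n_s - n_b - 1) + n_b))
  as.integer(min(max(n_l, n_s - n_b), n_s * (n_s - n_b - 1) + n_b))
}

# prey-by-predator logical incidence matrix
prey_matrix <- function(W) {
  m <- matrix(FALSE, W$n_s, W$n_s)
  m[W$links] <- TRUE
  m
}

#' @export
print.foodweb <- function(x, ...) {
  cat(sprintf("foodweb: %d species (%d basal), %d links, C = %.4f\n",
              x$n_s, x$n_b, x$n_l, x$C))
  cat(sprintf("  temperature = %g, incoherence q = %.4f, max trophic level = %.2f\n",
              x$temperature, x$q, max(x$tl)))
  invisible(x)
}

#' Export / import a food web as edge-list CSV
#'
#' `write_foodweb()` writes two CSV files: `<stem>_links.csv` (columns
#' `prey`, `predator`) and `<stem>_species.csv` (columns `id`, `is_basal`).
#' `read_foodweb()` reads them back; the temperature of a replayed web is
#' recorded as `NA`.
#'
#' @param W a `foodweb`.
#' @param stem path stem for the two CSV files.
#' @return `write_foodweb()` the stem, invisibly; `read_foodweb()` a
#'   `foodweb`.
#' @export
write_foodweb <- function(W, stem) {
  utils::write.csv(as.data.frame(W$links), paste0(stem, "_links.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(id = seq_len(W$n_s),
                              is_basal = seq_len(W$n_s) <= W$n_b),
                   paste0(stem, "_species.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname write_foodweb
#' @export
read_foodweb <- function(stem) {
  links <- utils::read.csv(paste0(stem, "_links.csv"))
  species <- utils::read.csv(paste0(stem, "_species.csv"))
  n_s <- nrow(species)
  n_b <- sum(species$is_basal)
  new_foodweb(n_s, n_b, as.matrix(links[, c("prey", "predator")]), NA_real_)
}
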