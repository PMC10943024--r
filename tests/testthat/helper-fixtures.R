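# small systems used across test files; everything built in code

# 2-species predator-prey with a known equilibrium:
# x1 = 1.02/1.3, x2 = 0.8*x1 - 0.02
pair_dynamics <- function() {
  M <- matrix(c(-0.5, 0.4, -1, -0.5), 2, 2)
  prey <- matrix(FALSE, 2, 2)
  prey[1, 2] <- TRUE
  local_dynamics(M, r = c(1, -0.01), basal = 1L, prey = prey, lam = 0.5)
}

# a parameterized stable community from the standard generator
test_community <- function(n_s = 12, temperature = 0.1, lam = 1, seed = 1,
                           connectance = 0.2) {
  n_b <- max(1L, round(0.2 * n_s))
  n_l <- links_for_connectance(n_s, n_b, connectance)
  generate_stable_regional_community(n_s, n_b, n_l, temperature, lam,
                                     seed = seed)
}

# an always-active single-interval schedule (used to decouple dispersal
# tests from the yearly activation pattern)
always_active_schedule <- function(L, years) {
  n_p <- n_sites(L)
  structure(list(w = rep(years, n_p),
                 intervals = rep(list(matrix(c(0, years), 1, 2,
                                             dimnames = list(NULL, c("start", "end")))),
                                 n_p),
                 A = 0, years = years, mainland = L$mainland, n_p = n_p),
            class = "activation_schedule")
}

# independent cascade oracle: recompute the equilibrium of a species set by
# brute-force iteration (structural pruning + solve + threshold) written
# separately from the package's implementation
cascade_oracle <- function(dyn, present, threshold = 0.001) {
  S <- sort(unique(present))
  n <- nrow(dyn$M)
  repeat {
    changed <- FALSE
    # drop consumers with no prey, one at a time
    repeat {
      bad <- Filter(function(j) !(j %in% dyn$basal) &&
                      !any(dyn$prey[S, j]), S)
      if (!length(bad)) break
      S <- setdiff(S, bad[[1]])
      changed <- TRUE
    }
    if (!length(S)) return(list(survivors = integer(0), biomass = numeric(0)))
    x <- solve(dyn$M[S, S, drop = FALSE], -dyn$r[S])
    if (all(x >= threshold)) return(list(survivors = S,
                                         biomass = as.numeric(x)))
    S <- S[x >= threshold]
    if (!length(S)) return(list(survivors = integer(0), biomass = numeric(0)))
  }
}

# presence replay from a trajectory's event log (independent of snapshots)
replay_presence <- function(traj) {
  pres <- matrix(FALSE, traj$n_p, traj$n_s)
  pres[traj$mainland, ] <- TRUE
  states <- list()
  ev <- traj$events
  for (i in seq_len(nrow(ev))) {
    kind <- ev$kind[i]
    if (kind == "dispersal") pres[ev$to[i], ev$species[i]] <- TRUE
    else if (kind == "extinction") pres[ev$to[i], ev$species[i]] <- FALSE
    else if (kind == "deactivate") pres[ev$from[i], ] <- FALSE
    states[[i]] <- pres
  }
  states
}
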