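#' Build a Lotka-Volterra community matrix from a food web
#'
#' Entry `M[i, j]` is the per-unit-biomass effect of species `j` on the
#' growth rate of species `i`. The diagonal is the self-limitation `-lam`
#' (`lam > 0`). For each predation link (prey `i`, predator `j`) an
#' interaction strength `X` is drawn from a lognormal distribution with mean
#' 1 and standard deviation 0.25, and `M[i, j] = -X`, `M[j, i] = 0.4 * X`
#' (a fixed 0.4 biomass-conversion efficiency). Non-interacting off-diagonal
#' pairs are 0.
#'
#' @param W a [foodweb][generate_foodweb].
#' @param lam self-limitation strength, > 0 (the community-matrix diagonal is
#'   `-lam`).
#' @param seed optional integer seed.
#' @param moments `"variate"` (default) reads "mean 1, sd 0.25" as moments of
#'   the lognormal variate itself; `"log"` as the meanlog/sdlog of the
#'   underlying normal.
#' @return an `n_s` x `n_s` numeric matrix.
#' @export
build_community_matrix <- function(W, lam, seed = NULL,
                                   moments = c("variate", "log")) {
  stopifnot(inherits(W, "foodweb"), lam > 0)
  moments <- match.arg(moments)
  with_seed(seed, {
    n <- W$n_s
    M <- matrix(0, n, n)
    diag(M) <- -lam
    if (moments == "variate") {
      s2 <- log(1 + 0.25^2)            # variate mean 1, sd 0.25
      X <- stats::rlnorm(nrow(W$links), meanlog = -s2 / 2, sdlog = sqrt(s2))
    } else {
      X <- stats::rlnorm(nrow(W$links), meanlog = 1, sdlog = 0.25)
    }
    prey <- W$links[, 1L]; pred <- W$links[, 2L]
    M[cbind(prey, pred)] <- -X
    M[cbind(pred, prey)] <- 0.4 * X
    M
  })
}

#' Parameterize growth rates by linear programming
#'
#' Chooses intrinsic growth rates `r` so that the full species pool has a
#' feasible interior equilibrium with the *largest possible smallest*
#' abundance: maximize `y` over `(r, x, y)` subject to `r + M x = 0`,
#' `x_i >= y`, `y >= 0`, `r_i <= rho` for basal species and `r_i <= -mu` for
#' consumers. Substituting `r = -M x` reduces this to an LP in `(x, y)`,
#' solved with the simplex method ([boot::simplex()]). Infeasibility means no
#' growth-rate vector gives all-positive equilibrium abundances; the caller
#' is expected to discard the web and generate a new one.
#'
#' @param M community matrix.
#' @param basal integer indices of basal species.
#' @param rho cap on basal intrinsic growth rates (default 1).
#' @param mu minimum mortality rate for consumers (default 0.01), i.e.
#'   `r_i <= -mu` for non-basal `i`.
#' @return a list with `feasible` (logical); when feasible also `r`, `x_star`
#'   (equilibrium biomasses) and `y_star` (the maximized minimum abundance).
#' @examples
#' parameterize_growth_rates(matrix(-0.5), basal = 1L)  # r = 1, x* = y* = 2
#' @export
parameterize_growth_rates <- function(M, basal, rho = 1, mu = 0.01) {
  n <- nrow(M)
  stopifnot(ncol(M) == n, all(basal >= 1L), all(basal <= n))
  is_basal <- seq_len(n) %in% basal
  # variables v = (x_1..x_n, y), all >= 0; maximize y
  obj <- c(rep(0, n), 1)
  # basal:    r_i = -(Mx)_i <= rho   ->  (-M x)_i <= rho
  nb <- sum(is_basal); nc <- sum(!is_basal)
  A1 <- cbind(-M[is_basal, , drop = FALSE], rep(0, nb))
  b1 <- rep(rho, nb)
  # consumer: r_i <= -mu             ->  (M x)_i >= mu
  # feasibility: x_i - y >= 0
  A2 <- rbind(cbind(M[!is_basal, , drop = FALSE], rep(0, nc)),
              cbind(diag(n), rep(-1, n)))
  b2 <- c(rep(mu, nc), rep(0, n))
  sol <- tryCatch(
    boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                  maxi = TRUE, n.iter = 50L * (n + 1L) * (2L * n)),
    error = function(e) NULL)
  if (is.null(sol) || sol$solved != 1L)
    return(list(feasible = FALSE))
  x <- unname(sol$soln[seq_len(n)])
  list(feasible = TRUE, r = as.numeric(-M %*% x), x_star = x,
       y_star = unname(sol$value))
}

#' Lyapunov stability of an interior equilibrium
#'
#' At an interior equilibrium (`r + M x* = 0`, `x* > 0`) the Jacobian of the
#' Lotka-Volterra system is `J = diag(x*) %*% M`. The equilibrium is locally
#' stable iff all eigenvalues of `J` have negative real parts.
#'
#' @param M community matrix.
#' @param x_star equilibrium biomasses, strictly positive.
#' @return `TRUE` if `max Re(eig(J)) < 0`.
#' @export
is_locally_stable <- function(M, x_star) {
  stopifnot(length(x_star) == nrow(M), all(x_star > 0))
  J <- x_star * M  # row i scaled by x_star[i]
  max(Re(eigen(J, only.values = TRUE)$values)) < 0
}

#' Construct a local-dynamics object
#'
#' Bundles everything the equilibrium machinery needs about a parameterized
#' community: the community matrix, growth rates, the basal set and the
#' prey incidence structure. Usually produced by
#' [generate_stable_regional_community()]; exposed for replaying exported
#' communities and for building small test systems.
#'
#' @param M community matrix.
#' @param r intrinsic growth rates.
#' @param basal integer indices of basal species.
#' @param prey logical prey-by-predator incidence matrix (`prey[i, j]` is
#'   `TRUE` iff `i` is a prey of `j`); defaults to no trophic structure.
#' @param lam self-limitation (defaults to `-M[1, 1]`).
#' @param x_star optional full-pool equilibrium.
#' @param y_star optional LP objective value.
#' @param rho,mu the growth-rate caps used at parameterization.
#' @return an object of class `local_dynamics`.
#' @export
local_dynamics <- function(M, r, basal, prey = NULL, lam = -M[1, 1],
                           x_star = NULL, y_star = NULL, rho = 1, mu = 0.01) {
  n <- nrow(M)
  stopifnot(ncol(M) == n, length(r) == n, all(basal %in% seq_len(n)))
  if (is.null(prey)) prey <- matrix(FALSE, n, n)
  stopifnot(dim(prey) == c(n, n))
  structure(list(M = M, r = as.numeric(r), lam = lam, x_star = x_star,
                 y_star = y_star, basal = as.integer(basal), prey = prey,
                 rho = rho, mu = mu),
            class = "local_dynamics")
}

#' Generate a feasible, stable regional community
#'
#' Loops over {generate food web, draw interaction strengths, LP growth-rate
#' parameterization, Jacobian eigenvalue screening} until a web is found that
#' is both LP-feasible (all-positive full-pool equilibrium) and locally
#' stable at that equilibrium. Webs failing either screen are discarded, as
#' are webs whose link budget cannot be placed.
#'
#' @inheritParams generate_foodweb
#' @inheritParams build_community_matrix
#' @param max_tries attempts before giving up with an error.
#' @return a list of class `regional_community` with `web` (the `foodweb`),
#'   `dyn` (a `local_dynamics` object: `M`, `r`, `lam`, `x_star`, `y_star`,
#'   `basal`, `prey` incidence matrix, `rho`, `mu`) and `tries`.
#' @export
generate_stable_regional_community <- function(n_s, n_b, n_l, temperature,
                                               lam, seed = NULL,
                                               max_tries = 100L,
                                               rho = 1, mu = 0.01) {
  stopifnot(max_tries >= 1)
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      W <- tryCatch(generate_foodweb(n_s, n_b, n_l, temperature),
                    error = function(e) NULL)
      if (is.null(W)) next
      M <- build_community_matrix(W, lam)
      lp <- parameterize_growth_rates(M, W$basal, rho = rho, mu = mu)
      if (!lp$feasible) next
      if (!is_locally_stable(M, lp$x_star)) next
      dyn <- local_dynamics(M, lp$r, W$basal, prey_matrix(W), lam = lam,
                            x_star = lp$x_star, y_star = lp$y_star,
                            rho = rho, mu = mu)
      return(structure(list(web = W, dyn = dyn, tries = try),
                       class = "regional_community"))
    }
    stop("no feasible, stable community found in ", max_tries, " tries ",
         sprintf("(n_s=%d, n_l=%d, temperature=%g, lam=%g)",
                 n_s, n_l, temperature, lam))
  })
}

#' @export
print.regional_community <- function(x, ...) {
  cat(sprintf("regional community: accepted after %d tries\n", x$tries))
  print(x$web)
  cat(sprintf("  lam = %g, y* = %.4g, biomass range [%.4g, %.4g]\n",
              x$dyn$lam, x$dyn$y_star, min(x$dyn$x_star), max(x$dyn$x_star)))
  invisible(x)
}

#' Local equilibrium with secondary-extinction cascades
#'
#' Computes the equilibrium community of a subset of the regional pool at a
#' single site. Iteratively: (i) structurally remove consumers left with no
#' prey in the set; (ii) solve the linear subsystem
#' `r_S + M[S, S] x_S = 0`; (iii) remove every species whose biomass falls
#' below the extinction threshold (0.001, including non-positive values);
#' repeat until nothing is removed. The removal policy is simultaneous (all
#' below-threshold species drop in the same iteration), which is
#' deterministic and terminates in at most `length(present)` iterations.
#'
#' @param dyn a `local_dynamics` object (see
#'   [generate_stable_regional_community()]).
#' @param present integer indices of the species present.
#' @param invader optional index of the most recently arrived species; if the
#'   subsystem solve is singular (non-generic), the invader is declared
#'   extinct and the solve retried.
#' @param threshold extinction threshold on biomass (default 0.001).
#' @return a list of class `equilibrium_result`: `survivors` (sorted integer
#'   indices), `biomass` (named by species index), `extinctions` (species
#'   removed, in removal order), `iterations`.
#' @export
local_equilibrium <- function(dyn, present, invader = NULL,
                              threshold = 0.001) {
  stopifnot(inherits(dyn, "local_dynamics"), length(present) >= 1L)
  S <- sort(unique(as.integer(present)))
  is_basal <- seq_along(dyn$r) %in% dyn$basal
  removed <- integer(0)
  iterations <- 0L
  x <- numeric(0)
  while (length(S) > 0L) {
    iterations <- iterations + 1L
    # structural pruning: consumers with no surviving prey (cascades through
    # chains, so iterate)
    repeat {
      has_prey <- is_basal[S] |
        colSums(dyn$prey[S, S, drop = FALSE]) > 0L
      if (all(has_prey)) break
      removed <- c(removed, S[!has_prey])
      S <- S[has_prey]
      if (length(S) == 0L) break
    }
    if (length(S) == 0L) break
    x <- tryCatch(solve(dyn$M[S, S, drop = FALSE], -dyn$r[S]),
                  error = function(e) NULL)
    if (is.null(x)) {
      if (!is.null(invader) && invader %in% S) {
        removed <- c(removed, invader)
        S <- setdiff(S, invader)
        next
      }
      stop("singular community subsystem and no invader to remove")
    }
    dead <- x < threshold
    if (!any(dead)) break
    removed <- c(removed, S[dead])
    S <- S[!dead]
    x <- numeric(0)
  }
  structure(list(survivors = S,
                 biomass = if (length(S)) stats::setNames(as.numeric(x), S)
                           else stats::setNames(numeric(0), integer(0)),
                 extinctions = removed, iterations = iterations),
            class = "equilibrium_result")
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat(sprintf("equilibrium: %d survivor(s), %d extinction(s) in %d iteration(s)\n",
              length(x$survivors), length(x$extinctions), x$iterations))
  invisible(x)
}

#' Assemble a single community from a regional pool
#'
#' Emulates the limiting case of one permanently available site with
#' unlimited access to the regional pool (a site adjacent to the mainland
#' with fast dispersal): absent species invade one at a time in random
#' order, each arrival triggering an equilibrium recomputation with
#' secondary-extinction cascades, until no absent species can establish.
#' Colonization is prey-gated (a consumer needs a resident prey) and an
#' invader that fails under a given resident composition is not retried
#' until that composition changes. Although the full pool coexists stably
#' by construction, the one-at-a-time assembly path can terminate in an
#' invasion-resistant sub-community; unstable-prone pools (high
#' temperature, weak self-limitation) lose more species on the way.
#'
#' @param dyn the `local_dynamics` of an accepted regional community.
#' @param seed optional integer seed for the arrival order.
#' @param max_attempts cap on invasion attempts (default `50 * n_s`).
#' @return a list: `survivors`, `biomass`, `persistence`
#'   (`length(survivors) / n_s`), `attempts`.
#' @export
assemble_community <- function(dyn, seed = NULL,
                               max_attempts = 50L * nrow(dyn$M)) {
  stopifnot(inherits(dyn, "local_dynamics"))
  n <- nrow(dyn$M)
  basal <- seq_len(n) %in% dyn$basal
  with_seed(seed, {
    pres <- rep(FALSE, n)
    failed <- rep(FALSE, n)
    attempts <- 0L
    repeat {
      gate <- basal | as.vector(crossprod(dyn$prey, pres)) > 0
      cand <- which(!pres & gate & !failed)
      if (!length(cand) || attempts >= max_attempts) break
      s <- resample(cand)
      attempts <- attempts + 1L
      res <- invade_site(dyn, pres, s)
      if (res$changed) {
        pres <- res$present
        biom <- res$biomass
        failed[] <- FALSE
      }
      if (!res$established) failed[s] <- TRUE
    }
    list(survivors = which(pres),
         biomass = if (any(pres)) biom[pres] else numeric(0),
         persistence = sum(pres) / n, attempts = attempts)
  })
}

#' Single-site assembly persistence
#'
#' Convenience wrapper for the local-stability experiment: generates an
#' accepted (feasible, stable) regional community at the given parameters
#' and assembles a single always-available site from it
#' ([assemble_community()]). Returns the fraction of the pool present at
#' saturation. Persistence decreases with food-web temperature and
#' increases with self-limitation.
#'
#' @inheritParams generate_stable_regional_community
#' @return persistence in `[0, 1]`.
#' @export
assembly_persistence <- function(n_s, n_b, n_l, temperature, lam,
                                 seed = NULL, max_tries = 500L) {
  with_seed(seed, {
    comm <- generate_stable_regional_community(n_s, n_b, n_l, temperature,
                                               lam, max_tries = max_tries)
    assemble_community(comm$dyn)$persistence
  })
}
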