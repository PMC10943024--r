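#' Effective dispersal rate between two sites
#'
#' The per-species rate of dispersal events along an edge is the dispersal
#' ability divided by the Euclidean distance, `a / d`, floored to zero when
#' the ratio falls below 0.1 (dispersal between such distant sites is
#' impossible).
#'
#' @param a dispersal ability, >= 0 (equal for all species).
#' @param d Euclidean distance, > 0. Vectorized.
#' @return rate(s), `a/d` or 0.
#' @examples
#' effective_rate(30, 300)  # exactly 0.1: kept
#' effective_rate(30, 301)  # below the cutoff: 0
#' @export
effective_rate <- function(a, d) {
  stopifnot(a >= 0, all(d > 0))
  r <- a / d
  ifelse(r < 0.1, 0, r)
}

#' Create a metacommunity state
#'
#' Bundles the discrete and continuous state variables of the metacommunity:
#' per-site presence/absence, per-site equilibrium biomasses, per-site
#' activity, and the current time. The mainland row is permanently present
#' and holds the full-pool equilibrium.
#'
#' @param present `n_p` x `n_s` logical occupancy matrix.
#' @param biomass `n_p` x `n_s` nonnegative biomass matrix
#'   (`biomass > 0` iff `present`).
#' @param active logical vector of per-site activity.
#' @param mainland mainland site index.
#' @param t current time.
#' @return an object of class `metacommunity_state`.
#' @export
metacommunity_state <- function(present, biomass, active, mainland, t = 0) {
  stopifnot(is.matrix(present), dim(biomass) == dim(present),
            length(active) == nrow(present))
  structure(list(present = present, biomass = biomass, active = active,
                 mainland = as.integer(mainland), t = t),
            class = "metacommunity_state")
}

#' Enumerate eligible dispersal events
#'
#' A dispersal event of species `s` along the directed edge `p -> q` is
#' eligible iff both sites are active, `s` is present in `p` and absent from
#' `q`, and `s` is basal or has at least one prey species present in `q`
#' (prey-gated colonization). Both directions of every landscape edge are
#' considered; the mainland is a valid source. Events whose effective rate
#' is floored to zero are omitted.
#'
#' @param state a [metacommunity_state()].
#' @param L the [landscape][generate_landscape].
#' @param W the [foodweb][generate_foodweb].
#' @param a dispersal ability.
#' @return a data frame with columns `species`, `from`, `to`, `rate`.
#' @export
eligible_dispersal_events <- function(state, L, W, a) {
  basal <- seq_len(W$n_s) %in% W$basal
  preyM <- prey_matrix(W)
  from <- c(L$edges[, 1L], L$edges[, 2L])
  to <- c(L$edges[, 2L], L$edges[, 1L])
  rate <- effective_rate(a, c(L$weights, L$weights))
  keep <- rate > 0 & state$active[from] & state$active[to]
  out <- list()
  for (k in which(keep)) {
    p <- from[k]; q <- to[k]
    gate <- basal | (crossprod(preyM, state$present[q, ]) > 0)
    s <- which(state$present[p, ] & !state$present[q, ] & gate)
    if (length(s))
      out[[length(out) + 1L]] <- data.frame(species = s, from = p, to = q,
                                            rate = rate[k])
  }
  if (!length(out))
    return(data.frame(species = integer(0), from = integer(0),
                      to = integer(0), rate = numeric(0)))
  do.call(rbind, out)
}

# next deterministic activation/deactivation strictly after time t
next_schedule_event <- function(S, t, horizon) {
  best <- list(time = Inf, kind = NA_character_, site = NA_integer_)
  for (p in seq_len(S$n_p)) {
    if (p == S$mainland) next
    iv <- S$intervals[[p]]
    st <- iv[iv[, 1L] > t & iv[, 1L] <= horizon, 1L]
    en <- iv[iv[, 2L] > t & iv[, 2L] <= horizon, 2L]
    # deactivations sort before activations at equal times
    if (length(en) && (min(en) < best$time ||
                       (min(en) == best$time && best$kind == "activate")))
      best <- list(time = min(en), kind = "deactivate", site = p)
    if (length(st) && min(st) < best$time)
      best <- list(time = min(st), kind = "activate", site = p)
  }
  best
}

#' Draw the next event with the first-reaction method
#'
#' Each eligible dispersal event draws an independent exponential waiting
#' time at its effective rate; the next event is the earliest of these
#' firing times, the next scheduled (de)activation, and the horizon.
#' Scheduled events win ties against dispersal.
#'
#' @param state a [metacommunity_state()].
#' @param schedule an [activation_schedule][sample_activation_schedule].
#' @param events a data frame of eligible events
#'   ([eligible_dispersal_events()]).
#' @param horizon end of the simulation window.
#' @return a list `(time, event)` where `event` is a list with `kind`
#'   (`"dispersal"`, `"activate"`, `"deactivate"`, or `"end"`) and, for
#'   dispersal, `species`, `from`, `to`.
#' @export
first_reaction_step <- function(state, schedule, events, horizon) {
  sched <- next_schedule_event(schedule, state$t, horizon)
  td <- Inf; kd <- NA_integer_
  if (nrow(events) > 0L) {
    wt <- stats::rexp(nrow(events), rate = events$rate)
    kd <- which.min(wt)
    td <- state$t + wt[kd]
  }
  if (horizon <= min(td, sched$time))
    return(list(time = horizon, event = list(kind = "end")))
  if (sched$time <= td)
    return(list(time = sched$time,
                event = list(kind = sched$kind, site = sched$site)))
  list(time = td,
       event = list(kind = "dispersal", species = events$species[kd],
                    from = events$from[kd], to = events$to[kd]))
}

# attempt an invasion of species s into a site with logical occupancy pres;
# returns the recomputed site composition and whether anything changed
invade_site <- function(dyn, pres, s) {
  eq <- local_equilibrium(dyn, c(which(pres), s), invader = s)
  new_pres <- rep(FALSE, length(pres))
  new_pres[eq$survivors] <- TRUE
  biom <- rep(0, length(pres))
  biom[eq$survivors] <- eq$biomass
  list(established = s %in% eq$survivors,
       changed = !identical(new_pres, pres),
       present = new_pres, biomass = biom,
       extinctions = setdiff(eq$extinctions, s))
}

#' Apply an event to a metacommunity state
#'
#' Site deactivation zeroes the site (species and biomass); activation makes
#' an empty site available for colonization; a dispersal event adds the
#' species to the destination and recomputes the destination's equilibrium
#' with extinction cascades (the arrival itself may fail to establish). The
#' source site is unchanged by dispersal, and the mainland never changes.
#'
#' @param state a [metacommunity_state()].
#' @param event a list with `kind` and its payload (as returned inside
#'   [first_reaction_step()]), plus `time`.
#' @param dyn the `local_dynamics` of the regional community.
#' @return the updated `metacommunity_state`.
#' @export
apply_event <- function(state, event, dyn) {
  if (!is.null(event$time)) {
    stopifnot(event$time >= state$t)
    state$t <- event$time
  }
  switch(event$kind,
    deactivate = {
      p <- event$site
      if (p == state$mainland) stop("the mainland cannot deactivate")
      state$active[p] <- FALSE
      state$present[p, ] <- FALSE
      state$biomass[p, ] <- 0
    },
    activate = {
      state$active[event$site] <- TRUE
    },
    dispersal = {
      q <- event$to
      if (!state$active[q] || !state$active[event$from])
        stop("dispersal event references an inactive site")
      if (q != state$mainland) {
        res <- invade_site(dyn, state$present[q, ], event$species)
        state$present[q, ] <- res$present
        state$biomass[q, ] <- res$biomass
      }
    },
    end = NULL,
    stop("unknown event kind: ", event$kind))
  state
}

#' Simulate a metacommunity run
#'
#' Event-driven simulation of the coupled system: deterministic site
#' (de)activations from the schedule, stochastic dispersal along landscape
#' edges as a continuous-time Markov chain (first-reaction method), and
#' instantaneous local-equilibrium recomputation with secondary-extinction
#' cascades at every arrival. The run starts at `t = 0` with the mainland
#' active and holding the full-pool equilibrium, and every other site empty
#' (active if its schedule covers 0).
#'
#' Failed invasions (arrivals that are cascade-removed without altering the
#' destination) do not change the state, so they are logged on first
#' occurrence and then suppressed from the candidate set until the
#' destination's composition changes; this is statistically exact for the
#' state trajectory and keeps high-dispersal runs tractable.
#'
#' @param L the [landscape][generate_landscape].
#' @param schedule an [activation_schedule][sample_activation_schedule].
#' @param W the [foodweb][generate_foodweb].
#' @param dyn the regional `local_dynamics`
#'   ([generate_stable_regional_community()]).
#' @param a dispersal ability (>= 0; 0 disables dispersal entirely).
#' @param horizon simulated years (defaults to the schedule's).
#' @param seed optional integer seed for the event randomness.
#' @param distance_scale physical side length of the landscape's unit square,
#'   in the distance units of `a`. Effective rates are
#'   `a / (distance_scale * d)` with the usual 0.1 cutoff. The default 1
#'   uses raw coordinates; experiment-level configs typically set a scale of
#'   order 10^3 so that a dispersal-ability range like `[30, 3000]` spans
#'   dispersal-limited to saturated regimes (see [sweep_config()]).
#' @return an object of class `metacom_trajectory`: piecewise-constant
#'   snapshots between events (`intervals` with `t0`,`t1`; per-site
#'   `richness`, `biomass`, `active` matrices; non-mainland species-pool
#'   `union_count`), the event log `events`, and run metadata.
#' @export
simulate_run <- function(L, schedule, W, dyn, a, horizon = schedule$years,
                         seed = NULL, distance_scale = 1) {
  stopifnot(inherits(L, "landscape"), inherits(schedule, "activation_schedule"),
            inherits(W, "foodweb"), inherits(dyn, "local_dynamics"),
            horizon > 0, distance_scale > 0)
  with_seed(seed, {
    n_p <- n_sites(L); n_s <- W$n_s; ml <- L$mainland
    basal <- seq_len(n_s) %in% W$basal
    preyM <- dyn$prey
    basalM <- matrix(basal, n_p, n_s, byrow = TRUE)

    # directed edges with nonzero effective rate
    efrom <- c(L$edges[, 1L], L$edges[, 2L])
    eto <- c(L$edges[, 2L], L$edges[, 1L])
    erate <- effective_rate(a, distance_scale * c(L$weights, L$weights))
    keep <- erate > 0
    efrom <- efrom[keep]; eto <- eto[keep]; erate <- erate[keep]

    # deterministic schedule events within (0, horizon], tie order
    # deactivate < activate
    sev <- list()
    for (p in seq_len(n_p)) {
      if (p == ml) next
      iv <- schedule$intervals[[p]]
      st <- iv[iv[, 1L] > 0 & iv[, 1L] <= horizon, 1L]
      en <- iv[iv[, 2L] > 0 & iv[, 2L] <= horizon, 2L]
      if (length(st) || length(en))
        sev[[length(sev) + 1L]] <- data.frame(
          time = c(en, st), type = rep(1:2, c(length(en), length(st))),
          site = p)
    }
    sev <- if (length(sev)) do.call(rbind, sev) else
      data.frame(time = numeric(0), type = integer(0), site = integer(0))
    sev <- sev[order(sev$time, sev$type, sev$site), , drop = FALSE]
    n_sev <- nrow(sev); si <- 1L

    # state
    active <- vapply(seq_len(n_p), function(p)
      p == ml || any(schedule$intervals[[p]][, 1L] <= 0 &
                     0 <= schedule$intervals[[p]][, 2L]), logical(1L))
    present <- matrix(FALSE, n_p, n_s)
    biomass <- matrix(0, n_p, n_s)
    present[ml, ] <- TRUE
    biomass[ml, ] <- dyn$x_star
    prey_avail <- matrix(FALSE, n_p, n_s)
    prey_avail[ml, ] <- as.vector(crossprod(preyM, present[ml, ])) > 0
    failed <- matrix(FALSE, n_p, n_s)

    richness <- rowSums(present)
    biomtot <- rowSums(biomass)
    union_count <- sum(colSums(present[-ml, , drop = FALSE]) > 0L)

    # accumulators
    sn_t0 <- numeric(0); sn_t1 <- numeric(0)
    sn_rich <- list(); sn_biom <- list(); sn_act <- list(); sn_union <- numeric(0)
    ev_time <- numeric(0); ev_kind <- character(0)
    ev_species <- integer(0); ev_from <- integer(0); ev_to <- integer(0)
    log_event <- function(time, kind, species = NA_integer_,
                          from = NA_integer_, to = NA_integer_) {
      ev_time[length(ev_time) + 1L] <<- time
      ev_kind[length(ev_kind) + 1L] <<- kind
      ev_species[length(ev_species) + 1L] <<- species
      ev_from[length(ev_from) + 1L] <<- from
      ev_to[length(ev_to) + 1L] <<- to
    }
    t0 <- 0
    close_interval <- function(t1) {
      sn_t0[length(sn_t0) + 1L] <<- t0
      sn_t1[length(sn_t1) + 1L] <<- t1
      sn_rich[[length(sn_rich) + 1L]] <<- richness
      sn_biom[[length(sn_biom) + 1L]] <<- biomtot
      sn_act[[length(sn_act) + 1L]] <<- active
      sn_union[length(sn_union) + 1L] <<- union_count
      t0 <<- t1
    }
    refresh_site <- function(q) {
      prey_avail[q, ] <<- as.vector(crossprod(preyM, present[q, ])) > 0
      failed[q, ] <<- FALSE
      richness[q] <<- sum(present[q, ])
      biomtot[q] <<- sum(biomass[q, ])
      union_count <<- sum(colSums(present[-ml, , drop = FALSE]) > 0L)
    }

    t <- 0
    repeat {
      # candidate dispersal events under the current state
      ae <- which(active[efrom] & active[eto])
      td <- Inf; cand_edge <- NA_integer_; cand_sp <- NA_integer_
      if (length(ae)) {
        cm <- present[efrom[ae], , drop = FALSE] &
          !present[eto[ae], , drop = FALSE] &
          (basalM[eto[ae], , drop = FALSE] |
             prey_avail[eto[ae], , drop = FALSE]) &
          !failed[eto[ae], , drop = FALSE]
        idx <- which(cm)
        if (length(idx)) {
          nr <- length(ae)
          rows <- (idx - 1L) %% nr + 1L
          sp <- (idx - 1L) %/% nr + 1L
          wt <- stats::rexp(length(idx), rate = erate[ae[rows]])
          k <- which.min(wt)
          td <- t + wt[k]
          cand_edge <- ae[rows[k]]; cand_sp <- sp[k]
        }
      }
      ts <- if (si <= n_sev) sev$time[si] else Inf

      if (horizon <= min(td, ts)) { close_interval(horizon); t <- horizon; break }

      if (ts <= td) {
        t <- ts
        close_interval(t)
        while (si <= n_sev && sev$time[si] == ts) {
          p <- sev$site[si]
          if (sev$type[si] == 1L) {       # deactivate
            active[p] <- FALSE
            present[p, ] <- FALSE
            biomass[p, ] <- 0
            refresh_site(p)
            log_event(t, "deactivate", from = p)
          } else {                        # activate (empty)
            active[p] <- TRUE
            refresh_site(p)
            log_event(t, "activate", to = p)
          }
          si <- si + 1L
        }
      } else {
        t <- td
        p <- efrom[cand_edge]; q <- eto[cand_edge]; s <- cand_sp
        res <- invade_site(dyn, present[q, ], s)
        if (!res$changed) {
          failed[q, s] <- TRUE
          log_event(t, "failed_invasion", species = s, from = p, to = q)
        } else {
          close_interval(t)
          present[q, ] <- res$present
          biomass[q, ] <- res$biomass
          refresh_site(q)
          if (!res$established) failed[q, s] <- TRUE
          log_event(t, if (res$established) "dispersal" else "failed_invasion",
                    species = s, from = p, to = q)
          for (e in res$extinctions)
            log_event(t, "extinction", species = e, to = q)
        }
      }
    }

    structure(list(
      intervals = data.frame(t0 = sn_t0, t1 = sn_t1),
      richness = do.call(rbind, sn_rich),
      biomass = do.call(rbind, sn_biom),
      active = do.call(rbind, sn_act),
      union_count = sn_union,
      events = data.frame(time = ev_time, kind = ev_kind,
                          species = ev_species, from = ev_from, to = ev_to),
      horizon = horizon, n_s = n_s, n_p = n_p, mainland = ml, a = a),
      class = "metacom_trajectory")
  })
}

#' @export
print.metacom_trajectory <- function(x, ...) {
  cat(sprintf("metacommunity trajectory: %d sites, %d species, %g year(s), a = %g\n",
              x$n_p, x$n_s, x$horizon, x$a))
  cat(sprintf("  %d state interval(s), %d event(s) (%s)\n",
              nrow(x$intervals), nrow(x$events),
              paste(sprintf("%s: %d", names(table(x$events$kind)),
                            table(x$events$kind)), collapse = ", ")))
  invisible(x)
}

#' Export a trajectory's events, snapshots and metadata
#'
#' Writes `<stem>_events.csv` (time, kind, species, from, to),
#' `<stem>_snapshots.csv` (t0, t1, site, richness, biomass, active) and
#' `<stem>_meta.json` (run parameters).
#'
#' @param traj a `metacom_trajectory`.
#' @param stem path stem.
#' @return the stem, invisibly.
#' @export
write_trajectory <- function(traj, stem) {
  utils::write.csv(traj$events, paste0(stem, "_events.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(horizon = traj$horizon, n_s = traj$n_s, n_p = traj$n_p,
         mainland = traj$mainland, a = traj$a,
         n_events = nrow(traj$events), n_intervals = nrow(traj$intervals)),
    paste0(stem, "_meta.json"), auto_unbox = TRUE, digits = NA)
  n_int <- nrow(traj$intervals)
  snaps <- data.frame(
    t0 = rep(traj$intervals$t0, traj$n_p),
    t1 = rep(traj$intervals$t1, traj$n_p),
    site = rep(seq_len(traj$n_p), each = n_int),
    richness = as.vector(traj$richness),
    biomass = as.vector(traj$biomass),
    active = as.vector(traj$active))
  utils::write.csv(snaps, paste0(stem, "_snapshots.csv"), row.names = FALSE)
  invisible(stem)
}
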