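test_that("effective rates apply the 0.1 cutoff exactly as printed", {
  expect_equal(effective_rate(30, 300), 0.1)   # not less than 0.1: kept
  expect_equal(effective_rate(30, 301), 0)     # 0.0997 < 0.1: zeroed
  expect_equal(effective_rate(3000, 1), 3000)
  expect_equal(effective_rate(0, 5), 0)
})

star_setup <- function(n_leaves = 1, radius = 0.2, n_s = 5, temperature = 0.1,
                       lam = 1, seed = 1) {
  comm <- test_community(n_s = n_s, temperature = temperature, lam = lam,
                         seed = seed)
  L <- generate_star_landscape(n_leaves, radius)
  list(comm = comm, L = L)
}

full_state <- function(L, dyn, active = rep(TRUE, n_sites(L))) {
  n_p <- n_sites(L); n_s <- nrow(dyn$M)
  present <- matrix(FALSE, n_p, n_s)
  biomass <- matrix(0, n_p, n_s)
  present[L$mainland, ] <- TRUE
  biomass[L$mainland, ] <- dyn$x_star
  metacommunity_state(present, biomass, active, L$mainland)
}

test_that("dispersal candidates are prey-gated and activity-gated", {
  st <- star_setup(n_leaves = 2, n_s = 10, seed = 2)
  dyn <- st$comm$dyn; W <- st$comm$web; L <- st$L
  state <- full_state(L, dyn)
  ev <- eligible_dispersal_events(state, L, W, a = 10)
  # empty active leaves can only receive basal species, at rate a/d each
  expect_equal(sort(unique(ev$species)), W$basal)
  expect_equal(nrow(ev), 2 * W$n_b)
  expect_equal(unique(ev$rate), 10 / 0.2)
  expect_true(all(ev$from == L$mainland))
  # deactivating a leaf removes its incoming events
  state$active[2] <- FALSE
  ev2 <- eligible_dispersal_events(state, L, W, a = 10)
  expect_true(all(ev2$to != 2))
  # a consumer becomes eligible once one of its prey is present
  cons <- setdiff(seq_len(W$n_s), W$basal)[1]
  pr <- which(dyn$prey[, cons])[1]
  state$active[2] <- TRUE
  state$present[3, pr] <- TRUE
  state$biomass[3, pr] <- 1
  ev3 <- eligible_dispersal_events(state, L, W, a = 10)
  expect_true(any(ev3$species == cons & ev3$to == 3))
  # rates below the cutoff drop events entirely
  ev4 <- eligible_dispersal_events(state, L, W, a = 0.01)
  expect_equal(nrow(ev4), 0)
})

test_that("first-reaction winners follow competing-exponential statistics", {
  st <- star_setup(n_s = 5)
  L <- st$L
  S <- always_active_schedule(L, years = 100)
  state <- full_state(L, st$comm$dyn)
  # single candidate: waiting time is Exp(rate)
  ev1 <- data.frame(species = 1L, from = 1L, to = 2L, rate = 3)
  set.seed(1)
  wt <- replicate(4000, first_reaction_step(state, S, ev1, horizon = 1e9)$time)
  expect_gt(suppressWarnings(stats::ks.test(wt, stats::pexp, rate = 3))$p.value,
            0.01)
  # two candidates at rates (1, 3): winner frequencies (0.25, 0.75)
  ev2 <- data.frame(species = 1:2, from = 1L, to = 2L, rate = c(1, 3))
  set.seed(2)
  win <- replicate(4000,
    first_reaction_step(state, S, ev2, horizon = 1e9)$event$species)
  expect_lt(abs(mean(win == 2) - 0.75), 0.025)
  # nothing pending: the horizon ends the run
  ev0 <- ev1[0, ]
  out <- first_reaction_step(state, S, ev0, horizon = 100)
  expect_equal(out$time, 100)
  expect_equal(out$event$kind, "end")
})

test_that("events update the state per the model's rules", {
  st <- star_setup(n_leaves = 2, n_s = 8, seed = 4)
  dyn <- st$comm$dyn; L <- st$L
  state <- full_state(L, dyn)
  b <- dyn$basal[1]
  # basal arrival at an empty site equilibrates at r/lam
  s1 <- apply_event(state, list(kind = "dispersal", species = b, from = 1L,
                                to = 2L, time = 0.1), dyn)
  expect_true(s1$present[2, b])
  expect_equal(s1$biomass[2, b], dyn$r[b] / dyn$lam, tolerance = 1e-9)
  # the source is untouched, the regional pool intact
  expect_equal(s1$present[1, ], state$present[1, ])
  # deactivation zeroes the site
  s2 <- apply_event(s1, list(kind = "deactivate", site = 2L, time = 0.2), dyn)
  expect_false(any(s2$present[2, ]))
  expect_equal(sum(s2$biomass[2, ]), 0)
  expect_equal(s2$present[3, ], s1$present[3, ])
  expect_error(apply_event(s2, list(kind = "deactivate", site = L$mainland,
                                    time = 0.3), dyn), "mainland")
})

test_that("invasions recompute equilibria with cascades (oracle check)", {
  comm <- test_community(n_s = 12, temperature = 0.7, lam = 0.4, seed = 6)
  dyn <- comm$dyn
  set.seed(3)
  n_checked <- 0
  for (k in 1:40) {
    base <- cascade_oracle(dyn, sort(sample(12, 6)))$survivors
    if (!length(base)) next
    s <- metacomdyn:::resample(setdiff(1:12, base))
    if (!length(s)) next
    res <- metacomdyn:::invade_site(dyn, seq_len(12) %in% base, s)
    orc <- cascade_oracle(dyn, c(base, s))
    # oracle cannot arbitrate which of {invader, residents} dies in a
    # failed invasion; compare the full post-event composition
    expect_equal(which(res$present), orc$survivors)
    expect_equal(res$biomass[res$present], orc$biomass, tolerance = 1e-10)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 10)
})

test_that("a = 0 leaves every non-mainland site empty forever", {
  st <- star_setup(n_leaves = 3, n_s = 6, seed = 2)
  S <- sample_activation_schedule(st$L, A = 0.3, years = 3, seed = 5)
  traj <- simulate_run(st$L, S, st$comm$web, st$comm$dyn, a = 0, seed = 1)
  expect_true(all(traj$richness[, -1] == 0))
  expect_equal(sum(traj$events$kind == "dispersal"), 0)
  expect_equal(summarize_run(traj)$P_alpha, 0)
  expect_equal(summarize_run(traj)$P_gamma, 0)
})

test_that("trajectories respect the schedule and the horizon", {
  st <- star_setup(n_leaves = 4, n_s = 8, seed = 3)
  S <- sample_activation_schedule(st$L, A = 0.4, years = 3, seed = 9)
  traj <- simulate_run(st$L, S, st$comm$web, st$comm$dyn, a = 50, seed = 2)
  ev <- traj$events
  expect_true(all(ev$time >= 0 & ev$time <= 3))
  # deactivations occur exactly at merged interval endpoints
  for (p in 2:5) {
    ends <- S$intervals[[p]][, "end"]
    deact <- ev$time[ev$kind == "deactivate" & ev$from == p]
    expect_true(all(deact %in% ends[ends <= 3]))
  }
  # snapshot intervals partition [0, horizon]
  expect_equal(traj$intervals$t0[1], 0)
  expect_equal(traj$intervals$t1[nrow(traj$intervals)], 3)
  expect_equal(traj$intervals$t0[-1],
               traj$intervals$t1[-nrow(traj$intervals)])
})

test_that("no snapshot ever contains a consumer without prey", {
  comm <- test_community(n_s = 12, temperature = 0.6, lam = 0.5, seed = 8)
  L <- generate_landscape(8, 16, 2, f = 5, x = 2, seed = 4)
  S <- sample_activation_schedule(L, A = 0.3, years = 3, seed = 6)
  traj <- simulate_run(L, S, comm$web, comm$dyn, a = 100, seed = 11)
  dyn <- comm$dyn
  states <- replay_presence(traj)
  for (st in states[unique(round(seq(1, length(states), length.out = 60)))]) {
    for (p in seq_len(nrow(st))) {
      cons <- setdiff(which(st[p, ]), dyn$basal)
      for (j in cons) expect_true(any(dyn$prey[st[p, ], j]))
    }
  }
  # mainland holds the full pool at all times
  expect_true(all(traj$richness[, traj$mainland] == traj$n_s))
})

test_that("stored biomasses equal freshly solved site equilibria", {
  comm <- test_community(n_s = 10, temperature = 0.3, lam = 0.8, seed = 9)
  L <- generate_landscape(6, 12, 2, f = 5, x = 2, seed = 7)
  S <- sample_activation_schedule(L, A = 0.2, years = 2, seed = 8)
  traj <- simulate_run(L, S, comm$web, comm$dyn, a = 60, seed = 3)
  states <- replay_presence(traj)
  ev_t <- traj$events$time
  # probe only the last event at each instant, so simultaneous cascade
  # entries are fully applied in the replayed state
  last_at_t <- which(c(diff(ev_t) > 0, TRUE))
  probe <- last_at_t[unique(round(seq(1, length(last_at_t), length.out = 20)))]
  for (i in probe) {
    st <- states[[i]]
    # the snapshot interval that starts when this event fires
    row <- max(which(traj$intervals$t0 <= ev_t[i]))
    for (p in setdiff(seq_len(traj$n_p), traj$mainland)) {
      pres <- which(st[p, ])
      if (!length(pres)) next
      eq <- local_equilibrium(comm$dyn, pres)
      expect_equal(sum(eq$biomass), traj$biomass[row, p], tolerance = 1e-8)
      expect_equal(eq$survivors, pres)
    }
  }
})

test_that("trajectories and equilibria export to plain-text formats", {
  st <- star_setup(n_leaves = 2, n_s = 6, seed = 5)
  S <- sample_activation_schedule(st$L, A = 0.2, years = 2, seed = 5)
  traj <- simulate_run(st$L, S, st$comm$web, st$comm$dyn, a = 30, seed = 5)
  stem <- tempfile()
  write_trajectory(traj, stem)
  ev <- utils::read.csv(paste0(stem, "_events.csv"))
  expect_equal(nrow(ev), nrow(traj$events))
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"))
  expect_equal(meta$a, 30)
  expect_equal(meta$n_s, 6)
  eq <- local_equilibrium(st$comm$dyn, seq_len(6))
  f <- tempfile(fileext = ".json")
  write_equilibrium(eq, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$survivors, eq$survivors)
  expect_equal(back$biomass, unname(eq$biomass), tolerance = 1e-12)
})

test_that("fast dispersal keeps an active leaf occupied almost always", {
  # one basal species reachable at rate 1e4 / 0.2 = 5e4 per year
  comm <- test_community(n_s = 5, temperature = 0.05, lam = 1, seed = 12)
  L <- generate_star_landscape(1, 0.2)
  frac <- vapply(1:10, function(s) {
    S <- sample_activation_schedule(L, A = 0, years = 2, seed = 100 + s)
    traj <- simulate_run(L, S, comm$web, comm$dyn, a = 1e4, seed = s)
    wid <- traj$intervals$t1 - traj$intervals$t0
    act <- traj$active[, 2] & wid > 0
    sum(wid[act & traj$richness[, 2] > 0]) / sum(wid[act])
  }, numeric(1))
  expect_gt(mean(frac), 0.95)
})

test_that("doubling dispersal ability halves the mean first-arrival time", {
  comm <- test_community(n_s = 4, temperature = 0.05, lam = 1, seed = 13)
  L <- generate_star_landscape(1, 0.25)
  S <- always_active_schedule(L, years = 50)
  mean_first <- function(a, seeds) {
    mean(vapply(seeds, function(s) {
      traj <- simulate_run(L, S, comm$web, comm$dyn, a = a, seed = s)
      min(traj$events$time[traj$events$kind == "dispersal"])
    }, numeric(1)))
  }
  # n_b basal candidates race at rate a/d each; time scales as 1/a
  ratio <- mean_first(2, 1:300) / mean_first(4, 301:600)
  expect_equal(ratio, 2, tolerance = 0.3)
})
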