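mini_state <- function(present, active, biomass = NULL, mainland = 1L) {
  if (is.null(biomass)) biomass <- present * 1.0
  metacommunity_state(present, biomass, active, mainland)
}

test_that("instantaneous persistence does the set arithmetic", {
  # mainland (site 1) + two sites holding disjoint halves of a 10-species pool
  pres <- rbind(rep(TRUE, 10),
                c(rep(TRUE, 5), rep(FALSE, 5)),
                c(rep(FALSE, 5), rep(TRUE, 5)))
  st <- mini_state(pres, active = c(TRUE, TRUE, TRUE))
  expect_equal(instantaneous_persistence(st, 10, "alpha"), 0.5)
  expect_equal(instantaneous_persistence(st, 10, "gamma"), 1.0)
  # all active sites holding the full pool
  st2 <- mini_state(rbind(rep(TRUE, 10), rep(TRUE, 10)), c(TRUE, TRUE))
  expect_equal(instantaneous_persistence(st2, 10, "alpha"), 1)
  expect_equal(instantaneous_persistence(st2, 10, "gamma"), 1)
  # no active non-mainland site: alpha undefined
  st3 <- mini_state(pres, active = c(TRUE, FALSE, FALSE))
  expect_true(is.na(instantaneous_persistence(st3, 10, "alpha")))
  # random occupancies against a row-mean / union oracle
  set.seed(4)
  for (k in 1:20) {
    p <- matrix(stats::runif(40) < 0.4, 4, 10)
    p[1, ] <- TRUE
    act <- c(TRUE, stats::runif(3) < 0.7)
    p[!act, ] <- FALSE
    st <- mini_state(p, act)
    if (any(act[-1]))
      expect_equal(instantaneous_persistence(st, 10, "alpha"),
                   mean(rowSums(p[-1, , drop = FALSE][act[-1], , drop = FALSE]) / 10))
    expect_equal(instantaneous_persistence(st, 10, "gamma"),
                 sum(colSums(p[-1, , drop = FALSE]) > 0) / 10)
  }
})

test_that("instantaneous biomass sums and CVs per definition", {
  biom <- rbind(c(5, 5), c(1, 1), c(2, 1), c(1, 1))
  pres <- biom > 0
  st <- mini_state(pres, active = rep(TRUE, 4), biomass = biom)
  expect_equal(instantaneous_biomass(st, "gamma"), 7)
  # totals (2, 3, 2): population SD / mean
  tot <- c(2, 3, 2)
  expect_equal(instantaneous_biomass(st, "beta"),
               sqrt(mean((tot - mean(tot))^2)) / mean(tot))
  # equal totals give CV 0; totals (1, 3) give 0.5
  st2 <- mini_state(matrix(TRUE, 3, 1), rep(TRUE, 3),
                    biomass = matrix(c(9, 2, 2), 3, 1))
  expect_equal(instantaneous_biomass(st2, "beta"), 0)
  st3 <- mini_state(matrix(TRUE, 3, 1), rep(TRUE, 3),
                    biomass = matrix(c(9, 1, 3), 3, 1))
  expect_equal(instantaneous_biomass(st3, "beta"), 0.5)
  # fewer than two active sites: CV undefined
  st4 <- mini_state(matrix(TRUE, 2, 1), c(TRUE, TRUE),
                    biomass = matrix(1, 2, 1))
  expect_true(is.na(instantaneous_biomass(st4, "beta")))
})

test_that("the continuous power mean reproduces closed forms", {
  expect_equal(power_mean(c(2, 4), c(3, 3), 1), 3)
  expect_equal(power_mean(c(2, 4), c(3, 3), -1), 8 / 3)
  expect_equal(power_mean(c(2, 4), c(3, 3), 0), sqrt(8))   # geometric
  for (p in c(-2, -1, 0, 0.5, 1, 2))
    expect_equal(power_mean(c(7, 7, 7), c(1, 2, 3), p), 7)
  # missing intervals are excluded from the measure
  expect_equal(power_mean(c(2, NA, 4), c(3, 10, 3), 1), 3)
  expect_true(is.na(power_mean(c(NA, NA), c(1, 1))))
})

test_that("summarized runs match an interval-weighting oracle", {
  # hand-built 3-interval trajectory: mainland site 1 + 2 sites, 4 species
  traj <- structure(list(
    intervals = data.frame(t0 = c(0, 1, 2), t1 = c(1, 2, 3)),
    richness = rbind(c(4, 2, 0), c(4, 4, 2), c(4, 0, 0)),
    biomass = rbind(c(9, 2, 0), c(9, 4, 2), c(9, 0, 0)),
    active = rbind(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, TRUE),
                   c(TRUE, FALSE, FALSE)),
    union_count = c(2, 4, 0),
    events = data.frame(), horizon = 3, n_s = 4, n_p = 3, mainland = 1L,
    a = 1), class = "metacom_trajectory")
  rs <- summarize_run(traj)
  # alpha: interval means 2/4/1, (4+2)/2/4, NA (no active site)
  expect_equal(rs$P_alpha, (0.5 + 0.75) / 2)
  expect_equal(rs$P_gamma, (0.5 + 1 + 0) / 3)
  expect_equal(rs$P_beta, rs$P_gamma / rs$P_alpha)
  expect_equal(rs$B_gamma, (2 + 6 + 0) / 3)
  # CV defined only on the middle interval: totals (4, 2)
  expect_equal(rs$B_beta, sqrt(mean((c(4, 2) - 3)^2)) / 3)
  # counting empty intervals as zero changes the alpha measure
  rs0 <- summarize_run(traj, count_empty_as_zero = TRUE)
  expect_equal(rs0$P_alpha, (0.5 + 0.75 + 0) / 3)
})

test_that("beta persistence is the gamma/alpha ratio when defined", {
  comm <- test_community(n_s = 8, temperature = 0.2, lam = 1, seed = 21)
  L <- generate_landscape(6, 12, 2, f = 5, x = 2, seed = 21)
  S <- sample_activation_schedule(L, A = 0.25, years = 2, seed = 21)
  rs <- summarize_run(simulate_run(L, S, comm$web, comm$dyn, a = 40, seed = 1))
  if (!is.na(rs$P_beta))
    expect_equal(rs$P_beta * rs$P_alpha, rs$P_gamma, tolerance = 1e-12)
})

test_that("sensitivity is the finite difference of the printed formula", {
  expect_equal(sensitivity(0.8, 0.6), -0.4)
  expect_equal(sensitivity(0.3, 0.3), 0)
  expect_equal(sensitivity(1, 3, 0, 0.5), 4)
  set.seed(2)
  for (k in 1:20) {
    xl <- stats::runif(1); xh <- stats::runif(1)
    expect_equal(sign(sensitivity(xl, xh)), sign(xh - xl))
    expect_equal(sensitivity(xl, xh), 2 * (xh - xl), tolerance = 1e-12)
  }
  expect_error(sensitivity(1, 2, 0.5, 0.5), "exceed")
})

make_design <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(temperature = stats::runif(n, 0, 1.2),
             lam = stats::runif(n, 1 / 3, 1),
             ahat = stats::runif(n, log10(30), log10(3000)))
}

test_that("noiseless synthetic responses are recovered exactly", {
  d <- make_design(60)
  zT <- scale(d$temperature)[, 1]; zL <- scale(d$lam)[, 1]
  d$S <- 2 * zT - 1 * zL
  # a perfect fit makes lm's summary grumble, by design here
  et <- suppressWarnings(effect_sizes(d))
  est <- stats::setNames(et$coefficients$estimate, et$coefficients$term)
  expect_equal(unname(est["T"]), 2, tolerance = 1e-10)
  expect_equal(unname(est["lam"]), -1, tolerance = 1e-10)
  expect_lt(max(abs(est[setdiff(names(est), c("T", "lam", "(Intercept)"))])),
            1e-10)
  expect_equal(et$best_terms, "T+lam")
  expect_false(et$full_model_best)
})

test_that("AICc matches the hand formula on a fitted model", {
  d <- make_design(20, seed = 3)
  zT <- scale(d$temperature)[, 1]
  set.seed(4)
  d$S <- 1.5 * zT + stats::rnorm(20, 0, 0.3)
  et <- effect_sizes(d)
  fit <- stats::lm(d$S ~ zT)
  rss <- sum(stats::residuals(fit)^2)
  n <- 20; k <- 2
  aicc_oracle <- n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  expect_equal(et$aicc$aicc[et$aicc$terms == "T"], aicc_oracle,
               tolerance = 1e-9)
  expect_equal(nrow(et$aicc), 512)
})

test_that("standardization makes effect sizes scale- and order-invariant", {
  d <- make_design(80, seed = 5)
  zT <- scale(d$temperature)[, 1]; zA <- scale(d$ahat)[, 1]
  set.seed(6)
  d$S <- 0.8 * zT - 0.5 * zA + 0.3 * zT * zA + stats::rnorm(80, 0, 0.05)
  base <- effect_sizes(d)$coefficients$estimate
  # permuting rows changes nothing
  perm <- d[sample(80), ]
  expect_equal(effect_sizes(perm)$coefficients$estimate, base,
               tolerance = 1e-10)
  # rescaling a raw predictor changes nothing after z-scoring
  resc <- d; resc$temperature <- d$temperature * 37
  expect_equal(effect_sizes(resc)$coefficients$estimate, base,
               tolerance = 1e-10)
})

test_that("coefficients are recovered within tolerance under noise", {
  d <- make_design(300, seed = 7)
  zT <- scale(d$temperature)[, 1]; zL <- scale(d$lam)[, 1]
  zA <- scale(d$ahat)[, 1]
  set.seed(8)
  d$S <- 2 * zT - zL + 0.5 * zT * zA + stats::rnorm(300, 0, 0.1)
  est <- stats::setNames(effect_sizes(d)$coefficients$estimate,
                         effect_sizes(d)$coefficients$term)
  truth <- c("T" = 2, "lam" = -1, "ahat" = 0, "T:lam" = 0, "T:ahat" = 0.5,
             "lam:ahat" = 0, "T^2" = 0, "lam^2" = 0, "ahat^2" = 0)
  expect_lt(max(abs(est[names(truth)] - truth)), 0.05)
})

test_that("degenerate designs are rejected with useful errors", {
  d <- make_design(30, seed = 9)
  d$S <- stats::rnorm(30)
  d$lam <- 0.5                     # constant predictor
  expect_error(effect_sizes(d), "does not vary")
  d2 <- make_design(8, seed = 10); d2$S <- stats::rnorm(8)
  expect_error(effect_sizes(d2), "at least 11 rows")
})
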