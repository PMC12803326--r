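test_that("a fully quiescent system produces no events", {
  tr <- ssa_simulate(quiescent_params(), system_state("A", "B", 0, 0),
                     t_end = 10, seed = 1)
  expect_equal(nrow(tr), 1L)  # just the initial state
  expect_equal(attr(tr, "t_end"), 10)
})

test_that("trajectories are reproducible byte-for-byte under the seed", {
  pa <- default_parameters(allostery_ratios(2, 0.5), beta = 3)
  tr1 <- ssa_simulate(pa, t_end = 20, seed = 99)
  tr2 <- ssa_simulate(pa, t_end = 20, seed = 99)
  expect_identical(tr1, tr2)
  tr3 <- ssa_simulate(pa, t_end = 20, seed = 100)
  expect_false(identical(tr1$time, tr3$time))
})

test_that("trajectory structure is a valid jump chain", {
  pa <- default_parameters(beta = 4)
  tr <- ssa_simulate(pa, t_end = 50, seed = 5)
  expect_true(all(diff(tr$time) > 0))
  expect_true(all(tr$s >= 0) && all(tr$p >= 0))
  # consecutive states differ by exactly one channel's delta
  chans <- reaction_channels(pa)
  deltas <- lapply(chans, `[[`, "delta")
  a <- match(tr$sigmaA, enzyme_states)
  b <- match(tr$sigmaB, protein_states)
  for (i in seq_len(nrow(tr) - 1L)) {
    hit <- FALSE
    for (d in deltas) {
      ok_a <- if (is.na(d$a)) a[i + 1] == a[i] else a[i + 1] == d$a
      ok_b <- if (is.na(d$b)) b[i + 1] == b[i] else b[i + 1] == d$b
      if (ok_a && ok_b && tr$s[i + 1] - tr$s[i] == d$ds &&
          tr$p[i + 1] - tr$p[i] == d$dp) { hit <- TRUE; break }
    }
    if (!hit) break
  }
  expect_true(hit)
})

test_that("pure production is a Poisson process", {
  pa <- quiescent_params()
  pa$beta <- 1
  pa$gammaS <- 0
  validate_parameters(pa)
  T_end <- 5
  counts <- vapply(1:2000, function(r) {
    nrow(ssa_simulate(pa, t_end = T_end, seed = 1000 + r)) - 1L
  }, integer(1))
  # mean event count within 3 standard errors of beta * T
  se <- sqrt(T_end / length(counts))
  expect_lt(abs(mean(counts) - T_end), 3 * se)
  # and a Poisson process is not over/under-dispersed
  expect_lt(abs(var(counts) / mean(counts) - 1), 0.15)
})

test_that("stationary s-histogram of the birth-death submodel is Poisson", {
  pa <- decoupled_params(beta = 2)
  emp <- ssa_sample_at(pa, t_obs = 30, n = 20000, seed = 7)
  s <- emp$finals$s
  # Pearson chi-square against Poisson(2), pooling the tail so expected
  # counts stay above 5
  kmax <- max(s)
  pk <- stats::dpois(0:kmax, 2)
  pk <- c(pk[1:8], 1 - sum(pk[1:8]))
  obs <- c(tabulate(factor(pmin(s, 8), levels = 0:8), nbins = 9))
  expd <- length(s) * pk
  X2 <- sum((obs - expd)^2 / expd)
  expect_lt(X2, stats::qchisq(0.999, df = length(pk) - 1))
})

test_that("a single-segment schedule reproduces plain simulation exactly", {
  pa <- default_parameters(beta = 2)
  tr1 <- ssa_simulate(pa, t_end = 30, seed = 12)
  tr2 <- ssa_schedule_simulate(pa, beta_schedule(0, 2), t_end = 30, seed = 12)
  expect_identical(tr1$time, tr2$time)
  expect_identical(tr1$s, tr2$s)
})

test_that("with beta = 0 throughout, copy numbers stay at zero", {
  pa <- default_parameters(beta = 0)
  sch <- beta_schedule(c(0, 10), c(0, 0))
  tr <- ssa_schedule_simulate(pa, sch, t_end = 50, seed = 3)
  expect_true(all(tr$s == 0))
  expect_true(all(tr$p == 0))
  expect_true(all(tr$sigmaA %in% c("A", "A*")))
  expect_true(all(tr$sigmaB == "B"))
})

test_that("sampling at t = 0 returns the initial cell; n = 1 a unit count", {
  pa <- default_parameters(beta = 1)
  e0 <- ssa_sample_at(pa, system_state("A*", "BP", 0, 0), t_obs = 0,
                      n = 500, seed = 2)
  expect_equal(e0$counts["A*", "BP"], 500L)
  e1 <- ssa_sample_at(pa, t_obs = 1, n = 1, seed = 2)
  expect_equal(sum(e1$counts), 1L)
})

test_that("empirical occupancy of a long trajectory matches the steady state", {
  pa <- default_parameters(beta = 1)
  ss <- steady_state(build_generator(pa, state_space(16, 8)))
  q <- marginal_ab(ss)
  tr <- ssa_simulate(pa, t_end = 4000, seed = 17)
  occ <- trajectory_occupancy(tr, burn_in = 100)
  # time-averaged occupancies carry autocorrelation, so allow a broad band
  expect_lt(max(abs(occ - q)), 0.02)
})

test_that("ensemble means under a square wave track the master equation", {
  pa <- default_parameters(beta = 16)
  sch <- square_wave_schedule(0, 16, period = 20, duty = 0.5, cycles = 1)
  sp <- auto_truncate(pa, tol = 1e-8)
  p0 <- steady_state(build_generator(default_parameters(beta = 0), sp))
  t_grid <- seq(2, 20, by = 2)
  dists <- evolve(pa, sch, p0, t_grid)
  cme_s <- vapply(dists, function(d) unname(state_moments(d)["mean_s"]),
                  numeric(1))
  ens <- ssa_ensemble_moments(pa, sch, t_grid = t_grid, n = 3000, seed = 31)
  z <- abs(ens$mean_s - cme_s) / pmax(ens$se_s, 1e-9)
  expect_lt(max(z), 3.5)
})
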