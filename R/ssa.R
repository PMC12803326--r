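#' Exact Gillespie simulation of the signaling network
#'
#' Simulates one trajectory of the reaction network by the stochastic
#' simulation algorithm (direct method): exponential waiting times with the
#' total propensity, channel chosen with probability proportional to its
#' propensity.  The simulation is exact for the underlying Markov jump
#' process and, unlike the master-equation solvers, involves no state-space
#' truncation.  Trajectories are byte-for-byte reproducible given the seed.
#'
#' @param params An `alo_params` object.
#' @param init Initial [system_state()] (default: unbound enzyme and
#'   protein, no substrate or product).
#' @param t_end Final time (> 0).
#' @param seed Integer seed of the trajectory's own random-number generator.
#' @param max_events Safety cap on the number of reaction events.
#' @return An object of class `alo_trajectory`: a data.frame with columns
#'   `time`, `sigmaA`, `sigmaB`, `s`, `p` (the first row is the initial
#'   state at time 0; each later row is the state just after an event);
#'   attributes `t_end` and `seed`.  If all propensities vanish before
#'   `t_end`, the trajectory simply ends with a quiescent final segment.
#' @examples
#' tr <- ssa_simulate(default_parameters(beta = 2), t_end = 10, seed = 1)
#' tail(tr)
#' @export
ssa_simulate <- function(params, init = system_state(), t_end, seed,
                         max_events = 5e7) {
  validate_parameters(params)
  if (!inherits(init, "alo_state")) stop("invalid 'init'", call. = FALSE)
  if (t_end <= 0) stop("'t_end' must be > 0", call. = FALSE)
  m <- ssa_trajectory_cpp(.param_vector(params),
                          c(init$a, init$b, init$s, init$p),
                          0, params$beta, t_end, as.numeric(seed),
                          max_events)
  .trajectory_df(m, init, t_end, seed)
}

#' Gillespie simulation under a piecewise-constant production schedule
#'
#' As [ssa_simulate()], but the substrate production rate follows a
#' [beta_schedule()].  Waiting-time draws never cross a segment boundary:
#' the clock is re-drawn at each boundary, which is exact for
#' piecewise-constant rates by the memoryless property.
#'
#' @param params_base An `alo_params` object; its `beta` is overridden by
#'   the schedule.
#' @param schedule An [beta_schedule()].
#' @param init Initial [system_state()].
#' @param t_end Final time (> first segment start).
#' @param seed Integer seed.
#' @param max_events Safety cap on the number of reaction events.
#' @return An `alo_trajectory` (see [ssa_simulate()]).
#' @export
ssa_schedule_simulate <- function(params_base, schedule,
                                  init = system_state(), t_end, seed,
                                  max_events = 5e7) {
  validate_parameters(params_base)
  if (!inherits(schedule, "alo_schedule"))
    stop("invalid 'schedule'", call. = FALSE)
  if (t_end <= schedule$t_start[1L])
    stop("'t_end' must exceed the first segment start", call. = FALSE)
  m <- ssa_trajectory_cpp(.param_vector(params_base),
                          c(init$a, init$b, init$s, init$p),
                          schedule$t_start, schedule$beta, t_end,
                          as.numeric(seed), max_events)
  .trajectory_df(m, init, t_end, seed, t0 = schedule$t_start[1L])
}

.trajectory_df <- function(m, init, t_end, seed, t0 = 0) {
  df <- data.frame(
    time = c(t0, m[, 1]),
    sigmaA = enzyme_states[c(init$a, m[, 2])],
    sigmaB = protein_states[c(init$b, m[, 3])],
    s = as.integer(c(init$s, m[, 4])),
    p = as.integer(c(init$p, m[, 5])),
    stringsAsFactors = FALSE
  )
  attr(df, "t_end") <- t_end
  attr(df, "seed") <- seed
  class(df) <- c("alo_trajectory", "data.frame")
  df
}

#' Export a trajectory to CSV
#'
#' @param traj An `alo_trajectory`.
#' @param path Output file path.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Sample independent replicates of the network at a fixed time
#'
#' Runs `n` independent trajectories (replicate `r` uses seed
#' `seed + r`), records each at time `t_obs`, and tallies the
#' `(sigmaA, sigmaB)` cell counts.  This is the synthetic-data generator
#' used as the independent oracle for the transient and stationary
#' master-equation solvers.
#'
#' @param params An `alo_params` object.
#' @param init Initial [system_state()].
#' @param t_obs Observation time (>= 0).
#' @param n Number of replicates (>= 1).
#' @param seed Base seed.
#' @param schedule Optional [beta_schedule()]; by default constant
#'   `params$beta`.
#' @return An object of class `alo_empirical`: a list with the 4 x 2
#'   integer `counts` table over (sigmaA, sigmaB), the matching `freq` and
#'   binomial standard-error `se` tables, `n`, and the full data.frame
#'   `finals` of per-replicate final states.
#' @examples
#' ej <- ssa_sample_at(default_parameters(beta = 1), t_obs = 5,
#'                     n = 1000, seed = 7)
#' ej$freq
#' @export
ssa_sample_at <- function(params, init = system_state(), t_obs, n, seed,
                          schedule = NULL) {
  validate_parameters(params)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be >= 1", call. = FALSE)
  if (t_obs < 0) stop("'t_obs' must be >= 0", call. = FALSE)
  if (is.null(schedule)) schedule <- beta_schedule(0, params$beta)
  if (t_obs < schedule$t_start[1L])
    stop("'t_obs' before the first segment start", call. = FALSE)
  fin <- ssa_finals_cpp(.param_vector(params),
                        c(init$a, init$b, init$s, init$p),
                        schedule$t_start, schedule$beta,
                        t_obs, n, as.numeric(seed))
  counts <- matrix(0L, 4, 2, dimnames = list(enzyme_states, protein_states))
  tab <- table(factor(fin[, 1], levels = 1:4),
               factor(fin[, 2], levels = 1:2))
  counts[] <- as.integer(tab)
  freq <- counts / n
  structure(list(
    counts = counts,
    freq = freq,
    se = sqrt(freq * (1 - freq) / n),
    n = n,
    finals = data.frame(sigmaA = enzyme_states[fin[, 1]],
                        sigmaB = protein_states[fin[, 2]],
                        s = fin[, 3], p = fin[, 4],
                        stringsAsFactors = FALSE)
  ), class = "alo_empirical")
}

#' @export
print.alo_empirical <- function(x, ...) {
  cat(sprintf("Empirical (sigmaA, sigmaB) joint from %d replicates:\n", x$n))
  print(round(x$freq, 4))
  invisible(x)
}

#' Ensemble moments and state occupancies on a time grid
#'
#' Runs `n` independent replicates under a production schedule (replicate
#' `r` uses seed `seed + r`) and records, at every grid time, the running
#' sums needed for the ensemble means of S and P and the empirical
#' `(sigmaA, sigmaB)` occupancies.  Used to cross-validate [evolve()] on
#' pulsed-input protocols.
#'
#' @param params_base An `alo_params` object.
#' @param schedule An [beta_schedule()].
#' @param init Initial [system_state()].
#' @param t_grid Increasing observation times.
#' @param n Number of replicates.
#' @param seed Base seed.
#' @return A data.frame with columns `time`, `mean_s`, `mean_p`, `se_s`,
#'   `se_p`, and `ab1`..`ab8` (empirical frequencies of the eight
#'   (sigmaA, sigmaB) cells, enzyme state varying fastest); attribute `n`.
#' @export
ssa_ensemble_moments <- function(params_base, schedule,
                                 init = system_state(), t_grid, n, seed) {
  validate_parameters(params_base)
  if (!inherits(schedule, "alo_schedule"))
    stop("invalid 'schedule'", call. = FALSE)
  if (any(diff(t_grid) <= 0) || t_grid[1L] < schedule$t_start[1L])
    stop("'t_grid' must be increasing and start within the schedule",
         call. = FALSE)
  res <- ssa_grid_cpp(.param_vector(params_base),
                      c(init$a, init$b, init$s, init$p),
                      schedule$t_start, schedule$beta,
                      t_grid, as.integer(n), as.numeric(seed))
  mean_s <- res$sum_s / n
  mean_p <- res$sum_p / n
  var_s <- pmax(res$sum_s2 / n - mean_s^2, 0)
  var_p <- pmax(res$sum_p2 / n - mean_p^2, 0)
  ab <- t(res$ab_counts) / n
  colnames(ab) <- paste0("ab", 1:8)
  out <- data.frame(time = t_grid, mean_s = mean_s, mean_p = mean_p,
                    se_s = sqrt(var_s / n), se_p = sqrt(var_p / n))
  out <- cbind(out, as.data.frame(ab))
  attr(out, "n") <- n
  out
}

#' Time-averaged state occupancies along one long trajectory
#'
#' Computes the fraction of time a trajectory spends in each
#' `(sigmaA, sigmaB)` cell after discarding a burn-in, the ergodic estimate
#' of the stationary joint used to cross-check [steady_state()].
#'
#' @param traj An `alo_trajectory`.
#' @param burn_in Time discarded from the start (default `100`, i.e.
#'   `100 / gammaS`).
#' @return A 4 x 2 matrix of occupancy fractions.
#' @export
trajectory_occupancy <- function(traj, burn_in = 100) {
  t_end <- attr(traj, "t_end")
  if (burn_in >= t_end) stop("burn-in exceeds trajectory length", call. = FALSE)
  tt <- c(traj$time, t_end)
  dur <- pmin(tt[-1L], t_end) - pmax(tt[-length(tt)], burn_in)
  keep <- dur > 0
  a <- match(traj$sigmaA, enzyme_states)
  b <- match(traj$sigmaB, protein_states)
  cell <- a + 4L * (b - 1L)
  occ <- vapply(1:8, function(k) sum(dur[keep & cell == k]), numeric(1))
  occ <- occ / sum(occ)
  matrix(occ, 4, 2, dimnames = list(enzyme_states, protein_states))
}
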