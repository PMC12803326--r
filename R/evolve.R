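#' Piecewise-constant substrate production schedule
#'
#' Represents a time-dependent substrate production rate `beta(t)` as an
#' ordered list of segments: from `t_start[k]` until `t_start[k + 1]` (or
#' forever for the last segment) the rate is `beta[k]`.
#'
#' @param t_start Numeric vector of strictly increasing segment start times.
#' @param beta Numeric vector of per-segment production rates (>= 0), same
#'   length as `t_start`.
#' @return An object of class `alo_schedule`: a data.frame with columns
#'   `t_start` and `beta`.
#' @examples
#' beta_schedule(c(0, 10, 20), c(0, 16, 0))
#' @export
beta_schedule <- function(t_start, beta) {
  if (length(t_start) == 0L) stop("schedule is empty", call. = FALSE)
  if (length(t_start) != length(beta))
    stop("'t_start' and 'beta' must have the same length", call. = FALSE)
  if (any(diff(t_start) <= 0))
    stop("segment start times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(beta)) || any(beta < 0))
    stop("beta values must be finite and >= 0", call. = FALSE)
  structure(data.frame(t_start = as.numeric(t_start),
                       beta = as.numeric(beta)),
            class = c("alo_schedule", "data.frame"))
}

#' Square-wave substrate production schedule
#'
#' Builds the pulsed-input protocol: each cycle of length `period` starts
#' with a low phase at `beta_low` of length `(1 - duty) * period`, followed
#' by a high phase at `beta_high` of length `duty * period`.  With the
#' default `beta_low = 0` the input periodically switches between zero and a
#' high value.
#'
#' @param beta_low,beta_high Low- and high-phase production rates
#'   (`beta_high >= beta_low >= 0`).
#' @param period Cycle length (> 0), in units of `1 / gammaS`.
#' @param duty Fraction of the period spent at `beta_high`, in (0, 1).
#' @param cycles Number of cycles (>= 1).
#' @param t0 Start time of the first cycle.
#' @return An `alo_schedule`.
#' @export
square_wave_schedule <- function(beta_low = 0, beta_high = 16, period = 20,
                                 duty = 0.5, cycles = 3, t0 = 0) {
  if (beta_low < 0 || beta_high < beta_low)
    stop("need beta_high >= beta_low >= 0", call. = FALSE)
  if (period <= 0) stop("'period' must be > 0", call. = FALSE)
  if (duty <= 0 || duty >= 1) stop("'duty' must be in (0, 1)", call. = FALSE)
  cycles <- as.integer(cycles)
  if (is.na(cycles) || cycles < 1L) stop("'cycles' must be >= 1", call. = FALSE)
  starts <- as.vector(vapply(seq_len(cycles) - 1L, function(k)
    t0 + k * period + c(0, (1 - duty) * period), numeric(2)))
  beta_schedule(starts, rep(c(beta_low, beta_high), cycles))
}

#' Production rate at given times under a schedule
#'
#' @param schedule An `alo_schedule`.
#' @param t Numeric vector of times (>= first segment start).
#' @return Numeric vector of `beta(t)`.
#' @export
schedule_beta_at <- function(schedule, t) {
  idx <- findInterval(t, schedule$t_start)
  if (any(idx < 1L))
    stop("times before the first schedule segment", call. = FALSE)
  schedule$beta[idx]
}

#' Time evolution of the master equation
#'
#' Propagates an initial distribution through the chemical master equation
#' under a piecewise-constant production schedule.  Within each constant-beta
#' segment the propagation is the action of the matrix exponential
#' `exp(Q t)`, computed by uniformization: the Poisson-weighted power series
#' in the uniformized transition matrix, with the series tail truncated below
#' `expm_tol` and long steps split so the Poisson mean per step stays
#' moderate.  Probability conservation is monitored: the un-renormalized mass
#' defect at every grid time must stay below 1e-8.
#'
#' @param params_base An `alo_params` object; its `beta` is overridden
#'   segment by segment by the schedule.
#' @param schedule An [beta_schedule()] (or [square_wave_schedule()]).
#' @param p0 Initial `alo_distribution`, taken at the first segment's start
#'   time.
#' @param t_grid Strictly increasing times (all >= the first segment start)
#'   at which to return the solution.
#' @param expm_tol Tail tolerance of the uniformization series per step.
#' @return A list of `alo_distribution`s, one per grid time; attribute
#'   `max_drift` records the largest observed mass defect before
#'   renormalization.
#' @examples
#' sp <- state_space(10, 6)
#' gen0 <- build_generator(default_parameters(beta = 0), sp)
#' p0 <- steady_state(gen0)
#' out <- evolve(default_parameters(beta = 4),
#'               beta_schedule(0, 4), p0, t_grid = c(1, 2, 5))
#' @export
evolve <- function(params_base, schedule, p0, t_grid, expm_tol = 1e-12) {
  validate_parameters(params_base)
  if (!inherits(schedule, "alo_schedule")) stop("invalid schedule", call. = FALSE)
  if (!inherits(p0, "alo_distribution")) stop("invalid p0", call. = FALSE)
  if (length(t_grid) == 0L || any(diff(t_grid) <= 0))
    stop("'t_grid' must be non-empty and strictly increasing", call. = FALSE)
  t0 <- schedule$t_start[1L]
  if (t_grid[1L] < t0)
    stop("all grid times must be >= the first segment start", call. = FALSE)
  space <- p0$space

  gens <- new.env(parent = emptyenv())  # cache generators per beta value
  gen_for <- function(beta) {
    key <- format(beta, digits = 17)
    if (is.null(gens[[key]])) {
      pa <- params_base
      pa$beta <- beta
      gens[[key]] <- build_generator(pa, space)$Q
    }
    gens[[key]]
  }

  seg_end <- c(schedule$t_start[-1L], Inf)
  out <- vector("list", length(t_grid))
  max_drift <- 0
  p <- p0$p
  t_cur <- t0
  for (g in seq_along(t_grid)) {
    t_target <- t_grid[g]
    while (t_cur < t_target) {
      k <- findInterval(t_cur, schedule$t_start)
      t_next <- min(seg_end[k], t_target)
      p <- .expmv_uniform(gen_for(schedule$beta[k]), p, t_next - t_cur,
                          tol = expm_tol)
      t_cur <- t_next
    }
    drift <- abs(sum(p) - 1)
    if (drift >= 1e-8)
      stop(sprintf("probability mass drift %.3e >= 1e-8 at t = %g",
                   drift, t_target), call. = FALSE)
    max_drift <- max(max_drift, drift)
    if (min(p) < -1e-12)
      stop(sprintf("transient probability %.3e < -1e-12 at t = %g",
                   min(p), t_target), call. = FALSE)
    out[[g]] <- distribution(p, space, time = t_target)
  }
  attr(out, "max_drift") <- max_drift
  out
}

# Action of the matrix exponential exp(Q t) on v by uniformization.
# Splits t so the Poisson mean per step is at most 64 (avoiding dpois
# underflow), and truncates each step's Poisson series when the remaining
# tail mass drops below tol / steps.
.expmv_uniform <- function(Q, v, t, tol = 1e-12) {
  if (t <= 0) return(v)
  lam <- max(-Matrix::diag(Q))
  if (lam <= 0) return(v)
  m_total <- lam * t
  steps <- max(1L, ceiling(m_total / 64))
  m <- m_total / steps
  K <- stats::qpois(tol / (2 * steps), m, lower.tail = FALSE) + 1L
  w <- stats::dpois(0:K, m)
  P <- Q / lam
  Matrix::diag(P) <- Matrix::diag(P) + 1
  for (st in seq_len(steps)) {
    u <- v
    acc <- w[1L] * v
    for (k in seq_len(K)) {
      u <- as.numeric(P %*% u)
      acc <- acc + w[k + 1L] * u
    }
    v <- acc
  }
  v
}
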