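#' Default allosteric conditions for the sweep protocols
#'
#' The ratio combinations examined by the steady-state protocols: the silent
#' pair plus inhibiting/activating V-type and K-type modulation.
#'
#' @return A list of [allostery_ratios()] objects.
#' @export
default_xi_pairs <- function() {
  list(
    allostery_ratios(1, 1),
    allostery_ratios(1, 0.1),
    allostery_ratios(1, 10),
    allostery_ratios(0.1, 1),
    allostery_ratios(10, 1)
  )
}

#' Default log-spaced grid of substrate production rates
#'
#' @param log2_min,log2_max Range of `log2(beta / gammaS)`.
#' @param n Number of grid points.
#' @return Numeric vector of beta values.
#' @export
default_beta_grid <- function(log2_min = -4, log2_max = 6, n = 11) {
  2^seq(log2_min, log2_max, length.out = n)
}

# Steady-state summary row at one condition; on a truncation-cap failure the
# row is computed at the cap and flagged rather than dropped.
.steady_row <- function(xi, beta, tol, s_start, p_start, cap) {
  pa <- default_parameters(xi, beta)
  space <- tryCatch(
    auto_truncate(pa, tol = tol, s_start = s_start, p_start = p_start,
                  cap = cap),
    error = function(e) NULL)
  ok <- !is.null(space)
  if (!ok) {
    space <- state_space(cap, cap)
    ss <- steady_state(build_generator(pa, space))
  } else {
    ss <- attr(space, "steady_state")
  }
  info <- info_summary(ss)
  list(row = data.frame(
    beta = beta, xiK = xi$xiK, xiV = xi$xiV, t_or_steady = "steady",
    mi_ab_nats = info$mi_ab, mean_s = info$mean_s, mean_p = info$mean_p,
    boundary_mass = info$boundary_mass,
    s_max = space$s_max, p_max = space$p_max, truncation_ok = ok,
    stringsAsFactors = FALSE),
    bounds = c(space$s_max, space$p_max),
    dist = ss)
}

# 3-point parabolic refinement of a grid argmax on the log2(beta) axis.
.refine_argmax <- function(log2_beta, mi) {
  i <- which.max(mi)
  interior <- i > 1L && i < length(mi)
  if (!interior) return(list(beta_opt = 2^log2_beta[i], interior = FALSE))
  h <- log2_beta[i + 1L] - log2_beta[i]
  denom <- mi[i - 1L] - 2 * mi[i] + mi[i + 1L]
  shift <- if (denom < 0) 0.5 * h * (mi[i - 1L] - mi[i + 1L]) / denom else 0
  list(beta_opt = 2^(log2_beta[i] + shift), interior = TRUE)
}

#' Steady-state mutual information across substrate production rates
#'
#' For every combination of allosteric ratios and every beta on the grid:
#' choose a certified truncation ([auto_truncate()]), solve for the steady
#' state, and record the mutual information between the enzyme and
#' downstream states together with the mean substrate/product copy numbers
#' and the boundary mass.  Across all allosteric conditions the mutual
#' information depends non-monotonically on beta: communication is weak both
#' at low substrate flux (components rarely engaged) and at high flux
#' (upstream saturation), and is maximized at an intermediate flux whose
#' position depends on the allosteric ratios.
#'
#' @param betas Numeric vector of production rates (>= 0).
#' @param xi_pairs List of [allostery_ratios()].
#' @param tol Truncation tolerance for [auto_truncate()].
#' @param cap Truncation hard cap.
#' @return A data.frame with one row per (beta, xiK, xiV): columns `beta`,
#'   `xiK`, `xiV`, `t_or_steady`, `mi_ab_nats`, `mean_s`, `mean_p`,
#'   `boundary_mass`, `s_max`, `p_max`, `truncation_ok`.  Attribute
#'   `optima`: per xi pair, the grid argmax of MI refined by a 3-point
#'   parabola in log2(beta) (`beta_opt`, `mi_max`, `interior`).
#' @examples
#' \donttest{
#' sw <- run_beta_sweep(default_beta_grid(n = 7),
#'                      list(allostery_ratios(1, 1)))
#' attr(sw, "optima")
#' }
#' @export
run_beta_sweep <- function(betas = default_beta_grid(),
                           xi_pairs = default_xi_pairs(),
                           tol = 1e-8, cap = 256L) {
  if (!length(betas) || any(betas < 0))
    stop("'betas' must be a non-empty vector of rates >= 0", call. = FALSE)
  if (!length(xi_pairs)) stop("'xi_pairs' is empty", call. = FALSE)
  ord <- order(betas)
  rows <- list()
  opt <- list()
  for (xi in xi_pairs) {
    if (!inherits(xi, "alo_ratios")) xi <- do.call(allostery_ratios, as.list(xi))
    bounds <- c(8L, 8L)   # warm-start: bounds grow with beta along the sweep
    mi <- numeric(length(betas))
    for (k in ord) {
      res <- .steady_row(xi, betas[k], tol, bounds[1L], bounds[2L], cap)
      bounds <- res$bounds
      mi[k] <- res$row$mi_ab_nats
      rows[[length(rows) + 1L]] <- res$row
    }
    ref <- .refine_argmax(log2(betas[ord]), mi[ord])
    opt[[length(opt) + 1L]] <- data.frame(
      xiK = xi$xiK, xiV = xi$xiV, beta_opt = ref$beta_opt,
      mi_max = max(mi), interior = ref$interior)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "optima") <- do.call(rbind, opt)
  out
}

#' Steady-state behavior across one allosteric ratio
#'
#' Holds the substrate production rate and one allosteric ratio fixed (the
#' fixed ratio at its neutral value 1) and sweeps the other over several
#' orders of magnitude, from strong inhibition to strong activation,
#' recording the steady-state mutual information and mean copy numbers at
#' each point.
#'
#' @param beta Fixed substrate production rate.
#' @param which Which ratio to sweep: `"K"` or `"V"`.
#' @param xi_grid Positive grid of ratio values (default spans 1e-2..1e2).
#' @param tol,cap As in [run_beta_sweep()].
#' @return A data.frame with one row per grid value; columns as in
#'   [run_beta_sweep()] plus `xi_swept`.
#' @export
run_xi_sweep <- function(beta, which = c("V", "K"),
                         xi_grid = 10^seq(-2, 2, by = 0.5),
                         tol = 1e-8, cap = 256L) {
  which <- match.arg(which)
  if (any(xi_grid <= 0)) stop("'xi_grid' must be positive", call. = FALSE)
  rows <- lapply(xi_grid, function(x) {
    xi <- if (which == "K") allostery_ratios(xiK = x, xiV = 1)
          else allostery_ratios(xiK = 1, xiV = x)
    r <- .steady_row(xi, beta, tol, 8L, 8L, cap)$row
    r$xi_swept <- which
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Square-wave (pulsed substrate) protocol specification
#'
#' @param beta_low,beta_high Low/high production rates
#'   (`beta_high >= beta_low >= 0`; equal values give a degenerate,
#'   constant-input pulse).
#' @param period Cycle length (> 0), units of `1 / gammaS`.
#' @param duty Fraction of each period at `beta_high`, in (0, 1).  Each
#'   cycle runs its low phase first, so the first up-switch occurs at
#'   `(1 - duty) * period`.
#' @param cycles Number of cycles.
#' @param resolution Output grid points per cycle.
#' @return An object of class `alo_pulse_spec`.
#' @export
pulse_spec <- function(beta_low = 0, beta_high = 16, period = 20,
                       duty = 0.5, cycles = 3, resolution = 100) {
  if (beta_low < 0 || beta_high < beta_low)
    stop("need beta_high >= beta_low >= 0", call. = FALSE)
  if (period <= 0 || duty <= 0 || duty >= 1)
    stop("'period' must be > 0 and 'duty' in (0, 1)", call. = FALSE)
  cycles <- as.integer(cycles); resolution <- as.integer(resolution)
  if (cycles < 1L || resolution < 2L)
    stop("'cycles' must be >= 1 and 'resolution' >= 2", call. = FALSE)
  structure(list(beta_low = beta_low, beta_high = beta_high,
                 period = period, duty = duty, cycles = cycles,
                 resolution = resolution),
            class = "alo_pulse_spec")
}

#' Time-resolved information transmission under pulsed substrate input
#'
#' Drives the network with a square-wave production rate and tracks, at each
#' grid time, the time-marginal mutual information between the enzyme and
#' downstream states together with the mean copy numbers, via [evolve()].
#' The initial condition is the steady state of the first (low) segment, so
#' cycles after the first are periodic.  Each up-switch in substrate supply
#' induces a rapid transient spike in the mutual information before the
#' product pool has fully responded; the spike is more pronounced for
#' inhibitory allosteric modulation, which avoids immediate saturation.
#'
#' @param spec An [pulse_spec()].
#' @param xi_pairs List of [allostery_ratios()] to run.
#' @param tol Truncation tolerance (the space is certified at the constant
#'   high rate, an upper envelope for the pulsed dynamics).
#' @param cap Truncation hard cap.
#' @return A data.frame with `cycles * resolution` rows per xi pair:
#'   columns `xiK`, `xiV`, `time`, `beta`, `t_or_steady`, `mi_ab_nats`,
#'   `mean_s`, `mean_p`, `boundary_mass`.
#' @export
run_pulse <- function(spec = pulse_spec(),
                      xi_pairs = list(allostery_ratios(1, 0.1),
                                      allostery_ratios(1, 1),
                                      allostery_ratios(1, 10)),
                      tol = 1e-8, cap = 256L) {
  if (!inherits(spec, "alo_pulse_spec")) stop("invalid 'spec'", call. = FALSE)
  t_total <- spec$cycles * spec$period
  t_grid <- seq_len(spec$cycles * spec$resolution) *
    (spec$period / spec$resolution)
  schedule <- square_wave_schedule(spec$beta_low, spec$beta_high,
                                   spec$period, spec$duty, spec$cycles)
  rows <- list()
  for (xi in xi_pairs) {
    if (!inherits(xi, "alo_ratios")) xi <- do.call(allostery_ratios, as.list(xi))
    pa_high <- default_parameters(xi, spec$beta_high)
    space <- auto_truncate(pa_high, tol = tol, cap = cap)
    pa_low <- default_parameters(xi, spec$beta_low)
    p0 <- steady_state(build_generator(pa_low, space))
    dists <- evolve(pa_high, schedule, p0, t_grid)
    for (g in seq_along(t_grid)) {
      info <- info_summary(dists[[g]])
      rows[[length(rows) + 1L]] <- data.frame(
        xiK = xi$xiK, xiV = xi$xiV, time = t_grid[g],
        beta = schedule_beta_at(schedule, min(t_grid[g], t_total - 1e-12)),
        t_or_steady = "transient",
        mi_ab_nats = info$mi_ab, mean_s = info$mean_s,
        mean_p = info$mean_p, boundary_mass = info$boundary_mass,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "spec") <- spec
  out
}

#' Write a results table as tidy CSV
#'
#' Column conventions: `mi_ab_nats` is the mutual information in nats;
#' `mean_s`/`mean_p` are molecule counts; `boundary_mass` certifies the
#' truncation; `t_or_steady` distinguishes stationary rows from transients.
#'
#' @param df A results data.frame from one of the `run_*` drivers.
#' @param path Output path.
#' @export
write_results_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
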