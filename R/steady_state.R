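#' Stationary distribution of the truncated master equation
#'
#' Solves `Q p = 0`, `sum(p) = 1` for the generator's stationary
#' distribution.  The primary route pins the probability of one reference
#' state and solves the sparse linear system obtained by deleting that
#' state's balance equation and column (nonsingular whenever the chain has a
#' unique stationary distribution whose closed class contains the reference
#' state), then renormalizes - a deterministic direct solve with no burn-in.
#' If that system is singular or ill-conditioned, the solver falls back to
#' power iteration on the uniformized transition matrix starting from the
#' uniform distribution (the ergodic projection of the uniform prior).  The
#' result is certified by the residual `max |Q p|`; entries more negative
#' than `-1e-12` are an error, and entries in `[-1e-12, 0)` are clipped
#' before renormalization.
#'
#' @param gen An `alo_generator` from [build_generator()].
#' @param tol Residual tolerance: `max(abs(Q %*% p))` must be below `tol`.
#' @return An `alo_distribution` (with `time = NA`); attribute `residual`
#'   records the achieved residual.
#' @examples
#' gen <- build_generator(default_parameters(beta = 1), state_space(12, 8))
#' ss <- steady_state(gen)
#' attr(ss, "residual")
#' @export
steady_state <- function(gen, tol = 1e-10) {
  if (!inherits(gen, "alo_generator"))
    stop("'gen' must be an alo_generator", call. = FALSE)
  Q <- gen$Q
  n <- ncol(Q)
  p <- .ss_direct(Q, n)
  res <- if (is.null(p)) Inf else max(abs(Q %*% p))
  if (!is.finite(res) || res >= tol) {
    p2 <- .ss_power(Q, n, tol)
    res2 <- max(abs(Q %*% p2))
    if (res2 < res) { p <- p2; res <- res2 }
    if (!is.finite(res) || res >= tol)
      stop(sprintf(
        "steady-state solver did not converge: residual %.3e >= tol %.3e",
        res, tol), call. = FALSE)
  }
  if (min(p) < -1e-12)
    stop(sprintf("steady state has entry %.3e < -1e-12", min(p)),
         call. = FALSE)
  d <- distribution(pmax(p, 0) / sum(pmax(p, 0)), gen$space)
  attr(d, "residual") <- res
  d
}

# Pin p[1] = 1 (state (A, B, 0, 0), always in the closed class of this
# network), solve Q[-1, -1] x = -Q[-1, 1], renormalize.
.ss_direct <- function(Q, n) {
  if (n == 1L) return(1)
  x <- tryCatch(
    as.numeric(Matrix::solve(Q[-1L, -1L, drop = FALSE],
                             -Q[-1L, 1L, drop = FALSE])),
    error = function(e) NULL,
    warning = function(w) NULL)
  if (is.null(x) || !all(is.finite(x))) return(NULL)
  p <- c(1, x)
  s <- sum(p)
  if (!is.finite(s) || abs(s) < 1e-300) return(NULL)
  p / s
}

# Uniformized power iteration from the uniform distribution.  The halved
# uniformization rate keeps the chain aperiodic even when the embedded
# structure is periodic.
.ss_power <- function(Q, n, tol) {
  lam <- 2 * max(-Matrix::diag(Q))
  if (lam <= 0) return(rep(1 / n, n))
  P <- Q / lam
  Matrix::diag(P) <- Matrix::diag(P) + 1
  p <- rep(1 / n, n)
  for (it in seq_len(1000000L)) {
    p <- as.numeric(P %*% p)
    p <- p / sum(p)
    if (it %% 100L == 0L && max(abs(Q %*% p)) < tol) break
  }
  p
}
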