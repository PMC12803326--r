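#' Probability mass on the truncation boundary
#'
#' The closed truncation of the master equation is accurate when the
#' stationary (or transient) distribution places negligible mass on the rim
#' of the box, i.e. on states with `s = s_max` or `p = p_max`.  This is the
#' a posteriori quality certificate used by [auto_truncate()].
#'
#' @param dist An `alo_distribution`.
#' @param space The [state_space()] the distribution lives on (defaults to
#'   the distribution's own space).
#' @return Total probability on boundary states.
#' @export
boundary_mass <- function(dist, space = dist$space) {
  if (length(dist$p) != space$n)
    stop("distribution and space sizes differ", call. = FALSE)
  sum(dist$p[space$s == space$s_max | space$p == space$p_max])
}

#' Choose a truncation that certifies the steady state
#'
#' Grows the truncation bounds geometrically (doubling the `s` and/or `p`
#' bound, independently, according to which rim carries mass) until the
#' steady-state boundary mass falls below `tol`, starting from
#' `(s_start, p_start)` and aborting at the hard cap.
#'
#' @param params An `alo_params` object.
#' @param tol Boundary-mass tolerance, in (0, 1).
#' @param s_start,p_start Initial bounds.
#' @param cap Hard limit on either bound; exceeding it is an error that
#'   reports the mass achieved.
#' @return The final [state_space()]; attributes `steady_state` (the
#'   certified `alo_distribution`) and `boundary_mass` are attached so
#'   callers need not re-solve.
#' @examples
#' sp <- auto_truncate(default_parameters(beta = 2), tol = 1e-8)
#' attr(sp, "boundary_mass")
#' @export
auto_truncate <- function(params, tol = 1e-8, s_start = 8L, p_start = 8L,
                          cap = 256L) {
  validate_parameters(params)
  if (!is.numeric(tol) || tol <= 0 || tol >= 1)
    stop("'tol' must be in (0, 1)", call. = FALSE)
  s_max <- as.integer(s_start)
  p_max <- as.integer(p_start)
  repeat {
    space <- state_space(s_max, p_max)
    ss <- steady_state(build_generator(params, space))
    mass_s <- sum(ss$p[space$s == s_max])
    mass_p <- sum(ss$p[space$p == p_max])
    grow_s <- mass_s >= tol / 2
    grow_p <- mass_p >= tol / 2
    if (!grow_s && !grow_p) {
      attr(space, "steady_state") <- ss
      attr(space, "boundary_mass") <- boundary_mass(ss, space)
      return(space)
    }
    if ((grow_s && s_max >= cap) || (grow_p && p_max >= cap))
      stop(sprintf(
        paste0("truncation cap %d exceeded: boundary mass %.3e ",
               "(s rim %.3e, p rim %.3e) above tol %.3e"),
        cap, mass_s + mass_p, mass_s, mass_p, tol), call. = FALSE)
    if (grow_s) s_max <- min(2L * s_max, as.integer(cap))
    if (grow_p) p_max <- min(2L * p_max, as.integer(cap))
  }
}
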