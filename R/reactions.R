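# Internal channel table.  Each entry fully specifies one unidirectional
# reaction channel: an optional guard on the enzyme/protein state, a
# mass-action rate as a function of the free copy numbers, and the state
# change (new sigmaA/sigmaB and increments to s and p).  `req_a`/`req_b` of
# NA mean "any"; `new_a`/`new_b` of NA mean "unchanged".
.channel_table <- function(pa) {
  ch <- function(label, rate, req_a = NA_integer_, req_b = NA_integer_,
                 new_a = NA_integer_, new_b = NA_integer_,
                 ds = 0L, dp = 0L)
    list(label = label, rate = rate, req_a = req_a, req_b = req_b,
         new_a = new_a, new_b = new_b, ds = ds, dp = dp)
  # sigmaA codes: 1 = A, 2 = A*, 3 = AS, 4 = A*S; sigmaB: 1 = B, 2 = BP
  list(
    ch("S_production",   function(s, p) rep_len(pa$beta, length(s)), ds = +1L),
    ch("S_degradation",  function(s, p) pa$gammaS * s,               ds = -1L),
    ch("A_bind_S",       function(s, p) pa$kA_on * s,
       req_a = 1L, new_a = 3L, ds = -1L),
    ch("AS_unbind",      function(s, p) rep_len(pa$kA_off, length(s)),
       req_a = 3L, new_a = 1L, ds = +1L),
    ch("Astar_bind_S",   function(s, p) pa$kAstar_on * s,
       req_a = 2L, new_a = 4L, ds = -1L),
    ch("AstarS_unbind",  function(s, p) rep_len(pa$kAstar_off, length(s)),
       req_a = 4L, new_a = 2L, ds = +1L),
    ch("A_to_Astar",     function(s, p) rep_len(pa$alpha, length(s)),
       req_a = 1L, new_a = 2L),
    ch("Astar_to_A",     function(s, p) rep_len(pa$alpha_star, length(s)),
       req_a = 2L, new_a = 1L),
    ch("AS_to_AstarS",   function(s, p) rep_len(pa$alphaS, length(s)),
       req_a = 3L, new_a = 4L),
    ch("AstarS_to_AS",   function(s, p) rep_len(pa$alphaS_star, length(s)),
       req_a = 4L, new_a = 3L),
    ch("AS_catalysis",   function(s, p) rep_len(pa$nu, length(s)),
       req_a = 3L, new_a = 1L, dp = +1L),
    ch("AstarS_catalysis", function(s, p) rep_len(pa$nu_star, length(s)),
       req_a = 4L, new_a = 2L, dp = +1L),
    ch("P_degradation",  function(s, p) pa$gammaP * p,               dp = -1L),
    ch("B_bind_P",       function(s, p) pa$kB_on * p,
       req_b = 1L, new_b = 2L, dp = -1L),
    ch("BP_unbind",      function(s, p) rep_len(pa$kB_off, length(s)),
       req_b = 2L, new_b = 1L, dp = +1L)
  )
}

#' Reaction channels of the allosteric signaling network
#'
#' Constructs the complete list of unidirectional reaction channels of the
#' network: substrate production (`beta`) and degradation (`gammaS * s`),
#' substrate binding/unbinding to each enzyme conformation (`kA_on * s`,
#' `kA_off`, `kAstar_on * s`, `kAstar_off`), conformational switching of the
#' unbound (`alpha`, `alpha_star`) and bound (`alphaS`, `alphaS_star`)
#' enzyme, catalysis releasing one product (`nu`, `nu_star`; the bound
#' substrate is consumed, having already left the free pool at binding),
#' free-product degradation (`gammaP * p`), and reversible sequestration of
#' product by the downstream protein (`kB_on * p`, `kB_off`).  Only free
#' substrate and free product degrade; sequestered product is returned to
#' the free pool on unbinding.
#'
#' @param params An `alo_params` object from [default_parameters()].
#' @return A list of 15 channels, each of class `alo_channel` with elements
#'   `label`, `propensity` (a function of an [system_state()] returning a
#'   rate >= 0, zero whenever the guard state or copy-number support is
#'   absent) and `delta` (named list `a`, `b`, `ds`, `dp`; `a`/`b` of `NA`
#'   mean unchanged).
#' @examples
#' chans <- reaction_channels(default_parameters(beta = 1))
#' length(chans)
#' sapply(chans, `[[`, "label")
#' @export
reaction_channels <- function(params) {
  validate_parameters(params)
  tab <- .channel_table(params)
  lapply(tab, function(ch) {
    force(ch)
    structure(list(
      label = ch$label,
      propensity = function(state) {
        if (!is.na(ch$req_a) && state$a != ch$req_a) return(0)
        if (!is.na(ch$req_b) && state$b != ch$req_b) return(0)
        if (state$s + ch$ds < 0L || state$p + ch$dp < 0L) return(0)
        ch$rate(state$s, state$p)
      },
      delta = list(a = ch$new_a, b = ch$new_b, ds = ch$ds, dp = ch$dp)
    ), class = "alo_channel")
  })
}

#' Apply a reaction channel's state change
#'
#' @param state An [system_state()] object.
#' @param channel An `alo_channel` from [reaction_channels()].
#' @return The post-reaction `alo_state`.
#' @export
apply_channel <- function(state, channel) {
  d <- channel$delta
  system_state(
    if (is.na(d$a)) state$a else d$a,
    if (is.na(d$b)) state$b else d$b,
    state$s + d$ds,
    state$p + d$dp
  )
}

#' Total propensities of all channels at one configuration
#'
#' @param params An `alo_params` object.
#' @param state An [system_state()] object.
#' @return Named numeric vector of per-channel propensities.
#' @export
channel_propensities <- function(params, state) {
  chans <- reaction_channels(params)
  vapply(chans, function(ch) ch$propensity(state), numeric(1),
         USE.NAMES = FALSE) -> v
  names(v) <- vapply(chans, `[[`, "", "label")
  v
}
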