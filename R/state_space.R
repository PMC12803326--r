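#' @useDynLib allosinfo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods as is
NULL

#' Enzyme and downstream-protein state labels
#'
#' The upstream enzyme occupies one of four internal states `sigmaA`:
#' unbound baseline `A`, unbound allosterically modified `A*`, and their
#' substrate-bound complexes `AS` and `A*S`.  The downstream protein occupies
#' one of two states `sigmaB`: free `B` or product-bound `BP`.
#'
#' @format Character vectors of length 4 (`enzyme_states`) and 2
#'   (`protein_states`); their order defines the integer coding used
#'   throughout the package.
#' @export
enzyme_states <- c("A", "A*", "AS", "A*S")

#' @rdname enzyme_states
#' @export
protein_states <- c("B", "BP")

#' A single system configuration
#'
#' The full system configuration is `(sigmaA, sigmaB, s, p)`: the enzyme
#' state, the downstream protein state, and the free substrate and free
#' product copy numbers.  Exactly one copy each of the enzyme A and the
#' protein B is present, so stochasticity comes from state switching and
#' molecular turnover, not enzyme copy-number fluctuations.
#'
#' @param sigmaA Enzyme state: one of `"A"`, `"A*"`, `"AS"`, `"A*S"` (or the
#'   integer code 1:4).
#' @param sigmaB Protein state: `"B"` or `"BP"` (or 1:2).
#' @param s,p Non-negative integer copy numbers of free substrate and free
#'   product.
#' @return An object of class `alo_state`: a list with integer-coded
#'   `a`, `b` and counts `s`, `p`.
#' @examples
#' system_state("A*S", "BP", s = 1, p = 1)
#' @export
system_state <- function(sigmaA = "A", sigmaB = "B", s = 0L, p = 0L) {
  a <- if (is.character(sigmaA)) match(sigmaA, enzyme_states) else as.integer(sigmaA)
  b <- if (is.character(sigmaB)) match(sigmaB, protein_states) else as.integer(sigmaB)
  if (is.na(a) || length(a) != 1L || a < 1L || a > 4L)
    stop("invalid 'sigmaA'", call. = FALSE)
  if (is.na(b) || length(b) != 1L || b < 1L || b > 2L)
    stop("invalid 'sigmaB'", call. = FALSE)
  s <- as.integer(s); p <- as.integer(p)
  if (is.na(s) || s < 0L || is.na(p) || p < 0L)
    stop("'s' and 'p' must be non-negative integers", call. = FALSE)
  structure(list(a = a, b = b, s = s, p = p), class = "alo_state")
}

#' @export
print.alo_state <- function(x, ...) {
  cat(sprintf("(%s, %s, s=%d, p=%d)\n",
              enzyme_states[x$a], protein_states[x$b], x$s, x$p))
  invisible(x)
}

#' Truncated enumeration of the system state space
#'
#' The chemical master equation lives on a countably infinite space; for
#' numerical work it is truncated to the box `s <= s_max`, `p <= p_max`,
#' giving `8 * (s_max + 1) * (p_max + 1)` configurations.  States are
#' enumerated with the enzyme state varying fastest, then the protein state,
#' then `s`, then `p`; [state_index()] and [index_state()] implement the
#' bijection between configurations and 1-based indices.
#'
#' @param s_max,p_max Non-negative integer truncation bounds.
#' @return An object of class `alo_space`: a list with `s_max`, `p_max`, the
#'   size `n`, and parallel integer vectors `a`, `b`, `s`, `p` giving the
#'   configuration at each index.
#' @examples
#' sp <- state_space(2, 2)
#' sp$n  # 8 * 3 * 3 = 72
#' @export
state_space <- function(s_max, p_max) {
  s_max <- as.integer(s_max); p_max <- as.integer(p_max)
  if (is.na(s_max) || s_max < 0L || is.na(p_max) || p_max < 0L)
    stop("'s_max' and 'p_max' must be non-negative integers", call. = FALSE)
  g <- expand.grid(a = 1:4, b = 1:2, s = 0:s_max, p = 0:p_max,
                   KEEP.OUT.ATTRS = FALSE)
  structure(list(s_max = s_max, p_max = p_max, n = nrow(g),
                 a = g$a, b = g$b, s = g$s, p = g$p),
            class = "alo_space")
}

#' @export
print.alo_space <- function(x, ...) {
  cat(sprintf("State space: s <= %d, p <= %d, %d configurations\n",
              x$s_max, x$p_max, x$n))
  invisible(x)
}

#' Map a configuration to its index in a state space
#'
#' @param space An [state_space()] object.
#' @param a,b,s,p Integer-coded configuration components (vectorized).
#' @return 1-based integer index (vector).
#' @export
state_index <- function(space, a, b, s, p) {
  ((p * (space$s_max + 1L) + s) * 2L + (b - 1L)) * 4L + a
}

#' Map an index back to its configuration
#'
#' @param space An [state_space()] object.
#' @param i 1-based index (vector).
#' @return A data.frame with columns `a`, `b`, `s`, `p`.
#' @export
index_state <- function(space, i) {
  i <- as.integer(i)
  if (any(i < 1L | i > space$n)) stop("index out of range", call. = FALSE)
  data.frame(a = space$a[i], b = space$b[i], s = space$s[i], p = space$p[i])
}

# integer 1..8 coding of the (sigmaA, sigmaB) cell of each configuration
.ab_cell <- function(space) space$a + 4L * (space$b - 1L)
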