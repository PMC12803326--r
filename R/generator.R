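#' Build the truncated master-equation generator
#'
#' Assembles the transition-rate matrix Q of the continuous-time Markov jump
#' process on a truncated state space: the off-diagonal entry `(i, j)` is the
#' propensity of the (unique) channel taking configuration `j` to
#' configuration `i`, and each diagonal entry is minus the sum of the
#' retained outgoing rates, so every column sums to exactly zero.  The
#' truncation is closed (reflecting): transitions that would leave the box
#' `s <= s_max`, `p <= p_max` are deleted, and their rate is excluded from
#' the diagonal, so the generator remains a proper rate matrix and
#' probability is exactly conserved.  Truncation accuracy is certified a
#' posteriori with [boundary_mass()].
#'
#' @param params An `alo_params` object.
#' @param space An [state_space()] object.
#' @return An object of class `alo_generator`: a list with the sparse
#'   `dgCMatrix` `Q`, the `space`, and the `params` used.
#' @examples
#' gen <- build_generator(default_parameters(beta = 1), state_space(6, 6))
#' max(abs(Matrix::colSums(gen$Q)))  # columns sum to zero
#' @export
build_generator <- function(params, space) {
  validate_parameters(params)
  if (!inherits(space, "alo_space")) stop("'space' must be an alo_space",
                                          call. = FALSE)
  n <- space$n
  if (n < 1L) stop("state space has size 0", call. = FALSE)
  tab <- .channel_table(params)
  ii <- jj <- vector("list", length(tab))
  xx <- vector("list", length(tab))
  for (k in seq_along(tab)) {
    ch <- tab[[k]]
    ok <- rep(TRUE, n)
    if (!is.na(ch$req_a)) ok <- ok & (space$a == ch$req_a)
    if (!is.na(ch$req_b)) ok <- ok & (space$b == ch$req_b)
    s2 <- space$s + ch$ds
    p2 <- space$p + ch$dp
    ok <- ok & s2 >= 0L & s2 <= space$s_max & p2 >= 0L & p2 <= space$p_max
    src <- which(ok)
    if (!length(src)) next
    rate <- ch$rate(space$s[src], space$p[src])
    pos <- rate > 0
    src <- src[pos]
    if (!length(src)) next
    a2 <- if (is.na(ch$new_a)) space$a[src] else rep_len(ch$new_a, length(src))
    b2 <- if (is.na(ch$new_b)) space$b[src] else rep_len(ch$new_b, length(src))
    jj[[k]] <- src
    ii[[k]] <- state_index(space, a2, b2, s2[src], p2[src])
    xx[[k]] <- rate[pos]
  }
  i <- unlist(ii); j <- unlist(jj); x <- unlist(xx)
  if (is.null(i)) {
    Q <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n, n))
  } else {
    # duplicate (i, j) pairs cannot arise: each channel has a distinct delta
    Q <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
    Q <- Q - Matrix::Diagonal(n, Matrix::colSums(Q))
  }
  structure(list(Q = methods::as(Q, "CsparseMatrix"),
                 space = space, params = params),
            class = "alo_generator")
}

#' @export
print.alo_generator <- function(x, ...) {
  cat(sprintf(
    "Master-equation generator: %d x %d, %d nonzeros (s<=%d, p<=%d)\n",
    x$space$n, x$space$n, length(x$Q@x), x$space$s_max, x$space$p_max))
  invisible(x)
}

#' Construct a probability distribution over a state space
#'
#' @param p Numeric vector of probabilities aligned with `space` (entries
#'   >= 0, summing to 1 within 1e-10).
#' @param space An [state_space()] object.
#' @param time Optional timestamp.
#' @return An object of class `alo_distribution`.
#' @export
distribution <- function(p, space, time = NA_real_) {
  if (length(p) != space$n)
    stop("length(p) must equal the state-space size", call. = FALSE)
  if (any(p < -1e-12))
    stop("negative probabilities beyond -1e-12", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-10)
    stop("probabilities must sum to 1 within 1e-10; got ", sum(p),
         call. = FALSE)
  p <- pmax(p, 0)
  p <- p / sum(p)
  structure(list(p = as.numeric(p), space = space, time = time),
            class = "alo_distribution")
}

#' Point-mass distribution on one configuration
#'
#' @param state An [system_state()] object.
#' @param space An [state_space()] object containing it.
#' @param time Optional timestamp.
#' @return An `alo_distribution` with all mass on `state`.
#' @export
point_mass <- function(state, space, time = NA_real_) {
  if (state$s > space$s_max || state$p > space$p_max)
    stop("state lies outside the state space", call. = FALSE)
  p <- numeric(space$n)
  p[state_index(space, state$a, state$b, state$s, state$p)] <- 1
  distribution(p, space, time)
}

#' @export
print.alo_distribution <- function(x, ...) {
  cat(sprintf("Distribution over %d states%s\n", x$space$n,
              if (is.na(x$time)) " (steady state or untimed)"
              else sprintf(" at t = %g", x$time)))
  invisible(x)
}

#' @export
as.data.frame.alo_distribution <- function(x, ...) {
  data.frame(
    sigmaA = enzyme_states[x$space$a],
    sigmaB = protein_states[x$space$b],
    s = x$space$s, p = x$space$p,
    probability = x$p,
    stringsAsFactors = FALSE
  )
}

#' Export a distribution to CSV
#'
#' Columns: `sigmaA`, `sigmaB`, `s`, `p`, `probability`.
#'
#' @param dist An `alo_distribution`.
#' @param path Output file path.
#' @export
write_distribution_csv <- function(dist, path) {
  utils::write.csv(as.data.frame(dist), path, row.names = FALSE)
  invisible(path)
}

#' Export a generator in coordinate (MatrixMarket) sparse text format
#'
#' @param gen An `alo_generator`.
#' @param path Output file path.
#' @export
write_generator_mtx <- function(gen, path) {
  Matrix::writeMM(gen$Q, path)
  invisible(path)
}
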