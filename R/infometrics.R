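#' Joint distribution of the enzyme and downstream-protein states
#'
#' Marginalizes a full distribution over (sigmaA, sigmaB, s, p) onto the
#' 4 x 2 joint table q(sigmaA, sigmaB) by summing over the substrate and
#' product copy numbers.
#'
#' @param dist An `alo_distribution`.
#' @return A 4 x 2 matrix with rows named by [enzyme_states] and columns by
#'   [protein_states], summing to 1.
#' @export
marginal_ab <- function(dist) {
  if (!inherits(dist, "alo_distribution"))
    stop("'dist' must be an alo_distribution", call. = FALSE)
  cell <- .ab_cell(dist$space)
  q <- vapply(1:8, function(k) sum(dist$p[cell == k]), numeric(1))
  matrix(q, nrow = 4, ncol = 2,
         dimnames = list(enzyme_states, protein_states))
}

#' Shannon entropy in nats
#'
#' `H = -sum(q * log(q))` with the convention `0 * log(0) = 0`; entries
#' below 1e-300 are treated as exact zeros to avoid log underflow.
#'
#' @param q Non-negative numeric vector (need not be normalized for internal
#'   use, but entropies of probability vectors are the intended call).
#' @return Entropy in nats.
#' @examples
#' shannon_entropy(c(0.5, 0.5))  # log(2)
#' @export
shannon_entropy <- function(q) {
  q <- as.numeric(q)
  if (any(q < 0)) stop("probabilities must be >= 0", call. = FALSE)
  q <- q[q > 1e-300]
  if (!length(q)) return(0)
  -sum(q * log(q))
}

#' Mutual information between enzyme and downstream states
#'
#' `MI = sum_{a,b} q(a,b) * log( q(a,b) / (q_A(a) q_B(b)) )` in nats
#' (natural logarithm), with `0 * log(0) = 0`.  Small values indicate weak
#' statistical dependence between the enzyme's regulatory state and the
#' downstream protein's occupancy; larger values indicate stronger coupling
#' and more effective communication.
#'
#' @param q A joint probability table (any dimensions; here 4 x 2 from
#'   [marginal_ab()]), entries >= 0 and summing to 1 within 1e-8.
#' @return Mutual information in nats (>= 0).
#' @examples
#' q <- matrix(0, 4, 2); q[1, 1] <- 0.5; q[2, 2] <- 0.5
#' mutual_information(q)  # log(2): perfectly correlated binary
#' @export
mutual_information <- function(q) {
  q <- as.matrix(q)
  if (any(q < 0)) stop("joint table has negative entries", call. = FALSE)
  if (abs(sum(q) - 1) > 1e-8)
    stop("joint table not normalized: sum = ", sum(q), call. = FALSE)
  qa <- rowSums(q)
  qb <- colSums(q)
  mi <- shannon_entropy(qa) + shannon_entropy(qb) - shannon_entropy(q)
  # the three-entropy identity is algebraically identical to the double sum
  # and immune to 0 * log(0) cells; clamp the roundoff floor
  max(mi, 0)
}

#' Mean substrate and product copy numbers
#'
#' @param dist An `alo_distribution`.
#' @return Named numeric vector `c(mean_s =, mean_p =)`: the expected free
#'   substrate and free product copy numbers.
#' @export
state_moments <- function(dist) {
  if (!inherits(dist, "alo_distribution"))
    stop("'dist' must be an alo_distribution", call. = FALSE)
  c(mean_s = sum(dist$space$s * dist$p),
    mean_p = sum(dist$space$p * dist$p))
}

#' Information-theoretic summary of a distribution
#'
#' Computes the quantities the analysis pipelines report at every condition:
#' the mutual information between sigmaA and sigmaB, the marginal entropies,
#' and the mean copy numbers.
#'
#' @param dist An `alo_distribution`.
#' @return An object of class `alo_info`: a list with `mi_ab` (nats), `h_a`
#'   (nats, <= log 4), `h_b` (nats, <= log 2), `mean_s`, `mean_p`
#'   (molecules), and `boundary_mass`.
#' @export
info_summary <- function(dist) {
  q <- marginal_ab(dist)
  mom <- state_moments(dist)
  structure(list(
    mi_ab = mutual_information(q),
    h_a = shannon_entropy(rowSums(q)),
    h_b = shannon_entropy(colSums(q)),
    mean_s = unname(mom["mean_s"]),
    mean_p = unname(mom["mean_p"]),
    boundary_mass = boundary_mass(dist)
  ), class = "alo_info")
}

#' @export
print.alo_info <- function(x, ...) {
  cat(sprintf(
    "MI(sigmaA; sigmaB) = %.6g nats (H_A = %.4g, H_B = %.4g)\n<S> = %.6g, <P> = %.6g molecules; boundary mass %.2e\n",
    x$mi_ab, x$h_a, x$h_b, x$mean_s, x$mean_p, x$boundary_mass))
  invisible(x)
}
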