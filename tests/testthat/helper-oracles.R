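# Independent oracles used across the suite.  These deliberately avoid the
# package's own solver code paths: dense linear algebra for stationary
# distributions, a literal double sum for mutual information, closed forms
# for the birth-death limit.

# stationary distribution as the dense null vector of Q (smallest singular
# value), normalized
dense_stationary <- function(Q) {
  sv <- svd(as.matrix(Q))
  v <- sv$v[, ncol(sv$v)]
  v / sum(v)
}

# mutual information by the literal double sum over cells
mi_double_sum <- function(q) {
  qa <- rowSums(q)
  qb <- colSums(q)
  tot <- 0
  for (i in seq_len(nrow(q))) {
    for (j in seq_len(ncol(q))) {
      if (q[i, j] > 0) tot <- tot + q[i, j] * log(q[i, j] / (qa[i] * qb[j]))
    }
  }
  tot
}

# parameters with the substrate-binding channels disabled: the substrate
# pool decouples into a birth-death process with Poisson(beta/gammaS)
# stationary law
decoupled_params <- function(beta) {
  pa <- default_parameters(beta = beta)
  pa$kA_on <- 0
  pa$kAstar_on <- 0
  validate_parameters(pa)
}

# marginal distribution of the substrate copy number
s_marginal <- function(dist) {
  vapply(0:dist$space$s_max, function(k) sum(dist$p[dist$space$s == k]),
         numeric(1))
}

# mean and Fano factor of the substrate copy number
s_stats <- function(dist) {
  m <- s_marginal(dist)
  k <- 0:dist$space$s_max
  mu <- sum(k * m)
  v <- sum(k^2 * m) - mu^2
  c(mean = mu, fano = v / mu)
}

# parameters in which every rate is zero except gammaS (which must stay
# positive); on the s_max = p_max = 0 box this yields the zero generator
quiescent_params <- function() {
  pa <- default_parameters(beta = 0)
  for (k in setdiff(names(pa), "gammaS")) pa[[k]] <- 0
  validate_parameters(pa)
}
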