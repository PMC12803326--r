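test_that("entropy follows the 0 log 0 convention", {
  expect_equal(shannon_entropy(c(1, 0, 0, 0)), 0)
  expect_equal(shannon_entropy(rep(0.25, 4)), log(4))
  expect_equal(shannon_entropy(c(0.5, 0.5)), log(2))
  expect_error(shannon_entropy(c(-0.1, 1.1)), ">= 0")
})

test_that("marginalization collapses the copy numbers correctly", {
  sp <- state_space(2, 2)
  pm <- point_mass(system_state("A", "B", 0, 0), sp)
  q <- marginal_ab(pm)
  expect_equal(q["A", "B"], 1)
  expect_equal(sum(q), 1)
  u <- distribution(rep(1 / sp$n, sp$n), sp)
  expect_equal(as.vector(marginal_ab(u)), rep(1 / 8, 8))
})

test_that("mutual information matches the brute-force double sum", {
  # perfectly correlated binary support: exactly log 2
  q <- matrix(0, 4, 2)
  q[1, 1] <- 0.5
  q[2, 2] <- 0.5
  expect_equal(mutual_information(q), log(2), tolerance = 1e-12)

  # product joints carry zero information
  qa <- c(0.4, 0.3, 0.2, 0.1)
  qb <- c(0.7, 0.3)
  expect_equal(mutual_information(outer(qa, qb)), 0, tolerance = 1e-12)

  # a four-cell joint, against the independent double-sum oracle
  q <- matrix(0, 4, 2)
  q[1, 1] <- 0.4; q[1, 2] <- 0.1; q[3, 1] <- 0.1; q[3, 2] <- 0.4
  expect_equal(mutual_information(q), mi_double_sum(q), tolerance = 1e-12)

  # random joints: oracle agreement, bounds, and the entropy identity
  set.seed(21)
  for (i in 1:25) {
    q <- matrix(stats::rexp(8), 4, 2)
    q <- q / sum(q)
    mi <- mutual_information(q)
    expect_equal(mi, mi_double_sum(q), tolerance = 1e-12)
    expect_gte(mi, 0)
    expect_lte(mi, min(shannon_entropy(rowSums(q)),
                       shannon_entropy(colSums(q))) + 1e-12)
  }
  expect_error(mutual_information(matrix(0.3, 4, 2)), "not normalized")
})

test_that("mutual information is invariant under relabeling", {
  set.seed(33)
  q <- matrix(stats::rexp(8), 4, 2)
  q <- q / sum(q)
  for (i in 1:10) {
    expect_equal(mutual_information(q[sample(4), sample(2)]),
                 mutual_information(q), tolerance = 1e-14)
  }
})

test_that("coarsening the enzyme state never increases information", {
  coarsen <- function(q) rbind(q[1, ] + q[2, ], q[3, ] + q[4, ])
  set.seed(55)
  for (i in 1:25) {
    q <- matrix(stats::rexp(8), 4, 2)
    q <- q / sum(q)
    expect_lte(mutual_information(coarsen(q)),
               mutual_information(q) + 1e-12)
  }
  # and on a real steady state
  ss <- steady_state(build_generator(default_parameters(beta = 2),
                                     state_space(16, 8)))
  q <- marginal_ab(ss)
  expect_lte(mutual_information(coarsen(q)), mutual_information(q) + 1e-12)
})

test_that("without substrate production the channel is silent", {
  sp <- auto_truncate(default_parameters(beta = 0), tol = 1e-8,
                      s_start = 4, p_start = 4)
  info <- info_summary(attr(sp, "steady_state"))
  expect_lt(info$mi_ab, 1e-9)
  expect_lt(info$h_b, 1e-9)  # B is deterministically unbound
})

test_that("moments report the expected copy numbers", {
  sp <- state_space(4, 4)
  pm <- point_mass(system_state("A", "B", 3, 2), sp)
  expect_equal(unname(state_moments(pm)), c(3, 2))
  sp2 <- auto_truncate(decoupled_params(2), tol = 1e-10)
  mom <- state_moments(attr(sp2, "steady_state"))
  expect_equal(unname(mom["mean_s"]), 2, tolerance = 1e-6)
  info <- info_summary(attr(sp2, "steady_state"))
  expect_lte(info$h_a, log(4) + 1e-12)
  expect_lte(info$h_b, log(2) + 1e-12)
})
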