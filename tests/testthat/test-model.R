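test_that("default parameters encode the fixed kinetic baseline", {
  pa <- default_parameters(allostery_ratios(1, 1), beta = 1)
  expect_equal(pa$gammaS, 1)
  expect_equal(pa$gammaP, 1)
  expect_equal(pa$kA_on, 1)
  expect_equal(pa$kA_off, 1)
  expect_equal(pa$kAstar_on, 1)
  expect_equal(pa$kAstar_off, 1)
  expect_equal(pa$alpha, 1)
  expect_equal(pa$alpha_star, 2)
  expect_equal(pa$alphaS, 4)
  expect_equal(pa$alphaS_star, 1)
  expect_equal(pa$nu, 1)
  expect_equal(pa$nu_star, 1)
  expect_equal(pa$kB_on, 1)
  expect_equal(pa$kB_off, 1)
  expect_equal(pa$beta, 1)

  # the ratios enter as kAstar_on = xiK and nu_star = xiV
  expect_equal(default_parameters(allostery_ratios(10, 1), 1)$kAstar_on, 10)
  expect_equal(default_parameters(allostery_ratios(1, 0.1), 1)$nu_star, 0.1)
  xi <- allostery_ratios_of(default_parameters(allostery_ratios(3, 0.2), 2))
  expect_equal(xi$xiK, 3)
  expect_equal(xi$xiV, 0.2)
})

test_that("invalid ratios and rates are rejected", {
  expect_error(allostery_ratios(xiK = 0), "positive")
  expect_error(allostery_ratios(xiV = -1), "positive")
  expect_error(default_parameters(beta = -1), "beta")
  pa <- default_parameters()
  pa$kB_on <- -2
  expect_error(validate_parameters(pa), "kB_on")
  pa <- default_parameters()
  pa$extra_rate <- 1
  expect_error(validate_parameters(pa), "unknown")
})

test_that("stability asymmetry of the conformational rates holds", {
  pa <- default_parameters()
  # unbound: baseline A more stable than A*; bound: A*S more stable than AS
  expect_gt(pa$alpha_star, pa$alpha)
  expect_gt(pa$alphaS, pa$alphaS_star)
})

test_that("the network has 15 unidirectional channels with unique labels", {
  chans <- reaction_channels(default_parameters())
  expect_length(chans, 15L)
  labels <- vapply(chans, `[[`, "", "label")
  expect_equal(anyDuplicated(labels), 0L)
})

test_that("propensities vanish off their support and match hand sums", {
  pa <- default_parameters(allostery_ratios(1, 1), beta = 1)

  # (A, B, 0, 0): only production (beta) and A -> A* (alpha) can fire
  w <- channel_propensities(pa, system_state("A", "B", 0, 0))
  expect_equal(sort(names(w[w > 0])), sort(c("S_production", "A_to_Astar")))
  expect_equal(unname(w["S_production"]), pa$beta)
  expect_equal(unname(w["A_to_Astar"]), pa$alpha)

  # (AS, B, s = 2, p = 0): beta, gammaS * 2, kA_off, alphaS, nu
  w <- channel_propensities(pa, system_state("AS", "B", 2, 0))
  expect_equal(sort(names(w[w > 0])),
               sort(c("S_production", "S_degradation", "AS_unbind",
                      "AS_to_AstarS", "AS_catalysis")))
  expect_equal(unname(w["S_degradation"]), 2)

  # total outflow from (A*S, BP, 1, 1):
  # beta + gammaS + kAstar_off + alphaS_star + nu_star + gammaP + kB_off = 7
  w <- channel_propensities(pa, system_state("A*S", "BP", 1, 1))
  expect_equal(sum(w), 7)
})

test_that("channel deltas keep copy numbers non-negative wherever the propensity is positive", {
  pa <- default_parameters(allostery_ratios(2, 0.5), beta = 3)
  chans <- reaction_channels(pa)
  set.seed(11)
  for (rep in 1:50) {
    st <- system_state(sample(4, 1), sample(2, 1),
                       sample(0:3, 1), sample(0:3, 1))
    for (ch in chans) {
      if (ch$propensity(st) > 0) {
        st2 <- apply_channel(st, ch)
        expect_gte(st2$s, 0)
        expect_gte(st2$p, 0)
      }
    }
  }
})

test_that("parameters round-trip through the flat key-value config file", {
  f <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("beta: 4", "kAstar_on: 10", "nu_star: 0.1"), f)
  pa <- read_parameters(f)
  expect_equal(pa$beta, 4)
  expect_equal(pa$kAstar_on, 10)
  expect_equal(pa$nu_star, 0.1)
  expect_equal(pa$alphaS, 4)  # untouched keys keep defaults

  writeLines(c("beta: 1", "mystery_key: 2"), f)
  expect_error(read_parameters(f), "unknown")
  writeLines("gammaP: -1", f)
  expect_error(read_parameters(f), "gammaP")
})
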