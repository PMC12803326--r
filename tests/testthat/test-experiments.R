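test_that("a beta = 0 sweep point reports a silent channel", {
  sw <- run_beta_sweep(0, list(allostery_ratios(1, 1)))
  expect_equal(nrow(sw), 1L)
  expect_lt(sw$mi_ab_nats, 1e-9)
  expect_true(sw$truncation_ok)
})

test_that("xi sweep at the neutral point equals the matching beta-sweep row", {
  xs <- run_xi_sweep(1, "V", 1)
  sw <- run_beta_sweep(1, list(allostery_ratios(1, 1)))
  expect_equal(xs$mi_ab_nats, sw$mi_ab_nats, tolerance = 1e-10)
  expect_equal(xs$mean_s, sw$mean_s, tolerance = 1e-10)
  expect_equal(xs$mean_p, sw$mean_p, tolerance = 1e-10)
})

test_that("every sweep row carries its truncation certificate", {
  sw <- run_beta_sweep(c(0.5, 2), list(allostery_ratios(1, 1),
                                       allostery_ratios(1, 10)))
  expect_true(all(c("boundary_mass", "truncation_ok") %in% names(sw)))
  expect_true(all(sw$boundary_mass[sw$truncation_ok] < 1e-8))
  expect_equal(nrow(sw), 4L)
})

test_that("product output grows with catalytic activation", {
  xs <- run_xi_sweep(1, "V", c(0.01, 0.1, 1, 10, 100))
  expect_true(all(diff(xs$mean_p) > 0))
})

test_that("degenerate pulse input stays at the steady state", {
  spec <- pulse_spec(beta_low = 4, beta_high = 4, period = 10, duty = 0.5,
                     cycles = 2, resolution = 10)
  pu <- run_pulse(spec, list(allostery_ratios(1, 1)))
  expect_equal(nrow(pu), 2L * 10L)
  last_cycle <- pu$mi_ab_nats[pu$time > 10]
  expect_lt(max(last_cycle) - min(last_cycle), 1e-6)
  # matches the constant-input steady state
  sp <- auto_truncate(default_parameters(beta = 4), tol = 1e-8)
  mi_ss <- info_summary(attr(sp, "steady_state"))$mi_ab
  expect_equal(mean(last_cycle), mi_ss, tolerance = 1e-6)
})

test_that("pulse output has the contracted shape and records beta(t)", {
  spec <- pulse_spec(beta_low = 0, beta_high = 8, period = 8, duty = 0.5,
                     cycles = 2, resolution = 8)
  pu <- run_pulse(spec, list(allostery_ratios(1, 1),
                             allostery_ratios(1, 0.1)))
  expect_equal(nrow(pu), 2L * 2L * 8L)
  expect_setequal(unique(pu$beta), c(0, 8))
  expect_true(all(pu$boundary_mass < 1e-6))
})

test_that("drivers are deterministic on re-run", {
  sw1 <- run_beta_sweep(c(1, 4), list(allostery_ratios(1, 0.1)))
  sw2 <- run_beta_sweep(c(1, 4), list(allostery_ratios(1, 0.1)))
  expect_identical(sw1, sw2)
})

test_that("the command-line driver runs sweeps from a config file", {
  dir <- withr::local_tempdir()
  cfg <- list(
    xi_pairs = list(list(xiK = 1, xiV = 1)),
    beta_grid = list(log2_min = -1, log2_max = 1, n = 3),
    output_dir = dir
  )
  f <- file.path(dir, "cfg.yml")
  yaml::write_yaml(cfg, f)
  status <- suppressMessages(cli_main(c("beta-sweep", "--config", f)))
  expect_equal(status, 0L)
  out <- utils::read.csv(file.path(dir, "beta_sweep.csv"))
  expect_equal(nrow(out), 3L)
  expect_true(all(c("beta", "xiK", "xiV", "mi_ab_nats", "mean_s", "mean_p",
                    "boundary_mass") %in% names(out)))
})

test_that("the command-line driver fails cleanly on bad input", {
  expect_equal(suppressMessages(
    cli_main(c("beta-sweep", "--config", "missing.yml"))), 1L)
  expect_equal(suppressMessages(cli_main("frobnicate")), 1L)
  expect_equal(suppressMessages(cli_main(character(0))), 1L)
})

test_that("the validate subcommand reports all oracle checks passing", {
  msgs <- character(0)
  status <- withCallingHandlers(
    cli_main("validate"),
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  expect_equal(status, 0L)
  expect_true(any(grepl("3/3 oracle checks passed", msgs)))
  expect_false(any(grepl("FAIL", msgs)))
})
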