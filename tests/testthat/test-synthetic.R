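test_that("scenario presets encode the reported per-medium contrasts", {
  rich <- rich_scn(); poor <- poor_scn()
  expect_equal(rich$S0 / poor$S0, 2)
  expect_equal(rich$VL / poor$VL, 60)
  expect_equal(rich$kdL / poor$kdL, 2)
  expect_error(make_scenario("medium"), "arg")
  expect_error(scenario("x", S0 = -1, N0 = 1, L0 = 1, VL = 1, kdL = 1),
               "positive")
})

test_that("clean tables are deterministic with monotone biomass and one light peak", {
  tab <- rich_clean()
  expect_named(tab, c("time_h", "od660", "lum"))
  expect_true(all(diff(tab$od660) >= -1e-9))
  # luminescence has exactly one interior local maximum
  s <- sign(diff(tab$lum))
  expect_equal(sum(diff(s) < 0), 1L)
  expect_identical(tab, generate_clean(rich_scn()))
  # single-row table from a single-time grid
  one <- generate_clean(scenario("tiny", 10, 3e-5, 0.2, 600, 0.5, t_grid = 0))
  expect_equal(nrow(one), 1L)
})

test_that("noise model: identity at zero, reproducible, calibrated CV", {
  tab <- rich_clean()
  expect_identical(add_noise(tab, noise_config(0, 0, seed = 1)), tab)
  n1 <- add_noise(tab, noise_config(0.05, 0.01, seed = 7))
  n2 <- add_noise(tab, noise_config(0.05, 0.01, seed = 7))
  expect_identical(n1, n2)
  expect_false(identical(n1$lum, tab$lum))
  expect_true(all(n1$od660 >= 0))
  # caller's RNG stream is not disturbed
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(add_noise(tab, noise_config(0.05, seed = 9)))
  expect_identical(rnorm(1), before)
  # empirical CV of replicated noisy points matches the configuration
  base <- data.frame(time_h = 1, lum = 100)
  draws <- vapply(1:10000, function(i)
    add_noise(base, noise_config(0.1, 0, seed = i))$lum, numeric(1))
  expect_lt(abs(sd(draws) / mean(draws) - 0.1) / 0.1, 0.05)
})

test_that("the rich trace shows the full batch-luminescence signature", {
  traj <- rich_traj()
  scn <- rich_scn()
  # slow strict decline while luciferase from the inoculum decays
  early <- traj$I[traj$time_h <= 4]
  expect_true(all(diff(early) < 0))
  expect_gt(min(early) / early[1], 0.2)  # slow, not collapsing
  # ignition to a unique interior peak
  pk <- lum_peak(traj)
  expect_gt(pk$time, traj$time_h[1])
  expect_lt(pk$time, max(traj$time_h))
  expect_gt(pk$intensity, traj$I[1])
  # post-peak collapse faster than luciferase inactivation alone
  expect_gt(post_peak_decay(traj), scn$kdL)
})

test_that("poor-medium quorum onset precedes the rich-medium onset", {
  on_rich <- qs_onset_time(rich_traj(), rel_threshold = 0.1)
  on_poor <- qs_onset_time(poor_traj(), rel_threshold = 0.1)
  expect_false(is.na(on_rich))
  expect_false(is.na(on_poor))
  expect_lt(on_poor, on_rich)
})

test_that("recovery harness is a fixed point at truth and deterministic", {
  rep0 <- recovery_experiment(n_rep = 1, seed = 5, start_frac1 = 1,
                              start_frac2 = 1)
  expect_equal(rep0$n_fail, 0L)
  expect_true(all(rep0$per_rep$rel_err < 1e-4))
  rep0b <- recovery_experiment(n_rep = 1, seed = 5, start_frac1 = 1,
                               start_frac2 = 1)
  expect_identical(rep0$per_rep, rep0b$per_rep)
  expect_error(recovery_experiment(n_rep = 0), "n_rep")
})
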