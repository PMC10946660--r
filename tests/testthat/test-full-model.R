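test_that("a sterile flask is invariant and basal relations hold", {
  p <- default_params()
  d <- full_rhs(c(S = 5, N = 0, a = 1.4, A = 0, R = 0.193, L = 0.2), p)
  expect_identical(unname(d[c("S", "N", "A")]), c(0, 0, 0))
  # basal state: A = 0, R at CR/k3, L = 0 -> dR = 0 and dL = 0 (D = 0)
  st <- stationary_states(5, p$energy, p$growth, batch_energy_config(p))
  a_eq <- max(st$value[st$stability == "stable"])
  d <- full_rhs(c(S = 5, N = 1, a = a_eq, A = 0, R = p$qs$CR / p$qs$k3,
                  L = 0), p)
  expect_lt(abs(d[["R"]]), 1e-12)
  expect_identical(unname(d[["L"]]), 0)
  expect_lt(abs(d[["a"]]), 1e-6 / p$scale$eps1)
  expect_error(full_rhs(c(-1, 1, 1, 0, 0.2, 0.2), p), "negative")
})

test_that("compiled and reference right-hand sides integrate identically", {
  scn <- rich_scn()
  t1 <- rich_traj()
  t2 <- simulate_batch(scenario = scn, compiled = FALSE)
  for (v in c("S", "N", "a", "A", "R", "L", "I"))
    expect_lt(max(abs(t1[[v]] - t2[[v]])) / max(t1[[v]]), 1e-6)
})

test_that("trajectories are positive with monotone S, N and A", {
  for (traj in list(rich_traj(), poor_traj())) {
    expect_true(all(as.matrix(traj[, c("S", "N", "a", "A", "R", "L", "I")]) >= 0))
    expect_true(all(diff(traj$S) <= 1e-9))
    expect_true(all(diff(traj$N) >= -1e-9))
    expect_true(all(diff(traj$A) >= -1e-9))
  }
})

test_that("the realized specific growth rate equals fg along the trajectory", {
  p <- default_params()
  traj <- simulate_batch(p, t_grid = seq(0, 6, by = 0.05),
                         scenario = rich_scn())
  n <- nrow(traj)
  lnN <- log(traj$N)
  mu_obs <- (lnN[-1] - lnN[-n]) / diff(traj$time_h)
  mid_fg <- growth_rate((traj$S[-1] + traj$S[-n]) / 2,
                        (traj$a[-1] + traj$a[-n]) / 2, p$growth)
  expect_lt(max(abs(mu_obs - mid_fg) / mid_fg), 1e-3)
})

test_that("without substrate the biomass is frozen and light only decays", {
  scn <- rich_scn()
  p <- update_params(default_params(), c(VL = scn$VL, kdL = scn$kdL))
  traj <- simulate_batch(p, t_grid = seq(0, 8, by = 0.5),
                         init = c(S = 0, N = 0.5, a = 1.4, A = 0,
                                  R = 0.193, L = 0.2))
  expect_lt(diff(range(traj$N)), 1e-8)
  expect_true(all(diff(traj$I) <= 1e-12))
})

test_that("a single-time grid returns the initial state", {
  scn <- rich_scn()
  traj <- simulate_batch(t_grid = 0, scenario = scn)
  expect_equal(nrow(traj), 1L)
  expect_equal(traj$S, scn$S0)
  expect_equal(traj$N, scn$N0)
})

test_that("displaced ATP relaxes to the stable energy-block root well within an hour", {
  p <- default_params()
  scn <- rich_scn()
  cfg <- batch_energy_config(p)
  st <- stationary_states(scn$S0, p$energy, p$growth, cfg)
  a_eq <- max(st$value[st$stability == "stable"])
  init <- default_initial_state(update_params(p, c(VL = scn$VL, kdL = scn$kdL)),
                                scn)
  init[["a"]] <- 0.5 * a_eq
  traj <- simulate_batch(p, t_grid = c(0, 0.2), init = init, cfg = cfg)
  expect_lt(abs(traj$a[2] - a_eq) / a_eq, 0.01)
})

test_that("onset detection handles pinned, stepped and simulated traces", {
  p <- default_params()
  alpha <- p$qs$CR / p$qs$k3
  beta <- p$qs$VR / p$qs$k3
  flat <- data.frame(time_h = 0:10, R = rep(alpha, 11))
  expect_true(is.na(qs_onset_time(flat, p)))
  step <- data.frame(time_h = 0:10, R = c(rep(alpha, 6), rep(alpha + beta, 5)))
  expect_equal(qs_onset_time(step, p, rel_threshold = 0.5), 6)
  expect_error(qs_onset_time(step, p, rel_threshold = 2), "rel_threshold")
  expect_error(qs_onset_time(data.frame(x = 1), p), "columns")
})

test_that("luminescence peak picks the earliest maximum", {
  dec <- data.frame(time_h = 0:5, I = 6:1)
  expect_equal(lum_peak(dec)$time, 0)
  hump <- data.frame(time_h = 0:4, I = c(1, 5, 9, 5, 1))
  expect_equal(lum_peak(hump), list(time = 2, intensity = 9))
  tie <- data.frame(time_h = 0:3, I = c(1, 7, 7, 1))
  expect_equal(lum_peak(tie)$time, 1)
  expect_error(lum_peak(data.frame(time_h = numeric(0), I = numeric(0))),
               "nonempty")
})
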