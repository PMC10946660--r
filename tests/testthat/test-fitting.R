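test_that("the simplex solves convex and Rosenbrock benchmarks", {
  bowl <- function(x) sum((x - c(2, -1, 0.5))^2)
  r <- nelder_mead(bowl, c(0, 0, 0))
  expect_true(r$converged)
  expect_lt(max(abs(r$par - c(2, -1, 0.5))), 1e-6)
  rosen <- function(x) 100 * (x[2] - x[1]^2)^2 + (1 - x[1])^2
  r <- nelder_mead(rosen, c(-1.2, 1))
  expect_lt(max(abs(r$par - c(1, 1))), 1e-4)
  expect_error(nelder_mead(function(x) NaN, 1), "finite")
  expect_error(nelder_mead(bowl, c(NA, 0, 0)), "finite")
})

test_that("the in-package simplex agrees with the stats::optim reference", {
  fn <- function(x) (x[1] - 3)^2 + 2 * (x[2] + 1)^2 + x[1] * x[2] / 10
  ours <- nelder_mead(fn, c(0, 0))
  ref <- optim(c(0, 0), fn, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 5000))
  expect_equal(ours$value, ref$value, tolerance = 1e-6)
  expect_equal(ours$par, ref$par, tolerance = 1e-3)
})

test_that("goal is zero at truth and rises under single-parameter perturbation", {
  obs <- rich_clean()
  spec <- fit_spec(c("Vg", "S0"), obs, scn = rich_scn(),
                   weights = c(od = 1, lum = 0))
  x0 <- log(c(Vg = 2.18, S0 = 10))
  g0 <- goal_function(x0, spec)
  expect_lt(g0, 1e-6)
  expect_gt(goal_function(x0 + c(log(1.1), 0), spec), g0)
  expect_gt(goal_function(x0 + c(0, log(1.1)), spec), g0)
  # out-of-bounds and non-finite candidates get the penalty, not an error
  expect_gte(goal_function(log(c(1e6, 10)), spec), 1e12)
  expect_identical(goal_function(c(NaN, 1), spec), 1e12)
})

test_that("each stage only touches its own block (freeze contract)", {
  obs <- rich_clean()
  base <- default_params()
  ctl <- list(passes = 1L, maxit = 200L)
  s1 <- fit_stage1(obs, base = base, scn = rich_scn(),
                   start = c(Vg = 2.18 * 0.9, Kg = 3.99, S0 = 10, N0 = 3e-5),
                   control = ctl)
  qs_names <- c("VR", "CR", "CA", "k3", "gamma", "KR", "KL")
  expect_identical(flatten_params(s1$params)[qs_names],
                   flatten_params(base)[qs_names])
  s2 <- fit_stage2(obs, s1, free = c("VL", "kdL"), control = ctl)
  eco_names <- c("Vg", "Kg", "Ka", "Ve", "Ke", "Kae", "kd", "k0", "eps2")
  expect_identical(flatten_params(s2$params)[eco_names],
                   flatten_params(s1$params)[eco_names])
  expect_equal(s2$scn$S0, s1$scn$S0)
  expect_error(fit_stage1(obs, free = "VL"), "ecological")
  expect_error(fit_stage2(obs, s1, free = "Vg"), "quorum")
  expect_error(fit_stage1(data.frame(time_h = 1:3)), "od660")
})

test_that("log-transform with bounds suppresses the half-saturation collapse", {
  # data generated in the substrate-saturated regime: Kg is driven toward 0
  scn <- scenario("sat", S0 = 10, N0 = 3e-5, L0 = 0.2, VL = 600, kdL = 0.5,
                  t_grid = seq(0, 10, by = 1))
  p_true <- update_params(default_params(), c(Kg = 1e-6))
  obs <- generate_clean(scn, p_true)
  ctl <- list(passes = 2L, maxit = 400L)
  # unconstrained linear search: the Monod constant collapses by orders of
  # magnitude (the classic pathology of local search on saturated data)
  lin <- fit_stage1(obs, scn = scn, free = "Kg", start = c(Kg = 1),
                    transform = "linear",
                    bounds = cbind(lower = 1e-300, upper = 1e6),
                    control = ctl)
  expect_lt(lin$best_params[["Kg"]], 0.01)
  # default log-transform with positive box bounds: the estimate stays inside
  reg <- fit_stage1(obs, scn = scn, free = "Kg", start = c(Kg = 1),
                    bounds = cbind(lower = 0.5, upper = 50), control = ctl)
  expect_true(reg$best_params[["Kg"]] >= 0.5 && reg$best_params[["Kg"]] <= 50)
})

test_that("multistart is nested-consistent and beats a single start on a bimodal goal", {
  bimod <- function(x) min(sum((x - 2)^2), 0.5 + sum((x + 2)^2))
  wrap <- function(x0) nelder_mead(bimod, x0)
  r1 <- multistart_fit(wrap, c(-2, -2), n_starts = 1, seed = 1)
  single <- wrap(c(-2, -2))
  expect_identical(r1$value, single$value)
  expect_identical(r1$par, single$par)
  r3 <- multistart_fit(wrap, c(-2, -2), n_starts = 3, seed = 1)
  expect_lte(r3$value, r1$value)
  hits <- function(n_starts) sum(vapply(1:50, function(s)
    multistart_fit(wrap, c(-2, -2), n_starts = n_starts, dispersion = 2,
                   seed = s)$value < 0.4, logical(1)))
  expect_gt(hits(20), hits(1))
  expect_error(multistart_fit(wrap, c(0, 0), n_starts = 0), "n_starts")
})

test_that("a short stage-1 fit recovers a single freed growth parameter", {
  obs <- rich_clean()
  s1 <- fit_stage1(obs, scn = rich_scn(), free = "Vg",
                   start = c(Vg = 2.18 * 0.8),
                   control = list(passes = 2L, maxit = 500L))
  expect_lt(abs(s1$best_params[["Vg"]] - 2.18) / 2.18, 0.01)
  expect_true(is.finite(s1$loss))
  expect_gt(s1$n_eval, 0)
})
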