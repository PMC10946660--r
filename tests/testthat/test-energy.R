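test_that("growth rate vanishes without substrate or ATP and has the product form", {
  g <- growth_params(Vg = 2.18, Kg = 3.99, Ka = 0.0033)
  expect_identical(growth_rate(0, 1, g), 0)
  expect_identical(growth_rate(5, 0, g), 0)
  # half-saturation in both factors gives Vg/4
  expect_equal(growth_rate(g$Kg, g$Ka, g), 2.18 * 0.25)
  expect_error(growth_rate(-1, 1, g), "nonnegative")
})

test_that("ATP production is zero at a = 0, saturates at Ve, honors the pool", {
  e <- energy_params(Ve = 3.30)
  cfg <- energy_config(activation_exponent = 1L, pool_size = Inf)
  for (S in c(0, 0.1, 5, 1e4)) expect_identical(atp_production(S, 0, e, cfg), 0)
  expect_equal(atp_production(1e9, 1e9, e, cfg), 3.30, tolerance = 1e-6)
  expect_equal(atp_production(e$Ke, e$Kae, e, cfg), 3.30 * 0.25)
  cfg2 <- energy_config(activation_exponent = 2L, pool_size = Inf)
  expect_equal(atp_production(e$Ke, sqrt(e$Kae), e, cfg2), 3.30 * 0.25)
  # finite pool: production vanishes when all adenylate is charged
  cfgp <- energy_config(pool_size = 1.4)
  expect_identical(atp_production(5, 1.4, e, cfgp), 0)
  expect_identical(atp_production(5, 2.0, e, cfgp), 0)
  expect_gt(atp_production(5, 0.7, e, cfgp), 0)
})

test_that("ATPase saturates at kd and is near-constant for a >> eps2", {
  e <- energy_params(kd = 0.5, eps2 = 0.05)
  expect_identical(atpase_activity(0, e), 0)
  expect_equal(atpase_activity(e$eps2, e), 0.25)
  expect_equal(atpase_activity(10 * e$eps2, e), 0.5 * 10 / 11)
  a <- 100 * e$eps2
  expect_lt(abs(atpase_activity(a, e) - e$kd), e$kd * e$eps2 / a)
})

test_that("death intensity is nonincreasing in ATP with the documented half-point", {
  e <- energy_params()
  a <- seq(0, 10, length.out = 100)
  expect_true(all(diff(death_rate(a, e)) <= 0))
  expect_equal(death_rate(0.1, e, d0 = 0.1, K_d0 = 0.1), 0.05)
  expect_lt(death_rate(1e9, e), 1e-8)
})

test_that("a = 0 is a fixed point of the ATP balance for any substrate", {
  set.seed(11)
  for (i in 1:10) {
    e <- energy_params(Ve = runif(1, 0.5, 5), Ke = runif(1, 0.5, 5),
                       Kae = runif(1, 0.01, 1), kd = runif(1, 0.01, 1),
                       eps2 = runif(1, 0.05, 2))
    g <- growth_params(Vg = runif(1, 0.5, 3))
    cfg <- energy_config(include_growth_cost = i %% 2 == 0,
                         activation_exponent = 1L + i %% 2)
    expect_identical(atp_rate(runif(1, 0, 10), 0, e, g, cfg), 0)
  }
})

test_that("the published case-B rates are positive just above the zero state", {
  d <- energy_demo("B")
  for (S in d$S_grid)
    expect_gt(atp_rate(S, 1e-6, d$energy, d$growth, d$cfg), 0)
})

test_that("the rate is negative at large ATP when production saturates below consumption", {
  # production asymptote Ve*sat(S,Ke) below kd + k0*Vg*sat(S,Kg)
  e <- energy_params(Ve = 1, Ke = 1, Kae = 0.1, kd = 2, eps2 = 0.5)
  g <- growth_params(Vg = 1, Kg = 1)
  cfg <- energy_config(include_growth_cost = TRUE, activation_exponent = 1L)
  expect_lt(atp_rate(5, 1e4, e, g, cfg), 0)
})

test_that("stationary states match a 10x-finer brute-force oracle", {
  set.seed(42)
  for (i in 1:50) {
    # positive parameters, log-uniform over two decades
    lu <- function(lo) 10^runif(1, log10(lo), log10(lo) + 2)
    e <- energy_params(Ve = lu(0.1), Ke = lu(0.1), Kae = lu(0.01),
                       kd = lu(0.05), eps2 = lu(0.05))
    g <- growth_params(Vg = lu(0.1), Kg = lu(0.1), Ka = lu(0.01))
    cfg <- energy_config(include_growth_cost = i %% 2 == 0,
                         activation_exponent = 1L + i %% 2,
                         pool_size = if (i %% 3 == 0) lu(0.5) else Inf)
    S <- lu(0.05)
    st <- stationary_states(S, e, g, cfg, a_max = 4, n_grid = 2000L)
    or <- brute_states(function(a) atp_rate(S, a, e, g, cfg), a_max = 4)
    expect_equal(nrow(st), nrow(or),
                 info = sprintf("draw %d: root count", i))
    expect_equal(st$stability, or$stability,
                 info = sprintf("draw %d: stability labels", i))
    expect_equal(st$value, or$value, tolerance = 1e-6)
    expect_true(0 %in% st$value)
  }
})

test_that("rate keeps a constant sign between consecutive stationary states", {
  d <- energy_demo("A")
  S <- 0.26
  st <- stationary_states(S, d$energy, d$growth, d$cfg, a_max = d$a_max)
  r <- st$value
  for (i in seq_len(length(r) - 1L)) {
    aa <- seq(r[i] + 1e-4, r[i + 1L] - 1e-4, length.out = 200)
    sg <- sign(atp_rate(S, aa, d$energy, d$growth, d$cfg))
    expect_true(all(sg == sg[1]))
  }
  # stability alternates along the root sequence
  expect_identical(st$stability, c("stable", "unstable", "stable"))
})

test_that("closed-form fixed point matches the numeric root (linear activation, no growth cost)", {
  # with n = 1 and no biomass cost, clearing denominators of
  # Ve*sat(S,Ke)*a/(Kae+a) = kd*a/(eps2+a) gives a linear condition in a:
  # a* = (V*eps2 - kd*Kae) / (kd - V), V = Ve*sat(S,Ke)
  e <- energy_params(Ve = 1, Ke = 1, Kae = 0.5, kd = 0.8, eps2 = 2)
  g <- growth_params()
  cfg <- energy_config(include_growth_cost = FALSE, activation_exponent = 1L)
  S <- 1  # V = 0.5 < kd, V*eps2 = 1 > kd*Kae = 0.4
  V <- e$Ve * saturation(S, e$Ke)
  a_star <- (V * e$eps2 - e$kd * e$Kae) / (e$kd - V)
  st <- stationary_states(S, e, g, cfg, a_max = 8)
  pos <- st$value[st$value > 0]
  expect_length(pos, 1L)
  expect_equal(pos, a_star, tolerance = 1e-8)
})

test_that("a zero-substrate scan has only the zero state", {
  d <- energy_demo("B")
  sc <- regime_scan(d$energy, d$growth, d$cfg, S_grid = 0, a_max = d$a_max)
  expect_equal(sc$per_S$n_states, 1L)
  expect_error(regime_scan(d$energy, d$growth, d$cfg, S_grid = numeric(0)),
               "nonempty")
  expect_error(stationary_states(1, d$energy, d$growth, d$cfg, a_max = -1),
               "positive")
})
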