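test_that("dimer quasi-steady state has the collapsed quadratic form", {
  expect_identical(dimer_qss(1, 0, 4), 0)
  expect_identical(dimer_qss(0, 1, 4), 0)
  expect_equal(dimer_qss(1, 1, 4), 0.25)
  expect_error(dimer_qss(1, 1, 0), "positive")
  expect_error(dimer_qss(-1, 1, 1), "nonnegative")
})

test_that("LuxR rate has the basal and saturated fixed points", {
  qs <- demo_qs()
  expect_equal(luxr_rate(qs$CR / qs$k3, 0, qs), 0)
  # saturated fixed point (CR+VR)/k3 in the large-autoinducer limit
  expect_lt(abs(luxr_rate((qs$CR + qs$VR) / qs$k3, 1e8, qs)), 1e-9)
})

test_that("the stationary autoinducer curve inverts the LuxR equation", {
  rp <- demo_rp()
  expect_equal(stationary_autoinducer(0.5, rp), sqrt(0.4 / 0.6) / 0.5,
               tolerance = 1e-12)
  # vanishes at the basal end, diverges at the saturated end
  expect_lt(stationary_autoinducer(rp$alpha + 1e-10, rp), 1e-4)
  expect_gt(stationary_autoinducer(rp$alpha + rp$beta - 1e-10, rp), 1e3)
  expect_error(stationary_autoinducer(rp$alpha, rp), "alpha")
  expect_error(stationary_autoinducer(rp$alpha + rp$beta, rp), "alpha")

  # inverse-function identity across random parameter draws
  set.seed(3)
  for (i in 1:20) {
    qs <- qs_params(VR = 10^runif(1, -1, 1), CR = 10^runif(1, -2.5, -1),
                    k3 = 10^runif(1, -1.5, 0), gamma = 10^runif(1, -1, 1),
                    KR = 10^runif(1, -2, 0))
    rp <- as_reduced(qs)
    Rg <- seq(rp$alpha + 1e-6, rp$alpha + rp$beta - 1e-6, length.out = 200)
    res <- abs(luxr_rate(Rg, stationary_autoinducer(Rg, rp), qs))
    expect_lt(max(res), 1e-9)
  }
})

test_that("branch structure: one state outside the bistable window, three inside", {
  rp <- demo_rp()
  fr <- fold_points(rp)
  expect_true(fr$is_bistable)
  expect_lt(fr$A_switch_down, fr$A_switch_up)
  expect_true(rp$alpha < fr$R_fold_low && fr$R_fold_low < fr$R_fold_high &&
                fr$R_fold_high < rp$alpha + rp$beta)
  A_in <- (fr$A_switch_down + fr$A_switch_up) / 2
  br <- stationary_branches(rp, c(0, 0.9 * fr$A_switch_down, A_in,
                                  1.1 * fr$A_switch_up))
  counts <- table(br$A)
  expect_equal(unname(c(counts)), c(1L, 1L, 3L, 1L))
  # A = 0: single stable basal state at alpha
  b0 <- br[br$A == 0, ]
  expect_equal(b0$R, rp$alpha, tolerance = 1e-6)
  expect_identical(b0$stability, "stable")
  # inside the window: stable/unstable/stable ordered in R
  bi <- br[br$A == A_in, ]
  expect_identical(bi$stability[order(bi$R)], c("stable", "unstable", "stable"))
})

test_that("branches agree with inversion of the stationary curve", {
  rp <- demo_rp()
  br <- stationary_branches(rp, seq(0.5, 3, by = 0.5))
  inside <- br$R > rp$alpha + 1e-9 & br$R < rp$alpha + rp$beta - 1e-9
  expect_gt(sum(inside), 0)
  A_back <- stationary_autoinducer(br$R[inside], rp)
  expect_equal(A_back, br$A[inside], tolerance = 1e-5)
})

test_that("weak induction gives a monotone curve and no bistability", {
  rp <- reduced_qs_params(alpha = 0.1, beta = 0.001, sigma = 1)
  fr <- fold_points(rp)
  expect_false(fr$is_bistable)
  expect_null(fr$A_switch_up)
})

test_that("the up-switch threshold does not increase with induction strength", {
  ups <- vapply(c(1, 2, 4), function(beta)
    fold_points(reduced_qs_params(alpha = 0.1, beta = beta, sigma = 1))$A_switch_up,
    numeric(1))
  expect_true(all(diff(ups) <= 1e-9))
})

test_that("LuxR held below the up-switch stays in the basal basin", {
  qs <- demo_qs()
  rp <- as_reduced(qs)
  fr <- fold_points(rp)
  # far below the window the basal shift is negligible: within 1% of alpha
  path <- data.frame(time = seq(0, 500, by = 1), A = 0.3)
  hl <- hysteresis_loop(qs, path)
  expect_lt(max(abs(hl$R - rp$alpha)) / rp$alpha, 0.01)
  # just below the window: R settles on the low branch, never crossing the fold
  A_hold <- 0.8 * fr$A_switch_down
  hl2 <- hysteresis_loop(qs, data.frame(time = seq(0, 500, by = 1), A = A_hold))
  expect_true(all(hl2$R < fr$R_fold_low))
  low <- stationary_branches(rp, A_hold)
  R_low <- min(low$R[low$stability == "stable"])
  expect_lt(abs(hl2$R[nrow(hl2)] - R_low) / R_low, 1e-3)
})

test_that("a slow triangular autoinducer ramp traces a hysteresis loop", {
  qs <- demo_qs()
  rp <- as_reduced(qs)
  fr <- fold_points(rp)
  run_ramp <- function(Thalf) {
    tt <- seq(0, 2 * Thalf, by = Thalf / 2000)
    path <- data.frame(time = tt, A = 2 * (1 - abs(tt - Thalf) / Thalf))
    hysteresis_loop(qs, path)
  }
  mid <- rp$alpha + 0.5 * rp$beta
  switches <- function(hl) {
    hi <- which(hl$R > mid)
    c(up = hl$A[hi[1]], down = hl$A[hi[length(hi)]])
  }
  h1 <- run_ramp(4000); s1 <- switches(h1)
  h2 <- run_ramp(16000); s2 <- switches(h2)
  # loop area in the (A, R) plane is positive (path dependence)
  area <- function(hl) abs(sum(diff(hl$A) * (hl$R[-1] + hl$R[-nrow(hl)]) / 2))
  expect_gt(area(h1), 0.01)
  # switches happen near the folds, and approach them as the ramp slows
  expect_lt(abs(s2[["up"]] - fr$A_switch_up), abs(s1[["up"]] - fr$A_switch_up))
  expect_lt(abs(s2[["up"]] - fr$A_switch_up), 0.1)
  expect_lt(abs(s2[["down"]] - fr$A_switch_down), 0.05)
})
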