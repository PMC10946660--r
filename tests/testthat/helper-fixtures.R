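# shared fixtures, built once per test run
.fix <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

rich_scn <- function() make_scenario("rich")
poor_scn <- function() make_scenario("poor")

rich_traj <- function() fixture("rich_traj",
  simulate_batch(scenario = rich_scn()))
poor_traj <- function() fixture("poor_traj",
  simulate_batch(scenario = poor_scn()))
rich_clean <- function() fixture("rich_clean", generate_clean(rich_scn()))

# reduced switch parameters of the published stationary-curve regime
demo_rp <- function() reduced_qs_params(alpha = 0.1, beta = 1, sigma = 1)
# a qs_params object reducing exactly to demo_rp()
demo_qs <- function() qs_params(CR = 0.01, k3 = 0.1, VR = 0.1, KR = 1, gamma = 1)

# brute-force stationary-state oracle: dense sign scan at higher resolution
brute_states <- function(rate_fn, a_max, n = 20000L, h = 1e-6) {
  xs <- seq(0, a_max, length.out = n + 1L)
  fs <- vapply(xs, rate_fn, numeric(1))
  roots <- 0
  for (i in 2:(n)) {
    if (fs[i] == 0) { roots <- c(roots, xs[i]); next }
    if (sign(fs[i]) * sign(fs[i + 1L]) < 0)
      roots <- c(roots, uniroot(rate_fn, c(xs[i], xs[i + 1L]), tol = 1e-12)$root)
  }
  roots <- sort(unique(roots))
  roots <- roots[c(TRUE, diff(roots) > 1e-6)]
  stab <- vapply(roots, function(r) {
    above <- rate_fn(min(r + h, a_max))
    below <- if (r - h > 0) rate_fn(r - h) else NA_real_
    if (is.na(below)) { if (above < 0) "stable" else "unstable" }
    else if (below > 0 && above < 0) "stable"
    else if (below < 0 && above > 0) "unstable"
    else if (above < 0) "stable" else "unstable"
  }, character(1))
  data.frame(value = roots, stability = stab)
}
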