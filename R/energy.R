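#' Energy-block rate configuration
#'
#' Structural switches of the ATP balance. `activation_exponent` sets the
#' cooperativity of ATP activation of its own production (`a^n / (Kae + a^n)`,
#' n = 1 or 2). `include_growth_cost` controls whether the balance charges the
#' ATP cost of biomass synthesis (`k0 * fg`). `pool_size` optionally bounds
#' production by a finite adenylate pool: when finite, production carries a
#' factor `max(0, 1 - a/pool_size)` (no free ADP, no ATP synthesis); `Inf`
#' disables the pool, recovering a production rate monotone in `a`.
#'
#' @param include_growth_cost Logical flag.
#' @param activation_exponent Integer, 1 or 2.
#' @param pool_size Positive total adenylate pool, or `Inf` for none.
#' @return Object of class `energy_config`.
#' @export
energy_config <- function(include_growth_cost = TRUE, activation_exponent = 1L,
                          pool_size = Inf) {
  if (!activation_exponent %in% c(1L, 2L))
    stop("energy_config: activation_exponent must be 1 or 2")
  if (!is.logical(include_growth_cost) || is.na(include_growth_cost))
    stop("energy_config: include_growth_cost must be TRUE/FALSE")
  if (!is.numeric(pool_size) || is.na(pool_size) || pool_size <= 0)
    stop("energy_config: pool_size must be positive (possibly Inf)")
  structure(list(include_growth_cost = include_growth_cost,
                 activation_exponent = as.integer(activation_exponent),
                 pool_size = pool_size),
            class = "energy_config")
}

# combined-model default: pool-limited production with the printed k0 cost
batch_energy_config <- function(p) {
  energy_config(include_growth_cost = TRUE, activation_exponent = 1L,
                pool_size = p$energy$a0)
}

#' ATP-dependent biomass synthesis rate
#'
#' `fg(S, a) = Vg * sat(S, Kg) * sat(a, Ka)`: growth requires both substrate
#' and ATP; it vanishes when either is absent.
#'
#' @param S Substrate concentration (nonnegative, vectorized).
#' @param a Intracellular ATP concentration (nonnegative).
#' @param p A [growth_params()] object.
#' @return Specific growth rate (1/h).
#' @export
growth_rate <- function(S, a, p) {
  stopifnot(inherits(p, "growth_params"))
  if (any(S < 0) || any(a < 0)) stop("growth_rate: S and a must be nonnegative")
  p$Vg * saturation(S, p$Kg) * saturation(a, p$Ka)
}

#' ATP production rate
#'
#' Substrate-limited, ATP-activated production
#' `Ve * sat(S, Ke) * a^n/(Kae + a^n)`, optionally throttled by the free
#' fraction of a finite adenylate pool (`cfg$pool_size`). Production is zero
#' at `a = 0` for any substrate level, which makes `a = 0` a fixed point of
#' the ATP balance.
#'
#' @param S Substrate concentration (nonnegative, vectorized).
#' @param a ATP concentration (nonnegative).
#' @param p An [energy_params()] object.
#' @param cfg An [energy_config()].
#' @return Production rate (ATP units/h).
#' @export
atp_production <- function(S, a, p, cfg = energy_config()) {
  stopifnot(inherits(p, "energy_params"), inherits(cfg, "energy_config"))
  if (any(S < 0) || any(a < 0)) stop("atp_production: S and a must be nonnegative")
  an <- if (cfg$activation_exponent == 2L) a^2 else a
  out <- p$Ve * saturation(S, p$Ke) * an / (p$Kae + an)
  out[a == 0] <- 0  # 0/0 guard when Kae + an underflows is moot; explicit zero
  if (is.finite(cfg$pool_size)) out <- out * pmax(0, 1 - a / cfg$pool_size)
  out
}

#' Generalized ATPase activity
#'
#' `kd * sat(a, eps2)`: the lumped draw of all ATP-consuming processes.
#' For `a >> eps2` the activity is within `eps2/a` of `kd` (near-constant
#' load); it drops only at low ATP.
#'
#' @param a ATP concentration (nonnegative, vectorized).
#' @param p An [energy_params()] object.
#' @return Consumption rate.
#' @export
atpase_activity <- function(a, p) {
  stopifnot(inherits(p, "energy_params"))
  if (any(a < 0)) stop("atpase_activity: a must be nonnegative")
  p$kd * saturation(a, p$eps2)
}

#' Death intensity as a function of ATP
#'
#' Nonincreasing in ATP: starved cells die faster. Implemented as
#' `d0 * K_d0 / (K_d0 + a)` with documented defaults. The term is provided
#' for the ecological block in isolation; the combined batch model excludes
#' it (cultures are followed only to the end of the log phase, where
#' mortality is not observable).
#'
#' @param a ATP concentration (nonnegative, vectorized).
#' @param p An [energy_params()] object (unused fields reserved).
#' @param d0 Maximal death intensity (1/h).
#' @param K_d0 ATP level halving the death intensity.
#' @return Death intensity (1/h).
#' @export
death_rate <- function(a, p, d0 = 0.1, K_d0 = 0.1) {
  stopifnot(inherits(p, "energy_params"))
  if (any(a < 0)) stop("death_rate: a must be nonnegative")
  d0 * K_d0 / (K_d0 + a)
}

#' Net rate of ATP concentration change
#'
#' `fE(S, a) - k0 * fg(S, a) - ATPase(a)` (the growth-cost term subject to
#' `cfg$include_growth_cost`). Zero at `a = 0` for every `S`, so the zero
#' state always exists; its stability and the number of positive stationary
#' states depend on the parameter regime (see [regime_scan()]).
#'
#' @param S Substrate concentration.
#' @param a ATP concentration (vectorized).
#' @param p An [energy_params()] object.
#' @param g A [growth_params()] object.
#' @param cfg An [energy_config()].
#' @return Net rate (ATP units/h).
#' @export
atp_rate <- function(S, a, p, g, cfg = energy_config()) {
  prod <- atp_production(S, a, p, cfg)
  cost <- if (cfg$include_growth_cost) p$k0 * growth_rate(S, a, g) else 0
  prod - cost - atpase_activity(a, p)
}

# root refinement by bisection on a bracketing interval
.bisect <- function(f, lo, hi, tol = 1e-10, maxit = 200L) {
  flo <- f(lo)
  for (i in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    if ((hi - lo) < tol) return(mid)
    fm <- f(mid)
    if (fm == 0) return(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

# generic 1-D stationary-state finder: sign-change bracketing on a uniform
# grid + bisection, stability by the sign of the rate on either side
.scan_states <- function(rate_fn, x_max, n_grid, include_zero = TRUE,
                         x_min = 0, dedup = 1e-6, h = 1e-6) {
  xs <- seq(x_min, x_max, length.out = n_grid + 1L)
  fs <- vapply(xs, rate_fn, numeric(1))
  roots <- numeric(0)
  for (i in seq_len(n_grid)) {
    f1 <- fs[i]; f2 <- fs[i + 1L]
    if (is.na(f1) || is.na(f2)) next
    if (f1 == 0 && xs[i] > x_min) { roots <- c(roots, xs[i]); next }
    if (sign(f1) * sign(f2) < 0)
      roots <- c(roots, .bisect(rate_fn, xs[i], xs[i + 1L]))
  }
  if (include_zero) roots <- c(x_min, roots)
  roots <- sort(roots)
  if (length(roots) > 1L)
    roots <- roots[c(TRUE, diff(roots) > dedup)]
  stab <- vapply(roots, function(r) {
    below <- if (r - h > x_min) rate_fn(r - h) else NA_real_
    above <- if (r + h < x_max) rate_fn(r + h) else NA_real_
    if (!is.na(below) && !is.na(above)) {
      if (below > 0 && above < 0) "stable"
      else if (below < 0 && above > 0) "unstable"
      else if (above < 0) "stable" else "unstable"   # tangent: one-sided call
    } else if (is.na(below)) {
      if (above < 0) "stable" else "unstable"        # boundary root at x_min
    } else {
      if (below > 0) "stable" else "unstable"        # boundary root at x_max
    }
  }, character(1))
  data.frame(value = roots, stability = stab, stringsAsFactors = FALSE)
}

#' Stationary states of the fast ATP subsystem
#'
#' Finds all roots of [atp_rate()] in `a` over `[0, a_max]` at fixed
#' substrate, by sign-change bracketing on a uniform grid followed by
#' bisection (absolute tolerance 1e-10, deduplication at 1e-6), and labels
#' each root stable when the rate is positive immediately below and negative
#' immediately above (central difference step 1e-6; tangent roots are called
#' from the one available side). The zero state is always included.
#'
#' @param S Substrate concentration (scalar, nonnegative).
#' @param p An [energy_params()] object.
#' @param g A [growth_params()] object.
#' @param cfg An [energy_config()].
#' @param a_max Upper end of the search interval (default `4 * max(1, a0)`).
#' @param n_grid Number of grid intervals (>= 100).
#' @return data.frame with columns `value`, `stability`.
#' @export
stationary_states <- function(S, p, g, cfg = energy_config(),
                              a_max = 4 * max(1, p$a0), n_grid = 2000L) {
  if (!is.numeric(a_max) || a_max <= 0) stop("stationary_states: a_max must be positive")
  if (n_grid < 100L) stop("stationary_states: n_grid must be >= 100")
  if (S < 0) stop("stationary_states: S must be nonnegative")
  .scan_states(function(a) atp_rate(S, a, p, g, cfg), a_max, as.integer(n_grid))
}

#' Regime scan of the ATP subsystem over substrate levels
#'
#' Summarizes [stationary_states()] across a substrate grid: per-`S` root
#' count, stability of the zero state and the largest stable root, plus a
#' regime summary (maximal root count; whether zero is stable everywhere;
#' whether every positive-substrate level has exactly one stable positive
#' state — the homeostatic regime).
#'
#' @param p,g,cfg As in [stationary_states()].
#' @param S_grid Nonempty vector of nonnegative substrate concentrations.
#' @param a_max,n_grid Search-interval settings.
#' @return Object of class `energy_scan`: list with `per_S` (data.frame) and
#'   `summary` (list).
#' @export
regime_scan <- function(p, g, cfg = energy_config(), S_grid,
                        a_max = 4 * max(1, p$a0), n_grid = 2000L) {
  if (length(S_grid) == 0L) stop("regime_scan: S_grid must be nonempty")
  rows <- lapply(S_grid, function(S) {
    st <- stationary_states(S, p, g, cfg, a_max = a_max, n_grid = n_grid)
    pos_stable <- st$value[st$stability == "stable" & st$value > 0]
    data.frame(S = S,
               n_states = nrow(st),
               zero_stable = st$stability[st$value == 0][1] == "stable",
               n_pos_stable = length(pos_stable),
               largest_stable = if (length(pos_stable)) max(pos_stable) else 0)
  })
  per_S <- do.call(rbind, rows)
  pos <- per_S[per_S$S > 0, , drop = FALSE]
  out <- list(
    per_S = per_S,
    summary = list(
      max_root_count = max(per_S$n_states),
      zero_stable_all = all(per_S$zero_stable),
      zero_unstable_all_positive_S = nrow(pos) > 0 && !any(pos$zero_stable),
      single_positive_stable_all = nrow(pos) > 0 && all(pos$n_pos_stable == 1)))
  class(out) <- "energy_scan"
  out
}

#' @export
print.energy_scan <- function(x, ...) {
  cat("ATP subsystem regime scan over", nrow(x$per_S), "substrate levels\n")
  print(x$per_S, row.names = FALSE)
  cat("max root count:", x$summary$max_root_count,
      "| zero stable at all S:", x$summary$zero_stable_all,
      "| one positive stable state at all S>0:",
      x$summary$single_positive_stable_all, "\n")
  invisible(x)
}

#' Demonstration configurations of the two ATP regimes
#'
#' Two documented parameter/form configurations of the energy block:
#'
#' * Case `"A"` (bistable): quadratic ATP activation (`n = 2`), no
#'   growth-cost term. Depending on substrate the subsystem has either a
#'   single stable zero state or three states (stable zero, unstable
#'   threshold, stable working point). Parameters start from the published
#'   case-A set with the ATPase half-saturation raised to 0.5, the one
#'   adjustment needed for the fold pair to exist within this rate family
#'   (see the methods vignette for the closed-form condition).
#' * Case `"B"` (homeostatic): linear activation (`n = 1`) with the biomass
#'   ATP cost included (`k0 = 0.082`); the zero state is unstable and exactly
#'   one stable positive state exists at every substrate level in the scan
#'   window.
#'
#' @param case `"A"` or `"B"`.
#' @return List with elements `growth`, `energy`, `cfg`, `S_grid`, `a_max`.
#' @export
energy_demo <- function(case = c("A", "B")) {
  case <- match.arg(case)
  if (case == "A") {
    list(growth = growth_params(Vg = 1.22, Kg = 1.94, Ka = 0.01),
         energy = energy_params(Ve = 2, Ke = 1, Kae = 0.2, kd = 0.5,
                                eps2 = 0.5, k0 = 0.082, a0 = 1),
         cfg = energy_config(include_growth_cost = FALSE,
                             activation_exponent = 2L),
         S_grid = c(0.05, 0.12, 0.19, 0.26, 0.30),
         a_max = 10)
  } else {
    list(growth = growth_params(Vg = 2.18, Kg = 4, Ka = 0.004),
         energy = energy_params(Ve = 3.299, Ke = 4, Kae = 0.008, kd = 0.026,
                                eps2 = 0.85, k0 = 0.082, a0 = 1),
         cfg = energy_config(include_growth_cost = TRUE,
                             activation_exponent = 1L),
         S_grid = seq(0.004, 0.032, by = 0.004),
         a_max = 25)
  }
}
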