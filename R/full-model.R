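#' Right-hand side of the combined batch-culture model
#'
#' Reference (pure-R) implementation of the six-variable model coupling the
#' ecological, energy, quorum-sensing and luminescence blocks:
#'
#' * `dS/dt = -eps0 * N * (fE + k0*fg)` — flask substrate consumed by ATP
#'   production and biomass synthesis, with `eps0` converting intracellular
#'   rates to flask concentrations (volume-ratio conservation);
#' * `dN/dt = fg * N` — no death term: cultures are modeled from inoculation
#'   to the end of the log phase only;
#' * `eps1 * da/dt = fE - k0*fg - ATPase(a)` — fast ATP balance;
#' * `dA/dt = CA * N` — background, energy-independent autoinducer release
#'   (medium and intracellular concentrations taken equal);
#' * `eps3 * dR/dt = CR + VR * sat(a, a0) * D/(KR + D) - k3*R` — basal plus
#'   energy-dependent induced LuxR synthesis, `D = (R*A)^2/gamma`;
#' * `eps4 * dL/dt = sat(a, KL) * D/(KR + D) - kdL*L` — energy-dependent
#'   luciferase synthesis sharing the promoter activity, first-order
#'   inactivation.
#'
#' A compiled equivalent is used by [simulate_batch()] by default; this
#' function is the documented reference and is exercised against it in the
#' test suite.
#'
#' @param state Named numeric vector `(S, N, a, A, R, L)`, componentwise
#'   nonnegative (round-off slightly below zero is tolerated and clamped for
#'   rate evaluation).
#' @param p A [full_params()] object.
#' @param cfg An [energy_config()]; default is the combined-model
#'   configuration (linear activation, growth cost on, adenylate pool `a0`).
#' @return Named numeric vector of time derivatives.
#' @export
full_rhs <- function(state, p, cfg = NULL) {
  stopifnot(inherits(p, "full_params"))
  if (is.null(cfg)) cfg <- batch_energy_config(p)
  if (any(state < -1e-6)) stop("full_rhs: state has negative components")
  s <- pmax(as.numeric(state), 0)
  S <- s[1]; N <- s[2]; a <- s[3]; A <- s[4]; R <- s[5]; L <- s[6]
  fe <- atp_production(S, a, p$energy, cfg)
  fg <- growth_rate(S, a, p$growth)
  cost <- if (cfg$include_growth_cost) p$energy$k0 * fg else 0
  D <- dimer_qss(R, A, p$qs$gamma)
  prom <- D / (p$qs$KR + D)
  c(S = -p$scale$eps0 * N * (fe + p$energy$k0 * fg),
    N = fg * N,
    a = (fe - cost - atpase_activity(a, p$energy)) / p$scale$eps1,
    A = p$qs$CA * N,
    R = (p$qs$CR + p$qs$VR * saturation(a, p$energy$a0) * prom -
           p$qs$k3 * R) / p$scale$eps3,
    L = (saturation(a, p$lum$KL) * prom - p$lum$kdL * L) / p$scale$eps4)
}

#' Luminescence intensity observable
#'
#' `I = VL * L * sat(a, KL)`: light output needs both luciferase and energy.
#' The sharp post-peak collapse of culture luminescence arises from the ATP
#' factor, not from luciferase decay.
#'
#' @param L Luciferase amount (nonnegative, vectorized).
#' @param a ATP concentration (nonnegative).
#' @param lum A [lum_params()] object.
#' @return Luminescence intensity.
#' @export
luminescence <- function(L, a, lum) {
  stopifnot(inherits(lum, "lum_params"))
  if (any(L < 0) || any(a < 0)) stop("luminescence: L and a must be nonnegative")
  lum$VL * L * saturation(a, lum$KL)
}

#' Default initial state for a batch scenario
#'
#' Fresh medium: full substrate, small inoculum carrying luciferase from the
#' starter culture, ATP at the reference level `a0`, no autoinducer, LuxR at
#' its basal fixed point `CR/k3`.
#'
#' @param p A [full_params()] object.
#' @param scenario A [make_scenario()] object (supplies `S0`, `N0`, `L0`).
#' @return Named state vector `(S, N, a, A, R, L)`.
#' @export
default_initial_state <- function(p, scenario) {
  stopifnot(inherits(p, "full_params"), inherits(scenario, "medium_scenario"))
  c(S = scenario$S0, N = scenario$N0, a = p$energy$a0, A = 0,
    R = p$qs$CR / p$qs$k3, L = scenario$L0)
}

# parameter vector for the compiled right-hand side (layout in src/qslum_rhs.c)
.compiled_parms <- function(p, cfg) {
  v <- flatten_params(p)
  c(v[c("Vg", "Kg", "Ka", "Ve", "Ke", "Kae", "kd", "eps2", "k0", "a0",
        "VR", "CR", "CA", "k3", "gamma", "KR", "KL",
        "eps0", "eps1", "eps3", "eps4")],
    nact = cfg$activation_exponent,
    gcost = as.numeric(cfg$include_growth_cost),
    pool = if (is.finite(cfg$pool_size)) cfg$pool_size else -1,
    kdL = v[["kdL"]],
    reserved = 0)
}

#' Integrate the combined batch-culture model
#'
#' Solves the stiff six-variable system with `deSolve::ode` (lsoda; the
#' `eps1 = 0.001` ATP time scale makes the system stiff) and appends the
#' luminescence observable. Uses the compiled right-hand side by default;
#' `compiled = FALSE` switches to the pure-R reference [full_rhs()].
#'
#' @param p A [full_params()] object.
#' @param t_grid Strictly increasing output times (h).
#' @param init Named initial state; defaults to
#'   [default_initial_state()] when `scenario` is given.
#' @param scenario Optional [make_scenario()]; its `VL`/`kdL` override the
#'   luminescence block and its `S0`/`N0`/`L0` seed the initial state.
#' @param cfg An [energy_config()]; default [batch-model configuration]
#'   (linear activation, growth cost, adenylate pool `a0`).
#' @param control List: `rtol` (default 1e-8), `atol` (1e-10), `method`
#'   (`"lsoda"`).
#' @param compiled Use the compiled right-hand side (default `TRUE`).
#' @return Object of class `qs_trajectory`: data.frame with columns
#'   `time_h, S, N, a, A, R, L, I` (outputs clipped at zero) and attributes
#'   `params`, `cfg`, `scenario`.
#' @export
simulate_batch <- function(p = default_params(), t_grid = seq(0, 16, by = 0.5),
                           init = NULL, scenario = NULL, cfg = NULL,
                           control = list(), compiled = TRUE) {
  stopifnot(inherits(p, "full_params"))
  ctl <- modifyList(list(rtol = 1e-8, atol = 1e-10, method = "lsoda"), control)
  if (any(diff(t_grid) <= 0)) stop("simulate_batch: t_grid must be strictly increasing")
  if (!is.null(scenario)) {
    stopifnot(inherits(scenario, "medium_scenario"))
    p <- update_params(p, c(VL = scenario$VL, kdL = scenario$kdL))
    if (is.null(init)) init <- default_initial_state(p, scenario)
  }
  if (is.null(init)) stop("simulate_batch: provide init or scenario")
  if (any(init < 0)) stop("simulate_batch: initial state must be nonnegative")
  if (is.null(cfg)) cfg <- batch_energy_config(p)
  y0 <- setNames(as.numeric(init), c("S", "N", "a", "A", "R", "L"))
  if (length(t_grid) == 1L) {
    # integration starts at t_grid[1]; a single output time is the initial state
    d <- as.data.frame(as.list(c(time_h = t_grid, y0)))
    d$I <- luminescence(d$L, d$a, p$lum)
    return(structure(d, class = c("qs_trajectory", "data.frame"),
                     params = p, cfg = cfg, scenario = scenario))
  }
  o <- if (compiled) {
    deSolve::ode(y0, t_grid, func = "qslum_derivs",
                 parms = .compiled_parms(p, cfg), dllname = "qslum",
                 initfunc = "qslum_initmod", method = ctl$method,
                 rtol = ctl$rtol, atol = ctl$atol)
  } else {
    deSolve::ode(y0, t_grid, function(t, y, parms) list(unname(full_rhs(y, p, cfg))),
                 parms = NULL, method = ctl$method, rtol = ctl$rtol, atol = ctl$atol)
  }
  if (nrow(o) < length(t_grid))
    stop(sprintf("simulate_batch: integration failed at t = %.4g h", o[nrow(o), 1]))
  d <- as.data.frame(o)
  names(d) <- c("time_h", "S", "N", "a", "A", "R", "L")
  for (cl in c("S", "N", "a", "A", "R", "L")) d[[cl]] <- pmax(d[[cl]], 0)
  d$I <- luminescence(d$L, d$a, p$lum)
  structure(d, class = c("qs_trajectory", "data.frame"),
            params = p, cfg = cfg, scenario = scenario)
}

#' Quorum-sensing onset time of a trajectory
#'
#' First sampled time at which the LuxR trace exceeds
#' `alpha + rel_threshold * beta` (`alpha = CR/k3`, `beta = VR/k3`).
#' Note that with energy-dependent induction the high-LuxR plateau sits
#' below `alpha + beta` (the ATP factor caps the effective amplitude), so
#' scenario comparisons in this package use `rel_threshold = 0.1`.
#'
#' @param traj A `qs_trajectory` (or any data.frame with `time_h` and `R`).
#' @param p Parameters supplying `alpha` and `beta`; defaults to the
#'   trajectory's own.
#' @param rel_threshold Fraction of the nominal induction amplitude, in (0,1).
#' @return Onset time in hours, or `NA` if the threshold is never exceeded.
#' @export
qs_onset_time <- function(traj, p = attr(traj, "params"), rel_threshold = 0.5) {
  if (!is.data.frame(traj) || !all(c("time_h", "R") %in% names(traj)))
    stop("qs_onset_time: traj must have columns time_h and R")
  if (!is.numeric(rel_threshold) || rel_threshold <= 0 || rel_threshold >= 1)
    stop("qs_onset_time: rel_threshold must be in (0, 1)")
  if (is.null(p)) stop("qs_onset_time: parameters required")
  alpha <- p$qs$CR / p$qs$k3
  beta <- p$qs$VR / p$qs$k3
  i <- which(traj$R > alpha + rel_threshold * beta)
  if (length(i) == 0L) NA_real_ else traj$time_h[i[1]]
}

#' Luminescence peak of a trajectory
#'
#' @param traj A `qs_trajectory` (or data.frame with `time_h` and `I`).
#' @return List with `time` and `intensity` of the maximum of the
#'   luminescence trace; ties broken to the earliest time.
#' @export
lum_peak <- function(traj) {
  if (!is.data.frame(traj) || nrow(traj) == 0L ||
      !all(c("time_h", "I") %in% names(traj)))
    stop("lum_peak: traj must be a nonempty data.frame with time_h and I")
  i <- which.max(traj$I)  # which.max returns the first maximum
  list(time = traj$time_h[i], intensity = traj$I[i])
}

#' Post-peak luminescence decay rate
#'
#' Log-linear decay rate of the luminescence trace over a window after the
#' peak, for comparison with the luciferase inactivation rate `kdL`: a decay
#' faster than `kdL` cannot be explained by luciferase loss alone and
#' reflects the collapse of the energy factor.
#'
#' @param traj A `qs_trajectory`.
#' @param window_h Length of the post-peak window (h).
#' @param floor Intensities at or below this are excluded.
#' @return Decay rate (1/h, positive = decaying); `NA` if fewer than two
#'   usable points.
#' @export
post_peak_decay <- function(traj, window_h = 1.5, floor = 1e-12) {
  pk <- lum_peak(traj)
  d <- traj[traj$time_h >= pk$time & traj$time_h <= pk$time + window_h &
              traj$I > floor, c("time_h", "I")]
  if (nrow(d) < 2L) return(NA_real_)
  -unname(coef(lm(log(I) ~ time_h, data = d))[2])
}

#' Fast-slow consistency of the ATP trace
#'
#' With `eps1` small, ATP is the fast variable and should track the stable
#' stationary state of the energy block evaluated at the instantaneous
#' substrate level. For every sample after an initial boundary layer this
#' computes the relative deviation between `a(t)` and the largest stable
#' root: relative to the root when a positive root exists, relative to `a0`
#' when the only stable state is zero (where a ratio would be ill-defined).
#'
#' Tracking holds outside *layers*: besides the initial boundary layer, a
#' short interior layer forms when substrate exhaustion makes the stationary
#' root itself move quickly (the luminescence collapse); samples where the
#' root moved by more than `layer_tol` relative to the previous sample are
#' flagged and excluded from `max_rel` (they are reported separately).
#'
#' @param traj A `qs_trajectory` carrying its `params`/`cfg` attributes.
#' @param after Length of the discarded initial layer (h).
#' @param n_grid Root-finder grid size per sample.
#' @param layer_tol Relative root motion per sample above which a sample is
#'   treated as part of an interior layer.
#' @return List with `max_rel` (maximal relative deviation outside layers),
#'   `max_rel_all` (including layer samples) and `per_time`
#'   (data.frame `time_h`, `a`, `a_root`, `rel`, `layer`).
#' @export
atp_tracking_error <- function(traj, after = 0.5, n_grid = 2000L,
                               layer_tol = 0.2) {
  p <- attr(traj, "params"); cfg <- attr(traj, "cfg")
  if (is.null(p) || is.null(cfg))
    stop("atp_tracking_error: trajectory lacks params/cfg attributes")
  d <- traj[traj$time_h >= after, ]
  a0 <- p$energy$a0
  rows <- lapply(seq_len(nrow(d)), function(i) {
    st <- stationary_states(d$S[i], p$energy, p$growth, cfg,
                            a_max = 4 * max(1, a0), n_grid = n_grid)
    stab <- st$value[st$stability == "stable"]
    r <- max(stab)
    rel <- if (r > 0.01 * a0) abs(d$a[i] - r) / r else abs(d$a[i] - r) / a0
    data.frame(time_h = d$time_h[i], a = d$a[i], a_root = r, rel = rel)
  })
  per_time <- do.call(rbind, rows)
  root_move <- c(0, abs(diff(per_time$a_root)) /
                   pmax(per_time$a_root[-1], 0.01 * a0))
  per_time$layer <- root_move > layer_tol
  list(max_rel = max(per_time$rel[!per_time$layer]),
       max_rel_all = max(per_time$rel),
       per_time = per_time)
}

#' @export
plot.qs_trajectory <- function(x, which = c("biomass", "luminescence"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  op <- par(mfrow = c(1, length(which))); on.exit(par(op))
  if ("biomass" %in% which)
    plot(x$time_h, x$N, type = "l", xlab = "time (h)", ylab = "biomass N", ...)
  if ("luminescence" %in% which)
    plot(x$time_h, x$I, type = "l", xlab = "time (h)",
         ylab = "luminescence I", ...)
  invisible(x)
}
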