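# names that live on the scenario rather than the parameter object
.scenario_names <- c("S0", "N0", "L0")

#' Specification of a model fit
#'
#' Bundles everything the goal function needs: the freed parameter names
#' (model parameters and/or the scenario quantities `S0`, `N0`, `L0`), their
#' positive box bounds, the parameter transform, the observed table, series
#' weights and loss scales, the frozen base parameters and scenario, and the
#' solver settings used during fitting.
#'
#' @param free Character vector of freed names.
#' @param data data.frame with `time_h` and `od660` and/or `lum`.
#' @param base Frozen [full_params()] supplying every non-freed value.
#' @param scn A [make_scenario()] object (initial conditions, `VL`, `kdL`).
#' @param start Named start values for the freed names (natural scale);
#'   default: current base/scenario values.
#' @param bounds Two-column matrix (`lower`, `upper`) with one row per freed
#'   name; default `start/100` to `start*100`.
#' @param transform `"log"` (default: optimization in log space, which
#'   enforces positivity and suppresses the collapse of half-saturation
#'   constants toward zero) or `"linear"`.
#' @param weights Named weights for the `od` (linear scale) and `lum`
#'   (log10 scale, floor 1e-12) residual series.
#' @param cfg Optional [energy_config()].
#' @param control Solver settings for goal evaluations (`rtol` 1e-8,
#'   `atol` 1e-10, matching [simulate_batch()]: the luminescence collapse is
#'   steep, and on its log scale the residuals must not be dominated by
#'   integration error).
#' @return Object of class `fit_spec`.
#' @export
fit_spec <- function(free, data, base = default_params(),
                     scn = make_scenario("rich"), start = NULL, bounds = NULL,
                     transform = c("log", "linear"),
                     weights = c(od = 1, lum = 1), cfg = NULL,
                     control = list()) {
  transform <- match.arg(transform)
  if (length(free) == 0L) stop("fit_spec: free must be nonempty")
  known <- c(.param_names, .scenario_names)
  if (any(!free %in% known))
    stop("fit_spec: unknown names: ", paste(setdiff(free, known), collapse = ", "))
  if (!is.data.frame(data) || !"time_h" %in% names(data) ||
      any(diff(data$time_h) <= 0))
    stop("fit_spec: data must have strictly increasing time_h")
  base <- update_params(base, c(VL = scn$VL, kdL = scn$kdL))
  cur <- c(flatten_params(base), S0 = scn$S0, N0 = scn$N0, L0 = scn$L0)
  if (is.null(start)) start <- cur[free]
  start <- start[free]
  if (any(is.na(start)) || any(start <= 0))
    stop("fit_spec: start values must be positive and cover all freed names")
  if (is.null(bounds))
    bounds <- cbind(lower = start / 100, upper = start * 100)
  if (any(bounds[, 1] <= 0) || any(bounds[, 2] <= bounds[, 1]))
    stop("fit_spec: bounds must be positive intervals")
  ctl <- modifyList(list(rtol = 1e-8, atol = 1e-10), control)
  structure(list(free = free, data = data, base = base, scn = scn,
                 start = start, bounds = bounds, transform = transform,
                 weights = weights, cfg = cfg, control = ctl),
            class = "fit_spec")
}

.to_opt <- function(x, spec) if (spec$transform == "log") log(x) else x
.from_opt <- function(x, spec) {
  out <- if (spec$transform == "log") exp(x) else x
  setNames(out, spec$free)
}

# build candidate params + scenario from a natural-scale named vector;
# VL/kdL are per-medium, so they are routed through the scenario as well
# (simulate_batch takes them from there)
.apply_free <- function(v, spec) {
  scn <- spec$scn
  scn$VL <- spec$base$lum$VL
  scn$kdL <- spec$base$lum$kdL
  for (nm in intersect(names(v), c(.scenario_names, "VL", "kdL")))
    scn[[nm]] <- v[[nm]]
  pnames <- setdiff(names(v), .scenario_names)
  p <- update_params(spec$base, v[pnames])
  list(p = p, scn = scn)
}

#' Weighted least-squares goal of a candidate parameter vector
#'
#' Simulates the model with the freed values substituted and returns the
#' weighted sum of squared residuals: biomass (`od660`) on the linear scale,
#' luminescence on the log10 scale with floor 1e-12 (its dynamic range
#' spans orders of magnitude). Candidates outside the transformed bounds, or
#' for which the integration fails, receive a large finite penalty
#' (`1e12` plus the squared distance to the bounds) rather than an error,
#' so the simplex can recover.
#'
#' @param x Numeric vector in the spec's transform space.
#' @param spec A [fit_spec()] object.
#' @return Nonnegative goal value.
#' @export
goal_function <- function(x, spec) {
  stopifnot(inherits(spec, "fit_spec"))
  lo <- .to_opt(spec$bounds[, 1], spec); hi <- .to_opt(spec$bounds[, 2], spec)
  if (any(!is.finite(x))) return(1e12)
  viol <- pmax(lo - x, 0) + pmax(x - hi, 0)
  if (any(viol > 0)) return(1e12 + sum(viol^2))
  v <- .from_opt(x, spec)
  cand <- tryCatch(.apply_free(v, spec), error = function(e) NULL)
  if (is.null(cand)) return(1e12)
  sim <- tryCatch(
    simulate_batch(cand$p, t_grid = spec$data$time_h, scenario = cand$scn,
                   cfg = spec$cfg,
                   control = list(rtol = spec$control$rtol,
                                  atol = spec$control$atol)),
    error = function(e) NULL)
  if (is.null(sim)) return(1e12)
  loss <- 0
  w <- spec$weights
  if ("od660" %in% names(spec$data) && isTRUE(w[["od"]] > 0))
    loss <- loss + w[["od"]] * sum((sim$N - spec$data$od660)^2)
  if ("lum" %in% names(spec$data) && isTRUE(w[["lum"]] > 0))
    loss <- loss + w[["lum"]] *
      sum((log10(pmax(sim$I, 1e-12)) - log10(pmax(spec$data$lum, 1e-12)))^2)
  if (!is.finite(loss)) return(1e12)
  loss
}

# shared driver for both stages
.run_fit <- function(spec, n_starts, seed, control, stage) {
  ctl <- modifyList(list(maxit = 2000L, passes = 8L, steps = c(0.3, 0.05),
                         stop_loss = 1e-6, dispersion = 0.2,
                         profile_par = NULL), control)
  goal <- function(x) goal_function(x, spec)
  x0 <- .to_opt(spec$start, spec)
  use_prof <- !is.null(ctl$profile_par) && ctl$profile_par %in% spec$free &&
    length(spec$free) >= 2L && spec$transform == "log"
  fit1 <- if (use_prof)
    function(x) nm_profiled(goal, x, match(ctl$profile_par, spec$free), ctl)
  else
    function(x) nm_restarted(goal, x, ctl)
  res <- if (n_starts > 1L)
    multistart_fit(fit1, x0, n_starts = n_starts,
                   dispersion = ctl$dispersion, seed = seed)
  else c(fit1(x0), list(start_index = 1L, all_losses = NULL))
  est <- .from_opt(res$par, spec)
  cand <- .apply_free(est, spec)
  structure(list(stage = stage, free = spec$free, best_params = est,
                 params = cand$p, scn = cand$scn, loss = res$value,
                 n_eval = res$n_eval, converged = res$converged,
                 trace = res$trace, start_index = res$start_index,
                 all_losses = res$all_losses, spec = spec),
            class = "qs_stage_fit")
}

#' @export
print.qs_stage_fit <- function(x, ...) {
  cat(sprintf("Stage-%s fit: loss = %.6g after %d evaluations (%s)\n",
              x$stage, x$loss, x$n_eval,
              if (x$converged) "converged" else "iteration limit"))
  print(signif(x$best_params, 6))
  invisible(x)
}

#' Stage 1: fit the ecological/energy block to biomass data
#'
#' Adjusts growth and initial-condition parameters against the
#' optical-density series (linear least squares); quorum-sensing and
#' luminescence parameters are frozen. The default free set
#' `{Vg, Kg, S0, N0}` is the subset identifiable from a biomass curve alone;
#' any subset of the ecological/energy names
#' `{Vg, Kg, Ka, Ve, Ke, Kae, kd, k0, eps2, S0, N0}` may be freed.
#'
#' @param data data.frame with columns `time_h` and `od660`.
#' @param base Frozen [full_params()].
#' @param scn Scenario providing initial conditions and per-medium values.
#' @param free Names to adjust.
#' @param start Optional named start values (natural scale).
#' @param n_starts Multistart count (default 1).
#' @param seed Seed for multistart jitter.
#' @param control List merged over the defaults: `maxit`, `passes`, `steps`
#'   (restart schedule of the simplex), `stop_loss`, `dispersion`
#'   (multistart jitter), `profile_par` (name of one freed parameter to
#'   profile by golden-section search with simplex subfits; stage 2 defaults
#'   to `"VR"`), plus solver `rtol`/`atol`.
#' @param transform `"log"` (default) or `"linear"`.
#' @param bounds Optional bounds matrix (see [fit_spec()]).
#' @return A `qs_stage_fit` object.
#' @export
fit_stage1 <- function(data, base = default_params(),
                       scn = make_scenario("rich"),
                       free = c("Vg", "Kg", "S0", "N0"), start = NULL,
                       n_starts = 1L, seed = 1L, control = list(),
                       transform = "log", bounds = NULL) {
  if (!"od660" %in% names(data)) stop("fit_stage1: data needs an od660 column")
  allowed <- c("Vg", "Kg", "Ka", "Ve", "Ke", "Kae", "kd", "k0", "eps2",
               "S0", "N0")
  if (any(!free %in% allowed))
    stop("fit_stage1: stage-1 free names must be ecological/energy: ",
         paste(setdiff(free, allowed), collapse = ", "))
  spec <- fit_spec(free, data, base = base, scn = scn, start = start,
                   bounds = bounds, transform = transform,
                   weights = c(od = 1, lum = 0), control = control)
  .run_fit(spec, n_starts, seed, control, stage = "1 (ecology/energy)")
}

#' Stage 2: fit the quorum/luminescence block to luminescence data
#'
#' Adjusts quorum-sensing and luminescence parameters against the
#' luminescence series (log10 least squares) with every ecological and
#' energy value frozen at the stage-1 result. Default free set
#' `{VR, CA, VL, kdL, L0}`; any subset of
#' `{VR, CR, CA, k3, gamma, KR, KL, VL, kdL, L0}` may be freed.
#'
#' @param data data.frame with columns `time_h` and `lum`.
#' @param stage1 A stage-1 `qs_stage_fit` (its fitted parameters and
#'   scenario are frozen), or a list with elements `params` and `scn`.
#' @inheritParams fit_stage1
#' @return A `qs_stage_fit` object.
#' @export
fit_stage2 <- function(data, stage1, free = c("VR", "CA", "VL", "kdL", "L0"),
                       start = NULL, n_starts = 1L, seed = 1L,
                       control = list(), transform = "log", bounds = NULL) {
  if (!"lum" %in% names(data)) stop("fit_stage2: data needs a lum column")
  if (is.null(stage1$params) || is.null(stage1$scn))
    stop("fit_stage2: stage1 must provide fitted params and scenario")
  allowed <- c("VR", "CR", "CA", "k3", "gamma", "KR", "KL", "VL", "kdL", "L0")
  if (any(!free %in% allowed))
    stop("fit_stage2: stage-2 free names must be quorum/luminescence: ",
         paste(setdiff(free, allowed), collapse = ", "))
  # the induced-synthesis rate VR trades off against CA along a shallow
  # valley; profile it by default (disable with control$profile_par = NULL)
  if (!"profile_par" %in% names(control) && "VR" %in% free &&
      identical(transform, "log"))
    control$profile_par <- "VR"
  spec <- fit_spec(free, data, base = stage1$params, scn = stage1$scn,
                   start = start, bounds = bounds, transform = transform,
                   weights = c(od = 0, lum = 1), control = control)
  .run_fit(spec, n_starts, seed, control, stage = "2 (quorum/luminescence)")
}
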