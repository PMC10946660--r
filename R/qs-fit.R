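#' Fit the batch-culture quorum-sensing model to observed time series
#'
#' The main modelling entry point: runs the two-stage estimation procedure —
#' stage 1 adjusts the ecological/energy block against the biomass (OD)
#' series, stage 2 adjusts the quorum-sensing/luminescence block against the
#' luminescence series with the stage-1 values frozen — and returns a fitted
#' model object with the usual methods (`print`, `summary`, `coef`,
#' `predict`, `residuals`, `plot`, `simulate`).
#'
#' @param data data.frame with columns `time_h`, `od660` and (for stage 2)
#'   `lum`.
#' @param scn Scenario supplying initial conditions and per-medium values;
#'   default the rich preset.
#' @param base Frozen base parameters.
#' @param stage1_free,stage2_free Freed parameter names per stage (see
#'   [fit_stage1()], [fit_stage2()]).
#' @param stage1_start,stage2_start Optional named start values.
#' @param n_starts Multistart count applied to both stages.
#' @param seed Seed for multistart jitter.
#' @param control Fit control list (see [fit_stage1()]).
#' @return Object of class `qs_fit`.
#' @examples
#' \donttest{
#' scn <- make_scenario("rich")
#' obs <- generate_clean(scn)
#' fit <- qs_fit(obs, scn, control = list(passes = 2L))
#' coef(fit)
#' }
#' @export
qs_fit <- function(data, scn = make_scenario("rich"), base = default_params(),
                   stage1_free = c("Vg", "Kg", "S0", "N0"),
                   stage2_free = c("VR", "CA", "VL", "kdL", "L0"),
                   stage1_start = NULL, stage2_start = NULL,
                   n_starts = 1L, seed = 1L, control = list()) {
  cl <- match.call()
  if (!"od660" %in% names(data))
    stop("qs_fit: data needs an od660 column for stage 1")
  s1 <- fit_stage1(data, base = base, scn = scn, free = stage1_free,
                   start = stage1_start, n_starts = n_starts, seed = seed,
                   control = control)
  s2 <- NULL
  if ("lum" %in% names(data))
    s2 <- fit_stage2(data, s1, free = stage2_free, start = stage2_start,
                     n_starts = n_starts, seed = seed + 1L, control = control)
  final <- if (is.null(s2)) s1 else s2
  traj <- simulate_batch(final$params, t_grid = data$time_h,
                         scenario = final$scn)
  structure(list(call = cl, data = data, scn = final$scn,
                 params = final$params, stage1 = s1, stage2 = s2,
                 trajectory = traj),
            class = "qs_fit")
}

#' @export
print.qs_fit <- function(x, ...) {
  cat("Two-stage batch-culture quorum-sensing model fit\n")
  cat("Scenario:", x$scn$name, "|", nrow(x$data), "observations\n")
  cat(sprintf("Stage 1 loss (OD, linear): %.6g\n", x$stage1$loss))
  if (!is.null(x$stage2))
    cat(sprintf("Stage 2 loss (lum, log10): %.6g\n", x$stage2$loss))
  cat("Fitted parameters:\n")
  print(signif(coef(x), 6))
  invisible(x)
}

#' @export
coef.qs_fit <- function(object, ...) {
  out <- object$stage1$best_params
  if (!is.null(object$stage2)) out <- c(out, object$stage2$best_params)
  out
}

#' @export
summary.qs_fit <- function(object, ...) {
  res <- residuals(object)
  s <- list(call = object$call, scenario = object$scn$name,
            n_obs = nrow(object$data), coef = coef(object),
            stage1_loss = object$stage1$loss,
            stage2_loss = if (!is.null(object$stage2)) object$stage2$loss else NA,
            stage1_evals = object$stage1$n_eval,
            stage2_evals = if (!is.null(object$stage2)) object$stage2$n_eval else NA,
            rmse_od = sqrt(mean(res$od^2)),
            rmse_log10_lum = if (!is.null(res$lum)) sqrt(mean(res$lum^2)) else NA,
            onset_h = qs_onset_time(object$trajectory, object$params,
                                    rel_threshold = 0.1),
            peak = lum_peak(object$trajectory))
  class(s) <- "summary.qs_fit"
  s
}

#' @export
print.summary.qs_fit <- function(x, ...) {
  cat("Two-stage quorum-sensing model fit —", x$scenario, "scenario,",
      x$n_obs, "observations\n\n")
  cat("Coefficients:\n"); print(signif(x$coef, 6))
  cat(sprintf("\nStage 1: loss %.4g (%d evals) | Stage 2: loss %.4g (%d evals)\n",
              x$stage1_loss, x$stage1_evals, x$stage2_loss, x$stage2_evals))
  cat(sprintf("RMSE: OD %.4g | log10 luminescence %.4g\n",
              x$rmse_od, x$rmse_log10_lum))
  cat(sprintf("Fitted QS onset: %.1f h | luminescence peak: %.1f h (I = %.4g)\n",
              x$onset_h, x$peak$time, x$peak$intensity))
  invisible(x)
}

#' Predict observables from a fitted model
#'
#' @param object A `qs_fit` object.
#' @param newtimes Optional vector of times (h); defaults to the observed
#'   grid.
#' @param ... Unused.
#' @return data.frame with columns `time_h`, `od660`, `lum`.
#' @export
predict.qs_fit <- function(object, newtimes = NULL, ...) {
  tt <- if (is.null(newtimes)) object$data$time_h else newtimes
  traj <- simulate_batch(object$params, t_grid = tt, scenario = object$scn)
  data.frame(time_h = traj$time_h, od660 = traj$N, lum = traj$I)
}

#' @export
fitted.qs_fit <- function(object, ...) predict(object)

#' Residuals of a fitted model
#'
#' OD residuals on the linear scale, luminescence residuals on the log10
#' scale (the scales the two fitting stages use).
#'
#' @param object A `qs_fit` object.
#' @param ... Unused.
#' @return List with components `od` and (when luminescence was fitted)
#'   `lum`.
#' @export
residuals.qs_fit <- function(object, ...) {
  pred <- predict(object)
  out <- list(od = object$data$od660 - pred$od660)
  if ("lum" %in% names(object$data))
    out$lum <- log10(pmax(object$data$lum, 1e-12)) -
      log10(pmax(pred$lum, 1e-12))
  out
}

#' @export
plot.qs_fit <- function(x, ...) {
  pred <- predict(x, newtimes = seq(min(x$data$time_h), max(x$data$time_h),
                                    length.out = 200))
  op <- par(mfrow = c(1, 2)); on.exit(par(op))
  plot(x$data$time_h, x$data$od660, xlab = "time (h)", ylab = "OD660 (a.u.)",
       main = "biomass", ...)
  lines(pred$time_h, pred$od660)
  if ("lum" %in% names(x$data)) {
    plot(x$data$time_h, pmax(x$data$lum, 1e-12), log = "y", xlab = "time (h)",
         ylab = "luminescence (RLU)", main = "luminescence", ...)
    lines(pred$time_h, pmax(pred$lum, 1e-12))
  }
  invisible(x)
}

#' Simulate noisy datasets from a fitted model
#'
#' Parametric-bootstrap style: simulates the fitted model on the observed
#' grid and applies the given observation-noise model.
#'
#' @param object A `qs_fit` object.
#' @param nsim Number of datasets.
#' @param seed Integer seed.
#' @param noise A [noise_config()]; its seed is overridden per draw.
#' @param ... Unused.
#' @return List of `nsim` data.frames.
#' @export
simulate.qs_fit <- function(object, nsim = 1, seed = 1L,
                            noise = noise_config(lum_cv = 0.05), ...) {
  clean <- predict(object)
  lapply(seq_len(nsim), function(i)
    add_noise(clean, noise_config(noise$lum_cv, noise$od_sd,
                                  seed = seed + i - 1L)))
}
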