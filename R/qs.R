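#' Quasi-steady-state dimer concentration
#'
#' Concentration of the transcription-activating (LuxR-autoinducer) dimer
#' when both binding steps are at quasi-steady state:
#' `D = (R*A)^2 / gamma`, with the composite constant `gamma` absorbing the
#' monomer- and dimer-binding equilibria.
#'
#' @param R LuxR concentration (nonnegative, vectorized).
#' @param A Autoinducer concentration (nonnegative).
#' @param gamma Positive composite dimerization constant.
#' @return Dimer concentration.
#' @export
dimer_qss <- function(R, A, gamma) {
  if (!is.numeric(gamma) || gamma <= 0) stop("dimer_qss: gamma must be positive")
  if (any(R < 0) || any(A < 0)) stop("dimer_qss: R and A must be nonnegative")
  (R * A)^2 / gamma
}

#' Rate of change of LuxR at fixed autoinducer level
#'
#' The reduced LuxR equation with the autoinducer treated as an external
#' parameter: basal plus dimer-activated synthesis minus first-order loss,
#' `CR + VR * D/(KR + D) - k3 * R` with `D = dimer_qss(R, A, gamma)`.
#' At `A = 0` the unique fixed point is the basal level `R = CR/k3`.
#'
#' @param R LuxR concentration (nonnegative, vectorized).
#' @param A Autoinducer concentration (nonnegative).
#' @param qs A [qs_params()] object.
#' @return dR/dt.
#' @export
luxr_rate <- function(R, A, qs) {
  stopifnot(inherits(qs, "qs_params"))
  D <- dimer_qss(R, A, qs$gamma)
  qs$CR + qs$VR * D / (qs$KR + D) - qs$k3 * R
}

#' Stationary autoinducer level as an explicit function of LuxR
#'
#' Inverts the stationary condition of the reduced LuxR equation:
#' `A(R) = sqrt(sigma * (R - alpha) / (alpha + beta - R)) / R`, defined on
#' the open interval `alpha < R < alpha + beta`. `A(R) -> 0` as
#' `R -> alpha+` and diverges as `R -> (alpha + beta)-`.
#'
#' @param R LuxR value(s) strictly inside `(alpha, alpha + beta)`.
#' @param rp A [reduced_qs_params()] object.
#' @return Stationary autoinducer concentration(s).
#' @examples
#' rp <- reduced_qs_params(alpha = 0.1, beta = 1, sigma = 1)
#' stationary_autoinducer(0.5, rp)  # sqrt(0.4/0.6)/0.5 = 1.63299...
#' @export
stationary_autoinducer <- function(R, rp) {
  stopifnot(inherits(rp, "reduced_qs_params"))
  if (any(R <= rp$alpha) || any(R >= rp$alpha + rp$beta))
    stop("stationary_autoinducer: R must satisfy alpha < R < alpha + beta")
  sqrt(rp$sigma * (R - rp$alpha) / (rp$alpha + rp$beta - R)) / R
}

# reduced-form rate (time rescaled by k3): alpha + beta*(RA)^2/(sigma+(RA)^2) - R
.reduced_rate <- function(R, A, rp) {
  RA2 <- (R * A)^2
  rp$alpha + rp$beta * RA2 / (rp$sigma + RA2) - R
}

#' Stationary LuxR branches across autoinducer levels
#'
#' For each autoinducer level, locates all fixed points of the reduced LuxR
#' equation in `[alpha*(1 - 1e-9), alpha + beta]` by sign-change bracketing
#' and bisection, with stability from the sign of the rate on either side.
#' Fixed-point counts are 1 or 3 (2 exactly at folds).
#'
#' @param rp A [reduced_qs_params()] object.
#' @param A_grid Nonempty vector of nonnegative autoinducer levels.
#' @param n_grid Grid intervals for the bracketing scan.
#' @return data.frame with columns `A`, `R`, `stability`.
#' @export
stationary_branches <- function(rp, A_grid, n_grid = 4000L) {
  stopifnot(inherits(rp, "reduced_qs_params"))
  if (length(A_grid) == 0L) stop("stationary_branches: A_grid must be nonempty")
  if (any(A_grid < 0)) stop("stationary_branches: A_grid must be nonnegative")
  lo <- rp$alpha * (1 - 1e-9)
  hi <- rp$alpha + rp$beta
  rows <- lapply(A_grid, function(A) {
    st <- .scan_states(function(R) .reduced_rate(R, A, rp),
                       x_max = hi, n_grid = as.integer(n_grid),
                       include_zero = FALSE, x_min = lo, h = 1e-9)
    if (nrow(st) == 0L) return(NULL)
    data.frame(A = A, R = st$value, stability = st$stability,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fold points of the quorum switch
#'
#' Locates the interior extrema of the stationary curve `A(R)` on
#' `(alpha, alpha + beta)` by sign changes of the finite-difference
#' derivative on a 1e4-point grid, refined by bisection. The switch is
#' bistable when a local maximum (nearer `alpha`) is followed by a local
#' minimum; the corresponding autoinducer levels are the up- and down-switch
#' thresholds bounding the hysteresis window.
#'
#' @param rp A [reduced_qs_params()] object.
#' @param n_grid Grid size for the derivative scan.
#' @return Object of class `fold_report`: list with `is_bistable` and, when
#'   bistable, `R_fold_low`, `R_fold_high`, `A_switch_up`, `A_switch_down`.
#' @export
fold_points <- function(rp, n_grid = 10000L) {
  stopifnot(inherits(rp, "reduced_qs_params"))
  del <- 1e-6 * rp$beta
  Rg <- seq(rp$alpha + del, rp$alpha + rp$beta - del, length.out = n_grid)
  Av <- stationary_autoinducer(Rg, rp)
  dA <- diff(Av)
  sc <- which(dA[-length(dA)] * dA[-1] < 0)
  h <- del / 10
  dfun <- function(R) stationary_autoinducer(R + h, rp) - stationary_autoinducer(R - h, rp)
  ext <- vapply(sc, function(i) .bisect(dfun, Rg[i], Rg[i + 2L], tol = 1e-12),
                numeric(1))
  kind <- vapply(ext, function(R) if (dfun(R - 10 * h) > 0) "max" else "min",
                 character(1))
  bist <- length(ext) >= 2L && kind[1] == "max" && any(kind[-1] == "min")
  out <- list(is_bistable = bist)
  if (bist) {
    imin <- which(kind == "min")[1]
    out$R_fold_low <- ext[1]
    out$R_fold_high <- ext[imin]
    out$A_switch_up <- stationary_autoinducer(ext[1], rp)
    out$A_switch_down <- stationary_autoinducer(ext[imin], rp)
  }
  class(out) <- "fold_report"
  out
}

#' @export
print.fold_report <- function(x, ...) {
  if (x$is_bistable)
    cat(sprintf(paste0("Bistable quorum switch: folds at R = %.6g / %.6g; ",
                       "up-switch A = %.6g, down-switch A = %.6g\n"),
                x$R_fold_low, x$R_fold_high, x$A_switch_up, x$A_switch_down))
  else cat("Monostable: stationary curve A(R) has no interior folds\n")
  invisible(x)
}

#' Simulate LuxR along a prescribed autoinducer path
#'
#' Integrates `dR/dt = luxr_rate(R, A(t))` for a piecewise-continuous
#' autoinducer path (linear interpolation between way-points). A slow
#' up-then-down ramp across both thresholds traces the hysteresis loop: the
#' up-switch occurs near the fold of the low branch, the down-switch near
#' the fold of the high branch.
#'
#' @param qs A [qs_params()] object.
#' @param A_path data.frame with columns `time` and `A`.
#' @param R0 Initial LuxR concentration.
#' @param t_out Output times (default the path's way-points).
#' @param control List of solver settings (`rtol`, `atol`).
#' @return data.frame with columns `time`, `A`, `R`.
#' @export
hysteresis_loop <- function(qs, A_path, R0 = qs$CR / qs$k3, t_out = NULL,
                            control = list(rtol = 1e-8, atol = 1e-10)) {
  stopifnot(inherits(qs, "qs_params"))
  if (!all(c("time", "A") %in% names(A_path)))
    stop("hysteresis_loop: A_path needs columns 'time' and 'A'")
  Af <- approxfun(A_path$time, A_path$A, rule = 2)
  if (is.null(t_out)) t_out <- A_path$time
  rhs <- function(t, y, parms) list(luxr_rate(max(y[1], 0), Af(t), qs))
  o <- deSolve::ode(c(R = R0), t_out, rhs, parms = NULL, method = "lsoda",
                    rtol = control$rtol, atol = control$atol)
  data.frame(time = o[, 1], A = Af(o[, 1]), R = o[, 2])
}

#' Plot stationary LuxR branches (switch diagram)
#'
#' Draws stable branches as solid points and unstable ones as open points in
#' the `(A, R)` plane, optionally with fold thresholds marked.
#'
#' @param rp A [reduced_qs_params()] object.
#' @param A_max Upper autoinducer limit of the diagram.
#' @param n Number of autoinducer grid points.
#' @param ... Passed to [graphics::plot()].
#' @return The branch data.frame, invisibly.
#' @export
plot_qs_branches <- function(rp, A_max = NULL, n = 200, ...) {
  fr <- fold_points(rp)
  if (is.null(A_max))
    A_max <- if (fr$is_bistable) 1.5 * fr$A_switch_up else
      stationary_autoinducer(rp$alpha + 0.9 * rp$beta, rp)
  br <- stationary_branches(rp, seq(0, A_max, length.out = n))
  plot(br$A, br$R, type = "n", xlab = "autoinducer A", ylab = "stationary LuxR R", ...)
  pts <- br[br$stability == "stable", ]
  points(pts$A, pts$R, pch = 16, cex = 0.4)
  pts <- br[br$stability == "unstable", ]
  points(pts$A, pts$R, pch = 1, cex = 0.4)
  if (fr$is_bistable) abline(v = c(fr$A_switch_down, fr$A_switch_up), lty = 3)
  invisible(br)
}
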