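#' Nelder--Mead simplex minimization
#'
#' In-package implementation of the downhill simplex with the standard
#' coefficients (reflection 1, expansion 2, contraction 0.5, shrink 0.5).
#' Deterministic given the start point and control settings. Convergence is
#' declared when the simplex diameter falls below `tol_x`, or the spread of
#' goal values below `tol_f`, or after `maxit` iterations.
#'
#' @param fn Scalar goal function of a numeric vector; must be finite at
#'   `x0` (penalized goals return large finite values instead of failing).
#' @param x0 Finite numeric start vector.
#' @param control List: `maxit` (5000), `tol_x` (1e-8), `tol_f` (1e-13;
#'   tight enough that a quadratic bowl is located to 1e-6 in the
#'   parameters), `step` (initial simplex displacement, relative for
#'   nonzero coordinates; 0.05).
#' @return List with `par`, `value`, `n_eval`, `iterations`, `converged`
#'   (TRUE unless stopped by `maxit`), and `trace` (best goal value per
#'   iteration).
#' @examples
#' nelder_mead(function(x) sum((x - 3)^2), c(0, 0))$par
#' @export
nelder_mead <- function(fn, x0, control = list()) {
  ctl <- modifyList(list(maxit = 5000L, tol_x = 1e-8, tol_f = 1e-13,
                         step = 0.05), control)
  x0 <- as.numeric(x0)
  if (any(!is.finite(x0))) stop("nelder_mead: x0 must be finite")
  f0 <- fn(x0)
  if (!is.finite(f0)) stop("nelder_mead: goal is not finite at x0")
  n <- length(x0)
  V <- matrix(rep(x0, each = n + 1L), nrow = n + 1L)
  for (i in seq_len(n))
    V[i + 1L, i] <- x0[i] + if (x0[i] != 0) ctl$step * abs(x0[i]) else 0.00025
  fv <- c(f0, apply(V[-1L, , drop = FALSE], 1L, fn))
  n_eval <- n + 1L
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < ctl$maxit) {
    it <- it + 1L
    o <- order(fv)
    V <- V[o, , drop = FALSE]; fv <- fv[o]
    trace[it] <- fv[1L]
    diam <- max(abs(sweep(V[-1L, , drop = FALSE], 2L, V[1L, ])))
    if (diam < ctl$tol_x || (fv[n + 1L] - fv[1L]) < ctl$tol_f) {
      converged <- TRUE
      break
    }
    xc <- colMeans(V[seq_len(n), , drop = FALSE])
    xr <- xc + (xc - V[n + 1L, ])
    fr <- fn(xr); n_eval <- n_eval + 1L
    if (fr < fv[1L]) {
      xe <- xc + 2 * (xc - V[n + 1L, ])
      fe <- fn(xe); n_eval <- n_eval + 1L
      if (fe < fr) { V[n + 1L, ] <- xe; fv[n + 1L] <- fe }
      else { V[n + 1L, ] <- xr; fv[n + 1L] <- fr }
    } else if (fr < fv[n]) {
      V[n + 1L, ] <- xr; fv[n + 1L] <- fr
    } else {
      xk <- if (fr < fv[n + 1L]) xc + 0.5 * (xc - V[n + 1L, ])
            else xc - 0.5 * (xc - V[n + 1L, ])
      fk <- fn(xk); n_eval <- n_eval + 1L
      if (fk < min(fr, fv[n + 1L])) {
        V[n + 1L, ] <- xk; fv[n + 1L] <- fk
      } else {
        for (i in 2L:(n + 1L)) {
          V[i, ] <- V[1L, ] + 0.5 * (V[i, ] - V[1L, ])
          fv[i] <- fn(V[i, ])
        }
        n_eval <- n_eval + n
      }
    }
  }
  o <- order(fv)
  list(par = V[o[1L], ], value = fv[o[1L]], n_eval = n_eval, iterations = it,
       converged = converged, trace = trace)
}

# restarted simplex: plain Nelder-Mead stagnates in the narrow curved valleys
# of ODE goal surfaces; restarting from the incumbent with an alternating
# simplex scale recovers descent. Deterministic.
nm_restarted <- function(fn, x0, control = list()) {
  ctl <- modifyList(list(passes = 8L, steps = c(0.3, 0.05), stop_loss = 1e-6),
                    control)
  f0 <- fn(x0)
  if (is.finite(f0) && f0 < ctl$stop_loss)  # the start already meets the goal
    return(list(par = x0, value = f0, n_eval = 1L, iterations = 0L,
                converged = TRUE, trace = f0))
  best <- nelder_mead(fn, x0, control)
  n_eval <- best$n_eval
  trace <- best$trace
  stalls <- 0L
  for (k in seq_len(ctl$passes)) {
    if (best$value < ctl$stop_loss) break
    step_k <- ctl$steps[(k - 1L) %% length(ctl$steps) + 1L]
    r <- nelder_mead(fn, best$par, modifyList(control, list(step = step_k)))
    n_eval <- n_eval + r$n_eval
    trace <- c(trace, r$trace)
    if (r$value < best$value * (1 - 1e-3)) stalls <- 0L else stalls <- stalls + 1L
    if (r$value < best$value) best <- r
    if (stalls >= 3L) break
  }
  best$n_eval <- n_eval
  best$trace <- trace
  best
}

# golden-section-profiled simplex: one freed parameter (typically the
# induction rate VR, which trades off against CA along a long shallow valley
# of the luminescence goal) is profiled on a coarse log grid with simplex
# subfits of the remaining parameters, the bracket around the best grid
# point is refined by golden-section search on the profile loss, and the
# result is polished by the restarted joint simplex. Requires the log
# transform (ratios become offsets). Deterministic.
nm_profiled <- function(fn, x0, i_prof, control = list()) {
  ctl <- modifyList(list(span = 4, points = 7L, refine = 7L,
                         stop_loss = 1e-6), control)
  f0 <- fn(x0)
  if (is.finite(f0) && f0 < ctl$stop_loss)
    return(list(par = x0, value = f0, n_eval = 1L, iterations = 0L,
                converged = TRUE, trace = f0))
  n_eval <- 0L
  trace <- numeric(0)
  r0 <- nelder_mead(fn, x0, control)
  n_eval <- n_eval + r0$n_eval
  trace <- c(trace, r0$trace)
  best <- r0
  if (best$value < ctl$stop_loss) { best$n_eval <- n_eval + 1L; return(best) }
  others <- setdiff(seq_along(x0), i_prof)
  warm <- best$par[others]
  prof <- function(v) {
    sub <- function(z) { x <- numeric(length(x0)); x[i_prof] <- v; x[others] <- z; fn(x) }
    rs <- nelder_mead(sub, warm, modifyList(control, list(step = 0.2)))
    n_eval <<- n_eval + rs$n_eval
    trace <<- c(trace, rs$trace)
    warm <<- rs$par
    x <- numeric(length(x0)); x[i_prof] <- v; x[others] <- rs$par
    list(value = rs$value, par = x)
  }
  grid <- x0[i_prof] + log(ctl$span^seq(-1, 1, length.out = ctl$points))
  pts <- lapply(grid, prof)
  vals <- vapply(pts, `[[`, numeric(1), "value")
  i <- which.min(vals)
  if (vals[i] < best$value) best <- pts[[i]]
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  gr <- (sqrt(5) - 1) / 2
  a <- hi - gr * (hi - lo); b <- lo + gr * (hi - lo)
  fa <- prof(a); fb <- prof(b)
  for (k in seq_len(ctl$refine)) {
    if (fa$value < fb$value) {
      hi <- b; b <- a; fb <- fa
      a <- hi - gr * (hi - lo); fa <- prof(a)
    } else {
      lo <- a; a <- b; fa <- fb
      b <- lo + gr * (hi - lo); fb <- prof(b)
    }
  }
  pb <- if (fa$value < fb$value) fa else fb
  if (pb$value < best$value) best <- pb
  polish <- nm_restarted(fn, best$par,
                         modifyList(control, list(steps = c(0.05, 0.3))))
  n_eval <- n_eval + polish$n_eval
  trace <- c(trace, polish$trace)
  if (polish$value <= best$value) best <- polish
  best$n_eval <- n_eval
  best$trace <- trace
  if (is.null(best$converged)) best$converged <- TRUE
  best
}

#' Multistart wrapper around a fitting operation
#'
#' Runs a minimization from `n_starts` starting points — the supplied start
#' plus log-normally jittered copies — and returns the best result by loss.
#' A local simplex search often terminates in the nearest minimum; multiple
#' dispersed starts are the standard mitigation. For the same seed, the
#' first `k` starts of an `n`-start run (`k <= n`) are identical to a
#' `k`-start run, so the best loss is nonincreasing in `n_starts`.
#'
#' @param fit_fun Function taking a start vector and returning a list with
#'   at least elements `value` (or `loss`) and `par`.
#' @param x0 Start vector (in the space `fit_fun` expects; jitter is
#'   additive Gaussian there, i.e. log-normal for log-transformed
#'   parameters).
#' @param n_starts Number of starts (>= 1).
#' @param dispersion Standard deviation of the jitter.
#' @param seed Integer seed.
#' @return The best fit result, augmented with `start_index` and
#'   `all_losses`.
#' @export
multistart_fit <- function(fit_fun, x0, n_starts = 1L, dispersion = 0.2,
                           seed = 1L) {
  if (n_starts < 1L) stop("multistart_fit: n_starts must be >= 1")
  starts <- .with_seed(seed, {
    lapply(seq_len(n_starts), function(i)
      if (i == 1L) x0 else x0 + rnorm(length(x0), 0, dispersion))
  })
  results <- lapply(starts, fit_fun)
  losses <- vapply(results, function(r) {
    v <- if (!is.null(r$value)) r$value else r$loss
    if (is.null(v) || !is.finite(v)) Inf else v
  }, numeric(1))
  best <- which.min(losses)
  out <- results[[best]]
  out$start_index <- best
  out$all_losses <- losses
  out
}
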