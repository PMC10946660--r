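ck_pos <- function(x, what) {
  bad <- vapply(x, function(v) !is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0,
                logical(1))
  if (any(bad)) stop(sprintf("%s: fields must be positive finite scalars: %s",
                             what, paste(names(x)[bad], collapse = ", ")))
}

#' Growth-block parameters
#'
#' Kinetics of ATP-dependent biomass synthesis
#' `fg(S, a) = Vg * sat(S, Kg) * sat(a, Ka)`. Defaults are the fitted values
#' shared between the rich- and poor-medium scenarios.
#'
#' @param Vg Maximum specific growth rate (1/h).
#' @param Kg Substrate half-saturation.
#' @param Ka ATP half-saturation for growth.
#' @return Object of class `growth_params`.
#' @export
growth_params <- function(Vg = 2.18, Kg = 3.99, Ka = 0.0033) {
  p <- list(Vg = Vg, Kg = Kg, Ka = Ka)
  ck_pos(p, "growth_params")
  structure(p, class = "growth_params")
}

#' Energy-block parameters
#'
#' Kinetics of ATP production, the generalized ATPase (all ATP-consuming
#' housekeeping processes lumped together), the ATP cost of biomass synthesis
#' (`k0`) and the reference ATP level `a0`. `a0` serves both as the default
#' initial ATP concentration and, in the combined model's default
#' configuration, as the total adenylate pool limiting ATP production
#' (see [energy_config()]).
#'
#' @param Ve Maximum ATP production rate.
#' @param Ke Substrate half-saturation for ATP production.
#' @param Kae ATP-activation constant of ATP production (in units of `a^n`
#'   where `n` is the activation exponent).
#' @param kd Generalized-ATPase rate constant.
#' @param eps2 ATPase half-saturation: activity is near-constant for `a >>
#'   eps2` and drops only at low ATP.
#' @param k0 ATP cost coefficient of biomass synthesis.
#' @param a0 Reference/initial intracellular ATP concentration.
#' @return Object of class `energy_params`.
#' @export
energy_params <- function(Ve = 3.30, Ke = 4.02, Kae = 0.008, kd = 0.0315,
                          eps2 = 1.54, k0 = 0.082, a0 = 1.40) {
  p <- list(Ve = Ve, Ke = Ke, Kae = Kae, kd = kd, eps2 = eps2, k0 = k0, a0 = a0)
  ck_pos(p, "energy_params")
  structure(p, class = "energy_params")
}

#' Quorum-sensing block parameters
#'
#' LuxR/autoinducer kinetics: basal (`CR`) and induced (`VR`) LuxR synthesis,
#' per-biomass autoinducer production (`CA`), first-order LuxR loss (`k3`),
#' the composite dimerization constant `gamma` collapsing both binding steps
#' of the (LuxR-autoinducer) dimer, and the promoter half-saturation `KR`
#' in dimer units.
#'
#' @param VR Maximum induced LuxR synthesis rate.
#' @param CR Basal LuxR synthesis rate.
#' @param CA Per-biomass autoinducer production rate.
#' @param k3 LuxR first-order loss rate.
#' @param gamma Dimerization composite constant.
#' @param KR Promoter half-saturation (dimer units).
#' @return Object of class `qs_params`.
#' @export
qs_params <- function(VR = 1.50, CR = 0.011, CA = 0.14, k3 = 0.057,
                      gamma = 0.331, KR = 0.06) {
  p <- list(VR = VR, CR = CR, CA = CA, k3 = k3, gamma = gamma, KR = KR)
  ck_pos(p, "qs_params")
  structure(p, class = "qs_params")
}

#' Luminescence-block parameters
#'
#' `VL` scales luciferase amount and ATP availability into measured light
#' units; `KL` is the ATP half-saturation of luciferase synthesis and of the
#' light reaction; `kdL` is the first-order luciferase inactivation rate.
#' `VL` and `kdL` are per-medium quantities (see [make_scenario()]); defaults
#' are the rich-medium preset values. `KL` is shared across media.
#'
#' @param VL Luminescence scale factor (per-medium).
#' @param KL ATP half-saturation of luminescence.
#' @param kdL Luciferase inactivation rate (1/h, per-medium).
#' @return Object of class `lum_params`.
#' @export
lum_params <- function(VL = 600, KL = 0.17, kdL = 0.5) {
  p <- list(VL = VL, KL = KL, kdL = kdL)
  ck_pos(p, "lum_params")
  structure(p, class = "lum_params")
}

#' Time-scale parameters
#'
#' `eps0` is the ratio of total cell volume to flask volume; it converts
#' intracellular consumption rates to flask-level substrate depletion rates.
#' `eps1`, `eps3`, `eps4` multiply the time derivatives of ATP, LuxR and
#' luciferase respectively; the small `eps1` makes ATP the fast variable.
#'
#' @param eps0 Cell-to-flask volume ratio (must be `<= 1`).
#' @param eps1 ATP equation time-scale multiplier.
#' @param eps3 LuxR equation time-scale multiplier.
#' @param eps4 Luciferase equation time-scale multiplier.
#' @return Object of class `scale_params`.
#' @export
scale_params <- function(eps0 = 0.01, eps1 = 0.001, eps3 = 0.39, eps4 = 3.34) {
  p <- list(eps0 = eps0, eps1 = eps1, eps3 = eps3, eps4 = eps4)
  ck_pos(p, "scale_params")
  if (eps0 > 1) stop("scale_params: eps0 must be <= 1 (it is a volume ratio)")
  structure(p, class = "scale_params")
}

#' Full model parameter set
#'
#' Bundles the four kinetic blocks and the time-scale parameters. Defaults
#' reproduce the common fitted parameter vector shared by the rich- and
#' poor-medium scenarios (luminescence scale/decay default to the rich
#' preset).
#'
#' @param growth,energy,qs,lum,scale Block parameter objects.
#' @return Object of class `full_params`.
#' @seealso [default_params()], [flatten_params()]
#' @export
full_params <- function(growth = growth_params(), energy = energy_params(),
                        qs = qs_params(), lum = lum_params(),
                        scale = scale_params()) {
  stopifnot(inherits(growth, "growth_params"), inherits(energy, "energy_params"),
            inherits(qs, "qs_params"), inherits(lum, "lum_params"),
            inherits(scale, "scale_params"))
  structure(list(growth = growth, energy = energy, qs = qs, lum = lum,
                 scale = scale), class = "full_params")
}

#' Common fitted parameter vector
#'
#' The full parameter set with every field at its default (the fitted values
#' shared between media, plus the rich-medium preset for `VL`/`kdL`).
#'
#' @return Object of class `full_params`.
#' @export
default_params <- function() full_params()

#' @export
print.full_params <- function(x, ...) {
  v <- flatten_params(x)
  cat("Full model parameters:\n")
  print(round(v, 6))
  invisible(x)
}

#' Reduced quorum-switch parameters
#'
#' The three composites that govern the stationary LuxR curve:
#' `alpha = CR/k3` (basal stationary LuxR), `beta = VR/k3` (induction
#' amplitude) and `sigma = KR*gamma` (curve scale).
#'
#' @param alpha,beta,sigma Positive composites.
#' @return Object of class `reduced_qs_params`.
#' @export
reduced_qs_params <- function(alpha, beta, sigma) {
  p <- list(alpha = alpha, beta = beta, sigma = sigma)
  ck_pos(p, "reduced_qs_params")
  structure(p, class = "reduced_qs_params")
}

#' Reduce quorum-sensing parameters to stationary-curve composites
#'
#' @param qs A [qs_params()] object.
#' @return [reduced_qs_params()] with `alpha = CR/k3`, `beta = VR/k3`,
#'   `sigma = KR*gamma`.
#' @examples
#' as_reduced(qs_params(CR = 0.01, k3 = 0.1, VR = 0.1, KR = 1, gamma = 1))
#' @export
as_reduced <- function(qs) {
  stopifnot(inherits(qs, "qs_params"))
  reduced_qs_params(alpha = qs$CR / qs$k3, beta = qs$VR / qs$k3,
                    sigma = qs$KR * qs$gamma)
}

# canonical order of the flat parameter vector used by fitting and the
# compiled right-hand side
.param_names <- c("Vg", "Kg", "Ka",
                  "Ve", "Ke", "Kae", "kd", "eps2", "k0", "a0",
                  "VR", "CR", "CA", "k3", "gamma", "KR",
                  "VL", "KL", "kdL",
                  "eps0", "eps1", "eps3", "eps4")

#' Names of the flat parameter vector
#'
#' The documented name-to-index map used when fitting operates on flat
#' vectors. Scenario-level names (`S0`, `N0`, `L0`) are appended when a
#' scenario is part of the fit.
#'
#' @return Character vector of parameter names in canonical order.
#' @export
param_names <- function() .param_names

#' Flatten a parameter set to a named vector
#'
#' @param p A [full_params()] object.
#' @return Named numeric vector in [param_names()] order.
#' @export
flatten_params <- function(p) {
  stopifnot(inherits(p, "full_params"))
  c(Vg = p$growth$Vg, Kg = p$growth$Kg, Ka = p$growth$Ka,
    Ve = p$energy$Ve, Ke = p$energy$Ke, Kae = p$energy$Kae, kd = p$energy$kd,
    eps2 = p$energy$eps2, k0 = p$energy$k0, a0 = p$energy$a0,
    VR = p$qs$VR, CR = p$qs$CR, CA = p$qs$CA, k3 = p$qs$k3,
    gamma = p$qs$gamma, KR = p$qs$KR,
    VL = p$lum$VL, KL = p$lum$KL, kdL = p$lum$kdL,
    eps0 = p$scale$eps0, eps1 = p$scale$eps1, eps3 = p$scale$eps3,
    eps4 = p$scale$eps4)
}

#' Update a parameter set from a named vector
#'
#' Returns a new [full_params()] with the named entries replaced; all other
#' values are untouched (parameter objects are immutable).
#'
#' @param p A [full_params()] object.
#' @param x Named numeric vector; names must be among [param_names()].
#' @return A new `full_params` object.
#' @export
update_params <- function(p, x) {
  stopifnot(inherits(p, "full_params"))
  if (length(x) == 0L) return(p)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("update_params: x must be fully named")
  unknown <- setdiff(names(x), .param_names)
  if (length(unknown))
    stop("update_params: unknown parameter names: ", paste(unknown, collapse = ", "))
  v <- flatten_params(p)
  v[names(x)] <- x
  full_params(
    growth = growth_params(v[["Vg"]], v[["Kg"]], v[["Ka"]]),
    energy = energy_params(v[["Ve"]], v[["Ke"]], v[["Kae"]], v[["kd"]],
                           v[["eps2"]], v[["k0"]], v[["a0"]]),
    qs = qs_params(v[["VR"]], v[["CR"]], v[["CA"]], v[["k3"]], v[["gamma"]],
                   v[["KR"]]),
    lum = lum_params(v[["VL"]], v[["KL"]], v[["kdL"]]),
    scale = scale_params(v[["eps0"]], v[["eps1"]], v[["eps3"]], v[["eps4"]]))
}
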