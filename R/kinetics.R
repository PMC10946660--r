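#' Monod/Michaelis saturation function
#'
#' The hyperbolic saturation primitive `x / (K + x)` used by every rate law in
#' the model: substrate limitation of growth and ATP production, ATP
#' activation of downstream synthesis, and ATPase loading.
#'
#' @param x Nonnegative quantity (concentration); may be a vector.
#' @param K Positive half-saturation constant.
#' @return Value in `[0, 1)`, monotone increasing in `x`; `0.5` at `x = K`.
#' @examples
#' saturation(0, 1)    # 0
#' saturation(2, 2)    # 0.5
#' saturation(3, 1)    # 0.75
#' @export
saturation <- function(x, K) {
  if (any(!is.finite(K)) || any(K <= 0)) stop("saturation: K must be positive")
  if (any(is.na(x)) || any(x < 0)) stop("saturation: x must be nonnegative")
  x / (K + x)
}

#' Verhulst (logistic) growth-rate parameters
#'
#' Two parameterizations of the logistic baseline: the carrying-capacity form
#' `mu0 * N * (Nmax - N)` and the intraspecific-competition form
#' `mu0 * N - alpha_v * N^2`. The two are algebraically equivalent under
#' `mu0' = mu0 * Nmax`, `alpha_v = mu0`.
#'
#' @param form `"carrying_capacity"` or `"competition"`.
#' @param mu0 Positive rate constant (1/h).
#' @param Nmax Carrying capacity (required for the carrying-capacity form).
#' @param alpha_v Competition coefficient (required for the competition form).
#' @return Object of class `verhulst_params`.
#' @export
verhulst_params <- function(form = c("carrying_capacity", "competition"),
                            mu0, Nmax = NULL, alpha_v = NULL) {
  form <- match.arg(form)
  if (!is.numeric(mu0) || mu0 <= 0) stop("mu0 must be positive")
  if (form == "carrying_capacity") {
    if (is.null(Nmax) || Nmax <= 0) stop("Nmax must be positive for the carrying-capacity form")
  } else {
    if (is.null(alpha_v) || alpha_v <= 0) stop("alpha_v must be positive for the competition form")
  }
  structure(list(form = form, mu0 = mu0, Nmax = Nmax, alpha_v = alpha_v),
            class = "verhulst_params")
}

#' Verhulst population growth rate
#'
#' @param N Nonnegative population size (vectorized).
#' @param p A [verhulst_params()] object.
#' @return dN/dt under the chosen parameterization; `0` at `N = 0` and, for
#'   the carrying-capacity form, at `N = Nmax`.
#' @export
verhulst_rate <- function(N, p) {
  stopifnot(inherits(p, "verhulst_params"))
  if (any(is.na(N)) || any(N < 0)) stop("verhulst_rate: N must be nonnegative")
  if (p$form == "carrying_capacity") p$mu0 * N * (p$Nmax - N)
  else p$mu0 * N - p$alpha_v * N^2
}
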