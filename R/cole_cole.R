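#' One-pole Cole-Cole dispersion parameters
#'
#' Container for the parameters of a single Cole-Cole dispersion pole:
#' the high-frequency permittivity `eps_inf`, the static permittivity
#' `eps_s` (so the dispersion magnitude is `delta_eps = eps_s - eps_inf`),
#' the relaxation time `tau` in seconds, the broadening exponent `alpha`
#' and an optional static (ionic) conductivity `sigma_s` in S/m that adds
#' a `sigma_s / (omega * eps0)` loss term.  The water-based model sets
#' `sigma_s = 0`.
#'
#' @param eps_inf Permittivity far above the relaxation frequency, >= 1.
#' @param eps_s Static permittivity, `eps_s >= eps_inf`.
#' @param tau Relaxation time in seconds (6.36 ps for free water).
#' @param alpha Broadening parameter in `[0, 1)` (0 recovers Debye).
#' @param sigma_s Static conductivity in S/m, >= 0.
#' @return A list of class `"cole_cole_params"`.
#' @seealso [assign_parameters()], [cole_cole_spectrum()]
#' @export
#' @examples
#' cole_cole_params(eps_inf = 4, eps_s = 51.47, tau = 6.36e-12, alpha = 0.1)
cole_cole_params <- function(eps_inf, eps_s, tau = TAU_WATER, alpha = 0.1,
                             sigma_s = 0) {
  check_number(eps_inf, "eps_inf", lower = 1)
  check_number(eps_s, "eps_s", lower = eps_inf)
  check_number(tau, "tau", lower = 0, strict_lower = TRUE)
  check_number(alpha, "alpha", lower = 0, upper = 1, strict_upper = TRUE)
  check_number(sigma_s, "sigma_s", lower = 0)
  structure(list(eps_inf = eps_inf, eps_s = eps_s,
                 delta_eps = eps_s - eps_inf,
                 tau = tau, alpha = alpha, sigma_s = sigma_s),
            class = "cole_cole_params")
}

#' @export
print.cole_cole_params <- function(x, ...) {
  cat(sprintf(
    "Cole-Cole pole: eps_inf = %g, eps_s = %g (delta = %g), tau = %g ps, alpha = %g%s\n",
    x$eps_inf, x$eps_s, x$delta_eps, x$tau * 1e12, x$alpha,
    if (x$sigma_s > 0) sprintf(", sigma_s = %g S/m", x$sigma_s) else ""))
  invisible(x)
}

#' Assign water-based model parameters from the water volume fraction
#'
#' Implements the parameter-assignment rules of the water-based model:
#' tissues with water volume fraction above 50% are "high-water"
#' (`eps_inf = 4`, static permittivity from Fricke's formula with
#' `eps_p = 5`, `x = 2`); tissues below 50% are "low-water"
#' (`eps_inf = 2.5`, Maxwell's formula with `eps_p = 2.5`).  A water
#' fraction of exactly 0.5 maps to the high-water branch, since only
#' fractions strictly below 50% are defined as low-water.  For all
#' tissues `tau` is the free-water relaxation time (6.36 ps), `alpha`
#' is 0.1, and the static conductivity is 0.
#'
#' @param wc_volume Water volume fraction of the tissue, in `[0, 1]`.
#'   The solid volume fraction fed to the mixture formula is
#'   `P = 1 - wc_volume`.
#' @param eps_w Relative permittivity of water (78 at 100 MHz).
#' @param x Inclusion shape factor of the Fricke branch (2 for spheres;
#'   1.5, for prolate ellipsoids, is available but unused by default).
#' @return A [cole_cole_params()] object.
#' @export
#' @examples
#' assign_parameters(0.752)  # muscle-like: eps_inf 4, eps_s ~51.5
#' assign_parameters(0.052)  # fat-like: eps_inf 2.5, eps_s ~3.97
assign_parameters <- function(wc_volume, eps_w = 78, x = 2) {
  check_number(wc_volume, "wc_volume", lower = 0, upper = 1)
  P <- 1 - wc_volume
  if (wc_volume >= 0.5) {
    eps_s <- fricke_static_permittivity(mixture_inputs(P, eps_w, eps_p = 5, x = x))
    eps_inf <- 4
  } else {
    eps_s <- maxwell_static_permittivity(mixture_inputs(P, eps_w, eps_p = 2.5))
    eps_inf <- 2.5
  }
  # At extreme dryness (wc below ~1.6%) the Maxwell mixture permittivity
  # drops below eps_inf and a dispersion pole is no longer meaningful;
  # the dispersion magnitude is floored at zero (flat spectrum).
  cole_cole_params(eps_inf = eps_inf, eps_s = max(eps_s, eps_inf),
                   tau = TAU_WATER, alpha = 0.1, sigma_s = 0)
}

check_freq <- function(f) {
  if (any(!is.finite(f)) || any(f <= 0))
    abort_validation("frequencies must be positive and finite")
  invisible(f)
}

#' Complex relative permittivity of a Cole-Cole pole
#'
#' Direct complex evaluation
#' `eps(f) = eps_inf + delta_eps / (1 + (j*omega*tau)^(1-alpha)) -
#' j * sigma_s / (omega * eps0)` with `omega = 2*pi*f`.  The internal sign
#' convention is `eps = eps' - j*eps''` with a non-negative loss term
#' `eps''`.
#'
#' @param p A [cole_cole_params()] object.
#' @param f Frequency in Hz, positive; vectorized.
#' @return A complex vector, one value per frequency.
#' @seealso [cole_cole_real()], [cole_cole_imag()] for the closed-form
#'   decomposition.
#' @export
#' @examples
#' p <- cole_cole_params(4, 51.47)
#' cole_cole_complex(p, 1e9)
cole_cole_complex <- function(p, f) {
  stopifnot(inherits(p, "cole_cole_params"))
  check_freq(f)
  omega <- 2 * pi * f
  eps <- p$eps_inf + p$delta_eps / (1 + (1i * omega * p$tau)^(1 - p$alpha))
  if (p$sigma_s > 0)
    eps <- eps - 1i * p$sigma_s / (omega * EPS0)
  eps
}

# shared pieces of the closed-form real/imag expressions
cole_cole_den <- function(p, omega) {
  wt <- (omega * p$tau)^(1 - p$alpha)
  cw <- cos(pi / 2 * (1 - p$alpha)) * wt
  sw <- sin(pi / 2 * (1 - p$alpha)) * wt
  list(cw = cw, sw = sw, den = (1 + cw)^2 + sw^2)
}

#' Closed-form real part of the Cole-Cole permittivity
#'
#' Evaluates the analytic real-part expression of the one-pole Cole-Cole
#' model.  Agrees with `Re(cole_cole_complex(p, f))` to machine precision;
#' the static conductivity does not enter the real part.
#'
#' @inheritParams cole_cole_complex
#' @return Numeric vector of `eps'` values.
#' @export
#' @examples
#' cole_cole_real(cole_cole_params(4, 51.47), 1e9)  # ~50.93
cole_cole_real <- function(p, f) {
  stopifnot(inherits(p, "cole_cole_params"))
  check_freq(f)
  d <- cole_cole_den(p, 2 * pi * f)
  p$eps_inf + p$delta_eps * (1 + d$cw) / d$den
}

#' Closed-form loss term of the Cole-Cole permittivity
#'
#' Evaluates the analytic imaginary-part (loss) expression, reported as a
#' non-negative number.  With `sigma_s = 0` it equals
#' `|Im(cole_cole_complex(p, f))|` to machine precision; a positive static
#' conductivity adds exactly `sigma_s / (omega * eps0)` and affects only
#' this output.
#'
#' @inheritParams cole_cole_complex
#' @return Numeric vector of `eps''` values, >= 0.
#' @export
#' @examples
#' cole_cole_imag(cole_cole_params(4, 51.47), 1e9)  # ~2.53
cole_cole_imag <- function(p, f) {
  stopifnot(inherits(p, "cole_cole_params"))
  check_freq(f)
  omega <- 2 * pi * f
  d <- cole_cole_den(p, omega)
  out <- p$delta_eps * d$sw / d$den
  if (p$sigma_s > 0)
    out <- out + p$sigma_s / (omega * EPS0)
  out
}

#' Default 1-20 GHz frequency grid
#'
#' Linearly spaced grid from 1 to 20 GHz in 0.1 GHz steps (191 points),
#' the band over which the water-based model is evaluated and compared.
#'
#' @return Frequencies in Hz.
#' @export
default_frequency_grid <- function() seq(1e9, 20e9, by = 0.1e9)

#' Evaluate a permittivity spectrum on a frequency grid
#'
#' Element-wise evaluation of the closed-form real and imaginary parts on
#' a strictly increasing positive frequency grid.
#'
#' @inheritParams cole_cole_complex
#' @param frequencies Frequency grid in Hz (default: [default_frequency_grid()]).
#' @return A data frame of class `"permittivity_spectrum"` with columns
#'   `frequency_hz`, `eps_real`, `eps_imag`; the generating parameters are
#'   attached as attribute `"params"`.
#' @export
#' @examples
#' sp <- cole_cole_spectrum(cole_cole_params(4, 51.47), c(1, 5, 20) * 1e9)
#' sp
cole_cole_spectrum <- function(p, frequencies = default_frequency_grid()) {
  if (length(frequencies) == 0L)
    abort_validation("`frequencies` must not be empty")
  check_freq(frequencies)
  if (any(diff(frequencies) <= 0))
    abort_validation("`frequencies` must be strictly increasing")
  out <- data.frame(frequency_hz = frequencies,
                    eps_real = cole_cole_real(p, frequencies),
                    eps_imag = cole_cole_imag(p, frequencies))
  attr(out, "params") <- p
  class(out) <- c("permittivity_spectrum", "data.frame")
  out
}
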