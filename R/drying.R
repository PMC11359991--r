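#' Noise-free single-exponential drying curve
#'
#' Kinetic model behind the synthetic weighing campaigns: the sample weight
#' decays exponentially from its wet weight `Ww` towards its dry weight `Wd`
#' with time constant `tau_d`, mimicking the loss of evaporable water in a
#' dehydration oven.
#'
#' @param t Time since the start of drying, in hours.  May be a vector.
#' @param Ww Wet (initial) weight in g.
#' @param Wd Dry weight in g; must satisfy `0 < Wd <= Ww`.
#' @param tau_d Drying time constant in hours.
#'
#' @return Weight in g at each `t`: `Wd + (Ww - Wd) * exp(-t / tau_d)`.
#'   Continuous and monotonically non-increasing in `t`.
#' @export
#' @examples
#' drying_curve(0, Ww = 10, Wd = 3, tau_d = 20)   # 10
#' drying_curve(20, Ww = 10, Wd = 3, tau_d = 20)  # 3 + 7/e
drying_curve <- function(t, Ww, Wd, tau_d) {
  check_number(Ww, "Ww", lower = 0, strict_lower = TRUE)
  check_number(Wd, "Wd", lower = 0, strict_lower = TRUE)
  check_number(tau_d, "tau_d", lower = 0, strict_lower = TRUE)
  if (Wd > Ww) abort_validation("`Wd` must not exceed `Ww`")
  if (any(!is.finite(t)) || any(t < 0))
    abort_validation("`t` must be non-negative and finite")
  Wd + (Ww - Wd) * exp(-t / tau_d)
}

#' Quantize a weight to the balance readability
#'
#' Rounds a weight to the nearest multiple of the balance readability
#' (10 mg for the balance emulated here).  Ties are rounded half away from
#' zero, matching common balance display behaviour; note that a decimal
#' weight that is not exactly representable in binary may fall on either
#' side of a tie.
#'
#' @param w Weight(s) in g, non-negative.
#' @param readability Balance readability in g (default 0.01, i.e. 10 mg).
#'
#' @return `w` rounded to the nearest multiple of `readability`.
#'   Idempotent: quantizing twice gives the same result.
#' @export
#' @examples
#' quantize_weight(5.3449)        # 5.34
#' quantize_weight(2.5, 1)        # 3 (tie, away from zero)
quantize_weight <- function(w, readability = 0.01) {
  check_number(readability, "readability", lower = 0, strict_lower = TRUE)
  if (any(!is.finite(w)) || any(w < 0))
    abort_validation("`w` must be non-negative and finite")
  floor(w / readability + 0.5) * readability
}
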