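# Transition-state-theory (Eyring) conversion between first-order rate
# constants and activation free energies:
#   k = (kB T / h) exp(-dG / (kB_molar T)),   transmission coefficient = 1,
# with kB/h = 2.0836612e10 s^-1 K^-1 and kB_molar = 0.0019872041
# kcal mol^-1 K^-1.  Units are explicit: rates must be tagged per_second or
# per_minute; no unit guessing.

.rate_in_per_second <- function(k, unit = c("per_second", "per_minute")) {
  unit <- match.arg(unit)
  if (unit == "per_minute") k / 60 else k
}

#' Convert a first-order rate constant to an activation free energy
#'
#' \eqn{\Delta G^\ddagger = k_B T \ln[(k_B T / h) / k]} (molar Boltzmann
#' constant in kcal/mol/K).  For example, an experimental turnover of
#' 20 min^-1 at 343.15 K (~70 C) corresponds to a barrier of ~20.9, i.e.
#' about 21 kcal/mol.
#'
#' @param k rate constant (> 0).
#' @param temperature temperature in K (> 0).
#' @param unit `"per_second"` or `"per_minute"` -- must be stated.
#' @return A `rate_result`: list with `k` (s^-1), `temperature`, `barrier`
#'   (kcal/mol) and `transmission` (fixed at 1).
#' @examples
#' rate_to_barrier(20, 343.15, unit = "per_minute")$barrier  # ~20.9
#' @export
rate_to_barrier <- function(k, temperature,
                            unit = c("per_second", "per_minute")) {
  ks <- .rate_in_per_second(k, unit)
  if (ks <= 0) stop("rate constant must be positive")
  if (temperature <= 0) stop("temperature must be positive")
  prefactor <- .KB_OVER_H * temperature
  dg <- .KB * temperature * log(prefactor / ks)
  structure(list(k = ks, temperature = temperature, barrier = dg,
                 transmission = 1), class = "rate_result")
}

#' Convert an activation free energy to a first-order rate constant
#'
#' Exact inverse of [rate_to_barrier()]:
#' \eqn{k = (k_B T / h) e^{-\Delta G^\ddagger / k_B T}}.
#'
#' @param barrier activation free energy, kcal/mol.
#' @param temperature temperature in K (> 0).
#' @return A `rate_result` (see [rate_to_barrier()]); `k` is in s^-1.
#' @examples
#' barrier_to_rate(0, 300)$k  # kB/h * 300 = 6.25e12 s^-1
#' @export
barrier_to_rate <- function(barrier, temperature) {
  if (temperature <= 0) stop("temperature must be positive")
  prefactor <- .KB_OVER_H * temperature
  k <- prefactor * exp(-barrier / (.KB * temperature))
  structure(list(k = k, temperature = temperature, barrier = barrier,
                 transmission = 1), class = "rate_result")
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf("k = %.6g s^-1 (= %.6g min^-1) at T = %g K  =>  dG+ = %.4g kcal/mol\n",
              x$k, x$k * 60, x$temperature, x$barrier))
  invisible(x)
}
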