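# Lumped local-assembly frequency responses: gamma-shaped neural response
# spectrum, excitatory/inhibitory population transfer functions, the
# alternating E-I loop, and the total cortical transfer function.

#' Gamma-shaped neural response spectrum
#'
#' Frequency-domain form of the lumped gamma-shaped neural impulse response,
#' `F(omega) = (1/tau^2) / (j*omega + 1/tau)^2`, normalized to unit DC gain:
#' `F(0) = 1` exactly, with magnitude rolling off quadratically in
#' `|omega|`. This response lumps synaptic membrane capacitance together
#' with the spread of dendritic/axonal delays in a large cortical region.
#'
#' @param tau time constant in seconds.
#' @param omega angular frequency (rad/s), scalar or vector.
#' @return complex vector of the same length as `omega`.
#' @examples
#' gamma_spectrum(0.012, 0)            # exactly 1+0i
#' Mod(gamma_spectrum(0.012, 2 * pi * 10))
#' @export
gamma_spectrum <- function(tau, omega) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0) {
    stop_sgm("tau must be a positive scalar (seconds)")
  }
  # algebraically (1/tau^2)/(j*omega + 1/tau)^2, written so F(0) is exactly 1
  ((1 / tau) / (1i * omega + 1 / tau))^2
}

#' Population transfer function
#'
#' Transfer function of a lumped excitatory or inhibitory population,
#' `H(omega) = 1 / (j*omega + (gain/tau) * F(omega))` with `F` the
#' gamma-shaped response at the same time constant. At `omega = 0` and unit
#' gain this equals `tau` exactly; at zero gain it is the pure integrator
#' `1/(j*omega)`.
#'
#' @param tau time constant in seconds.
#' @param gain population gain (`g_ee` or `g_ii`), `>= 0`.
#' @param omega angular frequency (rad/s), scalar or vector.
#' @return complex vector (units of seconds).
#' @export
population_transfer <- function(tau, gain, omega) {
  if (gain < 0) stop_sgm("gain must be >= 0")
  den <- 1i * omega + (gain / tau) * gamma_spectrum(tau, omega)
  if (any(den == 0)) {
    stop_sgm("singular population transfer (omega = 0 with zero gain)")
  }
  1 / den
}

#' Total local cortical transfer function
#'
#' Combines the excitatory population `H_e` (time constant `tau_e`, gain
#' `g_ee = 1`), the inhibitory population `H_i` (`tau_i`, `g_ii`), and the
#' alternating excitatory-inhibitory loop
#' `H_ei = H_e * H_i / (1 + g_ei * H_e * H_i)` into the total cortical
#' transfer function `H_local = H_e + H_i + H_ei`. All regions share this
#' transfer function; regional differences in the model arise purely from
#' network filtering.
#'
#' @param params an [sgm_params()] object.
#' @param omega angular frequency (rad/s), scalar or vector.
#' @param components if `TRUE`, return a list with `H_e`, `H_i`, `H_ei`,
#'   `H_local`; otherwise just the complex `H_local` vector.
#' @return complex vector (seconds), or a list when `components = TRUE`.
#' @examples
#' p <- sgm_params()
#' H <- local_transfer(p, 2 * pi * seq(2, 45, by = 0.5))
#' @export
local_transfer <- function(params, omega, components = FALSE) {
  stopifnot(inherits(params, "sgm_params"))
  He <- population_transfer(params$tau_e, params$g_ee, omega)
  Hi <- population_transfer(params$tau_i, params$g_ii, omega)
  Hei <- He * Hi / (1 + params$g_ei * He * Hi)
  H <- He + Hi + Hei
  if (components) list(H_e = He, H_i = Hi, H_ei = Hei, H_local = H) else H
}
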