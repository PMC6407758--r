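# Physical constants, CODATA 2018 (exact in the revised SI), stated to full
# precision so barrier-derived rate constants are reproducible bit-for-bit.
.nk_boltzmann <- 1.380649e-23        # J / K
.nk_planck <- 6.62607015e-34         # J * s
.nk_gas_constant <- 8.31446261815324 # J / (mol * K) = N_A * k_B

#' Eyring transition-state rate constant
#'
#' Converts a molar free-energy barrier into a rate constant via
#' transition-state theory, `k = (k_B T / h) exp(-dG / (R T))`, with
#' transmission coefficient 1. The returned value is on the s^-1 scale; for
#' bi- and termolecular rate terms the implied standard-state concentration
#' is 1 mol/l, so the number is used as-is against concentrations in mol/l.
#'
#' @param barrier Free-energy barrier of activation, J/mol. Negative barriers
#'   are accepted (the exponential then amplifies the frequency factor) but
#'   are flagged with a message.
#' @param temperature Absolute temperature, K. Must be positive.
#' @return Rate constant value(s), numeric, same length as `barrier`.
#' @examples
#' eyring_rate(113110.8, 298.15)
#' eyring_rate(0, 298.15) # frequency factor k_B T / h
#' @export
eyring_rate <- function(barrier, temperature) {
  if (!is.numeric(temperature) || any(!is.finite(temperature)) ||
      any(temperature <= 0)) {
    stop("`temperature` must be a positive, finite number (K)", call. = FALSE)
  }
  if (!is.numeric(barrier) || any(!is.finite(barrier))) {
    stop("`barrier` must be finite (J/mol)", call. = FALSE)
  }
  if (any(barrier < 0)) {
    message("eyring_rate: negative free-energy barrier supplied; ",
            "rate exceeds the frequency factor k_B*T/h")
  }
  (.nk_boltzmann * temperature / .nk_planck) *
    exp(-barrier / (.nk_gas_constant * temperature))
}
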