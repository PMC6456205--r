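# Unit conversions. All internal computation is in SI (Pa, m, s, m^3/s);
# user-facing values are mmHg and uL/min as customary in ocular physiology.

#' Pressure-unit conversion constant
#'
#' Pascals per millimetre of mercury. With this constant a no-flow pressure of
#' 3 mmHg corresponds to approximately 400 Pa.
#' @export
MMHG_PA <- 133.322

#' Convert pressure between mmHg and Pa
#'
#' @param p Pressure in mmHg (`mmHg_to_Pa`) or Pa (`Pa_to_mmHg`).
#' @return Converted pressure (numeric, vectorised).
#' @examples
#' mmHg_to_Pa(3)    # ~400 Pa
#' Pa_to_mmHg(400)  # ~3 mmHg
#' @export
mmHg_to_Pa <- function(p) p * MMHG_PA

#' @rdname mmHg_to_Pa
#' @export
Pa_to_mmHg <- function(p) p / MMHG_PA

#' Convert volumetric flow between uL/min and m^3/s
#'
#' @param q Flow in uL/min (`ulmin_to_m3s`) or m^3/s (`m3s_to_ulmin`).
#' @return Converted flow (numeric, vectorised).
#' @examples
#' ulmin_to_m3s(60)  # 1e-9 m^3/s
#' @export
ulmin_to_m3s <- function(q) q * 1e-9 / 60

#' @rdname ulmin_to_m3s
#' @export
m3s_to_ulmin <- function(q) q * 60 / 1e-9

# Surface hydraulic conductivity C^SL (uL/min/mmHg) to SI (m^3/s/Pa).
csl_to_si <- function(c_sl) ulmin_to_m3s(c_sl) / MMHG_PA

# Outflow decay constant alpha (1/mmHg) to SI (1/Pa).
alpha_to_si <- function(alpha) alpha / MMHG_PA
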