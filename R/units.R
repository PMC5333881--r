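## Unit conversions and physical constants used throughout the package.
## All internal computation is in SI (m, s, kg, Pa, m^3/s); tables and
## reports use the field's customary units (mm, mmHg, L/min, MPa).

#' Unit conversions
#'
#' Exact double-precision conversions between SI units and the customary
#' units of clinical hemodynamics (1 mmHg = 133.322 Pa).
#'
#' @param x numeric vector.
#' @return converted numeric vector.
#' @examples
#' mmHg_to_pa(1)        # 133.322
#' m3s_to_lmin(9.65e-5) # ~5.79
#' @export
mmHg_to_pa <- function(x) x * 133.322

#' @rdname mmHg_to_pa
#' @export
pa_to_mmHg <- function(x) x / 133.322

#' @rdname mmHg_to_pa
#' @export
lmin_to_m3s <- function(x) x * 1e-3 / 60

#' @rdname mmHg_to_pa
#' @export
m3s_to_lmin <- function(x) x * 60 * 1e3

#' Blood properties
#'
#' Default blood density (1060 kg/m^3) and dynamic viscosity (4.0 mPa s),
#' standard values for large-artery hemodynamics; both configurable in
#' [solver_config()].
#'
#' @return named list with `rho` (kg/m^3) and `mu` (Pa s).
#' @export
blood_properties <- function() list(rho = 1060, mu = 4.0e-3)
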