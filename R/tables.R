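## Bundled reference tables: regional wall properties by age, Windkessel
## outlet parameters by age, and population aorto-iliac PWV calibration
## targets. These are the printed inputs the pipeline runs from, so the
## full analysis requires no downloads.

#' Regional aortic wall properties by age
#'
#' Station-wise geometric and material properties of the aortic wall at the
#' three property stations -- ascending thoracic aorta (ATA, s = 0.12),
#' proximal descending thoracic aorta (DTA, s = 0.4) and infrarenal
#' abdominal aorta (IAA, s = 0.88) -- for the baseline 30-year-old subject
#' and the three virtually aged models (40, 60, 75 yo). Material stiffness
#' is the in vivo linearized biaxial stiffness (circumferential `K_th`,
#' axial `K_z`) obtained by small-on-large linearization at the transmural
#' pressure MAP - EP; for the 30 yo baseline only geometry and MAP are
#' available, which is why the baseline itself is never simulated.
#'
#' @return data.frame with columns `age` (years), `station` ("ATA", "DTA",
#'   "IAA"), `s` (normalized arc length of the station), `radius_mm` (inner
#'   radius), `thickness_mm`, `map_mmHg`, `ep_mmHg` (external pressure from
#'   perivascular support), `lambda_z`, `lambda_th` (in vivo axial and
#'   circumferential stretch) and `K_th_MPa`, `K_z_MPa`.
#' @seealso [assign_wall_properties()], [wall_from_table()]
#' @export
wall_property_table <- function() {
  st <- c("ATA", "DTA", "IAA")
  s  <- c(0.12, 0.40, 0.88)
  data.frame(
    age = rep(c(30, 40, 60, 75), each = 3),
    station = rep(st, 4),
    s = rep(s, 4),
    radius_mm    = c(13.2, 9.60, 7.81,  14.07, 11.63, 8.24,
                     16.13, 12.08, 8.27, 16.25, 12.71, 8.98),
    thickness_mm = c(1.80, 1.76, 1.14,  2.00, 1.70, 1.05,
                     2.45, 1.90, 1.50,  2.90, 2.15, 1.92),
    map_mmHg     = c(89, 89, 91,  93, 93, 95,  95, 95, 97,  102, 102, 105),
    ep_mmHg      = c(NA, NA, NA,  7, 2, 0,  17, 12, 0,  15, 10, 0),
    lambda_z     = c(NA, NA, NA,  1.15, 1.17, 1.23,
                     1.08, 1.09, 1.09,  1.03, 1.03, 1.04),
    lambda_th    = c(NA, NA, NA,  1.34, 1.24, 1.24,
                     1.22, 1.21, 1.12,  1.14, 1.22, 1.01),
    K_th_MPa     = c(NA, NA, NA,  0.40, 0.50, 1.46,
                     0.75, 0.71, 1.66,  0.91, 1.02, 2.14),
    K_z_MPa      = c(NA, NA, NA,  0.28, 0.46, 1.30,
                     0.27, 0.64, 1.51,  0.41, 0.58, 1.97),
    stringsAsFactors = FALSE
  )
}

#' Normalized arc-length coordinates of the three wall-property stations
#' @return named numeric vector (ATA, DTA, IAA).
#' @export
wall_stations <- function() c(ATA = 0.12, DTA = 0.40, IAA = 0.88)

#' Three-element Windkessel parameters for the fifteen outlets
#'
#' Proximal resistance, distal resistance and compliance of the RCR
#' (Resistance-Capacitance-Resistance) models coupled to every outlet of
#' the arterial tree. `R_prox` and `C` are age-invariant; `R_dist` carries
#' one column per age group (it is the only parameter that increases with
#' aging, reproducing the reported rise of MAP). The iliac outlets print a
#' single distal resistance, taken here as age-invariant. Resistances are
#' in 1e9 Pa s/m^3 and compliances in 1e-9 m^3/Pa.
#'
#' @return data.frame with columns `outlet`, `vessel`, `R_prox_e9`,
#'   `R_dist_40_e9`, `R_dist_60_e9`, `R_dist_75_e9`, `C_e9`.
#' @seealso [windkessel_set()] for one age in SI units.
#' @export
windkessel_table <- function() {
  data.frame(
    outlet = c("r_subclavian", "l_subclavian", "r_carotid", "l_carotid",
               "r_renal", "l_renal", "celiac", "gastric", "splenic",
               "sup_mesenteric", "inf_mesenteric",
               "r_ext_iliac", "r_int_iliac", "l_ext_iliac", "l_int_iliac"),
    vessel = c("Right Subclavian", "Left Subclavian", "Right Carotid",
               "Left Carotid", "Right Renal", "Left Renal", "Celiac Artery",
               "Gastric Artery", "Splenic Artery", "Superior Mesenteric",
               "Inferior Mesenteric", "Right Ext. Iliac", "Right Int. Iliac",
               "Left Ext. Iliac", "Left Int. Iliac"),
    R_prox_e9    = c(0.20, 0.18, 0.23, 0.22, 0.24, 0.25, 0.35, 1.20, 0.55,
                     0.23, 1.40, 0.08, 0.29, 0.08, 0.30),
    R_dist_40_e9 = c(1.60, 1.53, 1.91, 1.80, 1.12, 1.15, 1.53, 5.59, 2.50,
                     0.60, 3.82, 1.49, 5.50, 1.49, 5.45),
    R_dist_60_e9 = c(1.66, 1.58, 1.98, 1.86, 1.16, 1.20, 1.59, 5.81, 2.60,
                     0.63, 3.99, 1.49, 5.50, 1.49, 5.45),
    R_dist_75_e9 = c(1.75, 1.68, 2.09, 1.97, 1.24, 1.27, 1.70, 6.18, 2.76,
                     0.67, 4.28, 1.49, 5.50, 1.49, 5.45),
    C_e9         = c(1.68, 1.75, 1.40, 1.49, 2.43, 2.36, 1.78, 0.49, 1.09,
                     4.65, 0.73, 2.15, 0.56, 2.15, 0.56),
    stringsAsFactors = FALSE
  )
}

#' Windkessel boundary-condition set for one age, in SI units
#'
#' @param age one of 40, 60, 75.
#' @param p_out distal reference (venous) pressure, Pa. Default 0.
#' @return data.frame with columns `outlet`, `R_prox`, `R_dist`, `C`,
#'   `P_out` (Pa s/m^3, m^3/Pa, Pa).
#' @export
windkessel_set <- function(age, p_out = 0) {
  tab <- windkessel_table()
  col <- paste0("R_dist_", age, "_e9")
  if (!col %in% names(tab))
    stop("no Windkessel data for age ", age, "; available ages: 40, 60, 75")
  data.frame(
    outlet = tab$outlet,
    R_prox = tab$R_prox_e9 * 1e9,
    R_dist = tab[[col]] * 1e9,
    C      = tab$C_e9 * 1e-9,
    P_out  = p_out,
    stringsAsFactors = FALSE
  )
}

#' Population reference aorto-iliac pulse wave velocity by age
#'
#' Foot-to-foot aorto-iliac PWV values from population studies of subjects
#' with no cardiovascular risk factors (carotid-to-femoral measurements
#' standardized on the intersecting-tangent transit time and rescaled by
#' 0.8 from direct distance to true aorto-iliac path length). These are the
#' calibration targets of the external-support tuning loop.
#'
#' @return data.frame with columns `age` and `pwv_ms` (m/s).
#' @export
pwv_reference <- function() {
  data.frame(age = c(40, 60, 75), pwv_ms = c(6.9, 9.3, 10.9))
}
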