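## wall_mechanics: four-fiber-family constitutive model, small-on-large
## biaxial linearization about the in vivo state, linearized pressure-area
## tube law with external support, and assignment of wall properties along
## the tree.
##
## Default operating mode is "table": the published linearized stiffness
## values drive the simulation directly. The constitutive path exists for
## users supplying their own four-fiber parameters (the fitted parameter
## sets behind the bundled table are not printed) and powers the full
## re-linearization variant of the support calibration loop.

#' Four-fiber-family constitutive parameters
#'
#' Strain energy per unit reference volume of a single-layered arterial
#' wall: a neo-Hookean term for the elastin-dominated amorphous matrix
#' plus four Fung-type exponential fiber families (axial, circumferential
#' and two symmetric diagonal families),
#' `W = c/2 (I1 - 3) + sum_k c1_k/(4 c2_k) (exp(c2_k (lam_k^2 - 1)^2) - 1)`
#' with `lam_k^2 = lz^2 cos^2(a_k) + lth^2 sin^2(a_k)` and incompressible
#' kinematics `lr = 1/(lth lz)`.
#'
#' @param c neo-Hookean modulus (Pa).
#' @param c1 length-4 vector of fiber moduli (Pa), ordered axial,
#'   circumferential, and the two diagonal families.
#' @param c2 length-4 vector of dimensionless fiber exponents.
#' @param alpha_diag diagonal fiber angle from the axial direction (rad);
#'   the two diagonal families share the angle magnitude.
#' @return object of class `four_fiber_params`.
#' @export
four_fiber_params <- function(c, c1, c2, alpha_diag = pi / 4) {
  stopifnot(c >= 0, length(c1) == 4, length(c2) == 4,
            all(c1 >= 0), all(c2 >= 0))
  structure(list(c = c, c1 = c1, c2 = c2,
                 alpha = c(0, pi / 2, alpha_diag, -alpha_diag)),
            class = "four_fiber_params")
}

# strain energy and its first/second derivatives wrt (lth, lz); returns a
# list so the stress and stiffness routines share one code path
fiber_terms <- function(lth, lz, p) {
  s2 <- sin(p$alpha)^2; c2a <- cos(p$alpha)^2
  lam2 <- outer(lz^2, c2a) + outer(lth^2, s2)   # n x 4
  E <- lam2 - 1
  expo <- sweep(E^2, 2, p$c2, `*`)
  if (any(expo > 700)) {
    k <- which(apply(expo > 700, 2, any))[1]
    stop("exponential overflow in fiber family ", k,
         " at the requested stretch; reduce c2 or the stretch range")
  }
  e <- exp(expo)
  list(E = E, e = e, s2 = s2, c2a = c2a)
}

#' Strain energy of the four-fiber-family wall model
#'
#' @param lth,lz circumferential and axial stretch (vectorized).
#' @param params a [four_fiber_params()].
#' @return strain energy W (Pa). `W = 0` at `lth = lz = 1`.
#' @export
strain_energy <- function(lth, lz, params) {
  stopifnot(all(lth > 0), all(lz > 0))
  I1 <- lth^2 + lz^2 + 1 / (lth^2 * lz^2)
  ft <- fiber_terms(lth, lz, params)
  Wf <- sweep(ft$e - 1, 2, params$c1 / (4 * params$c2), `*`)
  Wf[, params$c1 == 0] <- 0   # 0/0 guard when a family is switched off
  params$c / 2 * (I1 - 3) + rowSums(Wf)
}

# first derivatives of W wrt stretches
strain_energy_grad <- function(lth, lz, p) {
  ft <- fiber_terms(lth, lz, p)
  g <- sweep(ft$E * ft$e, 2, p$c1, `*`)      # c1 E exp(c2 E^2)
  dW_dlt <- p$c * (lth - lth^-3 * lz^-2) +
    rowSums(sweep(g, 2, ft$s2, `*`)) * lth
  dW_dlz <- p$c * (lz - lz^-3 * lth^-2) +
    rowSums(sweep(g, 2, ft$c2a, `*`)) * lz
  list(dlt = dW_dlt, dlz = dW_dlz)
}

strain_energy_hess <- function(lth, lz, p) {
  ft <- fiber_terms(lth, lz, p)
  g  <- sweep(ft$E * ft$e, 2, p$c1, `*`)
  gp <- sweep(ft$e * (1 + 2 * sweep(ft$E^2, 2, p$c2, `*`)), 2, p$c1, `*`)
  d2_tt <- p$c * (1 + 3 * lth^-4 * lz^-2) +
    rowSums(sweep(gp, 2, ft$s2^2, `*`)) * 2 * lth^2 +
    rowSums(sweep(g, 2, ft$s2, `*`))
  d2_zz <- p$c * (1 + 3 * lz^-4 * lth^-2) +
    rowSums(sweep(gp, 2, ft$c2a^2, `*`)) * 2 * lz^2 +
    rowSums(sweep(g, 2, ft$c2a, `*`))
  d2_tz <- p$c * 2 * lth^-3 * lz^-3 +
    rowSums(sweep(gp, 2, ft$s2 * ft$c2a, `*`)) * 2 * lth * lz
  list(tt = d2_tt, zz = d2_zz, tz = d2_tz)
}

#' In vivo wall state
#'
#' The finitely deformed configuration about which the wall response is
#' linearized: thin-walled cylinder at the mean transmural pressure
#' `TP = MAP - EP`, elongated to the in vivo axial stretch.
#'
#' @param radius inner radius (m), `thickness` wall thickness (m).
#' @param lambda_z,lambda_th in vivo axial and circumferential stretch.
#' @param map mean arterial pressure (Pa).
#' @param ep external pressure from perivascular support (Pa).
#' @return object of class `in_vivo_state`.
#' @export
in_vivo_state <- function(radius, thickness, lambda_z, lambda_th, map,
                          ep = 0) {
  tp <- map - ep
  stopifnot(lambda_z > 0, lambda_th > 0, thickness < radius, tp > 0)
  structure(list(R = radius, h = thickness, lambda_z = lambda_z,
                 lambda_th = lambda_th, map = map, ep = ep, tp = tp),
            class = "in_vivo_state")
}

#' Biaxial Cauchy membrane stresses
#'
#' Stresses of the incompressible membrane under plane stress (zero mean
#' radial stress): `sigma_th = lth dW/dlth`, `sigma_z = lz dW/dlz` with the
#' radial stretch eliminated by incompressibility.
#'
#' @param lth,lz stretches (or pass an [in_vivo_state()] as `lth`).
#' @param params a [four_fiber_params()].
#' @return list with `sigma_th`, `sigma_z` (Pa).
#' @export
biaxial_stress <- function(lth, lz = NULL, params) {
  if (inherits(lth, "in_vivo_state")) {
    lz <- lth$lambda_z; lth <- lth$lambda_th
  }
  g <- strain_energy_grad(lth, lz, params)
  list(sigma_th = lth * g$dlt, sigma_z = lz * g$dlz)
}

#' Circumferential stretch in equilibrium with a transmural pressure
#'
#' Solves `sigma_th(lth, lz) = TP R / h` (thin-wall equilibrium at the
#' current radius and thickness) for the circumferential stretch.
#'
#' @param params a [four_fiber_params()].
#' @param tp transmural pressure (Pa).
#' @param radius,thickness current (in vivo) radius and thickness (m).
#' @param lambda_z prescribed axial stretch.
#' @param interval search interval for the stretch.
#' @return equilibrium circumferential stretch.
#' @export
equilibrium_stretch <- function(params, tp, radius, thickness, lambda_z,
                                interval = c(0.6, 3)) {
  target <- tp * radius / thickness
  f <- function(l) biaxial_stress(l, lambda_z, params)$sigma_th - target
  stats::uniroot(f, interval, tol = 1e-12)$root
}

#' Small-on-large linearization of the wall response
#'
#' Incremental plane-stress biaxial moduli about the in vivo state:
#' `K_thth = lth d(sigma_th)/d(lth)` at fixed axial stretch and
#' `K_zz = lz d(sigma_z)/d(lz)` at fixed circumferential stretch, i.e. the
#' stiffness of the finitely-deformed membrane against superimposed small
#' deformations. The state must satisfy thin-wall equilibrium
#' (`sigma_th = TP R/h`) to within `tol` relative error.
#'
#' @param state an [in_vivo_state()].
#' @param params a [four_fiber_params()].
#' @param tol relative equilibrium tolerance.
#' @return a [linearized_wall()] with `source = "constitutive"`.
#' @export
small_on_large <- function(state, params, tol = 1e-3) {
  lth <- state$lambda_th; lz <- state$lambda_z
  sig <- biaxial_stress(lth, lz, params)
  target <- state$tp * state$R / state$h
  if (abs(sig$sigma_th - target) > tol * max(abs(target), 1))
    stop("state is not in equilibrium (sigma_th = ",
         format(sig$sigma_th, digits = 4), " Pa vs TP*R/h = ",
         format(target, digits = 4),
         " Pa); solve equilibrium_stretch() first")
  K <- stiffness_matrix(lth, lz, params)
  linearized_wall(K_th = K[1, 1], K_z = K[2, 2], thickness = state$h,
                  radius = state$R, map = state$map, ep = state$ep,
                  source = "constitutive")
}

#' Incremental stiffness matrix about a biaxial state
#'
#' @inheritParams biaxial_stress
#' @return 2x2 matrix `[K_thth, K_thz; K_zth, K_zz]` (Pa); the off-diagonal
#'   terms are second-derivative cross moduli and are symmetric.
#' @export
stiffness_matrix <- function(lth, lz, params) {
  g <- strain_energy_grad(lth, lz, params)
  H <- strain_energy_hess(lth, lz, params)
  K_tt <- lth * g$dlt + lth^2 * H$tt
  K_zz <- lz * g$dlz + lz^2 * H$zz
  K_tz <- lth * lz * H$tz   # lth * d(sigma_z)/d(lth)
  K_zt <- lz * lth * H$tz   # lz  * d(sigma_th)/d(lz)
  matrix(c(K_tt, K_zt, K_tz, K_zz), 2, 2,
         dimnames = list(c("th", "z"), c("th", "z")))
}

#' Linearized wall description at one location
#'
#' Per-location in vivo biaxial material stiffness, thickness, radius and
#' pressures -- the quantities that close the 1D tube law. The axial
#' stiffness `K_z` is carried through the data model but does not enter
#' the radial tube law (documented limitation: only radial tethering and
#' motion are modelled).
#'
#' @param K_th,K_z circumferential and axial material stiffness (Pa).
#' @param thickness,radius wall thickness and inner radius (m).
#' @param map mean arterial pressure (Pa) at the location.
#' @param ep external pressure carried by perivascular support (Pa).
#' @param source `"table"` or `"constitutive"`.
#' @return object of class `linearized_wall`.
#' @export
linearized_wall <- function(K_th, K_z, thickness, radius, map, ep = 0,
                            source = "table") {
  stopifnot(K_th > 0, K_z > 0, thickness > 0, radius > thickness)
  structure(list(K_th = K_th, K_z = K_z, h = thickness, R = radius,
                 map = map, ep = ep, source = source),
            class = "linearized_wall")
}

#' Linearized wall at a published (age, station) table entry
#'
#' @param age 40, 60 or 75.
#' @param station `"ATA"`, `"DTA"` or `"IAA"`.
#' @param table the wall-property table.
#' @return a [linearized_wall()] with `source = "table"`.
#' @export
wall_from_table <- function(age, station, table = wall_property_table()) {
  row <- table[table$age == age & table$station == station, ]
  if (nrow(row) != 1 || is.na(row$K_th_MPa))
    stop("no linearized stiffness tabulated for age ", age, " at ", station)
  linearized_wall(K_th = row$K_th_MPa * 1e6, K_z = row$K_z_MPa * 1e6,
                  thickness = row$thickness_mm * 1e-3,
                  radius = row$radius_mm * 1e-3,
                  map = mmHg_to_pa(row$map_mmHg),
                  ep = mmHg_to_pa(row$ep_mmHg), source = "table")
}

#' Linearized pressure-area tube law with external support
#'
#' The wall and the perivascular support act as parallel linear springs on
#' the radius, sharing the lumen load from a common zero-traction radius
#' `r0` (the wall-unloaded radius, obtained by linear extrapolation of the
#' in vivo state): structural wall stiffness `Kw = K_th h / R^2` plus
#' support stiffness `k_s` give the area compliance
#' `dA/dP = 2 pi r / (Kw + k_s)` and the local (Moens-Korteweg-type) wave
#' speed `c = sqrt((K_th h / R + k_s R) / (2 rho))`, both evaluated at the
#' mean (MAP) configuration. The support damping `c_s` enters the solver
#' as a radial-velocity pressure contribution.
#'
#' @param wall a [linearized_wall()].
#' @param k_s support stiffness (Pa/m).
#' @param c_s support damping (Pa s/m).
#' @param rho blood density (kg/m^3).
#' @return object of class `tube_law` with fields `A_ref` (area at `P_ref`),
#'   `P_ref` (= MAP), `dAdP`, `c` (wave speed, m/s), `r0`, `k_wall`, `k_s`,
#'   `c_s`.
#' @export
tube_law <- function(wall, k_s = 0, c_s = 0, rho = blood_properties()$rho) {
  stopifnot(k_s >= 0, c_s >= 0)
  Kw <- wall$K_th * wall$h / wall$R^2
  tp <- wall$map - wall$ep
  r0 <- wall$R - tp / Kw
  if (r0 <= 0)
    stop("linearized unloaded radius is non-positive; wall too compliant ",
         "for the linear tube law")
  k_tot <- Kw + k_s
  r_op <- r0 + wall$map / k_tot
  A_ref <- pi * r_op^2
  dAdP <- 2 * pi * r_op / k_tot
  structure(list(A_ref = A_ref, P_ref = wall$map, dAdP = dAdP,
                 c = sqrt(A_ref / (rho * dAdP)), r0 = r0, r_op = r_op,
                 k_wall = Kw, k_s = k_s, c_s = c_s, rho = rho),
            class = "tube_law")
}

#' Local wave speed of a tube law
#' @param law a [tube_law()].
#' @return wave speed (m/s) at the reference configuration.
#' @export
wave_speed <- function(law) law$c

#' Default isotropic stiffness of the carotid and subclavian arteries
#'
#' The carotid (and, by the comparable-radius rule, subclavian) arteries
#' are the only vessels with isotropic prescribed properties. Published
#' regional data for them are limited to elastic-modulus trends, so the
#' defaults below are set to give age-typical carotid wave speeds
#' (approximately 6, 7.5 and 8.5 m/s at 40, 60 and 75 yo); they are
#' approximate and configurable.
#'
#' @return list with `carotid_K_MPa` (named by age), `carotid_h_mm`,
#'   `subclavian_h_mm`.
#' @export
branch_stiffness_defaults <- function() {
  list(carotid_K_MPa = c(`40` = 0.38, `60` = 0.59, `75` = 0.76),
       carotid_h_mm = 0.75, subclavian_h_mm = 0.85)
}

#' Assign wall properties along the tree for one age
#'
#' Builds the continuous wall-property field: trunk stiffness, thickness,
#' MAP and EP interpolate the station values linearly in s with constant
#' extrapolation beyond s = 0.12 and s = 0.88 (through the iliacs);
#' carotid and subclavian branches receive the isotropic age-dependent
#' stiffness; mesenteric, celiac, renal and other muscular branches keep
#' an age-invariant stiffness equal to the 75 yo abdominal aorta at the
#' renal level (muscular arteries do not stiffen with age).
#'
#' @param tree an `aorto_tree` already aged to `age`.
#' @param age 40, 60 or 75.
#' @param table wall-property station table.
#' @param branch_stiffness see [branch_stiffness_defaults()].
#' @return object of class `wall_field` with interpolators `K_of_s`,
#'   `Kz_of_s`, `h_of_s`, `map_of_s`, `ep_of_s` (SI units) and a
#'   `branches` data.frame of per-branch properties.
#' @export
assign_wall_properties <- function(tree, age,
                                   table = wall_property_table(),
                                   branch_stiffness =
                                     branch_stiffness_defaults()) {
  ta <- table[table$age == age, ]
  if (nrow(ta) != 3 || anyNA(ta$K_th_MPa))
    stop("no linearized stiffness tabulated for age ", age,
         "; available ages: 40, 60, 75")
  ta <- ta[match(c("ATA", "DTA", "IAA"), ta$station), ]
  s_st <- ta$s
  K_of_s  <- function(s) station_interp(s_st, ta$K_th_MPa * 1e6, pmin(s, 1))
  Kz_of_s <- function(s) station_interp(s_st, ta$K_z_MPa * 1e6, pmin(s, 1))
  h_of_s  <- function(s) station_interp(s_st, ta$thickness_mm * 1e-3,
                                        pmin(s, 1))
  map_of_s <- function(s) station_interp(s_st, mmHg_to_pa(ta$map_mmHg),
                                         pmin(s, 1))
  ep_of_s <- function(s) station_interp(s_st, mmHg_to_pa(ta$ep_mmHg),
                                        pmin(s, 1))

  t75 <- table[table$age == 75 & table$station == "IAA", ]
  seg <- tree$segments
  br <- seg[seg$type == "branch", , drop = FALSE]
  if (nrow(br)) {
    bad <- !(br$class %in% c("upper", "lower", "iliac"))
    if (any(bad))
      stop("unknown branch class for ", paste(br$name[bad], collapse = ", "),
           "; rules cover classes: upper (carotid-like stiffness), ",
           "lower (75 yo renal-level aortic stiffness), ",
           "iliac (IAA extrapolation)")
    r_b <- br$radius_mm * 1e-3
    K <- h <- ep <- numeric(nrow(br))
    aK <- branch_stiffness$carotid_K_MPa[[as.character(age)]]
    if (is.null(aK)) stop("no carotid stiffness default for age ", age)
    for (i in seq_len(nrow(br))) {
      cls <- br$class[i]
      if (cls == "upper") {
        K[i] <- aK * 1e6
        h[i] <- (if (grepl("subclavian", br$name[i]))
          branch_stiffness$subclavian_h_mm else
            branch_stiffness$carotid_h_mm) * 1e-3
        ep[i] <- ep_of_s(0.12)   # same support environment as the ATA
      } else if (cls == "lower") {
        K[i] <- t75$K_th_MPa * 1e6            # age-invariant, muscular
        h[i] <- r_b[i] * t75$thickness_mm / t75$radius_mm
        ep[i] <- ep_of_s(0.88)
      } else {                                 # iliac continuation
        K[i] <- K_of_s(1); h[i] <- h_of_s(1); ep[i] <- ep_of_s(1)
      }
    }
    branches <- data.frame(name = br$name, class = br$class,
                           radius_m = r_b, K_th = K, thickness_m = h,
                           map = map_of_s(pmin(br$s0, 1)), ep = ep,
                           stringsAsFactors = FALSE)
  } else {
    branches <- data.frame(name = character(), class = character(),
                           radius_m = numeric(), K_th = numeric(),
                           thickness_m = numeric(), map = numeric(),
                           ep = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(age = age, K_of_s = K_of_s, Kz_of_s = Kz_of_s,
                 h_of_s = h_of_s, map_of_s = map_of_s, ep_of_s = ep_of_s,
                 branches = branches, stations = ta),
            class = "wall_field")
}

#' Query the wall field at a trunk station or branch
#'
#' @param walls a `wall_field`.
#' @param tree the matching `aorto_tree`.
#' @param s trunk coordinate (used when `segment` is `NULL` or a trunk
#'   piece / iliac segment).
#' @param segment optional branch name.
#' @return a [linearized_wall()].
#' @export
wall_at <- function(walls, tree, s = NULL, segment = NULL) {
  seg <- tree$segments
  if (!is.null(segment) && seg$type[match(segment, seg$name)] == "branch") {
    b <- walls$branches[walls$branches$name == segment, ]
    if (!nrow(b)) stop("unknown branch ", segment)
    linearized_wall(K_th = b$K_th, K_z = b$K_th, thickness = b$thickness_m,
                    radius = b$radius_m, map = b$map, ep = b$ep,
                    source = "table")
  } else {
    stopifnot(!is.null(s))
    linearized_wall(K_th = walls$K_of_s(s), K_z = walls$Kz_of_s(s),
                    thickness = walls$h_of_s(s),
                    radius = trunk_radius(tree, pmin(s, 1)),
                    map = walls$map_of_s(s), ep = walls$ep_of_s(s),
                    source = "table")
  }
}
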