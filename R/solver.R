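## pulse_wave_solver: 1D distributed blood-flow solver over the aortic
## tree -- mesh assembly, external tissue support maps, time integration
## (C++ core), waveform probes and external-pressure reporting.

#' Solver configuration
#'
#' @param dx target node spacing (m). Short trunk pieces between adjacent
#'   branch take-offs are resolved with at least 4 nodes.
#' @param cfl Courant number for the explicit two-step Lax-Wendroff
#'   scheme (stability bound 1; the default leaves margin for systolic
#'   distension and convective velocity).
#' @param n_record waveform samples recorded per cycle (>= 100 required
#'   by the probe contract).
#' @param min_cycles,max_cycles cardiac cycles to run before/until the
#'   periodicity check.
#' @param tol_mmHg periodicity tolerance: maximum cycle-to-cycle nodal
#'   pressure difference (mmHg).
#' @param rho,mu blood density (kg/m^3) and dynamic viscosity (Pa s); the
#'   friction model is a Poiseuille-profile resistance `K_R = 8 pi mu/rho`
#'   with flat momentum-flux profile.
#' @param p_init initial pressure (Pa); default: root MAP minus 20 mmHg
#'   (age-specific diastolic estimate), zero flow.
#' @return object of class `solver_config`.
#' @export
solver_config <- function(dx = 0.01, cfl = 0.8, n_record = 2048,
                          min_cycles = 6, max_cycles = 24, tol_mmHg = 0.4,
                          rho = blood_properties()$rho,
                          mu = blood_properties()$mu, p_init = NULL) {
  stopifnot(dx > 0, cfl > 0, cfl <= 1, n_record >= 100,
            min_cycles >= 1, max_cycles >= min_cycles)
  structure(list(dx = dx, cfl = cfl, n_record = n_record,
                 min_cycles = min_cycles, max_cycles = max_cycles,
                 tol = mmHg_to_pa(tol_mmHg), rho = rho, mu = mu,
                 p_init = p_init),
            class = "solver_config")
}

#' External tissue support map
#'
#' Piecewise-constant viscoelastic support (stiffness `k_s`, damping
#' `c_s`) over the three aortic support regions: ATA for s in [0, 0.25],
#' DTA for s in (0.25, 0.66] and IAA for s > 0.66. Upper (arch) branches
#' inherit the ATA values, lower branches the IAA values.
#'
#' @param k_s named numeric vector (`ATA`, `DTA`, `IAA`) of support
#'   stiffness (Pa/m).
#' @param c_s named numeric vector of support damping (Pa s/m).
#' @param bounds region boundaries on s.
#' @return object of class `external_support`.
#' @export
external_support <- function(k_s = c(ATA = 0, DTA = 0, IAA = 0),
                             c_s = c(ATA = 0, DTA = 0, IAA = 0),
                             bounds = c(0.25, 0.66)) {
  stopifnot(all(k_s >= 0), all(c_s >= 0),
            all(c("ATA", "DTA", "IAA") %in% names(k_s)),
            all(c("ATA", "DTA", "IAA") %in% names(c_s)))
  structure(list(k_s = k_s, c_s = c_s, bounds = bounds),
            class = "external_support")
}

#' Support parameters at a location
#'
#' @param support an [external_support()].
#' @param s trunk coordinate (used for trunk and iliac locations).
#' @param class branch inheritance class: `"upper"` branches take the ATA
#'   values, `"lower"` branches the IAA values; `NULL`/`"trunk"`/`"iliac"`
#'   resolve by `s`.
#' @return list with `k_s` and `c_s`.
#' @export
support_at <- function(support, s = NULL, class = NULL) {
  region <- if (!is.null(class) && class == "upper") "ATA"
  else if (!is.null(class) && class == "lower") "IAA"
  else {
    if (is.null(s)) stop("support region uncovered: no s or class given")
    ifelse(s <= support$bounds[1], "ATA",
           ifelse(s <= support$bounds[2], "DTA", "IAA"))
  }
  list(k_s = unname(support$k_s[region]), c_s = unname(support$c_s[region]))
}

# node-level tube-law quantities from wall + support properties
# (parallel-spring closure; see tube_law())
node_tube <- function(R, K, h, map, ep, ks, cs, rho) {
  Kw <- K * h / R^2
  r0 <- R - (map - ep) / Kw
  if (any(r0 <= 0)) stop("non-positive unloaded radius in mesh assembly")
  ktot <- Kw + ks
  r_op <- r0 + map / ktot
  # solver tube law is linear in radius: P = Pref + beta (sqrt(A) - sqrt(Aref))
  list(Aref = pi * r_op^2, beta = ktot / sqrt(pi), Pref = map,
       Dv = cs * r_op / (2 * rho), r0 = r0, ks = ks, r_op = r_op)
}

# internal mesh/model builder shared by assemble() and
# vessel_network_model(); `segs` is a list of segment descriptors with a
# per-segment property closure prop(x_local)
build_pw_model <- function(segs, bcs, inflow, config) {
  names_ <- vapply(segs, `[[`, "", "name")
  parents <- vapply(segs, function(s) s$parent %||% NA_character_, "")
  if (is.na(parents[1]) == FALSE)
    stop("first segment must be the root (parent NA)")
  nodes <- list(); seg_off <- integer(); seg_n <- integer()
  seg_dx <- numeric(); off <- 0L
  for (k in seq_along(segs)) {
    sg <- segs[[k]]
    n <- max(4L, as.integer(ceiling(sg$length / config$dx)) + 1L)
    x <- seq(0, sg$length, length.out = n)
    pr <- sg$prop(x)
    tl <- node_tube(pr$R, pr$K_th, pr$h, pr$map, pr$ep, pr$ks, pr$cs,
                    config$rho)
    nodes[[k]] <- data.frame(
      seg = sg$name, x = x,
      s = if (is.null(sg$s_of_x)) NA_real_ else sg$s_of_x(x),
      Aref = tl$Aref, beta = tl$beta, Pref = tl$Pref, Dv = tl$Dv,
      r0 = tl$r0, ks = tl$ks, r_op = tl$r_op,
      stringsAsFactors = FALSE)
    seg_off <- c(seg_off, off); seg_n <- c(seg_n, n)
    seg_dx <- c(seg_dx, x[2] - x[1]); off <- off + n
  }
  nodes <- do.call(rbind, nodes)

  # junction list: every segment with children
  junctions <- list()
  for (k in seq_along(segs)) {
    ch <- which(parents == names_[k])
    if (length(ch))
      junctions[[length(junctions) + 1]] <-
        list(parent = k - 1L, children = as.integer(ch - 1L))
  }
  terminals <- which(!(names_ %in% parents))
  outlet_ids <- vapply(segs, function(s) s$outlet %||% NA_character_, "")
  out_seg <- integer(); Rp <- Rd <- Cc <- Po <- numeric()
  for (k in terminals) {
    oid <- outlet_ids[k]
    if (is.na(oid))
      stop("assembly error: terminal segment ", names_[k],
           " has no outlet id")
    row <- bcs[bcs$outlet == oid, ]
    if (nrow(row) != 1)
      stop("assembly error: no Windkessel boundary condition for outlet ",
           oid)
    stopifnot(row$R_prox > 0, row$R_dist > 0, row$C > 0)
    out_seg <- c(out_seg, k - 1L)
    Rp <- c(Rp, row$R_prox); Rd <- c(Rd, row$R_dist)
    Cc <- c(Cc, row$C); Po <- c(Po, row$P_out)
  }

  # time step: CFL on the reference wave speed with margin for systolic
  # distension and convection, plus the explicit-diffusion bound from the
  # support damping term
  cref <- sqrt(nodes$beta * sqrt(nodes$Aref) / (2 * config$rho))
  dt <- Inf
  for (k in seq_along(segs)) {
    idx <- seg_off[k] + seq_len(seg_n[k])
    dt <- min(dt, config$cfl * seg_dx[k] / max(2.0 + 1.35 * cref[idx]))
    dv <- nodes$Dv[idx]
    if (any(dv > 0)) dt <- min(dt, 0.25 * seg_dx[k]^2 / max(dv))
  }
  steps <- as.integer(ceiling(inflow$period / dt))
  dt <- inflow$period / steps

  p_init <- config$p_init %||% (nodes$Pref[1] - mmHg_to_pa(20))
  cpp <- list(seg_off = as.integer(seg_off), seg_n = as.integer(seg_n),
              seg_dx = seg_dx,
              Aref = nodes$Aref, beta = nodes$beta, Pref = nodes$Pref,
              Dv = nodes$Dv, rho = config$rho,
              Kr = 8 * pi * config$mu / config$rho,
              junctions = junctions,
              out_seg = as.integer(out_seg), out_Rp = Rp, out_Rd = Rd,
              out_C = Cc, out_Pout = Po,
              inflow_q = inflow$flow, period = inflow$period)
  control <- list(dt = dt, steps_per_cycle = steps,
                  min_cycles = config$min_cycles,
                  max_cycles = config$max_cycles, tol = config$tol,
                  rec_stride = max(1L, steps %/% config$n_record),
                  P_init = p_init)
  structure(list(cpp = cpp, control = control, nodes = nodes,
                 seg_names = names_, seg_off = seg_off, seg_n = seg_n,
                 outlets = data.frame(outlet = outlet_ids[terminals],
                                      seg = terminals,
                                      stringsAsFactors = FALSE),
                 inflow = inflow, config = config),
            class = "pw_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble the discrete 1D model of an aortic tree
#'
#' Meshes every segment, attaches the tube law (wall + external support),
#' the root inflow waveform and one Windkessel boundary condition per
#' terminal, and fixes the CFL-limited time step.
#'
#' @param tree an `aorto_tree` aged to the target age.
#' @param walls matching [assign_wall_properties()] field.
#' @param bcs Windkessel set, see [windkessel_set()] or
#'   [tune_windkessel()].
#' @param inflow an `inflow_waveform` from [generate_inflow()].
#' @param support an [external_support()].
#' @param config a [solver_config()].
#' @return object of class `pw_model`, ready for [run_until_periodic()].
#' @export
assemble <- function(tree, walls, bcs, inflow,
                     support = external_support(),
                     config = solver_config()) {
  segdf <- tree$segments
  segs <- vector("list", nrow(segdf))
  L <- tree$trunk_length
  for (i in seq_len(nrow(segdf))) {
    row <- segdf[i, ]
    if (row$type == "trunk") {
      s0 <- row$s0
      prop <- local({
        s0l <- s0
        function(x) {
          s <- s0l + x / L
          sup <- support_at(support, s = s)
          data.frame(R = trunk_radius(tree, s), K_th = walls$K_of_s(s),
                     h = walls$h_of_s(s), map = walls$map_of_s(s),
                     ep = walls$ep_of_s(s), ks = sup$k_s, cs = sup$c_s)
        }
      })
      s_of_x <- local({ s0l <- s0; function(x) s0l + x / L })
    } else {
      b <- walls$branches[walls$branches$name == row$name, ]
      if (!nrow(b)) stop("no wall properties for branch ", row$name)
      iliac <- row$class == "iliac"
      sup <- if (iliac) support_at(support, s = row$s0 + 1e-9)
             else support_at(support, class = row$class)
      prop <- local({
        bl <- b; supl <- sup
        function(x) data.frame(R = bl$radius_m, K_th = bl$K_th,
                               h = bl$thickness_m, map = bl$map,
                               ep = bl$ep, ks = supl$k_s, cs = supl$c_s)
      })
      s_of_x <- if (iliac) local({ s0l <- row$s0; function(x) s0l + x / L })
                else NULL
    }
    segs[[i]] <- list(name = row$name, parent = row$parent,
                      length = row$length_m, prop = prop,
                      s_of_x = s_of_x,
                      outlet = if (is.na(row$outlet)) NULL else row$outlet)
  }
  model <- build_pw_model(segs, bcs, inflow, config)
  model$tree <- tree
  model$walls <- walls
  model$support <- support
  model
}

#' Single-vessel model for verification studies
#'
#' A uniform (optionally series-split) elastic tube with prescribed
#' inflow and one RCR Windkessel outlet -- the standard configuration for
#' wave-speed, friction and boundary-condition verification.
#'
#' @param length tube length (m), `radius` inner radius (m), `thickness`
#'   wall thickness (m), `K_th` circumferential stiffness (Pa).
#' @param map reference pressure (Pa) at which `radius` holds.
#' @param k_s,c_s external support parameters.
#' @param n_split number of identical series segments (> 1 exercises the
#'   area-matched junction closure).
#' @param bc list with `R_prox`, `R_dist`, `C`, `P_out`.
#' @param inflow an `inflow_waveform` (or compatible list with `time`,
#'   `flow`, `period`).
#' @param config a [solver_config()].
#' @return a `pw_model`.
#' @export
uniform_tube_model <- function(length = 1, radius = 0.01,
                               thickness = 0.0015, K_th = 0.5e6,
                               map = mmHg_to_pa(93), k_s = 0, c_s = 0,
                               n_split = 1,
                               bc = list(R_prox = 1e7, R_dist = 1e8,
                                         C = 1e-8, P_out = 0),
                               inflow, config = solver_config()) {
  stopifnot(n_split >= 1)
  li <- length / n_split
  segs <- vector("list", n_split)
  for (k in seq_len(n_split)) {
    x0 <- (k - 1) * li
    segs[[k]] <- list(
      name = paste0("tube_", k),
      parent = if (k == 1) NA_character_ else paste0("tube_", k - 1),
      length = li,
      prop = function(x) data.frame(R = radius, K_th = K_th, h = thickness,
                                    map = map, ep = 0, ks = k_s, cs = c_s),
      s_of_x = local({ x0l <- x0; Ll <- length
                       function(x) (x0l + x) / Ll }),
      outlet = if (k == n_split) "distal" else NULL)
  }
  bcs <- data.frame(outlet = "distal", R_prox = bc$R_prox,
                    R_dist = bc$R_dist, C = bc$C, P_out = bc$P_out)
  build_pw_model(segs, bcs, inflow, config)
}

#' Run the model to a periodic state
#'
#' Advances cardiac cycles until the maximum cycle-to-cycle nodal pressure
#' difference drops below the periodicity tolerance (after at least
#' `min_cycles`), then returns the final recorded cycle. Warns with the
#' residual if the cycle budget is exhausted first.
#'
#' @param model a `pw_model`.
#' @return object of class `pw_solution`: recorded final-cycle pressure /
#'   flow / area at every node, cycle means, per-cycle convergence
#'   residuals and the model.
#' @export
run_until_periodic <- function(model) {
  out <- pw_run_cpp(model$cpp, model$control)
  if (!out$converged)
    warning(sprintf(paste0("periodicity not reached in %d cycles; ",
                           "last residual %.3g mmHg"),
                    out$cycles, pa_to_mmHg(out$resid[length(out$resid)])))
  structure(list(P = out$P, Q = out$Q, A = out$A, time = out$time,
                 meanA = out$meanA, meanP = out$meanP, meanQ = out$meanQ,
                 resid = out$resid, cycles = out$cycles,
                 converged = out$converged,
                 period = model$inflow$period, model = model),
            class = "pw_solution")
}

#' @export
print.pw_solution <- function(x, ...) {
  cat(sprintf(paste0("<pw_solution> %d nodes, %d cycles (%s), ",
                     "final residual %.3g mmHg\n"),
              ncol(x$P), x$cycles,
              if (x$converged) "periodic" else "NOT periodic",
              pa_to_mmHg(x$resid[length(x$resid)])))
  invisible(x)
}

# nearest mesh node for a station; trunk/iliac by s, branch by local x
locate_node <- function(model, s = NULL, segment = NULL, x = NULL) {
  nd <- model$nodes
  if (!is.null(segment)) {
    idx <- which(nd$seg == segment)
    if (!length(idx)) stop("unknown segment ", segment)
    xq <- x %||% (max(nd$x[idx]) / 2)
    idx[which.min(abs(nd$x[idx] - xq))]
  } else {
    stopifnot(!is.null(s))
    idx <- which(!is.na(nd$s))
    idx[which.min(abs(nd$s[idx] - s))]
  }
}

#' Extract a waveform probe at a station
#'
#' @param solution a `pw_solution`.
#' @param s trunk coordinate of the probe (trunk and iliac chain); or
#' @param segment,x segment name and local position (m) for branches.
#' @return object of class `waveform_probe`: `time` (s), `pressure` (Pa),
#'   `flow` (m^3/s), `area` (m^2) over the final cycle, plus the station.
#' @export
probe <- function(solution, s = NULL, segment = NULL, x = NULL) {
  i <- locate_node(solution$model, s = s, segment = segment, x = x)
  nd <- solution$model$nodes[i, ]
  structure(list(time = solution$time, pressure = solution$P[, i],
                 flow = solution$Q[, i], area = solution$A[, i],
                 s = nd$s, segment = nd$seg, x = nd$x,
                 period = solution$period),
            class = "waveform_probe")
}

#' Probe as a data frame (CSV-ready, customary units)
#'
#' @param probe a `waveform_probe`.
#' @return data.frame with `time_s`, `pressure_mmHg`, `flow_lmin`,
#'   `area_cm2`.
#' @export
probe_table <- function(probe) {
  data.frame(time_s = probe$time,
             pressure_mmHg = pa_to_mmHg(probe$pressure),
             flow_lmin = m3s_to_lmin(probe$flow),
             area_cm2 = probe$area * 1e4)
}

#' External pressure carried by the perivascular support at a station
#'
#' `EP = k_s x (time-averaged radial displacement from the zero-support
#' (wall-unloaded) reference radius)` over the converged cycle: the
#' transmural-pressure offset the support carries at mean pressure. Zero
#' support gives EP = 0; in the rigid-support limit the support carries
#' the full mean arterial pressure.
#'
#' @param solution a `pw_solution`.
#' @inheritParams probe
#' @return external pressure (Pa).
#' @export
external_pressure <- function(solution, s = NULL, segment = NULL,
                              x = NULL) {
  i <- locate_node(solution$model, s = s, segment = segment, x = x)
  nd <- solution$model$nodes[i, ]
  r_mean <- sqrt(solution$meanA[i] / pi)
  nd$ks * (r_mean - nd$r0)
}

#' Mean flow balance of a converged solution
#'
#' @param solution a `pw_solution`.
#' @return list with `inlet` (mean root inflow m^3/s), `outlets` (named
#'   mean outlet flows) and `error` (relative imbalance).
#' @export
flow_balance <- function(solution) {
  m <- solution$model
  q_in <- solution$meanQ[1]
  idx <- m$seg_off[m$outlets$seg] + m$seg_n[m$outlets$seg]
  q_out <- solution$meanQ[idx]
  names(q_out) <- m$outlets$outlet
  list(inlet = q_in, outlets = q_out,
       error = abs(sum(q_out) - q_in) / q_in)
}
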