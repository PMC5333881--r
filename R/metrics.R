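## metrics: the four stiffening metrics (pulse pressure, distensibility,
## foot-to-foot PWV via the intersecting-tangent algorithm, cyclic stored
## strain energy) and their spatial/temporal correlation with prescribed
## circumferential stiffness.

#' Six-segment aortic analysis grid
#'
#' Anatomical segments on the normalized trunk coordinate: ATA `[0,
#' 0.12]`, aortic arch `[0.12, 0.38]`, DTA `[0.38, 0.55]`, suprarenal
#' abdominal aorta `[0.55, 0.71]`, IAA `[0.71, 1]` and iliac artery `[1,
#' 1.27]`. Metrics are evaluated at the arc-length midpoint of each
#' segment.
#'
#' @return data.frame with `segment`, `label`, `s0`, `s1`, `s_mid`.
#' @export
segment_grid <- function() {
  s0 <- c(0, 0.12, 0.38, 0.55, 0.71, 1)
  s1 <- c(0.12, 0.38, 0.55, 0.71, 1, 1.27)
  data.frame(segment = 1:6,
             label = c("ATA", "arch", "DTA", "suprarenal", "IAA", "iliac"),
             s0 = s0, s1 = s1, s_mid = (s0 + s1) / 2)
}

check_probe <- function(probe) {
  if (length(probe$time) < 100)
    stop("probe must cover one full cycle with >= 100 samples")
  if (any(diff(probe$time) <= 0))
    stop("probe time samples must be strictly increasing")
  invisible(probe)
}

#' Pulse pressure of a waveform probe
#' @param probe a `waveform_probe`.
#' @return systolic minus diastolic pressure (Pa).
#' @export
pulse_pressure <- function(probe) {
  check_probe(probe)
  max(probe$pressure) - min(probe$pressure)
}

#' Mean arterial pressure from systolic and diastolic values
#'
#' The standard clinical estimate `MAP = P_dia + (P_sys - P_dia)/3`.
#'
#' @param p_sys,p_dia systolic and diastolic pressure (any common unit).
#' @return MAP in the same unit.
#' @export
map_formula <- function(p_sys, p_dia) p_dia + (p_sys - p_dia) / 3

#' MAP of a probe (formula-based) and time-averaged pressure
#' @param probe a `waveform_probe`.
#' @return list with `map` (formula) and `mean` (time average), Pa.
#' @export
mean_pressure <- function(probe) {
  check_probe(probe)
  list(map = map_formula(max(probe$pressure), min(probe$pressure)),
       mean = mean(probe$pressure))
}

#' Cross-sectional distensibility
#'
#' `D = (d_sys^2 - d_dia^2) / (d_dia^2 PP)` with equivalent circular
#' diameters `d = 2 sqrt(A/pi)`, which reduces to
#' `(A_sys - A_dia)/(A_dia PP)`.
#'
#' @param probe a `waveform_probe` with an area series.
#' @return distensibility (1/Pa).
#' @export
distensibility <- function(probe) {
  check_probe(probe)
  pp <- pulse_pressure(probe)
  if (pp <= 0) stop("distensibility undefined: zero pulse pressure")
  (max(probe$area) - min(probe$area)) / (min(probe$area) * pp)
}

#' Cyclic change in stored elastic strain energy
#'
#' `dW = 0.5 (P_sys - P_dia) (A_sys - A_dia) / A_dia` -- the cyclic work
#' done on the wall assuming no dissipation and no length change. The
#' no-length-change assumption does not hold in the ascending aorta
#' (which lengthens and shortens over the cycle), where the value is a
#' lower bound.
#'
#' @param probe a `waveform_probe`.
#' @return energy change (Pa, i.e. J/m^3).
#' @export
delta_w <- function(probe) {
  check_probe(probe)
  0.5 * (max(probe$pressure) - min(probe$pressure)) *
    (max(probe$area) - min(probe$area)) / min(probe$area)
}

#' Foot of a pressure waveform by the intersecting-tangent algorithm
#'
#' The foot is the intersection of the horizontal tangent through the
#' diastolic minimum with the tangent at the point of maximum systolic
#' gradient. The gradient is evaluated on a 3-point-smoothed series to
#' suppress discretization noise and the maximum-gradient point is refined
#' to sub-sample resolution by local quadratic interpolation. The search
#' runs over the initial systolic upstroke -- from the diastolic minimum
#' (cyclically unrolled) to the first crossing of half pulse amplitude --
#' so that reflection-augmented late-systolic gradients, which can exceed
#' the initial upstroke gradient in the proximal aorta, never capture the
#' tangent.
#'
#' @param probe a `waveform_probe` (or a list with `time`, `pressure`,
#'   `period`).
#' @return foot time (s), in `[0, period)`.
#' @export
foot_time <- function(probe) {
  check_probe(probe)
  p <- probe$pressure; tt <- probe$time; n <- length(p)
  if (max(p) - min(p) <= 1e-9 * max(1, abs(max(p))))
    stop("flat waveform: no systolic upstroke to locate")
  dtau <- tt[2] - tt[1]
  i_min <- which.min(p)
  ord <- c(i_min:n, seq_len(i_min - 1))
  pr <- p[ord]
  tu <- tt[ord]
  if (i_min > 1) tu[(n - i_min + 2):n] <- tu[(n - i_min + 2):n] + probe$period
  ps <- pr
  ps[2:(n - 1)] <- (pr[1:(n - 2)] + pr[2:(n - 1)] + pr[3:n]) / 3
  d <- rep(NA_real_, n)
  d[2:(n - 1)] <- (ps[3:n] - ps[1:(n - 2)]) / (2 * dtau)
  half <- min(pr) + 0.5 * (max(pr) - min(pr))
  i_half <- which(pr > half)[1]
  win <- 2:min(max(3, i_half), n - 1)
  i <- win[which.max(d[win])]
  dm <- d[i - 1]; d0 <- d[i]; dp <- d[i + 1]
  if (is.na(dm)) dm <- d0
  if (is.na(dp)) dp <- d0
  den <- dm - 2 * d0 + dp
  if (abs(den) > 1e-9 * abs(d0)) {
    delta <- 0.5 * (dm - dp) / den
    delta <- max(-0.5, min(0.5, delta))
  } else delta <- 0
  slope <- d0 + 0.5 * (dp - dm) * delta + 0.5 * den * delta^2
  t_ms <- tu[i] + delta * dtau
  p_ms <- stats::approx(tu, pr, xout = t_ms)$y
  if (slope <= 0) stop("flat waveform: non-positive maximum gradient")
  tf <- t_ms - (p_ms - min(p)) / slope
  tf %% probe$period
}

#' Foot-to-foot pulse wave velocity between two probes
#'
#' `PWV = path / (t_foot_b - t_foot_a)` with foot times from the
#' intersecting-tangent algorithm and the path measured along the vessel
#' centerline (not the straight-line distance). For comparison with
#' clinical direct-distance measurements a scale factor (conventionally
#' 0.8, converting direct distance to true aorto-iliac path) may be
#' applied via `scale`.
#'
#' @param probe_a,probe_b upstream and downstream `waveform_probe`s from
#'   the same converged cycle.
#' @param path centerline arc length between the stations (m).
#' @param scale optional multiplicative conversion factor on the result.
#' @return PWV (m/s).
#' @export
pwv <- function(probe_a, probe_b, path, scale = 1) {
  if (path <= 0) stop("path must be positive")
  ta <- foot_time(probe_a); tb <- foot_time(probe_b)
  dt <- (tb - ta) %% probe_a$period
  if (dt == 0 || dt > probe_a$period / 2)
    stop("non-positive transit time between probes; ",
         "are the probes reversed or the path too short?")
  scale * path / dt
}

#' Aorto-iliac (aortic root to iliac bifurcation) foot-to-foot PWV
#'
#' @param solution a `pw_solution` of the full aortic model.
#' @return PWV (m/s) over the trunk centerline from s = 0 to s = 1.
#' @export
aorto_iliac_pwv <- function(solution) {
  pa <- probe(solution, s = 0)
  pb <- probe(solution, s = 1)
  pwv(pa, pb, path = (pb$s - pa$s) * solution$model$tree$trunk_length)
}

#' Carotid-to-iliac foot-to-foot PWV
#'
#' The desk analogue of carotid-to-femoral PWV: transit time between a
#' mid-common-carotid probe and the iliac bifurcation, path measured along
#' the centerline through the arch (carotid station to take-off, then
#' take-off to bifurcation). Which carotid station population studies
#' probe is not standardized; the default is the mid right common carotid.
#'
#' @param solution a `pw_solution`.
#' @param carotid carotid segment name.
#' @param x probe position along the carotid (m); default mid-vessel.
#' @return PWV (m/s).
#' @export
carotid_iliac_pwv <- function(solution, carotid = "r_carotid", x = NULL) {
  m <- solution$model
  pa <- probe(solution, segment = carotid, x = x)
  pb <- probe(solution, s = 1)
  seg <- m$tree$segments
  s_take <- seg$s0[match(carotid, seg$name)]
  path <- pa$x + (pb$s - s_take) * m$tree$trunk_length
  pwv(pa, pb, path = path)
}

#' Segment-wise stiffening metrics for one or more converged solutions
#'
#' Evaluates pulse pressure, MAP, distensibility, PWV and cyclic stored
#' energy at the center of each of the six aortic segments, together with
#' the prescribed circumferential material stiffness at that station.
#' Segmental PWV is foot-to-foot between the segment end stations over
#' the segment arc length.
#'
#' @param solutions named list of `pw_solution`s, names = ages.
#' @return data.frame (one row per age x segment) with `age`, `segment`,
#'   `s_mid`, `K_th_MPa`, `PP_mmHg`, `MAP_mmHg`, `D_perPa`, `PWV_ms`,
#'   `dW_Pa`.
#' @export
metrics_table <- function(solutions) {
  grid <- segment_grid()
  out <- list()
  for (age in names(solutions)) {
    sol <- solutions[[age]]
    m <- sol$model
    L <- m$tree$trunk_length
    s_max <- max(m$nodes$s, na.rm = TRUE)
    for (k in seq_len(nrow(grid))) {
      smid <- min(grid$s_mid[k], s_max)
      s0 <- min(grid$s0[k], s_max); s1 <- min(grid$s1[k], s_max)
      pm <- probe(sol, s = smid)
      p0 <- probe(sol, s = s0);  p1 <- probe(sol, s = s1)
      pp <- pulse_pressure(pm)
      out[[length(out) + 1]] <- data.frame(
        age = as.numeric(age), segment = grid$segment[k],
        label = grid$label[k], s_mid = smid,
        K_th_MPa = m$walls$K_of_s(smid) / 1e6,
        PP_mmHg = pa_to_mmHg(pp),
        MAP_mmHg = pa_to_mmHg(map_formula(max(pm$pressure),
                                          min(pm$pressure))),
        D_perPa = distensibility(pm),
        PWV_ms = pwv(p0, p1, path = (p1$s - p0$s) * L),
        dW_Pa = delta_w(pm))
    }
  }
  do.call(rbind, out)
}

#' Spatial and temporal correlations of the metrics with stiffness
#'
#' Pearson correlation coefficients (covariance over the product of
#' standard deviations) of each metric with the prescribed
#' circumferential material stiffness: spatially over the six segments at
#' a given age, and temporally over the ages at a given segment. With 3
#' or 6 points the population- and sample-normalized conventions
#' coincide. Zero variance in either variable yields `NA`.
#'
#' @param metrics a [metrics_table()] result.
#' @return list with `spatial` (metric x age) and `temporal` (metric x
#'   segment) data.frames.
#' @export
correlation_tables <- function(metrics) {
  mets <- c(PP = "PP_mmHg", Distensibility = "D_perPa", PWV = "PWV_ms",
            dW = "dW_Pa")
  safe_cor <- function(x, y) {
    if (length(x) < 2) return(NA_real_)
    sx <- stats::sd(x); sy <- stats::sd(y)
    if (is.na(sx) || is.na(sy) || sx == 0 || sy == 0) return(NA_real_)
    stats::cor(x, y)
  }
  ages <- sort(unique(metrics$age))
  spatial <- data.frame(metric = names(mets))
  for (a in ages) {
    sub <- metrics[metrics$age == a, ]
    spatial[[paste0("age_", a)]] <-
      vapply(mets, function(col) safe_cor(sub[[col]], sub$K_th_MPa), 0)
  }
  segs <- sort(unique(metrics$segment))
  temporal <- data.frame(metric = names(mets))
  for (sgm in segs) {
    sub <- metrics[metrics$segment == sgm, ]
    temporal[[paste0("segment_", sgm)]] <-
      vapply(mets, function(col) safe_cor(sub[[col]], sub$K_th_MPa), 0)
  }
  list(spatial = spatial, temporal = temporal)
}

#' Aorto-iliac and carotid-to-iliac PWV summary across ages
#'
#' @param solutions named list of `pw_solution`s, names = ages.
#' @return data.frame with `age`, `aorto_iliac_ms`, `carotid_iliac_ms`.
#' @export
pwv_table <- function(solutions) {
  data.frame(
    age = as.numeric(names(solutions)),
    aorto_iliac_ms = vapply(solutions, aorto_iliac_pwv, 0),
    carotid_iliac_ms = vapply(solutions, carotid_iliac_pwv, 0),
    row.names = NULL)
}
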