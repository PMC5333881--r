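## geometry_aging: idealized baseline aortic tree, virtual aging
## transformations, inflow waveform generation and centerline I/O.
##
## The aortic trunk is parameterized by normalized arc length s: s = 0 at
## the aortic root, s = 1 at the aorto-iliac bifurcation (normalization is
## by the root-to-bifurcation centerline length of the *current* model, so
## the property stations s = 0.12/0.4/0.88 refer to each aged geometry's
## own coordinate). The common/external iliac path extends the coordinate
## beyond s = 1 (to 1.27 at baseline).

# interpolate station values along s with constant extrapolation beyond
# the outermost stations (rule used for radii, thickness, stiffness, MAP, EP)
station_interp <- function(s_stations, values, s) {
  stats::approx(s_stations, values, xout = s, rule = 2)$y
}

#' Virtual-aging specification
#'
#' Parameters controlling the multistep numerical aging of the baseline
#' tree: per-decade regional lengthening fractions (ascending 3%, arch 7%,
#' descending 5% per 10 years, compounding geometrically for fractional
#' decades), station radii and thicknesses per age, and the per-decade
#' fractional reduction of the straight-line root-to-bifurcation distance
#' (height loss; it increases tortuosity without changing arc length).
#'
#' @param per_decade named fractions of length increase per decade for the
#'   `ascending`, `arch` and `descending` aortic regions.
#' @param region_bounds s-intervals (in baseline coordinates) of the three
#'   lengthening regions; the aorta below the distal bound does not
#'   lengthen.
#' @param height_reduction_per_decade fractional decrease of the
#'   straight-line root-to-bifurcation distance per decade.
#' @param stations wall-property station table, see [wall_property_table()].
#' @param target_ages ages with station data available.
#' @return object of class `aging_spec`.
#' @export
aging_spec <- function(per_decade = c(ascending = 0.03, arch = 0.07,
                                      descending = 0.05),
                       region_bounds = list(ascending  = c(0, 0.13),
                                            arch       = c(0.13, 0.19),
                                            descending = c(0.19, 0.55)),
                       height_reduction_per_decade = 0.01,
                       stations = wall_property_table(),
                       target_ages = c(40, 60, 75)) {
  stopifnot(all(per_decade >= 0), height_reduction_per_decade >= 0)
  structure(list(per_decade = per_decade, region_bounds = region_bounds,
                 height_reduction_per_decade = height_reduction_per_decade,
                 stations = stations, target_ages = target_ages),
            class = "aging_spec")
}

#' Default branch geometry of the aortic tree
#'
#' Take-off positions (trunk s-coordinate), lengths and baseline radii of
#' the aortic branches and the iliac continuation. The 1D model needs only
#' junction locations along the trunk, not 3D branch angles; positions and
#' dimensions are literature-typical defaults and fully configurable.
#' `class` records the external-support inheritance rule: `upper` branches
#' (arch vessels) receive ascending-aorta support, `lower` branches
#' (splanchnic, renal, iliac) receive infrarenal support.
#'
#' @return data.frame with columns `name`, `parent` (`"trunk"` or the name
#'   of another branch), `takeoff_s`, `length_m`, `radius_mm`, `class`,
#'   `outlet` (Windkessel outlet id, `NA` for non-terminal segments).
#' @export
branch_defaults <- function() {
  data.frame(
    name = c("r_subclavian", "r_carotid", "l_carotid", "l_subclavian",
             "celiac", "gastric", "splenic", "sup_mesenteric",
             "r_renal", "l_renal", "inf_mesenteric",
             "r_common_iliac", "l_common_iliac",
             "r_ext_iliac", "r_int_iliac", "l_ext_iliac", "l_int_iliac"),
    parent = c(rep("trunk", 13),
               "r_common_iliac", "r_common_iliac",
               "l_common_iliac", "l_common_iliac"),
    takeoff_s = c(0.13, 0.15, 0.17, 0.19,
                  0.56, 0.58, 0.60, 0.62, 0.64, 0.66, 0.78,
                  1.00, 1.00, NA, NA, NA, NA),
    length_m = c(0.08, 0.12, 0.12, 0.08,
                 0.04, 0.05, 0.06, 0.06, 0.035, 0.035, 0.05,
                 0.055, 0.055, 0.08, 0.05, 0.08, 0.05),
    radius_mm = c(4.2, 3.7, 3.7, 4.2,
                  3.3, 1.8, 2.4, 3.8, 2.6, 2.6, 2.0,
                  5.5, 5.5, 4.0, 3.2, 4.0, 3.2),
    class = c("upper", "upper", "upper", "upper",
              rep("lower", 7), rep("iliac", 6)),
    outlet = c("r_subclavian", "r_carotid", "l_carotid", "l_subclavian",
               "celiac", "gastric", "splenic", "sup_mesenteric",
               "r_renal", "l_renal", "inf_mesenteric",
               NA, NA,
               "r_ext_iliac", "r_int_iliac", "l_ext_iliac", "l_int_iliac"),
    stringsAsFactors = FALSE
  )
}

# descriptive anatomical region from trunk coordinate
trunk_region_label <- function(s_mid) {
  cut(s_mid, c(-Inf, 0.12, 0.38, 0.55, 0.71, 1, Inf),
      labels = c("ascending", "arch", "descending-thoracic",
                 "suprarenal-abdominal", "infrarenal-abdominal", "iliac"))
}

#' Build the idealized baseline (30 yo) aortic tree
#'
#' Constructs a branched tree of tapered 1D vessel segments standing in for
#' the subject's MRI-derived geometry. Trunk radii linearly interpolate the
#' three station radii along s and are extrapolated constantly proximal of
#' s = 0.12 (to the aortic root) and distal of s = 0.88 (through the
#' iliacs). Branch take-offs split the trunk into contiguous pieces tiling
#' s in [0, 1]; the common/external iliac chain extends to s = 1.27 at the
#' default lengths.
#'
#' @param spec an [aging_spec()].
#' @param branches branch geometry table ([branch_defaults()]), or `NULL`
#'   for a degenerate single tapered tube with one terminal.
#' @param trunk_length root-to-bifurcation centerline arc length (m) of the
#'   baseline. The numeric length tables of the source geometry are not
#'   machine-readable here, so the default (0.50 m) is a literature-typical
#'   value for a young adult male; overridable, including from a
#'   centerline file via `centerline`.
#' @param straight_distance straight-line root-to-bifurcation distance (m),
#'   used only to track tortuosity.
#' @param centerline optional [read_centerline_vtk()] result; its longest
#'   polyline overrides `trunk_length` and `straight_distance`.
#' @return object of class `aorto_tree`.
#' @export
build_baseline_tree <- function(spec = aging_spec(),
                                branches = branch_defaults(),
                                trunk_length = 0.50,
                                straight_distance = 0.36,
                                centerline = NULL) {
  st30 <- spec$stations[spec$stations$age == 30, ]
  if (nrow(st30) != 3)
    stop("configuration error: baseline (30 yo) station radii missing")
  if (!is.null(centerline)) {
    main <- centerline$lines[[which.max(vapply(centerline$lines,
                                               function(l) l$arc_length, 0))]]
    trunk_length <- main$arc_length
    straight_distance <- sqrt(sum((main$points[nrow(main$points), ] -
                                   main$points[1, ])^2))
  }
  if (is.null(branches)) {
    branches <- data.frame(name = character(), parent = character(),
                           takeoff_s = numeric(), length_m = numeric(),
                           radius_mm = numeric(), class = character(),
                           outlet = character(), stringsAsFactors = FALSE)
  }
  direct <- branches[branches$parent == "trunk" & !is.na(branches$takeoff_s) &
                       branches$takeoff_s < 1, , drop = FALSE]
  breaks <- sort(unique(c(0, unlist(spec$region_bounds), direct$takeoff_s, 1)))
  breaks <- breaks[breaks >= 0 & breaks <= 1]

  stations <- data.frame(s = st30$s, r_base = st30$radius_mm * 1e-3,
                         r_now = st30$radius_mm * 1e-3)

  ntp <- length(breaks) - 1
  trunk <- data.frame(
    name = sprintf("trunk_%02d", seq_len(ntp)),
    type = "trunk",
    parent = c(NA, sprintf("trunk_%02d", seq_len(ntp - 1))),
    s0 = breaks[-length(breaks)], s1 = breaks[-1],
    length_m = diff(breaks) * trunk_length,
    radius_mm = NA_real_,
    class = "trunk",
    outlet = NA_character_,
    stringsAsFactors = FALSE
  )
  # material aging region, fixed at build time from baseline coordinates
  mid <- (trunk$s0 + trunk$s1) / 2
  trunk$aging_region <- "none"
  for (rg in names(spec$region_bounds)) {
    b <- spec$region_bounds[[rg]]
    trunk$aging_region[mid > b[1] & mid < b[2]] <- rg
  }
  trunk$region <- as.character(trunk_region_label(mid))

  if (nrow(branches)) {
    br <- data.frame(
      name = branches$name, type = "branch",
      parent = NA_character_,
      s0 = branches$takeoff_s, s1 = branches$takeoff_s,
      length_m = branches$length_m,
      radius_mm = branches$radius_mm,
      class = branches$class,
      outlet = branches$outlet,
      aging_region = "none",
      region = ifelse(branches$class == "iliac", "iliac", "branch"),
      stringsAsFactors = FALSE
    )
    # attach trunk branches to the trunk piece ending at their take-off
    for (i in seq_len(nrow(br))) {
      if (branches$parent[i] == "trunk") {
        k <- which(abs(trunk$s1 - branches$takeoff_s[i]) < 1e-12)
        if (length(k) != 1)
          stop("configuration error: no trunk junction at s = ",
               branches$takeoff_s[i], " for branch ", br$name[i])
        br$parent[i] <- trunk$name[k]
      } else br$parent[i] <- branches$parent[i]
    }
    segments <- rbind(trunk, br)
  } else {
    trunk$outlet[ntp] <- "outlet"   # degenerate single-tube configuration
    segments <- trunk
  }
  rownames(segments) <- NULL

  tree <- structure(list(age = 30, segments = segments, stations = stations,
                         trunk_length = trunk_length,
                         straight_distance = straight_distance,
                         spec = spec),
                    class = "aorto_tree")
  tree <- recompute_s(tree)
  validate_tree(tree)
  tree
}

# recompute normalized s-coordinates from current physical lengths
recompute_s <- function(tree) {
  seg <- tree$segments
  it <- which(seg$type == "trunk")
  L <- sum(seg$length_m[it])
  ends <- cumsum(seg$length_m[it]) / L
  seg$s0[it] <- c(0, ends[-length(ends)])
  seg$s1[it] <- ends
  tree$trunk_length <- L
  # branch take-offs move with their junction
  for (i in which(seg$type == "branch")) {
    p <- match(seg$parent[i], seg$name)
    seg$s0[i] <- seg$s1[p]
    # iliac chain carries the trunk coordinate past s = 1
    seg$s1[i] <- if (seg$class[i] == "iliac")
      seg$s0[i] + seg$length_m[i] / L else seg$s0[i]
  }
  tree$segments <- seg
  tree
}

validate_tree <- function(tree) {
  seg <- tree$segments
  stopifnot(all(seg$length_m > 0))
  it <- which(seg$type == "trunk")
  if (max(abs(diff(c(0, seg$s1[it])) - (seg$s1 - seg$s0)[it])) > 1e-10 ||
      abs(seg$s1[it[length(it)]] - 1) > 1e-10)
    stop("trunk segments must tile [0, 1] without gaps or overlaps")
  orphan <- !is.na(seg$parent) & !(seg$parent %in% seg$name)
  if (any(orphan)) stop("disconnected segments: ",
                        paste(seg$name[orphan], collapse = ", "))
  invisible(tree)
}

#' Trunk inner radius at normalized arc length s
#'
#' Baseline radii interpolate the 30 yo station values linearly in s with
#' constant extrapolation beyond s = 0.12 and s = 0.88; aged radii multiply
#' the baseline profile by a per-s scale factor that interpolates the
#' station radius ratios, so station radii match the aged table exactly.
#'
#' @param tree an `aorto_tree`.
#' @param s normalized arc length (vectorized), trunk range `[0, 1]`.
#' @return inner radius (m).
#' @export
trunk_radius <- function(tree, s) {
  st <- tree$stations
  base <- station_interp(st$s, st$r_base, s)
  fac  <- station_interp(st$s, st$r_now / st$r_base, s)
  base * fac
}

#' Terminal segments of the tree
#' @param tree an `aorto_tree`.
#' @return character vector of terminal segment names.
#' @export
tree_terminals <- function(tree) {
  seg <- tree$segments
  seg$name[!(seg$name %in% seg$parent)]
}

#' Apply the virtual-aging transformations to a tree
#'
#' Implements the multistep aging procedure: (i) regional lengthening
#' compounding geometrically per decade, `(1+f)^(dage/10)`, with f = 3%,
#' 7%, 5% for the ascending aorta, arch and descending aorta; (ii) radii
#' rescaled so that the station values match the target-age table, with the
#' per-s scale factor interpolated linearly between stations (branch radii
#' scale by the factor at the closest trunk s); (iii) straight-line
#' root-to-bifurcation distance reduced (height loss), recorded as
#' tortuosity metadata while the arc length is preserved; (iv) wall
#' thickness follows the target-age table when wall properties are
#' assigned.
#'
#' @param tree an `aorto_tree`.
#' @param to_age target age (years); station data must exist (30, 40, 60,
#'   75 with the bundled table).
#' @param spec an [aging_spec()]; defaults to the spec stored in the tree.
#' @param from_age starting age; defaults to the tree's current age.
#' @return the aged `aorto_tree`.
#' @export
age_geometry <- function(tree, to_age, spec = tree$spec,
                         from_age = tree$age) {
  if (to_age < from_age) stop("to_age must be >= from_age")
  ages_avail <- unique(spec$stations$age)
  if (!to_age %in% ages_avail)
    stop("no station data for age ", to_age, "; available ages: ",
         paste(ages_avail, collapse = ", "))
  ndec <- (to_age - from_age) / 10
  seg <- tree$segments

  for (rg in names(spec$per_decade)) {
    k <- seg$type == "trunk" & seg$aging_region == rg
    seg$length_m[k] <- seg$length_m[k] * (1 + spec$per_decade[[rg]])^ndec
  }
  tree$segments <- seg
  tree <- recompute_s(tree)

  # radii: scale factor relative to the *current* station radii
  st_to <- spec$stations[spec$stations$age == to_age, ]
  st_to <- st_to[match(c("ATA", "DTA", "IAA"), st_to$station), ]
  r_to <- st_to$radius_mm * 1e-3
  fac_fun <- function(s) station_interp(tree$stations$s,
                                        r_to / tree$stations$r_now, s)
  bseg <- tree$segments$type == "branch"
  tree$segments$radius_mm[bseg] <- tree$segments$radius_mm[bseg] *
    fac_fun(pmin(tree$segments$s0[bseg], 1))
  tree$stations$r_now <- r_to

  tree$straight_distance <- tree$straight_distance *
    (1 - spec$height_reduction_per_decade)^ndec
  tree$age <- to_age
  validate_tree(tree)
  tree
}

#' Aortic tortuosity metadata
#' @param tree an `aorto_tree`.
#' @return ratio of trunk arc length to straight-line root-to-bifurcation
#'   distance.
#' @export
tree_tortuosity <- function(tree) tree$trunk_length / tree$straight_distance

#' @export
print.aorto_tree <- function(x, ...) {
  cat(sprintf(paste0("<aorto_tree> age %s yo: %d segments, %d terminals,\n",
                     "  trunk arc length %.3f m, tortuosity %.3f\n"),
              x$age, nrow(x$segments), length(tree_terminals(x)),
              x$trunk_length, tree_tortuosity(x)))
  invisible(x)
}

#' Inflow waveform specification
#'
#' Shape family for the aortic-root flow waveform: a truncated-sine
#' systolic ejection pulse (two half-sine lobes, giving the rapid early
#' acceleration and slower late-systolic deceleration of measured aortic
#' flow), a small end-systolic reverse lobe (valve closure) and zero
#' diastolic flow. Only the waveform mean (5.79 L/min) and heart rate
#' (60 bpm) are prescribed data; the shape parameters are configurable
#' physiologic defaults (ejection occupies a third of the cycle, peak
#' flow about 100 ms after ejection onset).
#'
#' @param mean_flow_lmin mean volumetric flow, L/min.
#' @param heart_rate beats per minute.
#' @param systolic_fraction systolic ejection duration as a fraction of the
#'   cycle.
#' @param time_to_peak_fraction time from ejection onset to peak flow as a
#'   fraction of the ejection duration.
#' @param reverse_fraction reverse-lobe volume as a fraction of forward
#'   volume.
#' @param reverse_duration_fraction reverse-lobe duration as a fraction of
#'   the cycle.
#' @param n_samples samples per cycle.
#' @return object of class `inflow_spec`.
#' @export
inflow_spec <- function(mean_flow_lmin = 5.79, heart_rate = 60,
                        systolic_fraction = 0.33,
                        time_to_peak_fraction = 0.3,
                        reverse_fraction = 0.03,
                        reverse_duration_fraction = 0.08, n_samples = 512) {
  stopifnot(heart_rate > 0, systolic_fraction > 0, systolic_fraction < 1,
            time_to_peak_fraction > 0, time_to_peak_fraction < 1,
            reverse_duration_fraction >= 0, n_samples >= 64)
  structure(list(mean_flow = lmin_to_m3s(mean_flow_lmin),
                 heart_rate = heart_rate,
                 systolic_fraction = systolic_fraction,
                 time_to_peak_fraction = time_to_peak_fraction,
                 reverse_fraction = reverse_fraction,
                 reverse_duration_fraction = reverse_duration_fraction,
                 n_samples = n_samples),
            class = "inflow_spec")
}

#' Generate one period of the aortic-root inflow waveform
#'
#' @param spec an [inflow_spec()].
#' @return object of class `inflow_waveform`: list with `time` (s), `flow`
#'   (m^3/s), `period` (s) and `mean_flow` (m^3/s). The sampled mean equals
#'   the requested mean to double precision by construction.
#' @export
generate_inflow <- function(spec = inflow_spec()) {
  period <- 60 / spec$heart_rate
  tt <- seq(0, period, length.out = spec$n_samples + 1)[seq_len(spec$n_samples)]
  ts <- spec$systolic_fraction * period
  tr <- spec$reverse_duration_fraction * period
  if (spec$reverse_fraction >= 1)
    stop("shape parameters produce a non-positive systolic peak ",
         "(reverse_fraction must be < 1)")
  q <- numeric(length(tt))
  tp <- spec$time_to_peak_fraction * ts
  rise <- tt < tp
  fall <- tt >= tp & tt < ts
  q[rise] <- sin(pi * tt[rise] / (2 * tp))
  q[fall] <- cos(pi * (tt[fall] - tp) / (2 * (ts - tp)))
  if (tr > 0 && spec$reverse_fraction > 0) {
    rev <- tt >= ts & tt < ts + tr
    # reverse lobe amplitude set from the volume ratio of the two lobes
    amp <- spec$reverse_fraction * ts / tr
    q[rev] <- -amp * sin(pi * (tt[rev] - ts) / tr)
  }
  m <- mean(q)
  flow <- if (spec$mean_flow == 0) q * 0 else q * (spec$mean_flow / m)
  structure(list(time = tt, flow = flow, period = period,
                 mean_flow = spec$mean_flow),
            class = "inflow_waveform")
}

## ---- centerline I/O ------------------------------------------------------

#' Read a vascular centerline from a VTK polydata file
#'
#' Parses legacy ASCII VTK polydata (`.vtk`, `POINTS` + `LINES`) and ASCII
#' XML polydata (`.vtp`). Arc length is computed by summed chord lengths;
#' a point-data scalar array named `radius` is attached when present. The
#' result can override the default trunk length and tortuosity via
#' [build_baseline_tree()].
#'
#' @param path file path.
#' @return object of class `centerline_set`: list with `lines`, each a list
#'   holding `points` (n x 3 matrix), `arc_length` (m) and `radii` (or
#'   `NULL`).
#' @export
read_centerline_vtk <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (length(txt) && grepl("^\\s*<", txt[1]))
    return(read_centerline_vtp(path))
  toks_of <- function(lines) as.numeric(unlist(strsplit(trimws(lines), "\\s+")))
  ip <- grep("^POINTS", txt)
  if (!length(ip)) stop("malformed VTK file (no POINTS section): ", path)
  np <- as.integer(strsplit(trimws(txt[ip[1]]), "\\s+")[[1]][2])
  vals <- numeric(0); i <- ip[1] + 1
  while (length(vals) < 3 * np) {
    if (i > length(txt))
      stop("malformed VTK file: POINTS truncated at line ", i)
    vals <- c(vals, toks_of(txt[i])); i <- i + 1
  }
  pts <- matrix(vals[seq_len(3 * np)], ncol = 3, byrow = TRUE)
  il <- grep("^LINES", txt)
  if (!length(il))
    stop("empty geometry: no polylines (LINES) in ", path)
  hdr <- as.integer(strsplit(trimws(txt[il[1]]), "\\s+")[[1]][-1])
  nl <- hdr[1]; ntot <- hdr[2]
  vals <- numeric(0); i <- il[1] + 1
  while (length(vals) < ntot) {
    if (i > length(txt))
      stop("malformed VTK file: LINES truncated at line ", i)
    vals <- c(vals, toks_of(txt[i])); i <- i + 1
  }
  con <- as.integer(vals[seq_len(ntot)])
  radii <- read_vtk_scalar(txt, np, "radius")
  lines <- list(); k <- 1
  for (j in seq_len(nl)) {
    m <- con[k]; ids <- con[k + seq_len(m)] + 1; k <- k + m + 1
    p <- pts[ids, , drop = FALSE]
    lines[[j]] <- list(points = p,
                       arc_length = sum(sqrt(rowSums(diff(p)^2))),
                       radii = if (!is.null(radii)) radii[ids] else NULL)
  }
  if (!length(lines)) stop("empty geometry: no polylines in ", path)
  structure(list(lines = lines), class = "centerline_set")
}

read_vtk_scalar <- function(txt, np, name) {
  is_ <- grep(paste0("^SCALARS\\s+", name), txt)
  if (!length(is_)) return(NULL)
  i <- is_[1] + 1
  if (grepl("^LOOKUP_TABLE", txt[i])) i <- i + 1
  vals <- numeric(0)
  while (length(vals) < np && i <= length(txt)) {
    vals <- c(vals, as.numeric(strsplit(trimws(txt[i]), "\\s+")[[1]]))
    i <- i + 1
  }
  vals[seq_len(np)]
}

read_centerline_vtp <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  if (is.na(piece)) stop("malformed VTP file (no Piece element): ", path)
  num <- function(node) as.numeric(strsplit(trimws(xml2::xml_text(node)),
                                            "\\s+")[[1]])
  ptsn <- xml2::xml_find_first(piece, ".//Points/DataArray")
  pts <- matrix(num(ptsn), ncol = 3, byrow = TRUE)
  lines_el <- xml2::xml_find_first(piece, ".//Lines")
  if (is.na(lines_el)) stop("empty geometry: no Lines element in ", path)
  conn <- as.integer(num(xml2::xml_find_first(
    lines_el, "./DataArray[@Name='connectivity']")))
  offs <- as.integer(num(xml2::xml_find_first(
    lines_el, "./DataArray[@Name='offsets']")))
  rad_n <- xml2::xml_find_first(piece, ".//PointData/DataArray[@Name='radius']")
  radii <- if (!is.na(rad_n)) num(rad_n) else NULL
  lines <- list(); start <- 1
  for (j in seq_along(offs)) {
    ids <- conn[start:offs[j]] + 1; start <- offs[j] + 1
    p <- pts[ids, , drop = FALSE]
    lines[[j]] <- list(points = p,
                       arc_length = sum(sqrt(rowSums(diff(p)^2))),
                       radii = if (!is.null(radii)) radii[ids] else NULL)
  }
  if (!length(lines)) stop("empty geometry: no polylines in ", path)
  structure(list(lines = lines), class = "centerline_set")
}

#' Export the tree as VTK polyline polydata for visualization
#'
#' Writes a schematic legacy ASCII VTK polydata file: one polyline per
#' segment (trunk laid out along a planar arch curve, branches as straight
#' offshoots) with point-data arrays for inner radius.
#'
#' @param tree an `aorto_tree`.
#' @param path output path.
#' @param n_per_seg points per segment polyline.
#' @return `path`, invisibly.
#' @export
write_tree_vtk <- function(tree, path, n_per_seg = 8) {
  seg <- tree$segments
  L <- tree$trunk_length
  # schematic trunk layout: quarter-turn arch then straight descent
  trunk_xyz <- function(s) {
    arc <- s * L
    bend <- 0.06  # arch bend radius, m
    qarc <- pi * bend
    x <- ifelse(arc < qarc, bend * (1 - cos(arc / bend)), 2 * bend)
    z <- ifelse(arc < qarc, bend * sin(arc / bend), -(arc - qarc))
    cbind(x, 0, z)
  }
  pts <- NULL; radii <- NULL; polys <- list()
  for (i in seq_len(nrow(seg))) {
    if (seg$type[i] == "trunk" || seg$class[i] == "iliac") {
      ss <- seq(seg$s0[i], seg$s1[i], length.out = n_per_seg)
      xyz <- trunk_xyz(ss)
      rr <- if (seg$type[i] == "trunk") trunk_radius(tree, ss)
            else rep(seg$radius_mm[i] * 1e-3, n_per_seg)
      if (seg$class[i] == "iliac")  # offset the two iliacs laterally
        xyz[, 2] <- xyz[, 2] + (seg$s1[i] - seg$s0[i]) *
          ifelse(grepl("^r_", seg$name[i]), 0.2, -0.2) *
          seq(0, 1, length.out = n_per_seg)
    } else {
      p0 <- trunk_xyz(seg$s0[i])
      dirv <- c(0, ifelse(grepl("^r_", seg$name[i]), 1, -1), 0.2)
      dirv <- dirv / sqrt(sum(dirv^2))
      tt <- seq(0, seg$length_m[i], length.out = n_per_seg)
      xyz <- cbind(p0[1] + dirv[1] * tt, p0[2] + dirv[2] * tt,
                   p0[3] + dirv[3] * tt)
      rr <- rep(seg$radius_mm[i] * 1e-3, n_per_seg)
    }
    base <- if (is.null(pts)) 0 else nrow(pts)
    pts <- rbind(pts, xyz); radii <- c(radii, rr)
    polys[[i]] <- base + seq_len(n_per_seg) - 1
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "aortapulse tree export", "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(pts))), con)
  utils::write.table(format(pts, digits = 8, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("LINES %d %d", length(polys),
                     sum(lengths(polys)) + length(polys)), con)
  for (p in polys)
    writeLines(paste(c(length(p), p), collapse = " "), con)
  writeLines(c(sprintf("POINT_DATA %d", nrow(pts)),
               "SCALARS radius float 1", "LOOKUP_TABLE default"), con)
  writeLines(format(radii, digits = 8, trim = TRUE), con)
  invisible(path)
}

## ---- tree serialization --------------------------------------------------

#' Serialize / deserialize an aortic tree as JSON
#'
#' Topology and per-segment geometry are written as JSON; the per-node
#' radius/thickness profile is available separately via [tree_profile()]
#' for CSV export.
#'
#' @param tree an `aorto_tree`.
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @return `tree_to_json`: path or JSON string. `tree_from_json`: the
#'   reconstructed `aorto_tree`.
#' @export
tree_to_json <- function(tree, path = NULL) {
  obj <- list(age = tree$age, trunk_length = tree$trunk_length,
              straight_distance = tree$straight_distance,
              stations = tree$stations, segments = tree$segments)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname tree_to_json
#' @param x JSON string or path to a JSON file.
#' @export
tree_from_json <- function(x) {
  if (length(x) == 1 && file.exists(x)) x <- paste(readLines(x), collapse = "")
  obj <- jsonlite::fromJSON(x)
  tree <- structure(list(age = obj$age,
                         segments = as.data.frame(obj$segments),
                         stations = as.data.frame(obj$stations),
                         trunk_length = obj$trunk_length,
                         straight_distance = obj$straight_distance,
                         spec = aging_spec()),
                    class = "aorto_tree")
  validate_tree(tree)
  tree
}

#' Per-station geometry profile of the trunk
#'
#' @param tree an `aorto_tree`.
#' @param n number of s-stations.
#' @param walls optional wall field from [assign_wall_properties()]; adds
#'   thickness and stiffness columns.
#' @return data.frame with `s`, `radius_m` and optionally `thickness_m`,
#'   `K_th_Pa` -- suitable for CSV export.
#' @export
tree_profile <- function(tree, n = 200, walls = NULL) {
  s <- seq(0, 1, length.out = n)
  out <- data.frame(s = s, radius_m = trunk_radius(tree, s))
  if (!is.null(walls)) {
    out$thickness_m <- walls$h_of_s(s)
    out$K_th_Pa <- walls$K_of_s(s)
  }
  out
}
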