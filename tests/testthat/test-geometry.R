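test_that("baseline trunk radius interpolates stations with constant
          extrapolation", {
  tree <- build_baseline_tree()
  # hand linear interpolation between ATA (13.2 mm @ 0.12) and
  # DTA (9.60 mm @ 0.40): s = 0.26 is the midpoint
  expect_equal(trunk_radius(tree, 0.26), (13.2 + 9.60) / 2 * 1e-3,
               tolerance = 1e-12)
  # proximal of the ATA station the radius extrapolates constantly
  expect_equal(trunk_radius(tree, 0.05), 13.2e-3)
  expect_equal(trunk_radius(tree, 0), 13.2e-3)
  # and distally beyond the IAA station
  expect_equal(trunk_radius(tree, 0.95), 7.81e-3)
})

test_that("trunk segments tile [0,1] and terminals carry outlets", {
  tree <- build_baseline_tree()
  seg <- tree$segments
  it <- seg$type == "trunk"
  expect_equal(min(seg$s0[it]), 0)
  expect_equal(max(seg$s1[it]), 1)
  expect_true(all(seg$length_m > 0))
  term <- tree_terminals(tree)
  expect_length(term, 15)
  expect_setequal(seg$outlet[match(term, seg$name)],
                  windkessel_table()$outlet)
})

test_that("zero-branch configuration degenerates to a single tapered tube", {
  tree <- build_baseline_tree(branches = NULL)
  expect_length(tree_terminals(tree), 1)
  expect_true(all(tree$segments$type == "trunk"))
})

test_that("aging scales region lengths geometrically per decade", {
  tree <- build_baseline_tree()
  seg0 <- tree$segments
  arch0 <- sum(seg0$length_m[seg0$type == "trunk" &
                               seg0$aging_region == "arch"])
  asc0 <- sum(seg0$length_m[seg0$type == "trunk" &
                              seg0$aging_region == "ascending"])

  a40 <- age_geometry(tree, 40)
  seg40 <- a40$segments
  arch40 <- sum(seg40$length_m[seg40$type == "trunk" &
                                 seg40$aging_region == "arch"])
  expect_equal(arch40 / arch0, 1.07, tolerance = 1e-12)

  a75 <- age_geometry(tree, 75)
  asc75 <- sum(a75$segments$length_m[a75$segments$type == "trunk" &
                                       a75$segments$aging_region ==
                                         "ascending"])
  expect_equal(asc75 / asc0, 1.03^4.5, tolerance = 1e-12)

  # aging by zero years is the identity
  same <- age_geometry(tree, 30)
  expect_equal(same$segments$length_m, seg0$length_m)
  expect_equal(same$stations$r_now, tree$stations$r_now)

  # compounding: 30 -> 60 equals 30 -> 40 -> 60
  two_step <- age_geometry(age_geometry(tree, 40), 60)
  one_step <- age_geometry(tree, 60)
  expect_equal(two_step$segments$length_m, one_step$segments$length_m,
               tolerance = 1e-12)
  expect_equal(two_step$stations$r_now, one_step$stations$r_now,
               tolerance = 1e-12)
})

test_that("aging preserves topology and hits the station radii exactly", {
  tree <- build_baseline_tree()
  tab <- wall_property_table()
  for (age in c(40, 60, 75)) {
    aged <- age_geometry(tree, age)
    expect_equal(nrow(aged$segments), nrow(tree$segments))
    expect_equal(aged$segments$parent, tree$segments$parent)
    ta <- tab[tab$age == age, ]
    for (k in 1:3)
      expect_equal(trunk_radius(aged, ta$s[k]), ta$radius_mm[k] * 1e-3,
                   tolerance = 1e-12)
  }
})

test_that("radii and lengths are nondecreasing over 40 -> 60 -> 75", {
  tree <- build_baseline_tree()
  ss <- seq(0, 1, by = 0.02)
  prev_r <- NULL; prev_len <- NULL
  for (age in c(40, 60, 75)) {
    aged <- age_geometry(tree, age)
    r <- trunk_radius(aged, ss)
    len <- aged$segments$length_m
    if (!is.null(prev_r)) {
      expect_true(all(r >= prev_r - 1e-12))
      expect_true(all(len >= prev_len - 1e-12))
    }
    prev_r <- r; prev_len <- len
  }
})

test_that("height reduction increases tortuosity without changing arc
          length", {
  tree <- build_baseline_tree()
  spec <- aging_spec(per_decade = c(ascending = 0, arch = 0,
                                    descending = 0),
                     height_reduction_per_decade = 0.01)
  aged <- age_geometry(tree, 75, spec = spec)
  expect_equal(aged$trunk_length, tree$trunk_length, tolerance = 1e-12)
  expect_equal(aged$straight_distance / tree$straight_distance,
               0.99^4.5, tolerance = 1e-12)
  expect_gt(tree_tortuosity(aged), tree_tortuosity(tree))
})

test_that("inflow waveform honors mean, period and stroke volume", {
  infl <- generate_inflow()
  expect_equal(infl$period, 1.0)
  expect_equal(mean(infl$flow), lmin_to_m3s(5.79), tolerance = 1e-12)
  # stroke volume 5.79/60 L = 96.5 mL per beat
  sv <- mean(infl$flow) * infl$period
  expect_equal(sv * 1e6, 96.5, tolerance = 1e-3)
  # early-systolic peak, near-zero diastole
  expect_gt(max(infl$flow), 4e-4)
  expect_lt(infl$time[which.max(infl$flow)], 0.2)
  expect_equal(infl$flow[round(0.8 * length(infl$flow))], 0)

  zero <- generate_inflow(inflow_spec(mean_flow_lmin = 0))
  expect_true(all(zero$flow == 0))

  expect_error(generate_inflow(inflow_spec(reverse_fraction = 1.5)),
               "peak")
})

test_that("legacy VTK centerlines parse with correct arc length", {
  # straight 3-point polyline: 0.2 m
  f <- tempfile(fileext = ".vtk")
  writeLines(c("# vtk DataFile Version 3.0", "test", "ASCII",
               "DATASET POLYDATA", "POINTS 3 float",
               "0 0 0", "0 0 0.1", "0 0 0.2",
               "LINES 1 4", "3 0 1 2"), f)
  cl <- read_centerline_vtk(f)
  expect_length(cl$lines, 1)
  expect_equal(cl$lines[[1]]$arc_length, 0.2, tolerance = 1e-12)

  # semicircle of radius 0.1 sampled at 100 points: arc = pi * 0.1
  th <- seq(0, pi, length.out = 100)
  pts <- cbind(0.1 * cos(th), 0.1 * sin(th), 0)
  f2 <- tempfile(fileext = ".vtk")
  writeLines(c("# vtk DataFile Version 3.0", "arc", "ASCII",
               "DATASET POLYDATA", "POINTS 100 float",
               apply(pts, 1, paste, collapse = " "),
               "LINES 1 101", paste(c(100, 0:99), collapse = " ")), f2)
  cl2 <- read_centerline_vtk(f2)
  expect_rel(cl2$lines[[1]]$arc_length, pi * 0.1, 1e-3)

  # malformed file and branchless file raise informative errors
  f3 <- tempfile(fileext = ".vtk")
  writeLines(c("# vtk DataFile Version 3.0", "bad", "ASCII",
               "DATASET POLYDATA", "POINTS 3 float", "0 0 0"), f3)
  expect_error(read_centerline_vtk(f3), "truncated")
  f4 <- tempfile(fileext = ".vtk")
  writeLines(c("# vtk DataFile Version 3.0", "no lines", "ASCII",
               "DATASET POLYDATA", "POINTS 1 float", "0 0 0"), f4)
  expect_error(read_centerline_vtk(f4), "polylines")
})

test_that("XML polydata (.vtp) centerlines parse", {
  f <- tempfile(fileext = ".vtp")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<VTKFile type="PolyData">', "<PolyData>",
    '<Piece NumberOfPoints="3" NumberOfLines="1">',
    "<Points><DataArray>0 0 0 0 0 0.1 0 0 0.3</DataArray></Points>",
    '<Lines><DataArray Name="connectivity">0 1 2</DataArray>',
    '<DataArray Name="offsets">3</DataArray></Lines>',
    "</Piece></PolyData></VTKFile>"), f)
  cl <- read_centerline_vtk(f)   # dispatches on the XML header
  expect_equal(cl$lines[[1]]$arc_length, 0.3, tolerance = 1e-12)
})

test_that("tree serialization round-trips through JSON and VTK export", {
  tree <- age_geometry(build_baseline_tree(), 60)
  js <- tree_to_json(tree)
  back <- tree_from_json(js)
  expect_equal(back$age, 60)
  expect_equal(back$trunk_length, tree$trunk_length)
  expect_equal(back$segments$length_m, tree$segments$length_m)
  expect_equal(back$stations$r_now, tree$stations$r_now)

  f <- tempfile(fileext = ".vtk")
  write_tree_vtk(tree, f, n_per_seg = 32)
  cl <- read_centerline_vtk(f)
  arcs <- vapply(cl$lines, `[[`, 0, "arc_length")
  expect_length(cl$lines, nrow(tree$segments))
  # trunk pieces together reproduce the trunk arc length
  it <- which(tree$segments$type == "trunk")
  expect_rel(sum(arcs[it]), tree$trunk_length, 0.01)
})

test_that("a centerline file overrides the default trunk length", {
  f <- tempfile(fileext = ".vtk")
  writeLines(c("# vtk DataFile Version 3.0", "test", "ASCII",
               "DATASET POLYDATA", "POINTS 2 float",
               "0 0 0", "0 0 0.55", "LINES 1 3", "2 0 1"), f)
  tree <- build_baseline_tree(centerline = read_centerline_vtk(f))
  expect_equal(tree$trunk_length, 0.55, tolerance = 1e-12)
})
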