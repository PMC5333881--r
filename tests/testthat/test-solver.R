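test_that("a quiescent model at the venous pressure stays time-invariant", {
  p0 <- mmHg_to_pa(93)
  m <- uniform_tube_model(length = 0.6, radius = 0.008, map = p0,
                          bc = list(R_prox = 1e7, R_dist = 1e8, C = 1e-8,
                                    P_out = p0),
                          inflow = steady_inflow(0),
                          config = solver_config(min_cycles = 2,
                                                 max_cycles = 3,
                                                 p_init = p0))
  sol <- run_until_periodic(m)
  expect_lt(max(abs(sol$P - p0)), 1e-6)
  expect_lt(max(abs(sol$Q)), 1e-12)
})

test_that("constant inflow reaches the steady 0D limit with the Poiseuille
          pressure gradient", {
  q0 <- 5e-6
  bc <- list(R_prox = 5e7, R_dist = 1.5e9, C = 5e-9, P_out = 0)
  m <- uniform_tube_model(length = 0.5, radius = 0.002,
                          thickness = 4e-4, K_th = 1e6,
                          map = mmHg_to_pa(70),
                          bc = bc, inflow = steady_inflow(q0),
                          config = solver_config(min_cycles = 4,
                                                 max_cycles = 60,
                                                 tol_mmHg = 1e-4))
  sol <- suppressWarnings(run_until_periodic(m))
  n <- length(sol$meanP)
  # outlet pressure equals P_out + (R_prox + R_dist) Q
  expect_rel(sol$meanP[n], (bc$R_prox + bc$R_dist) * q0, 0.01)
  # interior mean gradient equals the configured Poiseuille friction drop
  nd <- m$nodes
  blood <- blood_properties()
  i1 <- 6; i2 <- n - 5
  drop <- sol$meanP[i1] - sol$meanP[i2]
  A <- mean(sol$meanA[i1:i2])
  drop_pred <- blood$rho * (8 * pi * blood$mu / blood$rho) * q0 / A^2 *
    (nd$x[i2] - nd$x[i1])
  expect_rel(drop, drop_pred, 0.01)
})

test_that("a narrow pulse travels at the tube-law wave speed", {
  rho <- blood_properties()$rho
  for (c_target in c(5, 10)) {
    R <- 0.01; h <- 0.0015
    K <- c_target^2 * 2 * rho * R / h
    Zc <- rho * c_target / (pi * R^2)
    m <- uniform_tube_model(length = 1.2, radius = R, thickness = h,
                            K_th = K, map = mmHg_to_pa(93),
                            bc = list(R_prox = Zc, R_dist = 1e9, C = 1e-8,
                                      P_out = mmHg_to_pa(93)),
                            inflow = pulse_inflow(),
                            config = solver_config(dx = 0.005,
                                                   min_cycles = 1,
                                                   max_cycles = 1,
                                                   p_init = mmHg_to_pa(93)))
    sol <- suppressWarnings(run_until_periodic(m))
    p1 <- probe(sol, s = 0.2 / 1.2); p2 <- probe(sol, s = 1.0 / 1.2)
    c_meas <- 0.8 / (p1$time[which.max(p2$pressure)] -
                       p1$time[which.max(p1$pressure)])
    expect_rel(c_meas, c_target, 0.02)
  }
})

test_that("outlet pressure matches the 0D RCR oracle driven by the
          computed outlet flow", {
  skip_if_not_installed("deSolve")
  bc <- list(R_prox = 1.5e7, R_dist = 1.3e8, C = 1.2e-8, P_out = 0)
  m <- uniform_tube_model(length = 0.4, radius = 0.009, K_th = 0.8e6,
                          bc = bc, inflow = generate_inflow(),
                          config = solver_config(max_cycles = 40,
                                                 tol_mmHg = 0.02))
  sol <- suppressWarnings(run_until_periodic(m))
  pr <- probe(sol, s = 1)
  qfun <- stats::approxfun(pr$time, pr$flow, rule = 2)
  rhs <- function(t, y, parms) {
    tau <- t %% pr$period
    list((qfun(tau) - (y - bc$P_out) / bc$R_dist) / bc$C)
  }
  out <- deSolve::lsoda(c(Pc = mean(pr$pressure)),
                        seq(0, 12, by = pr$period / 256), rhs, NULL)
  # final simulated period of the independent 0D integration
  nper <- 256
  pc <- out[(nrow(out) - nper + 1):nrow(out), "Pc"]
  tt <- out[(nrow(out) - nper + 1):nrow(out), "time"] %% pr$period
  p_pred <- pc + bc$R_prox * qfun(tt)
  p_sim <- stats::approx(pr$time, pr$pressure, xout = tt, rule = 2)$y
  expect_lt(max(abs(p_pred - p_sim)) / diff(range(p_sim)), 0.01)
})

test_that("junctions split symmetric daughters evenly and conserve mass to
          machine precision", {
  mk <- function(name, parent, len, R, outlet = NULL)
    list(name = name, parent = parent, length = len,
         prop = function(x) data.frame(R = R, K_th = 1e6, h = 0.0012,
                                       map = mmHg_to_pa(93), ep = 0,
                                       ks = 0, cs = 0),
         s_of_x = NULL, outlet = outlet)
  segs <- list(mk("parent", NA_character_, 0.3, 0.008),
               mk("d1", "parent", 0.25, 0.0057, outlet = "o1"),
               mk("d2", "parent", 0.25, 0.0057, outlet = "o2"))
  bcs <- data.frame(outlet = c("o1", "o2"), R_prox = 5e7, R_dist = 2.6e8,
                    C = 6e-9, P_out = 0)
  m <- aortapulse:::build_pw_model(segs, bcs, generate_inflow(),
                                   solver_config(max_cycles = 30,
                                                 tol_mmHg = 0.05))
  sol <- suppressWarnings(run_until_periodic(m))
  nd <- m$nodes
  ip <- max(which(nd$seg == "parent"))
  i1 <- min(which(nd$seg == "d1")); i2 <- min(which(nd$seg == "d2"))
  # identical daughters receive identical flows
  expect_equal(sol$Q[, i1], sol$Q[, i2], tolerance = 1e-12)
  # and the parent flow is their exact sum at every recorded step
  expect_equal(sol$Q[, ip], sol$Q[, i1] + sol$Q[, i2], tolerance = 1e-13)
  # static pressure continuity at the junction
  expect_equal(sol$P[, ip], sol$P[, i1], tolerance = 1e-9)
})

test_that("an area-matched junction reflects less than 2% of an incident
          pulse", {
  rho <- blood_properties()$rho
  c0 <- 5; R <- 0.01; h <- 0.0015
  K <- c0^2 * 2 * rho * R / h
  Zc <- rho * c0 / (pi * R^2)
  p0 <- mmHg_to_pa(93)
  m <- uniform_tube_model(length = 2, radius = R, thickness = h, K_th = K,
                          map = p0, n_split = 2,
                          bc = list(R_prox = Zc, R_dist = 1e9, C = 1e-8,
                                    P_out = p0),
                          inflow = pulse_inflow(),
                          config = solver_config(dx = 0.005,
                                                 min_cycles = 1,
                                                 max_cycles = 1,
                                                 p_init = p0))
  sol <- suppressWarnings(run_until_periodic(m))
  pr <- probe(sol, s = 0.25)        # x = 0.5 m; junction at x = 1 m
  inc <- max(pr$pressure) - p0
  t_inc <- pr$time[which.max(pr$pressure)]
  # junction echo would arrive 2 x 0.5 m / c0 = 0.2 s after the incident
  # peak; the outlet echo only after 2 x 1.5 m / c0 = 0.6 s
  win <- pr$time > t_inc + 0.12 & pr$time < t_inc + 0.45
  refl <- max(abs(pr$pressure[win] - p0))
  expect_lt(refl / inc, 0.02)
})

test_that("support regions map stations and branches per the inheritance
          rule", {
  sup <- external_support(k_s = c(ATA = 3e5, DTA = 1e5, IAA = 0),
                          c_s = c(ATA = 30, DTA = 20, IAA = 10))
  expect_equal(support_at(sup, s = 0.1)$k_s, 3e5)
  expect_equal(support_at(sup, s = 0.3)$k_s, 1e5)   # DTA region
  expect_equal(support_at(sup, s = 0.8)$k_s, 0)
  expect_equal(support_at(sup, s = 1.2)$k_s, 0)
  expect_equal(support_at(sup, class = "upper")$k_s, 3e5)
  expect_equal(support_at(sup, class = "lower")$k_s, 0)   # renal etc.
  expect_error(support_at(sup), "uncovered")
})

test_that("external pressure follows the support share of mean pressure", {
  p0 <- mmHg_to_pa(93)
  wallK <- 0.5e6; h <- 0.0017; R <- 0.0116
  Kw <- wallK * h / R^2
  run_ep <- function(ks) {
    m <- uniform_tube_model(length = 0.5, radius = R, thickness = h,
                            K_th = wallK, map = p0, k_s = ks,
                            bc = list(R_prox = 1e7, R_dist = 1.2e8,
                                      C = 1.2e-8, P_out = 0),
                            inflow = generate_inflow(),
                            config = solver_config(max_cycles = 40,
                                                   tol_mmHg = 0.02))
    sol <- suppressWarnings(run_until_periodic(m))
    list(ep = external_pressure(sol, s = 0.5),
         map = mean(probe(sol, s = 0.5)$pressure))
  }
  r0 <- run_ep(0)
  expect_equal(r0$ep, 0)
  r1 <- run_ep(Kw)        # equal springs share the load evenly
  expect_rel(r1$ep, r1$map / 2, 0.05)
  r2 <- run_ep(4 * Kw)    # stiff support carries most of the load
  expect_rel(r2$ep, r2$map * 0.8, 0.05)
  expect_gt(r2$ep, r1$ep)
})

test_that("the assembled aorta conserves mass, matches the 0D mean
          pressure and converges periodically", {
  fix <- fixture_40()
  expect_true(fix$sol$converged)
  expect_lt(tail(fix$sol$resid, 1), mmHg_to_pa(0.05))
  expect_lt(flow_balance(fix$sol)$error, 0.005)
  map_0d <- predicted_map(fix$wk$bcs, fix$inflow$mean_flow)
  expect_lt(abs(fix$sol$meanP[1] - map_0d), mmHg_to_pa(2))
})

test_that("stiffening and support move pulse pressure and PWV in the
          reported directions", {
  fix <- fixture_40()
  pwv0 <- aorto_iliac_pwv(fix$sol)
  pp0 <- pulse_pressure(probe(fix$sol, s = 0))

  # doubling every circumferential stiffness raises aorto-iliac PWV
  tab2 <- wall_property_table()
  tab2$K_th_MPa <- tab2$K_th_MPa * 2
  walls2 <- assign_wall_properties(fix$tree, 40, table = tab2)
  sol2 <- suppressWarnings(run_until_periodic(
    assemble(fix$tree, walls2, fix$wk$bcs, fix$inflow, fix$sup,
             solver_config(max_cycles = 30, tol_mmHg = 0.05))))
  expect_gt(aorto_iliac_pwv(sol2), pwv0)

  # quintupling the support stiffness raises both PP and PWV
  sup5 <- external_support(k_s = 5 * fix$sup$k_s, c_s = fix$sup$c_s)
  sol5 <- suppressWarnings(run_until_periodic(
    assemble(fix$tree, fix$walls, fix$wk$bcs, fix$inflow, sup5,
             solver_config(max_cycles = 30, tol_mmHg = 0.05))))
  expect_gt(aorto_iliac_pwv(sol5), pwv0)
  expect_gt(pulse_pressure(probe(sol5, s = 0)), pp0)
})

test_that("halving the mesh spacing changes root pulse pressure by less
          than 1%", {
  fix <- fixture_40()
  pp0 <- pulse_pressure(probe(fix$sol, s = 0))
  solf <- suppressWarnings(run_until_periodic(
    assemble(fix$tree, fix$walls, fix$wk$bcs, fix$inflow, fix$sup,
             solver_config(dx = 0.005, max_cycles = 30, tol_mmHg = 0.05))))
  expect_rel(pulse_pressure(probe(solf, s = 0)), pp0, 0.01)
})

test_that("missing boundary conditions fail assembly with the terminal
          named", {
  tree <- age_geometry(build_baseline_tree(), 40)
  walls <- assign_wall_properties(tree, 40)
  bcs <- windkessel_set(40)
  bcs <- bcs[bcs$outlet != "r_renal", ]
  expect_error(assemble(tree, walls, bcs, generate_inflow()), "r_renal")
})
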