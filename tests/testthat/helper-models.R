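# shared fixtures, built in code and memoized across test files

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

# calibrated-support 40 yo model run at default settings
fixture_40 <- function() memo("fix40", {
  tree <- build_baseline_tree()
  aged <- age_geometry(tree, 40)
  walls <- assign_wall_properties(aged, 40)
  inflow <- generate_inflow()
  wk <- tune_windkessel(windkessel_set(40), mmHg_to_pa(93),
                        inflow$mean_flow)
  base <- aortapulse:::support_base_ks(aged, walls)
  sup <- external_support(
    k_s = c(ATA = unname(base["ATA"]), DTA = unname(base["DTA"]), IAA = 0),
    c_s = c(ATA = 100, DTA = 100, IAA = 100))
  sol <- suppressWarnings(run_until_periodic(
    assemble(aged, walls, wk$bcs, inflow, sup,
             solver_config(max_cycles = 30, tol_mmHg = 0.05))))
  list(tree = aged, walls = walls, wk = wk, sup = sup, inflow = inflow,
       sol = sol)
})

# full calibrated three-age pipeline (acceptance suite)
acceptance_report <- function() memo("report", {
  suppressWarnings(age_report(quiet = TRUE))
})

# constant (steady) inflow pseudo-waveform
steady_inflow <- function(q0, period = 1, n = 256) {
  structure(list(time = seq(0, period, length.out = n + 1)[seq_len(n)],
                 flow = rep(q0, n), period = period, mean_flow = q0),
            class = "inflow_waveform")
}

# single narrow Gaussian pulse on a long quiet period
pulse_inflow <- function(t0 = 0.05, width = 0.01, amp = 5e-6, period = 2,
                         n = 4096) {
  tt <- seq(0, period, length.out = n + 1)[seq_len(n)]
  q <- amp * exp(-((tt - t0) / width)^2)
  structure(list(time = tt, flow = q, period = period, mean_flow = mean(q)),
            class = "inflow_waveform")
}

# synthetic waveform probe from analytic series
make_probe <- function(time, pressure, area = NULL, flow = NULL,
                       period = max(time) + time[2] - time[1]) {
  structure(list(time = time, pressure = pressure,
                 flow = flow %||% rep(0, length(time)),
                 area = area %||% rep(1e-4, length(time)),
                 period = period),
            class = "waveform_probe")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
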