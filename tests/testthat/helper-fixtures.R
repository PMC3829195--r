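# Memoized fixtures shared across test files. All synthetic data are
# generated in code under fixed seeds; the heavier pipeline runs are built
# once per test session.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fx[[name]])) assign(name, force(expr), envir = .fx)
  .fx[[name]]
}

# Scaled-down grid mirroring the full 90 x 190 field of view.
test_cfg <- function(...) {
  synth_config(ys = 32, xs = 64, stim_ms = 1000, n_trials = 30, ...)
}

# Noiseless, artifact-free experiment: exact-value oracle for the
# preprocessing chain and the rendering equation.
fx_noiseless <- function() fixture("noiseless", {
  cfg <- synth_config(ys = 24, xs = 48, stim_ms = 900, n_trials = 2,
                      noise_sd = 0, heartbeat_amp = 0, seed = 5)
  list(cfg = cfg, run = run_experiment(cfg))
})

# Calibrated two-experiment recovery study (8 comparison cells) at the
# study conditions: gains 1.45 / 1.2, indirect fraction 0.03, 30 trials.
fx_calibrated <- function() fixture("calibrated", {
  cfgs <- lapply(c(7L, 8L), function(s) test_cfg(seed = s))
  suppressWarnings(contextual_analysis(cfgs, seed = 42))
})

# Same geometry with equal coherent and incoherent gains: the
# specificity-null condition.
fx_equal_gains <- function() fixture("equal_gains", {
  cfgs <- lapply(c(107L, 108L), function(s)
    test_cfg(facilitation_gain_coh = 1.2, spread_gain_coh_y = 1.085,
             coupling_coh = 0, seed = s))
  suppressWarnings(contextual_analysis(cfgs, seed = 43))
})

# Geometry where the top-5% ROI matches the spot core
# (half-max area ~ 5% of pixels): used for ROI and time-course tests.
roi_cfg <- function(n_trials = 30, ...) {
  synth_config(ys = 20, xs = 40, spot_sigma_px = c(3, 3), stim_ms = 900,
               n_trials = n_trials, ...)
}

fx_roi_run <- function() fixture("roi_run", {
  cfg <- roi_cfg(seed = 9)
  run <- run_experiment(cfg)
  rois <- lapply(1:2, function(m)
    define_roi(time_average(run$evoked, paste0("A", m)),
               time_average(run$evoked, paste0("B", m))))
  list(cfg = cfg, evoked = run$evoked, rois = rois)
})

# Movie-1-only experiment renderer for repeated-seed simulations.
movie1_evoked <- function(cfg) {
  conds <- c("blank1", "blank2", "A1", "B1", "A1B1", "A1B2")
  preprocess_experiment(generate_experiment(cfg, conditions = conds))
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected) / pmax(abs(expected), 1e-300)), tol)
}
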