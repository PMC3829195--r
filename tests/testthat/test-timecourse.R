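test_that("percentile ROI selection matches a brute-force sort oracle", {
  # forced example: values 1..100, 95th percentile -> the six pixels >= 95
  prof <- matrix(sample(1:100), 10, 10)
  roi <- define_roi(prof, -prof, pct = 95)
  expect_identical(sort(prof[roi$mask_A]), 95:100)
  expect_identical(sum(roi$mask_A), 6L)

  # brute-force oracle on random profiles
  set.seed(51)
  for (i in 1:20) {
    p1 <- matrix(rnorm(15 * 12), 15, 12)
    p2 <- matrix(rnorm(15 * 12), 15, 12)
    roi <- define_roi(p1, p2, pct = 95)
    thr <- sort(as.vector(p1))[ceiling(0.95 * 180)]
    brute <- matrix(as.vector(p1) >= thr, 15, 12)
    # overlap resolution can only remove pixels from the raw threshold mask
    expect_true(all(roi$mask_A | !brute | p2 > p1))
    expect_true(all(brute[roi$mask_A]))
    expect_false(any(roi$mask_A & roi$mask_B))
  }
  expect_error(define_roi(matrix(1, 5, 5), matrix(rnorm(25), 5, 5)),
               "degenerate ROI")
})

test_that("ROI masks center on their activity spots", {
  fx <- fx_noiseless()
  ev <- fx$run$evoked
  roi <- define_roi(time_average(ev, "A1"), time_average(ev, "B1"))
  cA <- colMeans(which(roi$mask_A, arr.ind = TRUE))
  cB <- colMeans(which(roi$mask_B, arr.ind = TRUE))
  expect_lt(sqrt(sum((cA - fx$cfg$centerA)^2)), 2)
  expect_lt(sqrt(sum((cB - fx$cfg$centerB)^2)), 2)
})

test_that("ROI traces reduce to pixel traces and preserve constants", {
  set.seed(52)
  data <- array(rnorm(12 * 30 * 1), dim = c(12, 30, 1))
  ds <- evoked_dataset(data, ys = 3, xs = 4, frame_rate_hz = 220,
                       prestim_samples = 4, cond_map = c(z = 1L))
  mask <- matrix(FALSE, 3, 4); mask[2, 3] <- TRUE
  tr <- roi_trace(ds, "z", mask, rate_hz = NULL)
  expect_equal(as.numeric(tr), data[2 + 3 * 2, , 1])
  # spatially constant frames -> the constant, any mask
  dconst <- array(rep(rnorm(30), each = 12), dim = c(12, 30, 1))
  dsc <- evoked_dataset(dconst, ys = 3, xs = 4, frame_rate_hz = 220,
                        prestim_samples = 4, cond_map = c(z = 1L))
  m2 <- matrix(c(TRUE, FALSE), 3, 4)
  expect_equal(as.numeric(roi_trace(dsc, "z", m2, rate_hz = NULL)),
               dconst[1, , 1])
  expect_error(roi_trace(ds, "z", matrix(FALSE, 3, 4)), "empty")
})

test_that("220 to 200 Hz resampling preserves a 5 Hz sinusoid", {
  t220 <- (0:439) / 220
  tr <- sin(2 * pi * 5 * t220)
  out <- resample_trace(tr, t220 * 1000, rate_hz = 200)
  t200 <- attr(out, "time_ms") / 1000
  expect_equal(diff(attr(out, "time_ms"))[1], 5)
  ref <- sin(2 * pi * 5 * t200)
  # amplitude fidelity: regression gain within 1% of unity
  expect_equal(sum(out * ref) / sum(ref^2), 1, tolerance = 0.01)
})

test_that("facilitated coherent traces dominate direct traces without noise", {
  fx <- fx_noiseless()
  rois <- lapply(1:2, function(m)
    define_roi(time_average(fx$run$evoked, paste0("A", m)),
               time_average(fx$run$evoked, paste0("B", m))))
  tt <- type_traces(fx$run$evoked, rois)
  stim <- tt$time_ms > 5 & tt$time_ms < 750
  expect_true(all(tt$median$coherent[stim] >= tt$median$direct[stim]))
  expect_true(all(tt$diff$coh_minus_dir$median[stim] >= 0))
})

test_that("identical condition data give an exactly zero difference trace", {
  fx <- fx_roi_run()
  ev <- fx$evoked
  # make every cell's coherent input equal its direct input
  cm <- ev$cond_map
  ev$data[, , cm[["B1"]]] <- ev$data[, , cm[["A1"]]]
  ev$data[, , cm[["A1B1"]]] <- ev$data[, , cm[["A1"]]]
  ev$data[, , cm[["B2"]]] <- ev$data[, , cm[["A2"]]]
  ev$data[, , cm[["A2B2"]]] <- ev$data[, , cm[["A2"]]]
  tt <- type_traces(ev, fx$rois)
  expect_identical(max(abs(tt$diff$coh_minus_dir$median)), 0)
})

test_that("correlation statistics are affine-invariant and degenerate-safe", {
  fx <- fx_roi_run()
  tc1 <- timecourse_correlations(fx$evoked, fx$rois)
  ev2 <- fx$evoked
  ev2$data <- 3 * ev2$data + 1e-3
  tc2 <- timecourse_correlations(ev2, fx$rois)
  expect_equal(tc1$r_single, tc2$r_single, tolerance = 1e-12)
  expect_equal(tc1$r_coherent, tc2$r_coherent, tolerance = 1e-12)
  ev3 <- fx$evoked
  ev3$data[, , ev3$cond_map[["A1"]]] <- 0
  expect_warning(tc3 <- timecourse_correlations(ev3, fx$rois, movies = 1),
                 "zero-variance")
  expect_true(is.nan(tc3$r_single[1]))
})

test_that("perfectly shared drives yield unit cross-location correlation", {
  cfg <- roi_cfg(drive_coh = 1, noise_sd = 0, heartbeat_amp = 0,
                 coupling_coh = 0, seed = 53)
  ev <- movie1_evoked(cfg)
  rois <- list(define_roi(time_average(ev, "A1"), time_average(ev, "B1")))
  tc <- timecourse_correlations(ev, rois, movies = 1)
  expect_equal(tc$r_single, 1, tolerance = 1e-6)
  expect_equal(tc$r_coherent, 1, tolerance = 1e-6)
})

test_that("independent drives leave incoherent correlations near zero", {
  rs <- sapply(1:5, function(s) {
    cfg <- roi_cfg(drive_coh = 0, noise_sd = 0, heartbeat_amp = 0, seed = 60 + s)
    ev <- movie1_evoked(cfg)
    rois <- list(define_roi(time_average(ev, "A1"), time_average(ev, "B1")))
    timecourse_correlations(ev, rois, movies = 1)$r_incoherent
  })
  expect_lt(abs(mean(rs)), 0.2)
})
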