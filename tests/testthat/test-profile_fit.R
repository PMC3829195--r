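test_that("the Gaussian surface obeys its closed-form identities", {
  g <- gaussian2d(A = 2.5, mu_x = 20.3, mu_y = 10.7, sigma_x = 3, sigma_y = 4,
                  rho = 0.05)
  grid <- list(X = matrix(g$mu_x), Y = matrix(g$mu_y))
  expect_equal(as.numeric(eval_gaussian(g, grid)), 2.5)
  # half-maximum at mu_x + sigma_x*sqrt(2 ln 2) when rho = 0
  g0 <- gaussian2d(A = 1.8, mu_x = 25, mu_y = 15, sigma_x = 3.2, sigma_y = 2.1)
  xh <- g0$mu_x + g0$sigma_x * sqrt(2 * log(2))
  expect_equal(as.numeric(eval_gaussian(g0, list(X = matrix(xh),
                                                 Y = matrix(g0$mu_y)))),
               g0$A / 2)
  # volume ~ 2 pi A sigma_x sigma_y on a grid extending >= 6 sigma
  gv <- gaussian2d(A = 1.3, mu_x = 40, mu_y = 40, sigma_x = 4, sigma_y = 5)
  vol <- sum(eval_gaussian(gv, make_grid(80, 80)))
  expect_equal(vol, 2 * pi * gv$A * gv$sigma_x * gv$sigma_y, tolerance = 0.01)
  expect_error(gaussian2d(1, 0, 0, -1, 2), "sigma")
  expect_error(gaussian2d(1, 0, 0, 2, 2, rho = 0.3), "rho")
})

test_that("heuristic initialization locates spots without cross-talk", {
  grid <- make_grid(30, 60)
  g1 <- gaussian2d(3e-4, 15, 9, 3, 3)
  g2 <- gaussian2d(1.2e-4, 45, 21, 3, 3)
  prof <- eval_gaussian(g1, grid) + eval_gaussian(g2, grid)
  init <- init_heuristic(prof, list(c(9, 15), c(21, 45)))
  expect_lt(abs(init[[1]]$mu_x - 15), 1)
  expect_lt(abs(init[[1]]$mu_y - 9), 1)
  expect_lt(abs(init[[2]]$mu_x - 45), 1)
  # each spot's amplitude equals its own windowed maximum (brute force)
  brute1 <- max(prof[max(1, 9 - 8):min(30, 9 + 8), max(1, 15 - 8):min(60, 15 + 8)])
  brute2 <- max(prof[13:29, 37:53])
  expect_equal(init[[1]]$A, brute1)
  expect_equal(init[[2]]$A, brute2)
  # degenerate flat profile -> epsilon amplitude per spot, no exception
  w <- capture_warnings(z <- init_heuristic(matrix(0, 30, 60),
                                            list(c(9, 15), c(21, 45))))
  expect_match(w, "flat", all = TRUE)
  expect_length(w, 2)
  expect_gt(z[[1]]$A, 0)
  expect_error(init_heuristic(prof, list(c(9, 15), c(9, 15))), "coincide")
})

test_that("noiseless model-generated surfaces are recovered exactly", {
  grid <- make_grid(32, 64)
  g1 <- gaussian2d(2.1e-4, 30.2, 9.4, 3.3, 2.7, rho = 0.02)
  g2 <- gaussian2d(-0.4e-4, 33.8, 24.1, 2.6, 3.9, rho = -0.03)
  surf <- eval_gaussian(g1, grid) + eval_gaussian(g2, grid)
  fit <- fit_two_spots(surf, list(c(9.4, 30.2), c(24.1, 33.8)))
  expect_true(fit$converged)
  for (p in names(g1)) {
    expect_lt(abs(fit$gA[[p]] - g1[[p]]) / abs(g1[[p]]), 1e-6)
    expect_lt(abs(fit$gB[[p]] - g2[[p]]) / abs(g2[[p]]), 1e-6)
  }
  expect_equal(fit$r_fit, 1, tolerance = 1e-9)
})

test_that("the fit is translation-equivariant", {
  grid <- make_grid(40, 60)
  g1 <- gaussian2d(3e-4, 25, 12, 3, 3.5)
  g2 <- gaussian2d(2e-4, 32, 28, 3.2, 2.8)
  base <- eval_gaussian(g1, grid) + eval_gaussian(g2, grid)
  f0 <- fit_two_spots(base, list(c(12, 25), c(28, 32)))
  shift <- function(g, dy, dx) { g$mu_x <- g$mu_x + dx; g$mu_y <- g$mu_y + dy; g }
  shifted <- eval_gaussian(shift(g1, 4, 6), grid) +
    eval_gaussian(shift(g2, 4, 6), grid)
  f1 <- fit_two_spots(shifted, list(c(16, 31), c(32, 38)))
  expect_equal(f1$gA$mu_x, f0$gA$mu_x + 6, tolerance = 1e-5)
  expect_equal(f1$gA$mu_y, f0$gA$mu_y + 4, tolerance = 1e-5)
  expect_equal(f1$gA$sigma_x, f0$gA$sigma_x, tolerance = 1e-5)
  expect_equal(f1$gB$sigma_y, f0$gB$sigma_y, tolerance = 1e-5)
  expect_equal(f1$gA$A, f0$gA$A, tolerance = 1e-5)
})

test_that("constraints are honored and recorded", {
  grid <- make_grid(24, 48)
  g1 <- gaussian2d(2e-4, 12, 6, 3, 3)
  g2 <- gaussian2d(1e-4, 36, 18, 3, 3)
  surf <- eval_gaussian(g1, grid) + eval_gaussian(g2, grid)
  fit <- fit_two_spots(surf, list(c(6, 12), c(18, 36)), center_box = 4,
                       A_lim = c(-1e-4, 1.5e-4))
  # peak bound is binding: fitted A stays at the ceiling
  expect_lte(fit$gA$A, 1.5e-4 + 1e-12)
  expect_true(fit$constraints$active[1])
  expect_lte(abs(fit$gA$mu_x - 12), 4)
  expect_lte(abs(fit$gB$mu_y - 18), 4)
})

test_that("amplitudes are recovered under pixel noise (Monte Carlo)", {
  grid <- make_grid(28, 56)
  g1 <- gaussian2d(1, 14, 8, 3, 3)
  g2 <- gaussian2d(0.7, 42, 20, 3, 3)
  clean <- eval_gaussian(g1, grid) + eval_gaussian(g2, grid)
  set.seed(44)
  errs <- replicate(50, {
    noisy <- clean + matrix(rnorm(28 * 56, sd = 0.05), 28, 56)
    f <- fit_two_spots(noisy, list(c(8, 14), c(20, 42)),
                       sigma_lim = c(1.5, 9))
    abs(f$gA$A - 1)
  })
  expect_lt(median(errs), 0.05)
})

test_that("indirect amplitude is statistically null when no leak is injected", {
  vals <- c()
  for (s in c(7L, 8L)) {
    cfg <- test_cfg(amp_indirect_frac = 0, seed = s)
    run <- run_experiment(cfg)
    sg <- mean(cfg$spot_sigma_px)
    for (cond in c("A1", "B1", "A2", "B2")) {
      f <- fit_two_spots(time_average(run$evoked, cond),
                         list(cfg$centerA, cfg$centerB),
                         center_box = max(2, round(sg / 2)),
                         sigma_lim = c(sg / 2, 3 * sg))
      g <- if (substr(cond, 1, 1) == "A") f$gB else f$gA
      vals <- c(vals, g$A)
    }
  }
  # mean indirect peak indistinguishable from zero across 8 cells
  expect_gt(paired_t_p(vals), 0.05)
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(length(vals)) * 2)
})

test_that("fit quality flags degenerate inputs", {
  expect_warning(r <- fit_quality(matrix(1, 4, 4), matrix(2, 4, 4)), "zero-variance")
  expect_true(is.nan(r))
  grid <- make_grid(20, 20)
  g <- gaussian2d(1, 10, 10, 3, 3)
  set.seed(45)
  expect_lt(abs(fit_quality(eval_gaussian(g, grid),
                            matrix(rnorm(400), 20, 20))), 0.25)
})
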