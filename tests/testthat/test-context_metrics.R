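dummy_fits <- function() {
  conds <- setdiff(cond_labels(), c("blank1", "blank2"))
  fits <- lapply(seq_along(conds), function(i)
    list(gA = gaussian2d(i + 0.1, 10, 10, 3, 3),
         gB = gaussian2d(i + 0.2, 10, 30, 3, 3), converged = TRUE))
  names(fits) <- conds
  fits
}

test_that("characteristic types follow the condition taxonomy", {
  fits <- dummy_fits()
  cs <- build_characteristics(fits)
  enc <- function(cond, spot) fits[[cond]][[spot]]$A
  # hand enumeration of all four (location, movie) cells
  expected <- list(
    list(loc = "A", movie = 1, direct = enc("A1", "gA"),
         indirect = enc("B1", "gA"), coherent = enc("A1B1", "gA"),
         incoherent = enc("A1B2", "gA")),
    list(loc = "B", movie = 1, direct = enc("B1", "gB"),
         indirect = enc("A1", "gB"), coherent = enc("A1B1", "gB"),
         incoherent = enc("A2B1", "gB")),
    list(loc = "A", movie = 2, direct = enc("A2", "gA"),
         indirect = enc("B2", "gA"), coherent = enc("A2B2", "gA"),
         incoherent = enc("A2B1", "gA")),
    list(loc = "B", movie = 2, direct = enc("B2", "gB"),
         indirect = enc("A2", "gB"), coherent = enc("A2B2", "gB"),
         incoherent = enc("A1B2", "gB")))
  for (i in 1:4) {
    expect_identical(cs[[i]]$location, expected[[i]]$loc)
    for (ty in c("direct", "indirect", "coherent", "incoherent"))
      expect_identical(cs[[i]][[ty]]$A, expected[[i]][[ty]])
  }
  # (B, movie 2): incoherent comes from the spot-B fit of A1B2
  expect_identical(cs[[4]]$incoherent$A, fits[["A1B2"]]$gB$A)

  expect_error(build_characteristics(fits[c("A1", "B1")]), "A2B2")
  # single-only input names the four missing pair conditions
  err <- tryCatch(build_characteristics(fits[c("A1", "B1", "A2", "B2")]),
                  error = conditionMessage)
  for (p in c("A1B1", "A2B2", "A1B2", "A2B1")) expect_match(err, p)
})

test_that("normalization by direct values yields unit direct rows and sane medians", {
  fits <- dummy_fits()
  cs <- build_characteristics(fits)
  nm <- normalize_by_direct(cs)
  dir_rows <- nm$table[nm$table$type == "direct", ]
  expect_true(all(dir_rows$A == 1 & dir_rows$sigma_x == 1 & dir_rows$sigma_y == 1))
  # brute-force median oracle across cells
  coh <- nm$table[nm$table$type == "coherent", "A"]
  srt <- sort(coh)
  brute <- if (length(srt) %% 2) srt[(length(srt) + 1) / 2] else
    mean(srt[length(srt) / 2 + 0:1])
  expect_equal(nm$medians[nm$medians$type == "coherent", "A"], brute)
})

test_that("percent change handles the printed example and edge cases", {
  expect_equal(percent_change(6.67e-4, 7.86e-4), 17.84, tolerance = 1e-3)
  expect_equal(round(percent_change(6.67e-4, 7.86e-4)), 18)
  expect_identical(percent_change(5, 5), 0)
  expect_identical(percent_change(1, 2), 100)
  expect_warning(out <- percent_change(0, 1), "nonpositive")
  expect_true(is.na(out))
})

test_that("facilitation metric formulas are forced by their definitions", {
  mkcell <- function(a_dir, a_ind, a_coh, a_incoh, loc = "A", movie = 1)
    list(location = loc, movie = movie,
         direct = gaussian2d(a_dir, 10, 10, 3, 3),
         indirect = gaussian2d(a_ind, 10, 30, 3, 3),
         coherent = gaussian2d(a_coh, 10, 10, 3, 3),
         incoherent = gaussian2d(a_incoh, 10, 10, 3, 3),
         converged = TRUE)
  cs <- structure(list(mkcell(1, 0.1, 1.5, 1.25),
                       mkcell(1, 0.1, 1.5, 1.25, loc = "B")),
                  class = "characteristic_set")
  m <- facilitation_metrics(cs, n_boot = 200, seed = 1)
  est <- function(nm) m$estimate[m$metric == nm]
  expect_equal(est("total_fac_pct"), 50)
  expect_equal(est("superadd_pct"), 40)
  expect_equal(est("linear_pct"), 10)
  expect_equal(est("specificity_pct"), 100 * (1.5 - 1.25) / 1.25)
  expect_equal(est("incoh_vs_direct_pct"), 25)
  # identity: linear + superadd == total, per cell and in aggregate
  cells <- attr(m, "cells")
  expect_equal(cells$linear_pct + cells$superadd_pct, cells$total_fac_pct)
  expect_equal(est("linear_pct") + est("superadd_pct"), est("total_fac_pct"))
  # CI brackets the point estimate
  expect_true(all(m$ci_lo <= m$estimate & m$estimate <= m$ci_hi))
})

test_that("spread metrics follow the geometric-mean definition", {
  mkcell <- function(sy_gain, loc) list(
    location = loc, movie = 1,
    direct = gaussian2d(1, 10, 10, 3, 3),
    indirect = gaussian2d(0.1, 10, 30, 3, 3),
    coherent = gaussian2d(1.5, 10, 10, 3, 3 * sy_gain),
    incoherent = gaussian2d(1.2, 10, 10, 3, 3),
    converged = TRUE)
  cs <- structure(list(mkcell(1.2, "A"), mkcell(1.2, "B")),
                  class = "characteristic_set")
  m <- spread_metrics(cs, n_boot = 200, seed = 2)
  est <- function(nm) m$estimate[m$metric == nm]
  expect_equal(est("spread_sigma_y_coh_vs_dir_pct"), 20)
  expect_equal(est("spread_sigma_x_coh_vs_dir_pct"), 0)
  expect_equal(est("spread_joint_coh_vs_dir_pct"), 100 * (sqrt(1.2) - 1),
               tolerance = 1e-9)
  # identical fits -> all changes zero
  same <- structure(list(mkcell(1, "A"), mkcell(1, "B")),
                    class = "characteristic_set")
  same <- lapply(same, function(cl) { cl$incoherent <- cl$coherent; cl$direct <- cl$coherent; cl })
  class(same) <- "characteristic_set"
  m0 <- spread_metrics(same, n_boot = 200, seed = 3)
  expect_true(all(m0$estimate == 0))
})

test_that("cells with nonpositive direct peaks are excluded pairwise", {
  fits <- dummy_fits()
  fits[["A1"]]$gA <- gaussian2d(-0.5, 10, 10, 3, 3)  # kills cell (A, 1)
  cs <- build_characteristics(fits)
  expect_warning(m <- facilitation_metrics(cs, n_boot = 100, seed = 4),
                 "excluded")
  expect_true(all(m$n == 3))
})
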