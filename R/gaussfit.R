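# Constrained superposition-of-two-Gaussians modelling of spatial activity
# profiles. The surface for one spot is
#   G(x, y) = A * exp(-[ (x-mu_x)^2/(2 sigma_x^2)
#                      + (y-mu_y)^2/(2 sigma_y^2)
#                      + rho (x-mu_x)(y-mu_y) ])
# with sigma as standard deviations (FWHM = 2*sqrt(2*log 2)*sigma) and rho a
# rotation/cross-term coefficient. The exponent is negative definite iff
# |rho| < 1/(sigma_x*sigma_y); the fit enforces this through the internal
# parameterization rho = rho_n/(sigma_x*sigma_y) with |rho_n| <= 1 - 1e-3.

RHO_DELTA <- 1e-3

#' Construct a rotated 2D Gaussian parameter set
#'
#' @param A Peak value (delta-F/F); may be negative (suppression).
#' @param mu_x,mu_y Center position in pixels (medio-lateral column,
#'   antero-posterior row).
#' @param sigma_x,sigma_y Spreads in pixels (> 0).
#' @param rho Rotation/cross-term coefficient; the decaying-surface bound
#'   `|rho| < 1/(sigma_x*sigma_y)` must hold.
#' @return An object of class `gaussian2d`.
#' @export
gaussian2d <- function(A, mu_x, mu_y, sigma_x, sigma_y, rho = 0) {
  if (sigma_x <= 0 || sigma_y <= 0)
    stop("parameter error: sigma_x and sigma_y must be positive")
  if (abs(rho) * sigma_x * sigma_y >= 1)
    stop("parameter error: |rho| must be < 1/(sigma_x*sigma_y) for a decaying surface")
  structure(list(A = A, mu_x = mu_x, mu_y = mu_y,
                 sigma_x = sigma_x, sigma_y = sigma_y, rho = rho),
            class = "gaussian2d")
}

#' Pixel-coordinate grid for a ys x xs image
#'
#' @param ys,xs Image dimensions.
#' @return List of matrices `X` (column index) and `Y` (row index).
#' @export
make_grid <- function(ys, xs) {
  list(X = matrix(rep(seq_len(xs), each = ys), ys, xs),
       Y = matrix(rep(seq_len(ys), xs), ys, xs))
}

#' Evaluate a 2D Gaussian on a grid
#'
#' @param g A `gaussian2d`.
#' @param grid A grid from [make_grid()] (or a list with matrices `X`, `Y`).
#' @return Numeric matrix of the same shape as the grid.
#' @export
eval_gaussian <- function(g, grid) {
  dx <- grid$X - g$mu_x
  dy <- grid$Y - g$mu_y
  g$A * exp(-(dx^2 / (2 * g$sigma_x^2) + dy^2 / (2 * g$sigma_y^2) +
                g$rho * dx * dy))
}

eval_two_spots <- function(gA, gB, grid) {
  eval_gaussian(gA, grid) + eval_gaussian(gB, grid)
}

# Parameter vector packing for the 12-parameter simultaneous fit. rho is
# carried as rho_n = rho*sigma_x*sigma_y in (-1, 1).
pack_params <- function(gA, gB) {
  p1 <- c(gA$A, gA$mu_x, gA$mu_y, gA$sigma_x, gA$sigma_y,
          gA$rho * gA$sigma_x * gA$sigma_y)
  p2 <- c(gB$A, gB$mu_x, gB$mu_y, gB$sigma_x, gB$sigma_y,
          gB$rho * gB$sigma_x * gB$sigma_y)
  c(p1, p2)
}

unpack_params <- function(p) {
  one <- function(q) gaussian2d(A = q[1], mu_x = q[2], mu_y = q[3],
                                sigma_x = q[4], sigma_y = q[5],
                                rho = q[6] / (q[4] * q[5]))
  list(gA = one(p[1:6]), gB = one(p[7:12]))
}

#' Heuristic initialization for the two-spot fit
#'
#' Per spot: the initial amplitude and center are taken from the local
#' extremum of largest magnitude within a search box around the
#' approximate center (positive peaks and suppressive troughs are both
#' supported); initial spreads come from the second moments of the
#' half-extremum neighbourhood; the initial cross term is zero. A flat
#' neighbourhood yields a small positive epsilon amplitude with a warning
#' instead of an error.
#'
#' @param profile An `activity_profile` (or plain matrix).
#' @param approx_centers List of two `c(row, col)` approximate spot centers.
#' @param search_halfwidth Half-width of the search box in pixels.
#' @return List of two `gaussian2d` objects.
#' @export
init_heuristic <- function(profile, approx_centers, search_halfwidth = 8) {
  stopifnot(length(approx_centers) == 2)
  if (isTRUE(all.equal(approx_centers[[1]], approx_centers[[2]])))
    stop("argument error: approximate centers coincide")
  ys <- nrow(profile); xs <- ncol(profile)
  lapply(approx_centers, function(ctr) {
    rr <- max(1, round(ctr[1]) - search_halfwidth):min(ys, round(ctr[1]) + search_halfwidth)
    cc <- max(1, round(ctr[2]) - search_halfwidth):min(xs, round(ctr[2]) + search_halfwidth)
    sub <- profile[rr, cc, drop = FALSE]
    hi <- max(sub); lo <- min(sub)
    peak <- if (abs(hi) >= abs(lo)) hi else lo
    if (!is.finite(peak) || peak == 0) {
      warning("flat profile around approximate center; epsilon initialization")
      return(gaussian2d(A = 1e-9, mu_x = ctr[2], mu_y = ctr[1],
                        sigma_x = max(2, search_halfwidth / 3),
                        sigma_y = max(2, search_halfwidth / 3), rho = 0))
    }
    w <- which(sub == peak, arr.ind = TRUE)[1, ]
    mu_y <- rr[w[1]]; mu_x <- cc[w[2]]
    above <- which(sub * sign(peak) >= abs(peak) / 2, arr.ind = TRUE)
    sy <- stats::sd(rr[above[, 1]])
    sx <- stats::sd(cc[above[, 2]])
    # sd of the half-max support of a Gaussian underestimates sigma; the
    # optimizer only needs the right order of magnitude
    gaussian2d(A = peak, mu_x = mu_x, mu_y = mu_y,
               sigma_x = max(1, sx, na.rm = TRUE),
               sigma_y = max(1, sy, na.rm = TRUE), rho = 0)
  })
}

#' Fit a constrained superposition of two rotated 2D Gaussians
#'
#' Bounded nonlinear least squares over all 12 parameters simultaneously
#' (Levenberg-Marquardt with box constraints). Centers are constrained
#' within `center_box` pixels of the approximate centers, spreads within
#' `sigma_lim`, amplitudes within `A_lim` (the lower bound may be negative,
#' allowing indirect suppression), and the cross term is bounded so the
#' fitted surfaces always decay away from their centers. Two Gaussians are
#' fitted even when only one spot was stimulated: the second, constrained to
#' the distant location, estimates the indirect activation there.
#'
#' @param profile An `activity_profile` or matrix.
#' @param approx_centers List of two `c(row, col)` centers (spot A first).
#' @param center_box Half-width of the center constraint box (px).
#' @param sigma_lim `c(min, max)` bounds on the spreads (px); default
#'   `c(1, max(dim)/2)`.
#' @param A_lim `c(min, max)` bounds on the amplitudes; default
#'   `c(-1, 1) * 3 * max(|profile|)`.
#' @param max_fev Maximum residual evaluations.
#' @return A `two_spot_fit`: list with `gA`, `gB`, `r_fit`, `residual_norm`,
#'   `converged`, and a `constraints` record of the bounds and which were
#'   active at the solution.
#' @export
fit_two_spots <- function(profile, approx_centers, center_box = 5,
                          sigma_lim = NULL, A_lim = NULL, max_fev = 2000) {
  if (center_box <= 0) stop("argument error: center_box must be positive")
  prof <- unclass(profile)
  attributes(prof) <- list(dim = dim(profile))
  if (any(!is.finite(prof))) stop("profile contains non-finite values")
  ys <- nrow(prof); xs <- ncol(prof)
  if (is.null(sigma_lim)) sigma_lim <- c(1, max(ys, xs) / 2)
  if (is.null(A_lim)) {
    a <- 3 * max(abs(prof), 1e-12)
    A_lim <- c(-a, a)
  }
  init <- init_heuristic(prof, approx_centers,
                         search_halfwidth = max(3, ceiling(center_box)))
  grid <- make_grid(ys, xs)
  y <- as.vector(prof)

  bound_one <- function(ctr) list(
    lower = c(A_lim[1], ctr[2] - center_box, ctr[1] - center_box,
              sigma_lim[1], sigma_lim[1], -(1 - RHO_DELTA)),
    upper = c(A_lim[2], ctr[2] + center_box, ctr[1] + center_box,
              sigma_lim[2], sigma_lim[2], 1 - RHO_DELTA))
  bA <- bound_one(approx_centers[[1]]); bB <- bound_one(approx_centers[[2]])
  lower <- c(bA$lower, bB$lower)
  upper <- c(bA$upper, bB$upper)
  p0 <- pmin(pmax(pack_params(init[[1]], init[[2]]), lower), upper)

  resid_fn <- function(p) {
    gs <- unpack_params(p)
    y - as.vector(eval_two_spots(gs$gA, gs$gB, grid))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0, lower = lower, upper = upper, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 1000, maxfev = max_fev,
                         ftol = 1e-15, ptol = 1e-15, gtol = 0)),
    error = function(e) NULL)
  if (is.null(fit)) {
    p_hat <- p0
    converged <- FALSE
    rnorm_ <- sqrt(sum(resid_fn(p0)^2))
  } else {
    p_hat <- fit$par
    converged <- fit$info %in% 1:4
    rnorm_ <- sqrt(fit$deviance)
  }
  gs <- unpack_params(p_hat)
  at_bound <- abs(p_hat - lower) < 1e-8 | abs(upper - p_hat) < 1e-8
  model <- eval_two_spots(gs$gA, gs$gB, grid)
  structure(list(gA = gs$gA, gB = gs$gB,
                 r_fit = fit_quality(model, prof),
                 residual_norm = rnorm_,
                 converged = converged,
                 constraints = list(lower = lower, upper = upper,
                                    active = at_bound,
                                    center_box = center_box,
                                    sigma_lim = sigma_lim, A_lim = A_lim)),
            class = "two_spot_fit")
}

#' @export
print.two_spot_fit <- function(x, ...) {
  fmt <- function(g) sprintf(
    "A=%.3g mu=(%.1f,%.1f) sigma=(%.2f,%.2f) rho=%.3g",
    g$A, g$mu_x, g$mu_y, g$sigma_x, g$sigma_y, g$rho)
  cat("<two_spot_fit> r_fit =", format(x$r_fit, digits = 3),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("  spot A:", fmt(x$gA), "\n  spot B:", fmt(x$gB), "\n")
  invisible(x)
}

#' Goodness of fit as a correlation coefficient
#'
#' Pearson correlation between the model surface and the observed profile
#' over all pixels. Zero-variance inputs yield `NaN` with a warning.
#'
#' @param model A fitted surface (matrix), or a `two_spot_fit` (evaluated on
#'   the profile's grid).
#' @param profile Observed profile matrix.
#' @return Scalar correlation in `[-1, 1]`, or `NaN`.
#' @export
fit_quality <- function(model, profile) {
  if (inherits(model, "two_spot_fit"))
    model <- eval_two_spots(model$gA, model$gB,
                            make_grid(nrow(profile), ncol(profile)))
  m <- as.vector(model); d <- as.vector(unclass(profile))
  if (stats::sd(d) == 0 || stats::sd(m) == 0) {
    warning("zero-variance input; fit quality undefined")
    return(NaN)
  }
  stats::cor(m, d)
}

#' Fit spatial profiles of all stimulus conditions
#'
#' Computes the time-averaged profile of each of the eight stimulus
#' conditions and fits each with the constrained two-Gaussian model, using
#' the same pair of approximate centers throughout (spot A first).
#'
#' @param ds An `evoked_dataset`.
#' @param approx_centers List of two `c(row, col)` centers.
#' @param window Analysis window in ms after stimulus onset.
#' @param ... Passed to [fit_two_spots()].
#' @return Named list of `two_spot_fit` objects, one per stimulus condition.
#' @export
fit_conditions <- function(ds, approx_centers, window = c(0, 750), ...) {
  conds <- setdiff(names(ds$cond_map), c("blank1", "blank2"))
  fits <- lapply(conds, function(cond)
    fit_two_spots(time_average(ds, cond, window = window),
                  approx_centers, ...))
  names(fits) <- conds
  fits
}
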