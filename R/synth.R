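# Synthetic trial-stack generator. Emulates the statistical structure the
# analysis assumes: two Gaussian cortical spots driven by temporally
# correlated signals, multiplicative facilitation in paired conditions, a
# static illumination gain field, a heartbeat-like artifact phase-locked
# identically in blank and stimulus trials, and i.i.d. trial noise.

fwhm_factor <- function() 2 * sqrt(2 * log(2))

child_seed <- function(seed, k) {
  s <- (as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483629
  as.integer(s) + 1L
}

# Run `expr` under a private RNG stream without disturbing the caller's.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration for the synthetic VSDI experiment generator
#'
#' Defines the geometry, amplitudes and noise structure of a simulated
#' two-patch contextual experiment. Defaults reproduce the study design:
#' 220 Hz acquisition, 200 ms prestimulus, 2 s presentation with the first
#' 750 ms analyzed, aperture centers separated by 2.5 FWHM of the mean spot
#' width, 30 trials per condition.
#'
#' @param ys,xs Grid size in pixels (antero-posterior rows, medio-lateral
#'   columns). The default 90 x 190 echoes a ~10 x 5 mm field of view at
#'   `mm_per_px`; tests and examples use scaled-down grids.
#' @param mm_per_px Pixel pitch in millimetres.
#' @param frame_rate_hz Sampling rate (Hz).
#' @param prestim_ms,stim_ms Prestimulus and stimulus durations (ms).
#' @param analysis_ms Length of the analysis window after stimulus onset (ms).
#' @param spot_sigma_px Gaussian spot spreads `c(sigma_x, sigma_y)` in px;
#'   default scales with the grid (`max(2, round(ys/10))`).
#' @param spot_rho Rotation/cross-term coefficient of the generated spots.
#' @param sep_fwhm Center separation between the two spots in units of the
#'   mean-FWHM (default 2.5). Spots are placed along the antero-posterior
#'   (row) axis, mirroring the vertical arrangement of the apertures.
#' @param centerA,centerB Optional explicit spot centers `c(row, col)`; when
#'   given, `sep_fwhm` is rederived from them.
#' @param amp_direct Evoked delta-F/F amplitude of a directly stimulated spot
#'   (time-averaged peak over the analysis window).
#' @param amp_indirect_frac Fraction of `amp_direct` leaking to the distant,
#'   non-stimulated spot in single conditions (may be negative: suppression).
#' @param facilitation_gain_coh,facilitation_gain_incoh Multiplicative gain
#'   applied to both spots in coherent / incoherent paired conditions.
#' @param spread_gain_coh_y,spread_gain_incoh_y Multiplicative widening of
#'   `sigma_y` (the axis pointing to the contextual patch) in paired
#'   conditions.
#' @param drive_coh Shared-component weight c in \[0, 1\]: expected temporal
#'   correlation between the drives of the same movie at locations A and B.
#' @param coupling_coh,coupling_incoh Drive-mixing weight kappa applied in
#'   paired conditions: each spot's effective drive is
#'   `(1-kappa) * own + kappa * distant`, emulating interaction-driven
#'   entrainment of time courses.
#' @param drive_lp_span Width (samples) of the moving-average low-pass filter
#'   applied to the white-noise drives.
#' @param heartbeat_hz,heartbeat_amp Frequency and fractional amplitude of
#'   the periodic artifact (identical across all trials and conditions).
#' @param gain_field_amp Fractional amplitude of the static illumination
#'   inhomogeneity.
#' @param noise_sd Standard deviation of the i.i.d. fractional trial noise
#'   per pixel and sample.
#' @param n_trials Trials per condition (>= 2).
#' @param seed Master seed; all condition, drive and gain-field streams are
#'   derived from it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(ys = 90, xs = 190, mm_per_px = 0.05,
                         frame_rate_hz = 220, prestim_ms = 200,
                         stim_ms = 2000, analysis_ms = 750,
                         spot_sigma_px = NULL, spot_rho = 0,
                         sep_fwhm = 2.5, centerA = NULL, centerB = NULL,
                         amp_direct = 2.3e-4, amp_indirect_frac = 0.03,
                         facilitation_gain_coh = 1.45,
                         facilitation_gain_incoh = 1.2,
                         spread_gain_coh_y = 1.18,
                         spread_gain_incoh_y = 1.085,
                         drive_coh = 0.57,
                         coupling_coh = 0.2, coupling_incoh = 0,
                         drive_lp_span = 11,
                         heartbeat_hz = 2.5, heartbeat_amp = 1e-3,
                         gain_field_amp = 0.15, noise_sd = 6e-4,
                         n_trials = 30, seed = 1) {
  if (is.null(spot_sigma_px)) {
    s <- max(2, round(ys / 10))
    spot_sigma_px <- c(s, s)
  }
  sigma_mean <- mean(spot_sigma_px)
  if (is.null(centerA) || is.null(centerB)) {
    sep_px <- sep_fwhm * fwhm_factor() * sigma_mean
    centerA <- c((ys + 1) / 2 - sep_px / 2, (xs + 1) / 2)
    centerB <- c((ys + 1) / 2 + sep_px / 2, (xs + 1) / 2)
  } else {
    sep_fwhm <- sqrt(sum((centerA - centerB)^2)) / (fwhm_factor() * sigma_mean)
  }
  cfg <- list(ys = as.integer(ys), xs = as.integer(xs), mm_per_px = mm_per_px,
              frame_rate_hz = frame_rate_hz, prestim_ms = prestim_ms,
              stim_ms = stim_ms, analysis_ms = analysis_ms,
              spot_sigma_px = spot_sigma_px, spot_rho = spot_rho,
              sep_fwhm = sep_fwhm, centerA = centerA, centerB = centerB,
              amp_direct = amp_direct, amp_indirect_frac = amp_indirect_frac,
              facilitation_gain_coh = facilitation_gain_coh,
              facilitation_gain_incoh = facilitation_gain_incoh,
              spread_gain_coh_y = spread_gain_coh_y,
              spread_gain_incoh_y = spread_gain_incoh_y,
              drive_coh = drive_coh,
              coupling_coh = coupling_coh, coupling_incoh = coupling_incoh,
              drive_lp_span = as.integer(drive_lp_span),
              heartbeat_hz = heartbeat_hz, heartbeat_amp = heartbeat_amp,
              gain_field_amp = gain_field_amp, noise_sd = noise_sd,
              n_trials = as.integer(n_trials), seed = as.integer(seed))
  cfg$prestim_samples <- round(prestim_ms / 1000 * frame_rate_hz)
  cfg$n_time <- round((prestim_ms + stim_ms) / 1000 * frame_rate_hz)
  cfg$analysis_samples <- round(analysis_ms / 1000 * frame_rate_hz)
  class(cfg) <- "synth_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  with(cfg, {
    if (amp_direct < 0 || heartbeat_amp < 0 || gain_field_amp < 0 ||
        noise_sd < 0)
      stop("amplitudes must be >= 0")
    if (drive_coh < 0 || drive_coh > 1) stop("drive_coh must lie in [0, 1]")
    if (n_trials < 2) stop("n_trials must be >= 2")
    if (any(spot_sigma_px <= 0)) stop("spot sigmas must be positive")
    if (prestim_samples < 2) stop("need at least 2 prestimulus samples")
  })
  sep_px <- sqrt(sum((cfg$centerA - cfg$centerB)^2))
  implied <- sep_px / (fwhm_factor() * mean(cfg$spot_sigma_px))
  if (abs(implied - cfg$sep_fwhm) * fwhm_factor() * mean(cfg$spot_sigma_px) > 1)
    stop("center separation inconsistent with sep_fwhm (beyond 1 px)")
  invisible(cfg)
}

# Time of each sample in ms relative to stimulus onset.
sample_times_ms <- function(cfg) {
  (seq_len(cfg$n_time) - 1) / cfg$frame_rate_hz * 1000 - cfg$prestim_ms
}

lowpass_ma <- function(x, span) {
  as.numeric(stats::filter(x, rep(1 / span, span), sides = 2,
                           circular = TRUE))
}

standardize <- function(x) (x - mean(x)) / stats::sd(x)

#' Generate the temporal drive signal of one movie at one location
#'
#' Drives are low-pass-filtered Gaussian noise, zero during the prestimulus
#' interval and shifted to be non-negative (unit variance) during the
#' stimulus. The same movie at locations A and B shares a common component
#' with weight `sqrt(drive_coh)`, so the expected correlation between the
#' two locations' drives equals `drive_coh`; different movies are
#' independent. Deterministic given `cfg$seed`.
#'
#' @param cfg A `synth_config`.
#' @param movie Movie index, 1 or 2.
#' @param location `"A"` or `"B"`.
#' @param n_stim Optional override of the number of stimulus samples
#'   (default `cfg$n_time - cfg$prestim_samples`); the prestimulus zeros are
#'   prepended only when the default length is used.
#' @return Numeric vector: the drive time series.
#' @export
make_drive <- function(cfg, movie, location, n_stim = NULL) {
  stopifnot(movie %in% c(1, 2), location %in% c("A", "B"))
  default_len <- is.null(n_stim)
  if (default_len) n_stim <- cfg$n_time - cfg$prestim_samples
  loc_idx <- match(location, c("A", "B"))
  shared <- with_seed(child_seed(cfg$seed, 100 + movie),
                      stats::rnorm(n_stim))
  priv <- with_seed(child_seed(cfg$seed, 200 + 10 * movie + loc_idx),
                    stats::rnorm(n_stim))
  span <- cfg$drive_lp_span
  s <- standardize(lowpass_ma(shared, span))
  p <- standardize(lowpass_ma(priv, span))
  c_w <- cfg$drive_coh
  d <- standardize(sqrt(c_w) * s + sqrt(1 - c_w) * p)
  d <- d - min(d)  # rectify: evoked activity is net positive
  if (default_len) c(rep(0, cfg$prestim_samples), d) else d
}

# Static illumination gain field: smoothed spatial noise around 1.
gain_field <- function(cfg) {
  z <- with_seed(child_seed(cfg$seed, 1), {
    m <- matrix(stats::rnorm(cfg$ys * cfg$xs), cfg$ys, cfg$xs)
    k <- max(3, round(min(cfg$ys, cfg$xs) / 4))
    m <- apply(m, 2, lowpass_ma, span = k)
    m <- t(apply(m, 1, lowpass_ma, span = k))
    (m - mean(m)) / stats::sd(m)
  })
  g <- 1 + cfg$gain_field_amp * z
  pmax(g, 0.2)
}

heartbeat_wave <- function(cfg) {
  t_s <- (seq_len(cfg$n_time) - 1) / cfg$frame_rate_hz
  cfg$heartbeat_amp * sin(2 * pi * cfg$heartbeat_hz * t_s)
}

parse_condition <- function(condition) {
  if (condition %in% c("blank1", "blank2"))
    return(list(type = "blank", patches = list()))
  if (grepl("^[AB][12]$", condition)) {
    loc <- substr(condition, 1, 1)
    mov <- as.integer(substr(condition, 2, 2))
    return(list(type = "single",
                patches = list(list(loc = loc, movie = mov))))
  }
  if (grepl("^A[12]B[12]$", condition)) {
    mA <- as.integer(substr(condition, 2, 2))
    mB <- as.integer(substr(condition, 4, 4))
    return(list(type = if (mA == mB) "coherent" else "incoherent",
                patches = list(list(loc = "A", movie = mA),
                               list(loc = "B", movie = mB))))
  }
  stop(sprintf("condition error: unknown label '%s'", condition))
}

spot_center <- function(cfg, loc) if (loc == "A") cfg$centerA else cfg$centerB

# True spot parameter sets for one condition (the deterministic part of the
# rendering model). Each spot: gaussian2d parameters plus its drive series.
condition_spots <- function(cfg, condition) {
  info <- parse_condition(condition)
  sx <- cfg$spot_sigma_px[1]; sy <- cfg$spot_sigma_px[2]
  spots <- list()
  if (info$type == "single") {
    p <- info$patches[[1]]
    other <- setdiff(c("A", "B"), p$loc)
    d <- make_drive(cfg, p$movie, p$loc)
    spots[[p$loc]] <- list(loc = p$loc, movie = p$movie, role = "direct",
                           A = cfg$amp_direct, center = spot_center(cfg, p$loc),
                           sigma_x = sx, sigma_y = sy, rho = cfg$spot_rho,
                           drive = d)
    spots[[other]] <- list(loc = other, movie = p$movie, role = "indirect",
                           A = cfg$amp_indirect_frac * cfg$amp_direct,
                           center = spot_center(cfg, other),
                           sigma_x = sx, sigma_y = sy, rho = cfg$spot_rho,
                           drive = d)
  } else if (info$type %in% c("coherent", "incoherent")) {
    coh <- info$type == "coherent"
    g <- if (coh) cfg$facilitation_gain_coh else cfg$facilitation_gain_incoh
    sgy <- if (coh) cfg$spread_gain_coh_y else cfg$spread_gain_incoh_y
    kap <- if (coh) cfg$coupling_coh else cfg$coupling_incoh
    dA <- make_drive(cfg, info$patches[[1]]$movie, "A")
    dB <- make_drive(cfg, info$patches[[2]]$movie, "B")
    eff <- list(A = (1 - kap) * dA + kap * dB,
                B = (1 - kap) * dB + kap * dA)
    for (p in info$patches) {
      spots[[p$loc]] <- list(loc = p$loc, movie = p$movie, role = info$type,
                             A = g * cfg$amp_direct,
                             center = spot_center(cfg, p$loc),
                             sigma_x = sx, sigma_y = sy * sgy,
                             rho = cfg$spot_rho, drive = eff[[p$loc]])
    }
  }
  spots
}

# Scale a drive so its mean over the analysis window is exactly 1; the true
# spot amplitude then equals the time-averaged evoked peak by construction.
normalize_drive <- function(cfg, d) {
  n_stim <- length(d) - cfg$prestim_samples
  idx <- cfg$prestim_samples + seq_len(min(cfg$analysis_samples, n_stim))
  m <- mean(d[idx])
  if (m <= 0) stop("degenerate drive: nonpositive analysis-window mean")
  d / m
}

#' Render all trials of one stimulus condition
#'
#' Produces raw fluorescence frames
#' `gain_field * (1 + evoked + heartbeat + noise)` where the evoked term is
#' the sum over stimulated spots of
#' `gain_cond * amplitude * G_spot(x, y) * drive(t)` (zero during the
#' prestimulus interval and for blank conditions), the heartbeat artifact is
#' identical in expectation across blank and stimulus trials, and the noise
#' is i.i.d. Gaussian per pixel, sample and trial.
#'
#' @param cfg A `synth_config`.
#' @param condition One of the ten labels in [cond_labels()].
#' @param noise_seed Seed for the trial-noise stream; defaults to a child
#'   stream of `cfg$seed` specific to the condition.
#' @return A `trial_stack`: list with `frames` (`[n_px, n_time, n_trials]`),
#'   `condition`, `cfg`, and the true spot parameters as attribute `"truth"`.
#' @export
render_condition <- function(cfg, condition, noise_seed = NULL) {
  idx <- match(condition, cond_labels())
  if (is.na(idx)) stop(sprintf("condition error: unknown label '%s'", condition))
  if (is.null(noise_seed)) noise_seed <- child_seed(cfg$seed, 1000 + idx)
  n_px <- cfg$ys * cfg$xs
  spots <- condition_spots(cfg, condition)
  evoked <- matrix(0, n_px, cfg$n_time)
  grid <- make_grid(cfg$ys, cfg$xs)
  for (s in spots) {
    g <- gaussian2d(A = 1, mu_x = s$center[2], mu_y = s$center[1],
                    sigma_x = s$sigma_x, sigma_y = s$sigma_y, rho = s$rho)
    surf <- as.vector(eval_gaussian(g, grid))
    evoked <- evoked + s$A * surf %o% normalize_drive(cfg, s$drive)
  }
  base <- 1 + sweep(evoked, 2, heartbeat_wave(cfg), "+")
  gf <- as.vector(gain_field(cfg))
  frames <- with_seed(noise_seed, {
    out <- array(0, dim = c(n_px, cfg$n_time, cfg$n_trials))
    for (k in seq_len(cfg$n_trials)) {
      eps <- matrix(stats::rnorm(n_px * cfg$n_time, sd = cfg$noise_sd),
                    n_px, cfg$n_time)
      out[, , k] <- gf * (base + eps)
    }
    out
  })
  structure(list(frames = frames, condition = condition, cfg = cfg,
                 prestim_samples = cfg$prestim_samples,
                 frame_rate_hz = cfg$frame_rate_hz),
            class = "trial_stack",
            truth = lapply(spots, function(s) s[setdiff(names(s), "drive")]))
}

#' Generate a full synthetic experiment with ground truth
#'
#' Renders all ten conditions (two blanks plus eight stimulus conditions)
#' with per-condition child RNG streams derived from `cfg$seed`, and exports
#' the ground truth needed for recovery tests: true spot parameters per
#' condition, the four drive series, the expected same-movie drive
#' correlation, and the facilitation gains.
#'
#' @param cfg A `synth_config`.
#' @param conditions Subset of labels to render (default: all ten).
#' @return List with `stacks` (named list of `trial_stack`) and `truth`.
#' @export
generate_experiment <- function(cfg, conditions = cond_labels()) {
  stacks <- lapply(conditions, function(cond) render_condition(cfg, cond))
  names(stacks) <- conditions
  truth <- list(
    spots = lapply(stacks, function(s) attr(s, "truth")),
    drives = sapply(c("A", "B"), function(loc)
      sapply(1:2, function(m) make_drive(cfg, m, loc),
             simplify = FALSE), simplify = FALSE),
    drive_coh = cfg$drive_coh,
    facilitation_gain_coh = cfg$facilitation_gain_coh,
    facilitation_gain_incoh = cfg$facilitation_gain_incoh,
    amp_indirect_frac = cfg$amp_indirect_frac,
    centerA = cfg$centerA, centerB = cfg$centerB,
    spot_sigma_px = cfg$spot_sigma_px)
  list(stacks = stacks, truth = truth, cfg = cfg)
}
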