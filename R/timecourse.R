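# Percentile-ROI extraction and time-resolved analysis: per-type mean
# traces at 200 Hz, pairwise difference traces with per-bin sign-rank
# tests, and cross-location correlations (r_single, r_coherent,
# r_incoherent).

#' Define a pair of percentile regions of interest
#'
#' From the two single-condition profiles of one movie, selects per
#' location the pixels whose activity lies within the highest
#' `100 - pct` percent (default: the top 5th percentile, boundary value
#' included). Pixels falling in both masks are assigned to the location
#' with the larger profile value, so the masks never overlap.
#'
#' @param profile_A,profile_B `activity_profile`s of the two single
#'   conditions (patch at A, patch at B).
#' @param pct Percentile threshold (default 95).
#' @return A `roi_pair`: list with logical matrices `mask_A`, `mask_B`, the
#'   percentile used and the source condition labels.
#' @export
define_roi <- function(profile_A, profile_B, pct = 95) {
  one_mask <- function(prof) {
    v <- as.vector(unclass(prof))
    if (stats::sd(v) == 0)
      stop("degenerate ROI: constant profile, percentile selection undefined")
    thr <- stats::quantile(v, pct / 100, type = 1, names = FALSE)
    matrix(v >= thr, nrow(prof), ncol(prof))
  }
  mA <- one_mask(profile_A); mB <- one_mask(profile_B)
  both <- mA & mB
  if (any(both)) {
    a_wins <- unclass(profile_A) >= unclass(profile_B)
    mA[both] <- a_wins[both]
    mB[both] <- !a_wins[both]
  }
  if (!any(mA) || !any(mB))
    stop("degenerate ROI: empty mask after overlap resolution")
  structure(list(mask_A = mA, mask_B = mB, pct = pct,
                 conditions = c(attr(profile_A, "condition"),
                                attr(profile_B, "condition"))),
            class = "roi_pair")
}

resample_trace <- function(trace, t_ms, rate_hz = 200) {
  t_new <- seq(t_ms[1], t_ms[length(t_ms)], by = 1000 / rate_hz)
  out <- stats::approx(t_ms, trace, xout = t_new)$y
  attr(out, "time_ms") <- t_new
  attr(out, "rate_hz") <- rate_hz
  out
}

#' ROI-mean time course of one condition
#'
#' Averages the evoked data over the mask pixels per sample, then resamples
#' the trace to the analysis rate (200 Hz) by linear interpolation.
#'
#' @param ds An `evoked_dataset`.
#' @param cond Condition label or index.
#' @param mask Logical `ys` x `xs` matrix.
#' @param rate_hz Analysis rate; `NULL` keeps the acquisition rate.
#' @return Numeric trace with attributes `time_ms` (relative to stimulus
#'   onset) and `rate_hz`.
#' @export
roi_trace <- function(ds, cond, mask, rate_hz = 200) {
  stopifnot(inherits(ds, "evoked_dataset"))
  idx <- which(as.vector(mask))
  if (!length(idx)) stop("empty ROI mask")
  m <- cond_index(ds, cond)
  tr <- colMeans(ds$data[idx, , m, drop = FALSE])
  t_ms <- (seq_along(tr) - 1) / ds$frame_rate_hz * 1000 -
    ds$prestim_samples / ds$frame_rate_hz * 1000
  if (is.null(rate_hz) || rate_hz == ds$frame_rate_hz) {
    attr(tr, "time_ms") <- t_ms
    attr(tr, "rate_hz") <- ds$frame_rate_hz
    return(tr)
  }
  resample_trace(tr, t_ms, rate_hz)
}

# Condition and mask feeding each activation type for one (location, movie)
# cell: same taxonomy as the parametric analysis.
cell_trace_sources <- function() {
  lapply(characteristic_map(), function(cm) {
    list(location = cm$location, movie = cm$movie,
         direct = cm$direct[1], indirect = cm$indirect[1],
         coherent = cm$coherent[1], incoherent = cm$incoherent[1])
  })
}

#' Per-type median time courses with per-bin significance
#'
#' For every comparison cell (location x movie x experiment), extracts the
#' ROI-mean trace of each activation type from its matching condition (the
#' ROI masks come from the single conditions and are reused for the pair
#' conditions), then aggregates across cells with the per-bin median and a
#' per-bin sign-rank test against zero. Difference traces
#' (coherent - direct, coherent - incoherent) are computed pairwise per
#' cell before aggregation.
#'
#' @param ds An `evoked_dataset` or list of them (multiple experiments).
#' @param rois For each dataset, a list of two `roi_pair`s (movie 1 and
#'   movie 2); a single dataset may pass the inner list directly.
#' @param rate_hz Analysis rate (Hz).
#' @param alpha Per-bin significance level.
#' @return A `type_traces` list: `time_ms`, `median` (4 type traces),
#'   `p` and `sig` per type, and `diff` with the two aggregated
#'   difference traces (`median`, `p`, `sig` each).
#' @export
type_traces <- function(ds, rois, rate_hz = 200, alpha = 0.05) {
  if (inherits(ds, "evoked_dataset")) {
    ds <- list(ds)
    rois <- list(rois)
  }
  types <- c("indirect", "direct", "coherent", "incoherent")
  per_cell <- list()  # each: matrix [n_bins, 4 types]
  for (e in seq_along(ds)) {
    for (src in cell_trace_sources()) {
      roi <- rois[[e]][[src$movie]]
      mask <- if (src$location == "A") roi$mask_A else roi$mask_B
      traces <- lapply(types, function(ty)
        roi_trace(ds[[e]], src[[ty]], mask, rate_hz = rate_hz))
      per_cell[[length(per_cell) + 1L]] <-
        structure(do.call(cbind, traces),
                  time_ms = attr(traces[[1]], "time_ms"))
    }
  }
  time_ms <- attr(per_cell[[1]], "time_ms")
  n_bins <- length(time_ms)
  cube <- array(unlist(per_cell), dim = c(n_bins, 4, length(per_cell)),
                dimnames = list(NULL, types, NULL))
  med <- apply(cube, c(1, 2), stats::median)
  pvals <- apply(cube, c(1, 2), function(v) suppressWarnings(signrank_p(v)))
  diff_of <- function(a, b) {
    d <- cube[, a, , drop = TRUE] - cube[, b, , drop = TRUE]
    d <- matrix(d, nrow = n_bins)
    p <- apply(d, 1, function(v) suppressWarnings(signrank_p(v)))
    list(median = apply(d, 1, stats::median), p = p,
         sig = !is.na(p) & p < alpha)
  }
  structure(list(
    time_ms = time_ms,
    median = lapply(stats::setNames(types, types), function(ty) med[, ty]),
    p = lapply(stats::setNames(types, types), function(ty) pvals[, ty]),
    sig = lapply(stats::setNames(types, types), function(ty)
      !is.na(pvals[, ty]) & pvals[, ty] < alpha),
    diff = list(coh_minus_dir = diff_of("coherent", "direct"),
                coh_minus_incoh = diff_of("coherent", "incoherent")),
    n_cells = length(per_cell), alpha = alpha),
    class = "type_traces")
}

#' Cross-location time-course correlations
#'
#' For each movie, Pearson correlations between the ROI-mean traces at
#' locations A and B over the stimulus window:
#' \describe{
#'   \item{r_single}{between the A trace of the A-alone condition and the B
#'     trace of the B-alone condition (same movie).}
#'   \item{r_coherent}{between the A and B traces within the coherent pair
#'     condition.}
#'   \item{r_incoherent}{between the A and B traces within the incoherent
#'     pair condition containing this movie at location A.}
#' }
#'
#' @param ds An `evoked_dataset`.
#' @param rois List of `roi_pair`s indexed by movie.
#' @param window Correlation window in ms after stimulus onset.
#' @param rate_hz Analysis rate (Hz).
#' @param movies Movie indices to analyze (default both).
#' @return Data frame with columns `movie`, `r_single`, `r_coherent`,
#'   `r_incoherent`.
#' @export
timecourse_correlations <- function(ds, rois, window = c(0, 750),
                                    rate_hz = 200, movies = 1:2) {
  stopifnot(inherits(ds, "evoked_dataset"))
  corr_win <- function(a, b) {
    t_ms <- attr(a, "time_ms")
    sel <- t_ms >= window[1] & t_ms < window[2]
    va <- a[sel]; vb <- b[sel]
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
      warning("zero-variance trace; correlation undefined")
      return(NaN)
    }
    stats::cor(va, vb)
  }
  rows <- lapply(movies, function(m) {
    roi <- rois[[m]]
    single_A <- paste0("A", m); single_B <- paste0("B", m)
    coh <- paste0("A", m, "B", m)
    incoh <- paste0("A", m, "B", 3 - m)
    tr <- function(cond, mask) roi_trace(ds, cond, mask, rate_hz = rate_hz)
    data.frame(
      movie = m,
      r_single = corr_win(tr(single_A, roi$mask_A), tr(single_B, roi$mask_B)),
      r_coherent = corr_win(tr(coh, roi$mask_A), tr(coh, roi$mask_B)),
      r_incoherent = corr_win(tr(incoh, roi$mask_A), tr(incoh, roi$mask_B)))
  })
  do.call(rbind, rows)
}
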