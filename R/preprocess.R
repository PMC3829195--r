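# Two-step delta-F/F preprocessing: divisive prestimulus normalization per
# pixel and trial, then subtraction of the trial-averaged blank signal and
# division by it. Both steps are applied per trial before trial averaging.

stack_frames <- function(stack) {
  if (inherits(stack, "trial_stack")) stack$frames else stack
}

#' Divisive prestimulus normalization
#'
#' Divides every pixel's full time series by that pixel's own mean during
#' the prestimulus interval, separately for each trial. This removes static
#' differences in illumination and staining across pixels; the prestimulus
#' mean of the output is exactly 1 at every pixel.
#'
#' @param stack A `trial_stack` (or bare `[n_px, n_time, n_trials]` array
#'   with `prestim_samples` supplied).
#' @param prestim_samples Number of prestimulus samples (taken from the
#'   stack when available).
#' @return The normalized stack (same class/shape as the input).
#' @export
prestim_normalize <- function(stack, prestim_samples = NULL) {
  fr <- stack_frames(stack)
  if (is.null(prestim_samples)) prestim_samples <- stack$prestim_samples
  if (is.null(prestim_samples) || prestim_samples < 2)
    stop("need at least 2 prestimulus samples")
  pre <- seq_len(prestim_samples)
  out <- fr
  for (k in seq_len(dim(fr)[3L])) {
    m <- rowMeans(fr[, pre, k, drop = FALSE])
    bad <- which(m <= 0)
    if (length(bad))
      stop("degenerate pixels with nonpositive prestimulus mean: ",
           paste(utils::head(bad, 10), collapse = ", "),
           if (length(bad) > 10) " ..." else "")
    out[, , k] <- fr[, , k] / m
  }
  if (inherits(stack, "trial_stack")) {
    stack$frames <- out
    stack
  } else out
}

# Trial-averaged blank: mean over trials of one or several (already
# prestim-normalized) blank stacks, per pixel and sample.
mean_blank_signal <- function(blanks) {
  if (is.matrix(blanks)) return(blanks)  # already trial-averaged
  if (inherits(blanks, "trial_stack") || (is.array(blanks) && length(dim(blanks)) == 3L))
    blanks <- list(blanks)
  mats <- lapply(blanks, function(b) rowMeans(stack_frames(b), dims = 2))
  Reduce(`+`, mats) / length(mats)
}

#' Blank subtraction and blank normalization
#'
#' Converts a prestimulus-normalized stimulus stack into evoked delta-F/F:
#' `(stim - mean_blank) / mean_blank`, per pixel and sample, applied to each
#' trial separately. `mean_blank` is the blank signal averaged over trials
#' (and over both blank conditions when two are supplied). Because the
#' heartbeat-locked artifacts are shared between blank and stimulus trials,
#' this step removes them; dividing by the blank makes the result
#' independent of slow global fluctuations in fluorescence.
#'
#' @param stim A prestimulus-normalized `trial_stack`.
#' @param blank A normalized blank `trial_stack`, or a list of them.
#' @param mode `"per_sample"` (default) divides by the blank at the same
#'   pixel and sample; `"temporal_mean"` divides by the blank's temporal
#'   mean per pixel.
#' @return The evoked stack (same class/shape as `stim`).
#' @export
blank_correct <- function(stim, blank, mode = c("per_sample", "temporal_mean")) {
  mode <- match.arg(mode)
  fr <- stack_frames(stim)
  mb <- mean_blank_signal(blank)
  if (!all(dim(mb) == dim(fr)[1:2]))
    stop("shape mismatch between stimulus and blank stacks")
  if (any(mb <= 0))
    stop("degenerate blank: nonpositive trial-averaged blank signal")
  denom <- if (mode == "per_sample") mb else
    matrix(rowMeans(mb), nrow(mb), ncol(mb))
  out <- fr
  for (k in seq_len(dim(fr)[3L]))
    out[, , k] <- (fr[, , k] - mb) / denom
  if (inherits(stim, "trial_stack")) {
    stim$frames <- out
    stim
  } else out
}

#' Average a stack across trials
#'
#' @param stack A `trial_stack` or `[n_px, n_time, n_trials]` array.
#' @return Numeric matrix `[n_px, n_time]`.
#' @export
average_trials <- function(stack) {
  fr <- stack_frames(stack)
  if (dim(fr)[3L] < 1) stop("need at least one trial")
  rowMeans(fr, dims = 2)
}

#' Run the full preprocessing chain on one experiment
#'
#' Applies [prestim_normalize()], [blank_correct()] (against the mean of the
#' two blank conditions) and [average_trials()] to every condition of a
#' rendered experiment, and assembles the result into an [evoked_dataset()]
#' in the standard `[space, time, condition]` layout.
#'
#' @param stacks Named list of `trial_stack`s (both blank conditions plus
#'   any subset of the stimulus conditions), or the output of
#'   [generate_experiment()].
#' @param blank_mode Passed to [blank_correct()].
#' @return An `evoked_dataset`.
#' @export
preprocess_experiment <- function(stacks, blank_mode = "per_sample") {
  if (!is.null(stacks$stacks)) stacks <- stacks$stacks
  labs <- intersect(cond_labels(), names(stacks))
  if (!all(c("blank1", "blank2") %in% labs))
    stop("missing conditions: both blank conditions are required")
  cfg <- stacks[[1]]$cfg
  blanks <- lapply(stacks[c("blank1", "blank2")], prestim_normalize)
  mb <- mean_blank_signal(blanks)
  n_px <- dim(stack_frames(stacks[[1]]))[1L]
  n_time <- dim(stack_frames(stacks[[1]]))[2L]
  data <- array(0, dim = c(n_px, n_time, length(labs)))
  for (i in seq_along(labs)) {
    st <- if (labs[i] %in% c("blank1", "blank2")) blanks[[labs[i]]]
          else prestim_normalize(stacks[[labs[i]]])
    data[, , i] <- average_trials(blank_correct(st, mb, mode = blank_mode))
  }
  evoked_dataset(data, ys = cfg$ys, xs = cfg$xs,
                 frame_rate_hz = cfg$frame_rate_hz,
                 prestim_samples = cfg$prestim_samples,
                 cond_map = stats::setNames(seq_along(labs), labs))
}

#' Time-averaged spatial activity profile
#'
#' Averages the evoked data of one condition over the samples of an analysis
#' window and reshapes the result into a `ys` x `xs` map. Times are given in
#' ms relative to stimulus onset (sample `prestim_samples + 1` is t = 0);
#' the window is half-open, `[w0, w1)`.
#'
#' @param ds An `evoked_dataset`.
#' @param cond Condition label or index.
#' @param window Numeric `c(start, end)` in ms; default the initial 750 ms
#'   of stimulation.
#' @param window_includes_prestim If `TRUE`, times are measured from trial
#'   onset instead of stimulus onset (alternative reading of an
#'   "initial 750 ms" window).
#' @return An `activity_profile`: a `ys` x `xs` matrix with attributes
#'   `condition` and `window_ms`.
#' @export
time_average <- function(ds, cond, window = c(0, 750),
                         window_includes_prestim = FALSE) {
  stopifnot(inherits(ds, "evoked_dataset"))
  if (length(window) != 2 || window[2] <= window[1])
    stop("argument error: empty analysis window")
  m <- cond_index(ds, cond)
  t_ms <- (seq_len(dim(ds$data)[2L]) - 1) / ds$frame_rate_hz * 1000
  if (!window_includes_prestim)
    t_ms <- t_ms - ds$prestim_samples / ds$frame_rate_hz * 1000
  sel <- which(t_ms >= window[1] & t_ms < window[2])
  if (!length(sel)) stop("argument error: no samples fall in the window")
  v <- rowMeans(ds$data[, sel, m, drop = FALSE])
  structure(matrix(v, ds$ys, ds$xs),
            condition = if (is.character(cond)) cond else names(ds$cond_map)[m],
            window_ms = window, class = c("activity_profile", "matrix", "array"))
}
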