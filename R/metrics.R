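# Characteristic activation types and contextual-interaction metrics.
# Each (location, movie) comparison cell holds four fitted Gaussians:
#   direct    - own spot, own single condition
#   indirect  - own spot when only the distant patch was shown
#   coherent  - own spot in the same-movie pair
#   incoherent- own spot in the mixed-movie pair
# Four cells per experiment (2 locations x 2 movies).

characteristic_map <- function() {
  list(
    list(location = "A", movie = 1, direct = c("A1",   "gA"),
         indirect = c("B1", "gA"), coherent = c("A1B1", "gA"),
         incoherent = c("A1B2", "gA")),
    list(location = "B", movie = 1, direct = c("B1",   "gB"),
         indirect = c("A1", "gB"), coherent = c("A1B1", "gB"),
         incoherent = c("A2B1", "gB")),
    list(location = "A", movie = 2, direct = c("A2",   "gA"),
         indirect = c("B2", "gA"), coherent = c("A2B2", "gA"),
         incoherent = c("A2B1", "gA")),
    list(location = "B", movie = 2, direct = c("B2",   "gB"),
         indirect = c("A2", "gB"), coherent = c("A2B2", "gB"),
         incoherent = c("A1B2", "gB")))
}

#' Derive the four characteristic activation types from condition fits
#'
#' Maps the eight fitted stimulus conditions onto the four comparison cells
#' (location x movie), each holding the direct, indirect, coherent and
#' incoherent parameter sets for that location's spot.
#'
#' @param fits Named list of `two_spot_fit` objects covering the eight
#'   stimulus conditions (as returned by [fit_conditions()]).
#' @return A `characteristic_set`: list of 4 cells, each with fields
#'   `location`, `movie`, `direct`, `indirect`, `coherent`, `incoherent`
#'   (each a `gaussian2d`) and `converged`.
#' @export
build_characteristics <- function(fits) {
  needed <- setdiff(cond_labels(), c("blank1", "blank2"))
  missing <- setdiff(needed, names(fits))
  if (length(missing))
    stop("incomplete condition set; missing fits for: ",
         paste(missing, collapse = ", "))
  cells <- lapply(characteristic_map(), function(cm) {
    types <- c("direct", "indirect", "coherent", "incoherent")
    entry <- list(location = cm$location, movie = cm$movie)
    conv <- TRUE
    for (ty in types) {
      ref <- cm[[ty]]
      f <- fits[[ref[1]]]
      entry[[ty]] <- f[[ref[2]]]
      conv <- conv && isTRUE(f$converged)
    }
    entry$converged <- conv
    entry
  })
  structure(cells, class = "characteristic_set")
}

#' Normalize characteristic parameters by the direct values
#'
#' Divides every type's peak and spread parameters by the corresponding
#' direct-stimulation values, per comparison cell, and reports per-parameter
#' medians across cells (the outlier-robust summary). Cells with a
#' non-positive direct peak are excluded with a warning.
#'
#' @param cs A `characteristic_set` or list of them (multiple experiments).
#' @return List with `table` (long data frame: cell, location, movie, type,
#'   A, sigma_x, sigma_y) and `medians` (data frame of per-type medians).
#' @export
normalize_by_direct <- function(cs) {
  cells <- flatten_cells(cs)
  rows <- list()
  for (i in seq_along(cells)) {
    cell <- cells[[i]]
    dir <- cell$direct
    if (dir$A <= 0) {
      warning(sprintf("cell %d (loc %s, movie %d): direct peak <= 0; excluded",
                      i, cell$location, cell$movie))
      next
    }
    for (ty in c("direct", "indirect", "coherent", "incoherent")) {
      g <- cell[[ty]]
      rows[[length(rows) + 1L]] <- data.frame(
        cell = i, location = cell$location, movie = cell$movie, type = ty,
        A = g$A / dir$A, sigma_x = g$sigma_x / dir$sigma_x,
        sigma_y = g$sigma_y / dir$sigma_y)
    }
  }
  tab <- do.call(rbind, rows)
  meds <- do.call(rbind, lapply(split(tab, tab$type), function(d)
    data.frame(type = d$type[1], A = stats::median(d$A),
               sigma_x = stats::median(d$sigma_x),
               sigma_y = stats::median(d$sigma_y))))
  rownames(meds) <- NULL
  list(table = tab, medians = meds)
}

#' Percent change between a reference and a new value
#'
#' `100 * (x_new - x_ref) / x_ref`. A non-positive reference is undefined
#' and yields `NA` with a warning.
#'
#' @param x_ref Reference value(s), > 0.
#' @param x_new New value(s).
#' @return Percent change (vectorized).
#' @export
percent_change <- function(x_ref, x_new) {
  out <- 100 * (x_new - x_ref) / x_ref
  bad <- x_ref <= 0
  if (any(bad, na.rm = TRUE)) {
    warning("percent change undefined for nonpositive reference; returning NA")
    out[bad] <- NA_real_
  }
  out
}

flatten_cells <- function(cs) {
  if (inherits(cs, "characteristic_set")) return(unclass(cs))
  do.call(c, lapply(cs, unclass))
}

usable_cells <- function(cells) {
  keep <- vapply(cells, function(cell)
    isTRUE(cell$converged) && cell$direct$A > 0 && cell$incoherent$A > 0,
    logical(1))
  dropped <- sum(!keep)
  if (dropped)
    warning(sprintf("%d comparison cell(s) excluded (non-convergence or nonpositive direct/incoherent peak)", dropped))
  cells[keep]
}

aggregate_metric <- function(name, values, n_boot, alpha, seed) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) {
    warning(sprintf("metric %s: fewer than 2 cells; point estimate only", name))
    return(data.frame(metric = name,
                      estimate = if (n) mean(values) else NA_real_,
                      ci_lo = NA_real_, ci_hi = NA_real_, n = n,
                      p_signrank = NA_real_, p_signtest = NA_real_,
                      p_ttest = NA_real_))
  }
  ci <- bootstrap_ci(values, stat = "mean", n_boot = n_boot, alpha = alpha,
                     seed = seed)
  data.frame(metric = name, estimate = ci$point, ci_lo = ci$ci_lo,
             ci_hi = ci$ci_hi, n = n,
             p_signrank = suppressWarnings(signrank_p(values)),
             p_signtest = suppressWarnings(signtest_p(values)),
             p_ttest = tryCatch(paired_t_p(values),
                                error = function(e) NA_real_))
}

#' Facilitation, superadditivity and specificity metrics
#'
#' Per comparison cell, from the fitted peak values:
#' \describe{
#'   \item{total_fac_pct}{`100 (A_coh - A_dir) / A_dir` - total facilitation
#'     of coherent context over direct-only stimulation.}
#'   \item{superadd_pct}{`100 (A_coh - (A_dir + A_ind)) / A_dir` - excess of
#'     the coherent response over the linear sum of direct and indirect.}
#'   \item{linear_pct}{`total - superadd = 100 A_ind / A_dir` - the
#'     linearly-predicted share (holds exactly by construction).}
#'   \item{specificity_pct}{`100 (A_coh - A_incoh) / A_incoh` - advantage of
#'     the coherent over the incoherent context.}
#'   \item{incoh_vs_direct_pct}{`100 (A_incoh - A_dir) / A_dir`.}
#' }
#' Percentages are computed per cell, then averaged across cells; bootstrap
#' CIs and paired tests operate on the per-cell vectors. Cells whose direct
#' fit did not converge or whose direct or incoherent peak is non-positive
#' are dropped pairwise.
#'
#' @param cs A `characteristic_set` or list of them.
#' @param n_boot,alpha Bootstrap repetitions and significance level.
#' @param seed Seed for the bootstrap streams.
#' @return A `context_metrics` data frame (one row per metric) with the
#'   per-cell values attached as attribute `"cells"`.
#' @export
facilitation_metrics <- function(cs, n_boot = 1000, alpha = 0.05, seed = NULL) {
  cells <- usable_cells(flatten_cells(cs))
  if (!length(cells)) stop("no usable comparison cells")
  A <- function(ty) vapply(cells, function(cl) cl[[ty]]$A, numeric(1))
  a_dir <- A("direct"); a_ind <- A("indirect")
  a_coh <- A("coherent"); a_incoh <- A("incoherent")
  vals <- list(
    total_fac_pct = 100 * (a_coh - a_dir) / a_dir,
    superadd_pct = 100 * (a_coh - (a_dir + a_ind)) / a_dir,
    linear_pct = 100 * a_ind / a_dir,
    specificity_pct = 100 * (a_coh - a_incoh) / a_incoh,
    incoh_vs_direct_pct = 100 * (a_incoh - a_dir) / a_dir)
  rows <- mapply(function(nm, v, k)
    aggregate_metric(nm, v, n_boot, alpha,
                     seed = if (is.null(seed)) NULL else child_seed(seed, k)),
    names(vals), vals, seq_along(vals), SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("context_metrics", class(out))
  attr(out, "cells") <- as.data.frame(vals)
  out
}

joint_spread <- function(g, mode = "geometric") {
  if (mode == "geometric") sqrt(g$sigma_x * g$sigma_y)
  else (g$sigma_x + g$sigma_y) / 2
}

#' Spread-change metrics under contextual stimulation
#'
#' Percent changes of the joint spread (geometric mean of `sigma_x` and
#' `sigma_y` by default) and of each axis separately, for the
#' coherent-vs-direct and coherent-vs-incoherent contrasts, aggregated as in
#' [facilitation_metrics()].
#'
#' @param cs A `characteristic_set` or list of them.
#' @param joint_mode `"geometric"` (default) or `"arithmetic"` mean of the
#'   two spread parameters.
#' @param n_boot,alpha,seed As in [facilitation_metrics()].
#' @return A `context_metrics` data frame with per-cell values as attribute
#'   `"cells"`.
#' @export
spread_metrics <- function(cs, joint_mode = c("geometric", "arithmetic"),
                           n_boot = 1000, alpha = 0.05, seed = NULL) {
  joint_mode <- match.arg(joint_mode)
  cells <- usable_cells(flatten_cells(cs))
  if (!length(cells)) stop("no usable comparison cells")
  par_of <- function(ty, f) vapply(cells, function(cl) f(cl[[ty]]), numeric(1))
  pars <- list(joint = function(g) joint_spread(g, joint_mode),
               sigma_x = function(g) g$sigma_x,
               sigma_y = function(g) g$sigma_y)
  vals <- list()
  for (pn in names(pars)) {
    f <- pars[[pn]]
    vals[[paste0("spread_", pn, "_coh_vs_dir_pct")]] <-
      percent_change(par_of("direct", f), par_of("coherent", f))
    vals[[paste0("spread_", pn, "_coh_vs_incoh_pct")]] <-
      percent_change(par_of("incoherent", f), par_of("coherent", f))
  }
  rows <- mapply(function(nm, v, k)
    aggregate_metric(nm, v, n_boot, alpha,
                     seed = if (is.null(seed)) NULL else child_seed(seed, 50 + k)),
    names(vals), vals, seq_along(vals), SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("context_metrics", class(out))
  attr(out, "cells") <- as.data.frame(vals)
  out
}
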