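#' Condition labels of a two-patch contextual experiment
#'
#' Returns the canonical ordering of the ten recorded conditions: two blank
#' (no-stimulus) conditions followed by the eight stimulus conditions built
#' from two aperture locations (A, B) and two source movies (1, 2).
#' The ordering mirrors the layout of the deposited EVO files
#' (1-2 blank, 3 A1B1, 4 A1, 5 B1, 6 A2B2, 7 A2, 8 B2, 9 A1B2, 10 A2B1).
#'
#' @return Character vector of length 10.
#' @export
cond_labels <- function() {
  c("blank1", "blank2", "A1B1", "A1", "B1", "A2B2", "A2", "B2", "A1B2", "A2B1")
}

#' Construct an evoked dataset
#'
#' The canonical in-memory container for trial-averaged evoked delta-F/F
#' data, organized as `[space, time, condition]`. The space dimension is the
#' column-major flattening of a `ys` x `xs` image (antero-posterior rows,
#' medio-lateral columns), matching the deposited EVO layout.
#'
#' @param data Numeric array `[n_space, n_time, n_cond]` in delta-F/F units.
#' @param ys,xs Image dimensions in pixels; `n_space` must equal `ys * xs`.
#' @param frame_rate_hz Acquisition frame rate in Hz.
#' @param prestim_samples Number of samples before stimulus onset.
#' @param cond_map Named integer vector mapping condition label to the index
#'   along the third dimension of `data` (1-based). Defaults to the standard
#'   ten-condition map when `n_cond == 10`.
#' @return An object of class `evoked_dataset`.
#' @export
evoked_dataset <- function(data, ys, xs, frame_rate_hz = 220,
                           prestim_samples = round(0.2 * frame_rate_hz),
                           cond_map = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-dimensional array [space, time, condition]")
  d <- dim(data)
  if (d[1L] != ys * xs)
    stop(sprintf("shape error: n_space (%d) != ys*xs (%d x %d = %d)",
                 d[1L], ys, xs, ys * xs))
  if (is.null(cond_map)) {
    if (d[3L] == 10L) {
      cond_map <- stats::setNames(seq_len(10L), cond_labels())
    } else {
      cond_map <- stats::setNames(seq_len(d[3L]), paste0("cond", seq_len(d[3L])))
    }
  }
  if (length(cond_map) != d[3L] || anyDuplicated(cond_map) ||
      anyDuplicated(names(cond_map)))
    stop("`cond_map` must be a bijection between labels and condition indices")
  structure(list(data = data, ys = as.integer(ys), xs = as.integer(xs),
                 frame_rate_hz = frame_rate_hz,
                 prestim_samples = as.integer(prestim_samples),
                 cond_map = cond_map),
            class = "evoked_dataset")
}

#' @export
print.evoked_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<evoked_dataset> %d px (%d x %d), %d samples @ %g Hz, %d conditions\n",
              d[1], x$ys, x$xs, d[2], x$frame_rate_hz, d[3]))
  cat("  conditions:", paste(names(x$cond_map), collapse = ", "), "\n")
  invisible(x)
}

cond_index <- function(ds, cond) {
  if (is.numeric(cond)) {
    if (cond < 1 || cond > dim(ds$data)[3L]) stop("index error: condition out of range")
    return(as.integer(cond))
  }
  idx <- unname(ds$cond_map[match(cond, names(ds$cond_map))])
  if (is.na(idx)) stop(sprintf("unknown condition label '%s'", cond))
  idx
}

#' Extract one image frame from an evoked dataset
#'
#' Reshapes the space dimension of one (time, condition) column back into a
#' `ys`-row, `xs`-column image. The reshape is column-major, matching the
#' Matlab idiom `reshape(evo.d(:, N, M), evo.ys, evo.xs)` documented for the
#' deposited files.
#'
#' @param ds An `evoked_dataset`.
#' @param t Sample index (1-based).
#' @param cond Condition label or index.
#' @return A `ys` x `xs` numeric matrix.
#' @export
frame_image <- function(ds, t, cond) {
  stopifnot(inherits(ds, "evoked_dataset"))
  if (t < 1 || t > dim(ds$data)[2L]) stop("index error: sample out of range")
  m <- cond_index(ds, cond)
  matrix(ds$data[, t, m], nrow = ds$ys, ncol = ds$xs)
}

#' Flatten an image back to the space-vector convention
#'
#' Inverse of [frame_image()]: column-major flattening of a `ys` x `xs`
#' image into a length `ys*xs` vector.
#'
#' @param img Numeric matrix.
#' @return Numeric vector.
#' @export
flatten_image <- function(img) as.vector(img)

python_bin <- function() {
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p))
    stop("MAT-file I/O requires a python interpreter with scipy on the PATH")
  p
}

run_python <- function(code, args = character()) {
  f <- tempfile(fileext = ".py")
  on.exit(unlink(f))
  writeLines(code, f)
  out <- suppressWarnings(system2(python_bin(), c(f, args),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("python MAT bridge failed:\n", paste(out, collapse = "\n"))
  out
}

#' Read a deposited EVO-format MAT file
#'
#' Loads a MAT-file containing a structure (named `EVO`/`Evo`/`evo`) with
#' fields `d` (evoked data, `[space, time, condition]`), `ys` and `xs`
#' (image dimensions). MAT parsing is delegated to `scipy.io.loadmat`
#' through the system python; the numeric payload is transferred losslessly
#' as little-endian doubles in column-major order.
#'
#' The file itself does not record the acquisition frame rate or the
#' prestimulus sample count, so these are taken from arguments (defaults:
#' 220 Hz, 200 ms prestimulus).
#'
#' @param path Path to a `.mat` file.
#' @param frame_rate_hz Acquisition frame rate in Hz.
#' @param prestim_ms Prestimulus interval in milliseconds.
#' @return An `evoked_dataset` with the standard ten-condition `cond_map`
#'   when the file holds ten conditions.
#' @export
read_evo <- function(path, frame_rate_hz = 220, prestim_ms = 200) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw_out <- tempfile(fileext = ".bin")
  on.exit(unlink(raw_out))
  code <- c(
    "import sys, json",
    "import numpy as np",
    "from scipy.io import loadmat",
    "mat = loadmat(sys.argv[1], squeeze_me=False, struct_as_record=False)",
    "evo = None",
    "for k in ('EVO', 'Evo', 'evo'):",
    "    if k in mat:",
    "        evo = mat[k][0, 0]",
    "        break",
    "if evo is None:",
    "    sys.exit('format error: no EVO structure in file')",
    "for f in ('d', 'ys', 'xs'):",
    "    if not hasattr(evo, f):",
    "        sys.exit('format error: missing field ' + f)",
    "d = np.asarray(evo.d, dtype=np.float64)",
    "if d.ndim == 2:",
    "    d = d[:, :, None]",
    "d.flatten(order='F').tofile(sys.argv[2])",
    "print(json.dumps({'dims': list(d.shape),",
    "                  'ys': int(np.asarray(evo.ys).ravel()[0]),",
    "                  'xs': int(np.asarray(evo.xs).ravel()[0])}))"
  )
  out <- run_python(code, c(path, raw_out))
  meta <- jsonlite::fromJSON(out[length(out)])
  dims <- as.integer(meta$dims)
  vals <- readBin(raw_out, "double", n = prod(dims), endian = "little")
  data <- array(vals, dim = dims)
  evoked_dataset(data, ys = meta$ys, xs = meta$xs,
                 frame_rate_hz = frame_rate_hz,
                 prestim_samples = round(prestim_ms / 1000 * frame_rate_hz))
}

#' Write an evoked dataset to an EVO-format MAT file
#'
#' Inverse of [read_evo()]: stores the data array and grid dimensions in a
#' MAT-file structure named `EVO` with fields `d`, `ys`, `xs`, via
#' `scipy.io.savemat`. Values round-trip bit-exactly.
#'
#' @param ds An `evoked_dataset`.
#' @param path Output `.mat` path.
#' @return `path`, invisibly.
#' @export
write_evo <- function(ds, path) {
  stopifnot(inherits(ds, "evoked_dataset"))
  raw_in <- tempfile(fileext = ".bin")
  on.exit(unlink(raw_in))
  writeBin(as.vector(ds$data), raw_in, endian = "little")
  d <- dim(ds$data)
  code <- c(
    "import sys",
    "import numpy as np",
    "from scipy.io import savemat",
    "dims = [int(x) for x in sys.argv[3:6]]",
    "d = np.fromfile(sys.argv[1], dtype='<f8').reshape(dims, order='F')",
    "savemat(sys.argv[2], {'EVO': {'d': d,",
    "                              'ys': int(sys.argv[6]),",
    "                              'xs': int(sys.argv[7])}})"
  )
  run_python(code, c(raw_in, path, d[1], d[2], d[3], ds$ys, ds$xs))
  invisible(path)
}

#' Write context metrics to CSV with a JSON provenance sidecar
#'
#' Serializes a metrics table (see [facilitation_metrics()],
#' [spread_metrics()]) to a flat CSV with columns
#' `metric, estimate, ci_lo, ci_hi, n, p_signrank, p_signtest, p_ttest`,
#' plus a `<path>.json` sidecar recording the analysis configuration.
#'
#' @param metrics A `context_metrics` data frame (possibly zero rows).
#' @param path Output CSV path.
#' @param provenance Optional named list of configuration values for the
#'   sidecar.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path, provenance = list()) {
  cols <- c("metric", "estimate", "ci_lo", "ci_hi", "n",
            "p_signrank", "p_signtest", "p_ttest")
  df <- as.data.frame(metrics)
  for (cl in setdiff(cols, names(df))) df[[cl]] <- numeric(0)
  utils::write.csv(df[, cols, drop = FALSE], path, row.names = FALSE)
  side <- c(list(written_by = "vsdcontext", n_metrics = nrow(df)), provenance)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a metrics CSV written by [write_metrics()]
#'
#' @param path CSV path.
#' @return A `context_metrics` data frame; the JSON sidecar, if present, is
#'   attached as attribute `"provenance"`.
#' @export
read_metrics <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("context_metrics", class(df))
  side <- paste0(path, ".json")
  if (file.exists(side))
    attr(df, "provenance") <- jsonlite::fromJSON(side)
  df
}
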