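#' @importFrom stats approx median quantile rnorm runif rlnorm rpois sd
#' @importFrom utils head read.csv read.table write.csv
NULL

# ---- error helpers ----------------------------------------------------------

pb_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "pb_error")))
}

pb_assert <- function(cond, msg, class) {
  if (!isTRUE(cond)) pb_stop(msg, class)
}

# Liquid junction potentials (mV) for the internal solutions used in the
# study's whole-cell and perforated-patch recordings.
JUNCTION_POTENTIAL_MV <- c(cesium = 5.9, potassium = 7.0, perforated = 5.1)

CHANNEL_KINDS <- c("vclamp_current", "cclamp_voltage", "loose_seal")
INTERNALS <- c("cesium", "potassium", "perforated", "naCl_loose")

# ---- Recording --------------------------------------------------------------

#' Construct a recording
#'
#' A `pb_recording` is a uniformly sampled single-channel sweep: voltage-clamp
#' current (pA), current-clamp voltage (mV), or a loose-seal cell-attached
#' event trace (arbitrary units), together with its acquisition metadata.
#'
#' @param samples numeric vector of measured values.
#' @param rate_hz sampling rate in Hz (> 0).
#' @param channel_kind one of `"vclamp_current"`, `"cclamp_voltage"`,
#'   `"loose_seal"`.
#' @param t0_s start time of the first sample in seconds.
#' @param holding_mv commanded holding potential (voltage clamp only).
#' @param internal_solution one of `"cesium"`, `"potassium"`, `"perforated"`,
#'   `"naCl_loose"`.
#' @param jp_corrected has the liquid junction potential already been
#'   subtracted?
#' @param units unit string for `samples` (`"pA"`, `"mV"`, or `"au"`).
#' @return an object of class `pb_recording`.
#' @export
recording <- function(samples, rate_hz, channel_kind,
                      t0_s = 0, holding_mv = NULL,
                      internal_solution = NULL, jp_corrected = FALSE,
                      units = NULL) {
  pb_assert(is.numeric(samples) && length(samples) > 0L && all(is.finite(samples)),
            "samples must be a non-empty finite numeric vector", "pb_input_error")
  pb_assert(is.numeric(rate_hz) && length(rate_hz) == 1L && rate_hz > 0,
            "rate_hz must be a single positive number", "pb_input_error")
  channel_kind <- match.arg(channel_kind, CHANNEL_KINDS)
  if (!is.null(internal_solution))
    internal_solution <- match.arg(internal_solution, INTERNALS)
  if (is.null(units))
    units <- switch(channel_kind,
                    vclamp_current = "pA", cclamp_voltage = "mV",
                    loose_seal = "au")
  structure(list(samples = as.numeric(samples),
                 rate_hz = rate_hz,
                 channel_kind = channel_kind,
                 t0_s = t0_s,
                 holding_mv = holding_mv,
                 internal_solution = internal_solution,
                 jp_corrected = isTRUE(jp_corrected),
                 units = units),
            class = "pb_recording")
}

#' @export
print.pb_recording <- function(x, ...) {
  cat(sprintf("<pb_recording> %s, %d samples @ %g kHz (%.3f s), units %s\n",
              x$channel_kind, length(x$samples), x$rate_hz / 1000,
              length(x$samples) / x$rate_hz, x$units))
  if (!is.null(x$holding_mv))
    cat(sprintf("  holding %g mV%s\n", x$holding_mv,
                if (x$jp_corrected) " (JP-corrected)" else ""))
  invisible(x)
}

#' Sample times of a recording
#' @param rec a `pb_recording`.
#' @return numeric vector of times (s), one per sample.
#' @export
rec_times <- function(rec) {
  rec$t0_s + (seq_along(rec$samples) - 1) / rec$rate_hz
}

# ---- StimProtocol -----------------------------------------------------------

#' Construct a stimulus protocol
#'
#' Onset times of brief (default 1 ms) light/electrical pulses plus the
#' stimulation modality and relative intensity.
#'
#' @param pulse_onsets_s strictly increasing pulse onset times (s).
#' @param pulse_width_s pulse duration (s); default 1 ms.
#' @param intensity fraction of maximum source power, in `[0, 1]`.
#' @param modality one of `"full_field_led"`, `"focal_laser"`, `"electrical"`,
#'   `"uncaging"`.
#' @return an object of class `pb_protocol`.
#' @export
stim_protocol <- function(pulse_onsets_s, pulse_width_s = 0.001,
                          intensity = 1,
                          modality = c("full_field_led", "focal_laser",
                                       "electrical", "uncaging")) {
  modality <- match.arg(modality)
  pulse_onsets_s <- as.numeric(pulse_onsets_s)
  pb_assert(length(pulse_onsets_s) == 0L ||
              all(diff(pulse_onsets_s) > 0),
            "pulse onsets must be strictly increasing", "pb_input_error")
  pb_assert(pulse_width_s > 0, "pulse width must be > 0", "pb_input_error")
  pb_assert(intensity >= 0 && intensity <= 1,
            "intensity must be in [0, 1]", "pb_input_error")
  structure(list(pulse_onsets_s = pulse_onsets_s,
                 pulse_width_s = pulse_width_s,
                 intensity = intensity,
                 modality = modality),
            class = "pb_protocol")
}

#' Write / read a stimulus protocol as JSON
#' @param stim a `pb_protocol`.
#' @param path file path.
#' @return `read_protocol` returns a `pb_protocol`; `write_protocol` returns
#'   `path` invisibly.
#' @export
write_protocol <- function(stim, path) {
  jsonlite::write_json(unclass(stim), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  stim_protocol(x$pulse_onsets_s, x$pulse_width_s, x$intensity, x$modality)
}

# ---- recording IO -----------------------------------------------------------

rec_meta_fields <- c("rate_hz", "channel_kind", "t0_s", "holding_mv",
                     "internal_solution", "jp_corrected", "units")

#' Save / load a recording
#'
#' A single recording is stored as a two-column CSV (`t`, `value`, full
#' double precision) plus a JSON metadata sidecar `<path>.meta.json`. A CSV
#' without a sidecar can still be loaded when `channel_kind` (and optionally
#' the other metadata) is supplied explicitly; the sampling rate is then
#' recomputed from the time column, which must be uniform.
#'
#' @param rec a `pb_recording`.
#' @param path CSV file path.
#' @param channel_kind,units,internal_solution,holding_mv metadata overrides
#'   used when no sidecar is present.
#' @return `load_recording` returns a `pb_recording`; `save_recording`
#'   returns `path` invisibly.
#' @export
save_recording <- function(rec, path) {
  pb_assert(inherits(rec, "pb_recording"), "not a pb_recording", "pb_input_error")
  tt <- rec_times(rec)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("t,value", con)
  writeLines(sprintf("%.17g,%.17g", tt, rec$samples), con)
  meta <- rec[rec_meta_fields]
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_recording
#' @export
load_recording <- function(path, channel_kind = NULL, units = NULL,
                           internal_solution = NULL, holding_mv = NULL) {
  pb_assert(file.exists(path), sprintf("no such file: %s", path),
            "pb_format_error")
  df <- read.csv(path)
  pb_assert(all(c("t", "value") %in% names(df)),
            "recording CSV must have columns t,value", "pb_format_error")
  dt <- diff(df$t)
  pb_assert(length(dt) >= 1L && all(dt > 0),
            "time base must be strictly increasing", "pb_format_error")
  pb_assert(max(abs(dt - dt[1])) < 1e-6 * dt[1] + 1e-12,
            "time base must be uniform", "pb_format_error")
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  kind <- channel_kind %||% meta$channel_kind
  pb_assert(!is.null(kind),
            "channel kind not declared (no sidecar and no channel_kind argument)",
            "pb_format_error")
  un <- units %||% meta$units
  if (is.null(un) && is.null(meta$channel_kind))
    pb_stop("units not declared", "pb_format_error")
  recording(df$value,
            rate_hz = meta$rate_hz %||% (1 / dt[1]),
            channel_kind = kind,
            t0_s = meta$t0_s %||% df$t[1],
            holding_mv = holding_mv %||% meta$holding_mv,
            internal_solution = internal_solution %||% meta$internal_solution,
            jp_corrected = meta$jp_corrected %||% FALSE,
            units = un)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load a per-cell container
#'
#' One directory per cell holding `meta.json` (cell id + sweep index) and one
#' CSV per sweep, mirroring a group-per-sweep container layout. The cell is
#' the unit of analysis throughout.
#'
#' @param recs named list of `pb_recording` sweeps.
#' @param dir container directory.
#' @param cell_id identifier stored in the container.
#' @return `load_cell` returns a named list of recordings with attribute
#'   `cell_id`; `save_cell` returns `dir` invisibly.
#' @export
save_cell <- function(recs, dir, cell_id = basename(dir)) {
  pb_assert(length(recs) > 0L && all(vapply(recs, inherits, TRUE, "pb_recording")),
            "recs must be a list of pb_recording", "pb_input_error")
  if (is.null(names(recs)) || anyNA(names(recs)) || any(names(recs) == ""))
    names(recs) <- sprintf("sweep_%03d", seq_along(recs))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(recs))
    save_recording(recs[[nm]], file.path(dir, paste0(nm, ".csv")))
  jsonlite::write_json(list(cell_id = cell_id, sweeps = names(recs)),
                       file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_cell
#' @export
load_cell <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  pb_assert(file.exists(meta_path), "not a cell container (meta.json missing)",
            "pb_format_error")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  recs <- lapply(meta$sweeps, function(nm)
    load_recording(file.path(dir, paste0(nm, ".csv"))))
  names(recs) <- meta$sweeps
  attr(recs, "cell_id") <- meta$cell_id
  recs
}

# ---- junction potential -----------------------------------------------------

#' Correct the liquid junction potential
#'
#' Subtracts the internal-solution-specific liquid junction potential
#' (cesium 5.9 mV, potassium 7 mV, perforated 5.1 mV) from all commanded /
#' measured potentials. Package-wide sign convention: corrected potential =
#' recorded potential - JP, i.e. true membrane potentials are more negative
#' than their nominal values. Current-clamp voltage samples and voltage-clamp
#' holding potentials are shifted; voltage-clamp current samples are not.
#' The correction is applied exactly once per recording.
#'
#' @param rec an uncorrected `pb_recording` with a supported internal
#'   solution.
#' @return the corrected recording (`jp_corrected = TRUE`).
#' @export
correct_junction_potential <- function(rec) {
  pb_assert(inherits(rec, "pb_recording"), "not a pb_recording", "pb_input_error")
  if (rec$channel_kind == "loose_seal")
    pb_stop("junction-potential correction does not apply to loose-seal recordings",
            "pb_unsupported_error")
  if (isTRUE(rec$jp_corrected))
    pb_stop("recording is already junction-potential corrected", "pb_state_error")
  pb_assert(!is.null(rec$internal_solution) &&
              rec$internal_solution %in% names(JUNCTION_POTENTIAL_MV),
            "internal solution has no tabulated junction potential",
            "pb_input_error")
  jp <- JUNCTION_POTENTIAL_MV[[rec$internal_solution]]
  if (rec$channel_kind == "cclamp_voltage")
    rec$samples <- rec$samples - jp
  if (!is.null(rec$holding_mv))
    rec$holding_mv <- rec$holding_mv - jp
  rec$jp_corrected <- TRUE
  rec
}

# ---- epochs -----------------------------------------------------------------

#' Extract stimulus-aligned epochs
#'
#' Cuts one window per pulse out of a recording, sample-aligned to the pulse
#' onset. Epoch time axes have 0 at onset; windows are half-open
#' `[onset - pre_s, onset + post_s)`.
#'
#' @param rec a `pb_recording`.
#' @param stim a `pb_protocol` (or numeric onset times).
#' @param pre_s,post_s window extent before / after each onset (s).
#' @return list of `pb_epoch` objects, each with fields `t` (relative time),
#'   `y` (samples), `onset_s`, `rate_hz`.
#' @export
extract_epochs <- function(rec, stim, pre_s, post_s) {
  pb_assert(inherits(rec, "pb_recording"), "not a pb_recording", "pb_input_error")
  onsets <- if (inherits(stim, "pb_protocol")) stim$pulse_onsets_s else as.numeric(stim)
  pb_assert(pre_s >= 0 && post_s > 0, "pre_s must be >= 0 and post_s > 0",
            "pb_input_error")
  n <- length(rec$samples)
  n_pre <- round(pre_s * rec$rate_hz)
  n_post <- round(post_s * rec$rate_hz)
  lapply(onsets, function(on) {
    i0 <- round((on - rec$t0_s) * rec$rate_hz) + 1
    i_start <- i0 - n_pre
    i_end <- i0 + n_post - 1
    if (i_start < 1 || i_end > n)
      pb_stop(sprintf("epoch window [%g, %g) s outside recording",
                      on - pre_s, on + post_s), "pb_range_error")
    idx <- i_start:i_end
    structure(list(t = (idx - i0) / rec$rate_hz,
                   y = rec$samples[idx],
                   onset_s = on,
                   rate_hz = rec$rate_hz),
              class = "pb_epoch")
  })
}

#' Build an epoch from raw vectors
#'
#' Convenience constructor for tests and simulations: `t` is time relative to
#' the stimulus onset (0 at onset).
#' @param t relative time axis (s), uniform.
#' @param y samples.
#' @param onset_s absolute onset time.
#' @return a `pb_epoch`.
#' @export
epoch <- function(t, y, onset_s = 0) {
  pb_assert(length(t) == length(y) && length(t) > 1,
            "t and y must be equal-length vectors", "pb_input_error")
  structure(list(t = as.numeric(t), y = as.numeric(y), onset_s = onset_s,
                 rate_hz = 1 / (t[2] - t[1])),
            class = "pb_epoch")
}

# ---- morphology -------------------------------------------------------------

#' Read an SWC morphology
#'
#' Standard SWC semantics: columns id, type, x, y, z, radius, parent (-1 for
#' the root). Exactly one root is required and parent links must be acyclic.
#' Coordinates are in micrometres.
#'
#' @param path SWC file path.
#' @return a `pb_morphology`: a data.frame of nodes with precomputed
#'   path distance from the soma root (`path_um`).
#' @export
read_swc <- function(path) {
  pb_assert(file.exists(path), sprintf("no such file: %s", path),
            "pb_format_error")
  df <- read.table(path, comment.char = "#",
                   col.names = c("id", "type", "x", "y", "z", "radius", "parent"))
  morphology(df)
}

#' Construct a morphology from an SWC-style node table
#' @param nodes data.frame with columns id, type, x, y, z, radius, parent.
#' @return a `pb_morphology`.
#' @export
morphology <- function(nodes) {
  req <- c("id", "type", "x", "y", "z", "radius", "parent")
  pb_assert(all(req %in% names(nodes)), "nodes must have SWC columns",
            "pb_format_error")
  pb_assert(sum(nodes$parent == -1) == 1L,
            "morphology must have exactly one root", "pb_format_error")
  idx <- match(nodes$parent, nodes$id)
  pb_assert(all(!is.na(idx) | nodes$parent == -1),
            "parent ids must exist", "pb_format_error")
  # path distance from root via parent traversal; detects cycles
  n <- nrow(nodes)
  path_um <- rep(NA_real_, n)
  path_um[nodes$parent == -1] <- 0
  remaining <- which(is.na(path_um))
  for (pass in seq_len(n)) {
    if (length(remaining) == 0L) break
    ready <- remaining[!is.na(path_um[idx[remaining]])]
    if (length(ready) == 0L)
      pb_stop("parent links contain a cycle", "pb_format_error")
    p <- idx[ready]
    seg <- sqrt((nodes$x[ready] - nodes$x[p])^2 +
                  (nodes$y[ready] - nodes$y[p])^2 +
                  (nodes$z[ready] - nodes$z[p])^2)
    path_um[ready] <- path_um[p] + seg
    remaining <- setdiff(remaining, ready)
  }
  out <- nodes[req]
  out$path_um <- path_um
  structure(out, class = c("pb_morphology", "data.frame"))
}

#' Path distance from the soma to a point on the dendrite
#'
#' Snaps a 3-D point to the nearest dendritic segment (within `tol_um`,
#' default 3 um) and returns the path length along the tree from the soma
#' root to the snapped location - not the Euclidean distance.
#'
#' @param m a `pb_morphology`.
#' @param point numeric length-3 coordinate (um).
#' @param tol_um snap tolerance (um).
#' @return path distance in micrometres.
#' @export
path_distance <- function(m, point, tol_um = 3) {
  pb_assert(inherits(m, "pb_morphology"), "not a pb_morphology", "pb_input_error")
  pb_assert(is.numeric(point) && length(point) == 3L,
            "point must be a length-3 coordinate", "pb_input_error")
  child <- which(m$parent != -1)
  pb_assert(length(child) > 0L, "morphology has no segments", "pb_input_error")
  pidx <- match(m$parent[child], m$id)
  ax <- m$x[pidx]; ay <- m$y[pidx]; az <- m$z[pidx]
  bx <- m$x[child]; by <- m$y[child]; bz <- m$z[child]
  dx <- bx - ax; dy <- by - ay; dz <- bz - az
  len2 <- dx^2 + dy^2 + dz^2
  s <- ((point[1] - ax) * dx + (point[2] - ay) * dy + (point[3] - az) * dz) /
    pmax(len2, .Machine$double.eps)
  s <- pmin(pmax(s, 0), 1)
  qx <- ax + s * dx; qy <- ay + s * dy; qz <- az + s * dz
  d <- sqrt((point[1] - qx)^2 + (point[2] - qy)^2 + (point[3] - qz)^2)
  k <- which.min(d)
  if (d[k] > tol_um)
    pb_stop(sprintf("point is %.2f um from the nearest segment (tolerance %g um)",
                    d[k], tol_um), "pb_registration_error")
  m$path_um[pidx[k]] + s[k] * sqrt(len2[k])
}

# ---- tabular source data ----------------------------------------------------

#' Read a long-format per-cell source-data table
#'
#' Expects a UTF-8 CSV with header `figure_panel,cell_id,condition,value`,
#' one row per cell and condition; the (panel, cell, condition) triple must
#' be unique and values numeric.
#'
#' @param path CSV file path.
#' @return a data.frame of class `pb_source_data`.
#' @export
read_source_data <- function(path) {
  pb_assert(file.exists(path), sprintf("no such file: %s", path),
            "pb_format_error")
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("figure_panel", "cell_id", "condition", "value")
  pb_assert(all(req %in% names(df)),
            "source data must have columns figure_panel,cell_id,condition,value",
            "pb_format_error")
  pb_assert(is.numeric(df$value) && all(is.finite(df$value)),
            "source-data values must be numeric", "pb_format_error")
  key <- paste(df$figure_panel, df$cell_id, df$condition, sep = "\r")
  pb_assert(!anyDuplicated(key),
            "(panel, cell, condition) rows must be unique", "pb_format_error")
  structure(df[req], class = c("pb_source_data", "data.frame"))
}
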