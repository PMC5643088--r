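# Line-scan calcium imaging: background subtraction, dF/F0 normalization,
# transient area.

#' Construct a line-scan object
#'
#' Lines are acquired repeatedly along a short stretch of dendrite (the
#' study geometry: 512 pixels per line, 6 ms per line). Structure and
#' background pixel ranges are user-supplied; `shutter_lines` marks lines
#' during which the detector was gated off (e.g. while a stimulation laser
#' fired).
#'
#' @param frames numeric matrix, lines x pixels.
#' @param line_period_s time per line (s), default 0.006.
#' @param structure_px integer vector of pixel columns on the dendrite.
#' @param background_px pixel columns off-structure; must be disjoint from
#'   `structure_px`.
#' @param shutter_lines integer vector of gated-off line indices (optional).
#' @param t0_s time of the first line.
#' @return an object of class `pb_linescan`.
#' @export
linescan <- function(frames, line_period_s = 0.006,
                     structure_px, background_px,
                     shutter_lines = integer(0), t0_s = 0) {
  pb_assert(is.matrix(frames) && is.numeric(frames),
            "frames must be a numeric matrix (lines x pixels)", "pb_input_error")
  pb_assert(line_period_s > 0, "line period must be > 0", "pb_input_error")
  pb_assert(length(intersect(structure_px, background_px)) == 0L,
            "structure and background pixel ranges must be disjoint",
            "pb_input_error")
  pb_assert(all(structure_px >= 1 & structure_px <= ncol(frames)) &&
              all(background_px >= 1 & background_px <= ncol(frames)),
            "pixel ranges outside image", "pb_input_error")
  structure(list(frames = frames, line_period_s = line_period_s,
                 structure_px = as.integer(structure_px),
                 background_px = as.integer(background_px),
                 shutter_lines = as.integer(shutter_lines),
                 t0_s = t0_s),
            class = "pb_linescan")
}

#' Compute the background-subtracted dF/F0 time series
#'
#' Per line: F = mean over structure pixels, F_bg = mean over background
#' pixels, F_s = F - F_bg. Shutter-gated lines are replaced by linear
#' interpolation of F_s and flagged; they are excluded from the F0 window.
#' F0 is the mean of F_s over `f0_window_s` (which must precede the
#' stimulus) and dF/F0 = (F_s - F0) / F0.
#'
#' @param scan a `pb_linescan`.
#' @param f0_window_s closed baseline window `[t1, t2]` in seconds.
#' @return list of class `pb_dff`: `t`, `dff`, `f0`, `interpolated`
#'   (logical per line), `line_period_s`.
#' @export
compute_dff <- function(scan, f0_window_s) {
  pb_assert(inherits(scan, "pb_linescan"), "not a pb_linescan", "pb_input_error")
  fr <- scan$frames
  n <- nrow(fr)
  t <- scan$t0_s + (seq_len(n) - 1) * scan$line_period_s
  f <- rowMeans(fr[, scan$structure_px, drop = FALSE])
  fbg <- rowMeans(fr[, scan$background_px, drop = FALSE])
  fs <- f - fbg
  masked <- seq_len(n) %in% scan$shutter_lines
  if (any(masked)) {
    pb_assert(!all(masked), "every line is shutter-masked", "pb_input_error")
    fs[masked] <- approx(t[!masked], fs[!masked], xout = t[masked],
                         rule = 2)$y
  }
  f0_sel <- t >= f0_window_s[1] & t <= f0_window_s[2] & !masked
  pb_assert(any(f0_sel), "F0 window contains no usable lines", "pb_range_error")
  f0 <- mean(fs[f0_sel])
  if (f0 <= 0)
    pb_stop("baseline fluorescence F0 <= 0", "pb_normalization_error")
  structure(list(t = t, dff = (fs - f0) / f0, f0 = f0,
                 interpolated = masked,
                 line_period_s = scan$line_period_s),
            class = "pb_dff")
}

#' Area under a calcium transient
#'
#' Signed trapezoidal integral of dF/F0 over a closed time window, in
#' dF/F0 * s. When the window contains interpolated (shutter-gated) lines
#' the result carries attribute `interpolated = TRUE`.
#'
#' @param dff a `pb_dff`.
#' @param window_s closed integration window `[t1, t2]`.
#' @return area (numeric scalar) with attribute `interpolated`.
#' @export
transient_area <- function(dff, window_s) {
  pb_assert(inherits(dff, "pb_dff"), "not a pb_dff", "pb_input_error")
  pb_assert(window_s[1] < window_s[2], "bad window", "pb_input_error")
  eps <- dff$line_period_s / 2
  if (window_s[1] < dff$t[1] - eps ||
      window_s[2] > dff$t[length(dff$t)] + eps)
    pb_stop("integration window outside trace", "pb_range_error")
  sel <- dff$t >= window_s[1] - eps & dff$t <= window_s[2] + eps
  area <- pracma::trapz(dff$t[sel], dff$dff[sel])
  attr(area, "interpolated") <- any(dff$interpolated[sel])
  area
}
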