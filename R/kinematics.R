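# Joint-angle / marker time-series processing: zero-phase Butterworth
# smoothing, side-mirroring of recorded series, and the bilateral symmetry
# verification report (per-DOF RMSE between the two sides).

#' Butterworth filter specification
#'
#' @param cutoff low-pass cutoff (Hz), default 6.
#' @param order total (dual-pass) filter order; must be even, default 4. The
#'   per-pass design order is `order/2`, so after the forward-backward pass
#'   the gain at the cutoff frequency is exactly
#'   `|H(fc)|^2 = (1/sqrt(2))^2 = 0.5` (the raw cutoff is passed to the
#'   design; no dual-pass compensation is applied).
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(cutoff = 6, order = 4) {
  if (order %% 2 != 0 || order < 2)
    stop("filter order must be a positive even integer", call. = FALSE)
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  structure(list(cutoff = cutoff, order = order), class = "filter_spec")
}

#' Zero-phase low-pass filter a motion table
#'
#' Column-wise dual-pass (forward-backward) Butterworth low-pass; the time
#' column is untouched. Sampling must be uniform and the cutoff below the
#' Nyquist frequency.
#'
#' @param series a [motion_table()].
#' @param spec a [filter_spec()].
#' @return the filtered [motion_table()].
#' @export
butterworth_lowpass <- function(series, spec = filter_spec()) {
  stopifnot(inherits(series, "motion_table"), inherits(spec, "filter_spec"))
  dt <- diff(series$time)
  if (max(dt) - min(dt) > 1e-6 * mean(dt))
    stop("sampling must be uniform for filtering", call. = FALSE)
  fs <- 1 / mean(dt)
  if (spec$cutoff >= fs / 2)
    stop("cutoff ", spec$cutoff, " Hz is not below the Nyquist frequency ",
         fs / 2, " Hz", call. = FALSE)
  if (length(series$time) < 3 * spec$order)
    stop("series too short to filter (need >= 3 x order samples)", call. = FALSE)
  Wn <- spec$cutoff / (fs / 2)
  bf <- signal::butter(spec$order / 2, Wn, type = "low")
  out <- series$values
  for (k in seq_len(ncol(out))) {
    out[, k] <- zero_phase_filter(bf, series$values[, k], Wn)
  }
  motion_table(series$time, out, in_degrees = series$in_degrees,
               name = series$name)
}

# forward-backward filtering with odd-reflection end padding and endpoint
# offset removal, so edge transients decay inside the pads and the DC gain
# is exactly 1 (a constant column passes through bit-unchanged up to the
# filter's linear arithmetic)
zero_phase_filter <- function(bf, x, Wn) {
  n <- length(x)
  npad <- min(n - 1, ceiling(9 / Wn))
  x0 <- x[1]
  pre <- 2 * x0 - x[(npad + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - npad)]
  xp <- c(pre, x, post) - x0
  yp <- signal::filtfilt(bf, xp)
  yp[(npad + 1):(npad + n)] + x0
}

#' Mirror marker trajectories across a lab plane
#'
#' Negates the stated lab-frame component of every marker (columns named
#' `<marker>_<axis>`), leaving the other components unchanged — the standard
#' single-sided motion-capture workaround for obtaining contralateral marker
#' locations.
#'
#' @param markers a [motion_table()] of `_x/_y/_z` marker columns (e.g. from
#'   [read_trc()]).
#' @param lab_axis `"x"`, `"y"` or `"z"` — the lab axis normal to the mirror
#'   plane (default `"x"`).
#' @return the mirrored [motion_table()].
#' @export
mirror_markers <- function(markers, lab_axis = c("x", "y", "z")) {
  lab_axis <- match.arg(lab_axis)
  vals <- markers$values
  hit <- endsWith(colnames(vals), paste0("_", lab_axis))
  if (!any(hit)) stop("no '_", lab_axis, "' marker columns found", call. = FALSE)
  vals[, hit] <- -vals[, hit]
  motion_table(markers$time, vals, in_degrees = markers$in_degrees,
               name = markers$name)
}

#' Mirror a joint-angle table to the contralateral side
#'
#' Columns are renamed via the convention's side map and scaled by a
#' per-coordinate sign. The default sign is +1 for every coordinate because
#' bilateral models built by [build_bilateral()] absorb the reflection's sign
#' flip into the mirrored rotation-axis vectors, so identical coordinate
#' values already describe mirror-symmetric postures. Supply `sign_map` (a
#' named vector of +/-1) for models that instead keep the original axes and
#' flip axial-rotation/deviation coordinate signs.
#'
#' @param table a [motion_table()] of coordinate columns.
#' @param sign_map optional named numeric vector of +/-1 per column.
#' @param convention a [mirror_convention()] supplying the name map.
#' @return the mirrored [motion_table()].
#' @export
mirror_joint_angles <- function(table, sign_map = NULL,
                                convention = mirror_convention()) {
  vals <- table$values
  for (nm in names(sign_map)) {
    if (nm %in% colnames(vals)) vals[, nm] <- sign_map[[nm]] * vals[, nm]
  }
  colnames(vals) <- map_side_name(colnames(vals), convention)
  motion_table(table$time, vals, in_degrees = table$in_degrees,
               name = table$name)
}

#' Root mean squared error between two series
#'
#' @param a,b numeric vectors of equal length.
#' @return `sqrt(mean((a - b)^2))`, in the units of the inputs.
#' @export
rmse <- function(a, b) {
  if (length(a) != length(b))
    stop("series lengths differ (", length(a), " vs ", length(b), ")",
         call. = FALSE)
  sqrt(mean((a - b)^2))
}

#' Verify bilateral kinematic symmetry
#'
#' Pairs each right-side coordinate column with its contralateral twin and
#' reports the per-DOF RMSE between the two sides, flagging the report
#' `pass` when every RMSE is below `threshold` (default 1.5 deg, the
#' verification envelope for a well-mirrored model).
#'
#' @param model a bilateral [model_def()] (supplies the coordinate list).
#' @param left_kin,right_kin [motion_table()]s of coordinate columns for the
#'   two sides (degrees).
#' @param convention a [mirror_convention()].
#' @param threshold pass threshold in the tables' units, default 1.5.
#' @return a data frame with columns `coordinate_right`, `coordinate_left`,
#'   `rmse` and `pass`, with an overall `pass` attribute.
#' @export
verify_bilateral_symmetry <- function(model, left_kin, right_kin,
                                      convention = mirror_convention(),
                                      threshold = 1.5) {
  rcols <- colnames(right_kin$values)
  rcols <- rcols[is_sided_name(rcols, convention)]
  lcols <- map_side_name(rcols, convention)
  model_coords <- names(model_coordinates(model))
  keep <- rcols %in% model_coords
  rcols <- rcols[keep]; lcols <- lcols[keep]
  if (length(rcols) == 0)
    stop("no sided model coordinates found in right_kin", call. = FALSE)
  missing_l <- setdiff(lcols, colnames(left_kin$values))
  if (length(missing_l) > 0)
    stop("left_kin is missing column(s): ", paste(missing_l, collapse = ", "),
         call. = FALSE)
  if (length(left_kin$time) != length(right_kin$time))
    stop("left and right tables have different lengths", call. = FALSE)
  err <- vapply(seq_along(rcols), function(i)
    rmse(right_kin$values[, rcols[i]], left_kin$values[, lcols[i]]), 0)
  out <- data.frame(coordinate_right = rcols, coordinate_left = lcols,
                    rmse = err, pass = err < threshold,
                    stringsAsFactors = FALSE)
  attr(out, "pass") <- all(out$pass)
  out
}
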