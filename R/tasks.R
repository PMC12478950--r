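# The bimanual task battery as coordinate time profiles: two static box
# holds (waist height and above eye height), a minimum-jerk forward reach,
# and the two kinematic verification tasks. Profiles are defined per base
# coordinate name and expanded to both side suffixes when rendered to a
# motion table.

default_task_coords <- function() {
  list(elevation_angle = "elv_angle", shoulder_elevation = "shoulder_elv",
       shoulder_rotation = "shoulder_rot", elbow_flexion = "elbow_flexion",
       wrist = c("wrist_flex", "pro_sup"))
}

#' Construct a task definition
#'
#' @param name task name.
#' @param targets named list, base coordinate name to either a constant (deg)
#'   or a function of time returning degrees.
#' @param duration task duration (s), default 7.
#' @param rate sampling rate (Hz), default 100.
#' @param locked named numeric of locked coordinates held constant (deg),
#'   default wrist flexion and pronation/supination at 0.
#' @return an object of class `task_definition`.
#' @export
task_definition <- function(name, targets, duration = 7, rate = 100,
                            locked = c(wrist_flex = 0, pro_sup = 0)) {
  stopifnot(duration > 0, rate > 0, length(targets) > 0)
  structure(list(name = name, targets = targets, duration = duration,
                 rate = rate, locked = locked),
            class = "task_definition")
}

#' @export
print.task_definition <- function(x, ...) {
  cat("<task_definition> ", x$name, ": ", x$duration, " s @ ", x$rate,
      " Hz; coordinates: ", paste(names(x$targets), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

eval_profile <- function(target, t) {
  if (is.function(target)) vapply(t, target, 0) else rep(target, length(t))
}

# minimum-jerk 0 -> 1 -> 0 profile over [0, duration], peak at duration/2
minjerk_out_back <- function(duration) {
  half <- duration / 2
  function(t) {
    tau <- if (t <= half) t / half else (duration - t) / half
    tau <- min(max(tau, 0), 1)
    10 * tau^3 - 15 * tau^4 + 6 * tau^5
  }
}

#' Static box-hold tasks
#'
#' `low`: shoulder elevation 80 deg with elevation angle 80 deg (box held
#' with extended arms in front of the body at waist height). `high`:
#' shoulder elevation 130 deg, elevation angle 80 deg (extended arms above
#' eye height). Elbows extended (0 deg), wrists locked at 0 deg, both sides
#' identical.
#'
#' @param kind `"low"` or `"high"`.
#' @param duration,rate see [task_definition()].
#' @param coords base coordinate names, see `default_task_coords()`.
#' @return a [task_definition()].
#' @export
make_static_task <- function(kind = c("low", "high"), duration = 7, rate = 100,
                             coords = default_task_coords()) {
  kind <- match.arg(kind)
  elv <- if (kind == "low") 80 else 130
  targets <- stats::setNames(
    list(80, elv, 0, 0),
    c(coords$elevation_angle, coords$shoulder_elevation,
      coords$shoulder_rotation, coords$elbow_flexion))
  task_definition(paste0(kind, "_static"), targets, duration, rate,
                  locked = stats::setNames(rep(0, length(coords$wrist)),
                                           coords$wrist))
}

#' Dynamic forward-reach task
#'
#' Starts with the arms by the side at `start_elbow_flexion` (default
#' 90 deg), reaches forward in the sagittal plane following a minimum-jerk
#' out-and-back elevation profile peaking at `peak_elevation_angle`
#' (default 75 deg) at mid-duration, with the elbow extending linearly with
#' the elevation fraction toward `peak_elbow_flexion`, and returns to the
#' start pose. Both sides are mirror-symmetric.
#'
#' @param peak_elevation_angle peak shoulder elevation (deg), default 75.
#' @param start_elbow_flexion elbow flexion at rest (deg), default 90.
#' @param peak_elbow_flexion elbow flexion at peak reach (deg), default 20.
#' @param duration,rate see [task_definition()].
#' @param coords base coordinate names.
#' @param model optional [model_def()]; when given, the peak is checked
#'   against the elevation coordinate's range.
#' @return a [task_definition()].
#' @export
make_dynamic_reach <- function(peak_elevation_angle = 75,
                               start_elbow_flexion = 90,
                               peak_elbow_flexion = 20,
                               duration = 7, rate = 100,
                               coords = default_task_coords(), model = NULL) {
  if (!is.null(model)) {
    cn <- paste0(coords$shoulder_elevation, "_r")
    co <- model_coordinates(model)[[cn]]
    if (!is.null(co) &&
        (peak_elevation_angle * pi / 180 > co$range[2] + 1e-9 ||
         peak_elevation_angle * pi / 180 < co$range[1] - 1e-9))
      stop("peak elevation ", peak_elevation_angle,
           " deg is outside the range of '", cn, "'", call. = FALSE)
  }
  s <- minjerk_out_back(duration)
  targets <- stats::setNames(
    list(0,
         function(t) peak_elevation_angle * s(t),
         0,
         function(t) start_elbow_flexion -
           (start_elbow_flexion - peak_elbow_flexion) * s(t)),
    c(coords$elevation_angle, coords$shoulder_elevation,
      coords$shoulder_rotation, coords$elbow_flexion))
  task_definition("forward_reach", targets, duration, rate,
                  locked = stats::setNames(rep(0, length(coords$wrist)),
                                           coords$wrist))
}

#' Kinematic verification tasks
#'
#' The two 7 s symmetry-verification motions: a static hold with the arm by
#' the side (0 deg shoulder elevation, 0 deg elbow flexion, palm toward the
#' midline at -25 deg shoulder rotation) and a dynamic elevation with the
#' palm away from the midline (-45 deg shoulder rotation) raising shoulder
#' elevation from 0 to 90 deg and back. Wrists locked at 0 deg.
#'
#' @param duration,rate see [task_definition()].
#' @param coords base coordinate names.
#' @return list with elements `static` and `dynamic`, each a
#'   [task_definition()].
#' @export
make_verification_tasks <- function(duration = 7, rate = 100,
                                    coords = default_task_coords()) {
  locked <- stats::setNames(rep(0, length(coords$wrist)), coords$wrist)
  static <- task_definition(
    "verification_static",
    stats::setNames(list(0, 0, -25, 0),
                    c(coords$elevation_angle, coords$shoulder_elevation,
                      coords$shoulder_rotation, coords$elbow_flexion)),
    duration, rate, locked)
  s <- minjerk_out_back(duration)
  dynamic <- task_definition(
    "verification_dynamic",
    stats::setNames(list(0, function(t) 90 * s(t), -45, 0),
                    c(coords$elevation_angle, coords$shoulder_elevation,
                      coords$shoulder_rotation, coords$elbow_flexion)),
    duration, rate, locked)
  list(static = static, dynamic = dynamic)
}

#' Render a task to a bilateral motion table
#'
#' Evaluates every target profile on the task's time grid and emits one
#' column per side (suffixes from the convention), in degrees. When a model
#' is supplied, columns are checked to exist and stay within their
#' coordinate ranges.
#'
#' @param task a [task_definition()].
#' @param model optional [model_def()] for range validation.
#' @param sides character vector of side suffixes, default both.
#' @param convention a [mirror_convention()].
#' @return a [motion_table()] (degrees).
#' @export
task_to_motion <- function(task, model = NULL, sides = NULL,
                           convention = mirror_convention()) {
  if (is.null(sides)) sides <- convention$suffix_pairs[[1]]
  t <- seq(0, task$duration, by = 1 / task$rate)
  all_targets <- c(task$targets, as.list(task$locked))
  cols <- as.vector(t(outer(names(all_targets), sides, paste0)))
  vals <- matrix(0, length(t), length(cols), dimnames = list(NULL, cols))
  for (base in names(all_targets)) {
    prof <- eval_profile(all_targets[[base]], t)
    for (sd in sides) vals[, paste0(base, sd)] <- prof
  }
  if (!is.null(model)) {
    coords <- model_coordinates(model)
    for (cn in cols) {
      co <- coords[[cn]]
      if (is.null(co))
        stop("task targets coordinate '", cn, "' absent from model",
             call. = FALSE)
      v <- vals[, cn] * if (co$kind == "rotational") pi / 180 else 1
      if (min(v) < co$range[1] - 1e-9 || max(v) > co$range[2] + 1e-9)
        stop("task '", task$name, "' drives '", cn, "' outside its range",
             call. = FALSE)
    }
  }
  motion_table(t, vals, in_degrees = TRUE, name = task$name)
}
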