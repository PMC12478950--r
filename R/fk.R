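# Forward kinematics over the body tree, musculotendon path lengths, and
# tendon-excursion moment arms (r = -dL/dq by central finite differences).
#
# Joint transform convention (parent -> child), matching what the writer
# emits: X = T(location_in_parent) R_euler(orientation_in_parent)
#            R(axis1,q1) R(axis2,q2) R(axis3,q3) T(sum_i trans_axis_i q_i).

#' Complete a pose vector with model defaults
#'
#' @param model a [model_def()].
#' @param q named numeric vector of coordinate values (rad or m); missing
#'   coordinates take their defaults, locked coordinates are forced to their
#'   defaults.
#' @return full named pose vector over every model coordinate.
#' @export
full_pose <- function(model, q = NULL) {
  pose <- default_pose(model)
  if (!is.null(q) && length(q) > 0) {
    unknown <- setdiff(names(q), names(pose))
    if (length(unknown) > 0)
      stop("unknown coordinate(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    coords <- model_coordinates(model)
    for (nm in names(q)) {
      if (!coords[[nm]]$locked) pose[nm] <- q[[nm]]
    }
  }
  pose
}

joint_transform <- function(j, pose) {
  X <- hom_transform(p = j$location_in_parent) %*%
    hom_transform(R = euler_xyz_to_matrix(j$orientation_in_parent))
  if (j$type == "CustomJoint") {
    tr <- c(0, 0, 0)
    for (ax in j$spatial_transform) {
      qv <- if (is.na(ax$coordinate)) 0 else pose[[ax$coordinate]]
      if (startsWith(ax$name, "rotation")) {
        if (qv != 0) X <- X %*% hom_transform(R = rot_axis_angle(ax$axis, qv))
      } else {
        tr <- tr + ax$axis * qv
      }
    }
    if (any(tr != 0)) X <- X %*% hom_transform(p = tr)
  }
  X
}

#' Ground-frame transforms of every body at a pose
#'
#' @param model a [model_def()].
#' @param q pose as for [full_pose()].
#' @return named list of 4x4 homogeneous transforms (body frame -> ground),
#'   including `"ground"` (identity).
#' @export
body_transforms <- function(model, q = NULL) {
  pose <- full_pose(model, q)
  X <- list(ground = diag(4))
  joints_by_child <- stats::setNames(model$joints,
                                     vapply(model$joints, `[[`, "", "child"))
  pending <- names(model$bodies)
  while (length(pending) > 0) {
    progressed <- FALSE
    rest <- character(0)
    for (b in pending) {
      j <- joints_by_child[[b]]
      if (is.null(j))
        stop("body '", b, "' has no joint connecting it to the tree",
             call. = FALSE)
      if (!is.null(X[[j$parent]])) {
        X[[b]] <- X[[j$parent]] %*% joint_transform(j, pose)
        progressed <- TRUE
      } else {
        rest <- c(rest, b)
      }
    }
    if (!progressed)
      stop("body tree does not reach ground (cycle or orphan: ",
           paste(rest, collapse = ", "), ")", call. = FALSE)
    pending <- rest
  }
  X
}

#' Ground-frame location of a body-fixed point
#' @param transforms output of [body_transforms()].
#' @param body body name (or `"ground"`).
#' @param location length-3 point in the body frame (m).
#' @return length-3 ground-frame point (m).
#' @export
point_in_ground <- function(transforms, body, location) {
  X <- transforms[[body]]
  if (is.null(X)) stop("no transform for body '", body, "'", call. = FALSE)
  transform_point(X, location)
}

#' Musculotendon path lengths at a pose
#'
#' Straight-line polyline length of each muscle's path points placed in the
#' ground frame.
#'
#' @param model a [model_def()].
#' @param q pose as for [full_pose()].
#' @param transforms optional precomputed [body_transforms()].
#' @return named numeric vector of lengths (m).
#' @export
muscle_lengths <- function(model, q = NULL, transforms = NULL) {
  if (is.null(transforms)) transforms <- body_transforms(model, q)
  vapply(model$muscles, function(mu) {
    pts <- vapply(mu$path, function(p)
      point_in_ground(transforms, p$body, p$location), numeric(3))
    sum(sqrt(rowSums(diff(t(pts))^2)))
  }, 0)
}

#' Tendon-excursion moment arms
#'
#' Moment arm of every muscle about every (free) coordinate,
#' `r = -dL/dq`, by central finite differences with step `h`.
#'
#' @param model a [model_def()].
#' @param q pose as for [full_pose()].
#' @param coords coordinates to differentiate against (default: all unlocked).
#' @param h finite-difference step (rad or m), default `1e-5`.
#' @return matrix `[muscle, coordinate]` of moment arms (m).
#' @export
moment_arms <- function(model, q = NULL, coords = free_coordinates(model),
                        h = 1e-5) {
  pose <- full_pose(model, q)
  r <- matrix(0, length(model$muscles), length(coords),
              dimnames = list(names(model$muscles), coords))
  for (k in seq_along(coords)) {
    qp <- pose; qp[coords[k]] <- qp[coords[k]] + h
    qm <- pose; qm[coords[k]] <- qm[coords[k]] - h
    r[, k] <- -(muscle_lengths(model, qp) - muscle_lengths(model, qm)) / (2 * h)
  }
  r
}

# positions (ground) of each body's COM: named matrix [body, 3]
body_com_positions <- function(model, transforms) {
  t(vapply(model$bodies, function(b)
    point_in_ground(transforms, b$name, b$com), numeric(3)))
}

# Jacobian of a set of body-fixed stations w.r.t. coords, by central FD.
# stations: list of list(body=, location=). Returns array [3, nstation, ncoord].
station_jacobian <- function(model, q, stations,
                             coords = free_coordinates(model), h = 1e-5) {
  pose <- full_pose(model, q)
  J <- array(0, c(3, length(stations), length(coords)),
             dimnames = list(NULL, NULL, coords))
  for (k in seq_along(coords)) {
    qp <- pose; qp[coords[k]] <- qp[coords[k]] + h
    qm <- pose; qm[coords[k]] <- qm[coords[k]] - h
    Xp <- body_transforms(model, qp)
    Xm <- body_transforms(model, qm)
    for (s in seq_along(stations)) {
      st <- stations[[s]]
      J[, s, k] <- (point_in_ground(Xp, st$body, st$location) -
                    point_in_ground(Xm, st$body, st$location)) / (2 * h)
    }
  }
  J
}

# Angular-velocity Jacobian of bodies w.r.t. coords: array [3, nbody, ncoord];
# column k is the ground-frame rotation vector of body per unit coordinate k.
rotation_jacobian <- function(model, q, bodies,
                              coords = free_coordinates(model), h = 1e-5) {
  pose <- full_pose(model, q)
  X0 <- body_transforms(model, pose)
  J <- array(0, c(3, length(bodies), length(coords)),
             dimnames = list(NULL, bodies, coords))
  for (k in seq_along(coords)) {
    qp <- pose; qp[coords[k]] <- qp[coords[k]] + h
    qm <- pose; qm[coords[k]] <- qm[coords[k]] - h
    Xp <- body_transforms(model, qp)
    Xm <- body_transforms(model, qm)
    for (b in seq_along(bodies)) {
      R0 <- X0[[bodies[b]]][1:3, 1:3]
      dR <- (Xp[[bodies[b]]][1:3, 1:3] - Xm[[bodies[b]]][1:3, 1:3]) / (2 * h)
      J[, b, k] <- small_rotation_vector(dR %*% t(R0))
    }
  }
  J
}
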