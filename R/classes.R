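# S3 record types for the model container and its components. All are plain
# lists with a class attribute; constructors validate their own invariants and
# validate_model() checks the cross-reference invariants of an assembled model.

#' Construct a body definition
#'
#' A rigid segment of the model: mass properties, a center-of-mass location in
#' the body frame, and references to display meshes.
#'
#' @param name body name (unique within a model).
#' @param mass mass in kg, non-negative.
#' @param com center of mass in the body frame (m), length-3.
#' @param inertia length-6 numeric `(Ixx, Iyy, Izz, Ixy, Ixz, Iyz)` in kg m^2;
#'   must be symmetric positive semidefinite.
#' @param mesh_refs list of `list(file =, scale =)` display-mesh references.
#' @param extra character vector of opaque XML fragments carried for
#'   round-trip fidelity.
#' @return an object of class `body_def`.
#' @export
body_def <- function(name, mass, com, inertia = c(0.01, 0.01, 0.01, 0, 0, 0),
                     mesh_refs = list(), extra = character()) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (!is.numeric(mass) || length(mass) != 1 || !is.finite(mass) || mass < 0)
    stop("body '", name, "': mass must be a single non-negative number", call. = FALSE)
  stopifnot(length(com) == 3, all(is.finite(com)), length(inertia) == 6)
  ev <- eigen(inertia_to_matrix(inertia), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-9 * max(abs(ev), 1))
    stop("body '", name, "': inertia is not positive semidefinite", call. = FALSE)
  structure(list(name = name, mass = mass, com = as.numeric(com),
                 inertia = as.numeric(inertia), mesh_refs = mesh_refs,
                 extra = extra),
            class = "body_def")
}

#' Construct a coordinate definition
#'
#' @param name coordinate name (unique model-wide).
#' @param kind `"rotational"` (rad) or `"translational"` (m).
#' @param range length-2 `c(min, max)`.
#' @param default default value, must lie within `range`.
#' @param locked logical; locked coordinates are held at `default`.
#' @return an object of class `coordinate_def`.
#' @export
coordinate_def <- function(name, kind = c("rotational", "translational"),
                           range = c(-pi, pi), default = 0, locked = FALSE) {
  kind <- match.arg(kind)
  stopifnot(length(range) == 2, all(is.finite(range)))
  if (range[1] > range[2])
    stop("coordinate '", name, "': range min > max", call. = FALSE)
  if (default < range[1] - 1e-12 || default > range[2] + 1e-12)
    stop("coordinate '", name, "': default ", default,
         " outside range [", range[1], ", ", range[2], "]", call. = FALSE)
  structure(list(name = name, kind = kind, range = as.numeric(range),
                 default = default, locked = isTRUE(locked)),
            class = "coordinate_def")
}

#' Construct a transform-axis entry of a custom joint
#'
#' One of the six axes (`rotation1..3`, `translation1..3`) of a custom joint's
#' spatial transform. An axis with `coordinate = NA` is constant zero.
#'
#' @param name axis slot name, e.g. `"rotation1"`.
#' @param axis unit length-3 axis vector (joint frame).
#' @param coordinate name of the driving coordinate, or `NA`.
#' @return an object of class `transform_axis`.
#' @export
transform_axis <- function(name, axis, coordinate = NA_character_) {
  stopifnot(length(axis) == 3, all(is.finite(axis)))
  nrm <- sqrt(sum(axis^2))
  if (abs(nrm - 1) > 1e-6)
    stop("transform axis '", name, "': axis vector must be unit norm", call. = FALSE)
  structure(list(name = name, axis = as.numeric(axis),
                 coordinate = as.character(coordinate)),
            class = "transform_axis")
}

#' Construct a joint definition
#'
#' Joints connect a child body to a parent body (or ground). A
#' `"CustomJoint"` carries coordinates and a six-axis spatial transform
#' (three rotations applied in order, then three translations); a
#' `"WeldJoint"` is rigid.
#'
#' @param name joint name.
#' @param type `"CustomJoint"` or `"WeldJoint"`.
#' @param parent,child body names (`"ground"` allowed as parent).
#' @param location_in_parent,orientation_in_parent joint frame in the parent
#'   body (m; body-fixed XYZ Euler, rad).
#' @param coordinates list of [coordinate_def()] objects.
#' @param spatial_transform list of [transform_axis()] entries.
#' @param extra opaque XML fragments preserved on round-trip.
#' @return an object of class `joint_def`.
#' @export
joint_def <- function(name, type = c("CustomJoint", "WeldJoint"), parent, child,
                      location_in_parent = c(0, 0, 0),
                      orientation_in_parent = c(0, 0, 0),
                      coordinates = list(), spatial_transform = list(),
                      extra = character()) {
  type <- match.arg(type)
  stopifnot(length(location_in_parent) == 3, length(orientation_in_parent) == 3)
  if (type == "WeldJoint" && length(coordinates) > 0)
    stop("joint '", name, "': a WeldJoint has no coordinates", call. = FALSE)
  names(coordinates) <- vapply(coordinates, function(co) co$name, "")
  structure(list(name = name, type = type, parent = parent, child = child,
                 location_in_parent = as.numeric(location_in_parent),
                 orientation_in_parent = as.numeric(orientation_in_parent),
                 coordinates = coordinates, spatial_transform = spatial_transform,
                 extra = extra),
            class = "joint_def")
}

#' Construct a muscle path point
#' @param body body name the point is fixed to.
#' @param location length-3 location in the body frame (m).
#' @return an object of class `path_point`.
#' @export
path_point <- function(body, location) {
  stopifnot(length(location) == 3)
  if (!all(is.finite(location)))
    stop("path point on '", body, "': location must be finite", call. = FALSE)
  structure(list(body = body, location = as.numeric(location)),
            class = "path_point")
}

#' Construct a muscle actuator definition
#'
#' Only peak isometric force and the geometric path are interpreted by the
#' solver; fiber and tendon properties are carried through untouched, and the
#' muscle model class is treated as opaque.
#'
#' @param name muscle name.
#' @param max_isometric_force peak isometric force (N), non-negative.
#' @param path list of at least two [path_point()]s, origin to insertion.
#' @param optimal_fiber_length,tendon_slack_length m; carried, unused.
#' @param class XML element name of the muscle model (default
#'   `"Thelen2003Muscle"`).
#' @param extra opaque XML fragments preserved on round-trip.
#' @return an object of class `muscle_def`.
#' @export
muscle_def <- function(name, max_isometric_force, path,
                       optimal_fiber_length = 0.1, tendon_slack_length = 0.05,
                       class = "Thelen2003Muscle", extra = character()) {
  if (max_isometric_force < 0)
    stop("muscle '", name, "': max_isometric_force must be >= 0", call. = FALSE)
  if (length(path) < 2)
    stop("muscle '", name, "': path needs at least 2 points", call. = FALSE)
  structure(list(name = name, max_isometric_force = max_isometric_force,
                 path = path, optimal_fiber_length = optimal_fiber_length,
                 tendon_slack_length = tendon_slack_length, class = class,
                 extra = extra),
            class = "muscle_def")
}

#' Construct a weld constraint definition
#'
#' Closes a kinematic loop by rigidly tying a frame on `body_1` to a frame on
#' `body_2` (used to attach the shared load to the second hand).
#'
#' @param name constraint name.
#' @param body_1,body_2 body names.
#' @param location_in_body_1,orientation_in_body_1 frame on body 1.
#' @param location_in_body_2,orientation_in_body_2 frame on body 2.
#' @return an object of class `constraint_def`.
#' @export
constraint_def <- function(name, body_1, body_2,
                           location_in_body_1 = c(0, 0, 0),
                           orientation_in_body_1 = c(0, 0, 0),
                           location_in_body_2 = c(0, 0, 0),
                           orientation_in_body_2 = c(0, 0, 0)) {
  structure(list(name = name, kind = "weld", body_1 = body_1, body_2 = body_2,
                 location_in_body_1 = as.numeric(location_in_body_1),
                 orientation_in_body_1 = as.numeric(orientation_in_body_1),
                 location_in_body_2 = as.numeric(location_in_body_2),
                 orientation_in_body_2 = as.numeric(orientation_in_body_2)),
            class = "constraint_def")
}

#' Assemble a model definition
#'
#' The container every transform in the package acts on: bodies, joints with
#' their coordinates, muscle actuators and loop-closing constraints, plus
#' opaque pass-through XML for unsupported elements.
#'
#' @param name model name.
#' @param bodies,joints,muscles,constraints lists of the respective `_def`
#'   objects.
#' @param gravity gravity vector in ground frame (m/s^2).
#' @param extra opaque XML fragments preserved on round-trip.
#' @param validate run [validate_model()] (default `TRUE`).
#' @return an object of class `model_def`.
#' @export
model_def <- function(name, bodies = list(), joints = list(), muscles = list(),
                      constraints = list(), gravity = c(0, -9.80665, 0),
                      extra = character(), validate = TRUE) {
  names(bodies) <- vapply(bodies, function(b) b$name, "")
  names(joints) <- vapply(joints, function(j) j$name, "")
  names(muscles) <- vapply(muscles, function(m) m$name, "")
  names(constraints) <- vapply(constraints, function(k) k$name, "")
  m <- structure(list(name = name, gravity = as.numeric(gravity),
                      bodies = bodies, joints = joints, muscles = muscles,
                      constraints = constraints, extra = extra),
                 class = "model_def")
  if (validate) validate_model(m)
  m
}

#' Validate a model definition's cross-reference invariants
#'
#' Checks that body names are unique, that every joint's parent and child and
#' every path point's and constraint's body reference resolves to a body (or
#' ground), and that coordinate names are unique model-wide.
#'
#' @param model a [model_def()].
#' @return the model, invisibly; errors name the first dangling reference.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "model_def"))
  bnames <- names(model$bodies)
  if (anyDuplicated(bnames))
    stop("duplicate body names: ",
         paste(unique(bnames[duplicated(bnames)]), collapse = ", "), call. = FALSE)
  known <- c("ground", bnames)
  for (j in model$joints) {
    if (!(j$parent %in% known))
      stop("joint '", j$name, "': parent body '", j$parent, "' not found", call. = FALSE)
    if (!(j$child %in% bnames))
      stop("joint '", j$name, "': child body '", j$child, "' not found", call. = FALSE)
  }
  coords <- unlist(lapply(model$joints, function(j) names(j$coordinates)))
  if (anyDuplicated(coords))
    stop("duplicate coordinate names: ",
         paste(unique(coords[duplicated(coords)]), collapse = ", "), call. = FALSE)
  for (mu in model$muscles) {
    for (p in mu$path) {
      if (!(p$body %in% known))
        stop("muscle '", mu$name, "': path point body '", p$body,
             "' not found", call. = FALSE)
    }
  }
  for (k in model$constraints) {
    if (!(k$body_1 %in% known))
      stop("constraint '", k$name, "': body_1 '", k$body_1, "' not found", call. = FALSE)
    if (!(k$body_2 %in% known))
      stop("constraint '", k$name, "': body_2 '", k$body_2, "' not found", call. = FALSE)
  }
  invisible(model)
}

#' @export
print.model_def <- function(x, ...) {
  ncoord <- sum(vapply(x$joints, function(j) length(j$coordinates), 0L))
  cat("<model_def> ", x$name, "\n",
      "  bodies:      ", length(x$bodies), "\n",
      "  joints:      ", length(x$joints), " (", ncoord, " coordinates)\n",
      "  muscles:     ", length(x$muscles), "\n",
      "  constraints: ", length(x$constraints), "\n", sep = "")
  invisible(x)
}

# --- motion tables -----------------------------------------------------------

#' Construct a motion table
#'
#' Named time series backing `.mot`/`.sto` content: a strictly increasing time
#' vector and a value matrix with one named column per series. Angle columns
#' are in degrees when `in_degrees` is `TRUE` (the on-disk convention).
#'
#' @param time numeric vector (s), strictly increasing.
#' @param values numeric matrix, `length(time)` rows, with column names.
#' @param in_degrees logical, default `TRUE`.
#' @param name table name written to the file header.
#' @return an object of class `motion_table`.
#' @export
motion_table <- function(time, values, in_degrees = TRUE, name = "motion") {
  values <- as.matrix(values)
  if (length(time) != nrow(values))
    stop("time length (", length(time), ") does not match row count (",
         nrow(values), ")", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("time must be strictly increasing", call. = FALSE)
  if (is.null(colnames(values)) || any(!nzchar(colnames(values))))
    stop("all value columns must be named", call. = FALSE)
  structure(list(time = as.numeric(time), values = values,
                 in_degrees = isTRUE(in_degrees), name = name),
            class = "motion_table")
}

#' @export
print.motion_table <- function(x, ...) {
  cat("<motion_table> ", x$name, ": ", nrow(x$values), " rows x ",
      ncol(x$values), " columns, t = [", format(min(x$time)), ", ",
      format(max(x$time)), "] s",
      if (x$in_degrees) ", degrees" else "", "\n", sep = "")
  invisible(x)
}

# --- triangle meshes ---------------------------------------------------------

#' Construct a triangle mesh
#' @param vertices numeric N x 3 matrix (m).
#' @param faces integer M x 3 matrix of 1-based vertex indices.
#' @return an object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  if (nrow(vertices) == 0) stop("mesh has no vertices", call. = FALSE)
  if (ncol(vertices) != 3) stop("vertices must be N x 3", call. = FALSE)
  if (ncol(faces) != 3) stop("faces must be triangles (M x 3)", call. = FALSE)
  storage.mode(faces) <- "integer"
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("face indices out of range", call. = FALSE)
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat("<tri_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " triangles\n", sep = "")
  invisible(x)
}

# all coordinates of a model, as a named list of coordinate_def
model_coordinates <- function(model) {
  out <- list()
  for (j in model$joints) out <- c(out, j$coordinates)
  out
}

#' Default pose of a model
#'
#' @param model a [model_def()].
#' @return named numeric vector of every coordinate's default value (rad or m).
#' @export
default_pose <- function(model) {
  coords <- model_coordinates(model)
  stats::setNames(vapply(coords, function(co) co$default, 0), names(coords))
}

#' Names of the unlocked coordinates of a model
#' @param model a [model_def()].
#' @return character vector.
#' @export
free_coordinates <- function(model) {
  coords <- model_coordinates(model)
  names(coords)[!vapply(coords, function(co) co$locked, TRUE)]
}
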