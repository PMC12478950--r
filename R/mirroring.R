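# Mid-sagittal mirroring: points, meshes, orientations, inertia tensors,
# bodies, joints and muscle paths, plus the merge that turns a one-sided
# model into a bilateral one.
#
# The reflection is the conjugation X -> M X M with M = diag with -1 on the
# sagittal-normal axis. For rotations this is R(a, theta) -> R(M a, -theta),
# which we realize as R(-M a, theta): the axis vector is flipped and the
# coordinate keeps its sign, so identical coordinate values on both sides
# produce mirror-symmetric postures.

#' Mirror convention
#'
#' Defines the mirror plane (by its normal axis in the ground frame; the
#' default `"z"` is the medial/lateral direction, giving the mid-sagittal
#' plane) and the side-suffix renaming rule.
#'
#' @param axis `"x"`, `"y"` or `"z"` — the ground-frame axis normal to the
#'   mirror plane.
#' @param suffix_pairs list of length-2 character vectors of name suffixes
#'   swapped between sides, default `list(c("_r", "_l"))`. The induced name
#'   map is an involution.
#' @return an object of class `mirror_convention`.
#' @export
mirror_convention <- function(axis = c("z", "x", "y"),
                              suffix_pairs = list(c("_r", "_l"))) {
  axis <- match.arg(axis)
  structure(list(axis = axis, axis_index = match(axis, c("x", "y", "z")),
                 suffix_pairs = suffix_pairs),
            class = "mirror_convention")
}

# diag reflection matrix of a convention
mirror_matrix <- function(convention) {
  d <- c(1, 1, 1)
  d[convention$axis_index] <- -1
  diag(d)
}

#' Map a name to its contralateral twin
#'
#' @param name character vector of component names.
#' @param convention a [mirror_convention()].
#' @return character vector; names without a side suffix are returned
#'   unchanged.
#' @export
map_side_name <- function(name, convention) {
  vapply(name, function(nm) {
    for (pr in convention$suffix_pairs) {
      if (endsWith(nm, pr[1]))
        return(paste0(substr(nm, 1, nchar(nm) - nchar(pr[1])), pr[2]))
      if (endsWith(nm, pr[2]))
        return(paste0(substr(nm, 1, nchar(nm) - nchar(pr[2])), pr[1]))
    }
    nm
  }, "", USE.NAMES = FALSE)
}

is_sided_name <- function(name, convention) {
  map_side_name(name, convention) != name
}

#' Mirror a point across the sagittal plane
#'
#' @param p length-3 point (or 3-column matrix of row points).
#' @param convention a [mirror_convention()].
#' @return mirrored point(s): the component along the convention's normal
#'   axis is negated, the others are unchanged.
#' @export
mirror_point <- function(p, convention = mirror_convention()) {
  k <- convention$axis_index
  if (is.matrix(p)) {
    p[, k] <- -p[, k]
    p
  } else {
    p[k] <- -p[k]
    p
  }
}

#' Mirror a triangle mesh
#'
#' Every vertex is reflected and the winding order of every triangle is
#' reversed so that outward normals remain outward (the signed volume of a
#' closed mesh is preserved, sign included).
#'
#' @param mesh a [tri_mesh()].
#' @param convention a [mirror_convention()].
#' @return the mirrored [tri_mesh()].
#' @export
mirror_mesh <- function(mesh, convention = mirror_convention()) {
  tri_mesh(vertices = mirror_point(mesh$vertices, convention),
           faces = mesh$faces[, c(1, 3, 2), drop = FALSE])
}

#' Mirror a body-fixed XYZ Euler orientation
#'
#' Returns the Euler angles of `M R(e) M` where `M` is the reflection matrix:
#' rotations about the two in-plane axes negate and the rotation about the
#' plane normal is preserved, so the result is again a proper rotation
#' (det +1). Gimbal-degenerate inputs are resolved by the deterministic
#' extraction branch of [matrix_to_euler_xyz()].
#'
#' @param euler_xyz length-3 body-fixed XYZ Euler angles (rad).
#' @param convention a [mirror_convention()].
#' @return length-3 Euler angles (rad).
#' @export
mirror_orientation <- function(euler_xyz, convention = mirror_convention()) {
  M <- mirror_matrix(convention)
  matrix_to_euler_xyz(M %*% euler_xyz_to_matrix(euler_xyz) %*% M)
}

#' Mirror an inertia tensor
#'
#' Computes `M I M^T`; with the default z-normal, the products Ixz and Iyz
#' negate while the diagonal and Ixy are unchanged. Eigenvalues are
#' preserved.
#'
#' @param I symmetric 3x3 inertia matrix (kg m^2).
#' @param convention a [mirror_convention()].
#' @return mirrored 3x3 inertia matrix.
#' @export
mirror_inertia <- function(I, convention = mirror_convention()) {
  stopifnot(is.matrix(I), all(dim(I) == c(3, 3)))
  if (max(abs(I - t(I))) > 1e-9 * max(abs(I), 1))
    stop("inertia matrix must be symmetric", call. = FALSE)
  M <- mirror_matrix(convention)
  M %*% I %*% t(M)
}

mirrored_mesh_name <- function(file) {
  ext <- tools::file_ext(file)
  base <- tools::file_path_sans_ext(file)
  if (endsWith(base, "_mirrored")) {
    paste0(substr(base, 1, nchar(base) - nchar("_mirrored")), ".", ext)
  } else {
    paste0(base, "_mirrored.", ext)
  }
}

#' Mirror a body definition
#'
#' Renames the body to its contralateral twin, mirrors its center of mass and
#' inertia products, preserves its mass, and remaps display meshes to their
#' `_mirrored` counterparts.
#'
#' @param b a [body_def()].
#' @param convention a [mirror_convention()].
#' @return the mirrored [body_def()].
#' @export
mirror_body <- function(b, convention = mirror_convention()) {
  I2 <- mirror_inertia(inertia_to_matrix(b$inertia), convention)
  body_def(name = map_side_name(b$name, convention),
           mass = b$mass,
           com = mirror_point(b$com, convention),
           inertia = matrix_to_inertia(I2),
           mesh_refs = lapply(b$mesh_refs, function(g)
             list(file = mirrored_mesh_name(g$file), scale = g$scale)),
           extra = b$extra)
}

#' Mirror a joint definition
#'
#' Parent/child and coordinate names are mapped to the contralateral side,
#' the joint frame is mirrored ([mirror_point()] on the location,
#' [mirror_orientation()] on the orientation), each rotation axis `a` becomes
#' `-M a` with the coordinate's sign kept, and each translation axis becomes
#' `M a`. Ranges and defaults are therefore unchanged: equal coordinate
#' values on the two sides yield mirror-symmetric postures.
#'
#' The returned joint carries an `axis_flips` attribute: a named logical per
#' coordinate, `TRUE` where the rotation axis vector was flipped.
#'
#' @param j a [joint_def()].
#' @param convention a [mirror_convention()].
#' @return the mirrored [joint_def()].
#' @export
mirror_joint <- function(j, convention = mirror_convention()) {
  if (!(j$type %in% c("CustomJoint", "WeldJoint")))
    stop("cannot mirror joint class '", j$type, "'", call. = FALSE)
  M <- mirror_matrix(convention)
  flips <- logical(0)
  st <- lapply(j$spatial_transform, function(ax) {
    rotational <- startsWith(ax$name, "rotation")
    a2 <- if (rotational) drop(-M %*% ax$axis) else drop(M %*% ax$axis)
    if (rotational && !is.na(ax$coordinate)) {
      flips[[map_side_name(ax$coordinate, convention)]] <<-
        max(abs(a2 - ax$axis)) > 1e-12
    }
    transform_axis(ax$name, a2, ax$coordinate)
  })
  st <- lapply(st, function(ax) {
    ax$coordinate <- if (is.na(ax$coordinate)) NA_character_ else
      map_side_name(ax$coordinate, convention)
    ax
  })
  coords <- lapply(j$coordinates, function(co) {
    coordinate_def(name = map_side_name(co$name, convention), kind = co$kind,
                   range = co$range, default = co$default, locked = co$locked)
  })
  out <- joint_def(name = map_side_name(j$name, convention), type = j$type,
                   parent = map_side_name(j$parent, convention),
                   child = map_side_name(j$child, convention),
                   location_in_parent = mirror_point(j$location_in_parent, convention),
                   orientation_in_parent = mirror_orientation(j$orientation_in_parent,
                                                              convention),
                   coordinates = coords, spatial_transform = st,
                   extra = j$extra)
  attr(out, "axis_flips") <- flips
  out
}

#' Mirror a muscle actuator
#'
#' Renames the muscle and the body of every path point to the contralateral
#' side and mirrors every path-point location; peak isometric force and
#' fiber/tendon properties are preserved exactly.
#'
#' @param m a [muscle_def()].
#' @param convention a [mirror_convention()].
#' @return the mirrored [muscle_def()].
#' @export
mirror_muscle <- function(m, convention = mirror_convention()) {
  muscle_def(name = map_side_name(m$name, convention),
             max_isometric_force = m$max_isometric_force,
             path = lapply(m$path, function(p)
               path_point(body = map_side_name(p$body, convention),
                          location = mirror_point(p$location, convention))),
             optimal_fiber_length = m$optimal_fiber_length,
             tendon_slack_length = m$tendon_slack_length,
             class = m$class, extra = m$extra)
}

mirror_constraint <- function(k, convention = mirror_convention()) {
  constraint_def(name = map_side_name(k$name, convention),
                 body_1 = map_side_name(k$body_1, convention),
                 body_2 = map_side_name(k$body_2, convention),
                 location_in_body_1 = mirror_point(k$location_in_body_1, convention),
                 orientation_in_body_1 = mirror_orientation(k$orientation_in_body_1,
                                                            convention),
                 location_in_body_2 = mirror_point(k$location_in_body_2, convention),
                 orientation_in_body_2 = mirror_orientation(k$orientation_in_body_2,
                                                            convention))
}

#' Build a bilateral model from a one-sided model
#'
#' Every side-suffixed body, joint, muscle and constraint gains a mirrored
#' contralateral twin; shared (unsuffixed) bodies such as the trunk appear
#' once. Muscle and limb-coordinate counts double. If `mesh_dir` is given,
#' the mirrored copies of the sided bodies' display meshes are written there
#' as `<name>_mirrored.<ext>`.
#'
#' The result carries an `axis_flips` attribute (named logical over the new
#' coordinates, see [mirror_joint()]) and a `mirror_convention` attribute.
#'
#' @param model a one-sided [model_def()] (no component name may already have
#'   its contralateral twin present).
#' @param convention a [mirror_convention()].
#' @param mesh_dir optional directory containing the model's mesh files; if
#'   given, mirrored mesh files are produced alongside.
#' @return the bilateral [model_def()].
#' @export
build_bilateral <- function(model, convention = mirror_convention(),
                            mesh_dir = NULL) {
  sided_bodies <- Filter(function(b) is_sided_name(b$name, convention),
                         model$bodies)
  new_names <- map_side_name(names(model$bodies), convention)
  collide <- intersect(new_names[new_names != names(model$bodies)],
                       names(model$bodies))
  if (length(collide) > 0)
    stop("model is not one-sided; name collisions after mirroring: ",
         paste(collide, collapse = ", "), call. = FALSE)
  mirrored_bodies <- lapply(sided_bodies, mirror_body, convention = convention)
  mirrored_joints <- lapply(
    Filter(function(j) is_sided_name(j$child, convention), model$joints),
    mirror_joint, convention = convention)
  mirrored_muscles <- lapply(
    Filter(function(m) is_sided_name(m$name, convention), model$muscles),
    mirror_muscle, convention = convention)
  mirrored_constraints <- lapply(
    Filter(function(k) is_sided_name(k$name, convention), model$constraints),
    mirror_constraint, convention = convention)
  flips <- do.call(c, c(list(logical(0)),
                        lapply(mirrored_joints, attr, "axis_flips")))
  if (!is.null(mesh_dir)) {
    for (b in sided_bodies) {
      for (g in b$mesh_refs) {
        src <- file.path(mesh_dir, g$file)
        if (file.exists(src)) {
          write_mesh(mirror_mesh(read_mesh(src), convention),
                     file.path(mesh_dir, mirrored_mesh_name(g$file)))
        }
      }
    }
  }
  out <- model_def(name = paste0(model$name, "_bilateral"),
                   gravity = model$gravity,
                   bodies = c(model$bodies, mirrored_bodies),
                   joints = c(model$joints, mirrored_joints),
                   muscles = c(model$muscles, mirrored_muscles),
                   constraints = c(model$constraints, mirrored_constraints),
                   extra = model$extra)
  attr(out, "axis_flips") <- flips
  attr(out, "mirror_convention") <- convention
  out
}
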