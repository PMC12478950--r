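# Reader/writer for the subset of the OpenSim 3.3 `.osim` XML dialect that the
# toolkit manipulates: Body (with its Joint), Coordinate, SpatialTransform,
# muscle actuators (class treated as opaque beyond Fmax + path), WeldConstraint
# and display-mesh references. Anything else is carried as verbatim XML so a
# read-modify-write cycle preserves the source file's content.

num_fmt <- function(x) paste(sprintf("%.17g", x), collapse = " ")

parse_nums <- function(s, n = NULL, what = "numeric field") {
  v <- suppressWarnings(as.numeric(strsplit(trimws(s), "\\s+")[[1]]))
  if (any(is.na(v))) stop("cannot parse ", what, ": '", s, "'", call. = FALSE)
  if (!is.null(n) && length(v) != n)
    stop(what, ": expected ", n, " values, got ", length(v), call. = FALSE)
  v
}

xml_num <- function(node, child, n = NULL, default = NULL) {
  ch <- xml2::xml_find_first(node, child)
  if (inherits(ch, "xml_missing")) {
    if (is.null(default)) stop("missing element <", child, ">", call. = FALSE)
    return(default)
  }
  parse_nums(xml2::xml_text(ch), n, child)
}

xml_chr <- function(node, child, default = NULL) {
  ch <- xml2::xml_find_first(node, child)
  if (inherits(ch, "xml_missing")) {
    if (is.null(default)) stop("missing element <", child, ">", call. = FALSE)
    return(default)
  }
  trimws(xml2::xml_text(ch))
}

node_extras <- function(node, known) {
  kids <- xml2::xml_children(node)
  keep <- !(xml2::xml_name(kids) %in% known)
  vapply(kids[keep], function(k) as.character(k), "")
}

parse_coordinate <- function(node) {
  coordinate_def(
    name = xml2::xml_attr(node, "name"),
    kind = if (identical(xml_chr(node, "motion_type", "rotational"),
                         "translational")) "translational" else "rotational",
    range = xml_num(node, "range", 2, c(-pi, pi)),
    default = xml_num(node, "default_value", 1, 0),
    locked = identical(tolower(xml_chr(node, "locked", "false")), "true"))
}

parse_joint_node <- function(jnode, child_body) {
  type <- xml2::xml_name(jnode)
  if (!(type %in% c("CustomJoint", "WeldJoint", "PinJoint")))
    stop("unsupported joint class '", type, "' on body '", child_body,
         "'", call. = FALSE)
  coords <- lapply(xml2::xml_find_all(
    jnode, "./CoordinateSet/objects/Coordinate"), parse_coordinate)
  st <- lapply(xml2::xml_find_all(
    jnode, "./SpatialTransform/TransformAxis"), function(ax) {
      co <- xml_chr(ax, "coordinates", "")
      transform_axis(name = xml2::xml_attr(ax, "name"),
                     axis = xml_num(ax, "axis", 3),
                     coordinate = if (nzchar(co)) co else NA_character_)
    })
  joint_def(
    name = xml2::xml_attr(jnode, "name"),
    type = if (type == "WeldJoint") "WeldJoint" else "CustomJoint",
    parent = xml_chr(jnode, "parent_body"),
    child = child_body,
    location_in_parent = xml_num(jnode, "location_in_parent", 3, c(0, 0, 0)),
    orientation_in_parent = xml_num(jnode, "orientation_in_parent", 3, c(0, 0, 0)),
    coordinates = coords, spatial_transform = st,
    extra = node_extras(jnode, c("parent_body", "location_in_parent",
                                 "orientation_in_parent", "CoordinateSet",
                                 "SpatialTransform")))
}

parse_body <- function(bnode) {
  inertia <- c(xml_num(bnode, "inertia_xx", 1, 0.01),
               xml_num(bnode, "inertia_yy", 1, 0.01),
               xml_num(bnode, "inertia_zz", 1, 0.01),
               xml_num(bnode, "inertia_xy", 1, 0),
               xml_num(bnode, "inertia_xz", 1, 0),
               xml_num(bnode, "inertia_yz", 1, 0))
  meshes <- lapply(xml2::xml_find_all(
    bnode, "./VisibleObject/GeometrySet/objects/DisplayGeometry"), function(g) {
      list(file = xml_chr(g, "geometry_file"),
           scale = xml_num(g, "scale_factors", 3, c(1, 1, 1)))
    })
  jnodes <- xml2::xml_children(xml2::xml_find_first(bnode, "./Joint"))
  body <- body_def(
    name = xml2::xml_attr(bnode, "name"),
    mass = xml_num(bnode, "mass", 1),
    com = xml_num(bnode, "mass_center", 3, c(0, 0, 0)),
    inertia = inertia, mesh_refs = meshes,
    extra = node_extras(bnode, c("mass", "mass_center", "inertia_xx",
                                 "inertia_yy", "inertia_zz", "inertia_xy",
                                 "inertia_xz", "inertia_yz", "Joint",
                                 "VisibleObject")))
  joint <- if (length(jnodes) > 0) parse_joint_node(jnodes[[1]], body$name) else NULL
  list(body = body, joint = joint)
}

parse_muscle <- function(mnode) {
  pts <- lapply(xml2::xml_find_all(
    mnode, "./GeometryPath/PathPointSet/objects/*"), function(p) {
      path_point(body = xml_chr(p, "body"),
                 location = xml_num(p, "location", 3))
    })
  muscle_def(
    name = xml2::xml_attr(mnode, "name"),
    max_isometric_force = xml_num(mnode, "max_isometric_force", 1),
    path = pts,
    optimal_fiber_length = xml_num(mnode, "optimal_fiber_length", 1, 0.1),
    tendon_slack_length = xml_num(mnode, "tendon_slack_length", 1, 0.05),
    class = xml2::xml_name(mnode),
    extra = node_extras(mnode, c("max_isometric_force", "optimal_fiber_length",
                                 "tendon_slack_length", "GeometryPath")))
}

parse_constraint <- function(knode) {
  constraint_def(
    name = xml2::xml_attr(knode, "name"),
    body_1 = xml_chr(knode, "body_1"),
    body_2 = xml_chr(knode, "body_2"),
    location_in_body_1 = xml_num(knode, "location_in_body_1", 3, c(0, 0, 0)),
    orientation_in_body_1 = xml_num(knode, "orientation_in_body_1", 3, c(0, 0, 0)),
    location_in_body_2 = xml_num(knode, "location_in_body_2", 3, c(0, 0, 0)),
    orientation_in_body_2 = xml_num(knode, "orientation_in_body_2", 3, c(0, 0, 0)))
}

#' Read an OpenSim 3.3 model file
#'
#' Parses the supported subset (bodies with their joints and coordinates,
#' muscle actuators, weld constraints, display meshes) into a [model_def()];
#' unsupported elements are retained verbatim and re-emitted by
#' [write_model()]. Cross-references are validated after parsing, so a file
#' whose joint or path point cites a missing body is rejected with the name
#' of the dangling reference.
#'
#' @param path path to a `.osim` file.
#' @return a [model_def()].
#' @seealso [write_model()]
#' @export
read_model <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("parse error in '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  mnode <- xml2::xml_find_first(doc, "//Model")
  if (inherits(mnode, "xml_missing"))
    stop("'", path, "' contains no <Model> element", call. = FALSE)
  parsed <- lapply(xml2::xml_find_all(mnode, "./BodySet/objects/Body"), parse_body)
  bodies <- lapply(parsed, `[[`, "body")
  joints <- Filter(Negate(is.null), lapply(parsed, `[[`, "joint"))
  muscles <- lapply(xml2::xml_find_all(mnode, "./ForceSet/objects/*"), parse_muscle)
  constraints <- lapply(
    xml2::xml_find_all(mnode, "./ConstraintSet/objects/WeldConstraint"),
    parse_constraint)
  model_def(
    name = xml2::xml_attr(mnode, "name"),
    gravity = xml_num(mnode, "gravity", 3, c(0, -9.80665, 0)),
    bodies = bodies, joints = joints, muscles = muscles,
    constraints = constraints,
    extra = node_extras(mnode, c("gravity", "BodySet", "ForceSet",
                                 "ConstraintSet")))
}

add_text_child <- function(node, name, text) {
  xml2::xml_add_child(node, name, text)
}

add_extras <- function(node, extra) {
  for (frag in extra) {
    xml2::xml_add_child(node, xml2::read_xml(frag))
  }
}

emit_joint <- function(parent_node, j) {
  jwrap <- xml2::xml_add_child(parent_node, "Joint")
  jn <- xml2::xml_add_child(jwrap, j$type, name = j$name)
  add_text_child(jn, "parent_body", j$parent)
  add_text_child(jn, "location_in_parent", num_fmt(j$location_in_parent))
  add_text_child(jn, "orientation_in_parent", num_fmt(j$orientation_in_parent))
  if (j$type == "CustomJoint") {
    cs <- xml2::xml_add_child(jn, "CoordinateSet")
    cso <- xml2::xml_add_child(cs, "objects")
    for (co in j$coordinates) {
      cn <- xml2::xml_add_child(cso, "Coordinate", name = co$name)
      add_text_child(cn, "motion_type", co$kind)
      add_text_child(cn, "default_value", num_fmt(co$default))
      add_text_child(cn, "range", num_fmt(co$range))
      add_text_child(cn, "locked", if (co$locked) "true" else "false")
    }
    st <- xml2::xml_add_child(jn, "SpatialTransform")
    for (ax in j$spatial_transform) {
      an <- xml2::xml_add_child(st, "TransformAxis", name = ax$name)
      add_text_child(an, "coordinates",
                     if (is.na(ax$coordinate)) "" else ax$coordinate)
      add_text_child(an, "axis", num_fmt(ax$axis))
    }
  }
  add_extras(jn, j$extra)
}

#' Write an OpenSim 3.3 model file
#'
#' Emits XML that re-parses (via [read_model()]) to a model equal to the
#' input; opaque pass-through fragments are written back verbatim. The model
#' is validated first and the write is refused if an invariant fails.
#'
#' @param model a [model_def()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  validate_model(model)
  doc <- xml2::xml_new_root("OpenSimDocument", Version = "30000")
  mnode <- xml2::xml_add_child(doc, "Model", name = model$name)
  add_text_child(mnode, "gravity", num_fmt(model$gravity))
  bs <- xml2::xml_add_child(mnode, "BodySet")
  bso <- xml2::xml_add_child(bs, "objects")
  joints_by_child <- stats::setNames(model$joints,
                                     vapply(model$joints, `[[`, "", "child"))
  for (b in model$bodies) {
    bn <- xml2::xml_add_child(bso, "Body", name = b$name)
    add_text_child(bn, "mass", num_fmt(b$mass))
    add_text_child(bn, "mass_center", num_fmt(b$com))
    lab <- c("inertia_xx", "inertia_yy", "inertia_zz",
             "inertia_xy", "inertia_xz", "inertia_yz")
    for (i in 1:6) add_text_child(bn, lab[i], num_fmt(b$inertia[i]))
    if (!is.null(joints_by_child[[b$name]]))
      emit_joint(bn, joints_by_child[[b$name]])
    if (length(b$mesh_refs) > 0) {
      vo <- xml2::xml_add_child(bn, "VisibleObject")
      gs <- xml2::xml_add_child(vo, "GeometrySet")
      gso <- xml2::xml_add_child(gs, "objects")
      for (g in b$mesh_refs) {
        gn <- xml2::xml_add_child(gso, "DisplayGeometry")
        add_text_child(gn, "geometry_file", g$file)
        add_text_child(gn, "scale_factors", num_fmt(g$scale))
      }
    }
    add_extras(bn, b$extra)
  }
  if (length(model$constraints) > 0) {
    ks <- xml2::xml_add_child(mnode, "ConstraintSet")
    kso <- xml2::xml_add_child(ks, "objects")
    for (k in model$constraints) {
      kn <- xml2::xml_add_child(kso, "WeldConstraint", name = k$name)
      add_text_child(kn, "isDisabled", "false")
      add_text_child(kn, "body_1", k$body_1)
      add_text_child(kn, "body_2", k$body_2)
      add_text_child(kn, "location_in_body_1", num_fmt(k$location_in_body_1))
      add_text_child(kn, "orientation_in_body_1", num_fmt(k$orientation_in_body_1))
      add_text_child(kn, "location_in_body_2", num_fmt(k$location_in_body_2))
      add_text_child(kn, "orientation_in_body_2", num_fmt(k$orientation_in_body_2))
    }
  }
  if (length(model$muscles) > 0) {
    fs <- xml2::xml_add_child(mnode, "ForceSet")
    fso <- xml2::xml_add_child(fs, "objects")
    for (mu in model$muscles) {
      mn <- xml2::xml_add_child(fso, mu$class, name = mu$name)
      add_text_child(mn, "max_isometric_force", num_fmt(mu$max_isometric_force))
      add_text_child(mn, "optimal_fiber_length", num_fmt(mu$optimal_fiber_length))
      add_text_child(mn, "tendon_slack_length", num_fmt(mu$tendon_slack_length))
      gp <- xml2::xml_add_child(mn, "GeometryPath")
      pps <- xml2::xml_add_child(gp, "PathPointSet")
      ppo <- xml2::xml_add_child(pps, "objects")
      for (i in seq_along(mu$path)) {
        p <- mu$path[[i]]
        pn <- xml2::xml_add_child(ppo, "PathPoint",
                                  name = paste0(mu$name, "_P", i))
        add_text_child(pn, "location", num_fmt(p$location))
        add_text_child(pn, "body", p$body)
      }
      add_extras(mn, mu$extra)
    }
  }
  add_extras(mnode, model$extra)
  xml2::write_xml(doc, path)
  invisible(path)
}
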