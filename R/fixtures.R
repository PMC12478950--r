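# Self-contained synthetic fixture: a small right-sided upper-limb model
# (thorax + humerus + forearm/hand, 4 unlocked DOF, 14 shoulder-crossing
# actuators) plus matching box meshes and mirrored task kinematics, so the
# whole pipeline is exercisable without any external model files. Peak
# isometric forces are order-of-magnitude biomechanics defaults, not values
# from any published model.

#' Fixture specification
#'
#' @param seed integer; regeneration with the same seed is bit-identical
#'   (generation is deterministic; the seed feeds only noise options
#'   downstream, e.g. [make_symmetric_kinematics()]).
#' @param humerus_length,forearm_length segment lengths (m).
#' @param humerus_mass,forearm_mass,thorax_mass segment masses (kg).
#' @param shoulder_offset shoulder center in the thorax frame (m); the
#'   z-component is the half hand-spacing of the default posture.
#' @param fmax optional named numeric overriding individual actuator peak
#'   isometric forces (N).
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, humerus_length = 0.30, humerus_mass = 2.0,
                         forearm_length = 0.30, forearm_mass = 1.5,
                         thorax_mass = 20, shoulder_offset = c(0, 0.40, 0.20),
                         fmax = NULL) {
  structure(list(seed = as.integer(seed), humerus_length = humerus_length,
                 humerus_mass = humerus_mass, forearm_length = forearm_length,
                 forearm_mass = forearm_mass, thorax_mass = thorax_mass,
                 shoulder_offset = as.numeric(shoulder_offset), fmax = fmax),
            class = "fixture_spec")
}

# 14 shoulder-crossing actuators: origin offsets from the shoulder center
# (thorax frame) and insertions on the humerus (local frame), with plausible
# peak isometric forces. x forward, y up, z right-lateral.
fixture_muscle_table <- function() {
  m <- rbind(
    supraspinatus = c(-0.030,  0.025, -0.070,  0.000, -0.015,  0.020,  487),
    infraspinatus = c(-0.060, -0.010, -0.080, -0.015, -0.025,  0.015, 1210),
    subscapularis = c(-0.020, -0.010, -0.080,  0.020, -0.020,  0.000, 1378),
    teres_minor   = c(-0.060, -0.040, -0.060, -0.015, -0.035,  0.010,  354),
    teres_major   = c(-0.070, -0.080, -0.050,  0.010, -0.060, -0.010,  425),
    delt_ant      = c( 0.020,  0.020, -0.010,  0.015, -0.080,  0.005, 1147),
    delt_mid      = c( 0.000,  0.030,  0.010,  0.000, -0.080,  0.015, 1325),
    delt_post     = c(-0.040,  0.010,  0.000, -0.010, -0.080,  0.010,  896),
    pec_maj_c     = c( 0.050,  0.010, -0.150,  0.020, -0.040, -0.005,  364),
    pec_maj_s     = c( 0.060, -0.030, -0.180,  0.020, -0.050, -0.005,  516),
    pec_maj_r     = c( 0.050, -0.100, -0.160,  0.020, -0.055, -0.005,  390),
    lat_dorsi_t   = c(-0.070, -0.100, -0.120,  0.000, -0.050, -0.015,  290),
    lat_dorsi_l   = c(-0.060, -0.160, -0.100,  0.005, -0.055, -0.015,  317),
    lat_dorsi_i   = c(-0.050, -0.200, -0.080,  0.005, -0.060, -0.015,  189))
  colnames(m) <- c("ox", "oy", "oz", "ix", "iy", "iz", "fmax")
  m
}

make_box_mesh <- function(center = c(0, 0, 0), dims = c(0.06, 0.3, 0.06)) {
  h <- dims / 2
  corners <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  dimnames(corners) <- NULL
  v <- sweep(corners * rep(h, each = 8), 2, center, `+`)
  # outward-wound faces of the unit box (indices into expand.grid order)
  f <- rbind(c(1, 7, 3), c(1, 5, 7),
             c(2, 4, 8), c(2, 8, 6),
             c(1, 6, 5), c(1, 2, 6),
             c(3, 8, 4), c(3, 7, 8),
             c(1, 4, 2), c(1, 3, 4),
             c(5, 8, 7), c(5, 6, 8))
  tri_mesh(v, f)
}

deg <- function(x) x * pi / 180

#' Generate the canonical unilateral fixture model
#'
#' A right-side-only model: thorax welded to ground; a 3-rotation custom
#' shoulder joint (plane of elevation about y — 0 deg abduction, 90 deg
#' forward flexion —, elevation, axial rotation); an elbow custom joint
#' carrying elbow flexion plus locked wrist-flexion and pronation/supination
#' coordinates; and the 14 shoulder-crossing actuators of
#' `fixture_muscle_table()`, each with a usable moment arm about at least
#' one shoulder coordinate. Display-mesh references point at simple box
#' meshes, written when `dir` is given.
#'
#' @param spec a [fixture_spec()].
#' @param dir optional directory; when given, `model.osim` and the `.vtp`
#'   box meshes are written there.
#' @return a [model_def()] (right side only).
#' @export
make_unilateral_fixture <- function(spec = fixture_spec(), dir = NULL) {
  sh <- spec$shoulder_offset
  lh <- spec$humerus_length
  lf <- spec$forearm_length
  thorax <- body_def("thorax", spec$thorax_mass, com = c(0, 0, 0),
                     inertia = c(1.0, 0.6, 1.0, 0, 0, 0),
                     mesh_refs = list(list(file = "thorax.vtp",
                                           scale = c(1, 1, 1))))
  humerus <- body_def("humerus_r", spec$humerus_mass, com = c(0, -lh / 2, 0),
                      inertia = c(spec$humerus_mass * lh^2 / 12, 0.002,
                                  spec$humerus_mass * lh^2 / 12, 0, 0, 0),
                      mesh_refs = list(list(file = "humerus_r.vtp",
                                            scale = c(1, 1, 1))))
  forearm <- body_def("forearm_hand_r", spec$forearm_mass,
                      com = c(0, -0.6 * lf, 0),
                      inertia = c(spec$forearm_mass * lf^2 / 12, 0.002,
                                  spec$forearm_mass * lf^2 / 12, 0, 0, 0),
                      mesh_refs = list(list(file = "forearm_hand_r.vtp",
                                            scale = c(1, 1, 1))))
  ground_joint <- joint_def("ground_thorax", "WeldJoint", parent = "ground",
                            child = "thorax")
  shoulder <- joint_def(
    "shoulder_r", "CustomJoint", parent = "thorax", child = "humerus_r",
    location_in_parent = sh,
    coordinates = list(
      coordinate_def("elv_angle_r", range = deg(c(-95, 130))),
      coordinate_def("shoulder_elv_r", range = deg(c(-10, 180))),
      coordinate_def("shoulder_rot_r", range = deg(c(-90, 90)))),
    spatial_transform = list(
      transform_axis("rotation1", c(0, 1, 0), "elv_angle_r"),
      transform_axis("rotation2", c(-1, 0, 0), "shoulder_elv_r"),
      transform_axis("rotation3", c(0, 1, 0), "shoulder_rot_r"),
      transform_axis("translation1", c(1, 0, 0)),
      transform_axis("translation2", c(0, 1, 0)),
      transform_axis("translation3", c(0, 0, 1))))
  elbow <- joint_def(
    "elbow_r", "CustomJoint", parent = "humerus_r", child = "forearm_hand_r",
    location_in_parent = c(0, -lh, 0),
    coordinates = list(
      coordinate_def("elbow_flexion_r", range = deg(c(0, 150))),
      coordinate_def("wrist_flex_r", range = deg(c(-70, 70)), locked = TRUE),
      coordinate_def("pro_sup_r", range = deg(c(-90, 90)), locked = TRUE)),
    spatial_transform = list(
      transform_axis("rotation1", c(0, 0, 1), "elbow_flexion_r"),
      transform_axis("rotation2", c(1, 0, 0), "wrist_flex_r"),
      transform_axis("rotation3", c(0, 1, 0), "pro_sup_r"),
      transform_axis("translation1", c(1, 0, 0)),
      transform_axis("translation2", c(0, 1, 0)),
      transform_axis("translation3", c(0, 0, 1))))
  tab <- fixture_muscle_table()
  muscles <- lapply(rownames(tab), function(nm) {
    fx <- tab[nm, "fmax"]
    if (!is.null(spec$fmax) && nm %in% names(spec$fmax)) fx <- spec$fmax[[nm]]
    muscle_def(paste0(nm, "_r"), fx,
               path = list(path_point("thorax", sh + tab[nm, c("ox", "oy", "oz")]),
                           path_point("humerus_r", tab[nm, c("ix", "iy", "iz")])))
  })
  model <- model_def("mini_upper_limb_r",
                     bodies = list(thorax, humerus, forearm),
                     joints = list(ground_joint, shoulder, elbow),
                     muscles = muscles)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_mesh(make_box_mesh(c(0, 0.1, 0), c(0.2, 0.5, 0.3)),
               file.path(dir, "thorax.vtp"))
    write_mesh(make_box_mesh(c(0, -lh / 2, 0), c(0.06, lh, 0.06)),
               file.path(dir, "humerus_r.vtp"))
    write_mesh(make_box_mesh(c(0, -lf / 2, 0), c(0.05, lf, 0.05)),
               file.path(dir, "forearm_hand_r.vtp"))
    write_model(model, file.path(dir, "model.osim"))
  }
  model
}

#' Mirrored task kinematics with optional noise
#'
#' Renders a task for the right side, mirrors it to the left (sign-absorbed
#' convention, see [mirror_joint_angles()]), and optionally perturbs the
#' left table with additive Gaussian noise — the synthetic analogue of the
#' rounding noise a motion-capture mirroring workflow introduces, for
#' RMSE-sensitivity checks.
#'
#' @param task a [task_definition()].
#' @param noise_sd noise standard deviation (deg), default 0.
#' @param seed RNG seed used when `noise_sd > 0`.
#' @param convention a [mirror_convention()].
#' @return list with `left` and `right` [motion_table()]s (degrees).
#' @export
make_symmetric_kinematics <- function(task, noise_sd = 0, seed = 1L,
                                      convention = mirror_convention()) {
  right <- task_to_motion(task, sides = convention$suffix_pairs[[1]][1],
                          convention = convention)
  left <- mirror_joint_angles(right, convention = convention)
  if (noise_sd > 0) {
    vals <- left$values
    vals[] <- vals + withr_rnorm(seed, length(vals), sd = noise_sd)
    left <- motion_table(left$time, vals, in_degrees = left$in_degrees,
                         name = left$name)
  }
  list(left = left, right = right)
}

# seed-local normal draws without disturbing the caller's RNG state
withr_rnorm <- function(seed, n, sd) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  stats::rnorm(n, sd = sd)
}
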