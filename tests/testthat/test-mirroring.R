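conv <- mirror_convention()

test_that("point reflection fixes the plane and is an involution", {
  expect_identical(mirror_point(c(0, 0, 0)), c(0, 0, 0))
  expect_identical(mirror_point(c(0.1, 0.2, 0.05)), c(0.1, 0.2, -0.05))
  set.seed(11)
  for (i in 1:20) {
    p <- stats::rnorm(3)
    expect_identical(mirror_point(mirror_point(p)), p)
  }
  # configurable axis
  expect_identical(mirror_point(c(0.2, 1.1, 0.3), mirror_convention("x")),
                   c(-0.2, 1.1, 0.3))
})

test_that("mesh mirroring preserves signed volume and winding sanity", {
  tet <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                  rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4)))
  m <- mirror_mesh(tet)
  expect_equal(oracle_signed_volume(m), oracle_signed_volume(tet),
               tolerance = 1e-12)
  # double mirror: vertices bit-equal, faces equal up to winding rotation
  dd <- mirror_mesh(m)
  expect_identical(dd$vertices, tet$vertices)
  expect_identical(dd$faces, tet$faces)
  # flat triangle in the sagittal plane: vertices unchanged, winding reversed
  flat <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                   rbind(c(1, 2, 3)))
  fm <- mirror_mesh(flat)
  expect_identical(fm$vertices, flat$vertices)
  expect_identical(fm$faces, matrix(c(1L, 3L, 2L), 1))
})

test_that("orientation mirroring is the reflection conjugation", {
  expect_equal(mirror_orientation(c(0, 0, 0)), c(0, 0, 0))
  # oracle: conjugate the rotation matrix directly
  M <- diag(c(1, 1, -1))
  for (e in list(c(0.3, -0.1, 0.5), c(-1.2, 0.4, 2.0), c(0.01, 1.5, -0.7))) {
    R2 <- M %*% (rot_x(e[1]) %*% rot_y(e[2]) %*% rot_z(e[3])) %*% M
    got <- mirror_orientation(e)
    Rgot <- rot_x(got[1]) %*% rot_y(got[2]) %*% rot_z(got[3])
    expect_equal(Rgot, R2, tolerance = 1e-12)
    expect_equal(det(Rgot), 1, tolerance = 1e-12)
  }
  # closed form for the z-normal convention: (a, b, c) -> (-a, -b, c)
  expect_equal(mirror_orientation(c(0.3, -0.1, 0.5)), c(-0.3, 0.1, 0.5),
               tolerance = 1e-12)
  # pure z rotations are preserved: M Rz M = Rz
  expect_equal(mirror_orientation(c(0, 0, 1.1)), c(0, 0, 1.1),
               tolerance = 1e-12)
})

test_that("inertia mirroring negates the z-products and keeps eigenvalues", {
  I1 <- inertia_to_matrix(c(0.02, 0.03, 0.025, 0.002, 0.01, -0.004))
  I2 <- mirror_inertia(I1)
  expect_equal(I2[1, 3], -I1[1, 3])
  expect_equal(I2[2, 3], -I1[2, 3])
  expect_equal(I2[1, 2], I1[1, 2])
  expect_equal(diag(I2), diag(I1))
  expect_equal(eigen(I2, symmetric = TRUE)$values,
               eigen(I1, symmetric = TRUE)$values, tolerance = 1e-12)
  expect_equal(mirror_inertia(I2), I1, tolerance = 1e-15)
  Idiag <- diag(c(1, 2, 3))
  expect_equal(mirror_inertia(Idiag), Idiag)
  expect_error(mirror_inertia(matrix(1:9, 3)), "symmetric")
})

test_that("body mirroring renames, mirrors com/inertia, preserves mass", {
  b <- body_def("humerus_r", 1.99, com = c(0, -0.18, 0.01),
                inertia = c(0.01, 0.002, 0.01, 0, 0.001, 0),
                mesh_refs = list(list(file = "humerus.vtp", scale = c(1, 1, 1))))
  bl <- mirror_body(b)
  expect_identical(bl$name, "humerus_l")
  expect_identical(bl$mass, 1.99)
  expect_identical(bl$com, c(0, -0.18, -0.01))
  expect_identical(bl$mesh_refs[[1]]$file, "humerus_mirrored.vtp")
  expect_equal(mirror_body(bl), b, tolerance = 1e-15)
})

test_that("joint and muscle mirroring are involutions at tight tolerance", {
  for (j in fix_unilateral$joints) {
    back <- mirror_joint(mirror_joint(j))
    attr(back, "axis_flips") <- NULL
    expect_equal(back, j, tolerance = 1e-12)
  }
  for (mu in fix_unilateral$muscles) {
    expect_equal(mirror_muscle(mirror_muscle(mu)), mu, tolerance = 1e-15)
    ml <- mirror_muscle(mu)
    expect_identical(ml$max_isometric_force, mu$max_isometric_force)
  }
  # z-axis coordinates keep their axis; off-plane axes flip, sign kept
  sh <- mirror_joint(fix_unilateral$joints$shoulder_r)
  ax <- lapply(sh$spatial_transform, `[[`, "axis")
  expect_equal(ax[[1]], c(0, -1, 0))   # plane of elevation (about y): flipped
  expect_equal(ax[[2]], c(1, 0, 0))    # elevation (about x here): flipped
  expect_equal(ax[[3]], c(0, -1, 0))   # axial rotation: flipped
  el <- mirror_joint(fix_unilateral$joints$elbow_r)
  expect_equal(el$spatial_transform[[1]]$axis, c(0, 0, 1))  # flexion about z
  # ranges and defaults are untouched under the sign-absorbing policy
  expect_equal(sh$coordinates$shoulder_elv_l$range,
               fix_unilateral$joints$shoulder_r$coordinates$shoulder_elv_r$range)
})

test_that("the bilateral build doubles the sided components once", {
  expect_length(fix_bilateral$muscles, 28)
  expect_length(fix_bilateral$bodies, 5)        # thorax shared
  expect_length(free_coordinates(fix_bilateral), 8)
  # total mass = trunk + 2 x limb
  limb <- fix_unilateral$bodies$humerus_r$mass +
    fix_unilateral$bodies$forearm_hand_r$mass
  expect_equal(sum(vapply(fix_bilateral$bodies, `[[`, 0, "mass")),
               fix_unilateral$bodies$thorax$mass + 2 * limb)
  # a two-sided model is rejected with the collision list
  expect_error(build_bilateral(fix_bilateral), "collision")
})

test_that("forward kinematics of the bilateral model is mirror-symmetric", {
  hands <- c(r = "forearm_hand_r", l = "forearm_hand_l")
  for (q in random_poses(fix_bilateral, 8, seed = 7)) {
    # same values on both sides: make the pose symmetric
    qs <- q
    qs[map_side_name(names(q)[endsWith(names(q), "_r")], conv)] <-
      q[endsWith(names(q), "_r")]
    X <- body_transforms(fix_bilateral, qs)
    pr <- point_in_ground(X, hands["r"],
                          fix_bilateral$bodies$forearm_hand_r$com)
    pl <- point_in_ground(X, hands["l"],
                          fix_bilateral$bodies$forearm_hand_l$com)
    expect_lt(max(abs(pr - c(1, 1, -1) * pl)), 1e-9)
    # muscle-length symmetry for every actuator pair
    len <- muscle_lengths(fix_bilateral, qs)
    rn <- names(len)[endsWith(names(len), "_r")]
    expect_lt(max(abs(len[rn] - len[map_side_name(rn, conv)])), 1e-9)
  }
})

test_that("mirrored left/right twins have equal moment-arm magnitudes", {
  r <- moment_arms(fix_bilateral, pose_low)
  rn <- rownames(r)[endsWith(rownames(r), "_r")]
  for (nm in rn) {
    twin <- map_side_name(nm, conv)
    rc <- colnames(r)[endsWith(colnames(r), "_r")]
    expect_equal(abs(r[nm, rc]),
                 abs(r[twin, map_side_name(rc, conv)]),
                 tolerance = 1e-7, ignore_attr = TRUE)
  }
})

test_that("bilateral build mirrors mesh files on request", {
  dir <- withr::local_tempdir()
  make_unilateral_fixture(dir = dir)
  build_bilateral(read_model(file.path(dir, "model.osim")), mesh_dir = dir)
  expect_true(file.exists(file.path(dir, "humerus_r_mirrored.vtp")))
  m0 <- read_mesh(file.path(dir, "humerus_r.vtp"))
  m1 <- read_mesh(file.path(dir, "humerus_r_mirrored.vtp"))
  expect_equal(oracle_signed_volume(m1), oracle_signed_volume(m0),
               tolerance = 1e-12)
})
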