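test_that("moment arms reproduce pulley geometry", {
  # straight muscle passing a hinge at perpendicular distance 0.03 m
  hinge <- make_hinge_model(list(list(origin = c(-0.2, 0.03, 0),
                                      insertion = c(0.2, 0.03, 0),
                                      fmax = 1000)))
  r <- moment_arms(hinge, c(theta = 0))
  expect_equal(unname(r["mus1", "theta"]), 0.03, tolerance = 1e-4)
  # a path through the joint center has no moment arm
  through <- make_hinge_model(list(list(origin = c(-0.2, 0, 0),
                                        insertion = c(0.2, 0, 0),
                                        fmax = 1000)))
  expect_lt(abs(moment_arms(through, c(theta = 0))["mus1", "theta"]), 1e-8)
})

test_that("gravity demand matches closed form and the energy oracle", {
  # point mass at horizontal distance d: tau = m g d
  m <- 2.5; d <- 0.4
  hinge <- make_hinge_model(list(list(origin = c(-0.2, 0.03, 0),
                                      insertion = c(0.2, 0.03, 0),
                                      fmax = 1000)),
                            link_mass = m, link_com = c(d, 0, 0))
  tau <- static_torques(hinge, c(theta = 0))
  expect_equal(unname(tau["theta"]), m * 9.80665 * d, tolerance = 1e-6)
  # hanging vertically: no elevation demand
  tau0 <- static_torques(hinge, c(theta = -pi / 2))
  expect_lt(abs(tau0["theta"]), 1e-8)
  # multi-segment fixture posture vs potential-energy finite differences
  bal <- balance_coordinates(fix_bilateral)
  got <- static_torques(fix_bilateral, pose_low, bal)
  want <- oracle_gravity_demand(fix_bilateral, pose_low, bal)
  expect_equal(got, want, tolerance = 1e-6)
  expect_lt(max(abs(got - want)), 1e-8 * max(1, max(abs(want))))
})

test_that("solve_step handles the canonical closed-form instances", {
  # zero demand: all activations zero, zero slack
  hinge <- make_hinge_model(list(list(origin = c(-0.2, 0.03, 0),
                                      insertion = c(0.2, 0.03, 0),
                                      fmax = 1000)))
  s0 <- solve_step(hinge, c(theta = 0), tau = c(theta = 0))
  expect_equal(unname(s0$activations), 0, tolerance = 1e-9)
  expect_equal(unname(s0$slack), 0, tolerance = 1e-9)
  expect_true(s0$feasible)
  # single muscle, r = 0.02, Fmax = 1000, tau = 10 -> a = 0.5
  one <- make_hinge_model(list(list(origin = c(-0.2, 0.02, 0),
                                    insertion = c(0.2, 0.02, 0),
                                    fmax = 1000)))
  s1 <- solve_step(one, c(theta = 0), tau = c(theta = 10))
  expect_equal(unname(s1$activations), 0.5, tolerance = 1e-3)
  # two identical parallel muscles split the demand evenly
  two <- make_hinge_model(rep(list(list(origin = c(-0.2, 0.02, 0),
                                        insertion = c(0.2, 0.02, 0),
                                        fmax = 1000)), 2))
  s2 <- solve_step(two, c(theta = 0), tau = c(theta = 10))
  expect_equal(unname(s2$activations), c(0.25, 0.25), tolerance = 1e-3)
  # demand beyond capacity saturates and the slack carries the deficit
  s3 <- solve_step(one, c(theta = 0), tau = c(theta = 30))
  expect_equal(unname(s3$activations), 1, tolerance = 1e-3)
  expect_equal(unname(s3$slack), 30 - 0.02 * 1000, tolerance = 0.05)
  expect_false(s3$feasible)
})

test_that("the QP matches exhaustive grid search on small instances", {
  cases <- list(
    list(B = matrix(c(0.02 * 1000, 0.02 * 1000), 1), tau = 10),
    list(B = matrix(c(30, 12), 1), tau = 8),
    list(B = matrix(c(25, -10, 14, 22), 2), tau = c(6, 3)),
    list(B = matrix(c(18, 5, -4, 11, 9, 16), 2, 3), tau = c(5, 7)),
    list(B = matrix(c(12, 20, 8), 1, 3), tau = 35))   # near saturation
  for (cs in cases) {
    n <- ncol(cs$B)
    C <- rbind(diag(n), sqrt(1e6) * cs$B)
    b <- c(numeric(n), sqrt(1e6) * cs$tau)
    got <- bimanum:::solve_box_ls(C, b, rep(0, n), rep(1, n))
    want <- grid_search_qp(cs$B, cs$tau)
    expect_lt(max(abs(got - want)), 2e-3)
  }
})

test_that("the QP agrees with an independent quadratic-program solver", {
  skip_if_not_installed("pracma")
  set.seed(21)
  for (i in 1:5) {
    # moderate slack weight keeps the cross-solver's factorization stable
    n <- 6; k <- 3; w <- 1e4
    B <- matrix(stats::rnorm(k * n, sd = 15), k, n)
    tau <- stats::rnorm(k, sd = 8)
    C <- rbind(diag(n), sqrt(w) * B)
    b <- c(numeric(n), sqrt(w) * tau)
    got <- bimanum:::solve_box_ls(C, b, rep(0, n), rep(1, n))
    ref <- pracma::quadprog(2 * crossprod(C), -2 * drop(crossprod(C, b)),
                            lb = rep(0, n), ub = rep(1, n))$xmin
    expect_lt(max(abs(got - ref)), 1e-5)
  }
})

test_that("torque balance holds to numerical identity on the fixture", {
  ml <- make_shared_load(fix_bilateral, 44.5)
  for (q in list(pose_low, c(elv_angle_r = 80, shoulder_elv_r = 130,
                             elv_angle_l = 80, shoulder_elv_l = 130) * pi / 180)) {
    geom <- bimanum:::solver_geometry(ml, q)
    st <- solve_step(ml, geometry = geom)
    fmax <- vapply(ml$muscles, `[[`, 0, "max_isometric_force")
    lhs <- drop(t(geom$R) %*% (fmax * st$activations)) + st$slack
    expect_lt(max(abs(lhs - st$tau)), 1e-8)
    expect_true(st$feasible)
  }
})

test_that("symmetric tasks recruit both sides identically at severity none", {
  ml <- make_shared_load(fix_bilateral, 13.3)
  st <- solve_step(ml, pose_low)
  rn <- grep("_r$", names(st$activations), value = TRUE)
  ln <- map_side_name(rn, mirror_convention())
  expect_lt(max(abs(st$activations[rn] - st$activations[ln])), 1e-9)
  # load sharing: left + right support sums to the load's gravity wrench
  mg <- 13.3
  expect_equal(st$left_wrench + st$right_wrench, c(0, mg, 0, 0, 0, 0),
               tolerance = 1e-9)
})

test_that("slack maps to deviation with the directions gravity dictates", {
  ml <- make_shared_load(fix_bilateral, 44.5)
  geom <- bimanum:::solver_geometry(ml, pose_low)
  bal <- geom$coords
  # feasible step: exactly zero deviation
  st <- solve_step(ml, geometry = geom)
  expect_identical(load_deviation(ml, pose_low, st$slack, geometry = geom),
                   c(0, 0, 0))
  # a pure bilateral elevation deficit drops the load: strictly inferior
  s_elev <- stats::setNames(numeric(length(bal)), bal)
  s_elev[c("shoulder_elv_r", "shoulder_elv_l")] <- 5
  dev <- load_deviation(ml, pose_low, s_elev, geometry = geom)
  expect_lt(dev[2], 0)
  expect_equal(dev[3], 0, tolerance = 1e-9)
  # sign analysis: the gravity Jacobian raises the load with elevation,
  # so unmet elevation demand must lower it
  expect_gt(geom$Jload[2, "shoulder_elv_r"] + geom$Jload[2, "shoulder_elv_l"], 0)
  # an injured-(right-)side-only deficit also pushes toward the unaffected side
  s_r <- stats::setNames(numeric(length(bal)), bal)
  s_r["shoulder_elv_r"] <- 5
  dev_r <- load_deviation(ml, pose_low, s_r, geometry = geom)
  expect_lt(dev_r[2], 0)
  expect_lt(dev_r[3], 0)
})

test_that("task simulation is deterministic and honours degenerate limits", {
  ml <- make_shared_load(fix_bilateral, 13.3)
  task <- make_static_task("low", duration = 2, rate = 25)
  r1 <- simulate_task(ml, task)
  r2 <- simulate_task(ml, task)
  expect_identical(r1$activations, r2$activations)
  expect_identical(r1$load_com, r2$load_com)
  expect_true(all(r1$feasible))
  # zero gravity: nothing to hold, nothing recruited
  m0 <- ml
  m0$gravity <- c(0, 0, 0)
  r0 <- simulate_task(m0, task)
  expect_lt(max(abs(r0$activations)), 1e-9)
})

test_that("the elbow, uncrossed by any actuator, is excluded from balance", {
  bal <- balance_coordinates(fix_bilateral)
  expect_setequal(bal, c("elv_angle_r", "shoulder_elv_r", "shoulder_rot_r",
                         "elv_angle_l", "shoulder_elv_l", "shoulder_rot_l"))
})
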