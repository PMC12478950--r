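fs <- 100
tgrid <- seq(0, 20, by = 1 / fs)
mk_table <- function(x, deg = FALSE)
  motion_table(tgrid, cbind(sig = x), in_degrees = deg)
filt <- function(x, spec = filter_spec())
  butterworth_lowpass(mk_table(x), spec)$values[, 1]

test_that("the low-pass filter has unit DC gain and half gain at cutoff", {
  expect_equal(filt(rep(80, length(tgrid))), rep(80, length(tgrid)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # dual-pass amplitude at the cutoff frequency: |H|^2 = 0.5
  y <- filt(sin(2 * pi * 6 * tgrid))
  mid <- tgrid > 5 & tgrid < 15
  expect_equal(sqrt(2 * mean(y[mid]^2)), 0.5, tolerance = 0.01)
  # well below cutoff passes almost untouched, white noise is attenuated
  y1 <- filt(sin(2 * pi * 0.5 * tgrid))
  expect_equal(sqrt(2 * mean(y1[mid]^2)), 1, tolerance = 0.01)
  set.seed(4)
  noise <- stats::rnorm(length(tgrid))
  expect_lt(stats::var(filt(noise)), stats::var(noise))
})

test_that("filtering is linear and time is untouched", {
  x1 <- sin(2 * pi * 1.5 * tgrid)
  x2 <- cos(2 * pi * 4 * tgrid) + 0.3
  lhs <- filt(2 * x1 - 5 * x2)
  rhs <- 2 * filt(x1) - 5 * filt(x2)
  expect_lt(max(abs(lhs - rhs)), 1e-9)
  out <- butterworth_lowpass(mk_table(x1))
  expect_identical(out$time, tgrid)
})

test_that("filter preconditions are enforced", {
  expect_error(butterworth_lowpass(mk_table(tgrid), filter_spec(cutoff = 60)),
               "Nyquist")
  short <- motion_table(0:5 / 100, cbind(a = 1:6))
  expect_error(butterworth_lowpass(short), "too short")
  irregular <- motion_table(c(0, 0.01, 0.5, 1, 2, 2.01, 3, 4, 5, 6, 7, 8, 9),
                            cbind(a = 1:13))
  expect_error(butterworth_lowpass(irregular), "uniform")
  expect_error(filter_spec(order = 3), "even")
})

test_that("marker mirroring negates exactly the stated lab axis", {
  mk <- motion_table(c(0, 0.1), rbind(c(0.2, 1.1, 0.3), c(0.2, 1.1, 0.3)) |>
                       `colnames<-`(c("ACR_x", "ACR_y", "ACR_z")),
                     in_degrees = FALSE)
  mm <- mirror_markers(mk, "x")
  expect_equal(unname(mm$values[1, ]), c(-0.2, 1.1, 0.3))
  # a marker on the mirror plane is unchanged
  mk0 <- motion_table(c(0, 0.1), matrix(c(0, 0, 1, 1, 0.3, 0.3), 2,
                                        dimnames = list(NULL, c("M_x", "M_y", "M_z"))))
  expect_equal(mirror_markers(mk0, "x")$values[, "M_x"], c(0, 0))
  # involution
  expect_equal(mirror_markers(mm, "x")$values, mk$values)
})

test_that("joint-angle mirroring renames and applies the sign map", {
  tab <- motion_table(c(0, 1), cbind(shoulder_elv_r = c(80, 80),
                                     shoulder_rot_r = c(-45, -45)))
  out <- mirror_joint_angles(tab)
  expect_identical(colnames(out$values), c("shoulder_elv_l", "shoulder_rot_l"))
  expect_equal(unname(out$values[, "shoulder_elv_l"]), c(80, 80))
  out2 <- mirror_joint_angles(tab, sign_map = c(shoulder_rot_r = -1))
  expect_equal(unname(out2$values[, "shoulder_rot_l"]), c(45, 45))
  # involution (sign map expressed for the renamed columns on the way back)
  back <- mirror_joint_angles(out2, sign_map = c(shoulder_rot_l = -1))
  expect_equal(back$values, tab$values)
})

test_that("rmse matches hand computations and is a metric-like score", {
  expect_identical(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(5, 5, 5), c(3, 3, 3)), 2)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_equal(rmse(c(3, 4), c(0, 0)), rmse(c(0, 0), c(3, 4)))
  expect_error(rmse(1:3, 1:4), "lengths differ")
})

test_that("symmetry verification reports per-DOF RMSE with a pass flag", {
  vt <- make_verification_tasks()
  kin <- make_symmetric_kinematics(vt$dynamic)
  rep0 <- verify_bilateral_symmetry(fix_bilateral, kin$left, kin$right)
  expect_true(attr(rep0, "pass"))
  expect_true(all(rep0$rmse < 1e-9))
  expect_setequal(rep0$coordinate_right,
                  c("elv_angle_r", "shoulder_elv_r", "shoulder_rot_r",
                    "elbow_flexion_r", "wrist_flex_r", "pro_sup_r"))
  # 0.5 deg of one-sided noise comes back as ~0.5 deg RMSE
  kin5 <- make_symmetric_kinematics(vt$dynamic, noise_sd = 0.5, seed = 99)
  rep5 <- verify_bilateral_symmetry(fix_bilateral, kin5$left, kin5$right)
  expect_true(all(abs(rep5$rmse - 0.5) < 0.1))
  expect_true(attr(rep5, "pass"))   # still under the 1.5 deg envelope
  # mismatched column sets are an error
  broken <- kin$left
  broken$values <- broken$values[, -1, drop = FALSE]
  expect_error(verify_bilateral_symmetry(fix_bilateral, broken, kin$right),
               "missing column")
})
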