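test_that("severity scale factors match the graded tear definitions", {
  none <- rct_severity("none")$scale
  partial <- rct_severity("partial")$scale
  full <- rct_severity("full")$scale
  massive <- rct_severity("massive")$scale
  expect_equal(none, c(supraspinatus = 1, infraspinatus = 1, subscapularis = 1))
  expect_equal(partial[["supraspinatus"]], 0.5)
  expect_equal(full[["supraspinatus"]], 0)
  expect_equal(full[["infraspinatus"]], 0.75)
  expect_equal(massive[["supraspinatus"]], 0)
  expect_equal(massive[["infraspinatus"]], 0.25)
  expect_equal(massive[["subscapularis"]], 0.5)
  # severities are ordered per muscle
  for (mu in names(none)) {
    expect_true(none[[mu]] >= partial[[mu]] &&
                partial[[mu]] >= full[[mu]] &&
                full[[mu]] >= massive[[mu]])
  }
})

test_that("apply_rct scales exactly the affected-side cuff from baseline", {
  m <- fix_bilateral
  base <- vapply(m$muscles, `[[`, 0, "max_isometric_force")
  expect_equal(base[["supraspinatus_r"]], 487)
  mp <- apply_rct(m, "partial")
  expect_equal(mp$muscles$supraspinatus_r$max_isometric_force, 243.5)
  m0 <- apply_rct(m, "none")
  expect_equal(vapply(m0$muscles, `[[`, 0, "max_isometric_force"), base)
  mm <- apply_rct(m, "massive")
  expect_equal(mm$muscles$supraspinatus_r$max_isometric_force, 0)
  expect_equal(mm$muscles$infraspinatus_r$max_isometric_force,
               0.25 * base[["infraspinatus_r"]])
  expect_equal(mm$muscles$subscapularis_r$max_isometric_force,
               0.5 * base[["subscapularis_r"]])
  # mutation-diff: exactly the severity's muscles change, nothing else
  changed <- names(base)[vapply(names(base), function(nm)
    mm$muscles[[nm]]$max_isometric_force != base[[nm]], TRUE)]
  expect_setequal(changed, c("supraspinatus_r", "infraspinatus_r",
                             "subscapularis_r"))
  # contralateral side bit-equal to baseline
  left <- grep("_l$", names(base), value = TRUE)
  expect_identical(vapply(left, function(nm)
    mm$muscles[[nm]]$max_isometric_force, 0), base[left])
})

test_that("severities are absolute: re-application never compounds", {
  m <- apply_rct(fix_bilateral, "partial")
  m <- apply_rct(m, "partial")
  expect_equal(m$muscles$supraspinatus_r$max_isometric_force, 243.5)
  m <- apply_rct(m, "none")
  expect_equal(m$muscles$supraspinatus_r$max_isometric_force, 487)
  # injured-side capacity strictly decreases along the severity ladder
  caps <- vapply(c("none", "partial", "full", "massive"), function(s) {
    ms <- apply_rct(fix_bilateral, s)
    sum(vapply(c("supraspinatus_r", "infraspinatus_r", "subscapularis_r"),
               function(nm) ms$muscles[[nm]]$max_isometric_force, 0))
  }, 0)
  expect_true(all(diff(caps) < 0))
})

test_that("apply_rct names its failure modes", {
  expect_no_error(apply_rct(fix_bilateral, "full", side = "left"))
  # a right-only model has no left-side cuff to scale
  expect_error(apply_rct(fix_unilateral, "full", side = "left"),
               "supraspinatus_l")
})

test_that("the shared load is centred between the hands with mass W/g", {
  ml <- make_shared_load(fix_bilateral, 13.3)
  expect_equal(ml$bodies$shared_load$mass, 13.3 / 9.80665, tolerance = 1e-12)
  expect_equal(make_shared_load(fix_bilateral, 44.5)$bodies$shared_load$mass,
               4.537737, tolerance = 1e-6)
  X <- body_transforms(ml)
  pload <- point_in_ground(X, "shared_load", c(0, 0, 0))
  pl <- point_in_ground(X, "forearm_hand_l", ml$bodies$forearm_hand_l$com)
  pr <- point_in_ground(X, "forearm_hand_r", ml$bodies$forearm_hand_r$com)
  expect_equal(sqrt(sum((pload - pl)^2)), sqrt(sum((pload - pr)^2)),
               tolerance = 1e-12)
  expect_equal(pload, (pl + pr) / 2, tolerance = 1e-12)
  # the tracked load position stays the hand-COM midpoint under any
  # symmetric posture change
  X2 <- body_transforms(ml, pose_low)
  h2 <- (point_in_ground(X2, "forearm_hand_l", ml$bodies$forearm_hand_l$com) +
         point_in_ground(X2, "forearm_hand_r", ml$bodies$forearm_hand_r$com)) / 2
  expect_equal(shared_load_position(ml, pose_low), h2, tolerance = 1e-12)
  expect_equal(shared_load_position(ml), pload, tolerance = 1e-12)
  expect_error(make_shared_load(fix_bilateral, -5), ">= 0")
  expect_error(make_shared_load(fix_unilateral, 13.3), "hand")
})

test_that("a zero-weight load leaves the statics untouched", {
  m0 <- make_shared_load(fix_bilateral, 0)
  s_loaded <- solve_step(m0, pose_low)
  s_free <- solve_step(fix_bilateral, pose_low)
  expect_equal(s_loaded$activations, s_free$activations, tolerance = 1e-9)
  expect_equal(s_loaded$forces, s_free$forces, tolerance = 1e-9)
})
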