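# Shared fixtures and independent oracles for the test suite.

# canonical models, built once per test run
fix_unilateral <- make_unilateral_fixture()
fix_bilateral <- build_bilateral(fix_unilateral)

# a symmetric elevated pose (rad) used by several solver tests
pose_low <- c(elv_angle_r = 80, shoulder_elv_r = 80,
              elv_angle_l = 80, shoulder_elv_l = 80) * pi / 180

# single-hinge toy model: one rotational DOF about z at the origin,
# a link hanging along -y, and point-to-point muscles supplied by the caller
# as list(origin = ground point, insertion = link-local point, fmax).
make_hinge_model <- function(muscles, link_mass = 0, link_com = c(0, -0.5, 0)) {
  link <- body_def("link", link_mass, com = link_com)
  j <- joint_def("hinge", "CustomJoint", parent = "ground", child = "link",
                 coordinates = list(coordinate_def("theta",
                                                   range = c(-pi, pi))),
                 spatial_transform = list(
                   transform_axis("rotation1", c(0, 0, 1), "theta")))
  mus <- lapply(seq_along(muscles), function(i) {
    m <- muscles[[i]]
    muscle_def(paste0("mus", i), m$fmax,
               path = list(path_point("ground", m$origin),
                           path_point("link", m$insertion)))
  })
  model_def("hinge", bodies = list(link), joints = list(j), muscles = mus)
}

# brute-force grid minimizer for the heavily-penalized redundancy program:
# in the large-slack-weight limit the solution first minimizes the torque
# residual ||B a - tau|| and then the effort sum(a^2) among the (grid)
# points that tie for it up to grid resolution. Coarse pass, then local
# refinement at `step` (valid: both criteria are convex). Independent of
# the package's solver.
grid_search_qp <- function(B, tau, step = 1e-3) {
  B <- as.matrix(B)
  n <- ncol(B)
  bnorm <- sqrt(sum(B^2))
  pass <- function(center, half, st) {
    grids <- lapply(seq_len(n), function(i) {
      g <- seq(center[i] - half, center[i] + half, by = st)
      unique(pmin(1, pmax(0, g)))
    })
    A <- as.matrix(expand.grid(grids))
    dimnames(A) <- NULL
    resid <- sqrt(colSums((B %*% t(A) - tau)^2))
    keep <- resid <= min(resid) + st * bnorm
    Ak <- A[keep, , drop = FALSE]
    as.numeric(Ak[which.min(rowSums(Ak^2)), ])
  }
  coarse <- pass(rep(0.5, n), 0.5, if (n <= 2) 0.005 else 0.02)
  mid <- pass(coarse, if (n <= 2) 0.01 else 0.04, step)
  # final sweep well below the comparison tolerance so the oracle's own
  # grid noise cannot mask a solver error
  pass(mid, 6 * step, step / 8)
}

# signed tetra-sum volume, duplicated here as an independent check of
# mesh_signed_volume's role in the mirroring tests
oracle_signed_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  tot <- 0
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; cc <- v[f[i, 3], ]
    tot <- tot + (a[1] * (b[2] * cc[3] - b[3] * cc[2]) -
                  a[2] * (b[1] * cc[3] - b[3] * cc[1]) +
                  a[3] * (b[1] * cc[2] - b[2] * cc[1]))
  }
  tot / 6
}

# potential-energy finite-difference oracle for gravity torque demand
oracle_gravity_demand <- function(model, q, coords, h = 1e-6) {
  pot <- function(p) {
    X <- body_transforms(model, p)
    -sum(vapply(model$bodies, function(b)
      b$mass * sum(model$gravity *
                     point_in_ground(X, b$name, b$com)), 0))
  }
  pose <- full_pose(model, q)
  vapply(coords, function(cn) {
    qp <- pose; qp[cn] <- qp[cn] + h
    qm <- pose; qm[cn] <- qm[cn] - h
    (pot(qp) - pot(qm)) / (2 * h)
  }, 0)
}

random_poses <- function(model, n, seed) {
  set.seed(seed)
  coords <- model_coordinates(model)
  free <- free_coordinates(model)
  lapply(seq_len(n), function(i) {
    vapply(stats::setNames(nm = free), function(cn) {
      r <- coords[[cn]]$range
      stats::runif(1, r[1] + 0.05 * diff(r), r[2] - 0.05 * diff(r))
    }, 0)
  })
}
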