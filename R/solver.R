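# Reduced-order muscle-redundancy solver: a per-time-step stand-in for a
# tracking controller. At each pose it computes the gravity (+ shared load)
# torque demand on the muscle-actuated coordinates and resolves redundancy
# by bounded static optimization,
#
#   minimize  sum_i a_i^2  +  w ||tau_slack||^2  +  eps P(c)
#   subject to  sum_i r_ij Fmax_i a_i + tau_slack_j = tau_j(c),  0 <= a <= 1,
#
# where c is the free 6-component interaction wrench transmitted through the
# weld constraint at the second hand and P(c) is a small mirror-invariant
# tie-break penalizing both stations' deviation from the symmetric
# half-weight, zero-couple share. The slack carries any demand the
# saturated actuators cannot meet. The program is strictly convex; the
# minimizer is unique and found exactly by an active-set box-constrained
# least-squares solve.

# joints on the chain from ground to a body
body_chain_joints <- function(model, body) {
  joints_by_child <- stats::setNames(model$joints,
                                     vapply(model$joints, `[[`, "", "child"))
  out <- character(0)
  while (body != "ground") {
    j <- joints_by_child[[body]]
    if (is.null(j)) break
    out <- c(out, j$name)
    body <- j$parent
  }
  out
}

#' Muscle-actuated balance coordinates
#'
#' The unlocked coordinates whose joints are structurally crossed by at
#' least one muscle path. Torque balance is enforced on these; coordinates
#' no muscle can act on (e.g. an elbow in a shoulder-actuator-only model)
#' are treated as externally supported, the reduced analogue of a tracking
#' controller's reserve actuators at non-analysed degrees of freedom.
#'
#' @param model a [model_def()].
#' @return character vector of coordinate names.
#' @export
balance_coordinates <- function(model) {
  chains <- lapply(stats::setNames(nm = c("ground", names(model$bodies))),
                   function(b) body_chain_joints(model, b))
  crossed <- character(0)
  for (mu in model$muscles) {
    bs <- vapply(mu$path, `[[`, "", "body")
    for (i in seq_len(length(bs) - 1)) {
      # joints on the chain between consecutive path-point bodies
      crossed <- union(crossed, c(setdiff(chains[[bs[i]]], chains[[bs[i + 1]]]),
                                  setdiff(chains[[bs[i + 1]]], chains[[bs[i]]])))
    }
  }
  free <- free_coordinates(model)
  keep <- vapply(model$joints, function(j)
    j$name %in% crossed, TRUE)
  actuated <- unlist(lapply(model$joints[keep], function(j) names(j$coordinates)))
  intersect(free, actuated)
}

#' Tracked shared-load position
#'
#' The box sits centred between the hands (its construction rule), so its
#' tracked center of mass at any pose is the midpoint of the two hand COMs
#' — invariant under symmetric posture changes.
#'
#' @param model a [model_def()] with a shared load.
#' @param q pose as for [full_pose()].
#' @return length-3 ground-frame position (m).
#' @export
shared_load_position <- function(model, q = NULL) {
  load <- find_shared_load(model)
  if (is.null(load)) stop("model has no shared load", call. = FALSE)
  X <- body_transforms(model, q)
  (point_in_ground(X, load$joint_hand,
                   model$bodies[[load$joint_hand]]$com) +
   point_in_ground(X, load$constraint_hand,
                   model$bodies[[load$constraint_hand]]$com)) / 2
}

skew <- function(r) {
  matrix(c(0, r[3], -r[2], -r[3], 0, r[1], r[2], -r[1], 0), 3, 3)
}

# one-pass finite-difference geometry at a pose: moment arms, gravity
# demand, and (if a shared load is present) the load-COM position Jacobian
# and the interaction-wrench torque map.
#
# Load treatment: the box is a point mass at the hand-COM midpoint held at
# the two hand stations. The contact it exerts on the arms is a force f and
# couple n at each station, constrained by the box's rigid-body
# equilibrium (f_L + f_R = W; couples balance the station lever arms), so
# no net free wrench exists. The decision variable c = (f_R, n_R) is the
# wrench transmitted through the weld constraint at the second hand; the
# left-hand contact is the equilibrium remainder. The torque demand is
# affine in c: tau(c) = tau0 + D c, where tau0 is the all-on-the-left
# baseline (c = 0) and c0 the symmetric half-weight share.
solver_geometry <- function(model, q, coords = balance_coordinates(model),
                            h = 1e-5) {
  pose <- full_pose(model, q)
  load <- find_shared_load(model)
  eval_at <- function(p) {
    X <- body_transforms(model, p)
    out <- list(lens = muscle_lengths(model, transforms = X),
                coms = body_com_positions(model, X))
    if (!is.null(load)) {
      out$pL <- point_in_ground(X, load$joint_hand,
                                model$bodies[[load$joint_hand]]$com)
      out$pR <- point_in_ground(X, load$constraint_hand,
                                model$bodies[[load$constraint_hand]]$com)
      out$RL <- X[[load$joint_hand]][1:3, 1:3]
      out$RR <- X[[load$constraint_hand]][1:3, 1:3]
    }
    out
  }
  base <- eval_at(pose)
  nm <- length(model$muscles)
  nq <- length(coords)
  R <- matrix(0, nm, nq, dimnames = list(names(model$muscles), coords))
  G <- stats::setNames(numeric(nq), coords)
  Jload <- matrix(0, 3, nq, dimnames = list(NULL, coords))
  JpL <- JpR <- JrL <- JrR <- matrix(0, 3, nq)
  masses <- vapply(model$bodies, `[[`, 0, "mass")
  if (!is.null(load)) masses[load$body] <- 0    # carried at the stations
  gvec <- model$gravity
  for (k in seq_len(nq)) {
    qp <- pose; qp[coords[k]] <- qp[coords[k]] + h
    qm <- pose; qm[coords[k]] <- qm[coords[k]] - h
    ep <- eval_at(qp); em <- eval_at(qm)
    R[, k] <- -(ep$lens - em$lens) / (2 * h)
    Jcom <- (ep$coms - em$coms) / (2 * h)          # nbody x 3
    G[k] <- -sum(masses * (Jcom %*% gvec))
    if (!is.null(load)) {
      JpL[, k] <- (ep$pL - em$pL) / (2 * h)
      JpR[, k] <- (ep$pR - em$pR) / (2 * h)
      JrL[, k] <- small_rotation_vector(((ep$RL - em$RL) / (2 * h)) %*%
                                          t(base$RL))
      JrR[, k] <- small_rotation_vector(((ep$RR - em$RR) / (2 * h)) %*%
                                          t(base$RR))
      Jload[, k] <- (JpL[, k] + JpR[, k]) / 2
    }
  }
  out <- list(coords = coords, R = R, G = G, load = load,
              Jload = NULL, D = NULL, tau0 = G, c0 = NULL, load_com = NULL)
  if (!is.null(load)) {
    W <- load$mass * gvec                      # box weight vector (down)
    rL <- (base$pL - base$pR) / 2              # station offsets from midpoint
    rR <- -rL
    # demand is -(generalized contact force); with c = (f_R, n_R) = 0 the
    # whole weight hangs on the left station with the induced couple
    tau0 <- G - drop(t(JpL) %*% W) + drop(t(JrL) %*% (skew(rL) %*% W))
    Df <- t(JpL - JpR) - t(JrL) %*% skew(rL - rR)
    Dm <- t(JrL - JrR)
    out$tau0 <- stats::setNames(tau0, coords)
    out$D <- cbind(Df, Dm)
    rownames(out$D) <- coords
    out$c0 <- c(W / 2, 0, 0, 0)
    out$Jload <- Jload
    out$rL <- rL
    out$load_com <- (base$pL + base$pR) / 2
  }
  out
}

#' Gravity and shared-load torque demand at a static posture
#'
#' The generalized torque the actuators must supply to hold pose `q`
#' (quasi-statically) against gravity acting on every body, the shared load
#' included: `tau_j = -sum_b m_b g . (d com_b / d q_j)`. A point mass m held
#' at horizontal distance d from an elevation axis demands `m g d`.
#'
#' @param model a [model_def()].
#' @param q pose as for [full_pose()].
#' @param coords coordinates to report, default [balance_coordinates()].
#' @return named numeric vector of torque demands (N m).
#' @export
static_torques <- function(model, q = NULL,
                           coords = balance_coordinates(model)) {
  geom <- solver_geometry(model, q, coords)
  if (is.null(geom$D)) geom$tau0
  else stats::setNames(geom$tau0 + drop(geom$D %*% geom$c0), coords)
}

# exact active-set solver for min ||C x - b||^2 with box bounds (primal-dual
# active set; the identity-like rows of C keep every free subproblem full
# rank). Infinite bounds are never activated.
solve_box_ls <- function(C, b, lo, hi, maxit = 100) {
  n <- ncol(C)
  state <- integer(n)                 # 0 free, -1 at lo, +1 at hi
  x <- numeric(n)
  for (it in seq_len(maxit)) {
    x[state == -1L] <- lo[state == -1L]
    x[state == +1L] <- hi[state == +1L]
    free <- state == 0L
    if (any(free)) {
      rhs <- b - if (any(!free)) C[, !free, drop = FALSE] %*% x[!free] else 0
      x[free] <- qr.solve(C[, free, drop = FALSE], rhs)
    }
    g <- drop(crossprod(C, C %*% x - b))          # gradient / 2
    gtol <- 1e-10 * max(1, max(abs(g)))
    new_state <- state
    new_state[free & x < lo - 1e-12] <- -1L
    new_state[free & x > hi + 1e-12] <- +1L
    new_state[state == -1L & g < -gtol] <- 0L
    new_state[state == +1L & g > gtol] <- 0L
    if (identical(new_state, state) &&
        all(x[free] >= lo[free] - 1e-12) && all(x[free] <= hi[free] + 1e-12))
      break
    state <- new_state
  }
  pmin(pmax(x, lo), hi)
}

#' Resolve muscle redundancy at one pose
#'
#' Solves the strictly convex static-optimization program described in the
#' package overview: squared-activation effort, activation bounds, torque
#' balance with heavily weighted slack, and (when a shared load is present)
#' a free interaction wrench through the bimanual weld pair. A step is
#' feasible when the slack is negligible; saturated demand leaves the
#' deficit in the slack.
#'
#' @param model a [model_def()].
#' @param q pose as for [full_pose()] (rad).
#' @param tau torque demand per balance coordinate (N m); computed from
#'   gravity and the shared load via [static_torques()] when `NULL`. When
#'   supplied explicitly, the interaction wrench is not re-derived: the
#'   demand is taken as given.
#' @param w slack weight, default `1e6` (N m)^-2.
#' @param exponent activation-effort exponent, default 2 (exact solve);
#'   other exponents use a bounded quasi-Newton refinement.
#' @param share_tiebreak weight of the tie-break pulling the interaction
#'   wrench toward the symmetric half-weight share, default `1e-4`.
#' @param feasible_tol slack infinity-norm below which the step is flagged
#'   feasible (N m), default `1e-5`.
#' @param geometry optional precomputed `solver_geometry()` result.
#' @return a list with `activations`, `forces` (N), `slack` (N m, per
#'   balance coordinate), `feasible`, `share` (the interaction wrench, or
#'   `NULL`), `left_wrench`/`right_wrench` (force+couple each hand
#'   contributes to supporting the load), `tau` (the demand actually
#'   balanced) and `load_com`.
#' @export
solve_step <- function(model, q = NULL, tau = NULL, w = 1e6, exponent = 2,
                       share_tiebreak = 1e-4, feasible_tol = 1e-5,
                       geometry = NULL) {
  geom <- if (is.null(geometry)) solver_geometry(model, q) else geometry
  fmax <- vapply(model$muscles, `[[`, 0, "max_isometric_force")
  nm <- length(fmax)
  nq <- length(geom$coords)
  Ba <- t(geom$R) * rep(fmax, each = nq)           # nq x nm torque map
  demand_given <- !is.null(tau)
  use_share <- !demand_given && !is.null(geom$load) && !is.null(geom$D) &&
    geom$load$mass > 0    # a zero-weight box transmits nothing
  if (!demand_given) tau <- geom$tau0
  tau <- tau[geom$coords]
  # stacked least-squares form; identity blocks keep it full column rank
  sw <- sqrt(w); se <- sqrt(share_tiebreak)
  if (use_share) {
    # residual = Ba a - (tau0 + D c); the tie-break penalizes the deviation
    # of BOTH stations from the symmetric half-weight/zero-couple share
    # (f_L is the equilibrium remainder and n_L carries the lever terms),
    # which keeps the program mirror-invariant
    W <- geom$load$mass * model$gravity
    K2 <- skew(2 * geom$rL)                 # K(r_L - r_R)
    KLW <- drop(skew(geom$rL) %*% W)
    Z3 <- matrix(0, 3, 3)
    C <- rbind(cbind(diag(nm), matrix(0, nm, 6)),
               cbind(matrix(0, 3, nm), se * diag(3), Z3),       # f_R - W/2
               cbind(matrix(0, 3, nm), Z3, se * diag(3)),       # n_R
               cbind(matrix(0, 3, nm), se * K2, -se * diag(3)), # n_L
               sw * cbind(Ba, -geom$D))
    b <- c(numeric(nm), se * W / 2, numeric(3), se * KLW, sw * geom$tau0)
    lo <- c(rep(0, nm), rep(-Inf, 6))
    hi <- c(rep(1, nm), rep(Inf, 6))
  } else {
    C <- rbind(diag(nm), sw * Ba)
    b <- c(numeric(nm), sw * tau)
    lo <- rep(0, nm); hi <- rep(1, nm)
  }
  x <- solve_box_ls(C, b, lo, hi)
  if (exponent != 2) {
    # general-exponent effort: quasi-Newton refinement from the quadratic
    # solution, against the same penalized least-squares rows
    Cq <- C[-seq_len(nm), , drop = FALSE]
    bq <- b[-seq_len(nm)]
    obj <- function(z) {
      sum(abs(z[seq_len(nm)])^exponent) + sum((Cq %*% z - bq)^2)
    }
    grad <- function(z) {
      g <- 2 * drop(crossprod(Cq, Cq %*% z - bq))
      g[seq_len(nm)] <- g[seq_len(nm)] +
        exponent * sign(z[seq_len(nm)]) * abs(z[seq_len(nm)])^(exponent - 1)
      g
    }
    x <- stats::optim(x, obj, grad, method = "L-BFGS-B", lower = lo,
                      upper = hi,
                      control = list(maxit = 500, factr = 10))$par
  }
  a <- x[seq_len(nm)]
  names(a) <- names(fmax)
  share <- if (use_share) x[nm + 1:6] else NULL
  tau_eff <- if (use_share) geom$tau0 + drop(geom$D %*% share) else tau
  slack <- tau_eff - drop(Ba %*% a)
  names(slack) <- geom$coords
  feasible <- max(abs(slack)) <= feasible_tol
  left_wrench <- right_wrench <- NULL
  if (use_share) {
    # hand-on-box wrenches about the box COM; they sum to the gravity
    # wrench (weight up-reaction, zero couple) by construction
    W <- geom$load$mass * model$gravity
    fR <- share[1:3]; nR <- share[4:6]
    fL <- W - fR
    rL <- geom$rL; rR <- -rL
    nL <- -nR - drop(skew(rL) %*% fL) - drop(skew(rR) %*% fR)
    right_wrench <- c(-fR, -nR - drop(skew(rR) %*% fR))
    left_wrench <- c(-fL, -nL - drop(skew(rL) %*% fL))
  }
  list(activations = a, forces = a * fmax, slack = slack,
       feasible = feasible, share = share,
       right_wrench = right_wrench, left_wrench = left_wrench,
       tau = tau_eff, load_com = geom$load_com)
}

#' Map torque slack to a load-position deviation
#'
#' The declared surrogate for tracking the box position under actuator
#' saturation: unmet demand (slack) is converted to a load center-of-mass
#' displacement through the load's position Jacobian with unit generalized
#' compliance, `delta = -J (1 rad / N m) tau_slack`, so a feasible step maps
#' to exactly zero, an elevation deficit maps inferior (gravity wins along
#' the coordinates it loads), and one-sided deficits acquire a mediolateral
#' component.
#'
#' @param model a [model_def()] with a shared load.
#' @param q pose as for [full_pose()].
#' @param slack named slack vector (N m) from [solve_step()].
#' @param feasible_tol slack norm treated as exactly feasible, default `1e-5`.
#' @param geometry optional precomputed `solver_geometry()` result.
#' @return length-3 ground-frame deviation (m; reported scale is metres per
#'   unit-compliance slack).
#' @export
load_deviation <- function(model, q = NULL, slack, feasible_tol = 1e-5,
                           geometry = NULL) {
  geom <- if (is.null(geometry)) solver_geometry(model, q) else geometry
  if (is.null(geom$Jload))
    stop("model has no shared load to track", call. = FALSE)
  if (max(abs(slack)) <= feasible_tol) return(c(0, 0, 0))
  -drop(geom$Jload[, names(slack), drop = FALSE] %*% slack)
}

#' Simulate a task with the reduced solver
#'
#' Renders (or takes) the task kinematics, low-pass filters them, and runs
#' [solve_step()] at every time step, quasi-statically. Repeated poses are
#' solved once. Deterministic given its inputs.
#'
#' @param model a bilateral [model_def()]; typically with a shared load
#'   ([make_shared_load()]) already attached.
#' @param task a [task_definition()] or a [motion_table()] of coordinate
#'   columns (degrees).
#' @param weight optional load weight (N) to attach if the model has none.
#' @param severity optional [rct_severity()] (or label) applied before
#'   solving.
#' @param side affected side for `severity`, default `"right"`.
#' @param filter a [filter_spec()] applied to the kinematics, or `NULL` to
#'   skip smoothing.
#' @param w,exponent,share_tiebreak,feasible_tol passed to [solve_step()].
#' @param convention a [mirror_convention()].
#' @return an object of class `solver_result`: time, pose matrix `q` (rad),
#'   `activations`, `forces`, `slack`, `feasible`, `load_com` and
#'   `deviation` matrices, plus `fmax`, `fmax_baseline` and metadata.
#' @export
simulate_task <- function(model, task, weight = NULL, severity = NULL,
                          side = "right", filter = filter_spec(),
                          w = 1e6, exponent = 2, share_tiebreak = 1e-4,
                          feasible_tol = 1e-5,
                          convention = mirror_convention()) {
  if (!is.null(severity))
    model <- apply_rct(model, severity, side, convention)
  if (!is.null(weight) && is.null(find_shared_load(model)))
    model <- make_shared_load(model, weight, convention = convention)
  motion <- if (inherits(task, "task_definition"))
    task_to_motion(task, model, convention = convention) else task
  if (!is.null(filter)) motion <- butterworth_lowpass(motion, filter)
  coords_all <- model_coordinates(model)
  use_cols <- intersect(colnames(motion$values), names(coords_all))
  if (length(use_cols) == 0)
    stop("no motion column matches a model coordinate", call. = FALSE)
  scale <- vapply(use_cols, function(cn)
    if (motion$in_degrees && coords_all[[cn]]$kind == "rotational")
      pi / 180 else 1, 0)
  qmat <- motion$values[, use_cols, drop = FALSE] *
    rep(scale, each = nrow(motion$values))
  bal <- balance_coordinates(model)
  fmax <- vapply(model$muscles, `[[`, 0, "max_isometric_force")
  nsteps <- nrow(qmat)
  key <- apply(round(qmat, 12), 1, paste, collapse = ",")
  uniq <- !duplicated(key)
  idx <- match(key, key[uniq])
  sols <- vector("list", sum(uniq))
  has_load <- !is.null(find_shared_load(model))
  ui <- 0
  for (i in which(uniq)) {
    ui <- ui + 1
    qrow <- qmat[i, ]
    geom <- solver_geometry(model, qrow, bal)
    st <- solve_step(model, tau = NULL, w = w, exponent = exponent,
                     share_tiebreak = share_tiebreak,
                     feasible_tol = feasible_tol, geometry = geom)
    st$deviation <- if (has_load)
      load_deviation(model, slack = st$slack, feasible_tol = feasible_tol,
                     geometry = geom) else c(0, 0, 0)
    sols[[ui]] <- st
  }
  pick <- function(field, ncolumns) {
    t(vapply(idx, function(k) as.numeric(sols[[k]][[field]]),
             numeric(ncolumns)))
  }
  nm <- length(fmax)
  res <- list(
    time = motion$time,
    coords = colnames(qmat), q = qmat,
    muscles = names(fmax), fmax = fmax,
    fmax_baseline = attr(model, "fmax_baseline") %||% fmax,
    activations = `colnames<-`(pick("activations", nm), names(fmax)),
    forces = `colnames<-`(pick("forces", nm), names(fmax)),
    slack = `colnames<-`(pick("slack", length(bal)), bal),
    feasible = vapply(idx, function(k) sols[[k]]$feasible, TRUE),
    load_com = if (has_load) pick("load_com", 3) else NULL,
    deviation = if (has_load) pick("deviation", 3) else NULL,
    left_wrench = if (has_load) pick("left_wrench", 6) else NULL,
    right_wrench = if (has_load) pick("right_wrench", 6) else NULL,
    task = if (inherits(task, "task_definition")) task$name else motion$name,
    severity = if (is.null(severity)) "none"
               else if (is.character(severity)) severity else severity$label)
  class(res) <- "solver_result"
  res
}

#' @export
print.solver_result <- function(x, ...) {
  cat("<solver_result> task '", x$task, "': ", length(x$time), " steps, ",
      length(x$muscles), " actuators, severity ", x$severity, "; ",
      sum(x$feasible), "/", length(x$feasible), " steps feasible\n", sep = "")
  invisible(x)
}
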