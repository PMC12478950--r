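# Graded unilateral rotator-cuff-tear severities (peak-isometric-force
# scaling of the cuff actuators on the affected side) and the bimanual
# shared-load construction (a load body welded to the left hand and
# weld-constrained to the right hand, centred between the hand COMs).

#' Rotator-cuff-tear severity
#'
#' Per-muscle scale factors of baseline peak isometric force, on the
#' assumption that muscle force capacity is linearly related to the torn
#' tendon fraction:
#'
#' * `none` — supraspinatus 1.0, infraspinatus 1.0, subscapularis 1.0
#' * `partial` — supraspinatus 0.5
#' * `full` — supraspinatus 0.0, infraspinatus 0.75
#' * `massive` — supraspinatus 0.0, infraspinatus 0.25, subscapularis 0.5
#'
#' Teres minor is never scaled. Scales are non-increasing along
#' none > partial > full > massive for every muscle.
#'
#' @param label one of `"none"`, `"partial"`, `"full"`, `"massive"`.
#' @return an object of class `rct_severity` with fields `label` and `scale`
#'   (named numeric over the cuff muscle roles).
#' @export
rct_severity <- function(label = c("none", "partial", "full", "massive")) {
  label <- match.arg(label)
  scale <- switch(label,
    none    = c(supraspinatus = 1.0, infraspinatus = 1.0, subscapularis = 1.0),
    partial = c(supraspinatus = 0.5, infraspinatus = 1.0, subscapularis = 1.0),
    full    = c(supraspinatus = 0.0, infraspinatus = 0.75, subscapularis = 1.0),
    massive = c(supraspinatus = 0.0, infraspinatus = 0.25, subscapularis = 0.5))
  structure(list(label = label, scale = scale), class = "rct_severity")
}

side_suffix <- function(side, convention) {
  pr <- convention$suffix_pairs[[1]]
  # convention stores the (right, left) suffix pair in order
  if (side == "right") pr[1] else pr[2]
}

#' Apply a unilateral rotator-cuff-tear severity
#'
#' Scales the peak isometric force of the affected side's supraspinatus,
#' infraspinatus and subscapularis actuators by the severity's factors. The
#' pristine baseline is snapshotted on the model the first time a severity is
#' applied, and every application scales that baseline — so severities are
#' absolute and never compound. All other muscles, and the contralateral
#' side, are untouched.
#'
#' @param model a bilateral [model_def()] containing side-suffixed cuff
#'   actuators (e.g. `supraspinatus_r`).
#' @param severity an [rct_severity()] (or its label).
#' @param side `"right"` (default, the affected side) or `"left"`.
#' @param convention a [mirror_convention()] supplying the side suffixes.
#' @return the modified [model_def()]; carries an `rct` attribute recording
#'   the severity and side, and an `fmax_baseline` attribute.
#' @export
apply_rct <- function(model, severity, side = c("right", "left"),
                      convention = mirror_convention()) {
  if (is.character(severity)) severity <- rct_severity(severity)
  stopifnot(inherits(severity, "rct_severity"))
  side <- match.arg(side)
  suffix <- side_suffix(side, convention)
  baseline <- attr(model, "fmax_baseline")
  if (is.null(baseline)) {
    baseline <- vapply(model$muscles, `[[`, 0, "max_isometric_force")
  }
  for (role in names(severity$scale)) {
    target <- paste0(role, suffix)
    if (!(target %in% names(model$muscles)))
      stop("model has no actuator '", target, "' for the ", side,
           " side", call. = FALSE)
    model$muscles[[target]]$max_isometric_force <-
      baseline[[target]] * severity$scale[[role]]
  }
  attr(model, "fmax_baseline") <- baseline
  attr(model, "rct") <- list(label = severity$label, side = side)
  model
}

# locate the shared-load construction in a model: the body hanging from a
# WeldJoint off one hand and tied to the other via a WeldConstraint
find_shared_load <- function(model) {
  for (k in model$constraints) {
    j <- Find(function(jj) jj$child == k$body_1 && jj$type == "WeldJoint",
              model$joints)
    if (!is.null(j)) {
      return(list(body = k$body_1, joint_hand = j$parent,
                  constraint_hand = k$body_2,
                  constraint_location = k$location_in_body_2,
                  mass = model$bodies[[k$body_1]]$mass))
    }
  }
  NULL
}

#' Attach a bimanual shared load
#'
#' Adds a load body of mass `weight / g` whose center of mass sits at the
#' midpoint of the two hand COMs in the model's default posture, rigidly
#' welded to the left hand and tied to the right hand by a weld constraint
#' (closing the bimanual loop). The load's inertia is that of a uniform
#' 0.2 x 0.2 x 0.4 m box (long axis mediolateral, the hand spacing).
#'
#' Presets: 13.3 N and 44.5 N, the weights of typical household and
#' occupational objects. The weight is authoritative; mass is derived with
#' g = |model gravity|.
#'
#' @param model a bilateral [model_def()] with left/right hand bodies.
#' @param weight load weight in N, `>= 0`.
#' @param hands length-2 character `c(left, right)` hand body names; by
#'   default the bodies whose names contain `"hand"`, left first.
#' @param load_name name for the load body, default `"shared_load"`.
#' @param convention a [mirror_convention()].
#' @return the augmented [model_def()].
#' @export
make_shared_load <- function(model, weight, hands = NULL,
                             load_name = "shared_load",
                             convention = mirror_convention()) {
  if (weight < 0) stop("load weight must be >= 0", call. = FALSE)
  if (is.null(hands)) {
    cand <- grep("hand", names(model$bodies), value = TRUE)
    pr <- convention$suffix_pairs[[1]]
    left <- cand[endsWith(cand, pr[2])]
    right <- cand[endsWith(cand, pr[1])]
    if (length(left) != 1 || length(right) != 1)
      stop("could not identify left/right hand bodies; pass `hands`",
           call. = FALSE)
    hands <- c(left, right)
  }
  if (!all(hands %in% names(model$bodies)))
    stop("hand body not found: ",
         paste(setdiff(hands, names(model$bodies)), collapse = ", "),
         call. = FALSE)
  g <- sqrt(sum(model$gravity^2))
  mass <- weight / g
  X <- body_transforms(model)
  pL <- point_in_ground(X, hands[1], model$bodies[[hands[1]]]$com)
  pR <- point_in_ground(X, hands[2], model$bodies[[hands[2]]]$com)
  mid <- (pL + pR) / 2
  # load frame aligned with ground at the default posture, origin at the COM
  XL <- X[[hands[1]]]
  RL <- XL[1:3, 1:3]
  loc_in_left <- drop(t(RL) %*% (mid - XL[1:3, 4]))
  ori_in_left <- matrix_to_euler_xyz(t(RL))
  XR <- X[[hands[2]]]
  RR <- XR[1:3, 1:3]
  loc_in_right <- drop(t(RR) %*% (mid - XR[1:3, 4]))
  ori_in_right <- matrix_to_euler_xyz(t(RR))
  dims <- c(0.2, 0.2, 0.4)
  inertia <- mass / 12 * c(dims[2]^2 + dims[3]^2,
                           dims[1]^2 + dims[3]^2,
                           dims[1]^2 + dims[2]^2)
  load <- body_def(name = load_name, mass = mass, com = c(0, 0, 0),
                   inertia = c(inertia, 0, 0, 0))
  jt <- joint_def(name = paste0(load_name, "_weld"), type = "WeldJoint",
                  parent = hands[1], child = load_name,
                  location_in_parent = loc_in_left,
                  orientation_in_parent = ori_in_left)
  ct <- constraint_def(name = paste0(load_name, "_constraint"),
                       body_1 = load_name, body_2 = hands[2],
                       location_in_body_1 = c(0, 0, 0),
                       location_in_body_2 = loc_in_right,
                       orientation_in_body_2 = ori_in_right)
  out <- model_def(name = model$name, gravity = model$gravity,
                   bodies = c(model$bodies, list(load)),
                   joints = c(model$joints, list(jt)),
                   muscles = model$muscles,
                   constraints = c(model$constraints, list(ct)),
                   extra = model$extra)
  for (a in c("axis_flips", "mirror_convention", "fmax_baseline", "rct"))
    attr(out, a) <- attr(model, a)
  out
}
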