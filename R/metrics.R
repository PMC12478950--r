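# Outcome measures: normalized muscle force (% maximum), time-averaged
# contributions and severity/load contrasts, and load-position deviation
# summaries.
#
# Direction conventions: vertical = ground Y (superior positive);
# mediolateral = ground Z (affected/right side positive), so "toward the
# unaffected side" is a negative-Z displacement magnitude.

#' Normalized muscle force series (% maximum)
#'
#' `100 * F_i(t) / Fmax_i` per muscle. By default the post-injury peak
#' isometric force is the denominator; muscles torn to zero capacity are
#' reported as 0% and flagged in the `torn_zero` attribute. Set
#' `denominator = "pre"` to normalize by the pristine baseline instead.
#'
#' @param result a [simulate_task()] result.
#' @param denominator `"post"` (default) or `"pre"`.
#' @return matrix `[time, muscle]` of % maximum, `torn_zero` attribute
#'   naming zero-capacity muscles.
#' @export
normalized_force <- function(result, denominator = c("post", "pre")) {
  denominator <- match.arg(denominator)
  fm <- if (denominator == "post") result$fmax else result$fmax_baseline
  torn <- names(fm)[fm <= 0]
  fm_safe <- ifelse(fm > 0, fm, 1)
  out <- 100 * result$forces / rep(fm_safe, each = nrow(result$forces))
  out[, torn] <- 0
  attr(out, "torn_zero") <- torn
  out
}

#' Time-averaged contribution (% maximum)
#'
#' @param series numeric vector, or matrix with one column per muscle (e.g.
#'   from [normalized_force()]).
#' @return scalar or named vector of time means.
#' @export
average_contribution <- function(series) {
  if (is.matrix(series)) colMeans(series) else mean(series)
}

avg_from <- function(x) {
  if (inherits(x, "solver_result")) average_contribution(normalized_force(x))
  else x
}

#' Contrast two model permutations
#'
#' Percentage-point change in average normalized force per muscle between a
#' reference permutation (e.g. no tear) and a comparison permutation
#' (`mean_b - mean_a`); the relative change is reported alongside.
#' Antisymmetric: `contrast(a, b)$delta_pp == -contrast(b, a)$delta_pp`.
#'
#' @param perm_a reference: a [simulate_task()] result or a named vector of
#'   average contributions (% maximum).
#' @param perm_b comparison, same form.
#' @return data frame with `muscle`, `mean_ref`, `mean_cmp`, `delta_pp`
#'   (percentage points) and `delta_rel` (fraction of the reference, `NA`
#'   when the reference mean is 0).
#' @export
contrast <- function(perm_a, perm_b) {
  a <- avg_from(perm_a); b <- avg_from(perm_b)
  common <- intersect(names(a), names(b))
  if (length(common) == 0) stop("permutations share no muscles", call. = FALSE)
  a <- a[common]; b <- b[common]
  data.frame(muscle = common, mean_ref = unname(a), mean_cmp = unname(b),
             delta_pp = unname(b - a),
             delta_rel = ifelse(a != 0, unname((b - a) / a), NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarize load-position deviation
#'
#' For static tasks: the maximum displacement from the starting position,
#' decomposed by direction (inferior/superior from ground Y,
#' toward-affected/toward-unaffected from ground Z), in mm. For the dynamic
#' task: per-direction RMSE of the predicted trajectory against the
#' reference (input-kinematics) trajectory, in mm.
#'
#' @param trajectory predicted load positions, `n x 3` matrix (m), or a
#'   [simulate_task()] result (in which case the predicted position is
#'   `load_com + deviation` and the reference defaults to the
#'   input-kinematics `load_com`).
#' @param reference for `"static"`, a length-3 start point (default: first
#'   predicted position); for `"dynamic"`, the `n x 3` reference trajectory.
#' @param task_kind `"static"` or `"dynamic"`.
#' @return for static: named vector `max_inferior_mm`, `max_superior_mm`,
#'   `toward_unaffected_mm`, `toward_affected_mm`, `max_magnitude_mm`; for
#'   dynamic: `rmse_vertical_mm`, `rmse_mediolateral_mm`,
#'   `rmse_anteroposterior_mm`.
#' @export
deviation_summary <- function(trajectory, reference = NULL,
                              task_kind = c("static", "dynamic")) {
  task_kind <- match.arg(task_kind)
  if (inherits(trajectory, "solver_result")) {
    res <- trajectory
    if (is.null(res$load_com)) stop("result has no load trajectory", call. = FALSE)
    if (is.null(reference))
      reference <- if (task_kind == "static") res$load_com[1, ] else res$load_com
    trajectory <- res$load_com + res$deviation
  }
  trajectory <- matrix(trajectory, ncol = 3)
  if (task_kind == "static") {
    ref <- if (is.null(reference)) trajectory[1, ] else as.numeric(reference)
    d <- sweep(trajectory, 2, ref)
    c(max_inferior_mm = 1000 * max(0, -min(d[, 2])),
      max_superior_mm = 1000 * max(0, max(d[, 2])),
      toward_unaffected_mm = 1000 * max(0, -min(d[, 3])),
      toward_affected_mm = 1000 * max(0, max(d[, 3])),
      max_magnitude_mm = 1000 * sqrt(max(rowSums(d^2))))
  } else {
    if (is.null(reference)) stop("dynamic summary needs a reference trajectory",
                                 call. = FALSE)
    ref <- matrix(reference, ncol = 3)
    c(rmse_vertical_mm = 1000 * rmse(trajectory[, 2], ref[, 2]),
      rmse_mediolateral_mm = 1000 * rmse(trajectory[, 3], ref[, 3]),
      rmse_anteroposterior_mm = 1000 * rmse(trajectory[, 1], ref[, 1]))
  }
}
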