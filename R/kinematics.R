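# Egocentric kinematics: thrust/slip/yaw extraction and the joint
# translational z-scoring applied before clustering.

#' Compute egocentric thrust, slip and yaw velocities
#'
#' Converts tracked head positions and headings into per-interval velocities in
#' the animal's body frame. For the interval from frame `n` to `n + 1` with
#' world-frame head displacement `d` and heading `theta(n)`:
#' thrust is the component of `d / dt` along the heading unit vector, slip the
#' component along its 90 degree counterclockwise rotation (positive to the
#' animal's left), and yaw the wrapped heading change divided by `dt`. Each
#' velocity triple is assigned to the leading frame `n`; the last frame of every
#' contiguous segment carries no kinematics. Gaps in `frame` indices split the
#' series into segments and no velocity spans a gap.
#'
#' @param session a `tracked_session` (see [generate_session()]) or a data frame
#'   with columns `frame`, `t_s`, `x_cm`, `y_cm`, `heading_deg` (and optionally
#'   `gt_pm`, `gt_behavior`, which are carried through).
#' @return a data frame of class `kinematic_series` with one row per interval:
#'   `frame`, `t_s`, `dt_s`, `thrust`, `slip`, `yaw`, `segment` (units cm/s,
#'   cm/s, deg/s).
#' @examples
#' fr <- data.frame(frame = 1:3, t_s = c(0, 0.04, 0.08),
#'                  x_cm = c(0, 1, 2), y_cm = 0, heading_deg = 0)
#' compute_kinematics(fr)
#' @export
compute_kinematics <- function(session) {
  fr <- if (inherits(session, "tracked_session")) session$frames else session
  need <- c("frame", "t_s", "x_cm", "y_cm", "heading_deg")
  miss <- setdiff(need, names(fr))
  if (length(miss)) stopf("missing columns: %s", paste(miss, collapse = ", "))
  if (nrow(fr) < 2L) stopf("need at least 2 frames")
  if (any(diff(fr$t_s) <= 0)) stopf("timestamps must be strictly increasing")

  seg <- cumsum(c(1L, as.integer(diff(fr$frame) != 1L)))
  n <- nrow(fr)
  lead <- which(seg[-n] == seg[-1])  # rows that start an intra-segment interval
  if (!length(lead)) stopf("no contiguous interval of >= 2 frames")
  nxt <- lead + 1L

  dt <- fr$t_s[nxt] - fr$t_s[lead]
  if (any(dt <= 0)) stopf("zero or negative dt within a segment")
  dx <- fr$x_cm[nxt] - fr$x_cm[lead]
  dy <- fr$y_cm[nxt] - fr$y_cm[lead]
  th <- fr$heading_deg[lead] * pi / 180
  out <- data.frame(
    frame = fr$frame[lead],
    t_s = fr$t_s[lead],
    x_cm = fr$x_cm[lead],
    y_cm = fr$y_cm[lead],
    dt_s = dt,
    thrust = (dx * cos(th) + dy * sin(th)) / dt,
    slip = (-dx * sin(th) + dy * cos(th)) / dt,
    yaw = wrap_degrees(fr$heading_deg[nxt] - fr$heading_deg[lead]) / dt,
    segment = seg[lead]
  )
  for (col in intersect(c("gt_pm", "gt_behavior"), names(fr))) out[[col]] <- fr[[col]][lead]
  if (inherits(session, "tracked_session")) {
    out$session_id <- session$session_id
    out$night_id <- session$night_id
    out$condition <- session$condition
  }
  class(out) <- c("kinematic_series", "data.frame")
  out
}

#' Fit the kinematic z-scaler
#'
#' Translational velocities (thrust and slip) are z-scored jointly with a single
#' mean and SD computed from the concatenation of all thrust and all slip
#' values, normalising for the different dimensionality of translational and
#' rotational kinematics; yaw gets its own mean and SD.
#'
#' @param kin a `kinematic_series` or data frame with `thrust`, `slip`, `yaw`.
#' @return an object of class `kinematic_scaler`: list with `trans_mean`,
#'   `trans_sd`, `yaw_mean`, `yaw_sd`.
#' @seealso [apply_scaler()], [invert_scaler()]
#' @export
fit_scaler <- function(kin) {
  if (nrow(kin) < 2L) stopf("need at least 2 records to fit a scaler")
  tv <- c(kin$thrust, kin$slip)
  p <- list(trans_mean = mean(tv), trans_sd = stats::sd(tv),
            yaw_mean = mean(kin$yaw), yaw_sd = stats::sd(kin$yaw))
  if (p$trans_sd == 0) stopf("translational channel (thrust/slip) is constant")
  if (p$yaw_sd == 0) stopf("rotational channel (yaw) is constant")
  class(p) <- "kinematic_scaler"
  p
}

#' Apply or invert the kinematic z-scaler
#'
#' @param params a `kinematic_scaler` from [fit_scaler()].
#' @param kin data frame with `thrust`, `slip`, `yaw` (for `apply_scaler`) or a
#'   matrix/data frame of z-scored triples (for `invert_scaler`).
#' @return `apply_scaler`: numeric matrix with columns `z_thrust`, `z_slip`,
#'   `z_yaw`; `invert_scaler`: matrix with columns `thrust`, `slip`, `yaw` in
#'   raw units.
#' @export
apply_scaler <- function(params, kin) {
  z <- cbind(z_thrust = (kin$thrust - params$trans_mean) / params$trans_sd,
             z_slip = (kin$slip - params$trans_mean) / params$trans_sd,
             z_yaw = (kin$yaw - params$yaw_mean) / params$yaw_sd)
  z
}

#' @rdname apply_scaler
#' @export
invert_scaler <- function(params, kin) {
  z <- as.matrix(kin)
  cbind(thrust = z[, 1] * params$trans_sd + params$trans_mean,
        slip = z[, 2] * params$trans_sd + params$trans_mean,
        yaw = z[, 3] * params$yaw_sd + params$yaw_mean)
}

#' @export
print.kinematic_scaler <- function(x, ...) {
  cat(sprintf("kinematic z-scaler: translational %.3f +/- %.3f cm/s (thrust & slip pooled), yaw %.3f +/- %.3f deg/s\n",
              x$trans_mean, x$trans_sd, x$yaw_mean, x$yaw_sd))
  invisible(x)
}
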