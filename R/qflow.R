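# Phase-contrast (Q-flow) carotid flow quantification: linear velocity
# encoding, per-frame spatial integration over vessel ROIs, and time
# averaging over the cardiac cycle.

#' Velocity-encoded phase-contrast cine
#'
#' @param magnitude 3D array (x, y, frame).
#' @param phase 3D array (x, y, frame), radians in `[-pi, pi]`.
#' @param venc encoding velocity (cm/s); a spin moving at `venc` acquires a
#'   phase of `pi`.
#' @param pixel_area in-plane pixel area (cm^2).
#' @param aliased set by simulators when the true peak velocity exceeded
#'   `venc`, so downstream conversion can warn.
#' @return an object of class `pc_cine`.
#' @export
pc_cine <- function(magnitude, phase, venc = 120, pixel_area,
                    aliased = FALSE) {
  check_same_grid(magnitude, phase, "magnitude", "phase")
  if (length(dim(phase)) != 3L) {
    stop_devoxel("cine arrays must be 3D (x, y, frame)",
                 class = "devoxel_parameter_error")
  }
  if (any(abs(phase) > pi + 1e-9)) {
    stop_devoxel("phase values outside [-pi, pi]; aliasing is not unwrapped",
                 class = "devoxel_phase_range_error")
  }
  if (venc <= 0 || pixel_area <= 0) {
    stop_devoxel("venc and pixel_area must be > 0",
                 class = "devoxel_parameter_error")
  }
  structure(
    list(magnitude = magnitude, phase = phase, venc = venc,
         pixel_area = pixel_area, n_frames = dim(phase)[3],
         aliased = isTRUE(aliased)),
    class = "pc_cine"
  )
}

#' Vessel region of interest
#'
#' @param mask 2D logical array delineating one vessel cross-section, drawn
#'   on the magnitude image.
#' @param side `"left"` or `"right"`.
#' @return an object of class `vessel_roi`.
#' @export
vessel_roi <- function(mask, side = c("left", "right")) {
  side <- match.arg(side)
  if (length(dim(mask)) != 2L || !is.logical(mask)) {
    stop_devoxel("ROI mask must be a 2D logical array",
                 class = "devoxel_roi_error")
  }
  if (!any(mask)) {
    stop_devoxel("ROI mask for side '", side, "' is empty",
                 class = "devoxel_roi_error")
  }
  structure(list(mask = mask, side_label = side), class = "vessel_roi")
}

#' Convert phase to through-plane velocity
#'
#' Standard linear velocity encoding: `v = venc * phase / pi` cm/s, positive
#' in the craniocaudal direction.  Warns when the cine is flagged as
#' aliased or the phase saturates the encoding range.
#'
#' @param cine a [pc_cine()].
#' @param static_mask optional 2D logical mask of static tissue; if given,
#'   the per-frame median phase inside it is subtracted before conversion
#'   (background phase-offset correction; off by default).
#' @return 3D velocity array (x, y, frame) in cm/s.
#' @export
phase_to_velocity <- function(cine, static_mask = NULL) {
  stopifnot(inherits(cine, "pc_cine"))
  phase <- cine$phase
  if (!is.null(static_mask)) {
    check_same_grid(phase[, , 1], static_mask, "phase frame", "static mask")
    for (f in seq_len(cine$n_frames)) {
      phase[, , f] <- phase[, , f] - stats::median(phase[, , f][static_mask])
    }
  }
  if (cine$aliased || any(abs(cine$phase) > pi - 1e-6)) {
    warning("velocities at or beyond venc = ", cine$venc,
            " cm/s: possible phase aliasing (not unwrapped)")
  }
  cine$venc * phase / pi
}

#' Integrate velocity over a vessel cross-section per cardiac frame
#'
#' `flow(frame) = sum over ROI pixels of v(pixel, frame) * pixel_area`,
#' in cm^3/s.
#'
#' @param velocity 3D velocity array (x, y, frame), cm/s.
#' @param roi a [vessel_roi()] on the same in-plane grid.
#' @param pixel_area pixel area (cm^2).
#' @return numeric vector of per-frame flow (cm^3/s).
#' @export
frame_flow <- function(velocity, roi, pixel_area) {
  stopifnot(inherits(roi, "vessel_roi"))
  check_same_grid(velocity[, , 1], roi$mask, "velocity frame", "ROI mask")
  n_frames <- dim(velocity)[3]
  vapply(seq_len(n_frames), function(f) {
    sum(velocity[, , f][roi$mask]) * pixel_area
  }, numeric(1))
}

#' Time-average per-side flows and combine sides
#'
#' Averages each side's flow waveform over the cardiac cycle and combines
#' the sides.  The bilateral total is the sum of left and right by default
#' (both internal carotids feed the cerebrum); `combine = "mean"` is
#' available.  A missing side yields an explicit single-side result flagged
#' incomplete.
#'
#' @param left,right per-frame flow vectors (cm^3/s); at least one required.
#' @param combine `"sum"` (default) or `"mean"`.
#' @return an object of class `flow_result` with fields `per_frame_flow`
#'   (list per side), `side_mean_flow`, `total_flow`, `combine`,
#'   `incomplete`.
#' @export
time_average_and_combine <- function(left = NULL, right = NULL,
                                     combine = c("sum", "mean")) {
  combine <- match.arg(combine)
  sides <- list(left = left, right = right)
  sides <- sides[!vapply(sides, is.null, logical(1))]
  if (length(sides) == 0L) {
    stop_devoxel("at least one side's flow waveform is required",
                 class = "devoxel_roi_error")
  }
  if (length(sides) == 2L && length(sides$left) != length(sides$right)) {
    stop_devoxel("left and right waveforms have different frame counts",
                 class = "devoxel_parameter_error")
  }
  side_mean <- vapply(sides, mean, numeric(1))
  total <- switch(combine, sum = sum(side_mean), mean = mean(side_mean))
  structure(
    list(per_frame_flow = sides, side_mean_flow = side_mean,
         total_flow = total, combine = combine,
         incomplete = length(sides) < 2L),
    class = "flow_result"
  )
}

#' @export
print.flow_result <- function(x, ...) {
  cat(sprintf("Carotid flow (%s of sides%s): total %.2f cm^3/s [%s]\n",
              x$combine, if (x$incomplete) ", INCOMPLETE" else "",
              x$total_flow,
              paste(sprintf("%s %.2f", names(x$side_mean_flow),
                            x$side_mean_flow), collapse = ", ")))
  invisible(x)
}

#' Full phase-contrast flow quantification
#'
#' Convenience wrapper: phase-to-velocity conversion, per-frame integration
#' over each supplied vessel ROI, and time averaging/combination.
#'
#' @param cine a [pc_cine()].
#' @param roi_left,roi_right [vessel_roi()]s; at least one required.
#' @param combine passed to [time_average_and_combine()].
#' @param static_mask passed to [phase_to_velocity()].
#' @return a `flow_result`.
#' @export
quantify_flow <- function(cine, roi_left = NULL, roi_right = NULL,
                          combine = "sum", static_mask = NULL) {
  v <- phase_to_velocity(cine, static_mask = static_mask)
  left <- if (!is.null(roi_left)) frame_flow(v, roi_left, cine$pixel_area)
  right <- if (!is.null(roi_right)) frame_flow(v, roi_right, cine$pixel_area)
  time_average_and_combine(left = left, right = right, combine = combine)
}
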