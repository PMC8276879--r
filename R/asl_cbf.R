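# pCASL CBF quantification: control/label differencing, robust pair QC,
# single-compartment whitepaper model with 2D multislice slice-timing and
# background-suppression correction, and GM partial-volume correction.

#' ASL acquisition parameters
#'
#' Bundles the quantification constants of the single-compartment pCASL
#' model for a 2D multislice readout.  Times are given in milliseconds (as
#' usually printed on the console) and converted to seconds internally so
#' that the 6000 factor yields ml/100 g/min.
#'
#' Defaults are those of a 3T pCASL protocol with background suppression:
#' blood-brain partition coefficient 0.9 ml/g, labeling efficiency 0.85,
#' background-suppression factor 0.83, T1 of blood 1650 ms, first-slice
#' post-labeling delay 1525 ms, 35 ms per slice, label duration 1650 ms,
#' 17 slices acquired feet-head.
#'
#' @param lambda_bp blood-brain partition coefficient (ml/g).
#' @param alpha labeling efficiency, in (0, 1].
#' @param alpha_inv background-suppression correction factor, in (0, 1].
#' @param t1_blood longitudinal relaxation time of blood (ms).
#' @param t_delay post-labeling delay of the first acquired slice (ms).
#' @param t_slice acquisition time per slice (ms).
#' @param tau label duration (ms).
#' @param n_slices number of slices.
#' @param slice_order integer vector mapping spatial slice index to temporal
#'   acquisition index (1-based).  Default: ascending, i.e. spatial order
#'   equals temporal order (feet-head acquisition).
#' @return an object of class `asl_acquisition`.
#' @export
asl_acquisition <- function(lambda_bp = 0.9, alpha = 0.85, alpha_inv = 0.83,
                            t1_blood = 1650, t_delay = 1525, t_slice = 35,
                            tau = 1650, n_slices = 17,
                            slice_order = seq_len(n_slices)) {
  if (t1_blood <= 0 || tau <= 0 || t_delay <= 0 || t_slice <= 0) {
    stop_devoxel("all acquisition times must be > 0",
                 class = "devoxel_parameter_error")
  }
  if (alpha <= 0 || alpha > 1 || alpha_inv <= 0 || alpha_inv > 1) {
    stop_devoxel("alpha and alpha_inv must lie in (0, 1]",
                 class = "devoxel_parameter_error")
  }
  if (lambda_bp <= 0) {
    stop_devoxel("lambda_bp must be > 0", class = "devoxel_parameter_error")
  }
  n_slices <- as.integer(n_slices)
  if (n_slices < 1) {
    stop_devoxel("n_slices must be >= 1", class = "devoxel_parameter_error")
  }
  slice_order <- as.integer(slice_order)
  if (length(slice_order) != n_slices ||
      !setequal(slice_order, seq_len(n_slices))) {
    stop_devoxel("slice_order must be a permutation of 1..n_slices",
                 class = "devoxel_parameter_error")
  }
  structure(
    list(lambda_bp = lambda_bp, alpha = alpha, alpha_inv = alpha_inv,
         t1_blood = t1_blood, t_delay = t_delay, t_slice = t_slice,
         tau = tau, n_slices = n_slices, slice_order = slice_order),
    class = "asl_acquisition"
  )
}

#' @export
print.asl_acquisition <- function(x, ...) {
  cat("ASL acquisition:",
      sprintf("lambda=%.2f ml/g, alpha=%.2f, alpha_inv=%.2f", x$lambda_bp,
              x$alpha, x$alpha_inv), "\n ",
      sprintf("T1,blood=%g ms, T_delay=%g ms, T_slice=%g ms, tau=%g ms, %d slices",
              x$t1_blood, x$t_delay, x$t_slice, x$tau, x$n_slices), "\n")
  invisible(x)
}

#' Interleaved ASL control/label series
#'
#' @param volumes 4D array (x, y, slice, repetition) in scanner units.
#' @param pairing `"control_first"` if odd repetitions are control volumes,
#'   `"label_first"` otherwise.
#' @param voxel_dims physical voxel size in mm, length 3.
#' @return an object of class `asl_series`.
#' @export
asl_series <- function(volumes, pairing = c("control_first", "label_first"),
                       voxel_dims = c(3, 3, 7)) {
  pairing <- match.arg(pairing)
  if (length(dim(volumes)) != 4L) {
    stop_devoxel("ASL series must be a 4D array (x, y, slice, repetition)",
                 class = "devoxel_malformed_series")
  }
  n_rep <- dim(volumes)[4]
  if (n_rep %% 2L != 0L) {
    stop_devoxel("odd repetition count (", n_rep,
                 "): control/label volumes must come in pairs",
                 class = "devoxel_malformed_series")
  }
  if (any(voxel_dims <= 0)) {
    stop_devoxel("voxel_dims must be > 0", class = "devoxel_parameter_error")
  }
  if (all(volumes == 0)) {
    warning("ASL series is identically zero")
  }
  structure(
    list(volumes = volumes, pairing = pairing, n_pairs = n_rep %/% 2L,
         voxel_dims = as.numeric(voxel_dims)),
    class = "asl_series"
  )
}

# per-pair 3D difference stack (x, y, slice, pair), control minus label
pair_differences <- function(series) {
  d <- dim(series$volumes)
  idx <- seq_len(series$n_pairs)
  if (series$pairing == "control_first") {
    ctrl <- series$volumes[, , , 2L * idx - 1L, drop = FALSE]
    labl <- series$volumes[, , , 2L * idx, drop = FALSE]
  } else {
    ctrl <- series$volumes[, , , 2L * idx, drop = FALSE]
    labl <- series$volumes[, , , 2L * idx - 1L, drop = FALSE]
  }
  ctrl - labl
}

new_perfusion_difference <- function(series, si_pd, brain_mask, kept, rejected) {
  diffs <- pair_differences(series)
  delta <- apply(diffs[, , , kept, drop = FALSE], 1:3, mean)
  delta[!brain_mask] <- NA_real_
  structure(
    list(delta_si = delta, si_pd = si_pd, brain_mask = brain_mask,
         kept_pairs = kept, rejected_pairs = rejected,
         voxel_dims = series$voxel_dims),
    class = "perfusion_difference"
  )
}

#' Average control-minus-label difference
#'
#' Splits an interleaved series into control and label volumes, subtracts
#' label from control per pair, and averages over all pairs.  Pair quality
#' control is a separate step ([reject_outlier_pairs()]); here every pair is
#' kept.
#'
#' @param series an [asl_series()].
#' @param si_pd 3D proton-density image used later to scale the difference
#'   signal to absolute units.
#' @param brain_mask 3D logical array; the difference is only defined where
#'   `TRUE`.  Default: everywhere.
#' @return an object of class `perfusion_difference` with fields `delta_si`,
#'   `si_pd`, `brain_mask`, `kept_pairs`, `rejected_pairs`.
#' @export
split_and_difference <- function(series, si_pd,
                                 brain_mask = array(TRUE, dim(series$volumes)[1:3])) {
  stopifnot(inherits(series, "asl_series"))
  check_same_grid(si_pd, brain_mask, "PD image", "brain mask")
  check_same_grid(array(0, dim(series$volumes)[1:3]), si_pd,
                  "ASL volume", "PD image")
  new_perfusion_difference(series, si_pd, brain_mask,
                           kept = seq_len(series$n_pairs),
                           rejected = integer(0))
}

#' Robust rejection of corrupted control-label pairs
#'
#' Deterministic surrogate for visual pair inspection: each pair is
#' summarised by the mean absolute subtraction signal over the brain mask,
#' and pairs whose summary deviates from the median by more than
#' `k` times the SD-consistent MAD (constant 1.4826) are rejected.  With
#' MAD = 0 (e.g. identical pairs) nothing is rejected.
#'
#' @inheritParams split_and_difference
#' @param k rejection threshold in robust SD units (default 3); `Inf`
#'   disables rejection.
#' @return a `perfusion_difference` averaged over the kept pairs, with the
#'   rejected indices recorded in `rejected_pairs`.
#' @export
reject_outlier_pairs <- function(series, si_pd,
                                 brain_mask = array(TRUE, dim(series$volumes)[1:3]),
                                 k = 3) {
  stopifnot(inherits(series, "asl_series"))
  if (series$n_pairs < 4L) {
    stop_devoxel("pair QC needs at least 4 pairs, got ", series$n_pairs,
                 class = "devoxel_malformed_series")
  }
  diffs <- pair_differences(series)
  score <- vapply(seq_len(series$n_pairs), function(j) {
    mean(abs(diffs[, , , j][brain_mask]))
  }, numeric(1))
  med <- stats::median(score)
  mad <- stats::mad(score, center = med, constant = 1.4826)
  rejected <- if (mad == 0 || !is.finite(k)) {
    integer(0)
  } else {
    which(abs(score - med) > k * mad)
  }
  kept <- setdiff(seq_len(series$n_pairs), rejected)
  if (length(kept) == 0L) {
    stop_devoxel("all ", series$n_pairs, " pairs rejected at k = ", k,
                 "; manual review required",
                 class = "devoxel_qc_error")
  }
  if (length(rejected)) {
    message("pair QC rejected ", length(rejected), "/", series$n_pairs,
            " pairs: ", paste(rejected, collapse = ", "))
  }
  new_perfusion_difference(series, si_pd, brain_mask, kept, rejected)
}

#' Effective post-labeling delay of a slice
#'
#' In a 2D multislice readout every slice is acquired `t_slice` later than
#' the previous one, so the effective post-labeling delay grows linearly
#' with the temporal slice position: `t_delay + t_slice * (z - 1)` ms, where
#' `z` is the slice's 1-based temporal acquisition index.
#'
#' @param slice_index 1-based spatial slice index (vectorised).
#' @param acq an [asl_acquisition()].
#' @return effective PLD in milliseconds.
#' @export
effective_pld <- function(slice_index, acq) {
  stopifnot(inherits(acq, "asl_acquisition"))
  if (any(slice_index < 1L | slice_index > acq$n_slices)) {
    stop_devoxel("slice_index out of range 1..", acq$n_slices,
                 class = "devoxel_index_error")
  }
  z <- acq$slice_order[slice_index]
  acq$t_delay + acq$t_slice * (z - 1)
}

# slice-wise scale factor mapping delta-SI / SI_PD to CBF in ml/100 g/min;
# times converted from ms to s
cbf_scale_factor <- function(slice_index, acq) {
  t1b <- acq$t1_blood / 1000
  tau <- acq$tau / 1000
  pld <- effective_pld(slice_index, acq) / 1000
  6000 * acq$lambda_bp * exp(pld / t1b) /
    (2 * acq$alpha * acq$alpha_inv * t1b * (1 - exp(-tau / t1b)))
}

#' Quantify CBF from an averaged ASL difference
#'
#' Applies the single-compartment model
#' \deqn{CBF = \frac{6000\,\lambda\,\Delta SI\, e^{(T_{delay}+T_{slice}(z-1))/T_{1,blood}}}
#'   {2\,\alpha\,\alpha_{inv}\,T_{1,blood}\,SI_{PD}\,(1-e^{-\tau/T_{1,blood}})}}
#' slice by slice, with times in seconds, yielding ml/100 g/min.  Voxels
#' with non-positive proton-density signal are removed from the validity
#' mask; negative CBF values are retained (not clipped) so that downstream
#' z-statistics stay unbiased — their count is recorded in the
#' `n_negative` attribute.
#'
#' @param diff a `perfusion_difference` from [split_and_difference()] or
#'   [reject_outlier_pairs()].
#' @param acq an [asl_acquisition()]; `n_slices` must match the data.
#' @return an object of class `cbf_map` with fields `values` (3D,
#'   ml/100 g/min, `NA` outside `valid_mask`), `valid_mask`, `gm_corrected`,
#'   `gm_threshold_used`, `voxel_dims`.
#' @export
quantify_cbf <- function(diff, acq) {
  stopifnot(inherits(diff, "perfusion_difference"),
            inherits(acq, "asl_acquisition"))
  d <- dim(diff$delta_si)
  if (d[3] != acq$n_slices) {
    stop_devoxel("series has ", d[3], " slices but acquisition declares ",
                 acq$n_slices, class = "devoxel_parameter_error")
  }
  valid <- diff$brain_mask & diff$si_pd > 0
  values <- array(NA_real_, d)
  for (z in seq_len(d[3])) {
    f <- cbf_scale_factor(z, acq)
    sl <- f * diff$delta_si[, , z] / diff$si_pd[, , z]
    values[, , z] <- sl
  }
  values[!valid] <- NA_real_
  structure(
    list(values = values, valid_mask = valid, gm_corrected = FALSE,
         gm_threshold_used = NA_real_, voxel_dims = diff$voxel_dims,
         n_negative = sum(values < 0, na.rm = TRUE)),
    class = "cbf_map"
  )
}

#' Construct a CBF map from raw values
#'
#' Wraps an existing 3D array of perfusion values (ml/100 g/min) in the
#' container used throughout the package, e.g. for maps read back from disk
#' or simulated directly.
#'
#' @param values 3D numeric array.
#' @param valid_mask 3D logical array; defaults to finite voxels.
#' @param voxel_dims voxel size in mm.
#' @param gm_corrected whether GM partial-volume correction was applied.
#' @param gm_threshold_used GM probability cutoff used, if any.
#' @return a `cbf_map`.
#' @export
cbf_map <- function(values, valid_mask = is.finite(values),
                    voxel_dims = c(3, 3, 7), gm_corrected = FALSE,
                    gm_threshold_used = NA_real_) {
  stopifnot(length(dim(values)) == 3L)
  check_same_grid(values, valid_mask, "values", "valid_mask")
  values[!valid_mask] <- NA_real_
  structure(
    list(values = values, valid_mask = valid_mask, gm_corrected = gm_corrected,
         gm_threshold_used = gm_threshold_used,
         voxel_dims = as.numeric(voxel_dims),
         n_negative = sum(values < 0, na.rm = TRUE)),
    class = "cbf_map"
  )
}

#' @export
print.cbf_map <- function(x, ...) {
  v <- x$values[x$valid_mask]
  cat(sprintf("CBF map %s, %d valid voxels, mean %.1f ml/100 g/min%s\n",
              paste(dim(x$values), collapse = "x"), sum(x$valid_mask),
              mean(v), if (x$gm_corrected) " (GM-corrected)" else ""))
  invisible(x)
}

#' Grey-matter partial-volume correction
#'
#' Corrects voxel CBF for the amount of grey matter it contains by dividing
#' by the GM probability.  Voxels below `min_gm` are removed from the
#' validity mask instead of being divided, to avoid amplifying noise where
#' there is hardly any GM.
#'
#' @param cbf a `cbf_map`.
#' @param gm 3D GM probability map in `[0, 1]`, same grid.
#' @param min_gm minimum GM probability for a voxel to be corrected and
#'   kept (default 0.3).
#' @return a GM-corrected `cbf_map`.
#' @export
gm_partial_volume_correct <- function(cbf, gm, min_gm = 0.3) {
  stopifnot(inherits(cbf, "cbf_map"))
  check_same_grid(cbf$values, gm, "CBF map", "GM probability map")
  if (any(gm < 0 | gm > 1, na.rm = TRUE)) {
    stop_devoxel("GM probabilities must lie in [0, 1]",
                 class = "devoxel_parameter_error")
  }
  valid <- cbf$valid_mask & gm >= min_gm
  values <- array(NA_real_, dim(cbf$values))
  values[valid] <- cbf$values[valid] / gm[valid]
  if (!any(valid)) {
    warning("GM threshold ", min_gm, " removed every valid voxel")
  }
  structure(
    list(values = values, valid_mask = valid, gm_corrected = TRUE,
         gm_threshold_used = min_gm, voxel_dims = cbf$voxel_dims,
         n_negative = sum(values < 0, na.rm = TRUE)),
    class = "cbf_map"
  )
}
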