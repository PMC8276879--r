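# The 'distributed deviating voxels' statistic: voxelwise normative
# z-scores against a reference cohort (with exact leave-one-out for
# reference members), two-sided thresholding at a chosen confidence, and
# regional tallies expressed as a percentage of intracranial volume.
#
# The rationale: diffuse disease processes lower perfusion at scattered,
# subject-specific locations.  ROI averages dilute such effects and
# voxelwise parametric maps require spatial overlap across subjects;
# counting each subject's own deviating voxels requires neither.

#' Two-sided critical z threshold
#'
#' Returns the standard-normal quantile such that a fraction `confidence`
#' of null voxels falls inside `(-z, +z)`: `qnorm(1 - (1 - confidence)/2)`.
#' At the default 99% confidence this is 2.576.
#'
#' @param confidence two-sided coverage, in (0, 1).
#' @return the critical z value.
#' @export
critical_z <- function(confidence = 0.99) {
  if (!is.numeric(confidence) || any(confidence <= 0 | confidence >= 1)) {
    stop_devoxel("confidence must lie strictly between 0 and 1",
                 class = "devoxel_domain_error")
  }
  stats::qnorm(1 - (1 - confidence) / 2)
}

#' Region atlas
#'
#' A labelled GM atlas with five regions: four cortical lobes that
#' partition the cerebral cortex, plus subcortical grey matter (accumbens,
#' caudate, pallidum, putamen, thalamus combined).  Label 0 is non-GM
#' tissue.
#'
#' @param labels 3D integer array of region labels.
#' @param region_names named integer vector mapping region name to label;
#'   default `c(frontal=1, temporal=2, parietal=3, occipital=4,
#'   subcortical_gm=5)`.
#' @param cortex_labels labels whose union is the cerebral cortex.
#' @param voxel_dims voxel size in mm.
#' @return an object of class `region_atlas`.
#' @export
region_atlas <- function(labels,
                         region_names = c(frontal = 1L, temporal = 2L,
                                          parietal = 3L, occipital = 4L,
                                          subcortical_gm = 5L),
                         cortex_labels = region_names[c("frontal", "temporal",
                                                        "parietal", "occipital")],
                         voxel_dims = c(3, 3, 7)) {
  stopifnot(length(dim(labels)) == 3L)
  labels <- array(as.integer(labels), dim(labels))
  missing <- region_names[!region_names %in% labels]
  if (length(missing)) {
    stop_devoxel("regions absent from atlas: ",
                 paste(names(missing), collapse = ", "),
                 class = "devoxel_region_error")
  }
  structure(
    list(labels = labels, region_names = region_names,
         cortex_labels = as.integer(cortex_labels),
         gm_mask = labels > 0L, voxel_dims = as.numeric(voxel_dims)),
    class = "region_atlas"
  )
}

# region name -> label set, including the two composite regions used for
# reporting and for the staged gate
atlas_label_sets <- function(atlas) {
  sets <- lapply(atlas$region_names, function(l) l)
  sets$cerebral_cortex <- atlas$cortex_labels
  sets$whole_cerebrum <- unname(atlas$region_names)
  sets[c("whole_cerebrum", "cerebral_cortex",
         names(atlas$region_names))]
}

#' Build a normative reference model
#'
#' Computes the per-voxel mean and sample standard deviation (n-1
#' denominator) of CBF over a reference group, on the intersection of the
#' individual validity masks.  Optionally the input maps are smoothed with
#' an isotropic Gaussian before aggregation (default: none).
#'
#' The model stores the per-voxel sum of squared deviations so that
#' leave-one-out means/SDs can be recovered exactly from the aggregates
#' (see [zscore_map()]).
#'
#' @param ref_maps list of `cbf_map`s on one grid, length >= 3.
#' @param member_ids character ids of the reference subjects (defaults to
#'   list names or `ref1..refN`).
#' @param smoothing_fwhm Gaussian FWHM in mm applied to each map before
#'   aggregation; 0 (default) disables smoothing.
#' @return an object of class `reference_model` with fields `mean_map`,
#'   `sd_map`, `ss_map`, `n_ref`, `member_ids`, `common_mask`,
#'   `smoothing_fwhm`, `voxel_dims`.
#' @export
build_reference <- function(ref_maps, member_ids = NULL, smoothing_fwhm = 0) {
  n <- length(ref_maps)
  if (n < 3L) {
    stop_devoxel("a reference model needs at least 3 subjects, got ", n,
                 class = "devoxel_insufficient_reference")
  }
  stopifnot(all(vapply(ref_maps, inherits, logical(1), "cbf_map")))
  member_ids <- member_ids %||% names(ref_maps) %||% paste0("ref", seq_len(n))
  if (anyDuplicated(member_ids)) {
    stop_devoxel("member_ids must be unique", class = "devoxel_parameter_error")
  }
  d <- dim(ref_maps[[1]]$values)
  common <- Reduce(`&`, lapply(ref_maps, function(m) {
    check_same_grid(ref_maps[[1]]$values, m$values, "first map", "a map")
    m$valid_mask
  }))
  if (!any(common)) {
    stop_devoxel("reference maps share no valid voxels",
                 class = "devoxel_insufficient_reference")
  }
  vd <- ref_maps[[1]]$voxel_dims
  prep <- function(m) {
    v <- m$values
    v[!is.finite(v)] <- 0      # only read on the common mask
    if (smoothing_fwhm > 0) v <- gaussian_smooth_3d(v, smoothing_fwhm, vd)
    v
  }
  s1 <- array(0, d)
  for (m in ref_maps) s1 <- s1 + prep(m)
  mean_map <- s1 / n
  ss <- array(0, d)
  for (m in ref_maps) ss <- ss + (prep(m) - mean_map)^2
  sd_map <- sqrt(ss / (n - 1))
  mean_map[!common] <- NA_real_
  sd_map[!common] <- NA_real_
  ss[!common] <- NA_real_
  structure(
    list(mean_map = mean_map, sd_map = sd_map, ss_map = ss, n_ref = n,
         member_ids = as.character(member_ids), common_mask = common,
         smoothing_fwhm = smoothing_fwhm, voxel_dims = vd),
    class = "reference_model"
  )
}

#' @export
print.reference_model <- function(x, ...) {
  cat(sprintf(
    "Normative reference: n=%d subjects, %d common voxels, smoothing %g mm\n",
    x$n_ref, sum(x$common_mask), x$smoothing_fwhm))
  invisible(x)
}

#' Voxelwise normative z-score map
#'
#' Scores a subject's CBF map against the reference: `z = (x_i - x_ref) /
#' SD_ref` per voxel.  When the subject is itself a member of the reference
#' group (matched via `subject_id`), the reference mean and SD are first
#' recomputed without that subject (leave-one-out), using the exact
#' downdating identities
#' `mean_-i = (n*mean - x_i)/(n-1)` and
#' `SS_-i = SS - n/(n-1) * (x_i - mean)^2`,
#' which reproduce a brute-force rebuild to floating-point accuracy.
#'
#' Voxels where the (possibly leave-one-out) SD is zero, or which fall
#' outside the common mask or the subject's validity mask, are excluded and
#' counted.
#'
#' @param subject a `cbf_map` on the model grid.  If the model was built
#'   with smoothing, the same smoothing is applied to the subject map so
#'   subject and reference are processed identically.
#' @param model a [build_reference()] model.
#' @param subject_id id used to detect reference membership; `NULL` (default)
#'   means a non-member.
#' @return an object of class `z_map` with fields `z` (3D, `NA` where
#'   excluded), `subject_id`, `loo_applied`, `excluded_voxels`,
#'   `valid_mask`, `voxel_dims`.
#' @export
zscore_map <- function(subject, model, subject_id = NULL) {
  stopifnot(inherits(subject, "cbf_map"), inherits(model, "reference_model"))
  check_same_grid(subject$values, model$mean_map, "subject map", "reference")
  x <- subject$values
  x[!is.finite(x)] <- 0        # only read where masks allow
  if (model$smoothing_fwhm > 0) {
    x <- gaussian_smooth_3d(x, model$smoothing_fwhm, model$voxel_dims)
  }
  loo <- !is.null(subject_id) && subject_id %in% model$member_ids
  if (loo) {
    n <- model$n_ref
    if (n <= 3L) {
      warning("leave-one-out reference of only n-1 = ", n - 1L,
              " subjects: z-scores are unreliable")
    }
    mean_ref <- (n * model$mean_map - x) / (n - 1)
    ss_ref <- model$ss_map - n / (n - 1) * (x - model$mean_map)^2
    ss_ref[ss_ref < 0] <- 0    # guard tiny negative rounding residue
    sd_ref <- sqrt(ss_ref / (n - 2))
  } else {
    mean_ref <- model$mean_map
    sd_ref <- model$sd_map
  }
  valid <- model$common_mask & subject$valid_mask &
    is.finite(sd_ref) & sd_ref > 0
  z <- array(NA_real_, dim(x))
  z[valid] <- (x[valid] - mean_ref[valid]) / sd_ref[valid]
  structure(
    list(z = z, subject_id = subject_id %||% NA_character_,
         loo_applied = loo,
         excluded_voxels = sum(model$common_mask & subject$valid_mask) - sum(valid),
         valid_mask = valid, voxel_dims = model$voxel_dims),
    class = "z_map"
  )
}

#' Tally deviating voxels per region
#'
#' Counts, per atlas region, the voxels whose z-score deviates beyond the
#' two-sided threshold — strictly `z < -z_crit` (hypoperfusion) and
#' `z > +z_crit` (hyperperfusion), reported separately — and expresses the
#' counts as a percentage of the subject's intracranial volume:
#' `100 * count * voxel_volume / icv`.
#'
#' Counting is restricted to the intersection of the atlas GM mask and the
#' z-map's valid domain; the denominator stays the full ICV.  Reported
#' regions are the whole cerebrum (all GM labels), the cerebral cortex
#' (union of the four lobes) and each individual region.
#'
#' @param zmap a [zscore_map()] result.
#' @param atlas a [region_atlas()] on the same grid.
#' @param z_crit positive threshold, e.g. [critical_z()]`(0.99)`.
#' @param icv the subject's intracranial volume (mm^3).
#' @param voxel_volume voxel volume (mm^3); default from the z-map's voxel
#'   dimensions.
#' @return a `data.frame` (class `deviation_tally`) with columns `region`,
#'   `n_voxels_eval`, `n_neg`, `n_pos`, `frac_neg_icv_pct`,
#'   `frac_pos_icv_pct`, and attributes `icv`, `voxel_volume`, `z_crit`.
#' @export
flag_and_tally <- function(zmap, atlas, z_crit = critical_z(0.99), icv,
                           voxel_volume = prod(zmap$voxel_dims)) {
  stopifnot(inherits(zmap, "z_map"), inherits(atlas, "region_atlas"))
  check_same_grid(zmap$z, atlas$labels, "z map", "atlas")
  if (z_crit <= 0) {
    stop_devoxel("z_crit must be > 0", class = "devoxel_domain_error")
  }
  if (icv <= 0) {
    stop_devoxel("icv must be > 0", class = "devoxel_domain_error")
  }
  eval_mask <- zmap$valid_mask & atlas$gm_mask
  lab <- atlas$labels[eval_mask]
  z <- zmap$z[eval_mask]
  sets <- atlas_label_sets(atlas)
  rows <- lapply(names(sets), function(rn) {
    in_region <- lab %in% sets[[rn]]
    n_neg <- sum(z[in_region] < -z_crit)
    n_pos <- sum(z[in_region] > z_crit)
    data.frame(region = rn, n_voxels_eval = sum(in_region),
               n_neg = n_neg, n_pos = n_pos,
               frac_neg_icv_pct = 100 * n_neg * voxel_volume / icv,
               frac_pos_icv_pct = 100 * n_pos * voxel_volume / icv)
  })
  out <- do.call(rbind, rows)
  attr(out, "icv") <- icv
  attr(out, "voxel_volume") <- voxel_volume
  attr(out, "z_crit") <- z_crit
  attr(out, "subject_id") <- zmap$subject_id
  class(out) <- c("deviation_tally", "data.frame")
  out
}
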