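# Shared fixtures, all generated in code.

# desk-scale phantom used across tests (region sizes at this grid:
# frontal/occipital 302, temporal/parietal 234, subcortical 40 voxels)
small_spec <- phantom_spec(grid_dim = c(20, 24, 8))
small_anatomy <- make_phantom_anatomy(small_spec)

# ASL series whose per-pair control-label difference is uniform at the
# given values (one value per pair), on a tiny grid
uniform_diff_series <- function(pair_diffs, dim3 = c(4, 4, 3), baseline = 100) {
  n_pairs <- length(pair_diffs)
  vols <- array(0, c(dim3, 2L * n_pairs))
  for (p in seq_len(n_pairs)) {
    vols[, , , 2L * p - 1L] <- baseline + pair_diffs[p] / 2
    vols[, , , 2L * p] <- baseline - pair_diffs[p] / 2
  }
  asl_series(vols, pairing = "control_first", voxel_dims = c(3, 3, 7))
}

constant_pd <- function(dim3 = c(4, 4, 3), level = 100) array(level, dim3)

# cbf_map with given constant value on the small anatomy's brain
flat_map <- function(value, anatomy = small_anatomy, spec = small_spec) {
  v <- array(NA_real_, spec$grid_dim)
  v[anatomy$brain_mask] <- value
  cbf_map(v, valid_mask = anatomy$brain_mask, voxel_dims = spec$voxel_dims)
}

# iid-noise cbf_map on an arbitrary grid (for reference-model statistics)
noise_map <- function(dim3, mean = 0, sd = 1, voxel_dims = c(3, 3, 7)) {
  cbf_map(array(rnorm(prod(dim3), mean, sd), dim3),
          valid_mask = array(TRUE, dim3), voxel_dims = voxel_dims)
}

# the printed exclusion cascade: 47 T2DM / 41 controls recruited
paper_cascade_cohort <- function() {
  n_t2dm <- 47L
  n_ctrl <- 41L
  df <- data.frame(
    id = c(sprintf("t2dm%02d", 1:n_t2dm), sprintf("ctrl%02d", 1:n_ctrl)),
    group_t2dm = rep(c(TRUE, FALSE), c(n_t2dm, n_ctrl)),
    group_cognition = "high",
    exclusion_cbf = "", exclusion_flow = "",
    stringsAsFactors = FALSE
  )
  df$exclusion_cbf[1:6] <- c("claustrophobia", "claustrophobia",
                             "parkinsonism", "brain_injury",
                             "incidental_finding", "asl_artifact")
  df$exclusion_flow[7:11] <- "no_ecg"          # 5 further T2DM, flow only
  df$exclusion_cbf[n_t2dm + 1:2] <- "impaired_fasting_glucose"
  df$exclusion_flow[n_t2dm + 3:4] <- "no_ecg"  # 2 further controls
  cohort_table(df)
}

# one full simulate -> reference -> z -> tally -> group-test replicate;
# returns p-values of the deviating-voxel test and the ROI-mean test for
# the lesioned region
pipeline_replicate <- function(rep_seed, lesion = NULL,
                               region = if (is.null(lesion)) "whole_cerebrum"
                                        else lesion$region,
                               n_per_group = 12, spec = small_spec) {
  sim <- simulate_cohort(n_per_group = n_per_group, spec = spec,
                         lesion = lesion, seed = rep_seed)
  ref_ids <- sim$cohort$id[!sim$cohort$group_t2dm]
  model <- build_reference(sim$maps[ref_ids], member_ids = ref_ids)
  zc <- critical_z(0.99)
  frac <- vapply(sim$cohort$id, function(id) {
    zm <- zscore_map(sim$maps[[id]], model, subject_id = id)
    tl <- flag_and_tally(zm, sim$anatomy$atlas, z_crit = zc,
                         icv = sim$anatomy$icv)
    tl$frac_neg_icv_pct[tl$region == region]
  }, numeric(1))
  roi <- vapply(sim$cohort$id, function(id) {
    roi_mean_cbf(sim$maps[[id]], sim$anatomy$atlas)[[region]]
  }, numeric(1))
  g <- factor(ifelse(sim$cohort$group_t2dm, "t2dm", "control"))
  c(dev = group_compare(frac, g)$p_value,
    roi = group_compare(roi, g)$p_value)
}
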