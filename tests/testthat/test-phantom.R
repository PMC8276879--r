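test_that("phantom anatomy is deterministic with exact region structure", {
  an <- make_phantom_anatomy(small_spec)
  an2 <- make_phantom_anatomy(small_spec)
  expect_identical(an, an2)                     # construction is seed-free

  labs <- an$atlas$labels
  for (rn in names(an$atlas$region_names)) {
    expect_gt(sum(labs == an$atlas$region_names[[rn]]), 0)
  }
  # lobes partition the cortex shell exactly and regions do not overlap
  cortex <- labs %in% an$atlas$cortex_labels
  expect_identical(sum(cortex),
                   sum(vapply(an$atlas$cortex_labels,
                              function(l) sum(labs == l), integer(1))))
  expect_true(all(labs[labs == 5L] == 5L))
  expect_true(all(an$atlas$gm_mask == (labs > 0L)))
  expect_true(all(an$brain_mask[an$atlas$gm_mask]))

  # ICV is voxel count times voxel volume
  expect_equal(an$icv, sum(an$brain_mask) * prod(small_spec$voxel_dims))
  spec8 <- phantom_spec(grid_dim = small_spec$grid_dim,
                        voxel_dims = 2 * small_spec$voxel_dims)
  expect_equal(make_phantom_anatomy(spec8)$icv, 8 * an$icv)

  expect_error(make_phantom_anatomy(phantom_spec(grid_dim = c(4, 4, 4))),
               class = "devoxel_geometry_error")
})

test_that("ASL forward model inverts exactly without noise", {
  acq <- asl_acquisition(n_slices = 8)
  spec <- phantom_spec(grid_dim = c(10, 12, 8), asl_noise_sd = 0, n_pairs = 4)
  an <- make_phantom_anatomy(spec)
  truth <- devoxel:::phantom_true_cbf(spec, an)
  sim <- simulate_asl_series(truth, acq, spec)
  d <- split_and_difference(sim$series, sim$si_pd, an$brain_mask)
  cbf <- quantify_cbf(d, acq)
  sel <- an$brain_mask & truth > 0
  expect_lt(max(abs(cbf$values[sel] - truth[sel]) / truth[sel]), 1e-9)
})

test_that("noisy ASL recovery is unbiased within sampling error", {
  acq <- asl_acquisition(n_slices = 8)
  spec <- phantom_spec(grid_dim = c(8, 8, 8), asl_noise_sd = 2, n_pairs = 50)
  an <- make_phantom_anatomy(spec)
  truth <- devoxel:::phantom_true_cbf(spec, an)
  sim <- simulate_asl_series(truth, acq, spec, seed = 9)
  cbf <- quantify_cbf(split_and_difference(sim$series, sim$si_pd,
                                           an$brain_mask), acq)
  # delta-SI noise: sd sqrt(2)*asl_sd/sqrt(n_pairs), scaled per slice
  for (z in 1:8) {
    f <- devoxel:::cbf_scale_factor(z, acq)
    se_cbf <- f / spec$si_pd_level * sqrt(2) * spec$asl_noise_sd /
      sqrt(spec$n_pairs)
    sl_mask <- an$brain_mask[, , z]
    err <- abs(cbf$values[, , z][sl_mask] - truth[, , z][sl_mask])
    expect_true(all(err < 5 * se_cbf))
  }

  sim2 <- simulate_asl_series(truth, acq, spec, seed = 9)
  expect_identical(sim$series$volumes, sim2$series$volumes)  # determinism
})

test_that("lesion injection shifts the right voxels and stays disjoint", {
  an <- small_anatomy
  truth <- devoxel:::phantom_true_cbf(small_spec, an)
  les0 <- inject_lesions(truth, 5, lesion_spec(fraction = 0), an$atlas,
                         seed = 1)
  expect_identical(les0$values, truth)
  expect_false(any(les0$lesion_mask))

  les <- lesion_spec("frontal", fraction = 0.05, depth = -4)
  a <- inject_lesions(truth, 5, les, an$atlas, seed = 2)
  expect_true(all(an$atlas$labels[a$lesion_mask] ==
                  an$atlas$region_names[["frontal"]]))
  expect_equal(unique(truth[a$lesion_mask] - a$values[a$lesion_mask]), 20)
  b <- inject_lesions(truth, 5, les, an$atlas, exclude_mask = a$lesion_mask,
                      seed = 3)
  expect_false(any(a$lesion_mask & b$lesion_mask))

  expect_error(inject_lesions(truth, 5, lesion_spec("frontal", 1), an$atlas,
                              exclude_mask = a$lesion_mask, seed = 4),
               class = "devoxel_geometry_error")
  expect_error(inject_lesions(truth, 5, lesion_spec("cerebellum", 0.1),
                              an$atlas, seed = 5),
               class = "devoxel_region_error")
})

test_that("deep lesions are flagged at the normal-tail rate", {
  # oracle: a -4 SD shift against an exact reference flags with probability
  # P(N(-4,1) < -2.576) ~ 0.92; with a large noise-free-subject reference
  # and no subject noise essentially every lesion voxel is flagged
  set.seed(81)
  dim3 <- c(12, 12, 5)
  n_ref <- 60
  maps <- replicate(n_ref, noise_map(dim3, 30, 5), simplify = FALSE)
  model <- build_reference(maps)
  subj <- array(30, dim3)
  lesion_idx <- sample(prod(dim3), 50)
  subj[lesion_idx] <- 30 - 4 * 5
  z <- zscore_map(cbf_map(subj, voxel_dims = c(3, 3, 7)), model)
  flagged <- z$z[lesion_idx] < -critical_z(0.99)
  expect_gte(mean(flagged), 0.95)
})

test_that("cohort simulation is seeded and effects are region-specific", {
  les <- lesion_spec("subcortical_gm", fraction = 0.05, depth = -5)
  s1 <- simulate_cohort(n_per_group = 6, spec = small_spec, lesion = les,
                        seed = 11)
  s2 <- simulate_cohort(n_per_group = 6, spec = small_spec, lesion = les,
                        seed = 11)
  expect_identical(s1$maps, s2$maps)
  expect_identical(s1$cohort, s2$cohort)

  # lesions only in T2DM subjects, mutually disjoint
  expect_identical(sort(names(s1$lesion_masks)),
                   sort(s1$cohort$id[s1$cohort$group_t2dm]))
  overlap <- Reduce(`+`, s1$lesion_masks)
  expect_lte(max(overlap), 1)

  expect_error(simulate_cohort(n_per_group = 2, spec = small_spec),
               class = "devoxel_parameter_error")

  # specificity: a strong subcortical lesion is flagged voxel-for-voxel in
  # the subcortical tally and leaves the occipital tally silent.  The
  # global between-subject offset channel is switched off so the example
  # isolates effect routing (with it on, occasional globally hypoperfused
  # subjects legitimately flag voxels everywhere).
  strong <- lesion_spec("subcortical_gm", fraction = 0.075, depth = -6)
  spec_iso <- phantom_spec(grid_dim = c(20, 24, 8), between_subject_sd = 0)
  sim <- simulate_cohort(n_per_group = 12, spec = spec_iso,
                         lesion = strong, seed = 101)
  ref_ids <- sim$cohort$id[!sim$cohort$group_t2dm]
  model <- build_reference(sim$maps[ref_ids], member_ids = ref_ids)
  zc <- critical_z(0.99)
  tallies <- lapply(sim$cohort$id, function(id) {
    zm <- zscore_map(sim$maps[[id]], model, subject_id = id)
    if (id %in% names(sim$lesion_masks)) {       # lesion voxels recovered
      expect_gte(mean(zm$z[sim$lesion_masks[[id]]] < -zc), 0.9)
    }
    flag_and_tally(zm, sim$anatomy$atlas, z_crit = zc,
                   icv = sim$anatomy$icv)
  })
  count_in <- function(region) {
    vapply(tallies, function(tl) tl$n_neg[tl$region == region], integer(1))
  }
  t2dm <- sim$cohort$group_t2dm
  n_les <- sum(sim$lesion_masks[[1]])
  expect_gte(mean(count_in("subcortical_gm")[t2dm]) -
             mean(count_in("subcortical_gm")[!t2dm]), 0.8 * n_les)
  expect_lt(abs(mean(count_in("occipital")[t2dm]) -
                mean(count_in("occipital")[!t2dm])), 0.8 * n_les)
})

test_that("global group offset moves ROI means as configured", {
  s <- simulate_cohort(n_per_group = 8, spec = small_spec,
                       group_offset = -3.2, seed = 21)
  means <- vapply(s$cohort$id, function(id) {
    roi_mean_cbf(s$maps[[id]], s$anatomy$atlas)[["whole_cerebrum"]]
  }, numeric(1))
  diff_obs <- mean(means[s$cohort$group_t2dm]) -
    mean(means[!s$cohort$group_t2dm])
  se <- small_spec$between_subject_sd * sqrt(2 / 8)
  expect_lt(abs(diff_obs - (-3.2)), 4 * se)
})
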