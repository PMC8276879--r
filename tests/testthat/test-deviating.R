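test_that("critical z is the two-sided normal quantile", {
  expect_equal(round(critical_z(0.99), 3), 2.576)
  expect_equal(round(critical_z(0.9544997), 3), 2.000)
  expect_lt(critical_z(1e-8), 1e-7)            # coverage -> 0, threshold -> 0
  expect_error(critical_z(0), class = "devoxel_domain_error")
  expect_error(critical_z(1), class = "devoxel_domain_error")
  expect_error(critical_z(1.2), class = "devoxel_domain_error")
})

test_that("reference model aggregates per-voxel mean and sample SD", {
  m <- flat_map(30)
  model <- build_reference(list(a = m, b = m, c = m))
  expect_true(all(model$sd_map[model$common_mask] == 0))
  expect_true(all(model$mean_map[model$common_mask] == 30))

  maps <- lapply(c(28, 30, 32), flat_map)
  model2 <- build_reference(maps)
  expect_true(all(abs(model2$mean_map[model2$common_mask] - 30) < 1e-12))
  expect_true(all(abs(model2$sd_map[model2$common_mask] - 2) < 1e-12))
  expect_identical(model2$n_ref, 3L)

  expect_error(build_reference(list(m, m)),
               class = "devoxel_insufficient_reference")

  # common mask is the intersection of valid masks
  m2 <- m
  m2$valid_mask[1, 1, ] <- FALSE
  model3 <- build_reference(list(m, m2, m))
  expect_false(any(model3$common_mask[1, 1, ]))
})

test_that("reference statistics match their sampling distribution", {
  set.seed(13)
  dim3 <- c(12, 12, 5)
  n <- 20
  maps <- replicate(n, noise_map(dim3, 31.5, 5.9), simplify = FALSE)
  model <- build_reference(maps)
  se <- 5.9 / sqrt(n)
  expect_true(all(abs(model$mean_map - 31.5) < 5 * se))
  # sample SD lies within extreme chi-square sampling bounds per voxel
  bounds <- 5.9 * sqrt(qchisq(c(1e-7, 1 - 1e-7), n - 1) / (n - 1))
  expect_true(all(model$sd_map > bounds[1] & model$sd_map < bounds[2]))
})

test_that("z maps score against the reference; LOO matches brute force", {
  set.seed(17)
  dim3 <- c(8, 9, 4)
  n <- 8
  maps <- replicate(n, noise_map(dim3, 30, 6), simplify = FALSE)
  names(maps) <- paste0("s", 1:n)
  model <- build_reference(maps, member_ids = names(maps))

  # non-member identical to the mean scores zero
  ident <- cbf_map(model$mean_map, valid_mask = model$common_mask,
                   voxel_dims = c(3, 3, 7))
  z0 <- zscore_map(ident, model)
  expect_true(all(abs(z0$z[z0$valid_mask]) < 1e-12))
  expect_false(z0$loo_applied)

  # direct formula: (15 - 30) / 5 = -3
  lo <- build_reference(lapply(c(25, 30, 35), flat_map))
  subj <- flat_map(15)
  zlo <- zscore_map(subj, lo)
  expect_true(all(abs(zlo$z[zlo$valid_mask] + 3) < 1e-12))

  # LOO for every member equals a model rebuilt without that member
  for (i in c(1L, 4L, 8L)) {
    z_loo <- zscore_map(maps[[i]], model, subject_id = names(maps)[i])
    expect_true(z_loo$loo_applied)
    brute <- build_reference(maps[-i], member_ids = names(maps)[-i])
    z_brute <- zscore_map(maps[[i]], brute)
    expect_equal(z_loo$z, z_brute$z, tolerance = 1e-10)
  }

  # LOO z has larger spread than naive in-sample scoring
  z_in <- zscore_map(maps[[1]], model)                    # no LOO
  z_out <- zscore_map(maps[[1]], model, subject_id = "s1")
  expect_gt(sd(z_out$z[z_out$valid_mask]), sd(z_in$z[z_in$valid_mask]))

  # minimal reference: LOO proceeds with n-1 = 2 but warns
  small <- build_reference(maps[1:3], member_ids = names(maps)[1:3])
  expect_warning(zscore_map(maps[[1]], small, subject_id = "s1"),
                 "unreliable")
})

test_that("zero-SD voxels are excluded and counted", {
  maps <- lapply(c(28, 30, 32), flat_map)
  idx <- which(small_anatomy$brain_mask)[1]
  for (m in seq_along(maps)) maps[[m]]$values[idx] <- 99  # one common voxel
  model <- build_reference(maps)                          # sd = 0 there
  z <- zscore_map(flat_map(20), model)
  expect_false(z$valid_mask[idx])
  expect_identical(z$excluded_voxels, 1L)
  expect_true(all(is.finite(z$z[z$valid_mask])))
})

test_that("tallies count strict threshold exceedances per region", {
  atlas <- small_anatomy$atlas
  icv <- small_anatomy$icv
  vol <- prod(small_spec$voxel_dims)
  mk_z <- function(zvals) {
    structure(list(z = zvals, subject_id = "x", loo_applied = FALSE,
                   excluded_voxels = 0L,
                   valid_mask = array(TRUE, dim(zvals)),
                   voxel_dims = small_spec$voxel_dims),
              class = "z_map")
  }
  z0 <- mk_z(array(0, small_spec$grid_dim))
  t0 <- flag_and_tally(z0, atlas, z_crit = 2.576, icv = icv)
  expect_true(all(t0$n_neg == 0) && all(t0$n_pos == 0))
  expect_true(all(t0$frac_neg_icv_pct == 0))

  # reporting arithmetic: 100 voxels of 8 mm^3 against ICV 1.4e6 mm^3
  expect_equal(100 * 100 * 8 / 1.4e6, 0.05714286, tolerance = 1e-6)
  zz <- array(0, small_spec$grid_dim)
  frontal_idx <- which(atlas$labels == atlas$region_names[["frontal"]])
  zz[frontal_idx[1:100]] <- -3
  t1 <- flag_and_tally(mk_z(zz), atlas, z_crit = 2.576, icv = 1.4e6,
                       voxel_volume = 8)
  expect_identical(t1$n_neg[t1$region == "frontal"], 100L)
  expect_equal(t1$frac_neg_icv_pct[t1$region == "frontal"], 0.05714286,
               tolerance = 1e-6)

  # values exactly at the threshold are not flagged (strict inequality)
  zb <- array(0, small_spec$grid_dim)
  zb[frontal_idx[1:10]] <- 2.576
  zb[frontal_idx[11:20]] <- -2.576
  tb <- flag_and_tally(mk_z(zb), atlas, z_crit = 2.576, icv = icv)
  expect_true(all(tb$n_neg == 0) && all(tb$n_pos == 0))

  # region additivity: lobes partition the cortex; cortex + subcortical
  # partition the whole cerebrum
  set.seed(31)
  zr <- mk_z(array(rnorm(prod(small_spec$grid_dim), 0, 1.6),
                   small_spec$grid_dim))
  tr <- flag_and_tally(zr, atlas, z_crit = 2, icv = icv)
  g <- function(col, rn) tr[[col]][tr$region == rn]
  lobes <- c("frontal", "temporal", "parietal", "occipital")
  for (col in c("n_neg", "n_pos")) {
    expect_identical(sum(vapply(lobes, g, integer(1), col = col)),
                     g(col, "cerebral_cortex"))
    expect_identical(g(col, "cerebral_cortex") + g(col, "subcortical_gm"),
                     g(col, "whole_cerebrum"))
  }

  expect_error(flag_and_tally(z0, atlas, z_crit = -1, icv = icv),
               class = "devoxel_domain_error")
  expect_error(flag_and_tally(z0, atlas, z_crit = 2.576, icv = 0),
               class = "devoxel_domain_error")
  expect_error(region_atlas(array(0L, c(4, 4, 4))),
               class = "devoxel_region_error")
})

test_that("null tail fraction exceeds the Gaussian tail and converges", {
  # at finite n_ref the normative z has t-like tails: the flagged fraction
  # is above 2*(1 - pnorm(z_crit)) and decreases monotonically toward it
  set.seed(41)
  dim3 <- c(40, 25, 20)                       # 20k voxels
  z_crit <- critical_z(0.99)
  gauss_tail <- 2 * (1 - pnorm(z_crit))
  flagged <- vapply(c(10, 30, 100), function(n_ref) {
    maps <- replicate(n_ref, noise_map(dim3), simplify = FALSE)
    model <- build_reference(maps)
    z <- zscore_map(noise_map(dim3), model)
    mean(abs(z$z[z$valid_mask]) > z_crit)
  }, numeric(1))
  expect_true(all(flagged > gauss_tail))
  expect_true(all(diff(flagged) < 0))
  # exact finite-n oracle: |z| * sqrt(n/(n+1)) ~ t_{n-1}
  exact <- vapply(c(10, 30, 100), function(n) {
    2 * pt(z_crit * sqrt(n / (n + 1)), df = n - 1, lower.tail = FALSE)
  }, numeric(1))
  expect_equal(flagged, exact, tolerance = 0.15)
})

test_that("optional smoothing is applied consistently to subject and reference", {
  set.seed(51)
  dim3 <- c(10, 10, 6)
  maps <- replicate(6, noise_map(dim3, 30, 5), simplify = FALSE)
  names(maps) <- paste0("s", 1:6)
  sm <- build_reference(maps, member_ids = names(maps), smoothing_fwhm = 6)
  raw <- build_reference(maps, member_ids = names(maps))
  expect_lt(mean(sm$sd_map), mean(raw$sd_map))  # smoothing pools noise
  # constant maps are invariant under the renormalised kernel
  const <- build_reference(lapply(c(28, 30, 32), function(v) {
    cbf_map(array(v, dim3), voxel_dims = c(3, 3, 7))
  }), smoothing_fwhm = 6)
  expect_true(all(abs(const$mean_map - 30) < 1e-9))
  expect_true(all(abs(const$sd_map - 2) < 1e-9))
})
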