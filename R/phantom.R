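# Seeded synthetic phantoms: anatomy (atlas + GM probability + ICV), ASL
# forward simulation by algebraic inversion of the quantification model,
# scattered hypoperfusion lesions, phase-contrast cines, and whole cohorts.
#
# The stated world: a 2D multislice pCASL acquisition with 17 slices and 50
# control-label pairs; grey-matter CBF around 31.5 ml/100 g/min with a
# between-subject spread of 5.9 (the healthy-control distribution); lesions
# are small, scattered, and land at non-overlapping locations across
# subjects (a diffuse, non-focal disease process).

#' Phantom specification
#'
#' @param grid_dim grid size (x, y, slices).
#' @param voxel_dims voxel size in mm.
#' @param cbf_gm named true CBF per GM region (ml/100 g/min).
#' @param cbf_non_gm true CBF of non-GM brain tissue.
#' @param between_subject_sd SD of the per-subject global GM perfusion
#'   offset (ml/100 g/min).
#' @param voxel_noise_sd SD of voxel-level map noise (ml/100 g/min).
#' @param asl_noise_sd per-repetition Gaussian noise on the raw ASL signal
#'   (scanner units).
#' @param n_pairs control-label pairs per ASL series.
#' @param si_pd_level proton-density signal level (scanner units).
#' @param seed default RNG seed for generators consuming this spec.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_dim = c(40, 48, 17), voxel_dims = c(3, 3, 7),
                         cbf_gm = c(frontal = 32, temporal = 30,
                                    parietal = 32, occipital = 33,
                                    subcortical_gm = 31),
                         cbf_non_gm = 15,
                         between_subject_sd = 5.9, voxel_noise_sd = 5,
                         asl_noise_sd = 2, n_pairs = 50, si_pd_level = 800,
                         seed = 1L) {
  stopifnot(length(grid_dim) == 3L, all(grid_dim >= 4),
            length(voxel_dims) == 3L, all(voxel_dims > 0),
            all(c("frontal", "temporal", "parietal", "occipital",
                  "subcortical_gm") %in% names(cbf_gm)),
            between_subject_sd >= 0, voxel_noise_sd >= 0, asl_noise_sd >= 0,
            n_pairs >= 1)
  if (si_pd_level <= 0) {
    stop_devoxel("si_pd_level must be > 0", class = "devoxel_parameter_error")
  }
  structure(
    list(grid_dim = as.integer(grid_dim), voxel_dims = as.numeric(voxel_dims),
         cbf_gm = cbf_gm, cbf_non_gm = cbf_non_gm,
         between_subject_sd = between_subject_sd,
         voxel_noise_sd = voxel_noise_sd, asl_noise_sd = asl_noise_sd,
         n_pairs = as.integer(n_pairs), si_pd_level = si_pd_level,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Generate phantom anatomy
#'
#' Deterministic geometric anatomy: an ellipsoidal intracranial space whose
#' outer shell is the cerebral cortex, divided by axial angular sector into
#' four lobes that exactly partition it (frontal, temporal, parietal,
#' occipital), with a central ellipsoid of subcortical grey matter.  GM
#' probability is high (0.85) inside GM labels, low (0.15) in the remaining
#' brain tissue, 0 outside.  ICV is the intracranial voxel count times the
#' voxel volume.
#'
#' @param spec a [phantom_spec()].
#' @return list with `atlas` ([region_atlas()]), `gm_prob` (3D array),
#'   `brain_mask`, `icv` (mm^3), `voxel_volume` (mm^3).
#' @export
make_phantom_anatomy <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_dim
  cx <- (d + 1) / 2
  ax <- 0.45 * d
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  r <- sqrt(((g$x - cx[1]) / ax[1])^2 + ((g$y - cx[2]) / ax[2])^2 +
            ((g$z - cx[3]) / ax[3])^2)
  brain <- array(r <= 1, d)
  labels <- array(0L, d)
  theta <- atan2(g$y - cx[2], g$x - cx[1]) * 180 / pi  # [-180, 180)
  theta <- (theta + 360) %% 360
  cortex <- r > 0.65 & r <= 1
  sector <- ifelse(theta >= 45 & theta < 135, 1L,       # frontal
             ifelse(theta >= 135 & theta < 225, 2L,     # temporal
              ifelse(theta >= 225 & theta < 315, 4L,    # occipital
                     3L)))                              # parietal
  labels[cortex] <- sector[cortex]
  labels[array(r <= 0.30, d)] <- 5L
  gm_prob <- array(0, d)
  gm_prob[brain] <- 0.15
  gm_prob[labels > 0L] <- 0.85
  if (!all(1:5 %in% labels)) {
    stop_devoxel("grid too small: some atlas regions are empty",
                 class = "devoxel_geometry_error")
  }
  voxel_volume <- prod(spec$voxel_dims)
  list(
    atlas = region_atlas(labels, voxel_dims = spec$voxel_dims),
    gm_prob = gm_prob, brain_mask = brain,
    icv = sum(brain) * voxel_volume, voxel_volume = voxel_volume
  )
}

# true CBF array implied by a spec and its anatomy
phantom_true_cbf <- function(spec, anatomy) {
  cbf <- array(0, spec$grid_dim)
  cbf[anatomy$brain_mask] <- spec$cbf_non_gm
  for (rn in names(anatomy$atlas$region_names)) {
    lb <- anatomy$atlas$region_names[[rn]]
    cbf[anatomy$atlas$labels == lb] <- spec$cbf_gm[[rn]]
  }
  cbf
}

# delta-SI that makes quantify_cbf return exactly `cbf` at slice z,
# given the PD level: algebraic inversion of the quantification model
invert_cbf_to_delta_si <- function(cbf, acq, si_pd_level) {
  d <- dim(cbf)
  delta <- array(0, d)
  for (z in seq_len(d[3])) {
    delta[, , z] <- cbf[, , z] * si_pd_level / cbf_scale_factor(z, acq)
  }
  delta
}

#' Simulate an ASL control/label series
#'
#' Forward model: the per-voxel difference signal is obtained by algebraic
#' inversion of the quantification equation at that voxel's slice, then
#' `control = baseline + dSI/2 + noise`, `label = baseline - dSI/2 + noise`
#' with i.i.d. Gaussian noise per repetition; the proton-density image is
#' the constant `si_pd_level`.  With zero noise, [quantify_cbf()] recovers
#' the true map to numerical precision (forward/inverse consistency).
#'
#' @param true_cbf 3D array of true CBF (ml/100 g/min); its slice count
#'   must match `acq$n_slices`.
#' @param acq an [asl_acquisition()].
#' @param spec a [phantom_spec()] supplying `n_pairs`, `asl_noise_sd`,
#'   `si_pd_level`, `voxel_dims`.
#' @param seed RNG seed (default from spec).
#' @return list with `series` ([asl_series()]), `si_pd` (3D array),
#'   `delta_si_true`.
#' @export
simulate_asl_series <- function(true_cbf, acq, spec, seed = spec$seed) {
  stopifnot(inherits(acq, "asl_acquisition"), inherits(spec, "phantom_spec"))
  if (!all(is.finite(true_cbf))) {
    stop_devoxel("true_cbf must be finite", class = "devoxel_parameter_error")
  }
  d <- dim(true_cbf)
  if (d[3] != acq$n_slices) {
    stop_devoxel("true_cbf has ", d[3], " slices, acquisition declares ",
                 acq$n_slices, class = "devoxel_parameter_error")
  }
  set.seed(seed)
  delta <- invert_cbf_to_delta_si(true_cbf, acq, spec$si_pd_level)
  baseline <- 0.1 * spec$si_pd_level   # static tissue after suppression
  n_rep <- 2L * spec$n_pairs
  vols <- array(0, c(d, n_rep))
  for (p in seq_len(spec$n_pairs)) {
    noise_c <- array(stats::rnorm(prod(d), 0, spec$asl_noise_sd), d)
    noise_l <- array(stats::rnorm(prod(d), 0, spec$asl_noise_sd), d)
    vols[, , , 2L * p - 1L] <- baseline + delta / 2 + noise_c
    vols[, , , 2L * p] <- baseline - delta / 2 + noise_l
  }
  list(
    series = asl_series(vols, pairing = "control_first",
                        voxel_dims = spec$voxel_dims),
    si_pd = array(spec$si_pd_level, d),
    delta_si_true = delta
  )
}

#' Lesion specification
#'
#' @param region atlas region receiving the lesion.
#' @param fraction fraction of the region's voxels lesioned per subject,
#'   in `[0, 1]`.
#' @param depth lesion amplitude in units of the local reference SD
#'   (negative = hypoperfusion; default -4).
#' @param scatter `"non_overlapping"` (lesion locations are disjoint across
#'   subjects) or `"independent"`.
#' @return an object of class `lesion_spec`.
#' @export
lesion_spec <- function(region = "subcortical_gm", fraction = 0.03,
                        depth = -4,
                        scatter = c("non_overlapping", "independent")) {
  scatter <- match.arg(scatter)
  stopifnot(fraction >= 0, fraction <= 1, is.finite(depth))
  structure(list(region = region, fraction = fraction, depth = depth,
                 scatter = scatter),
            class = "lesion_spec")
}

#' Inject scattered lesions into a true CBF map
#'
#' Shifts a random subset of the target region's voxels by
#' `depth * local reference SD`.  When lesions must not overlap across
#' subjects, pass the union of previously used locations as
#' `exclude_mask`; sampling then avoids it.
#'
#' @param true_cbf 3D array.
#' @param ref_sd per-voxel reference SD (scalar or 3D array).
#' @param lesion a [lesion_spec()].
#' @param atlas a [region_atlas()] locating the target region.
#' @param exclude_mask optional 3D logical mask of forbidden locations.
#' @param seed RNG seed (`NULL`: use the current RNG stream).
#' @return list with `values` (modified map) and `lesion_mask` (3D logical
#'   ground truth).
#' @export
inject_lesions <- function(true_cbf, ref_sd, lesion, atlas,
                           exclude_mask = NULL, seed = NULL) {
  stopifnot(inherits(lesion, "lesion_spec"), inherits(atlas, "region_atlas"))
  if (!is.null(seed)) set.seed(seed)
  if (!lesion$region %in% names(atlas$region_names)) {
    stop_devoxel("unknown lesion region '", lesion$region, "'",
                 class = "devoxel_region_error")
  }
  lb <- atlas$region_names[[lesion$region]]
  region_idx <- which(atlas$labels == lb)
  n_target <- round(lesion$fraction * length(region_idx))
  mask <- array(FALSE, dim(true_cbf))
  if (n_target == 0L) {
    return(list(values = true_cbf, lesion_mask = mask))
  }
  pool <- if (is.null(exclude_mask)) region_idx else
    region_idx[!exclude_mask[region_idx]]
  if (length(pool) < n_target) {
    stop_devoxel("lesion fraction not realizable: need ", n_target,
                 " free voxels in '", lesion$region, "', have ", length(pool),
                 class = "devoxel_geometry_error")
  }
  sel <- sample(pool, n_target)
  sd_at <- if (length(ref_sd) == 1L) rep(ref_sd, n_target) else ref_sd[sel]
  values <- true_cbf
  values[sel] <- values[sel] + lesion$depth * sd_at
  mask[sel] <- TRUE
  list(values = values, lesion_mask = mask)
}

#' Simulate a phase-contrast cine with two vessels
#'
#' Places a left and right circular vessel on the grid, gives each a
#' parabolic velocity profile, and scales the profile per cardiac frame so
#' that the discrete integral over the vessel's pixels equals the requested
#' volumetric flow exactly.  Phase is `pi * v / venc` plus optional noise,
#' wrapped into `(-pi, pi]`; if the true peak velocity exceeds `venc` the
#' cine is flagged aliased.
#'
#' @param waveform_left,waveform_right per-frame volumetric flow per side
#'   (cm^3/s); default a 15-frame pulsatile cycle with mean 5.4 cm^3/s.
#' @param vessel_radius vessel radius (cm).
#' @param venc encoding velocity (cm/s).
#' @param grid_dim in-plane grid (x, y).
#' @param pixel_size pixel edge length (cm).
#' @param phase_noise_sd additive phase noise SD (radians).
#' @param seed RNG seed.
#' @return list with `cine` ([pc_cine()]), `roi_left`, `roi_right`
#'   ([vessel_roi()]s) and the true waveforms.
#' @export
simulate_pc_cine <- function(waveform_left = 5.4 + 2.2 * sin(2 * pi * (0:14) / 15),
                             waveform_right = waveform_left,
                             vessel_radius = 0.25, venc = 120,
                             grid_dim = c(48, 32), pixel_size = 0.1,
                             phase_noise_sd = 0, seed = 1L) {
  set.seed(seed)
  stopifnot(length(waveform_left) == length(waveform_right))
  n_frames <- length(waveform_left)
  pixel_area <- pixel_size^2
  centers <- list(left = c(0.3, 0.5) * grid_dim,
                  right = c(0.7, 0.5) * grid_dim)
  xs <- (seq_len(grid_dim[1]) - 0.5) * pixel_size
  ys <- (seq_len(grid_dim[2]) - 0.5) * pixel_size
  profile <- function(ctr) {
    cx <- ctr[1] * pixel_size
    cy <- ctr[2] * pixel_size
    r2 <- outer((xs - cx)^2, (ys - cy)^2, `+`)
    p <- 1 - r2 / vessel_radius^2
    p[p < 0] <- 0
    p
  }
  prof <- lapply(centers, profile)
  masks <- lapply(prof, function(p) p > 0)
  v <- array(0, c(grid_dim, n_frames))
  peak <- 0
  for (f in seq_len(n_frames)) {
    wl <- list(left = waveform_left[f], right = waveform_right[f])
    fr <- matrix(0, grid_dim[1], grid_dim[2])
    for (s in c("left", "right")) {
      scale <- wl[[s]] / (sum(prof[[s]]) * pixel_area)
      fr <- fr + prof[[s]] * scale
      peak <- max(peak, abs(scale))
    }
    v[, , f] <- fr
  }
  aliased <- peak > venc
  phase <- pi * v / venc
  if (phase_noise_sd > 0) {
    phase <- phase + array(stats::rnorm(length(phase), 0, phase_noise_sd),
                           dim(phase))
  }
  phase <- ((phase + pi) %% (2 * pi)) - pi      # wrap into (-pi, pi]
  phase[phase == -pi] <- pi
  magnitude <- array(0.2, c(grid_dim, n_frames))
  for (f in seq_len(n_frames)) {
    m <- magnitude[, , f]
    m[masks$left | masks$right] <- 1
    magnitude[, , f] <- m
  }
  list(
    cine = pc_cine(magnitude, phase, venc = venc, pixel_area = pixel_area,
                   aliased = aliased),
    roi_left = vessel_roi(masks$left, "left"),
    roi_right = vessel_roi(masks$right, "right"),
    waveform_left = waveform_left, waveform_right = waveform_right
  )
}

#' Simulate a two-group cohort of CBF maps
#'
#' Generates a lesion-free control group and a test (T2DM-like) group that
#' receives the requested effect: scattered lesions (disjoint across
#' subjects when the lesion's scatter mode is non-overlapping) and/or a
#' global GM CBF offset.  Each subject's map is
#' `regional true CBF + global subject offset (GM only) + voxel noise`,
#' so the per-voxel across-subject SD is
#' `sqrt(between_subject_sd^2 + voxel_noise_sd^2)` — the scale in which
#' lesion depth is expressed.  Covariates are drawn from plausible
#' defaults for a community-dwelling cohort around age 62.
#'
#' @param n_per_group subjects per group, >= 4.
#' @param spec a [phantom_spec()].
#' @param lesion optional [lesion_spec()] applied to the test group.
#' @param group_offset additive GM CBF offset for the test group
#'   (ml/100 g/min, e.g. -3.2 for a global hypoperfusion effect).
#' @param seed RNG seed (default from spec).
#' @return list with `maps` (named list of `cbf_map`s), `cohort`
#'   ([cohort_table()]), `anatomy` (see [make_phantom_anatomy()]),
#'   `lesion_masks` (named list for test subjects), `ref_sd` (the per-voxel
#'   generative SD).
#' @export
simulate_cohort <- function(n_per_group = 20, spec = phantom_spec(),
                            lesion = NULL, group_offset = 0,
                            seed = spec$seed) {
  if (n_per_group < 4L) {
    stop_devoxel("n_per_group must be >= 4", class = "devoxel_parameter_error")
  }
  set.seed(seed)
  anatomy <- make_phantom_anatomy(spec)
  base_cbf <- phantom_true_cbf(spec, anatomy)
  ref_sd <- sqrt(spec$between_subject_sd^2 + spec$voxel_noise_sd^2)
  gm <- anatomy$atlas$gm_mask
  brain <- anatomy$brain_mask
  d <- spec$grid_dim

  ids <- c(paste0("ctrl", sprintf("%02d", seq_len(n_per_group))),
           paste0("t2dm", sprintf("%02d", seq_len(n_per_group))))
  is_t2dm <- rep(c(FALSE, TRUE), each = n_per_group)
  maps <- vector("list", 2L * n_per_group)
  names(maps) <- ids
  lesion_masks <- list()
  used <- array(FALSE, d)
  for (i in seq_along(ids)) {
    true_i <- base_cbf
    if (is_t2dm[i]) {
      if (group_offset != 0) true_i[gm] <- true_i[gm] + group_offset
      if (!is.null(lesion) && lesion$fraction > 0) {
        li <- inject_lesions(true_i, ref_sd, lesion, anatomy$atlas,
                             exclude_mask = if (lesion$scatter ==
                                                "non_overlapping") used)
        true_i <- li$values
        used <- used | li$lesion_mask
        lesion_masks[[ids[i]]] <- li$lesion_mask
      }
    }
    subj_offset <- stats::rnorm(1, 0, spec$between_subject_sd)
    vals <- true_i
    vals[gm] <- vals[gm] + subj_offset
    vals[brain] <- vals[brain] + stats::rnorm(sum(brain), 0,
                                              spec$voxel_noise_sd)
    vals[!brain] <- NA_real_
    maps[[i]] <- cbf_map(vals, valid_mask = brain,
                         voxel_dims = spec$voxel_dims)
  }
  n_total <- 2L * n_per_group
  cohort <- cohort_table(data.frame(
    id = ids,
    group_t2dm = is_t2dm,
    group_cognition = sample(c("low", "high"), n_total, replace = TRUE),
    age = round(stats::rnorm(n_total, 62, 8), 1),
    sex = sample(c("m", "f"), n_total, replace = TRUE, prob = c(0.56, 0.44)),
    atrophy_ml = round(pmax(8, stats::rnorm(n_total, 35, 12)), 1),
    icv_mm3 = anatomy$icv,
    carotid_flow = round(stats::rnorm(n_total, ifelse(is_t2dm, 10.5, 10.8),
                                      ifelse(is_t2dm, 2.2, 1.8)), 2),
    depression = stats::runif(n_total) < 0.15,
    exclusion_cbf = "", exclusion_flow = "",
    stringsAsFactors = FALSE
  ))
  list(maps = maps, cohort = cohort, anatomy = anatomy,
       lesion_masks = lesion_masks, ref_sd = ref_sd, true_cbf = base_cbf)
}
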