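#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_devoxel <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "devoxel_error")))
}

check_same_grid <- function(a, b, what_a = "first", what_b = "second") {
  da <- dim(a)
  db <- dim(b)
  if (length(da) != length(db) || any(da != db)) {
    stop_devoxel(
      "grid mismatch: ", what_a, " is ", paste(da, collapse = "x"),
      " but ", what_b, " is ", paste(db, collapse = "x"),
      class = "devoxel_shape_error"
    )
  }
  invisible(TRUE)
}

#' Separable 3D Gaussian smoothing
#'
#' Smooths a 3D array with an isotropic Gaussian kernel specified by its
#' full width at half maximum in millimetres.  Used optionally before
#' aggregating reference CBF maps.  Boundaries are renormalised (kernel
#' weights outside the volume are dropped and the remaining weights rescaled)
#' so constant images stay constant.
#'
#' @param x 3D numeric array.
#' @param fwhm_mm kernel FWHM in mm; 0 returns `x` unchanged.
#' @param voxel_dims physical voxel size in mm, length 3.
#' @return smoothed array, same dimensions.
#' @keywords internal
gaussian_smooth_3d <- function(x, fwhm_mm, voxel_dims) {
  if (fwhm_mm <= 0) return(x)
  stopifnot(length(dim(x)) == 3L, length(voxel_dims) == 3L)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  out <- x
  for (ax in 1:3) {
    sigma_vox <- sigma_mm / voxel_dims[ax]
    half <- max(1L, ceiling(3 * sigma_vox))
    k <- exp(-((-half:half)^2) / (2 * sigma_vox^2))
    out <- convolve_axis(out, k / sum(k), ax)
  }
  out
}

# 1D convolution along one axis of a 3D array with boundary renormalisation
convolve_axis <- function(x, k, axis) {
  d <- dim(x)
  half <- (length(k) - 1L) / 2L
  perm <- c(axis, setdiff(1:3, axis))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  m <- matrix(xp, nrow = dp[1])
  n <- dp[1]
  acc <- matrix(0, n, ncol(m))
  wgt <- numeric(n)
  for (j in seq_along(k)) {
    off <- j - half - 1L
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    acc[ok, ] <- acc[ok, ] + k[j] * m[src[ok], , drop = FALSE]
    wgt[ok] <- wgt[ok] + k[j]
  }
  acc <- acc / wgt
  aperm(array(acc, dp), order(perm))
}

# seed derived deterministically from a base seed and a stream label,
# kept within 32-bit integer range
derive_seed <- function(seed, stream) {
  s <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 7919 + s) %% 2147483629)
}
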