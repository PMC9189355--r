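#' MIND descriptor parameters
#'
#' The modality-independent neighborhood descriptor compares Gaussian-weighted
#' patch self-dissimilarities at a set of spatial offsets, normalized by the
#' local mean dissimilarity, so the descriptor depends on local structure and
#' not on the intensity mapping. Defaults use the six axial unit offsets
#' (through-plane offset = 1 slice) and a 3 x 3 in-plane patch.
#'
#' @param ndim 3 for volumes, 2 for axial slices (drops the through-plane
#'   offsets and patch extent)
#' @param patch_radius patch half-width (z, y, x) in voxels
#' @param sigma_p Gaussian patch weight standard deviation (voxels)
#' @param eps_rel variance floor as a fraction of the mean patch dissimilarity
#' @param offsets optional integer matrix K x 3 of (dz, dy, dx) offsets
#' @return list of class `mind_params`
#' @export
mind_params <- function(ndim = 3, patch_radius = c(0, 1, 1), sigma_p = 1.0,
                        eps_rel = 1e-6, offsets = NULL) {
  stopifnot(ndim %in% c(2, 3), all(patch_radius >= 0), eps_rel > 0, sigma_p > 0)
  if (is.null(offsets)) {
    offsets <- rbind(c(1, 0, 0), c(-1, 0, 0),
                     c(0, 1, 0), c(0, -1, 0),
                     c(0, 0, 1), c(0, 0, -1))
    if (ndim == 2) offsets <- offsets[3:6, , drop = FALSE]
  }
  offsets <- matrix(as.integer(offsets), ncol = 3)
  if (nrow(offsets) < 2) stop("need at least 2 offsets")
  if (ndim == 2) patch_radius[1] <- 0
  pr <- as.integer(patch_radius)
  q <- expand.grid(z = -pr[1]:pr[1], y = -pr[2]:pr[2], x = -pr[3]:pr[3])
  w <- exp(-(q$z^2 + q$y^2 + q$x^2) / (2 * sigma_p^2))
  w <- w / sum(w)
  structure(list(ndim = ndim, offsets = offsets,
                 patch = matrix(as.integer(as.matrix(q)), ncol = 3),
                 pweights = as.double(w), eps_rel = eps_rel),
            class = "mind_params")
}

as_vol3 <- function(x) {
  a <- vox_of(x)
  if (length(dim(a)) == 2L) dim(a) <- c(1L, dim(a))
  if (length(dim(a)) != 3L) stop("expected a 2D slice or 3D volume")
  storage.mode(a) <- "double"
  a
}

#' MIND descriptor field
#'
#' One channel per offset, values in (0, 1\] with the per-voxel maximum equal
#' to 1; constant images give all channels 1. Borders use replicate padding.
#'
#' @param vol image volume, 3D array or 2D slice
#' @param params a [mind_params]
#' @return array (nz, ny, nx, K) of descriptor channels
#' @export
mind_descriptor <- function(vol, params = mind_params()) {
  a <- as_vol3(vol)
  mind_descriptor_cpp(a, as.integer(dim(a)), params$offsets, params$patch,
                      params$pweights, params$eps_rel)
}

#' MIND dissimilarity loss
#'
#' Mean absolute difference between the two descriptor fields over all
#' offsets and (optionally region-restricted) voxels. Zero for identical
#' images and, up to numerical precision, for images related by a positive
#' affine intensity map. When `grad = TRUE` the analytic gradient with
#' respect to `i2` is returned alongside (it is the training loss of both
#' the registration network and the CycleGAN similarity constraint).
#'
#' @param i1,i2 images of the same shape (2D slices or 3D volumes)
#' @param params a [mind_params]
#' @param region optional binary array restricting the averaged voxels
#' @param grad if TRUE return `list(loss, grad)`
#' @return scalar loss, or a list when `grad = TRUE`
#' @export
mind_loss <- function(i1, i2, params = mind_params(), region = NULL,
                      grad = FALSE) {
  a <- as_vol3(i1); b <- as_vol3(i2)
  if (!identical(dim(a), dim(b))) stop("images must have the same shape")
  reg <- if (is.null(region)) numeric(0) else {
    r <- as_vol3(region)
    if (!identical(dim(r), dim(a))) stop("region shape mismatch")
    if (sum(r != 0) == 0) stop("empty region")
    as.double(r != 0)
  }
  res <- mind_loss_cpp(a, b, as.integer(dim(a)), params$offsets, params$patch,
                       params$pweights, params$eps_rel, reg,
                       as.integer(grad))
  if (grad) {
    g <- res$grad
    if (length(dim(vox_of(i2))) == 2L) dim(g) <- dim(vox_of(i2))
    list(loss = res$loss, grad = g)
  } else res$loss
}
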