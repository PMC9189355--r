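#' Metrics configuration
#'
#' @param nmi_bins number of histogram bins for NMI (>= 2)
#' @param nmi_range shared intensity range (HU) used to bin both images, so
#'   NMI values are comparable across cases
#' @param ssim_radius half-width of the square SSIM window (window is
#'   `2*radius+1` pixels wide, applied per axial slice)
#' @param ssim_k1,ssim_k2 SSIM constants; `c1 = (k1*L)^2`, `c2 = (k2*L)^2`
#'   with `L` the dynamic range of the reference image
#' @return list of class `metrics_config`
#' @export
metrics_config <- function(nmi_bins = 64L, nmi_range = c(-1000, 1500),
                           ssim_radius = 5L, ssim_k1 = 0.01, ssim_k2 = 0.03) {
  stopifnot(nmi_bins >= 2L, nmi_range[2] > nmi_range[1],
            ssim_radius >= 1L, ssim_k1 > 0, ssim_k2 > 0)
  structure(list(nmi_bins = as.integer(nmi_bins), nmi_range = nmi_range,
                 ssim_radius = as.integer(ssim_radius),
                 ssim_k1 = ssim_k1, ssim_k2 = ssim_k2),
            class = "metrics_config")
}

vox_of <- function(x) {
  if (inherits(x, "image_volume")) x$voxels
  else if (inherits(x, "label_map")) x$labels
  else as.array(x)
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("volumes must have the same shape")
}

#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b binary (logical or 0/1) arrays of the same shape
#' @return scalar in \[0, 1\]
#' @export
dsc <- function(a, b) {
  a <- vox_of(a); b <- vox_of(b)
  check_same_shape(a, b)
  a <- a != 0; b <- b != 0
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

nmi_bin <- function(v, cfg) {
  lo <- cfg$nmi_range[1]; hi <- cfg$nmi_range[2]
  b <- floor((v - lo) / (hi - lo) * cfg$nmi_bins) + 1L
  pmin(pmax(b, 1L), cfg$nmi_bins)
}

#' Normalized mutual information
#'
#' `2 * MI(I1, I2) / (H(I1) + H(I2))` from a joint histogram over a fixed
#' shared intensity range; zero-count bins contribute nothing. Entropies use
#' natural logs (NMI is base-invariant).
#'
#' @param i1,i2 image volumes or arrays of the same shape
#' @param cfg a [metrics_config]
#' @return scalar; 1 when the images are identical
#' @export
nmi <- function(i1, i2, cfg = metrics_config()) {
  a <- vox_of(i1); b <- vox_of(i2)
  check_same_shape(a, b)
  nb <- cfg$nmi_bins
  ba <- nmi_bin(as.double(a), cfg)
  bb <- nmi_bin(as.double(b), cfg)
  joint <- tabulate(ba + nb * (bb - 1L), nbins = nb * nb) / length(ba)
  pj <- matrix(joint, nb, nb)
  pa <- rowSums(pj); pb <- colSums(pj)
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha == 0 || hb == 0)
    stop("degenerate entropy: an image is constant after binning")
  nz <- pj > 0
  mi <- sum(pj[nz] * log(pj[nz] / (pa[row(pj)[nz]] * pb[col(pj)[nz]])))
  2 * mi / (ha + hb)
}

#' Normalized cross-correlation
#'
#' Mean-centered, sigma-normalized voxelwise product (population standard
#' deviations).
#'
#' @inheritParams nmi
#' @return scalar in \[-1, 1\]
#' @export
ncc <- function(i1, i2) {
  a <- as.double(vox_of(i1)); b <- as.double(vox_of(i2))
  check_same_shape(vox_of(i1), vox_of(i2))
  ma <- mean(a); mb <- mean(b)
  sa <- sqrt(mean((a - ma)^2)); sb <- sqrt(mean((b - mb)^2))
  if (sa == 0 || sb == 0) stop("zero variance: constant image in NCC")
  mean((a - ma) * (b - mb)) / (sa * sb)
}

#' Intensity error metrics: MAE, RMSE, PSNR
#'
#' PSNR uses `MAX` = the maximum HU value of the reference image `i1`
#' (reported as `Inf` when the images are identical).
#'
#' @inheritParams nmi
#' @return named list with `mae`, `rmse`, `psnr`
#' @export
error_metrics <- function(i1, i2) {
  a <- as.double(vox_of(i1)); b <- as.double(vox_of(i2))
  check_same_shape(vox_of(i1), vox_of(i2))
  d <- a - b
  mae <- mean(abs(d))
  rmse <- sqrt(mean(d^2))
  mx <- max(a)
  psnr <- if (rmse == 0) Inf else 10 * log10(mx^2 / rmse^2)
  list(mae = mae, rmse = rmse, psnr = psnr)
}

#' Structural similarity
#'
#' Local-statistics SSIM with a uniform square window per axial slice,
#' averaged over all window positions and slices (`window = "local"`), or the
#' single global-statistics value (`window = "global"`). Constants are
#' `c1 = (k1*L)^2`, `c2 = (k2*L)^2` with `L` the dynamic range of the
#' reference `i1`.
#'
#' @inheritParams nmi
#' @param window `"local"` (default) or `"global"`
#' @return scalar, 1 for identical images
#' @export
ssim <- function(i1, i2, cfg = metrics_config(), window = c("local", "global")) {
  window <- match.arg(window)
  a <- vox_of(i1); b <- vox_of(i2)
  check_same_shape(a, b)
  L <- max(max(a) - min(a), 1e-6)
  c1 <- (cfg$ssim_k1 * L)^2
  c2 <- (cfg$ssim_k2 * L)^2
  if (window == "global") {
    m1 <- mean(a); m2 <- mean(b)
    v1 <- mean((a - m1)^2); v2 <- mean((b - m2)^2)
    cov <- mean((a - m1) * (b - m2))
    return(((2 * m1 * m2 + c1) * (2 * cov + c2)) /
             ((m1^2 + m2^2 + c1) * (v1 + v2 + c2)))
  }
  d <- dim(a)
  if (2 * cfg$ssim_radius + 1 > min(d[2], d[3]))
    stop("SSIM window larger than the image plane")
  ssim_slices_cpp(as.double(a), as.double(b), as.integer(d),
                  cfg$ssim_radius, c1, c2)
}

#' Organ volume-difference statistic
#'
#' `|V_CBCT - V_pCT| / min(V_CBCT, V_pCT) * 100`, volumes in mm^3. This is
#' the mismatch measure used to stratify cases: a value of 110 lands in the
#' ">100%" stratum.
#'
#' @param v_cbct,v_pct positive volumes in mm^3
#' @return percent difference
#' @export
volume_diff <- function(v_cbct, v_pct) {
  if (v_cbct <= 0 || v_pct <= 0) stop("volumes must be positive")
  abs(v_cbct - v_pct) / min(v_cbct, v_pct) * 100
}

#' Physical volume of an organ in a label map
#' @param lm a [label_map]
#' @param organ organ name
#' @return volume in mm^3
#' @export
organ_volume <- function(lm, organ) {
  sum(extract_mask(lm, organ)) * prod(lm$spacing)
}

#' Assign a volume-difference value to a stratum
#' @param diff percent difference from [volume_diff()]
#' @param breaks ascending stratum boundaries (percent)
#' @return stratum label such as `"<20%"` or `">100%"`
#' @export
diff_stratum <- function(diff, breaks = c(20, 50, 100)) {
  labs <- c(paste0("<", breaks[1], "%"),
            paste0(head(breaks, -1), "%-", tail(breaks, -1), "%"),
            paste0(">", tail(breaks, 1), "%"))
  idx <- findInterval(diff, breaks, left.open = TRUE) + 1L
  labs[idx]
}

#' Full image/contour metrics report for one pair
#'
#' @param ref reference [image_volume]
#' @param test test [image_volume]
#' @param labels_ref,labels_test optional [label_map]s for per-organ DSC and
#'   the volume-difference statistic
#' @param cfg a [metrics_config]
#' @return named list of class `metrics_report`
#' @export
evaluate_pair <- function(ref, test, labels_ref = NULL, labels_test = NULL,
                          cfg = metrics_config()) {
  em <- error_metrics(ref, test)
  rep <- list(nmi = nmi(ref, test, cfg), ncc = ncc(ref, test),
              mae = em$mae, rmse = em$rmse, psnr = em$psnr,
              ssim = ssim(ref, test, cfg))
  if (!is.null(labels_ref) && !is.null(labels_test)) {
    organs <- setdiff(names(labels_ref$organ_table), "body")
    rep$dsc <- sapply(organs, function(o)
      dsc(extract_mask(labels_ref, o), extract_mask(labels_test, o)))
    rep$diff <- sapply(organs, function(o)
      volume_diff(organ_volume(labels_ref, o), organ_volume(labels_test, o)))
  }
  structure(rep, class = "metrics_report")
}
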