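#' Preprocessing configuration
#'
#' Parameters of the common preprocessing chain (skin mask, couch removal,
#' air fill, resampling, rigid alignment, centered crop) and the two
#' normalizations used by the registration and synthesis branches.
#'
#' @param preset `"paper"` (1 x 1 mm in-plane, 400 x 288 crop) or `"desk"`
#'   (2 x 2 mm in-plane, 128 x 96 crop)
#' @param skin_threshold HU threshold separating tissue from air
#' @param morph_radius in-plane closing radius in voxels
#' @param reg_clip HU clip range for the registration branch
#' @param tanh_divisor divisor of the hyperbolic-tangent intensity mapping
#' @return list of class `preprocess_config`
#' @export
preprocess_config <- function(preset = c("desk", "paper"),
                              skin_threshold = -300, morph_radius = 2L,
                              reg_clip = c(-250, 200), tanh_divisor = 400) {
  preset <- match.arg(preset)
  g <- if (preset == "paper") list(spacing = c(5, 1, 1), crop = c(288L, 400L))
       else list(spacing = c(5, 2, 2), crop = c(96L, 128L))
  stopifnot(reg_clip[1] < reg_clip[2], tanh_divisor > 0,
            all(g$crop > 0), all(g$crop %% 2L == 0L))
  structure(list(preset = preset, target_spacing = g$spacing, crop = g$crop,
                 skin_threshold = skin_threshold,
                 morph_radius = as.integer(morph_radius),
                 reg_clip = reg_clip, tanh_divisor = tanh_divisor),
            class = "preprocess_config")
}

#' Extract the skin (body) mask
#'
#' Threshold, in-plane morphological closing, removal of couch-like
#' components (touching the posterior image border with a small
#' anterior-posterior extent relative to the body), largest connected
#' component, per-slice hole filling.
#'
#' @param vol an [image_volume]
#' @param cfg a [preprocess_config]
#' @return logical 3D array
#' @export
extract_skin_mask <- function(vol, cfg = preprocess_config()) {
  v <- vox_of(vol)
  m <- array(as.integer(v > cfg$skin_threshold), dim(v))
  if (sum(m) == 0) stop("no voxels above the skin threshold")
  d <- as.integer(dim(v))
  r <- cfg$morph_radius
  if (r > 0) {
    m <- dilate_inplane_cpp(m, d, r)
    m <- 1L - dilate_inplane_cpp(1L - m, d, r)   # erode = complement dilate
  }
  lab <- label_components_cpp(m, d)
  if (length(lab$sizes) == 0) stop("empty mask after closing")
  # couch rule: components touching the posterior (y = 1) image border whose
  # anterior-posterior extent is < 20% of the largest component's are dropped,
  # then the largest remaining component is the body
  la <- array(lab$labels, d)
  yext <- function(id) {
    ys <- which(apply(la == id, 2, any))
    if (length(ys) == 0) 0 else diff(range(ys)) + 1
  }
  ids <- seq_along(lab$sizes)
  body_ext <- yext(which.max(lab$sizes))
  touches_border <- vapply(ids, function(id) any(la[, 1, ] == id), logical(1))
  couchlike <- touches_border & vapply(ids, yext, numeric(1)) < 0.2 * body_ext
  keep <- ids[!couchlike]
  if (length(keep) == 0) stop("empty mask after component filtering")
  main_id <- keep[which.max(lab$sizes[keep])]
  m2 <- la == main_id
  if (sum(m2) == 0) stop("empty mask after component filtering")
  m2 <- fill_holes_inplane_cpp(array(as.integer(m2), d), d)
  array(m2 == 1L, d)
}

#' Set everything outside the body to air
#'
#' @param vol an [image_volume]
#' @param skin logical body mask of the same shape
#' @return [image_volume] with -1000 HU outside the mask
#' @export
fill_outside_body <- function(vol, skin) {
  stopifnot(inherits(vol, "image_volume"))
  skin <- vox_of(skin) != 0
  if (!identical(dim(skin), dim(vol$voxels))) stop("shape mismatch")
  v <- vol$voxels
  v[!skin] <- -1000
  image_volume(v, spacing = vol$spacing, origin = vol$origin)
}

#' Resample a volume to a target spacing
#'
#' Trilinear interpolation onto a new grid covering the same physical
#' extent; background fill is -1000 HU (0 for `mode = "nearest"`).
#'
#' @param vol an [image_volume] or [label_map]
#' @param target_spacing (sz, sy, sx) in mm
#' @param mode `"linear"` for images, `"nearest"` for labels
#' @return resampled object of the same class
#' @export
resample <- function(vol, target_spacing, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  if (any(target_spacing <= 0)) stop("target spacing must be positive")
  v <- vox_of(vol)
  sp <- vol$spacing
  d <- dim(v)
  nd <- pmax(1L, as.integer(round((d - 1) * sp / target_spacing)) + 1L)
  sc <- target_spacing / sp
  A <- c(sc[1], 0, 0, 0, sc[2], 0, 0, 0, sc[3])
  fill <- if (mode == "nearest") 0 else -1000
  out <- affine_sample_cpp(as.double(v), as.integer(d), nd, A, c(0, 0, 0),
                           fill, as.integer(mode == "nearest"))
  if (inherits(vol, "label_map"))
    label_map(array(as.integer(round(out)), nd), spacing = target_spacing,
              organ_table = vol$organ_table, origin = vol$origin)
  else image_volume(array(out, nd), spacing = target_spacing,
                    origin = vol$origin)
}

#' Rigid transform (translation + in-plane rotation)
#' @param translation (tz, ty, tx) in mm
#' @param rotation_deg rotation about the z axis in degrees, in (-180, 180]
#' @return list of class `rigid_transform`
#' @export
rigid_transform <- function(translation = c(0, 0, 0), rotation_deg = 0) {
  stopifnot(all(is.finite(translation)), is.finite(rotation_deg),
            rotation_deg > -180, rotation_deg <= 180)
  structure(list(translation = as.double(translation),
                 rotation_deg = as.double(rotation_deg)),
            class = "rigid_transform")
}

# Index-space affine (A, t) realizing the fixed-to-moving map
#   p_m = R^-1 (p_f - c) + c + t   (mm, rotation about the fixed-grid center)
# so sampling moving at A x + t for each fixed voxel x resamples the moving
# image into the fixed grid under (translation t, rotation theta).
rigid_affine <- function(tr, dims, spacing) {
  th <- -tr$rotation_deg * pi / 180     # inverse rotation
  R <- rbind(c(1, 0, 0),
             c(0, cos(th), -sin(th)),
             c(0, sin(th), cos(th)))
  S <- diag(spacing)
  Si <- diag(1 / spacing)
  ctr <- (dims - 1) / 2 * spacing
  A <- Si %*% R %*% S
  t <- Si %*% (R %*% (-ctr) + ctr + tr$translation)
  list(A = as.double(t(A)), t = as.double(t))
}

#' Apply a rigid transform, resampling into a fixed grid
#'
#' @param vol moving [image_volume] or [label_map]
#' @param tr a [rigid_transform] (moving-to-fixed, mm)
#' @param fixed_dims output grid shape (defaults to the input's)
#' @param mode `"linear"` or `"nearest"`
#' @return transformed object on the fixed grid
#' @export
apply_rigid <- function(vol, tr, fixed_dims = NULL,
                        mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  v <- vox_of(vol)
  d <- dim(v)
  fixed_dims <- as.integer(fixed_dims %||% d)
  af <- rigid_affine(tr, fixed_dims, vol$spacing)
  fill <- if (mode == "nearest") 0 else -1000
  out <- affine_sample_cpp(as.double(v), as.integer(d), fixed_dims, af$A,
                           af$t, fill, as.integer(mode == "nearest"))
  if (inherits(vol, "label_map"))
    label_map(array(as.integer(round(out)), fixed_dims), spacing = vol$spacing,
              organ_table = vol$organ_table)
  else image_volume(array(out, fixed_dims), spacing = vol$spacing)
}

mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  colMeans(idx)
}

#' Rigid alignment of a moving to a fixed volume
#'
#' Skin-centroid translation followed by a coarse-to-fine coordinate-descent
#' search over 3-DOF translation and 1-DOF in-plane rotation, maximizing the
#' normalized cross-correlation of clipped intensities. The moving image is
#' returned resampled into the fixed grid (same z extent as the fixed image).
#'
#' @param moving,fixed [image_volume]s on a common spacing
#' @param skin_moving,skin_fixed binary body masks (computed if NULL)
#' @param cfg a [preprocess_config]
#' @return list with `transform` ([rigid_transform]) and `aligned`
#'   ([image_volume])
#' @export
rigid_align <- function(moving, fixed, skin_moving = NULL, skin_fixed = NULL,
                        cfg = preprocess_config()) {
  if (is.null(skin_moving)) skin_moving <- extract_skin_mask(moving, cfg)
  if (is.null(skin_fixed)) skin_fixed <- extract_skin_mask(fixed, cfg)
  if (sum(skin_moving) == 0 || sum(skin_fixed) == 0)
    stop("empty skin mask in rigid alignment")
  sp <- fixed$spacing
  cm <- mask_centroid(skin_moving) * sp
  cf <- mask_centroid(skin_fixed) * sp
  t0 <- cm - cf                       # translation moving <- fixed, mm

  clip <- function(v) clamp(v, cfg$reg_clip[1], cfg$reg_clip[2])
  fx <- clip(fixed$voxels)
  fd <- as.integer(dim(fx))
  mv <- clip(moving$voxels)
  score <- function(tr) {
    af <- rigid_affine(tr, fd, sp)
    out <- affine_sample_cpp(as.double(mv), as.integer(dim(mv)), fd, af$A,
                             af$t, cfg$reg_clip[1], 0L)
    suppressWarnings(tryCatch(ncc(fx, array(out, fd)), error = function(e) -1))
  }
  par <- c(t0, 0)                     # tz, ty, tx (mm), rot (deg)
  best <- score(rigid_transform(par[1:3], par[4]))
  for (pass in list(c(4, 2), c(1, 0.5))) {
    step_t <- pass[1]; step_r <- pass[2]
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (k in 1:4) {
        st <- if (k == 4) step_r else step_t
        if (st == 0) next
        for (dir in c(-1, 1)) {
          cand <- par
          cand[k] <- cand[k] + dir * st
          if (k == 4 && (cand[4] <= -180 || cand[4] > 180)) next
          s <- score(rigid_transform(cand[1:3], cand[4]))
          if (s > best + 1e-7) { par <- cand; best <- s; improved <- TRUE }
        }
      }
    }
  }
  tr <- rigid_transform(par[1:3], par[4])
  list(transform = tr, aligned = apply_rigid(moving, tr, fd, "linear"),
       ncc = best)
}

#' Crop each slice to a fixed in-plane size centered on the skin centroid
#'
#' Uses the floor convention for even sizes; areas outside the original
#' volume are padded with `fill`. The z extent is unchanged.
#'
#' @param vol an [image_volume] or [label_map]
#' @param skin logical body mask on the same grid
#' @param size in-plane output size (ny, nx)
#' @param fill pad value (-1000 for images, 0 for labels)
#' @return cropped object, with attribute `crop_offset` = (y0, x0) 0-based
#' @export
crop_centered <- function(vol, skin, size, fill = NULL) {
  skin <- vox_of(skin) != 0
  if (sum(skin) == 0) stop("empty skin mask")
  v <- vox_of(vol)
  d <- dim(v)
  ctr <- floor(mask_centroid(skin)[2:3])
  size <- as.integer(size)
  y0 <- as.integer(ctr[1] - size[1] %/% 2)      # 0-based start, half-open
  x0 <- as.integer(ctr[2] - size[2] %/% 2)
  if (is.null(fill)) fill <- if (inherits(vol, "label_map")) 0 else -1000
  out <- array(fill, c(d[1], size))
  ys <- intersect(seq_len(size[1]) + y0, seq_len(d[2]))
  xs <- intersect(seq_len(size[2]) + x0, seq_len(d[3]))
  out[, ys - y0, xs - x0] <- v[, ys, xs]
  res <- if (inherits(vol, "label_map"))
    label_map(array(as.integer(out), dim(out)), spacing = vol$spacing,
              organ_table = vol$organ_table)
  else image_volume(out, spacing = vol$spacing, origin = vol$origin)
  attr(res, "crop_offset") <- c(y0, x0)
  res
}

#' Registration-branch normalization
#'
#' Clip HU to the configured range and map linearly onto (-1, 1):
#' the clip low end maps to -1 and the high end to +1.
#'
#' @param vol [image_volume] or array
#' @param cfg a [preprocess_config]
#' @return array in \[-1, 1\]
#' @export
normalize_registration <- function(vol, cfg = preprocess_config()) {
  v <- vox_of(vol)
  lo <- cfg$reg_clip[1]; hi <- cfg$reg_clip[2]
  v <- clamp(v, lo, hi)
  (v - lo) / (hi - lo) * 2 - 1
}

#' Hyperbolic-tangent intensity normalization (synthesis branch)
#'
#' Forward: `tanh(HU / divisor)`; inverse: `divisor * atanh(x)` with the
#' argument clamped to +/- tanh(3), bounding the inverse to
#' \[-3 * divisor, 3 * divisor\] (i.e. [-1200, 1200] HU at the default).
#' The round trip is exact to within 0.5 HU on that interval.
#'
#' @param vol [image_volume] or array (HU for forward, (-1,1) for inverse)
#' @param divisor positive scale (default 400)
#' @return array
#' @export
normalize_tanh <- function(vol, divisor = 400) {
  tanh(vox_of(vol) / divisor)
}

#' @rdname normalize_tanh
#' @export
inverse_tanh <- function(vol, divisor = 400) {
  v <- clamp(vox_of(vol), -tanh(3), tanh(3))
  divisor * atanh(v)
}

#' Run the full common preprocessing chain on a pCT/CBCT pair
#'
#' Order: skin masks, air fill, resample to the preset spacing, rigid
#' alignment of the pCT (moving) to the CBCT (fixed), centered crop of both
#' onto the CBCT skin centroid. Labels follow their volumes with nearest
#' interpolation.
#'
#' @param pct,cbct [image_volume]s
#' @param pct_labels,cbct_labels optional [label_map]s
#' @param cfg a [preprocess_config]
#' @param align if FALSE skip the rigid search (volumes already aligned)
#' @return list with preprocessed `pct`, `cbct`, labels, `transform`
#' @export
preprocess_pair <- function(pct, cbct, pct_labels = NULL, cbct_labels = NULL,
                            cfg = preprocess_config(), align = TRUE) {
  res_l <- function(lm) if (is.null(lm)) NULL else
    resample(lm, cfg$target_spacing, "nearest")
  pct <- resample(pct, cfg$target_spacing)
  cbct <- resample(cbct, cfg$target_spacing)
  pct_labels <- res_l(pct_labels); cbct_labels <- res_l(cbct_labels)

  skin_p <- extract_skin_mask(pct, cfg)
  skin_c <- extract_skin_mask(cbct, cfg)
  pct <- fill_outside_body(pct, skin_p)
  cbct <- fill_outside_body(cbct, skin_c)

  tr <- rigid_transform()
  if (align) {
    ra <- rigid_align(pct, cbct, skin_p, skin_c, cfg)
    tr <- ra$transform
    pct <- ra$aligned
    if (!is.null(pct_labels))
      pct_labels <- apply_rigid(pct_labels, tr, dim(cbct$voxels), "nearest")
    skin_p <- extract_skin_mask(pct, cfg)
  }
  crop_l <- function(o) if (is.null(o)) NULL else crop_centered(o, skin_c, cfg$crop)
  list(pct = crop_centered(pct, skin_c, cfg$crop),
       cbct = crop_centered(cbct, skin_c, cfg$crop),
       pct_labels = crop_l(pct_labels), cbct_labels = crop_l(cbct_labels),
       transform = tr)
}
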