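#' Pelvic phantom specification
#'
#' Geometric-primitive pelvis: an elliptical body, an ellipsoidal bladder,
#' a cylindrical spinal cord, two spherical femoral heads and paired
#' posterior bone-marrow arcs, each with a mean HU and seeded jitter plus a
#' smooth random texture that gives the registration something to grip.
#'
#' Two grid presets: `desk` (24 x 96 x 128 voxels at 5 x 2 x 2 mm, CPU-sized)
#' and `paper` (48 x 288 x 400 at 5 x 1 x 1 mm, the clinical grid).
#'
#' @param preset `"desk"` or `"paper"` grid preset
#' @param bladder_scale positive factor on the bladder linear size
#' @param hu named list of tissue mean HU values
#' @param jitter_sd white HU jitter standard deviation
#' @param texture_sd,texture_length smooth texture amplitude (HU) and
#'   correlation length (mm) inside the body
#' @param seed integer seed; same seed, same phantom, bitwise
#' @return list of class `phantom_spec`
#' @export
phantom_spec <- function(preset = c("desk", "paper"), bladder_scale = 1.0,
                         hu = list(air = -1000, body = 40, fat = -80,
                                   bladder = 10, spinal_cord = 25,
                                   femoral_head = 700, bone_marrow = 250),
                         jitter_sd = 5, texture_sd = 25, texture_length = 30,
                         seed = 1L) {
  preset <- match.arg(preset)
  if (bladder_scale <= 0) stop("bladder_scale must be positive")
  if (any(unlist(hu) < -1000 | unlist(hu) > 1500))
    stop("tissue HU means must lie in [-1000, 1500]")
  g <- if (preset == "desk") list(dims = c(24L, 96L, 128L), spacing = c(5, 2, 2))
       else list(dims = c(48L, 288L, 400L), spacing = c(5, 1, 1))
  structure(list(
    preset = preset, dims = g$dims, spacing = g$spacing,
    body_half = c(1000, 75, 110),                  # quasi-cylindrical in z
    organs = list(
      bladder = list(center = c(0, 15, 0), half = c(28, 28, 34)),
      spinal_cord = list(center = c(0, -45, 0), radius = 7),
      femoral_head_l = list(center = c(0, -8, -58), radius = 21),
      femoral_head_r = list(center = c(0, -8, 58), radius = 21),
      bone_marrow = list(center = c(0, -10, 0), r_inner = 40, r_outer = 52,
                         z_half = 80, x_max = 40)
    ),
    hu = hu, jitter_sd = jitter_sd, texture_sd = texture_sd,
    texture_length = texture_length,
    bladder_scale = bladder_scale, seed = as.integer(seed)),
    class = "phantom_spec")
}

# smooth seeded random field (HU or mm units) on the grid
smooth_noise <- function(dims, spacing, corr_len) {
  cd <- pmax(2L, as.integer(ceiling(dims * spacing / corr_len)) + 1L)
  coarse <- array(rnorm(prod(cd)), cd)
  array(zoom3d(coarse, dims), dims)
}

#' Generate a pelvic phantom CT and its organ labels
#'
#' @param spec a [phantom_spec]
#' @return list with `volume` ([image_volume]) and `labels` ([label_map])
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$dims; sp <- spec$spacing
  with_seed(spec$seed, {
    mm <- grid_mm(dims, sp)
    bh <- spec$body_half
    body <- (mm$z / bh[1])^2 + (mm$y / bh[2])^2 + (mm$x / bh[3])^2 <= 1

    og <- spec$organs
    s <- spec$bladder_scale
    bl <- og$bladder
    check_inside <- function(center, extent) {
      if ((abs(center[2]) + extent[2]) / bh[2] > 1 ||
          (abs(center[3]) + extent[3]) / bh[3] > 1)
        stop("organ extends outside the body ellipsoid")
    }
    check_inside(bl$center, bl$half * s)
    check_inside(og$spinal_cord$center, rep(og$spinal_cord$radius, 3))
    bladder <- ((mm$z - bl$center[1]) / (bl$half[1] * s))^2 +
               ((mm$y - bl$center[2]) / (bl$half[2] * s))^2 +
               ((mm$x - bl$center[3]) / (bl$half[3] * s))^2 <= 1
    sc <- og$spinal_cord
    cord <- ((mm$y - sc$center[2])^2 + (mm$x - sc$center[3])^2) <= sc$radius^2
    fh <- function(o) ((mm$z - o$center[1])^2 + (mm$y - o$center[2])^2 +
                         (mm$x - o$center[3])^2) <= o$radius^2
    fhl <- fh(og$femoral_head_l); fhr <- fh(og$femoral_head_r)
    bm <- og$bone_marrow
    rr <- sqrt((mm$y - bm$center[2])^2 + (mm$x - bm$center[3])^2)
    marrow <- rr >= bm$r_inner & rr <= bm$r_outer &
      mm$y < bm$center[2] & abs(mm$x) <= bm$x_max & abs(mm$z) <= bm$z_half

    # paint order fixes mutual exclusivity: later organs take precedence
    lab <- array(0L, dims)
    lab[body] <- 1L
    lab[marrow & body] <- 6L
    lab[fhl & body] <- 4L
    lab[fhr & body] <- 5L
    lab[cord & body] <- 3L
    lab[bladder & body] <- 2L

    hu <- spec$hu
    vol <- array(hu$air, dims)
    vol[lab == 1L] <- hu$body
    # subcutaneous fat layer just inside the skin (stays labeled body)
    rell <- sqrt((mm$z / bh[1])^2 + (mm$y / bh[2])^2 + (mm$x / bh[3])^2)
    fat <- lab == 1L & rell >= 0.80 & rell <= 0.94
    vol[fat] <- hu$fat
    vol[lab == 6L] <- hu$bone_marrow
    vol[lab == 4L] <- hu$femoral_head
    vol[lab == 5L] <- hu$femoral_head
    vol[lab == 3L] <- hu$spinal_cord
    vol[lab == 2L] <- hu$bladder

    if (spec$texture_sd > 0) {
      tex <- smooth_noise(dims, sp, spec$texture_length) * spec$texture_sd
      vol[body] <- vol[body] + tex[body]
    }
    if (spec$jitter_sd > 0) {
      jit <- array(rnorm(prod(dims), 0, spec$jitter_sd), dims)
      vol[body] <- vol[body] + jit[body]
    }
    list(volume = image_volume(vol, spacing = sp),
         labels = label_map(lab, spacing = sp))
  })
}

#' CBCT degradation specification
#'
#' Additive image-domain model of CBCT artifact content: white HU noise, a
#' smooth multiplicative-looking bias/scatter shading field, in-plane
#' streaks, an optional dark cavity artifact and an optional couch slab.
#'
#' @param noise_sd additive noise SD (HU)
#' @param noise_corr_mm correlation length of the noise mottle in mm
#'   (0 gives white noise; iterative reconstruction leaves correlated noise)
#' @param bias_amp,bias_length bias-field peak amplitude (HU) and correlation
#'   length (mm)
#' @param streak_n,streak_amp number and amplitude (HU) of in-plane streaks
#' @param cavity,cavity_depth dark cavity-artifact toggle and depth (HU)
#' @param offset global HU offset inside the body
#' @param couch if TRUE add a couch slab posterior to the body
#' @param seed integer seed
#' @return list of class `degradation_spec`
#' @export
degradation_spec <- function(noise_sd = 15, noise_corr_mm = 8,
                             bias_amp = 30, bias_length = 120,
                             streak_n = 6L, streak_amp = 25,
                             cavity = TRUE, cavity_depth = 80,
                             offset = 40, couch = FALSE, seed = 1L) {
  stopifnot(noise_sd >= 0, noise_corr_mm >= 0, bias_amp >= 0, bias_length > 0,
            streak_n >= 0, streak_amp >= 0, cavity_depth >= 0)
  structure(list(noise_sd = noise_sd, noise_corr_mm = noise_corr_mm,
                 bias_amp = bias_amp,
                 bias_length = bias_length, streak_n = as.integer(streak_n),
                 streak_amp = streak_amp, cavity = cavity,
                 cavity_depth = cavity_depth, offset = offset,
                 couch = couch, seed = as.integer(seed)),
            class = "degradation_spec")
}

#' Degrade a CT volume into a CBCT-like volume
#'
#' Purely additive inside the body (plus the couch outside), so the anatomy
#' and any label map remain valid. An all-zero spec returns the input
#' unchanged; fixed seed gives bitwise-identical output.
#'
#' @param ct an [image_volume]
#' @param body binary body mask of the same shape
#' @param spec a [degradation_spec]
#' @return degraded [image_volume]
#' @export
degrade_to_cbct <- function(ct, body, spec = degradation_spec()) {
  stopifnot(inherits(ct, "image_volume"), inherits(spec, "degradation_spec"))
  body <- vox_of(body) != 0
  dims <- dim(ct$voxels)
  if (!identical(dim(body), dims)) stop("body mask shape mismatch")
  sp <- ct$spacing
  out <- ct$voxels
  with_seed(spec$seed, {
    add <- array(0, dims)
    if (spec$bias_amp > 0) {
      bias <- smooth_noise(dims, sp, spec$bias_length)
      bias <- bias / max(abs(bias)) * spec$bias_amp
      add <- add + bias
    }
    if (spec$streak_n > 0 && spec$streak_amp > 0) {
      mm <- grid_mm(dims, sp)
      for (i in seq_len(spec$streak_n)) {
        th <- runif(1, 0, pi)
        d0 <- runif(1, -0.4, 0.4) * min(dims[2] * sp[2], dims[3] * sp[3])
        amp <- spec$streak_amp * sample(c(-1, 1), 1)
        dist <- mm$y * cos(th) + mm$x * sin(th) - d0
        add <- add + amp * exp(-dist^2 / (2 * (1.5 * sp[3])^2))
      }
    }
    if (spec$cavity && spec$cavity_depth > 0) {
      mm <- grid_mm(dims, sp)
      cz <- runif(1, -30, 30); cy <- runif(1, -35, -15); cx <- runif(1, -15, 15)
      r2 <- ((mm$z - cz) / 25)^2 + ((mm$y - cy) / 14)^2 + ((mm$x - cx) / 14)^2
      add <- add - spec$cavity_depth * exp(-r2)
    }
    if (spec$noise_sd > 0) {
      nz <- if (spec$noise_corr_mm > 0) {
        n0 <- smooth_noise(dims, sp, spec$noise_corr_mm)
        n0 / sd(n0) * spec$noise_sd
      } else rnorm(prod(dims), 0, spec$noise_sd)
      add <- add + nz
    }
    add <- add + spec$offset
    out[body] <- out[body] + add[body]
    if (spec$couch) {
      mm <- grid_mm(dims, sp)
      slab <- mm$y < -(max(abs(mm$y[body])) + 10) &
              mm$y > -(max(abs(mm$y[body])) + 40) & abs(mm$x) < 150
      out[slab & !body] <- 200
    }
  })
  image_volume(out, spacing = sp, origin = ct$origin)
}

#' Smooth random-deformation specification
#'
#' Ground-truth deformations are sampled as random control-point
#' perturbations interpolated to the grid, tapered to zero in a band at the
#' volume boundary and rescaled so the maximum displacement magnitude equals
#' `max_disp_mm`.
#'
#' @param control_mm control-point spacing in mm (scalar or per axis z,y,x);
#'   must be at least 2 voxels on each axis
#' @param max_disp_mm maximum displacement magnitude in mm
#' @param boundary_band voxels over which the field ramps to zero at the
#'   volume border (z, y, x)
#' @param focus_center_mm,focus_sigma_mm Gaussian envelope (mm, relative to
#'   the volume center) concentrating the deformation in the soft-tissue
#'   interior where day-to-day pelvic deformation actually occurs (organ
#'   filling); bones and skin stay nearly static. `focus_sigma_mm = NULL`
#'   disables the envelope
#' @param shift_mm amplitude of a coherent envelope-weighted shift in a
#'   seeded random (mostly in-plane) direction, emulating the bulk
#'   displacement of pelvic soft tissue by organ filling; 0 disables
#' @param seed integer seed
#' @return list of class `deformation_spec`
#' @export
deformation_spec <- function(control_mm = 96, max_disp_mm = 16,
                             boundary_band = c(2, 6, 6),
                             focus_center_mm = c(0, 10, 0),
                             focus_sigma_mm = c(70, 40, 55),
                             shift_mm = 14, seed = 1L) {
  stopifnot(all(control_mm > 0), max_disp_mm >= 0, shift_mm >= 0)
  structure(list(control_mm = rep(control_mm, length.out = 3),
                 max_disp_mm = max_disp_mm,
                 boundary_band = rep(as.integer(boundary_band), length.out = 3),
                 focus_center_mm = focus_center_mm,
                 focus_sigma_mm = focus_sigma_mm,
                 shift_mm = shift_mm,
                 seed = as.integer(seed)),
            class = "deformation_spec")
}

#' Sample a dense smooth displacement field
#'
#' @param spec a [deformation_spec]
#' @param dims grid shape (nz, ny, nx)
#' @param spacing voxel spacing (mm)
#' @return array (nz, ny, nx, 3), components (dz, dy, dx) in voxel units
#' @export
sample_deformation <- function(spec, dims, spacing) {
  stopifnot(inherits(spec, "deformation_spec"))
  dims <- as.integer(dims)
  if (any(spec$control_mm < 2 * spacing))
    stop("control spacing must be at least 2 voxels on each axis")
  with_seed(spec$seed, {
    field <- array(0, c(dims, 3))
    if (spec$max_disp_mm > 0) {
      cd <- pmax(2L, as.integer(ceiling(dims * spacing / spec$control_mm)) + 1L)
      taper <- array(1, dims)
      for (ax in 1:3) {
        b <- spec$boundary_band[ax]
        if (b > 0 && dims[ax] > 2 * b) {
          ramp <- c(seq(0, 1, length.out = b + 1)[-(b + 1)],
                    rep(1, dims[ax] - 2 * b),
                    rev(seq(0, 1, length.out = b + 1)[-(b + 1)]))
          rarr <- switch(ax,
            array(rep(ramp, times = prod(dims[2:3])), dims),
            array(rep(rep(ramp, each = dims[1]), times = dims[3]), dims),
            array(rep(ramp, each = prod(dims[1:2])), dims))
          taper <- taper * rarr
        }
      }
      env <- 1
      if (!is.null(spec$focus_sigma_mm)) {
        mm <- grid_mm(dims, spacing)
        fc <- spec$focus_center_mm; fs <- spec$focus_sigma_mm
        env <- exp(-(((mm$z - fc[1]) / fs[1])^2 + ((mm$y - fc[2]) / fs[2])^2 +
                       ((mm$x - fc[3]) / fs[3])^2) / 2)
      }
      for (c in 1:3) {
        coarse <- array(rnorm(prod(cd)), cd)
        field[, , , c] <- array(zoom3d(coarse, dims), dims) * taper * env /
          spacing[c]
      }
      # random component capped at half the budget, then the coherent shift
      mag_mm <- sqrt((field[, , , 1] * spacing[1])^2 +
                     (field[, , , 2] * spacing[2])^2 +
                     (field[, , , 3] * spacing[3])^2)
      mx <- max(mag_mm)
      rand_cap <- if (spec$shift_mm > 0) spec$max_disp_mm / 2 else spec$max_disp_mm
      if (mx > 0) field <- field * (rand_cap / mx)
      if (spec$shift_mm > 0) {
        dir <- rnorm(3) * c(0.4, 1, 1)        # predominantly in-plane
        dir <- dir / sqrt(sum(dir^2)) * spec$shift_mm
        envt <- if (length(env) == 1) taper else env * taper
        for (c in 1:3)
          field[, , , c] <- field[, , , c] + envt * dir[c] / spacing[c]
      }
      mag_mm <- sqrt((field[, , , 1] * spacing[1])^2 +
                     (field[, , , 2] * spacing[2])^2 +
                     (field[, , , 3] * spacing[3])^2)
      mx <- max(mag_mm)
      if (mx > spec$max_disp_mm)
        field <- field * (spec$max_disp_mm / mx)
    }
    field
  })
}

#' Jacobian determinant of a displacement field
#'
#' Determinant of `I + grad(u)` from central finite differences, per voxel.
#' @param field array (nz, ny, nx, 3) in voxel units
#' @return 3D array of determinants
#' @export
field_jacobian <- function(field) {
  d <- dim(field)[1:3]
  grad_c <- function(a, ax) {
    g <- array(0, dim(a))
    n <- dim(a)[ax]
    idx0 <- lapply(dim(a), seq_len)
    ip <- idx0; ip[[ax]] <- pmin(idx0[[ax]] + 1L, n)
    im <- idx0; im[[ax]] <- pmax(idx0[[ax]] - 1L, 1L)
    den <- array(2, dim(a))
    den_idx <- idx0[[ax]]
    den_v <- ifelse(den_idx == 1L | den_idx == n, 1, 2)
    den <- switch(ax,
      array(rep(den_v, times = prod(dim(a)[2:3])), dim(a)),
      array(rep(rep(den_v, each = dim(a)[1]), times = dim(a)[3]), dim(a)),
      array(rep(den_v, each = prod(dim(a)[1:2])), dim(a)))
    (do.call(`[`, c(list(a), ip)) - do.call(`[`, c(list(a), im))) / den
  }
  J <- array(0, c(d, 3, 3))
  for (c in 1:3) for (ax in 1:3) {
    J[, , , c, ax] <- grad_c(field[, , , c], ax) + (c == ax)
  }
  J[, , , 1, 1] * (J[, , , 2, 2] * J[, , , 3, 3] - J[, , , 2, 3] * J[, , , 3, 2]) -
  J[, , , 1, 2] * (J[, , , 2, 1] * J[, , , 3, 3] - J[, , , 2, 3] * J[, , , 3, 1]) +
  J[, , , 1, 3] * (J[, , , 2, 1] * J[, , , 3, 2] - J[, , , 2, 2] * J[, , , 3, 1])
}

# Analytic bladder inflation field: maps CBCT coordinates into pCT
# coordinates so that warp(pCT, u) has the bladder scaled by s about its
# center; smooth decay between the scaled boundary (rho = 1) and rho = 2.
bladder_inflation_field <- function(spec, s, dims, spacing) {
  bl <- spec$organs$bladder
  mm <- grid_mm(dims, spacing)
  dz <- mm$z - bl$center[1]; dy <- mm$y - bl$center[2]; dx <- mm$x - bl$center[3]
  ha <- bl$half * s
  rho <- sqrt((dz / ha[1])^2 + (dy / ha[2])^2 + (dx / ha[3])^2)
  t <- clamp(rho - 1, 0, 1)
  psi <- 1 - (3 * t^2 - 2 * t^3)      # 1 inside, smoothstep to 0 at rho = 2
  fac <- (1 / s - 1) * psi
  field <- array(0, c(dims, 3))
  field[, , , 1] <- fac * dz / spacing[1]
  field[, , , 2] <- fac * dy / spacing[2]
  field[, , , 3] <- fac * dx / spacing[3]
  field
}

#' Generate a paired pCT/CBCT phantom case
#'
#' The CBCT anatomy is the pCT anatomy warped by a known smooth deformation
#' composed with an analytic bladder inflation chosen so the measured bladder
#' volume-difference statistic lands within 10% (relative) of
#' `bladder_diff_target`, then degraded with CBCT-style artifacts. The exact
#' ground-truth field and warped labels are retained.
#'
#' @param spec a [phantom_spec] (its `bladder_scale` is the pCT scale)
#' @param dspec a [degradation_spec]
#' @param fspec a [deformation_spec]
#' @param bladder_diff_target target Diff statistic in percent (>= 0, <= 400)
#' @return list of class `phantom_pair` with elements `pct`, `pct_labels`,
#'   `cbct`, `cbct_labels`, `gt_field` (voxel units), `measured_diff`
#' @export
make_pair <- function(spec = phantom_spec(), dspec = degradation_spec(),
                      fspec = deformation_spec(),
                      bladder_diff_target = 0) {
  if (bladder_diff_target < 0) stop("bladder_diff_target must be >= 0")
  if (bladder_diff_target > 400) stop("bladder_diff_target above 400% is not reachable")
  ph <- generate_phantom(spec)
  dims <- spec$dims; sp <- spec$spacing
  u_r <- sample_deformation(fspec, dims, sp)

  s <- (1 + bladder_diff_target / 100)^(1 / 3)
  v_pct <- organ_volume(ph$labels, "bladder")
  build <- function(s) {
    u <- if (abs(s - 1) > 1e-9)
      compose_fields_cpp(bladder_inflation_field(spec, s, dims, sp), u_r,
                         as.integer(dims))
    else u_r
    lab <- warp3d_cpp(as.double(ph$labels$labels), as.integer(dims),
                      u, 1L, 0)
    list(u = array(u, c(dims, 3)), lab = array(as.integer(round(lab)), dims))
  }
  res <- build(s)
  if (bladder_diff_target > 0) {
    for (i in 1:3) {
      v_cbct <- sum(res$lab == 2L) * prod(sp)
      meas <- volume_diff(v_cbct, v_pct)
      if (abs(meas - bladder_diff_target) <= 0.1 * bladder_diff_target) break
      s <- s * ((1 + bladder_diff_target / 100) / (1 + meas / 100))^(1 / 3)
      res <- build(s)
    }
  }
  cbct_clean <- warp3d_cpp(ph$volume$voxels, as.integer(dims), res$u, 0L, -1000)
  cbct_labels <- label_map(res$lab, spacing = sp,
                           organ_table = ph$labels$organ_table)
  cbct <- degrade_to_cbct(image_volume(array(cbct_clean, dims), spacing = sp),
                          res$lab >= 1L, dspec)
  v_cbct <- sum(res$lab == 2L) * prod(sp)
  structure(list(pct = ph$volume, pct_labels = ph$labels,
                 cbct = cbct, cbct_clean = image_volume(array(cbct_clean, dims),
                                                        spacing = sp),
                 cbct_labels = cbct_labels,
                 gt_field = res$u,
                 measured_diff = volume_diff(v_cbct, v_pct),
                 bladder_scale_used = s),
            class = "phantom_pair")
}

#' @export
print.phantom_pair <- function(x, ...) {
  cat(sprintf("<phantom_pair> %s, bladder Diff %.1f%%\n",
              paste(dim(x$pct$voxels), collapse = "x"), x$measured_diff))
  invisible(x)
}

#' Write a phantom pair to a directory as NIfTI files
#' @param pair a `phantom_pair`
#' @param dir output directory (created if missing)
#' @return the directory, invisibly
#' @export
write_pair <- function(pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(pair$pct, file.path(dir, "pct.nii.gz"))
  write_volume(pair$pct_labels, file.path(dir, "pct_labels.nii.gz"))
  write_volume(pair$cbct, file.path(dir, "cbct.nii.gz"))
  write_volume(pair$cbct_labels, file.path(dir, "cbct_labels.nii.gz"))
  write_field(pair$gt_field, file.path(dir, "gt_field.nii.gz"),
              spacing = pair$pct$spacing)
  invisible(dir)
}
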