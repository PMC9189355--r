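#' Warp a volume or label map by a displacement field
#'
#' `out(x) = in(x + u(x))` with trilinear (images) or nearest-neighbour
#' (labels) sampling; out-of-bounds reads return `fill`.
#'
#' @param vol [image_volume], [label_map] or 3D array
#' @param field array (nz, ny, nx, 3), components (dz, dy, dx) in voxel units
#'   on the output grid
#' @param mode `"linear"` or `"nearest"` (label maps default to nearest)
#' @param fill out-of-bounds value (-1000 for images, 0 for labels)
#' @return object of the input's class
#' @export
warp <- function(vol, field, mode = NULL, fill = NULL) {
  is_lab <- inherits(vol, "label_map")
  mode <- mode %||% (if (is_lab) "nearest" else "linear")
  if (!mode %in% c("linear", "nearest")) stop("unknown warp mode: ", mode)
  fill <- fill %||% (if (is_lab) 0 else -1000)
  v <- vox_of(vol)
  if (!identical(dim(v), dim(field)[1:3])) stop("field grid mismatch")
  out <- warp3d_cpp(as.double(v), as.integer(dim(v)), as.double(field),
                    as.integer(mode == "nearest"), fill)
  if (is_lab)
    label_map(array(as.integer(round(out)), dim(v)), spacing = vol$spacing,
              organ_table = vol$organ_table)
  else if (inherits(vol, "image_volume"))
    image_volume(array(out, dim(v)), spacing = vol$spacing, origin = vol$origin)
  else array(out, dim(v))
}

#' Compose two displacement fields
#'
#' `compose(f_outer, f_inner)(x) = f_inner(x) + f_outer(x + f_inner(x))`,
#' so warping once by the composition equals warping by `f_outer` first and
#' `f_inner` second, up to interpolation error.
#'
#' @param f_outer,f_inner arrays (nz, ny, nx, 3) on the same grid
#' @return composed field
#' @export
compose_fields <- function(f_outer, f_inner) {
  if (!identical(dim(f_outer), dim(f_inner))) stop("field shape mismatch")
  d <- dim(f_outer)[1:3]
  array(compose_fields_cpp(as.double(f_outer), as.double(f_inner),
                           as.integer(d)), dim(f_outer))
}

#' Diffusion smoothness penalty of a displacement field
#'
#' Mean over voxels, components and spatial directions of squared forward
#' differences.
#' @param field array (nz, ny, nx, 3)
#' @return non-negative scalar
#' @export
smoothness_loss <- function(field) {
  smoothness_loss_cpp(as.double(field), as.integer(dim(field)[1:3]), 0L)$loss
}

#' Propagate organ contours through a displacement field
#'
#' Nearest-neighbour warp of the label volume; the organ table is preserved
#' and no new label values can appear.
#'
#' @param labels a [label_map] on the field's grid
#' @param field displacement field (voxel units)
#' @return warped [label_map] (the "dMask")
#' @export
propagate_contours <- function(labels, field) {
  stopifnot(inherits(labels, "label_map"))
  if (!identical(dim(labels$labels), dim(field)[1:3]))
    stop("label grid does not match field grid")
  warp(labels, field, mode = "nearest", fill = 0)
}

#' Mean endpoint error between two displacement fields
#' @param f_est,f_gt fields (voxel units) on the same grid
#' @param mask optional binary array restricting the average
#' @return mean Euclidean endpoint error in voxels
#' @export
endpoint_error <- function(f_est, f_gt, mask = NULL) {
  stopifnot(identical(dim(f_est), dim(f_gt)))
  e <- sqrt((f_est[, , , 1] - f_gt[, , , 1])^2 +
            (f_est[, , , 2] - f_gt[, , , 2])^2 +
            (f_est[, , , 3] - f_gt[, , , 3])^2)
  if (is.null(mask)) mean(e) else mean(e[vox_of(mask) != 0])
}

#' Multi-stage registration network configuration
#'
#' Three-stage coarse-to-fine cascade: each stage is an encoder-decoder with
#' two stride-2 down-sampling layers, six residual blocks at the bottleneck,
#' two nearest-up-sampling layers, and a zero-initialized field head so the
#' initial prediction is the identity. Stage k registers at 1/4, 1/2 and
#' full resolution and predicts a residual field composed onto the earlier
#' stages' result.
#'
#' @param preset `"desk"` (grid 8 x 96 x 128 after z pooling, 8 base channels, instance-wise
#'   fitting on CPU) or `"paper"` (48 x 288 x 400, wider, documented batch
#'   sizes 20/4/1)
#' @param stages number of cascade stages
#' @param scales per-stage down-sampling factors, descending to 1
#' @param base_ch encoder base channel width
#' @param n_res residual blocks at the bottleneck
#' @param iters per-stage optimization iterations
#' @param batch per-stage batch sizes (documentation of the full-scale
#'   schedule; instance fitting uses one pair per step)
#' @param w_mind,w_smooth loss weights
#' @param lr Adam step size
#' @param z_pool integer pooling factor applied to the z axis before
#'   registration (desk: 24-slice phantoms registered on 8 slices)
#' @param mind a [mind_params] for the image-similarity loss
#' @param seed parameter-initialization seed
#' @return list of class `msnet_config`
#' @export
msnet_config <- function(preset = c("desk", "paper"), stages = 3L,
                         scales = c(4L, 2L, 1L), base_ch = NULL,
                         n_res = 6L, iters = NULL, batch = c(20L, 4L, 1L),
                         w_mind = 1, w_smooth = 0.3, lr = 0.02,
                         z_pool = NULL, mind = mind_params(eps_rel = 1),
                         seed = 1L) {
  preset <- match.arg(preset)
  base_ch <- base_ch %||% (if (preset == "desk") 8L else 16L)
  iters <- iters %||% (if (preset == "desk") c(120L, 80L, 40L) else
                         c(400L, 400L, 400L))
  z_pool <- z_pool %||% (if (preset == "desk") 3L else 1L)
  stopifnot(stages >= 1L, length(scales) == stages,
            all(diff(scales) < 0), scales[stages] == 1L, base_ch >= 4L)
  structure(list(preset = preset, stages = as.integer(stages),
                 scales = as.integer(scales), base_ch = as.integer(base_ch),
                 n_res = as.integer(n_res), iters = as.integer(iters),
                 batch = as.integer(batch), w_mind = w_mind,
                 w_smooth = w_smooth, lr = lr, z_pool = as.integer(z_pool),
                 mind = mind, seed = as.integer(seed)),
            class = "msnet_config")
}

msnet_stage_net <- function(c0, n_res) {
  c1 <- 2L * c0; c2 <- 4L * c0
  res_block <- function() ly_res(list(
    ly_conv(3, c2, c2, 3), ly_in(3, c2), ly_lrelu(),
    ly_conv(3, c2, c2, 3), ly_in(3, c2)))
  c(list(
    ly_conv(3, 2L, c0, 3), ly_in(3, c0), ly_lrelu(),
    ly_conv(3, c0, c1, 3, stride = 2), ly_in(3, c1), ly_lrelu(),
    ly_conv(3, c1, c2, 3, stride = 2), ly_in(3, c2), ly_lrelu()),
    lapply(seq_len(n_res), function(i) res_block()),
    list(
      ly_conv(3, c2, c1, 3), ly_in(3, c1), ly_lrelu(),
      ly_up(3, 2),
      ly_conv(3, c1, c0, 3), ly_in(3, c0), ly_lrelu(),
      ly_up(3, 2),
      ly_conv(3, c0, 3L, 1, zero_init = TRUE)))   # 1x1x1 field head
}

#' Build a multi-stage registration model
#'
#' @param cfg an [msnet_config]
#' @return list of class `msnet_model` with one network per stage; a fresh
#'   model predicts a near-zero field (zero-initialized output layers)
#' @export
build_msnet <- function(cfg = msnet_config()) {
  with_seed(cfg$seed, {
    nets <- lapply(seq_len(cfg$stages), function(s)
      msnet_stage_net(cfg$base_ch, cfg$n_res))
    structure(list(cfg = cfg, nets = nets, trained = FALSE),
              class = "msnet_model")
  })
}

check_msnet_dims <- function(d_reg, scales) {
  if (d_reg[1] %% 4L != 0L)
    stop("registration grid z extent must be divisible by 4; adjust z_pool")
  for (sc in scales) {
    ip <- d_reg[2:3]
    if (any(ip %% sc != 0L) || any((ip %/% sc) %% 4L != 0L))
      stop("in-plane grid must be divisible by every stage scale times 4 ",
           "(two down-sampling layers per stage); pad the volume accordingly")
  }
}

check_normalized <- function(x) {
  if (min(x) < -1 - 1e-6 || max(x) > 1 + 1e-6)
    stop("registration inputs must be normalized to (-1, 1); ",
         "apply normalize_registration() first")
}

# stage pooling is in-plane only; the z axis is handled once by z_pool
pool3 <- function(x, f) {
  if (f == 1L) return(x)
  a <- x
  if (length(dim(a)) == 3L) dim(a) <- c(dim(a), 1L)
  out <- avgpool3d_cpp(a, dim(a), 1L, f, f)
  array(out, dim(out)[1:3])
}

poolz <- function(x, f) {
  if (f == 1L) return(x)
  a <- x
  if (length(dim(a)) == 3L) dim(a) <- c(dim(a), 1L)
  out <- avgpool3d_cpp(a, dim(a), f, 1L, 1L)
  array(out, dim(out)[1:3])
}

msnet_stage_pass <- function(net, m_pre, f_s) {
  x <- array(c(m_pre, f_s), c(dim(m_pre), 2L))
  nn_forward(net, x)
}

#' Train the multi-stage registration network (unsupervised)
#'
#' Coarse-to-fine: stage k warps the moving image by the composition of the
#' earlier stages' (frozen) fields, predicts a residual field at its scale,
#' and minimizes `w_mind * L_MIND(warped, fixed) + w_smooth *
#' L_smooth(residual)`. Deterministic for a fixed seed; with a single pair
#' this is instance-wise fitting of the pair being registered.
#'
#' @param pairs list of `list(moving=, fixed=)` 3D arrays normalized to
#'   (-1, 1) on a common grid
#' @param cfg an [msnet_config]
#' @param model optional prebuilt [build_msnet()] model
#' @return list of class `registration_result`: trained `model`, per-pair
#'   composed `fields` (registration grid), `fields_full` (input grid),
#'   per-stage fields and the per-iteration loss `history`
#' @export
train_registration <- function(pairs, cfg = msnet_config(), model = NULL) {
  stopifnot(length(pairs) >= 1)
  for (p in pairs) { check_normalized(p$moving); check_normalized(p$fixed) }
  model <- model %||% build_msnet(cfg)
  d_in <- dim(vox_of(pairs[[1]]$moving))
  m0 <- lapply(pairs, function(p) poolz(as_vol3(p$moving), cfg$z_pool))
  f0 <- lapply(pairs, function(p) poolz(as_vol3(p$fixed), cfg$z_pool))
  d_reg <- dim(m0[[1]])
  check_msnet_dims(as.integer(d_reg), cfg$scales)

  np <- length(pairs)
  comp <- vector("list", np)           # composed field per pair, prev stage grid
  hist <- list()
  stage_fields <- vector("list", cfg$stages)

  for (s in seq_len(cfg$stages)) {
    sc <- cfg$scales[s]
    ms <- lapply(m0, pool3, f = sc)
    fs <- lapply(f0, pool3, f = sc)
    d_s <- dim(ms[[1]])
    comp_s <- lapply(seq_len(np), function(i) {
      if (is.null(comp[[i]])) array(0, c(d_s, 3))
      else array(field_resize_cpp(comp[[i]], dim(comp[[i]])[1:3],
                                  as.integer(d_s)), c(d_s, 3))
    })
    m_pre <- lapply(seq_len(np), function(i)
      array(warp3d_cpp(ms[[i]], as.integer(d_s), comp_s[[i]], 0L, -1), d_s))

    net <- model$nets[[s]]
    opt <- adam_init(net)
    for (it in seq_len(cfg$iters[s])) {
      i <- (it - 1L) %% np + 1L
      fwd <- msnet_stage_pass(net, m_pre[[i]], fs[[i]])
      r <- fwd$y
      warped <- warp3d_cpp(m_pre[[i]], as.integer(d_s), r, 0L, -1)
      ml <- mind_loss_cpp(fs[[i]], warped, as.integer(d_s), cfg$mind$offsets,
                          cfg$mind$patch, cfg$mind$pweights,
                          cfg$mind$eps_rel, numeric(0), 1L)
      sl <- smoothness_loss_cpp(r, as.integer(d_s), 1L)
      dwarped <- cfg$w_mind * ml$grad
      dr <- warp3d_backward_field_cpp(m_pre[[i]], as.integer(d_s), r,
                                      dwarped, -1) + cfg$w_smooth * sl$grad
      dim(dr) <- c(d_s, 3L)
      bwd <- nn_backward(net, fwd$caches, dr)
      upd <- adam_update(net, bwd$grads, opt, cfg$lr, it)
      net <- upd$net; opt <- upd$state
      hist[[length(hist) + 1]] <- data.frame(
        stage = s, iter = it, pair = i,
        l_mind = ml$loss, l_smooth = sl$loss,
        total = cfg$w_mind * ml$loss + cfg$w_smooth * sl$loss)
    }
    model$nets[[s]] <- net
    rs <- lapply(seq_len(np), function(i) {
      fwd <- msnet_stage_pass(net, m_pre[[i]], fs[[i]])
      array(fwd$y, c(d_s, 3))
    })
    stage_fields[[s]] <- rs
    # stage warped warp(warp(m, comp_prev), r) == warp(m, compose(comp_prev, r))
    comp <- lapply(seq_len(np), function(i)
      array(compose_fields_cpp(comp_s[[i]], rs[[i]], as.integer(d_s)),
            c(d_s, 3)))
  }
  model$trained <- TRUE
  fields_full <- lapply(comp, function(f)
    array(field_resize_cpp(f, dim(f)[1:3], as.integer(d_in)), c(d_in, 3)))
  structure(list(model = model, fields = comp, fields_full = fields_full,
                 stage_fields = stage_fields,
                 history = do.call(rbind, hist)),
            class = "registration_result")
}

#' Apply a trained multi-stage model to a pair
#'
#' Runs the cascade (no parameter updates), composing the per-stage residual
#' fields up to full resolution.
#'
#' @param model a trained `msnet_model`
#' @param moving,fixed normalized 3D arrays matching the training preset
#' @return list of class `registration_result` with `field` (registration
#'   grid), `field_full` (input grid), `stage_fields`, `warped`
#' @export
register <- function(model, moving, fixed) {
  stopifnot(inherits(model, "msnet_model"))
  cfg <- model$cfg
  check_normalized(moving); check_normalized(fixed)
  d_in <- dim(vox_of(moving))
  m0 <- poolz(as_vol3(moving), cfg$z_pool)
  f0 <- poolz(as_vol3(fixed), cfg$z_pool)
  comp <- NULL
  stage_fields <- vector("list", cfg$stages)
  for (s in seq_len(cfg$stages)) {
    sc <- cfg$scales[s]
    ms <- pool3(m0, sc); fs <- pool3(f0, sc)
    d_s <- dim(ms)
    comp_s <- if (is.null(comp)) array(0, c(d_s, 3))
      else array(field_resize_cpp(comp, dim(comp)[1:3], as.integer(d_s)),
                 c(d_s, 3))
    m_pre <- array(warp3d_cpp(ms, as.integer(d_s), comp_s, 0L, -1), d_s)
    r <- array(msnet_stage_pass(model$nets[[s]], m_pre, fs)$y, c(d_s, 3))
    stage_fields[[s]] <- r
    comp <- array(compose_fields_cpp(comp_s, r, as.integer(d_s)), c(d_s, 3))
  }
  field_full <- array(field_resize_cpp(comp, dim(comp)[1:3], as.integer(d_in)),
                      c(d_in, 3))
  warped <- warp3d_cpp(as_vol3(moving), as.integer(d_in), field_full, 0L, -1)
  structure(list(field = comp, field_full = field_full,
                 stage_fields = stage_fields,
                 warped = array(warped, d_in)),
            class = "registration_result")
}
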