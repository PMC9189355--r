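#' Study design: bladder-mismatch strata
#'
#' Reproduces the clinical study design on phantoms: cases are generated
#' across bladder volume-difference strata, both methods (deformable
#' registration with contour propagation; CycleGAN synthesis) are run on
#' every case, and per-stratum statistics are aggregated. Stratum assignment
#' uses the measured (not targeted) Diff of the bladder label volumes.
#'
#' @param breaks ascending stratum boundaries in percent (defaults give
#'   strata <20%, 20-50%, 50-100%, >100%)
#' @param targets per-stratum bladder Diff targets used for generation
#' @param cases_per_stratum cases generated per stratum
#' @param train_pairs phantom pairs used to train the synthesis model
#' @param seed master seed (all case and model seeds derive from it)
#' @param reg_cfg an [msnet_config] for the per-case instance registration
#' @param syn_cfg,gen_cfg CycleGAN training/generator configurations
#' @param align run the rigid-alignment search during preprocessing
#' @return list of class `study_design`
#' @export
study_design <- function(breaks = c(20, 50, 100),
                         targets = c(10, 35, 75, 150),
                         cases_per_stratum = 3L,
                         train_pairs = 4L,
                         seed = 1L,
                         reg_cfg = msnet_config(iters = c(50L, 20L, 5L)),
                         syn_cfg = cyclegan_config(epochs = 6L,
                                                   slice_stride = 4L),
                         gen_cfg = generator_config("resnet15", base_ch = 4L),
                         align = FALSE) {
  stopifnot(length(targets) == length(breaks) + 1L, cases_per_stratum >= 1L,
            all(diff(breaks) > 0))
  structure(list(breaks = breaks, targets = targets,
                 cases_per_stratum = as.integer(cases_per_stratum),
                 train_pairs = as.integer(train_pairs),
                 seed = as.integer(seed), reg_cfg = reg_cfg,
                 syn_cfg = syn_cfg, gen_cfg = gen_cfg, align = align),
            class = "study_design")
}

#' Threshold-based organ mask on a synthetic CT
#'
#' Proxy for re-delineation on the sCT: the image is smoothed in-plane, an
#' HU band centered on the organ's own median intensity (so residual HU
#' calibration error does not shift the contour) is applied within a dilated
#' neighborhood of the reference organ, then closed and hole-filled per
#' slice. Deterministic and label-free on the sCT side; what it scores is
#' boundary placement, i.e. anatomy.
#'
#' @param sct an [image_volume] (synthetic CT)
#' @param ref_labels reference [label_map] (defines the search neighborhood)
#' @param organ organ name
#' @param half_width HU half-width of the band; defaults per organ from the
#'   phantom tissue model
#' @param dilate_r in-plane dilation radius of the search neighborhood
#' @return logical mask
#' @export
sct_organ_mask <- function(sct, ref_labels, organ, half_width = NULL,
                           dilate_r = 3L) {
  widths <- list(bladder = 20, spinal_cord = 15,
                 femoral_head_l = 250, femoral_head_r = 250,
                 bone_marrow = 90)
  half_width <- half_width %||% widths[[organ]]
  if (is.null(half_width)) stop("no HU band known for organ ", organ)
  d <- as.integer(dim(sct$voxels))
  core <- extract_mask(ref_labels, organ)
  hood <- dilate_inplane_cpp(array(as.integer(core), d), d,
                             as.integer(dilate_r))
  # in-plane 3x3 box smoothing suppresses noise before the HU band is applied
  sl <- array(aperm(sct$voxels, c(2, 3, 1)), c(d[2], d[3], 1, d[1]))
  sm <- conv2d_forward_cpp(sl, dim(sl), rep(1 / 9, 9), 3L, 1L, 0, 1L, 1L)
  smv <- aperm(array(sm, c(d[2], d[3], d[1])), c(3, 1, 2))
  ctr <- stats::median(smv[core])
  m <- array(as.integer(smv >= ctr - half_width & smv <= ctr + half_width &
                          hood == 1L), d)
  if (sum(m) == 0) return(array(FALSE, d))
  m <- dilate_inplane_cpp(m, d, 1L)
  m <- 1L - dilate_inplane_cpp(1L - m, d, 1L)
  lab <- label_components_cpp(m, d)
  if (length(lab$sizes) == 0) return(array(FALSE, d))
  m <- array(lab$labels == which.max(lab$sizes), d)
  m <- fill_holes_inplane_cpp(array(as.integer(m), d), d)
  array(m == 1L, d)
}

study_case <- function(target, case_seed, design, syn_model) {
  pair <- make_pair(phantom_spec(seed = case_seed),
                    degradation_spec(seed = case_seed + 1L),
                    deformation_spec(seed = case_seed + 2L),
                    bladder_diff_target = target)
  cfg_p <- preprocess_config("desk")
  pp <- preprocess_pair(pair$pct, pair$cbct, pair$pct_labels,
                        pair$cbct_labels, cfg_p, align = design$align)
  skin_c <- extract_skin_mask(pair$cbct, cfg_p)
  truth <- crop_centered(pair$cbct_clean, skin_c, cfg_p$crop)

  organs <- setdiff(names(pair$pct_labels$organ_table), "body")
  diff_bl <- volume_diff(organ_volume(pp$cbct_labels, "bladder"),
                         organ_volume(pp$pct_labels, "bladder"))

  mv <- normalize_registration(pp$pct, cfg_p)
  fx <- normalize_registration(pp$cbct, cfg_p)
  cfg_r <- design$reg_cfg
  cfg_r$seed <- case_seed + 3L
  reg <- train_registration(list(list(moving = mv, fixed = fx)), cfg_r)
  f <- reg$fields_full[[1]]
  dmask <- propagate_contours(pp$pct_labels, f)
  dpct <- warp(pp$pct, f)

  sct <- synthesize_ct(syn_model, pp$cbct)

  row <- list(case_seed = case_seed, target = target, diff = diff_bl,
              stratum = diff_stratum(diff_bl, design$breaks),
              nmi_before = nmi(pp$cbct, pp$pct),
              nmi_after = nmi(pp$cbct, dpct),
              ncc_before = ncc(pp$cbct, pp$pct),
              ncc_after = ncc(pp$cbct, dpct),
              mae_cbct = error_metrics(truth, pp$cbct)$mae,
              mae_sct = error_metrics(truth, sct)$mae,
              rmse_cbct = error_metrics(truth, pp$cbct)$rmse,
              rmse_sct = error_metrics(truth, sct)$rmse,
              psnr_sct = error_metrics(truth, sct)$psnr,
              ssim_cbct = ssim(truth, pp$cbct),
              ssim_sct = ssim(truth, sct))
  for (o in organs) {
    row[[paste0("dsc_pre_", o)]] <-
      dsc(extract_mask(pp$pct_labels, o), extract_mask(pp$cbct_labels, o))
    row[[paste0("dsc_reg_", o)]] <-
      dsc(extract_mask(dmask, o), extract_mask(pp$cbct_labels, o))
    row[[paste0("dsc_sct_", o)]] <-
      dsc(sct_organ_mask(sct, pp$cbct_labels, o),
          extract_mask(pp$cbct_labels, o))
  }
  as.data.frame(row, stringsAsFactors = FALSE)
}

#' Run the phantom study
#'
#' Trains the synthesis model once on a training split, then for every case:
#' generate a pair at the stratum's mismatch target, preprocess, register
#' (instance fit) and propagate contours, synthesize an sCT, and evaluate
#' the full metric suite. Failed cases are recorded and skipped. Fully
#' deterministic for a fixed design seed.
#'
#' @param design a [study_design]
#' @return list of class `comparison_report` with `cases` (per-case data
#'   frame), `strata` (per-stratum mean and SD), `failures`, `design`
#' @export
run_study <- function(design = study_design()) {
  stopifnot(inherits(design, "study_design"))
  with_seed(design$seed, {
    seeds <- sample.int(2^28, design$train_pairs +
                          length(design$targets) * design$cases_per_stratum)
  })
  tp <- design$train_pairs
  vlog("pipeline", "generating ", tp, " training pairs")
  train_pairs <- lapply(seq_len(tp), function(i)
    make_pair(phantom_spec(seed = seeds[i]),
              degradation_spec(seed = seeds[i] + 1L),
              deformation_spec(seed = seeds[i] + 2L),
              bladder_diff_target = c(10, 40, 80, 150)[(i - 1L) %% 4L + 1L]))
  syn_cfg <- design$syn_cfg
  syn_cfg$seed <- design$seed
  vlog("pipeline", "training synthesis model")
  fit <- train_cyclegan(lapply(train_pairs, `[[`, "cbct"),
                        lapply(train_pairs, `[[`, "pct"),
                        syn_cfg, design$gen_cfg)

  rows <- list(); failures <- list()
  k <- tp
  for (si in seq_along(design$targets)) {
    for (ci in seq_len(design$cases_per_stratum)) {
      k <- k + 1L
      cs <- seeds[k]
      res <- tryCatch(
        study_case(design$targets[si], cs, design, fit$models$g_cbct_ct),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1]] <-
          list(seed = cs, target = design$targets[si],
               message = conditionMessage(res))
        vlog("pipeline", "case failed: ", conditionMessage(res))
      } else rows[[length(rows) + 1]] <- res
    }
  }
  cases <- do.call(rbind, rows)
  num <- vapply(cases, is.numeric, logical(1))
  agg <- function(fn) aggregate(cases[num], by = list(stratum = cases$stratum),
                                FUN = fn)
  strata <- list(mean = agg(mean), sd = agg(stats::sd))
  structure(list(cases = cases, strata = strata, failures = failures,
                 design = design, history = fit$history),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %d cases, %d failures\n",
              nrow(x$cases), length(x$failures)))
  cols <- c("stratum", "dsc_reg_bladder", "dsc_sct_bladder", "mae_cbct",
            "mae_sct")
  print(x$strata$mean[, intersect(cols, names(x$strata$mean))])
  invisible(x)
}

#' Write a comparison report to disk
#'
#' Emits `report.json` (canonical JSON round-trippable to the in-memory
#' report), `cases.csv`, `strata_mean.csv` / `strata_sd.csv` and a boxplot
#' figure of bladder DSC by stratum and method.
#'
#' @param report a `comparison_report`
#' @param dir output directory (must exist or be creatable)
#' @return `dir`, invisibly
#' @export
render_report <- function(report, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, showWarnings = FALSE, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  jsonlite::write_json(
    list(cases = report$cases, strata_mean = report$strata$mean,
         strata_sd = report$strata$sd,
         failures = report$failures),
    file.path(dir, "report.json"), digits = NA, auto_unbox = TRUE,
    dataframe = "columns")
  write.csv(report$cases, file.path(dir, "cases.csv"), row.names = FALSE)
  write.csv(report$strata$mean, file.path(dir, "strata_mean.csv"),
            row.names = FALSE)
  write.csv(report$strata$sd, file.path(dir, "strata_sd.csv"),
            row.names = FALSE)
  grDevices::png(file.path(dir, "bladder_dsc.png"), width = 720, height = 480)
  on.exit(grDevices::dev.off(), add = TRUE)
  cs <- report$cases
  strata <- unique(cs$stratum)
  graphics::boxplot(
    c(split(cs$dsc_reg_bladder, cs$stratum)[strata],
      split(cs$dsc_sct_bladder, cs$stratum)[strata]),
    at = c(seq_along(strata) * 2 - 0.5, seq_along(strata) * 2 + 0.5),
    names = c(paste0(strata, "\nreg"), paste0(strata, "\nsCT")),
    col = rep(c("steelblue", "indianred"), each = length(strata)),
    ylab = "bladder DSC", main = "registration vs synthesis by mismatch")
  invisible(dir)
}

#' Read back a written report
#' @param dir directory written by [render_report()]
#' @return list with `cases`, `strata_mean`, `strata_sd`
#' @export
read_report <- function(dir) {
  jsonlite::read_json(file.path(dir, "report.json"), simplifyVector = TRUE)
}
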