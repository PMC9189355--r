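# Shared fixtures, memoised so expensive phantoms are built once per run.

.fix_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fix_env)) assign(key, force(expr), envir = .fix_env)
  get(key, envir = .fix_env)
}

fixture_pair <- function(seed = 11L, target = 10, clean = FALSE) {
  key <- sprintf("pair_%d_%g_%d", seed, target, clean)
  memo(key, {
    dsp <- if (clean)
      degradation_spec(noise_sd = 0, bias_amp = 0, streak_n = 0L,
                       cavity = FALSE, offset = 0, seed = seed + 1L)
    else degradation_spec(seed = seed + 1L)
    make_pair(phantom_spec(seed = seed), dsp,
              deformation_spec(seed = seed + 2L), bladder_diff_target = target)
  })
}

fixture_phantom <- function(seed = 5L) {
  memo(sprintf("ph_%d", seed), generate_phantom(phantom_spec(seed = seed)))
}

# smooth random test volume (values roughly in HU range)
smooth_vol <- function(dims, seed = 1, scale = 100, coarse = 4) {
  set.seed(seed)
  cg <- array(rnorm(prod(pmax(2, dims %/% coarse))), pmax(2, dims %/% coarse))
  array(cbctqi:::zoom3d(cg, dims), dims) * scale
}

micro_design <- function(seed = 3L) {
  study_design(
    breaks = c(50), targets = c(10, 150), cases_per_stratum = 1L,
    train_pairs = 1L, seed = seed,
    reg_cfg = msnet_config(iters = c(4L, 2L, 1L)),
    syn_cfg = cyclegan_config(epochs = 1L, slice_stride = 8L, disc_ch = 8L),
    gen_cfg = generator_config("resnet15", base_ch = 4L))
}

fixture_micro_report <- function(seed = 3L) {
  memo(sprintf("micro_%d", seed), run_study(micro_design(seed)))
}
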