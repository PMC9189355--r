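`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Structured log line
#'
#' Emits a single log line with module, elapsed time and message. Controlled
#' by `options(cbctqi.verbose = TRUE/FALSE)` (default off inside tests).
#' @param module character scalar naming the emitting module
#' @param ... message parts, pasted together
#' @keywords internal
vlog <- function(module, ...) {
  if (!isTRUE(getOption("cbctqi.verbose", FALSE))) return(invisible(NULL))
  msg <- paste0(...)
  cat(sprintf("[%s] %s %s\n", module, format(Sys.time(), "%H:%M:%S"), msg))
  invisible(NULL)
}

# Deterministic local RNG scope: runs `expr` under `seed` and restores the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

# Zoom a 3D array to new dims by trilinear interpolation (center-aligned).
zoom3d <- function(arr, newdim) {
  d <- dim(arr)
  sc <- d / newdim
  A <- c(sc[1], 0, 0, 0, sc[2], 0, 0, 0, sc[3])
  t <- 0.5 * sc - 0.5
  affine_sample_cpp(as.double(arr), as.integer(d), as.integer(newdim),
                    A, t, 0, 0L)
}

# mm coordinate arrays (relative to the volume center) on a (nz,ny,nx) grid.
grid_mm <- function(dims, spacing) {
  ax <- lapply(1:3, function(i) {
    v <- (seq_len(dims[i]) - 1) * spacing[i]
    v - mean(v)
  })
  list(
    z = array(rep(ax[[1]], times = dims[2] * dims[3]), dim = dims),
    y = array(rep(rep(ax[[2]], each = dims[1]), times = dims[3]), dim = dims),
    x = array(rep(ax[[3]], each = dims[1] * dims[2]), dim = dims)
  )
}
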