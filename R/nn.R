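# Minimal layer framework with explicit forward/backward passes.
# Tensors: 3D [nz,ny,nx,C] (single sample) and 2D [ny,nx,C,N] (batched).
# Convolutions run through the im2col+GEMM kernels in src/conv.cpp; the
# remaining layers are cheap and live in R. Parameters are plain arrays
# inside each layer; gradients come back in a parallel structure.

ly_conv <- function(nd, cin, cout, k, stride = 1L, zero_init = FALSE,
                    init_sd = NULL) {
  fan_in <- k^nd * cin
  w <- if (zero_init) numeric(k^nd * cin * cout)
       else rnorm(k^nd * cin * cout, 0, init_sd %||% sqrt(2 / fan_in))
  list(type = "conv", nd = nd, cin = cin, cout = cout, k = as.integer(k),
       stride = as.integer(stride), pad = as.integer((k - 1) %/% 2),
       w = w, b = numeric(cout))
}

ly_in <- function(nd, ch) {
  list(type = "in", nd = nd, ch = ch, g = rep(1, ch), b = numeric(ch))
}

ly_lrelu <- function(slope = 0.2) list(type = "lrelu", slope = slope)
ly_relu <- function() list(type = "lrelu", slope = 0)
ly_tanh <- function() list(type = "tanh")
ly_up <- function(nd, f = 2L) list(type = "up", nd = nd, f = as.integer(f))
ly_res <- function(inner) list(type = "res", inner = inner)

in_stats_dims <- function(nd, xdim) {
  # spatial size S and number of stat groups (channels x batch)
  if (nd == 3) list(S = prod(xdim[1:3]), G = xdim[4], rep = 1L)
  else list(S = prod(xdim[1:2]), G = xdim[3] * xdim[4], rep = xdim[4])
}

layer_forward <- function(ly, x) {
  switch(ly$type,
    conv = {
      y <- if (ly$nd == 3)
        conv3d_forward_cpp(x, dim(x), ly$w, ly$k, ly$cout, ly$b, ly$stride, ly$pad)
      else
        conv2d_forward_cpp(x, dim(x), ly$w, ly$k, ly$cout, ly$b, ly$stride, ly$pad)
      list(y = y, cache = x)
    },
    "in" = {
      sd_ <- in_stats_dims(ly$nd, dim(x))
      r <- instnorm_forward_cpp(x, sd_$S, sd_$G, ly$ch, ly$g, ly$b)
      y <- r$y
      dim(y) <- dim(x)
      list(y = y, cache = list(xhat = r$xhat, istd = r$istd, xdim = dim(x)))
    },
    lrelu = {
      r <- lrelu_forward_cpp(x, ly$slope)
      y <- r$y
      dim(y) <- dim(x)
      list(y = y, cache = r$neg)
    },
    tanh = {
      y <- tanh(x)
      list(y = y, cache = y)
    },
    up = {
      y <- upsample_nearest_cpp(x, dim(x), ly$f, ly$nd)
      list(y = y, cache = dim(x))
    },
    res = {
      inner <- nn_forward(ly$inner, x)
      y <- x + inner$y
      dim(y) <- dim(x)
      list(y = y, cache = inner$caches)
    },
    stop("unknown layer type"))
}

layer_backward <- function(ly, cache, dy) {
  switch(ly$type,
    conv = {
      bk <- if (ly$nd == 3)
        conv3d_backward_cpp(cache, dim(cache), ly$w, ly$k, ly$cout,
                            ly$stride, ly$pad, dy)
      else
        conv2d_backward_cpp(cache, dim(cache), ly$w, ly$k, ly$cout,
                            ly$stride, ly$pad, dy)
      list(dx = bk$dx, grads = list(w = bk$dw, b = bk$db))
    },
    "in" = {
      sd_ <- in_stats_dims(ly$nd, cache$xdim)
      r <- instnorm_backward_cpp(dy, cache$xhat, cache$istd, sd_$S, sd_$G,
                                 ly$ch, ly$g)
      dx <- r$dx
      dim(dx) <- cache$xdim
      list(dx = dx, grads = list(g = r$dg, b = r$db))
    },
    lrelu = {
      dx <- lrelu_backward_cpp(dy, cache, ly$slope)
      dim(dx) <- dim(dy)
      list(dx = dx, grads = NULL)
    },
    tanh = {
      dx <- dy * (1 - cache^2)
      dim(dx) <- dim(cache)
      list(dx = dx, grads = NULL)
    },
    up = {
      list(dx = upsample_nearest_backward_cpp(dy, dim(dy), ly$f, ly$nd),
           grads = NULL)
    },
    res = {
      inner <- nn_backward(ly$inner, cache, dy)
      dx <- dy + inner$dx
      dim(dx) <- dim(inner$dx)
      list(dx = dx, grads = inner$grads)
    },
    stop("unknown layer type"))
}

nn_forward <- function(net, x) {
  caches <- vector("list", length(net))
  for (i in seq_along(net)) {
    r <- layer_forward(net[[i]], x)
    x <- r$y
    caches[[i]] <- r$cache
  }
  list(y = x, caches = caches)
}

nn_backward <- function(net, caches, dy) {
  grads <- vector("list", length(net))
  for (i in rev(seq_along(net))) {
    r <- layer_backward(net[[i]], caches[[i]], dy)
    dy <- r$dx
    grads[i] <- list(r$grads)   # [[<-]] with NULL would drop the element
  }
  list(dx = dy, grads = grads)
}

# Accumulate two gradient structures (same shape); either may be NULL.
nn_acc_grads <- function(g1, g2) {
  if (is.null(g1)) return(g2)
  if (is.null(g2)) return(g1)
  for (i in seq_along(g1)) {
    if (is.null(g1[[i]])) next
    if (is.list(g1[[i]]) && is.null(g1[[i]]$w) && is.null(g1[[i]]$g)) {
      g1[[i]] <- nn_acc_grads(g1[[i]], g2[[i]])       # res inner grads
    } else {
      for (p in names(g1[[i]])) g1[[i]][[p]] <- g1[[i]][[p]] + g2[[i]][[p]]
    }
  }
  g1
}

# ---- Adam ----

param_names <- function(ly) {
  switch(ly$type, conv = c("w", "b"), "in" = c("g", "b"), NULL)
}

adam_init <- function(net) {
  lapply(net, function(ly) {
    if (ly$type == "res") return(list(inner = adam_init(ly$inner)))
    pn <- param_names(ly)
    if (is.null(pn)) return(NULL)
    st <- lapply(pn, function(p) list(m = numeric(length(ly[[p]])),
                                      v = numeric(length(ly[[p]]))))
    names(st) <- pn
    st
  })
}

adam_update <- function(net, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(net)) {
    ly <- net[[i]]
    if (ly$type == "res") {
      r <- adam_update(ly$inner, grads[[i]], state[[i]]$inner, lr, t,
                       beta1, beta2, eps)
      net[[i]]$inner <- r$net
      state[[i]]$inner <- r$state
      next
    }
    pn <- param_names(ly)
    if (is.null(pn) || is.null(grads[[i]])) next
    for (p in pn) {
      g <- as.numeric(grads[[i]][[p]])
      st <- state[[i]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      net[[i]][[p]] <- net[[i]][[p]] -
        lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
      state[[i]][[p]] <- st
    }
  }
  list(net = net, state = state)
}
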