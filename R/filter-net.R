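#' Configuration of the linear data-filtering network
#'
#' Architecture hyper-parameters of the strictly linear multi-resolution
#' ("U-Net"-style) network that filters half-scan data tensors.  The
#' network has `n_levels` encoder convolution blocks with stride-2
#' downsampling convolutions between them, `n_levels - 1` decoder blocks
#' with transposed-convolution upsampling and skip concatenations, and a
#' final 1x1x1 projection to one channel.  Channels start at
#' `base_channels` and double per level.  Being strictly linear, it has no
#' biases, activations or pooling anywhere, so it realizes a genuine linear
#' operator on the data space.
#'
#' @param n_levels Number of encoder blocks (>= 2); the full-scale
#'   reference configuration uses 7.
#' @param base_channels Feature channels at the first level (reference: 8).
#' @param conv_kernel Length-3 odd kernel of the feature-extraction
#'   convolution in each block (reference: 5, 5, 5).
#' @param down_kernel Length-3 kernel of the stride-2 downsampling
#'   convolution (reference: 3, 3, 3).
#' @param up_kernel Length-3 kernel of the stride-2 transposed
#'   upsampling convolution; must equal the stride (reference: 2, 2, 2).
#' @param ring_pad_taps Temporal taps of the learned ring-padding
#'   convolution (reference: 9).
#' @param ring_pad_edge Number of edge slices along the ring axis fed to
#'   the learned padding (reference: 5; clamped to the ring extent at
#'   deeper levels).
#' @param strictly_linear Must be `TRUE`; kept as an explicit contract
#'   marker.
#' @return An object of class `filter_net_config`.
#' @export
filter_net_config <- function(n_levels = 4L, base_channels = 8L,
                              conv_kernel = c(5L, 5L, 5L),
                              down_kernel = c(3L, 3L, 3L),
                              up_kernel = c(2L, 2L, 2L),
                              ring_pad_taps = 9L, ring_pad_edge = 5L,
                              strictly_linear = TRUE) {
  n_levels <- as.integer(n_levels)
  stopifnot(n_levels >= 2, base_channels >= 1,
            length(conv_kernel) == 3, all(conv_kernel %% 2 == 1),
            length(down_kernel) == 3, all(down_kernel %% 2 == 1),
            length(up_kernel) == 3, all(up_kernel == 2),
            ring_pad_taps %% 2 == 1, ring_pad_edge >= 1,
            isTRUE(strictly_linear))
  structure(
    list(n_levels = n_levels, base_channels = as.integer(base_channels),
         conv_kernel = as.integer(conv_kernel),
         down_kernel = as.integer(down_kernel), down_stride = 2L,
         up_kernel = as.integer(up_kernel), up_stride = 2L,
         ring_pad_taps = as.integer(ring_pad_taps),
         ring_pad_edge = as.integer(ring_pad_edge),
         strictly_linear = TRUE),
    class = "filter_net_config"
  )
}

#' Channel schedule of a configuration
#' @param config A [filter_net_config()].
#' @return Integer vector of encoder output channels, one per level
#'   (doubling from `base_channels`).
#' @export
channel_schedule <- function(config) {
  config$base_channels * 2L^(seq_len(config$n_levels) - 1L)
}

# --- small tensor helpers ---------------------------------------------------

# zero-padded shift of a (T, V, C) array along its first (time) axis:
# y[t] = x[t + s], zeros outside range
.shift_t3 <- function(x, s) {
  if (s == 0) return(x)
  Tn <- dim(x)[1]
  y <- array(0, dim(x))
  if (abs(s) >= Tn) return(y)
  if (s > 0) y[1:(Tn - s), , ] <- x[(1 + s):Tn, , , drop = FALSE]
  else y[(1 - s):Tn, , ] <- x[1:(Tn + s), , , drop = FALSE]
  y
}

# learned ring padding: edge slices (ring index as input channel) through a
# small temporal convolution, emitting pad slices for one side.
# x: (T, V, R, C); w: (taps, E, n_out); left side reads slices 1..E,
# right side reads slices (R-E+1)..R.  Shared across feature channels.
.ring_pad_fwd <- function(x, w, side) {
  d <- dim(x); taps <- dim(w)[1]; E <- dim(w)[2]; n_out <- dim(w)[3]
  ctr <- (taps + 1L) / 2L
  out <- array(0, c(d[1], d[2], n_out, d[4]))
  idx <- if (side == "left") seq_len(E) else (d[3] - E + 1L):d[3]
  for (o in seq_len(n_out)) {
    acc <- array(0, c(d[1], d[2], d[4]))
    for (e in seq_len(E)) {
      xe <- array(x[, , idx[e], , drop = FALSE], c(d[1], d[2], d[4]))
      for (a in seq_len(taps)) {
        wv <- w[a, e, o]
        if (wv != 0) acc <- acc + wv * .shift_t3(xe, a - ctr)
      }
    }
    out[, , o, ] <- acc
  }
  out
}

# backward of .ring_pad_fwd: returns gradient w.r.t. w and the additive
# gradient contribution to x
.ring_pad_bwd <- function(gout, x, w, side) {
  d <- dim(x); taps <- dim(w)[1]; E <- dim(w)[2]; n_out <- dim(w)[3]
  ctr <- (taps + 1L) / 2L
  gw <- array(0, dim(w))
  gx <- array(0, d)
  idx <- if (side == "left") seq_len(E) else (d[3] - E + 1L):d[3]
  for (o in seq_len(n_out)) {
    go <- array(gout[, , o, , drop = FALSE], c(d[1], d[2], d[4]))
    for (e in seq_len(E)) {
      xe <- array(x[, , idx[e], , drop = FALSE], c(d[1], d[2], d[4]))
      acc <- array(0, c(d[1], d[2], d[4]))
      for (a in seq_len(taps)) {
        s <- a - ctr
        gw[a, e, o] <- sum(.shift_t3(xe, s) * go)
        acc <- acc + w[a, e, o] * .shift_t3(go, -s)
      }
      gx[, , idx[e], ] <-
        array(gx[, , idx[e], , drop = FALSE], dim(acc)) + acc
    }
  }
  list(gw = gw, gx = gx)
}

#' Physics-informed per-axis padding of a data-tensor block input
#'
#' Pads a feature tensor `(time, view, ring, channel)` by `pad_w` slices on
#' each side of each spatial axis, honoring the acquisition geometry:
#' zeros along time (temporally untruncated measurement), cyclic wrap along
#' the view axis (azimuthal 2-pi periodicity), and along the ring axis
#' either zeros or a learned linear map of the `ring_pad_edge` edge slices
#' (small temporal convolutions, one per side) standing in for the
#' unmeasured data beyond the transducer arc.
#'
#' @param x Numeric 4D array `(T, V, R, C)`.
#' @param pad_w Pad width per side (matches the consuming kernel:
#'   2 for a 5x5x5 convolution, 1 for 3x3x3).
#' @param ring_pad Either `NULL` (zero ring padding, as used by the
#'   downsampling layers) or `list(left = wl, right = wr)` with weight
#'   arrays of dim `(taps, edge, pad_w)`.
#' @return Padded array `(T + 2 pad_w, V + 2 pad_w, R + 2 pad_w, C)`.
#' @export
pad_block_input <- function(x, pad_w, ring_pad = NULL) {
  d <- dim(x)
  stopifnot(length(d) == 4, pad_w >= 1)
  if (pad_w > d[2]) stop("pad width exceeding tensor extent on the view axis")
  # ring axis
  if (is.null(ring_pad)) {
    zl <- array(0, c(d[1], d[2], pad_w, d[4]))
    xr <- .abind3(zl, x, zl)
  } else {
    pl <- .ring_pad_fwd(x, ring_pad$left, "left")
    prr <- .ring_pad_fwd(x, ring_pad$right, "right")
    xr <- .abind3(pl, x, prr)
  }
  # view axis: cyclic
  V <- d[2]
  xv <- xr[, c((V - pad_w + 1L):V, seq_len(V), seq_len(pad_w)), , ,
           drop = FALSE]
  # time axis: zeros
  dt <- dim(xv)
  out <- array(0, c(dt[1] + 2L * pad_w, dt[2], dt[3], dt[4]))
  out[pad_w + seq_len(dt[1]), , , ] <- xv
  out
}

# concatenate three 4D arrays along the ring (third) axis
.abind3 <- function(a, b, c) {
  da <- dim(a); db <- dim(b); dc <- dim(c)
  out <- array(0, c(da[1], da[2], da[3] + db[3] + dc[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out[, , da[3] + db[3] + seq_len(dc[3]), ] <- c
  out
}

# backward of pad_block_input: fold the padded-tensor gradient back onto the
# unpadded tensor (and the ring-pad weights when learned)
.unpad_bwd <- function(g, d_in, pad_w, ring_pad = NULL, x = NULL) {
  # undo time zeros
  g <- g[pad_w + seq_len(dim(g)[1] - 2L * pad_w), , , , drop = FALSE]
  # undo cyclic view wrap: fold wrap slices back onto the interior
  V <- d_in[2]
  gv <- g[, pad_w + seq_len(V), , , drop = FALSE]
  gv[, (V - pad_w + 1L):V, , ] <- gv[, (V - pad_w + 1L):V, , , drop = FALSE] +
    g[, seq_len(pad_w), , , drop = FALSE]
  gv[, seq_len(pad_w), , ] <- gv[, seq_len(pad_w), , , drop = FALSE] +
    g[, pad_w + V + seq_len(pad_w), , , drop = FALSE]
  # split ring pads
  R <- d_in[3]
  gl <- gv[, , seq_len(pad_w), , drop = FALSE]
  gx <- array(gv[, , pad_w + seq_len(R), , drop = FALSE], d_in)
  gr <- gv[, , pad_w + R + seq_len(pad_w), , drop = FALSE]
  if (is.null(ring_pad)) {
    return(list(gx = gx, gpl = NULL, gpr = NULL))
  }
  bl <- .ring_pad_bwd(gl, x, ring_pad$left, "left")
  br <- .ring_pad_bwd(gr, x, ring_pad$right, "right")
  list(gx = gx + bl$gx + br$gx, gpl = bl$gw, gpr = br$gw)
}

# --- layer forward / backward ----------------------------------------------

.convblock_fwd <- function(x, pars, cfg) {
  pw <- (cfg$conv_kernel[1] - 1L) / 2L
  xp <- pad_block_input(x, pw, list(left = pars$pad_l, right = pars$pad_r))
  y <- .cpp_conv3d_fwd(xp, dim(xp), pars$w, dim(pars$w), 1L)
  list(y = y, cache = list(x = x, xp = xp))
}

.convblock_bwd <- function(gy, pars, cache, cfg) {
  pw <- (cfg$conv_kernel[1] - 1L) / 2L
  gxp <- .cpp_conv3d_bwd_x(gy, dim(cache$xp), pars$w, dim(pars$w), 1L)
  gw <- .cpp_conv3d_bwd_w(cache$xp, dim(cache$xp), gy, dim(pars$w), 1L)
  up <- .unpad_bwd(gxp, dim(cache$x), pw,
                   list(left = pars$pad_l, right = pars$pad_r), cache$x)
  list(gx = up$gx, gpars = list(pad_l = up$gpl, pad_r = up$gpr, w = gw))
}

.down_fwd <- function(x, pars, cfg) {
  pw <- (cfg$down_kernel[1] - 1L) / 2L
  xp <- pad_block_input(x, pw, ring_pad = NULL)
  y <- .cpp_conv3d_fwd(xp, dim(xp), pars$w, dim(pars$w), cfg$down_stride)
  list(y = y, cache = list(x = x, xp = xp))
}

.down_bwd <- function(gy, pars, cache, cfg) {
  pw <- (cfg$down_kernel[1] - 1L) / 2L
  gxp <- .cpp_conv3d_bwd_x(gy, dim(cache$xp), pars$w, dim(pars$w),
                           cfg$down_stride)
  gw <- .cpp_conv3d_bwd_w(cache$xp, dim(cache$xp), gy, dim(pars$w),
                          cfg$down_stride)
  up <- .unpad_bwd(gxp, dim(cache$x), pw)
  list(gx = up$gx, gpars = list(w = gw))
}

.up_fwd <- function(x, pars, cfg) {
  y <- .cpp_convt3d_fwd(x, dim(x), pars$w, dim(pars$w), cfg$up_stride)
  list(y = y, cache = list(x = x))
}

.up_bwd <- function(gy, pars, cache, cfg) {
  gx <- .cpp_convt3d_bwd_x(gy, dim(cache$x), pars$w, dim(pars$w),
                           cfg$up_stride)
  gw <- .cpp_convt3d_bwd_w(cache$x, dim(cache$x), gy, dim(pars$w),
                           cfg$up_stride)
  list(gx = gx, gpars = list(w = gw))
}

.concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

# --- network construction ---------------------------------------------------

#' Build a strictly linear data-filtering network
#'
#' Deterministically initializes all weights from `seed` (zero-mean
#' Gaussians scaled by `1/sqrt(fan-in)`).  The network is bound to a data
#' tensor shape: the time and view extents must survive
#' `n_levels - 1` stride-2 downsamplings (divisible by
#' `2^(n_levels - 1)`); a ring extent that is not divisible is right-padded
#' at network entry with learned padding to the next multiple and cropped
#' at exit.
#'
#' @param config A [filter_net_config()].
#' @param data_shape Integer length-3 `(Nt, Nv, Nr)` tensor shape the
#'   network will filter.
#' @param seed Integer seed for the deterministic initialization.
#' @return An object of class `filter_network`.
#' @export
init_network <- function(config, data_shape, seed = 1L) {
  stopifnot(inherits(config, "filter_net_config"), length(data_shape) == 3)
  data_shape <- as.integer(data_shape)
  L <- config$n_levels
  f <- 2L^(L - 1L)
  if (data_shape[1] %% f != 0L || data_shape[2] %% f != 0L) {
    stop(sprintf(
      "incompatible input dims: time and view extents must be divisible by %d",
      f))
  }
  ring_pad_entry <- (f - data_shape[3] %% f) %% f
  Rpad <- data_shape[3] + ring_pad_entry
  # per-level spatial shapes after entry padding
  shapes <- lapply(seq_len(L), function(l) {
    as.integer(c(data_shape[1], data_shape[2], Rpad) %/% 2L^(l - 1L))
  })
  if (any(vapply(shapes, function(s) s[2], 1L) <
          (config$conv_kernel[2] - 1L) / 2L)) {
    stop("incompatible input dims: view extent too small for cyclic padding")
  }
  ch <- channel_schedule(config)
  pw <- (config$conv_kernel[3] - 1L) / 2L

  params <- with_local_seed(seed, {
    rnd <- function(d, fan_in) array(stats::rnorm(prod(d), sd = 1 / sqrt(fan_in)), d)
    ring_pads <- function(level) {
      E <- min(config$ring_pad_edge, shapes[[level]][3])
      list(
        pad_l = rnd(c(config$ring_pad_taps, E, pw), config$ring_pad_taps * E),
        pad_r = rnd(c(config$ring_pad_taps, E, pw), config$ring_pad_taps * E))
    }
    pp <- list(enc = vector("list", L), down = vector("list", L - 1L),
               up = vector("list", L - 1L), dec = vector("list", L - 1L))
    if (ring_pad_entry > 0L) {
      E0 <- min(config$ring_pad_edge, data_shape[3])
      pp$entry_pad <- rnd(c(config$ring_pad_taps, E0, ring_pad_entry),
                          config$ring_pad_taps * E0)
    }
    for (i in seq_len(L)) {
      cin <- if (i == 1L) 1L else ch[i - 1L]
      pp$enc[[i]] <- c(ring_pads(i), list(
        w = rnd(c(config$conv_kernel, cin, ch[i]),
                prod(config$conv_kernel) * cin)))
      if (i < L) {
        pp$down[[i]] <- list(
          w = rnd(c(config$down_kernel, ch[i], ch[i]),
                  prod(config$down_kernel) * ch[i]))
      }
    }
    for (i in seq_len(L - 1L)) {
      # decoder stage i operates at level i (full resolution at i = 1)
      pp$up[[i]] <- list(
        w = rnd(c(config$up_kernel, ch[i + 1L], ch[i]),
                prod(config$up_kernel) * ch[i + 1L]))
      pp$dec[[i]] <- c(ring_pads(i), list(
        w = rnd(c(config$conv_kernel, 2L * ch[i], ch[i]),
                prod(config$conv_kernel) * 2L * ch[i])))
    }
    pp$head <- list(w = rnd(c(1L, 1L, 1L, ch[1L], 1L), ch[1L]))
    pp
  })

  structure(
    list(config = config, data_shape = data_shape,
         ring_pad_entry = ring_pad_entry, shapes = shapes, params = params,
         axis_semantics = c("time", "view", "ring")),
    class = "filter_network"
  )
}

#' Number of trainable parameters
#' @param net A [filter_network][init_network].
#' @return Integer parameter count.
#' @export
n_parameters <- function(net) {
  length(flatten_params(net$params))
}

# --- full network forward / backward ---------------------------------------

# x: (Nt, Nv, Nr, 1).  Returns list(y, cache); cache retained only when
# keep_cache = TRUE (training).
filter_forward <- function(net, x, keep_cache = FALSE) {
  cfg <- net$config
  L <- cfg$n_levels
  pp <- net$params
  cache <- list(enc = vector("list", L), down = vector("list", L - 1L),
                up = vector("list", L - 1L), dec = vector("list", L - 1L))
  if (net$ring_pad_entry > 0L) {
    if (keep_cache) cache$x_entry <- x
    pad <- .ring_pad_fwd(x, pp$entry_pad, "right")
    d <- dim(x)
    xx <- array(0, c(d[1], d[2], d[3] + net$ring_pad_entry, d[4]))
    xx[, , seq_len(d[3]), ] <- x
    xx[, , d[3] + seq_len(net$ring_pad_entry), ] <- pad
    x <- xx
  }
  skips <- vector("list", L - 1L)
  for (i in seq_len(L)) {
    cb <- .convblock_fwd(x, pp$enc[[i]], cfg)
    if (keep_cache) cache$enc[[i]] <- cb$cache
    x <- cb$y
    if (i < L) {
      skips[[i]] <- x
      dn <- .down_fwd(x, pp$down[[i]], cfg)
      if (keep_cache) cache$down[[i]] <- dn$cache
      x <- dn$y
    }
  }
  for (i in rev(seq_len(L - 1L))) {
    upf <- .up_fwd(x, pp$up[[i]], cfg)
    if (keep_cache) cache$up[[i]] <- upf$cache
    x <- .concat_ch(upf$y, skips[[i]])
    cb <- .convblock_fwd(x, pp$dec[[i]], cfg)
    if (keep_cache) cache$dec[[i]] <- cb$cache
    x <- cb$y
  }
  if (keep_cache) cache$head_x <- x
  y <- .cpp_conv3d_fwd(x, dim(x), pp$head$w, dim(pp$head$w), 1L)
  if (net$ring_pad_entry > 0L) {
    y <- y[, , seq_len(net$data_shape[3]), , drop = FALSE]
  }
  list(y = y, cache = if (keep_cache) cache else NULL)
}

# gy: gradient w.r.t. the network output, same shape as the (cropped)
# output.  Returns list(grads = <same structure as params>, gx).
filter_backward <- function(net, cache, gy) {
  cfg <- net$config
  L <- cfg$n_levels
  pp <- net$params
  gr <- list(enc = vector("list", L), down = vector("list", L - 1L),
             up = vector("list", L - 1L), dec = vector("list", L - 1L))
  if (net$ring_pad_entry > 0L) {
    d <- dim(gy)
    gfull <- array(0, c(d[1], d[2], d[3] + net$ring_pad_entry, d[4]))
    gfull[, , seq_len(d[3]), ] <- gy
    gy <- gfull
  }
  hx <- cache$head_x
  gr$head <- list(w = .cpp_conv3d_bwd_w(hx, dim(hx), gy, dim(pp$head$w), 1L))
  g <- .cpp_conv3d_bwd_x(gy, dim(hx), pp$head$w, dim(pp$head$w), 1L)
  gskips <- vector("list", L - 1L)
  for (i in seq_len(L - 1L)) {
    cb <- .convblock_bwd(g, pp$dec[[i]], cache$dec[[i]], cfg)
    gr$dec[[i]] <- cb$gpars
    # split concat: first block was the upsampled path, second the skip
    cup <- dim(pp$up[[i]]$w)[5]
    gup <- cb$gx[, , , seq_len(cup), drop = FALSE]
    gskips[[i]] <- cb$gx[, , , cup + seq_len(dim(cb$gx)[4] - cup),
                         drop = FALSE]
    ub <- .up_bwd(gup, pp$up[[i]], cache$up[[i]], cfg)
    gr$up[[i]] <- ub$gpars
    g <- ub$gx
  }
  for (i in rev(seq_len(L))) {
    if (i < L) {
      dn <- .down_bwd(g, pp$down[[i]], cache$down[[i]], cfg)
      gr$down[[i]] <- dn$gpars
      g <- dn$gx + gskips[[i]]
    }
    cb <- .convblock_bwd(g, pp$enc[[i]], cache$enc[[i]], cfg)
    gr$enc[[i]] <- cb$gpars
    g <- cb$gx
  }
  if (net$ring_pad_entry > 0L) {
    x0 <- cache$x_entry
    d0 <- dim(x0)
    gcore <- array(g[, , seq_len(d0[3]), , drop = FALSE], d0)
    gpadblk <- g[, , d0[3] + seq_len(net$ring_pad_entry), , drop = FALSE]
    bp <- .ring_pad_bwd(gpadblk, x0, pp$entry_pad, "right")
    gr$entry_pad <- bp$gw
    g <- gcore + bp$gx
  }
  list(grads = gr, gx = g)
}

#' Apply the filtering network to half-scan data
#'
#' @param net A [filter_network][init_network].
#' @param p A [pressure_data()] whose tensor shape matches the shape the
#'   network was built for.
#' @return The filtered [pressure_data()] (identical shape); the mapping is
#'   strictly linear in `p`.
#' @export
apply_filter <- function(net, p) {
  stopifnot(inherits(net, "filter_network"), inherits(p, "pressure_data"))
  if (!all(dim(p$values) == net$data_shape)) {
    stop("shape mismatch between data and network")
  }
  x <- array(p$values, c(dim(p$values), 1L))
  y <- filter_forward(net, x)$y
  pressure_data(p$scan, array(y, dim(p$values)))
}

# --- parameter vector utilities --------------------------------------------

#' Flatten / restore the network parameter collection
#'
#' Used by the optimizer and by finite-difference gradient checks; the
#' traversal order is fixed and deterministic.
#'
#' @param params A parameter list as stored in `net$params` (or a gradient
#'   list of identical structure).
#' @return `flatten_params` returns a numeric vector;
#'   `unflatten_params` restores the nested structure from one.
#' @export
flatten_params <- function(params) {
  unlist(params, use.names = FALSE)
}

#' @rdname flatten_params
#' @param template A parameter list providing the target structure.
#' @param theta Numeric vector from [flatten_params()].
#' @export
unflatten_params <- function(template, theta) {
  pos <- 0L
  rec <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.list(x)) return(lapply(x, rec))
    n <- length(x)
    v <- theta[(pos + 1L):(pos + n)]
    pos <<- pos + n
    dim(v) <- dim(x)
    v
  }
  out <- rec(template)
  if (pos != length(theta)) stop("parameter vector length mismatch")
  out
}

#' Save / load a trained network checkpoint
#'
#' The checkpoint embeds the architecture configuration, the bound data
#' shape, and all weights; the tensor layout contract is
#' `(time, view, ring)`.
#'
#' @param net A [filter_network][init_network].
#' @param path File path.
#' @return `save_filter_network` returns `path` invisibly;
#'   `load_filter_network` returns the restored network.
#' @export
save_filter_network <- function(net, path) {
  stopifnot(inherits(net, "filter_network"))
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_filter_network
#' @export
load_filter_network <- function(path) {
  net <- readRDS(path)
  if (!inherits(net, "filter_network")) stop("not a filter network checkpoint")
  net
}

#' @export
print.filter_network <- function(x, ...) {
  cat(sprintf(
    "filter_network: %d levels, channels %s, data shape (%s), %d parameters\n",
    x$config$n_levels,
    paste(channel_schedule(x$config), collapse = ","),
    paste(x$data_shape, collapse = ", "), n_parameters(x)))
  invisible(x)
}
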