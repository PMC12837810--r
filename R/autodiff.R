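# Minimal reverse-mode tape used by the network and the differentiable losses.
# Values are plain R arrays: feature maps (H, W, C), vectors, scalars. Heavy
# kernels (conv, pooling, WKV scan) live in src/kernels.cpp; everything else is
# vectorized R. Parameters are registered once per tape, so a weight-shared
# encoder applied to two modalities accumulates both gradient contributions.

tape_new <- function(params) {
  tp <- new.env(parent = emptyenv())
  tp$n <- 0L
  tp$val <- list()
  tp$back <- list()
  tp$parents <- list()
  tp$pid <- list()      # param name -> node id
  tp$params <- params   # named list of arrays
  tp
}

ad_node <- function(tp, val, parents = integer(0), back = NULL) {
  tp$n <- tp$n + 1L
  tp$val[[tp$n]] <- val
  tp$back[[tp$n]] <- if (is.null(back)) NA else back
  tp$parents[[tp$n]] <- parents
  tp$n
}

ad_value <- function(tp, id) {
  force(id)                      # the id may be an unbuilt expression
  tp$val[[id]]
}

ad_const <- function(tp, x) ad_node(tp, x)

ad_param <- function(tp, name) {
  id <- tp$pid[[name]]
  if (!is.null(id)) return(id)
  stopifnot(name %in% names(tp$params))
  id <- ad_node(tp, tp$params[[name]])
  tp$pid[[name]] <- id
  id
}

# Backward from a scalar loss node; returns named list of parameter gradients.
ad_backward <- function(tp, loss_id) {
  grads <- vector("list", tp$n)
  grads[[loss_id]] <- 1
  for (id in seq.int(tp$n, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    bk <- tp$back[[id]]
    if (!is.function(bk)) next
    gs <- bk(g)
    ps <- tp$parents[[id]]
    for (j in seq_along(ps)) {
      gj <- gs[[j]]
      if (is.null(gj)) next
      p <- ps[j]
      grads[[p]] <- if (is.null(grads[[p]])) gj else grads[[p]] + gj
    }
  }
  out <- list()
  for (name in names(tp$pid)) {
    g <- grads[[tp$pid[[name]]]]
    out[[name]] <- if (is.null(g)) array(0, dim_of(tp$params[[name]])) else g
  }
  out
}

dim_of <- function(x) if (is.null(dim(x))) length(x) else dim(x)

# ---- elementwise ------------------------------------------------------------

ad_add <- function(tp, a, b) {
  force(a); force(b)
  ad_node(tp, tp$val[[a]] + tp$val[[b]], c(a, b),
          function(g) list(g, g))
}

ad_sub <- function(tp, a, b) {
  force(a); force(b)
  ad_node(tp, tp$val[[a]] - tp$val[[b]], c(a, b),
          function(g) list(g, -g))
}

ad_mul <- function(tp, a, b) {
  force(a); force(b)
  av <- tp$val[[a]]; bv <- tp$val[[b]]
  ad_node(tp, av * bv, c(a, b), function(g) list(g * bv, g * av))
}

ad_div <- function(tp, a, b) {
  force(a); force(b)
  av <- tp$val[[a]]; bv <- tp$val[[b]]
  ad_node(tp, av / bv, c(a, b),
          function(g) list(g / bv, -g * av / (bv * bv)))
}

ad_smul <- function(tp, a, s) {         # multiply by a fixed scalar
  force(a)
  ad_node(tp, tp$val[[a]] * s, a, function(g) list(g * s))
}

ad_addc <- function(tp, a, cst) {       # add a fixed constant
  force(a)
  ad_node(tp, tp$val[[a]] + cst, a, function(g) list(g))
}

ad_relu <- function(tp, a) {
  force(a)
  av <- tp$val[[a]]
  mask <- av > 0
  ad_node(tp, av * mask, a, function(g) list(g * mask))
}

ad_sigmoid <- function(tp, a) {
  force(a)
  y <- 1 / (1 + exp(-tp$val[[a]]))
  ad_node(tp, y, a, function(g) list(g * y * (1 - y)))
}

ad_abs <- function(tp, a) {
  force(a)
  av <- tp$val[[a]]
  sg <- sign(av)
  ad_node(tp, abs(av), a, function(g) list(g * sg))
}

ad_log <- function(tp, a, eps = 1e-8) {
  force(a)
  av <- tp$val[[a]]
  ad_node(tp, log(av + eps), a, function(g) list(g / (av + eps)))
}

# ---- reductions -------------------------------------------------------------

ad_sum <- function(tp, a) {
  force(a)
  d <- dim_of(tp$val[[a]])
  ad_node(tp, sum(tp$val[[a]]), a, function(g) list(array(g, d)))
}

ad_mean <- function(tp, a) {
  force(a)
  n <- length(tp$val[[a]])
  d <- dim_of(tp$val[[a]])
  ad_node(tp, mean(tp$val[[a]]), a, function(g) list(array(g / n, d)))
}

ad_mulsum <- function(tp, a, b) {       # sum(a * b), scalar
  force(a); force(b)
  av <- tp$val[[a]]; bv <- tp$val[[b]]
  ad_node(tp, sum(av * bv), c(a, b), function(g) list(g * bv, g * av))
}

# ---- layers -----------------------------------------------------------------

ad_conv <- function(tp, x, wname, bname, k, stride = 1L, dil = 1L,
                    pad = NULL) {
  force(x)
  if (is.null(pad)) pad <- ((k - 1L) * dil) %/% 2L
  w <- ad_param(tp, wname); b <- ad_param(tp, bname)
  wv <- tp$val[[w]]; bv <- tp$val[[b]]; xv <- tp$val[[x]]
  wd <- dim(wv)   # (k, k, Cin, Cout)
  wm <- matrix(wv, nrow = k * k * wd[3], ncol = wd[4])
  y <- cpp_conv2d_fw(xv, wm, bv, k, pad, stride, dil)
  ad_node(tp, y, c(x, w, b), function(g) {
    bw <- cpp_conv2d_bw(xv, wm, g, k, pad, stride, dil)
    list(bw$dx, array(bw$dw, wd), as.numeric(bw$db))
  })
}

ad_dwconv <- function(tp, x, wname, bname) {
  force(x)
  w <- ad_param(tp, wname); b <- ad_param(tp, bname)
  wv <- tp$val[[w]]; bv <- tp$val[[b]]; xv <- tp$val[[x]]
  y <- cpp_dwconv_fw(xv, wv, bv)
  ad_node(tp, y, c(x, w, b), function(g) {
    bw <- cpp_dwconv_bw(xv, wv, g)
    list(bw$dx, bw$dw, as.numeric(bw$db))
  })
}

ad_dense <- function(tp, x, wname, bname = NULL) {
  force(x)
  w <- ad_param(tp, wname)
  wv <- tp$val[[w]]; xv <- tp$val[[x]]
  if (is.null(bname)) {
    y <- as.numeric(crossprod(wv, xv))
    return(ad_node(tp, y, c(x, w), function(g) {
      list(as.numeric(wv %*% g), outer(xv, g))
    }))
  }
  b <- ad_param(tp, bname)
  y <- as.numeric(crossprod(wv, xv)) + tp$val[[b]]
  ad_node(tp, y, c(x, w, b), function(g) {
    list(as.numeric(wv %*% g), outer(xv, g), g)
  })
}

# Instance norm: standardize each channel over its spatial extent, then a
# learnable per-channel affine.
ad_inorm <- function(tp, x, gname, bname, eps = 1e-5) {
  force(x)
  gam <- ad_param(tp, gname); bet <- ad_param(tp, bname)
  xv <- tp$val[[x]]; gv <- tp$val[[gam]]; bv <- tp$val[[bet]]
  d <- dim(xv); n <- d[1] * d[2]
  mu <- apply(xv, 3, mean)
  va <- apply(xv, 3, function(s) mean((s - mean(s))^2))
  sg <- sqrt(va + eps)
  xhat <- sweep(sweep(xv, 3, mu, "-"), 3, sg, "/")
  y <- sweep(sweep(xhat, 3, gv, "*"), 3, bv, "+")
  ad_node(tp, y, c(x, gam, bet), function(g) {
    dgam <- apply(g * xhat, 3, sum)
    dbet <- apply(g, 3, sum)
    dxh <- sweep(g, 3, gv, "*")
    m1 <- apply(dxh, 3, mean)
    m2 <- apply(dxh * xhat, 3, mean)
    dx <- sweep(dxh - sweep(array(1, d), 3, m1, "*") -
                  sweep(xhat, 3, m2, "*"), 3, sg, "/")
    list(dx, dgam, dbet)
  })
}

ad_gap <- function(tp, x) {
  force(x)
  xv <- tp$val[[x]]; d <- dim(xv); n <- d[1] * d[2]
  ad_node(tp, apply(xv, 3, mean), x, function(g) {
    sweep(array(1 / n, d), 3, g, "*") -> dx
    list(dx)
  })
}

ad_chmul <- function(tp, x, s) {        # per-channel scaling by vector node s
  force(x); force(s)
  xv <- tp$val[[x]]; sv <- tp$val[[s]]
  ad_node(tp, sweep(xv, 3, sv, "*"), c(x, s), function(g) {
    list(sweep(g, 3, sv, "*"), apply(g * xv, 3, sum))
  })
}

ad_upnn <- function(tp, x) {
  force(x)
  ad_node(tp, cpp_upnn_fw(tp$val[[x]]), x,
          function(g) list(cpp_upnn_bw(g)))
}

ad_sqshift <- function(tp, x) {
  force(x)
  stopifnot(dim(tp$val[[x]])[3] %% 4L == 0L)
  ad_node(tp, cpp_sqshift(tp$val[[x]], 1L), x,
          function(g) list(cpp_sqshift(g, -1L)))
}

ad_pool <- function(tp, x, s, type = c("max", "min")) {
  force(x)
  type <- match.arg(type)
  fw <- cpp_pool_fw(tp$val[[x]], s, type == "max")
  idx <- fw$idx
  ad_node(tp, fw$y, x, function(g) list(cpp_pool_bw(idx, g)))
}

ad_biwkv <- function(tp, kx, vx, wname, uname) {
  force(kx); force(vx)
  wn <- ad_param(tp, wname); un <- ad_param(tp, uname)
  kv <- tp$val[[kx]]; vv <- tp$val[[vx]]
  d <- dim(kv)
  km <- matrix(kv, nrow = d[1] * d[2], ncol = d[3])
  vm <- matrix(vv, nrow = d[1] * d[2], ncol = d[3])
  wv <- tp$val[[wn]]; uv <- tp$val[[un]]
  y <- cpp_biwkv_fw(km, vm, wv, uv)
  ad_node(tp, array(y, d), c(kx, vx, wn, un), function(g) {
    gm <- matrix(g, nrow = d[1] * d[2], ncol = d[3])
    bw <- cpp_biwkv_bw(km, vm, wv, uv, y, gm)
    list(array(bw$dk, d), array(bw$dv, d),
         as.numeric(bw$dw), as.numeric(bw$du))
  })
}

ad_concat_ch <- function(tp, a, b) {
  force(a); force(b)
  av <- tp$val[[a]]; bv <- tp$val[[b]]
  da <- dim(av); db <- dim(bv)
  y <- array(0, c(da[1], da[2], da[3] + db[3]))
  y[, , seq_len(da[3])] <- av
  y[, , da[3] + seq_len(db[3])] <- bv
  ad_node(tp, y, c(a, b), function(g) {
    list(g[, , seq_len(da[3]), drop = FALSE],
         g[, , da[3] + seq_len(db[3]), drop = FALSE])
  })
}

ad_concat_vec <- function(tp, ids) {
  ids <- as.integer(unlist(ids))
  vals <- lapply(ids, function(i) tp$val[[i]])
  lens <- vapply(vals, length, 1L)
  ends <- cumsum(lens)
  ad_node(tp, unlist(vals, use.names = FALSE), ids, function(g) {
    lapply(seq_along(ids), function(j) {
      g[(ends[j] - lens[j] + 1L):ends[j]]
    })
  })
}

ad_slice_ch <- function(tp, x, i) {     # one channel as an (H, W, 1) map
  force(x)
  xv <- tp$val[[x]]; d <- dim(xv)
  ad_node(tp, xv[, , i, drop = FALSE], x, function(g) {
    dx <- array(0, d)
    dx[, , i] <- g
    list(dx)
  })
}

# ---- softmax ----------------------------------------------------------------

ad_softmax_vec <- function(tp, x) {
  force(x)
  xv <- tp$val[[x]]
  e <- exp(xv - max(xv)); y <- e / sum(e)
  ad_node(tp, y, x, function(g) list(y * (g - sum(g * y))))
}

# Softmax over all spatial positions of a single-channel map.
ad_softmax_spatial <- function(tp, x) {
  force(x)
  xv <- tp$val[[x]]; d <- dim(xv)
  e <- exp(xv - max(xv)); y <- e / sum(e)
  ad_node(tp, y, x, function(g) list(y * (g - sum(g * y))))
}

# Per-pixel softmax across channels (segmentation probabilities).
ad_softmax_ch <- function(tp, x) {
  force(x)
  xv <- tp$val[[x]]; d <- dim(xv)
  mx <- apply(xv, c(1, 2), max)
  e <- exp(xv - array(mx, d))
  s <- apply(e, c(1, 2), sum)
  y <- e / array(s, d)
  ad_node(tp, y, x, function(g) {
    gy <- apply(g * y, c(1, 2), sum)
    list(y * (g - array(gy, d)))
  })
}

# Attention-weighted pooling: out_c = sum_hw A[h, w] * F[h, w, c].
ad_attnpool <- function(tp, f, a) {
  force(f); force(a)
  fv <- tp$val[[f]]; av <- tp$val[[a]]
  d <- dim(fv)
  am <- array(av[, , 1], d)
  ad_node(tp, apply(fv * am, 3, sum), c(f, a), function(g) {
    df <- sweep(am, 3, g, "*")
    da <- array(apply(sweep(fv, 3, g, "*"), c(1, 2), sum),
                c(d[1], d[2], 1))
    list(df, da)
  })
}

# 2x2 mean pooling (stride 2), used by the full-resolution decoder skip.
ad_pool2x2_mean <- function(tp, x) {
  force(x)
  xv <- tp$val[[x]]; d <- dim(xv)
  H <- d[1] %/% 2L; W <- d[2] %/% 2L
  y <- (xv[2 * seq_len(H) - 1L, 2 * seq_len(W) - 1L, , drop = FALSE] +
          xv[2 * seq_len(H), 2 * seq_len(W) - 1L, , drop = FALSE] +
          xv[2 * seq_len(H) - 1L, 2 * seq_len(W), , drop = FALSE] +
          xv[2 * seq_len(H), 2 * seq_len(W), , drop = FALSE]) / 4
  ad_node(tp, y, x, function(g) list(cpp_upnn_bw_mean(g)))
}

# Parameter-free standardization of a vector (used ahead of the prediction
# head to keep effect-score magnitudes bounded).
ad_vecnorm <- function(tp, x, eps = 1e-5) {
  force(x)
  xv <- tp$val[[x]]
  n <- length(xv)
  mu <- mean(xv)
  sg <- sqrt(mean((xv - mu)^2) + eps)
  xh <- (xv - mu) / sg
  ad_node(tp, xh, x, function(g) {
    (g - mean(g) - xh * mean(g * xh)) / sg -> dx
    list(dx)
  })
}
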