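# The multitask network: a weight-shared hybrid encoder (Hadamard-product
# attention blocks in stages 1-2, bidirectional-WKV token mixing in stages
# 3-4), global-context attention fusion per modality, an OCT-only four-stage
# decoder for lesion segmentation, and a causal-attention prediction head that
# scores treatment response as the difference between the factual prediction
# and the mean prediction under randomized attention interventions.

#' Model configuration
#'
#' @param widths Channel widths of the four encoder stages (strides 4/8/16/32).
#' @param input_size Square input side; must be divisible by 32.
#' @param n_classes Segmentation classes (background, ERM, IRC, SRF).
#' @param head_hidden Hidden width of the prediction head (linear-ReLU-linear).
#' @param n_samples Attention interventions averaged per prediction.
#' @param modalities "both", or "oct" (UWF channel zeroed).
#' @param encoder "hybrid" (HPA stages 1-2, WKV stages 3-4), "hpa" or "rwkv"
#'   (single-block ablations).
#' @param use_cal Causal-attention head on (off: plain softmax on Y).
#' @param use_gca Global-context fusion on (off: plain aligned sum).
#' @return Config list.
#' @export
model_config <- function(widths = c(32L, 64L, 128L, 256L), input_size = 512L,
                         n_classes = 4L, head_hidden = 64L, n_samples = 4L,
                         modalities = "both", encoder = "hybrid",
                         use_cal = TRUE, use_gca = TRUE) {
  stopifnot(length(widths) == 4L, input_size %% 32L == 0L,
            input_size >= 64L, all(widths %% 4L == 0L),
            encoder %in% c("hybrid", "hpa", "rwkv"))
  list(widths = as.integer(widths), input_size = as.integer(input_size),
       n_classes = as.integer(n_classes), head_hidden = as.integer(head_hidden),
       n_samples = as.integer(n_samples), modalities = modalities,
       encoder = encoder, use_cal = isTRUE(use_cal),
       use_gca = isTRUE(use_gca))
}

block_types <- function(config) {
  switch(config$encoder,
         hybrid = c("hpa", "hpa", "rwkv", "rwkv"),
         hpa = rep("hpa", 4L),
         rwkv = rep("rwkv", 4L))
}

he_conv <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}
he_dense <- function(cin, cout) {
  matrix(rnorm(cin * cout, 0, sqrt(2 / cin)), cin, cout)
}

#' Initialize model parameters
#'
#' @param config From [model_config()].
#' @param seed Integer seed for the weight draw.
#' @return A model object (list with `params` and `config`).
#' @export
model_init <- function(config = model_config(), seed = 1L) {
  Cw <- config$widths
  with_seed(seed, {
    p <- list()
    add_conv <- function(name, k, cin, cout) {
      p[[paste0(name, ".w")]] <<- he_conv(k, cin, cout)
      p[[paste0(name, ".b")]] <<- numeric(cout)
    }
    add_norm <- function(name, c) {
      p[[paste0(name, ".g")]] <<- rep(1, c)
      p[[paste0(name, ".o")]] <<- numeric(c)
    }
    add_hpa <- function(name, c) {
      p[[paste0(name, ".dw")]] <<- array(rnorm(9 * c, 0, sqrt(2 / 9)), c(3, 3, c))
      p[[paste0(name, ".dwb")]] <<- numeric(c)
      add_conv(paste0(name, ".pw"), 1L, c, c)
    }
    add_rwkv <- function(name, c) {
      add_norm(paste0(name, ".n1"), c)
      add_conv(paste0(name, ".k"), 1L, c, c)
      add_conv(paste0(name, ".v"), 1L, c, c)
      add_conv(paste0(name, ".r"), 1L, c, c)
      add_conv(paste0(name, ".o"), 1L, c, c)
      p[[paste0(name, ".decay")]] <<- seq(0.5, 1.5, length.out = c)
      p[[paste0(name, ".bonus")]] <<- rep(0.5, c)
      add_norm(paste0(name, ".n2"), c)
      add_conv(paste0(name, ".m1"), 1L, c, 2L * c)
      add_conv(paste0(name, ".m2"), 1L, 2L * c, c)
    }
    bt <- block_types(config)
    add_block <- function(name, c, type) {
      if (type == "hpa") add_hpa(name, c) else add_rwkv(name, c)
    }
    c0 <- max(4L, Cw[1] %/% 2L)
    add_conv("stem1", 3L, 3L, c0);  add_norm("stem1n", c0)
    add_conv("stem2", 3L, c0, Cw[1]); add_norm("stem2n", Cw[1])
    add_block("enc1", Cw[1], bt[1])
    add_conv("down2", 3L, Cw[1], Cw[2]); add_norm("down2n", Cw[2])
    add_block("enc2", Cw[2], bt[2])
    add_conv("down3", 3L, Cw[2], Cw[3]); add_norm("down3n", Cw[3])
    add_block("enc3", Cw[3], bt[3])
    add_conv("down4", 3L, Cw[3], Cw[4]); add_norm("down4n", Cw[4])
    add_block("enc4", Cw[4], bt[4])
    # GCA: align to stride-4 grid at width Cw[1]
    Cf <- Cw[1]
    for (i in 1:4) add_conv(paste0("gca.p", i), 1L, Cw[i], Cf)
    p[["gca.a1"]] <- he_dense(Cf, max(4L, Cf %/% 2L))
    p[["gca.a1b"]] <- numeric(max(4L, Cf %/% 2L))
    p[["gca.a2"]] <- he_dense(max(4L, Cf %/% 2L), Cf)
    p[["gca.a2b"]] <- numeric(Cf)
    for (i in 1:4) add_conv(paste0("gca.d", i), 3L, Cf, Cf)
    add_conv("gca.attn", 1L, Cf, 1L)
    # decoder (stem0: full-resolution low-level detail skip)
    add_conv("stem0", 3L, 3L, 8L)
    add_conv("dec.l4", 1L, Cw[4], Cw[3])
    add_conv("dec.c3", 3L, 2L * Cw[3], Cw[3]); add_norm("dec.n3", Cw[3])
    add_conv("dec.c2", 3L, Cw[3] + Cw[2], Cw[2]); add_norm("dec.n2", Cw[2])
    add_conv("dec.f", 1L, Cf, Cw[1])
    add_conv("dec.c1", 3L, Cw[2] + Cw[1], Cw[1]); add_norm("dec.n1", Cw[1])
    add_conv("dec.c0", 3L, Cw[1] + 8L, Cw[1])
    add_conv("dec.out", 1L, Cw[1], config$n_classes)
    # prediction head: linear -> ReLU -> linear on pooled + attended features
    p[["head.l1"]] <- he_dense(4L * Cf, config$head_hidden)
    p[["head.l1b"]] <- numeric(config$head_hidden)
    # no bias on the final head layer: it cancels exactly in Y - mean(Y_hat);
    # small init keeps the initial effect scores away from softmax saturation
    p[["head.l2"]] <- 0.1 * he_dense(config$head_hidden, 2L)
    structure(list(params = p, config = config), class = "dmerwkv_model")
  })
}

#' Count trainable parameters
#' @param model A model object.
#' @return Integer count.
#' @export
count_params <- function(model) {
  sum(vapply(model$params, length, 1L))
}

# ---- functional ops (exported for direct use and testing) -------------------

#' Quad-directional channel-group shift
#'
#' Channel quarters are shifted one pixel up, down, left and right
#' respectively, zero-filled at the borders; the token neighbourhood seen by
#' the WKV mixer is thereby enlarged. Channel count must be divisible by 4.
#'
#' @param x H x W x C array.
#' @return Shifted array of the same shape.
#' @export
sq_shift <- function(x) {
  if (dim(x)[3] %% 4L != 0L) stopf("sq_shift: channels must be divisible by 4")
  cpp_sqshift(x, 1L)
}

#' Bidirectional WKV token mixing
#'
#' For each channel c and position t the output is the exponentially-decayed
#' weighted average
#' \deqn{(\sum_{i \ne t} e^{-(|t-i|-1) w_c / T + k_{ic}} v_{ic}
#'        + e^{u_c + k_{tc}} v_{tc}) / (\textrm{same weights})}
#' computed by a numerically-stabilized O(T) two-pass scan.
#'
#' @param k,v T x C key and value matrices.
#' @param w Per-channel decay (length C).
#' @param u Per-channel self-bonus (length C).
#' @return T x C mixed output.
#' @export
bi_wkv <- function(k, v, w, u) {
  k <- as.matrix(k); v <- as.matrix(v)
  if (!all(is.finite(k)) || !all(is.finite(v)))
    stopf("bi_wkv: non-finite input")
  stopifnot(all(dim(k) == dim(v)), length(w) == ncol(k),
            length(u) == ncol(k))
  cpp_biwkv_fw(k, v, as.numeric(w), as.numeric(u))
}

#' Hadamard-product attention block (standalone)
#'
#' `y = x + DW(x) * sigmoid(PW(x))` with a depthwise 3x3 filter DW and a
#' pointwise filter PW: a residual elementwise-product gate whose parameter
#' count (9C + C^2 + 2C) stays strictly below a dense 3x3 convolution (9C^2).
#'
#' @param x H x W x C array.
#' @param params From [hpa_init()].
#' @return Array of the same shape.
#' @export
hpa_block <- function(x, params) {
  if (!all(is.finite(x))) stopf("hpa_block: non-finite input")
  dw <- cpp_dwconv_fw(x, params$dw, params$dwb)
  d <- dim(x)
  wm <- matrix(params$pw.w, nrow = d[3], ncol = d[3])
  pw <- cpp_conv2d_fw(x, wm, params$pw.b, 1L, 0L, 1L, 1L)
  x + dw * (1 / (1 + exp(-pw)))
}

#' @rdname hpa_block
#' @param channels Channel count C.
#' @param seed Weight seed.
#' @export
hpa_init <- function(channels, seed = 1L) {
  with_seed(seed, list(
    dw = array(rnorm(9 * channels, 0, sqrt(2 / 9)), c(3, 3, channels)),
    dwb = numeric(channels),
    pw.w = array(rnorm(channels^2, 0, sqrt(2 / channels)),
                 c(1, 1, channels, channels)),
    pw.b = numeric(channels)))
}

#' @rdname hpa_block
#' @return `hpa_param_count`: parameters of the block vs a dense 3x3 conv.
#' @export
hpa_param_count <- function(channels) {
  c(hpa = 9 * channels + channels + channels^2 + channels,
    dense3x3 = 9 * channels^2)
}

#' Randomized attention intervention
#'
#' The do-operation: an i.i.d. uniform(0,1) map of the same shape as the
#' attention map, renormalized to the same convention (sums to 1 over
#' positions). Seeded and reproducible.
#'
#' @param A Attention map (matrix or H x W x 1 array), nonnegative.
#' @param seed Integer seed.
#' @return Intervened map of identical shape.
#' @export
cal_intervene <- function(A, seed = 1L) {
  d <- dim_of(A)
  with_seed(seed, {
    r <- array(runif(length(A)), d)
    r / sum(r)
  })
}

#' Causal effect of attention on the prediction
#'
#' `Y` is the factual prediction `head(X, A)`; `Y_hat` the prediction averaged
#' over `n_samples` randomized attention interventions; the effect output is
#' `softmax(Y - mean(Y_hat))`. A head that ignores its attention argument
#' yields a uniform effect distribution.
#'
#' @param X Pooled feature vector (or whatever the head consumes).
#' @param A Attention map.
#' @param head `function(X, A) -> numeric class scores`.
#' @param n_samples Number of interventions (>= 1).
#' @param seed Integer seed for the interventions.
#' @return List `Y`, `Y_hat` (mean intervened scores), `Y_effect`
#'   (probabilities, sum 1).
#' @export
causal_effect <- function(X, A, head, n_samples = 16L, seed = 1L) {
  if (n_samples < 1L) stopf("causal_effect: n_samples must be >= 1")
  Y <- head(X, A)
  acc <- 0
  for (j in seq_len(n_samples))
    acc <- acc + head(X, cal_intervene(A, seed = seed + j))
  Y_hat <- acc / n_samples
  d <- Y - Y_hat
  e <- exp(d - max(d))
  list(Y = Y, Y_hat = Y_hat, Y_effect = e / sum(e))
}

# ---- graph builders (tape nodes) --------------------------------------------

g_norm <- function(tp, x, name) ad_inorm(tp, x, paste0(name, ".g"),
                                         paste0(name, ".o"))

g_hpa <- function(tp, x, name) {
  dw <- ad_dwconv(tp, x, paste0(name, ".dw"), paste0(name, ".dwb"))
  pw <- ad_conv(tp, x, paste0(name, ".pw.w"), paste0(name, ".pw.b"), 1L)
  ad_add(tp, x, ad_mul(tp, dw, ad_sigmoid(tp, pw)))
}

g_rwkv <- function(tp, x, name) {
  xs <- ad_sqshift(tp, g_norm(tp, x, paste0(name, ".n1")))
  k <- ad_conv(tp, xs, paste0(name, ".k.w"), paste0(name, ".k.b"), 1L)
  v <- ad_conv(tp, xs, paste0(name, ".v.w"), paste0(name, ".v.b"), 1L)
  r <- ad_conv(tp, xs, paste0(name, ".r.w"), paste0(name, ".r.b"), 1L)
  wk <- ad_biwkv(tp, k, v, paste0(name, ".decay"), paste0(name, ".bonus"))
  mix <- ad_conv(tp, ad_mul(tp, ad_sigmoid(tp, r), wk),
                 paste0(name, ".o.w"), paste0(name, ".o.b"), 1L)
  y <- ad_add(tp, x, mix)
  z <- g_norm(tp, y, paste0(name, ".n2"))
  m <- ad_conv(tp, ad_relu(tp, ad_conv(tp, z, paste0(name, ".m1.w"),
                                       paste0(name, ".m1.b"), 1L)),
               paste0(name, ".m2.w"), paste0(name, ".m2.b"), 1L)
  ad_add(tp, y, m)
}

g_down <- function(tp, x, name, relu = TRUE) {
  y <- g_norm(tp, ad_conv(tp, x, paste0(name, ".w"), paste0(name, ".b"),
                          3L, stride = 2L), paste0(name, "n"))
  if (relu) ad_relu(tp, y) else y
}

g_encoder <- function(tp, x, cfg) {
  bt <- block_types(cfg)
  blk <- function(x, name, type) {
    if (type == "hpa") g_hpa(tp, x, name) else g_rwkv(tp, x, name)
  }
  s1 <- ad_relu(tp, g_norm(tp, ad_conv(tp, x, "stem1.w", "stem1.b", 3L,
                                       stride = 2L), "stem1n"))
  s2 <- ad_relu(tp, g_norm(tp, ad_conv(tp, s1, "stem2.w", "stem2.b", 3L,
                                       stride = 2L), "stem2n"))
  p1 <- blk(s2, "enc1", bt[1])
  p2 <- blk(g_down(tp, p1, "down2", relu = bt[2] == "hpa"), "enc2", bt[2])
  p3 <- blk(g_down(tp, p2, "down3", relu = FALSE), "enc3", bt[3])
  p4 <- blk(g_down(tp, p3, "down4", relu = FALSE), "enc4", bt[4])
  list(p1, p2, p3, p4)
}

g_gca <- function(tp, pyr, cfg = list(use_gca = TRUE)) {
  al <- vector("list", 4L)
  for (i in 1:4) {
    a <- ad_conv(tp, pyr[[i]], sprintf("gca.p%d.w", i),
                 sprintf("gca.p%d.b", i), 1L)
    if (i >= 2) for (r in seq_len(i - 1L)) a <- ad_upnn(tp, a)
    al[[i]] <- a
  }
  s <- ad_add(tp, ad_add(tp, al[[1]], al[[2]]), ad_add(tp, al[[3]], al[[4]]))
  if (!isTRUE(cfg$use_gca)) {
    a_logit <- ad_conv(tp, s, "gca.attn.w", "gca.attn.b", 1L)
    return(list(fused = s, attn = ad_softmax_spatial(tp, a_logit)))
  }
  g <- ad_gap(tp, s)
  att <- ad_sigmoid(tp, ad_dense(tp, ad_relu(tp, ad_dense(tp, g, "gca.a1",
                                                          "gca.a1b")),
                                 "gca.a2", "gca.a2b"))
  f <- ad_add(tp, ad_chmul(tp, s, att), s)
  dil <- c(1L, 2L, 5L, 7L)
  o <- f
  for (i in 1:4)
    o <- ad_add(tp, o, ad_conv(tp, f, sprintf("gca.d%d.w", i),
                               sprintf("gca.d%d.b", i), 3L, dil = dil[i]))
  a_logit <- ad_conv(tp, o, "gca.attn.w", "gca.attn.b", 1L)
  list(fused = o, attn = ad_softmax_spatial(tp, a_logit))
}

g_decoder <- function(tp, fused, skips, xin) {
  d4 <- ad_conv(tp, skips[[4]], "dec.l4.w", "dec.l4.b", 1L)
  u3 <- ad_relu(tp, g_norm(tp, ad_conv(tp, ad_concat_ch(tp, ad_upnn(tp, d4),
                                                        skips[[3]]),
                                       "dec.c3.w", "dec.c3.b", 3L), "dec.n3"))
  u2 <- ad_relu(tp, g_norm(tp, ad_conv(tp, ad_concat_ch(tp, ad_upnn(tp, u3),
                                                        skips[[2]]),
                                       "dec.c2.w", "dec.c2.b", 3L), "dec.n2"))
  s1 <- ad_add(tp, skips[[1]], ad_conv(tp, fused, "dec.f.w", "dec.f.b", 1L))
  u1 <- ad_relu(tp, g_norm(tp, ad_conv(tp, ad_concat_ch(tp, ad_upnn(tp, u2),
                                                        s1),
                                       "dec.c1.w", "dec.c1.b", 3L), "dec.n1"))
  s0 <- ad_relu(tp, ad_conv(tp, xin, "stem0.w", "stem0.b", 3L))
  half <- ad_pool2x2_mean(tp, s0)
  u0 <- ad_relu(tp, ad_conv(tp, ad_concat_ch(tp, ad_upnn(tp, u1), half),
                            "dec.c0.w", "dec.c0.b", 3L))
  ad_conv(tp, ad_upnn(tp, u0), "dec.out.w", "dec.out.b", 1L)
}

g_head_scores <- function(tp, h) {
  hn <- ad_vecnorm(tp, h)
  ad_dense(tp, ad_relu(tp, ad_dense(tp, hn, "head.l1", "head.l1b")),
           "head.l2")
}

g_head <- function(tp, o_oct, o_uwf, a_oct, a_uwf, n_samples, seed,
                   cfg = list(use_cal = TRUE)) {
  gx <- ad_concat_vec(tp, list(ad_gap(tp, o_oct), ad_gap(tp, o_uwf)))
  pa <- ad_concat_vec(tp, list(ad_attnpool(tp, o_oct, a_oct),
                               ad_attnpool(tp, o_uwf, a_uwf)))
  y <- g_head_scores(tp, ad_concat_vec(tp, list(gx, pa)))
  if (!isTRUE(cfg$use_cal)) {
    return(list(Y = y, Y_hat = ad_const(tp, c(0, 0)),
                Y_effect = ad_softmax_vec(tp, y)))
  }
  acc <- NULL
  for (j in seq_len(n_samples)) {
    ab_o <- ad_const(tp, cal_intervene(ad_value(tp, a_oct), seed = seed + 2L * j))
    ab_u <- ad_const(tp, cal_intervene(ad_value(tp, a_uwf),
                                       seed = seed + 2L * j + 1L))
    pj <- ad_concat_vec(tp, list(ad_attnpool(tp, o_oct, ab_o),
                                 ad_attnpool(tp, o_uwf, ab_u)))
    yj <- g_head_scores(tp, ad_concat_vec(tp, list(gx, pj)))
    acc <- if (is.null(acc)) yj else ad_add(tp, acc, yj)
  }
  yhat <- ad_smul(tp, acc, 1 / n_samples)
  yeff <- ad_softmax_vec(tp, ad_sub(tp, y, yhat))
  list(Y = y, Y_hat = yhat, Y_effect = yeff)
}

# Build the full graph; returns the tape plus node ids for every output.
net_graph <- function(model, oct, uwf, n_samples = NULL, seed = 1L) {
  cfg <- model$config
  if (is.null(n_samples)) n_samples <- cfg$n_samples
  if (!all(dim(oct) == c(cfg$input_size, cfg$input_size, 3L)))
    stopf("oct input must be %d x %d x 3", cfg$input_size, cfg$input_size)
  if (!all(dim(uwf) == dim(oct))) stopf("uwf input shape mismatch")
  tp <- tape_new(model$params)
  xo <- ad_const(tp, oct)
  xu <- ad_const(tp, uwf)
  po <- g_encoder(tp, xo, cfg)
  pu <- g_encoder(tp, xu, cfg)  # shared weights: same param nodes
  go <- g_gca(tp, po, cfg)
  gu <- g_gca(tp, pu, cfg)
  seg <- g_decoder(tp, go$fused, po, xo)
  hd <- g_head(tp, go$fused, gu$fused, go$attn, gu$attn, n_samples, seed,
               cfg)
  list(tape = tp, seg = seg, head = hd, pyr_oct = po, pyr_uwf = pu,
       gca_oct = go, gca_uwf = gu)
}

#' Full forward pass
#'
#' Shared-encoder pass over both modalities, per-modality global-context
#' fusion, OCT-branch decoding to segmentation logits, and the causal-attention
#' prediction head. Deterministic for fixed weights, inputs and seed.
#'
#' @param model Model object.
#' @param oct,uwf Preprocessed `input_size` x `input_size` x 3 arrays. Pass
#'   `uwf = NULL` to run single-modality (UWF channel zeroed).
#' @param n_samples Attention interventions (default from config).
#' @param seed Seed for the interventions.
#' @return List: `seg` (H x W x 4 logits), `effect` (list Y, Y_hat, Y_effect),
#'   `attention` (H/4 x W/4 x 1 OCT attention map).
#' @export
net_forward <- function(model, oct, uwf = NULL, n_samples = NULL, seed = 1L) {
  if (is.null(uwf)) uwf <- array(0, dim(oct))
  gr <- net_graph(model, oct, uwf, n_samples, seed)
  tp <- gr$tape
  list(seg = ad_value(tp, gr$seg),
       effect = list(Y = ad_value(tp, gr$head$Y),
                     Y_hat = ad_value(tp, gr$head$Y_hat),
                     Y_effect = ad_value(tp, gr$head$Y_effect)),
       attention = ad_value(tp, gr$gca_oct$attn))
}

#' Encode both modalities with the shared encoder
#'
#' @inheritParams net_forward
#' @return List of two feature pyramids (four maps each, strides 4/8/16/32).
#' @export
encode <- function(model, oct, uwf) {
  if (!all(dim(oct) == dim(uwf))) stopf("encode: input shape mismatch")
  gr <- net_graph(model, oct, uwf, n_samples = 1L)
  tp <- gr$tape
  list(oct = lapply(gr$pyr_oct, function(i) ad_value(tp, i)),
       uwf = lapply(gr$pyr_uwf, function(i) ad_value(tp, i)))
}

#' Global-context attention fusion of a feature pyramid
#'
#' Aligns all levels to the stride-4 grid, reweights channels by a pooled
#' global context through a learnable bottleneck, fuses by elementwise
#' multiplication plus residual addition, and passes the result through four
#' parallel dilated 3x3 branches (d = 1, 2, 5, 7) summed onto the fused map.
#'
#' @param model Model object.
#' @param pyramid List of four feature maps (as from [encode()]).
#' @return List `fused` (stride-4 map) and `attn` (spatial softmax map).
#' @export
gca_fuse <- function(model, pyramid) {
  if (length(pyramid) != 4L) stopf("gca_fuse: need a complete 4-level pyramid")
  tp <- tape_new(model$params)
  ids <- lapply(pyramid, function(x) ad_const(tp, x))
  g <- g_gca(tp, ids, model$config)
  list(fused = ad_value(tp, g$fused), attn = ad_value(tp, g$attn))
}

#' Decode fused features to segmentation logits
#'
#' Four upsample + concat + conv stages over the OCT skip pyramid, restoring
#' the input resolution with `n_classes` channels.
#'
#' @param model Model object.
#' @param fused Stride-4 fused map from [gca_fuse()].
#' @param skips OCT feature pyramid from [encode()].
#' @param input Optional raw network input feeding the full-resolution
#'   detail skip (zeros when omitted).
#' @return Input-resolution logits with `n_classes` channels.
#' @export
decode <- function(model, fused, skips, input = NULL) {
  tp <- tape_new(model$params)
  f <- ad_const(tp, fused)
  ids <- lapply(skips, function(x) ad_const(tp, x))
  if (is.null(input)) {
    side <- dim(fused)[1] * 4L
    input <- array(0, c(side, side, 3L))
  }
  ad_value(tp, g_decoder(tp, f, ids, ad_const(tp, input)))
}

# ---- cost accounting --------------------------------------------------------

#' Token-mixing cost model
#'
#' Multiply-accumulate counts for one WKV mixing pass over T tokens with C
#' channels (linear in T) and for a reference quadratic self-attention
#' (T^2-scaled), used to verify the linear-complexity claim.
#'
#' @param T Token count.
#' @param C Channels.
#' @return Named vector of MAC counts.
#' @export
token_mixing_flops <- function(T, C) {
  c(biwkv = 8 * T * C,            # two stabilized scans + combination
    quadratic_attention = 2 * T^2 * C)
}

#' Save / load a model as a single RDS-free text bundle
#'
#' Weights are serialized to JSON (names, dims, values); adequate for the
#' model sizes this package trains and fully text-based.
#'
#' @param model Model object.
#' @param path File path.
#' @name checkpoint
#' @export
save_model <- function(model, path) {
  obj <- list(config = model$config,
              params = lapply(model$params, function(x)
                list(dim = dim_of(x), val = as.numeric(x))))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname checkpoint
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- obj$config
  cfg$widths <- as.integer(cfg$widths)
  p <- lapply(obj$params, function(e) {
    d <- as.integer(e$dim)
    if (length(d) > 1L) array(e$val, d) else as.numeric(e$val)
  })
  structure(list(params = p, config = cfg), class = "dmerwkv_model")
}

#' Receptive-field arithmetic for the dilated fusion branches
#'
#' Extent (in pixels) covered by 3x3 convolutions with the given dilation
#' rates: `2 * sum(d) + 1` when composed sequentially, `2 * max(d) + 1` for
#' the parallel arrangement used inside the fusion module.
#'
#' @param dilations Dilation rates (default c(1, 2, 5, 7)).
#' @param mode "stacked" or "parallel".
#' @return Extent in pixels.
#' @export
dilated_receptive_field <- function(dilations = c(1L, 2L, 5L, 7L),
                                    mode = c("stacked", "parallel")) {
  mode <- match.arg(mode)
  if (mode == "stacked") 2L * sum(dilations) + 1L else 2L * max(dilations) + 1L
}
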