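# Encoder blocks, token mixing, fusion, decoder, causal-attention head.

test_that("HPA block is a residual gate with sub-quadratic parameter count", {
  set.seed(1)
  x <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  p <- hpa_init(8, seed = 2)
  y <- hpa_block(x, p)
  expect_equal(dim(y), dim(x))
  # zero weights -> exact residual identity
  p0 <- p
  p0$dw[] <- 0; p0$pw.w[] <- 0; p0$dwb[] <- 0; p0$pw.b[] <- 0
  expect_identical(hpa_block(x, p0), x)
  pc <- hpa_param_count(64L)
  expect_lt(pc["hpa"], pc["dense3x3"])
  expect_equal(unname(pc["hpa"]), 9 * 64 + 64 + 64^2 + 64)
})

test_that("sq_shift moves channel quarters to their four neighbours", {
  x <- array(0, c(3, 3, 4)); x[2, 2, ] <- 1
  y <- sq_shift(x)
  expect_equal(which(y[, , 1] == 1, arr.ind = TRUE), cbind(row = 1L, col = 2L))
  expect_equal(which(y[, , 2] == 1, arr.ind = TRUE), cbind(row = 3L, col = 2L))
  expect_equal(which(y[, , 3] == 1, arr.ind = TRUE), cbind(row = 2L, col = 1L))
  expect_equal(which(y[, , 4] == 1, arr.ind = TRUE), cbind(row = 2L, col = 3L))
  # 1x1 grid: every shift falls off the edge
  expect_true(all(sq_shift(array(rnorm(4), c(1, 1, 4))) == 0))
  # double application composes to a two-pixel shift
  x2 <- array(0, c(5, 5, 4)); x2[3, 3, ] <- 1
  y2 <- sq_shift(sq_shift(x2))
  expect_equal(which(y2[, , 1] == 1, arr.ind = TRUE), cbind(row = 1L, col = 3L))
  expect_equal(which(y2[, , 4] == 1, arr.ind = TRUE), cbind(row = 3L, col = 5L))
  expect_error(sq_shift(array(0, c(3, 3, 5))), "divisible by 4")
})

test_that("bi_wkv scan matches the naive double sum and its limits", {
  set.seed(10)
  for (r in 1:30) {
    T <- sample(1:64, 1); C <- sample(1:6, 1)
    k <- matrix(rnorm(T * C), T, C); v <- matrix(rnorm(T * C), T, C)
    w <- runif(C, 0, 3); u <- rnorm(C)
    expect_lt(max(abs(bi_wkv(k, v, w, u) - oracle_biwkv(k, v, w, u))), 1e-5)
  }
  # T = 1: only the bonus term survives
  v1 <- matrix(c(2, -3), 1, 2)
  expect_equal(bi_wkv(matrix(0.2, 1, 2), v1, c(1, 1), c(0, 0)), v1)
  # strong decay kills all cross terms (positions collapse to v_t)
  T <- 16
  k <- matrix(0, T, 1); v <- matrix(rnorm(T), T, 1)
  # the distance-minus-one decay leaves immediate neighbours untouched, so
  # the collapse to v_t additionally needs the self bonus to dominate
  out <- bi_wkv(k, v, w = 50 * T, u = 12)
  expect_lt(max(abs(out - v)), 1e-3)
  expect_error(bi_wkv(matrix(NA_real_, 2, 1), matrix(0, 2, 1), 1, 1),
               "non-finite")
})

test_that("token-mixing cost is linear in tokens; quadratic reference is not", {
  f1 <- token_mixing_flops(256, 32); f2 <- token_mixing_flops(1024, 32)
  slope <- log(f2 / f1) / log(4)
  expect_equal(unname(slope["biwkv"]), 1, tolerance = 1e-12)
  expect_equal(unname(slope["quadratic_attention"]), 2, tolerance = 1e-12)
})

test_that("shared encoder yields identical pyramids at strides 4/8/16/32", {
  m <- tiny_model(1)
  x <- rand_input(3)
  enc <- encode(m, x, x)
  expect_identical(enc$oct, enc$uwf)
  expect_equal(vapply(enc$oct, function(p) dim(p)[1], 1L),
               c(16L, 8L, 4L, 2L))
  expect_equal(vapply(enc$oct, function(p) dim(p)[3], 1L),
               m$config$widths)
  expect_error(encode(m, x, rand_input(4, 32)), "mismatch")
})

test_that("global-context fusion contracts hold", {
  m <- tiny_model(2)
  x <- rand_input(5)
  pyr <- encode(m, x, x)$oct
  fz <- gca_fuse(m, pyr)
  expect_equal(dim(fz$fused)[1:2], c(16L, 16L))
  expect_equal(sum(fz$attn), 1, tolerance = 1e-9)
  expect_error(gca_fuse(m, pyr[1:3]), "4-level")
  # context weights forced to 1 and dilated branches zeroed:
  # output collapses to the aligned residual sum (here 2 * S)
  m1 <- m
  m1$params[["gca.a2b"]][] <- 1e4      # sigmoid -> 1
  for (i in 1:4) {
    m1$params[[sprintf("gca.d%d.w", i)]][] <- 0
    m1$params[[sprintf("gca.d%d.b", i)]][] <- 0
  }
  f1 <- gca_fuse(m1, pyr)$fused
  aligned <- Reduce(`+`, lapply(1:4, function(i) {
    wd <- dim(m$params[[sprintf("gca.p%d.w", i)]])
    a <- dmerwkv:::cpp_conv2d_fw(pyr[[i]],
      matrix(m$params[[sprintf("gca.p%d.w", i)]], wd[3], wd[4]),
      m$params[[sprintf("gca.p%d.b", i)]], 1L, 0L, 1L, 1L)
    while (dim(a)[1] < 16) a <- dmerwkv:::cpp_upnn_fw(a)
    a
  }))
  expect_equal(f1, 2 * aligned, tolerance = 1e-8)
  # receptive-field arithmetic of the dilated set
  expect_equal(dilated_receptive_field(c(1, 2, 5, 7), "stacked"), 31L)
})

test_that("decoder restores input resolution with 4 class channels", {
  m <- tiny_model(3)
  x <- rand_input(6)
  pyr <- encode(m, x, x)$oct
  fz <- gca_fuse(m, pyr)
  seg <- decode(m, fz$fused, pyr, input = x)
  expect_equal(dim(seg), c(64L, 64L, 4L))
  # constant features -> spatially constant logits
  pyr0 <- lapply(pyr, function(p) array(0.3, dim(p)))
  seg0 <- decode(m, array(0.2, dim(fz$fused)), pyr0,
                 input = array(0.1, dim(x)))
  expect_lt(max(apply(seg0, 3, function(s) diff(range(s)))), 1e-9)
})

test_that("attention intervention is seeded, shaped, and mean-uniform", {
  A <- matrix(runif(64), 8, 8); A <- A / sum(A)
  expect_identical(cal_intervene(A, seed = 4), cal_intervene(A, seed = 4))
  expect_false(identical(cal_intervene(A, seed = 4), cal_intervene(A, seed = 5)))
  b <- cal_intervene(A, seed = 4)
  expect_equal(dim(b), dim(A))
  expect_equal(sum(b), 1, tolerance = 1e-12)
  # per-position mean over many draws approaches the uniform value 1/N
  draws <- vapply(1:2000, function(s) cal_intervene(A, seed = s)[1, 1], 1)
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 1 / 64), 3 * se)
})

test_that("causal effect honours its contracts", {
  set.seed(8)
  X <- rnorm(6)
  A <- matrix(runif(36), 6, 6); A <- A / sum(A)
  # head ignoring attention -> zero effect -> uniform probabilities
  h0 <- function(X, A) c(sum(X), -sum(X))
  ce <- causal_effect(X, A, h0, n_samples = 8, seed = 2)
  expect_equal(ce$Y_effect, c(0.5, 0.5), tolerance = 1e-12)
  # linear head: mean intervention equals the uniform map exactly
  W1 <- matrix(rnorm(36), 6, 6); W2 <- matrix(rnorm(36), 6, 6)
  hl <- function(X, A) c(sum(W1 * A), sum(W2 * A))
  ce2 <- causal_effect(X, A, hl, n_samples = 10000, seed = 3)
  closed <- {
    yh <- c(sum(W1) / 36, sum(W2) / 36)
    d <- hl(X, A) - yh
    exp(d - max(d)) / sum(exp(d - max(d)))
  }
  expect_equal(ce2$Y_effect, closed, tolerance = 0.02)
  expect_equal(sum(ce2$Y_effect), 1, tolerance = 1e-9)
  expect_identical(causal_effect(X, A, hl, 16, seed = 9),
                   causal_effect(X, A, hl, 16, seed = 9))
  expect_error(causal_effect(X, A, hl, 0, seed = 1), "n_samples")
})

test_that("full forward is deterministic with valid output ranges", {
  m <- tiny_model(4)
  oct <- rand_input(11); uwf <- rand_input(12)
  f1 <- net_forward(m, oct, uwf, seed = 3)
  f2 <- net_forward(m, oct, uwf, seed = 3)
  expect_identical(f1, f2)
  expect_equal(dim(f1$seg), c(64L, 64L, 4L))
  expect_true(all(f1$effect$Y_effect >= 0 & f1$effect$Y_effect <= 1))
  expect_equal(sum(f1$effect$Y_effect), 1, tolerance = 1e-9)
  # single-modality configuration still yields valid shapes
  f3 <- net_forward(m, oct, uwf = NULL, seed = 3)
  expect_equal(dim(f3$seg), dim(f1$seg))
  expect_equal(sum(f3$attention), 1, tolerance = 1e-9)
})

test_that("every trainable parameter receives gradient on a random batch", {
  m <- tiny_model(5)
  withr::with_seed(31, {
    masks <- list(ERM = matrix(0L, 64, 64), IRC = matrix(0L, 64, 64),
                  SRF = matrix(0L, 64, 64))
    masks$IRC[20:28, 12:30] <- 1L
    masks$ERM[10, 5:40] <- 1L
    masks$SRF[40:45, 20:44] <- 1L
    smp <- list(oct = rand_input(13), uwf = rand_input(14), masks = masks,
                label = TRUE)
  })
  sg <- dmerwkv:::sample_grads(m, smp, loss_weights(), 2, seed = 7)
  mx <- vapply(sg$grads, function(g) max(abs(g)), 1)
  expect_true(all(mx > 0), info = paste(names(mx)[mx == 0], collapse = ", "))
})

test_that("analytic gradients agree with central differences", {
  m <- tiny_model(6)
  withr::with_seed(77, {
    masks <- list(ERM = matrix(0L, 64, 64), IRC = matrix(0L, 64, 64),
                  SRF = matrix(0L, 64, 64))
    masks$IRC[30:36, 30:40] <- 1L
    smp <- list(oct = rand_input(15), uwf = rand_input(16), masks = masks,
                label = FALSE)
  })
  w <- loss_weights()
  lossfun <- function(model) {
    gr <- dmerwkv:::net_graph(model, smp$oct, smp$uwf, n_samples = 2,
                              seed = 5)
    cl <- dmerwkv:::g_composite(gr$tape, gr$seg, gr$head, smp$masks,
                                smp$label, w)
    dmerwkv:::ad_value(gr$tape, cl$total)
  }
  sg <- dmerwkv:::sample_grads(m, smp, w, 2, seed = 5)
  for (pn in c("stem2.w", "enc1.dw", "enc3.decay", "enc4.bonus", "gca.a1",
               "gca.d2.w", "dec.c1.w", "head.l1", "stem0.w")) {
    idx <- 3L
    eps <- 1e-5
    m1 <- m; m1$params[[pn]][idx] <- m1$params[[pn]][idx] + eps
    m2 <- m; m2$params[[pn]][idx] <- m2$params[[pn]][idx] - eps
    num <- (lossfun(m1) - lossfun(m2)) / (2 * eps)
    ana <- sg$grads[[pn]][idx]
    expect_equal(ana, num, tolerance = 1e-4,
                 info = paste("gradient of", pn))
  }
})

test_that("checkpoint JSON round-trips to an identical forward pass", {
  m <- tiny_model(7)
  d <- withr::local_tempdir()
  save_model(m, file.path(d, "ckpt.json"))
  m2 <- load_model(file.path(d, "ckpt.json"))
  x <- rand_input(21)
  expect_equal(net_forward(m, x, x, seed = 2), net_forward(m2, x, x, seed = 2),
               tolerance = 1e-12)
  expect_equal(count_params(m2), count_params(m))
})
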