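# Component filtering, slim-region top-hat, GC loss, composite objective.

test_that("component filtering keeps instances by area and connectivity", {
  M <- matrix(0L, 20, 20)
  M[2:4, 2] <- 1L                 # area 3
  M[8:17, 5:9] <- 1L              # area 50
  inst <- filter_components(M, min_area = 10, max_area = 10000)
  expect_equal(max(inst), 1L)
  expect_equal(sum(inst > 0), 50)
  # the "outside" reading inverts the selection
  inst2 <- filter_components(M, min_area = 10, max_area = 10000,
                             keep = "outside")
  expect_equal(sum(inst2 > 0), 3)
  expect_equal(max(filter_components(matrix(0L, 5, 5))), 0L)
  expect_equal(max(filter_components(matrix(1L, 5, 5), max_area = 100)), 1L)
  expect_error(filter_components(M, min_area = 10, max_area = 5), "min_area")
  expect_error(filter_components(matrix(2L, 3, 3)), "binary")
  # diagonal pair: one component under 8-connectivity, two under 4
  D <- matrix(0L, 4, 4); D[1, 1] <- 1L; D[2, 2] <- 1L
  expect_equal(max(filter_components(D, connectivity = 8, min_area = 1)), 1L)
  expect_equal(max(filter_components(D, connectivity = 4, min_area = 1)), 2L)
})

test_that("component labelling agrees with an established labeller", {
  set.seed(12)
  for (i in 1:20) {
    M <- matrix(rbinom(400, 1, 0.35), 20, 20)
    ours <- filter_components(M, connectivity = 4, min_area = 1,
                              max_area = 1e6)
    ref <- EBImage::bwlabel(M)      # 4-connectivity reference
    expect_equal(max(ours), max(ref))
    # identical partitions up to label permutation
    expect_equal(length(unique(paste(ours, ref))), max(ref) + 1L)
  }
})

test_that("slim region equals the white top-hat with replicate borders", {
  # 1-px line thinner than s survives whole
  L <- matrix(0, 30, 30); L[15, 4:23] <- 1
  expect_equal(extract_slim_region(L, 5)$SR, oracle_open_tophat(L, 5))
  expect_equal(extract_slim_region(L, 5)$SR, L)
  # all-ones mask: opening is the identity, top-hat vanishes
  expect_true(all(extract_slim_region(matrix(1, 10, 10), 5)$SR == 0))
  # 4x4 block is erased by s = 5 opening (SR == M); 6x6 keeps its core
  B4 <- matrix(0, 16, 16); B4[6:9, 6:9] <- 1
  expect_equal(extract_slim_region(B4, 5)$SR, B4)
  B6 <- matrix(0, 16, 16); B6[6:11, 6:11] <- 1
  sr6 <- extract_slim_region(B6, 5)$SR
  expect_true(all(sr6[8:9, 8:9] == 0))
  expect_equal(sr6, oracle_open_tophat(B6, 5))
  expect_error(extract_slim_region(L, 4), "odd")
})

test_that("slim region matches the opening oracle on random soft masks", {
  set.seed(5)
  for (i in 1:50) {
    M <- matrix(runif(32 * 32), 32, 32)
    for (s in c(3L, 5L, 7L)) {
      sr <- extract_slim_region(M, s)$SR
      expect_lt(max(abs(sr - oracle_open_tophat(M, s))), 1e-12)
      expect_true(all(sr >= 0 & sr <= M + 1e-12))
    }
  }
})

test_that("gc loss is zero at agreement and bounded in [0, 1]", {
  set.seed(9)
  L <- matrix(0, 40, 40); L[20, 5:36] <- 1
  expect_lt(gc_loss(L, L), 1e-6)
  expect_lt(gc_loss(matrix(0, 20, 20), matrix(0, 20, 20)), 1e-6)
  for (i in 1:25) {
    P <- matrix(runif(30 * 30), 30, 30)
    G <- matrix(rbinom(900, 1, 0.3), 30, 30)
    l <- gc_loss(P, G)
    expect_gte(l, 0); expect_lte(l, 1)
  }
  expect_error(gc_loss(matrix(0.5, 3, 3), matrix(0L, 4, 4)), "mismatch")
})

test_that("gc loss grows monotonically with the gap in a thin line", {
  G <- matrix(0, 40, 40); G[20, 3:38] <- 1
  base <- gc_loss(G, G)
  prev <- base
  for (gap in 1:7) {
    P <- G
    P[20, 19:(18 + gap)] <- 0
    l <- gc_loss(P, G)
    expect_gt(l, base)
    expect_gte(l, prev - 1e-12)
    prev <- l
  }
})

test_that("gc loss backpropagates nonzero gradients to skeleton pixels", {
  G <- matrix(0, 32, 32); G[16, 4:28] <- 1
  P <- G * 0.9
  gr <- gc_loss_grad(P, G)
  on_line <- gr[16, 4:28]
  expect_true(any(abs(on_line) > 0))
  expect_true(all(is.finite(gr)))
  # l1 variant is also differentiable
  gr2 <- gc_loss_grad(P, G, metric = "l1")
  expect_true(any(abs(gr2) > 0))
})

test_that("composite objective decomposes and degenerates as configured", {
  masks <- list(ERM = matrix(0L, 32, 32), IRC = matrix(0L, 32, 32),
                SRF = matrix(0L, 32, 32))
  masks$IRC[10:16, 8:20] <- 1L
  masks$ERM[5, 4:28] <- 1L
  tgt <- dmerwkv:::onehot_masks(masks)
  # near-perfect logits and a confidently correct label
  seg <- (tgt * 2 - 1) * 25
  pred <- list(Y_effect = c(0.0005, 0.9995))
  out <- composite_loss(seg, masks, pred, label = TRUE)
  expect_lt(out$total, 5e-3)
  expect_named(out$breakdown, c("dice", "bce", "cls", "gc"))
  # lambda_gc = 0 reduces to the Dice + BCE + CE configuration
  w0 <- loss_weights(gc = 0)
  out0 <- composite_loss(seg, masks, pred, TRUE, w0)
  expect_equal(out0$total,
               sum(out0$breakdown[c("dice", "bce", "cls")]),
               tolerance = 1e-12)
  expect_equal(out0$breakdown[["gc"]], 0)
  # clDice substitute produces a finite, different topology term
  wc <- loss_weights(use_cldice = TRUE)
  outc <- composite_loss(seg + rnorm(length(seg)), masks, pred, TRUE, wc)
  expect_true(is.finite(outc$total))
})
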