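# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's computational paths (pooling kernels, scans) so the
# tests compare two independent routes to the same quantity.

# Grayscale erosion/dilation with a flat s x s element and replicate borders,
# built from shifted copies with clamped indices.
shift_clamped <- function(M, di, dj) {
  H <- nrow(M); W <- ncol(M)
  M[pmin(pmax(seq_len(H) + di, 1L), H), pmin(pmax(seq_len(W) + dj, 1L), W)]
}

oracle_open_tophat <- function(M, s) {
  r <- (s - 1L) %/% 2L
  offs <- expand.grid(di = -r:r, dj = -r:r)
  er <- Reduce(pmin, Map(function(di, dj) shift_clamped(M, di, dj),
                         offs$di, offs$dj))
  dl <- Reduce(pmax, Map(function(di, dj) shift_clamped(er, di, dj),
                         offs$di, offs$dj))
  pmax(M - dl, 0)
}

# Naive O(T^2) bidirectional WKV by direct summation of the weight definition.
oracle_biwkv <- function(k, v, w, u) {
  T <- nrow(k); C <- ncol(k)
  out <- matrix(0, T, C)
  for (c in seq_len(C)) for (t in seq_len(T)) {
    lw <- vapply(seq_len(T), function(i) {
      if (i == t) u[c] + k[t, c]
      else -(abs(t - i) - 1) / T * w[c] + k[i, c]
    }, 1)
    wt <- exp(lw - max(lw))
    out[t, c] <- sum(wt * v[, c]) / sum(wt)
  }
  out
}

# Exhaustive Mann-Whitney AUC by pair counting.
oracle_auc <- function(scores, labels) {
  sp <- scores[labels]; sn <- scores[!labels]
  mean(outer(sp, sn, ">") + 0.5 * outer(sp, sn, "=="))
}

# All-pairs surface distances for hd95. Boundary = 4-neighbourhood inner
# boundary with the outside counting as background (same convention as the
# implementation; the independent part is the distance computation).
oracle_hd95 <- function(P, G) {
  bd <- function(M) {
    H <- nrow(M); W <- ncol(M)
    pad <- matrix(0L, H + 2L, W + 2L)
    pad[2:(H + 1L), 2:(W + 1L)] <- M
    core <- pad[2:(H + 1L), 2:(W + 1L)] &
      pad[1:H, 2:(W + 1L)] & pad[3:(H + 2L), 2:(W + 1L)] &
      pad[2:(H + 1L), 1:W] & pad[2:(H + 1L), 3:(W + 2L)]
    which(M == 1 & !core, arr.ind = TRUE)
  }
  bp <- bd(P); bg <- bd(G)
  dmat <- sqrt(outer(bp[, 1], bg[, 1], "-")^2 + outer(bp[, 2], bg[, 2], "-")^2)
  stats::quantile(c(apply(dmat, 1, min), apply(dmat, 2, min)), 0.95,
                  names = FALSE)
}

# A small single-eye cohort for split tests.
toy_records <- function(n, seed = 1, two_eye = 0L) {
  withr::with_seed(seed, {
    pid <- sprintf("T%03d", seq_len(n))
    eyes <- c(pid, if (two_eye > 0) pid[seq_len(two_eye)])
    data.frame(patient_id = eyes,
               eye_id = paste0(eyes, ifelse(duplicated(eyes), "_OS", "_OD")),
               responder = runif(length(eyes)) < 0.4,
               stringsAsFactors = FALSE)
  })
}

# Tiny model shared by network tests (built once per file load).
tiny_model <- function(seed = 1, ...) {
  model_init(model_config(widths = c(8L, 12L, 16L, 20L), input_size = 64L,
                          n_samples = 2L, head_hidden = 16L, ...),
             seed = seed)
}

rand_input <- function(seed, side = 64L) {
  withr::with_seed(seed, array(rnorm(side * side * 3), c(side, side, 3L)))
}

# Synthetic single-lesion sample with controllable area/contrast/noise.
make_lesion_sample <- function(id, area_px, contrast, noise = 0.01,
                               side = 48L, seed = 1L) {
  withr::with_seed(seed, {
    img <- matrix(0.6, side, side)
    masks <- list(ERM = matrix(0L, side, side), IRC = matrix(0L, side, side),
                  SRF = matrix(0L, side, side))
    r <- max(1L, round(sqrt(area_px) / 2))
    c0 <- side %/% 2
    masks$IRC[(c0 - r):(c0 + r), (c0 - r):(c0 + r)] <- 1L
    img[masks$IRC == 1L] <- 0.6 - contrast
    img <- img + matrix(rnorm(side^2, 0, noise), side)
    list(id = id, image = img, masks = masks)
  })
}
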