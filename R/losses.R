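# The global-completion (GC) topology loss and the composite training
# objective. The GC loss runs in three steps: connected-component filtering of
# the masks, extraction of a thin central "slim region" skeleton by a
# differentiable min/max-pool top-hat, and a soft-Dice difference between the
# prediction and ground-truth skeletons.

#' Connected-component filtering of a binary mask
#'
#' Labels connected components (4- or 8-connectivity) and keeps those whose
#' pixel area lies in `[min_area, max_area]`; everything else is zeroed.
#' Retained instances are relabelled 1..N in scan order.
#'
#' @param M Binary matrix.
#' @param connectivity 4 or 8.
#' @param min_area,max_area Area bounds in pixels.
#' @param keep "inside" (default) keeps components within the bounds;
#'   "outside" inverts the selection (both readings of size-based isolation
#'   are available).
#' @return Integer instance matrix (0 = background).
#' @export
filter_components <- function(M, connectivity = 8L, min_area = 5L,
                              max_area = 2000L, keep = c("inside", "outside")) {
  keep <- match.arg(keep)
  if (min_area > max_area) stopf("min_area (%d) > max_area (%d)",
                                 min_area, max_area)
  if (!all(M %in% c(0, 1))) stopf("filter_components: mask must be binary")
  lab <- cpp_label_components(matrix(as.integer(M != 0), nrow(M)),
                              as.integer(connectivity))
  if (max(lab) == 0L) return(lab)
  areas <- tabulate(lab[lab > 0L], nbins = max(lab))
  ok <- areas >= min_area & areas <= max_area
  if (keep == "outside") ok <- !ok
  remap <- integer(max(lab))
  remap[ok] <- seq_len(sum(ok))
  out <- matrix(0L, nrow(M), ncol(M))
  out[lab > 0L] <- remap[lab[lab > 0L]]
  out
}

#' Extract the slim region (skeleton) of a mask
#'
#' `SR = ReLU(M - maxpool(minpool(M, s), s))` with stride-1 pooling and
#' replicate padding: on binary masks this is the white top-hat under an s x s
#' flat structuring element, which keeps exactly the structures thinner than s
#' (the central topological line of elongated lesions). For soft masks the
#' operation is differentiable.
#'
#' @param M Matrix in [0, 1].
#' @param s Odd pooling kernel size >= 3 (default 5).
#' @return List: `SR` (same-shape matrix, `0 <= SR <= M`), `s`.
#' @export
extract_slim_region <- function(M, s = 5L) {
  if (s %% 2L == 0L || s < 3L) stopf("kernel size s must be odd and >= 3")
  x <- array(M, c(nrow(M), ncol(M), 1L))
  er <- cpp_pool_fw(x, s, FALSE)$y
  op <- cpp_pool_fw(er, s, TRUE)$y
  sr <- pmax(M - op[, , 1], 0)
  list(SR = sr, s = s)
}

# Tape version: returns a node for relu(P - open(P)) with the gate premixed.
g_slim <- function(tp, p, s) {
  er <- ad_pool(tp, p, s, "min")
  op <- ad_pool(tp, er, s, "max")
  ad_relu(tp, ad_sub(tp, p, op))
}

gc_gate <- function(P, G, connectivity, min_area, max_area) {
  gG <- filter_components(G, connectivity, min_area, max_area) > 0L
  gP <- filter_components((P >= 0.5) * 1, connectivity, min_area,
                          max_area) > 0L
  list(gate_p = (gG | gP) * 1, gate_g = gG * 1)
}

# Loss node on the tape; `p` is an (H, W, 1) probability map node.
g_gc_loss <- function(tp, p, G, s = 5L, connectivity = 8L, min_area = 5L,
                      max_area = 2000L, eps = 1e-6, metric = "dice") {
  gt <- gc_gate(ad_value(tp, p)[, , 1], G, connectivity, min_area, max_area)
  d <- dim_of(ad_value(tp, p))
  pf <- ad_mul(tp, p, ad_const(tp, array(gt$gate_p, d)))
  gf <- ad_const(tp, array(G * gt$gate_g, d))
  srp <- g_slim(tp, pf, s)
  srg <- g_slim(tp, gf, s)
  if (metric == "l1") {
    return(ad_mean(tp, ad_abs(tp, ad_sub(tp, srp, srg))))
  }
  num <- ad_addc(tp, ad_smul(tp, ad_mulsum(tp, srp, srg), 2), eps)
  den <- ad_addc(tp, ad_add(tp, ad_sum(tp, srp), ad_sum(tp, srg)), eps)
  ad_addc(tp, ad_smul(tp, ad_div(tp, num, den), -1), 1)
}

#' Global-completion (GC) topology loss
#'
#' Soft-Dice difference between the slim-region skeletons of a predicted
#' probability mask and a binary ground truth, after connected-component
#' filtering (on the ground truth, and on the prediction thresholded at 0.5
#' for instance gating). Zero iff the skeletons agree; bounded in [0, 1];
#' differentiable in `P` (see `gc_loss_grad`).
#'
#' @param P Soft prediction in [0, 1], same shape as `G`.
#' @param G Binary ground-truth mask.
#' @param s Top-hat kernel size (odd, default 5).
#' @param connectivity,min_area,max_area Component filter, see
#'   [filter_components()].
#' @param eps Stabilizer.
#' @param metric "dice" (default) or "l1" skeleton difference.
#' @return Nonnegative scalar.
#' @export
gc_loss <- function(P, G, s = 5L, connectivity = 8L, min_area = 5L,
                    max_area = 2000L, eps = 1e-6, metric = "dice") {
  if (!all(dim(P) == dim(G))) stopf("gc_loss: shape mismatch")
  if (min(P) < 0 || max(P) > 1) stopf("gc_loss: P must lie in [0, 1]")
  tp <- tape_new(list())
  p <- ad_const(tp, array(P, c(nrow(P), ncol(P), 1L)))
  ad_value(tp, g_gc_loss(tp, p, G, s, connectivity, min_area, max_area,
                         eps, metric))
}

#' @rdname gc_loss
#' @return `gc_loss_grad`: the gradient of the loss with respect to `P`.
#' @export
gc_loss_grad <- function(P, G, s = 5L, connectivity = 8L, min_area = 5L,
                         max_area = 2000L, eps = 1e-6, metric = "dice") {
  tp <- tape_new(list(P = array(P, c(nrow(P), ncol(P), 1L))))
  p <- ad_param(tp, "P")
  l <- g_gc_loss(tp, p, G, s, connectivity, min_area, max_area, eps, metric)
  g <- ad_backward(tp, l)$P
  matrix(g, nrow(P), ncol(P))
}

# ---- segmentation + prediction objective ------------------------------------

#' Default loss weights
#' @export
loss_weights <- function(dice = 1, bce = 1, cls = 1, gc = 0.5,
                         gc_s = 5L, use_cldice = FALSE) {
  list(dice = dice, bce = bce, cls = cls, gc = gc, gc_s = as.integer(gc_s),
       use_cldice = use_cldice)
}

# one-hot (H, W, K) target from a lesion mask set; channel 1 = background
onehot_masks <- function(masks, n_classes = 4L) {
  d <- dim(masks$ERM)
  t <- array(0, c(d, n_classes))
  t[, , 2] <- masks$ERM
  t[, , 3] <- masks$IRC
  t[, , 4] <- masks$SRF
  t[, , 1] <- pmax(1 - pmax(pmax(t[, , 2], t[, , 3]), t[, , 4]), 0)
  t
}

# Soft clDice: optional comparison loss sharing the same skeleton extractor.
g_cldice <- function(tp, probs_ch, G, s, eps = 1e-6) {
  d <- dim_of(ad_value(tp, probs_ch))
  gf <- ad_const(tp, array(G, d))
  srp <- g_slim(tp, probs_ch, s)
  srg <- g_slim(tp, gf, s)
  tprec <- ad_div(tp, ad_addc(tp, ad_mulsum(tp, srp, gf), eps),
                  ad_addc(tp, ad_sum(tp, srp), eps))
  tsens <- ad_div(tp, ad_addc(tp, ad_mulsum(tp, srg, probs_ch), eps),
                  ad_addc(tp, ad_sum(tp, srg), eps))
  num <- ad_smul(tp, ad_mul(tp, tprec, tsens), 2)
  den <- ad_add(tp, tprec, tsens)
  ad_addc(tp, ad_smul(tp, ad_div(tp, num, den), -1), 1)
}

# Full objective on the tape; returns the total node plus per-term values.
g_composite <- function(tp, seg, head, masks, label, weights, eps = 1e-6,
                        gc_filter = list(connectivity = 8L, min_area = 5L,
                                         max_area = 2000L)) {
  n_cl <- dim_of(ad_value(tp, seg))[3]
  probs <- ad_softmax_ch(tp, seg)
  tgt <- onehot_masks(masks, n_cl)
  tnode <- ad_const(tp, tgt)
  # soft Dice over the lesion classes (background is covered by the BCE term)
  dice_terms <- lapply(seq.int(2L, n_cl), function(ci) {
    pc <- ad_slice_ch(tp, probs, ci)
    tc <- ad_const(tp, tgt[, , ci, drop = FALSE])
    num <- ad_addc(tp, ad_smul(tp, ad_mulsum(tp, pc, tc), 2), eps)
    den <- ad_addc(tp, ad_add(tp, ad_sum(tp, pc), ad_sum(tp, tc)), eps)
    ad_addc(tp, ad_smul(tp, ad_div(tp, num, den), -1), 1)
  })
  dice <- ad_smul(tp, Reduce(function(a, b) ad_add(tp, a, b), dice_terms),
                  1 / (n_cl - 1L))
  # BCE on the class probabilities
  one_m <- ad_addc(tp, ad_smul(tp, probs, -1), 1)
  one_t <- ad_const(tp, 1 - tgt)
  bce <- ad_smul(tp, ad_add(tp,
                            ad_mulsum(tp, tnode, ad_log(tp, probs, eps)),
                            ad_mulsum(tp, one_t, ad_log(tp, one_m, eps))),
                 -1 / length(tgt))
  # topology term averaged over lesion classes
  lesions <- list(masks$ERM, masks$IRC, masks$SRF)
  topo <- NULL
  if (weights$gc > 0) {
    terms <- lapply(seq_along(lesions), function(i) {
      pc <- ad_slice_ch(tp, probs, i + 1L)
      if (isTRUE(weights$use_cldice))
        g_cldice(tp, pc, lesions[[i]], weights$gc_s, eps)
      else
        g_gc_loss(tp, pc, lesions[[i]], s = weights$gc_s,
                  connectivity = gc_filter$connectivity,
                  min_area = gc_filter$min_area,
                  max_area = gc_filter$max_area, eps = eps)
    })
    topo <- ad_smul(tp, Reduce(function(a, b) ad_add(tp, a, b), terms),
                    1 / length(terms))
  }
  # responder cross-entropy on the causal-effect probabilities
  yeff <- head$Y_effect
  idx <- if (isTRUE(label)) 2L else 1L
  pcls <- ad_node(tp, ad_value(tp, yeff)[idx], yeff, function(g) {
    gv <- numeric(2); gv[idx] <- g; list(gv)
  })
  cls <- ad_smul(tp, ad_log(tp, pcls, eps), -1)

  total <- ad_smul(tp, dice, weights$dice)
  total <- ad_add(tp, total, ad_smul(tp, bce, weights$bce))
  total <- ad_add(tp, total, ad_smul(tp, cls, weights$cls))
  if (!is.null(topo)) total <- ad_add(tp, total, ad_smul(tp, topo, weights$gc))
  list(total = total,
       breakdown = c(dice = ad_value(tp, dice), bce = ad_value(tp, bce),
                     cls = ad_value(tp, cls),
                     gc = if (is.null(topo)) 0 else ad_value(tp, topo)))
}

#' Composite training objective (evaluation form)
#'
#' `lambda_dice * softDice + lambda_bce * BCE + lambda_gc * GC (mean over
#' lesion classes) + lambda_cls * cross-entropy` on the responder
#' probabilities. Returns the total and the per-term breakdown. The same
#' objective (built on the autodiff tape) drives training.
#'
#' @param seg H x W x 4 segmentation logits.
#' @param masks Lesion mask set (list `ERM`, `IRC`, `SRF`).
#' @param pred Effect prediction list with `Y_effect` (probabilities).
#' @param label Responder label (logical).
#' @param weights See [loss_weights()].
#' @return List `total` and `breakdown`.
#' @export
composite_loss <- function(seg, masks, pred, label, weights = loss_weights()) {
  stopifnot(all(unlist(weights[c("dice", "bce", "cls", "gc")]) >= 0))
  tp <- tape_new(list())
  segn <- ad_const(tp, seg)
  yeff <- ad_const(tp, pred$Y_effect)
  cl <- g_composite(tp, segn, list(Y_effect = yeff), masks, label, weights)
  list(total = ad_value(tp, cl$total), breakdown = cl$breakdown)
}

#' Count continuity breaks along a thin ground-truth structure
#'
#' Number of connected components of `G & !P`: the disjoint segments of the
#' ground-truth line missed by the prediction. A topologically complete
#' prediction scores 0; fragmentation raises the count.
#'
#' @param P Predicted binary mask.
#' @param G Ground-truth binary mask (thin structure).
#' @param connectivity 4 or 8.
#' @return Integer break count.
#' @export
count_line_breaks <- function(P, G, connectivity = 8L) {
  miss <- (G != 0) & (P == 0)
  max(cpp_label_components(matrix(as.integer(miss), nrow(G)),
                           as.integer(connectivity)))
}
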