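# Adam trainer over the composite objective, with gradient accumulation over
# mini-batches. Samples are lists with preprocessed `oct` and `uwf` arrays, a
# lesion mask set `masks` at input resolution, and a responder `label`.

#' Trainer configuration
#'
#' @param epochs Training epochs.
#' @param batch_size Gradient-accumulation batch size.
#' @param lr Adam step size.
#' @param weights Loss weights, see [loss_weights()].
#' @param n_samples Attention interventions per forward pass.
#' @param cosine Apply cosine decay of the step size over epochs.
#' @param clip Global gradient-norm clip (0 disables).
#' @param seed Seed controlling shuffling and interventions.
#' @param verbose Emit per-epoch loss lines.
#' @return Config list.
#' @export
trainer_config <- function(epochs = 5L, batch_size = 4L, lr = 2e-3,
                           weights = loss_weights(), n_samples = 2L,
                           cosine = TRUE, clip = 1, seed = 1L,
                           verbose = FALSE) {
  list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       lr = lr, weights = weights, n_samples = as.integer(n_samples),
       cosine = cosine, clip = clip, seed = as.integer(seed),
       verbose = verbose)
}

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, st, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  for (n in names(params)) {
    g <- grads[[n]]
    if (is.null(g)) next
    st$m[[n]] <- b1 * st$m[[n]] + (1 - b1) * g
    st$v[[n]] <- b2 * st$v[[n]] + (1 - b2) * g * g
    mh <- st$m[[n]] / (1 - b1^st$t)
    vh <- st$v[[n]] / (1 - b2^st$t)
    params[[n]] <- params[[n]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = st)
}

# One sample's loss + parameter gradients.
sample_grads <- function(model, smp, weights, n_samples, seed) {
  gr <- net_graph(model, smp$oct, smp$uwf, n_samples = n_samples, seed = seed)
  cl <- g_composite(gr$tape, gr$seg, gr$head, smp$masks, smp$label, weights)
  list(grads = ad_backward(gr$tape, cl$total),
       loss = ad_value(gr$tape, cl$total), breakdown = cl$breakdown)
}

#' Train a model
#'
#' Plain (single-stage) Adam training of the full multitask objective.
#'
#' @param model Model from [model_init()].
#' @param samples List of training samples.
#' @param config See [trainer_config()].
#' @param state Optional Adam state to resume from.
#' @return List `model`, `trace` (per-epoch mean loss and term breakdown),
#'   `state`.
#' @export
train_model <- function(model, samples, config = trainer_config(),
                        state = NULL) {
  st <- if (is.null(state)) adam_new(model$params) else state
  trace <- list()
  n <- length(samples)
  for (ep in seq_len(config$epochs)) {
    lr <- if (config$cosine)
      config$lr * 0.5 * (1 + cos(pi * (ep - 1) / config$epochs))
    else config$lr
    ord <- with_seed(config$seed * 1000L + ep, sample.int(n))
    ep_loss <- c(); ep_bd <- NULL
    i <- 1L
    while (i <= n) {
      idx <- ord[i:min(n, i + config$batch_size - 1L)]
      acc <- NULL
      for (j in seq_along(idx)) {
        sg <- sample_grads(model, samples[[idx[j]]], config$weights,
                           config$n_samples,
                           seed = config$seed + ep * 7919L + idx[j])
        ep_loss <- c(ep_loss, sg$loss)
        ep_bd <- if (is.null(ep_bd)) sg$breakdown else ep_bd + sg$breakdown
        acc <- if (is.null(acc)) sg$grads
               else mapply(function(a, b) a + b, acc, sg$grads,
                           SIMPLIFY = FALSE)
      }
      acc <- lapply(acc, function(g) g / length(idx))
      if (!is.null(config$clip) && config$clip > 0) {
        gn <- sqrt(sum(vapply(acc, function(g) sum(g * g), 1)))
        if (gn > config$clip)
          acc <- lapply(acc, function(g) g * (config$clip / gn))
      }
      up <- adam_step(model$params, acc, st, lr)
      model$params <- up$params; st <- up$state
      i <- i + config$batch_size
    }
    trace[[ep]] <- c(epoch = ep, loss = mean(ep_loss),
                     ep_bd / length(ep_loss))
    if (config$verbose)
      notice("epoch %d: loss %.4f", ep, mean(ep_loss))
  }
  list(model = model, trace = do.call(rbind, trace), state = st)
}

#' Evaluate a model on a sample set
#'
#' Segmentation Dice/IOU on the lesion-union foreground (argmax prediction)
#' and classification metrics from the responder probability
#' (`Y_effect[2]`).
#'
#' @param model Model object.
#' @param samples Sample list (with masks and labels).
#' @param seed Seed for the intervention draws.
#' @param n_boot Bootstrap resamples for the CIs (0 disables).
#' @return List `dice`, `iou`, `per_sample`, `auc`, `cls` (or NA when only
#'   one class is present), `scores`, `labels`.
#' @export
evaluate_model <- function(model, samples, seed = 1L, n_boot = 0L) {
  dice <- iou <- scores <- numeric(length(samples))
  labels <- logical(length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    fw <- net_forward(model, s$oct, s$uwf, seed = seed + i)
    cls_map <- apply(fw$seg, c(1, 2), which.max)
    P <- (cls_map > 1) * 1L
    G <- pmax(pmax(s$masks$ERM, s$masks$IRC), s$masks$SRF)
    m <- seg_metrics(P, G)
    dice[i] <- m["dice"]; iou[i] <- m["iou"]
    scores[i] <- fw$effect$Y_effect[2]
    labels[i] <- isTRUE(s$label)
  }
  auc <- if (length(unique(labels)) == 2L)
    auc_delong(scores, labels)$auc else NA_real_
  cls <- if (n_boot > 0L && length(unique(labels)) == 2L)
    classification_metrics(scores, labels, n_boot = n_boot, seed = seed)
  else NULL
  list(dice = mean(dice), iou = mean(iou),
       per_sample = data.frame(dice = dice, iou = iou, score = scores,
                               label = labels),
       auc = auc, cls = cls, scores = scores, labels = labels)
}
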