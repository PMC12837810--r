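# Curriculum learning: score per-sample difficulty from ROI signal contrast,
# relative lesion area, and image sharpness; bin into easy/medium/hard by
# cohort tertiles; train in three cumulative stages.

#' Raw difficulty measurements for one sample
#'
#' Returns the unnormalized ingredients: ROI-vs-background intensity contrast,
#' relative lesion area, and mean-gradient sharpness. Cohort-level min-max
#' normalization happens in [difficulty_table()]. An empty ROI marks the
#' sample hardest on the intensity and area factors.
#'
#' @param img H x W intensity matrix.
#' @param masks Lesion mask set aligned to `img`.
#' @return Named vector `contrast`, `rel_area`, `sharpness`, `empty_roi`.
#' @export
difficulty_score <- function(img, masks) {
  roi <- pmax(pmax(masks$ERM, masks$IRC), masks$SRF) > 0
  if (!all(dim(roi) == dim(img))) stopf("masks not aligned to image")
  gx <- abs(img[, -1, drop = FALSE] - img[, -ncol(img), drop = FALSE])
  gy <- abs(img[-1, , drop = FALSE] - img[-nrow(img), , drop = FALSE])
  sharp <- (mean(gx) + mean(gy)) / 2
  if (!any(roi)) {
    notice("empty ROI; sample scored hardest on intensity and area")
    return(c(contrast = NA_real_, rel_area = 0, sharpness = sharp,
             empty_roi = 1))
  }
  c(contrast = abs(mean(img[roi]) - mean(img[!roi])),
    rel_area = mean(roi), sharpness = sharp, empty_roi = 0)
}

minmax <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (diff(r) < 1e-12) return(rep(0.5, length(x)))
  (x - r[1]) / diff(r)
}

#' Cohort difficulty table with tertile levels
#'
#' Min-max normalizes the raw factors over the cohort, forms
#' `intensity_term = 1 - contrast`, `area_term = 1 - rel_area`,
#' `quality_term = 1 - sharpness` (each in [0, 1]), averages them into
#' `total`, and assigns easy/medium/hard by cohort tertiles of `total`
#' (deterministic tie-break by sample id). Samples with an empty ROI receive
#' intensity and area terms of 1.
#'
#' @param samples List of samples (each with `image` or `oct`, plus `masks`
#'   and an `id`).
#' @return data.frame: id, three terms, total, level.
#' @export
difficulty_table <- function(samples) {
  raw <- t(vapply(samples, function(s) {
    img <- if (!is.null(s$image)) s$image else s$oct[, , 1]
    difficulty_score(img, s$masks)
  }, c(contrast = 0, rel_area = 0, sharpness = 0, empty_roi = 0)))
  ids <- vapply(seq_along(samples), function(i) {
    if (!is.null(samples[[i]]$id)) as.character(samples[[i]]$id)
    else sprintf("S%04d", i)
  }, "")
  it <- 1 - minmax(raw[, "contrast"])
  at <- 1 - minmax(raw[, "rel_area"])
  qt <- 1 - minmax(raw[, "sharpness"])
  it[raw[, "empty_roi"] == 1] <- 1
  at[raw[, "empty_roi"] == 1] <- 1
  total <- (it + at + qt) / 3
  n <- length(total)
  ord <- order(total, ids)
  sizes <- diff(floor(n * (0:3) / 3))
  level <- character(n)
  level[ord] <- rep(c("easy", "medium", "hard"), times = sizes)
  data.frame(id = ids, intensity_term = it, area_term = at,
             quality_term = qt, total = total,
             level = factor(level, levels = c("easy", "medium", "hard")),
             stringsAsFactors = FALSE)
}

#' Build the three curriculum stages
#'
#' Stage I trains on easy samples, stage II on easy + medium, stage III on
#' all: the stage sample sets are cumulative (a disjoint mode is available).
#'
#' @param scores Difficulty table from [difficulty_table()].
#' @param epochs Per-stage epoch budget (length 3, recycled).
#' @param cumulative Cumulative stages (default) or disjoint.
#' @return List of stages: `stage`, `levels`, `ids`, `epochs`.
#' @export
build_stages <- function(scores, epochs = c(2L, 2L, 2L), cumulative = TRUE) {
  if (nrow(scores) < 3L) stopf("curriculum needs at least 3 samples")
  epochs <- rep_len(as.integer(epochs), 3L)
  lv <- list(I = "easy", II = c("easy", "medium"),
             III = c("easy", "medium", "hard"))
  if (!cumulative) lv <- list(I = "easy", II = "medium", III = "hard")
  lapply(seq_along(lv), function(i) {
    list(stage = names(lv)[i], levels = lv[[i]],
         ids = scores$id[scores$level %in% lv[[i]]], epochs = epochs[i])
  })
}

#' Staged curriculum training
#'
#' Trains sequentially over stages I -> III without resetting the weights,
#' evaluating on a validation set after each stage; the per-stage trace
#' carries Dice/IOU and AUC/ACC/SEN/SPE columns.
#'
#' @param model Model from [model_init()].
#' @param samples Named list of training samples (names = sample ids).
#' @param stages From [build_stages()].
#' @param config Trainer config; `config$val` (sample list) enables the
#'   per-stage validation metrics.
#' @return List `model`, `stage_trace` (data.frame, one row per stage),
#'   `loss_trace`.
#' @export
staged_fit <- function(model, samples, stages, config = trainer_config()) {
  st <- NULL
  stage_rows <- list()
  loss_trace <- list()
  for (sg in stages) {
    sub <- samples[sg$ids]
    cfg <- config
    cfg$epochs <- sg$epochs
    fit <- train_model(model, sub, cfg, state = st)
    model <- fit$model; st <- fit$state
    loss_trace[[sg$stage]] <- fit$trace
    row <- data.frame(stage = sg$stage, n_train = length(sub),
                      dice = NA_real_, iou = NA_real_, auc = NA_real_,
                      acc = NA_real_, sen = NA_real_, spe = NA_real_)
    if (!is.null(config$val)) {
      ev <- evaluate_model(model, config$val, seed = config$seed)
      row$dice <- ev$dice; row$iou <- ev$iou; row$auc <- ev$auc
      if (length(unique(ev$labels)) == 2L) {
        pm <- classification_metrics(ev$scores, ev$labels, n_boot = 0L)
        row$acc <- pm$estimates["acc"]; row$sen <- pm$estimates["sen"]
        row$spe <- pm$estimates["spe"]
      }
    }
    stage_rows[[sg$stage]] <- row
  }
  list(model = model, stage_trace = do.call(rbind, stage_rows),
       loss_trace = loss_trace)
}
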