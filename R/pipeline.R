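# Pipeline orchestration: dataset assembly (in memory or on disk), training
# runs with ablation switches, evaluation reports, and run manifests. The
# inst/cli/dmerwkv script is a thin wrapper over the cmd_* functions.

#' Build a network-ready sample from a cohort record
#'
#' Generates the paired B-scan phantom and UWF phantom at the network input
#' size, normalizes both (no gradient crop is needed: phantoms carry no
#' scanner margin), and attaches masks and the responder label.
#'
#' @param record One cohort row.
#' @param input_size Network input side.
#' @param seed Integer seed.
#' @param geometry Optional geometry overrides (see [bscan_geometry()]).
#' @param uwf UWF parameter overrides (see [uwf_params()]).
#' @return Sample list: `oct`, `uwf`, `masks`, `label`, `id`, `image`.
#' @export
phantom_sample <- function(record, input_size = 64L, seed = 1L,
                           geometry = NULL, uwf = NULL) {
  if (is.null(geometry))
    geometry <- bscan_geometry(height = input_size, width = input_size)
  if (is.null(uwf))
    uwf <- uwf_params(height = input_size, width = input_size)
  bs <- generate_bscan(record, geometry, seed = seed)
  uw <- generate_uwf(record, seed = seed + 1L, params = uwf)
  list(oct = zscore(array(rep(bs$image, 3L), c(dim(bs$image), 3L))),
       uwf = zscore(uw$pixels),
       masks = bs$masks, label = isTRUE(record$responder),
       id = record$eye_id, image = bs$image)
}

#' Generate an in-memory phantom dataset
#'
#' @param records Cohort data.frame (or NULL to generate one).
#' @param n_eyes,n_patients Cohort size when generating.
#' @param input_size Image side.
#' @param seed Master seed; per-sample seeds are derived from it.
#' @param geometry,uwf Parameter overrides.
#' @return Named list of samples (names = eye ids).
#' @export
make_dataset <- function(records = NULL, n_eyes = 100L,
                         n_patients = ceiling(n_eyes / 1.08), input_size = 64L,
                         seed = 1L, geometry = NULL, uwf = NULL) {
  if (is.null(records))
    records <- generate_cohort(n_patients = as.integer(n_patients),
                               n_eyes = as.integer(n_eyes), seed = seed)
  out <- lapply(seq_len(nrow(records)), function(i)
    phantom_sample(records[i, ], input_size, seed = seed * 10000L + 2L * i,
                   geometry = geometry, uwf = uwf))
  names(out) <- records$eye_id
  attr(out, "records") <- records
  out
}

default_run_config <- function() {
  list(out_dir = "dmerwkv_run", n_patients = 40L, n_eyes = 43L, seed = 1L,
       input_size = 64L, widths = c(12L, 24L, 36L, 48L), epochs = 5L,
       batch_size = 4L, lr = 3e-3, curriculum = TRUE, encoder = "hybrid",
       use_cal = TRUE, use_gca = TRUE, loss = "dce+gc", gc_s = 5L,
       n_samples = 2L)
}

read_run_config <- function(config) {
  base <- default_run_config()
  user <- if (is.character(config)) yaml::read_yaml(config)
          else if (is.list(config)) config else list()
  base[names(user)] <- user
  base
}

#' Generate a phantom dataset on disk
#'
#' Writes OCT and UWF images (PNG), label masks (PNG, values 0..3), the
#' cohort CSV, and a JSON manifest. Identical config + seed reproduce
#' identical files.
#'
#' @param config Config list or path to a YAML file; see
#'   `default_run_config` fields `out_dir`, `n_patients`, `n_eyes`, `seed`,
#'   `input_size`.
#' @return The manifest (invisibly).
#' @export
cmd_generate <- function(config = list()) {
  cfg <- read_run_config(config)
  dir.create(file.path(cfg$out_dir, "oct"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(cfg$out_dir, "uwf"), showWarnings = FALSE)
  dir.create(file.path(cfg$out_dir, "masks"), showWarnings = FALSE)
  rec <- generate_cohort(cfg$n_patients, cfg$n_eyes, seed = cfg$seed)
  geometry <- bscan_geometry(height = cfg$input_size, width = cfg$input_size)
  uwfp <- uwf_params(height = cfg$input_size, width = cfg$input_size)
  for (i in seq_len(nrow(rec))) {
    eid <- rec$eye_id[i]
    bs <- generate_bscan(rec[i, ], geometry, seed = cfg$seed * 10000L + 2L * i)
    uw <- generate_uwf(rec[i, ], seed = cfg$seed * 10000L + 2L * i + 1L,
                       params = uwfp)
    write_image_png(bs$image, file.path(cfg$out_dir, "oct",
                                        paste0(eid, ".png")))
    write_image_png(uw$pixels, file.path(cfg$out_dir, "uwf",
                                         paste0(eid, ".png")))
    write_mask_png(bs$masks, file.path(cfg$out_dir, "masks",
                                       paste0(eid, ".png")))
  }
  utils::write.csv(rec, file.path(cfg$out_dir, "cohort.csv"),
                   row.names = FALSE)
  manifest <- list(kind = "generate", seed = cfg$seed,
                   n_patients = cfg$n_patients, n_eyes = cfg$n_eyes,
                   input_size = cfg$input_size,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Load a generated dataset from disk
#'
#' @param dir Directory written by [cmd_generate()].
#' @return Named sample list with the cohort attached as attribute
#'   `records`.
#' @export
load_dataset <- function(dir) {
  rec <- utils::read.csv(file.path(dir, "cohort.csv"),
                         stringsAsFactors = FALSE)
  rec$responder <- as.logical(rec$responder)
  rec$erm_present <- as.logical(rec$erm_present)
  out <- lapply(seq_len(nrow(rec)), function(i) {
    eid <- rec$eye_id[i]
    img <- read_image_png(file.path(dir, "oct", paste0(eid, ".png")))
    uw <- read_image_png(file.path(dir, "uwf", paste0(eid, ".png")))
    masks <- read_mask_png(file.path(dir, "masks", paste0(eid, ".png")))
    list(oct = zscore(array(rep(img, 3L), c(dim(img), 3L))),
         uwf = zscore(uw), masks = masks,
         label = isTRUE(rec$responder[i]), id = eid, image = img)
  })
  names(out) <- rec$eye_id
  attr(out, "records") <- rec
  out
}

#' Train a model over a phantom dataset
#'
#' Grouped 4:1 split, optional three-stage curriculum, ablation switches
#' (encoder variant, causal-attention head, global-context fusion, loss
#' configuration with topology kernel size s), JSON checkpoint + manifest.
#'
#' @param config Config list or YAML path; see `default_run_config`.
#' @param samples Optional pre-built sample list (else generated in memory).
#' @return List `model`, `split`, `trace`, `manifest` (+ `stage_trace` when
#'   the curriculum is on).
#' @export
cmd_train <- function(config = list(), samples = NULL) {
  cfg <- read_run_config(config)
  if (!cfg$loss %in% c("dce", "dce+gc", "dce+cldice"))
    stopf("unknown loss configuration '%s'", cfg$loss)
  if (is.null(samples))
    samples <- make_dataset(n_eyes = cfg$n_eyes, n_patients = cfg$n_patients,
                            input_size = cfg$input_size, seed = cfg$seed)
  rec <- attr(samples, "records")
  sp <- split_grouped(rec, seed = cfg$seed)
  train <- samples[sp$train]; test <- samples[sp$test]
  mc <- model_config(widths = cfg$widths, input_size = cfg$input_size,
                     n_samples = cfg$n_samples, encoder = cfg$encoder,
                     use_cal = cfg$use_cal, use_gca = cfg$use_gca)
  model <- model_init(mc, seed = cfg$seed)
  w <- loss_weights(gc = if (cfg$loss == "dce") 0 else 0.5,
                    gc_s = cfg$gc_s, use_cldice = cfg$loss == "dce+cldice")
  tc <- trainer_config(epochs = cfg$epochs, batch_size = cfg$batch_size,
                       lr = cfg$lr, weights = w, n_samples = cfg$n_samples,
                       seed = cfg$seed)
  tc$val <- test
  stage_trace <- NULL
  if (isTRUE(cfg$curriculum) && length(train) >= 3L) {
    dt <- difficulty_table(train)
    per_stage <- max(1L, round(cfg$epochs / 3))
    stages <- build_stages(dt, epochs = per_stage)
    fit <- staged_fit(model, train, stages, tc)
    model <- fit$model; trace <- fit$loss_trace
    stage_trace <- fit$stage_trace
  } else {
    fit <- train_model(model, train, tc)
    model <- fit$model; trace <- fit$trace
  }
  manifest <- list(kind = "train", seed = cfg$seed,
                   ablation = cfg[c("encoder", "use_cal", "use_gca", "loss",
                                    "gc_s", "curriculum")],
                   n_train = length(train), n_test = length(test),
                   epochs = cfg$epochs, widths = cfg$widths,
                   input_size = cfg$input_size)
  if (!is.null(cfg$checkpoint)) save_model(model, cfg$checkpoint)
  list(model = model, split = sp, trace = trace, stage_trace = stage_trace,
       manifest = manifest, samples = samples)
}

#' Evaluate a trained model on a held-out split
#'
#' @param model Model (or path to a JSON checkpoint).
#' @param samples Sample list.
#' @param eye_ids Which eyes to evaluate (default all).
#' @param seed Seed for the intervention draws.
#' @param n_boot Bootstrap resamples for the classification CIs.
#' @return Metrics report: `dice`, `iou`, classification metrics with CIs,
#'   confusion counts, ROC data.
#' @export
cmd_evaluate <- function(model, samples, eye_ids = NULL, seed = 1L,
                         n_boot = 500L) {
  if (is.character(model)) model <- load_model(model)
  if (!is.null(eye_ids)) {
    missing_ids <- setdiff(eye_ids, names(samples))
    if (length(missing_ids) > 0)
      stopf("split/dataset mismatch: %d eye ids absent", length(missing_ids))
    samples <- samples[eye_ids]
  }
  ev <- evaluate_model(model, samples, seed = seed, n_boot = n_boot)
  roc <- NULL
  if (length(unique(ev$labels)) == 2L) {
    r <- pROC::roc(as.integer(ev$labels), ev$scores, levels = c(0, 1),
                   direction = "<", quiet = TRUE)
    roc <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities)
  }
  list(dice = ev$dice, iou = ev$iou, cls = ev$cls, auc = ev$auc,
       per_sample = ev$per_sample, roc = roc)
}
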