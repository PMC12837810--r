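# Difficulty scoring, tertile binning, staged training.

test_that("difficulty is monotone in lesion area and anchored at extremes", {
  small <- make_lesion_sample("a", 16, 0.4, seed = 2)
  large <- make_lesion_sample("b", 400, 0.4, seed = 2)
  smp <- list(small, large)
  dt <- difficulty_table(smp)
  expect_gte(dt$total[dt$id == "a"], dt$total[dt$id == "b"])
  # maximal contrast + area + sharpness sample scores exactly 0
  hi <- make_lesion_sample("hi", 500, 0.55, noise = 0.05, seed = 3)
  lo <- make_lesion_sample("lo", 9, 0.10, noise = 0.001, seed = 3)
  dt2 <- difficulty_table(list(hi, lo))
  expect_equal(dt2$total[dt2$id == "hi"], 0)
  expect_equal(dt2$total[dt2$id == "lo"], 1)
})

test_that("empty ROI is scored hardest with a notice", {
  e <- make_lesion_sample("e", 16, 0.4)
  e$masks$IRC[] <- 0L
  expect_message(sc <- difficulty_score(e$image, e$masks), "empty ROI")
  expect_equal(unname(sc["empty_roi"]), 1)
  filled <- make_lesion_sample("f", 100, 0.4)
  dt <- suppressMessages(difficulty_table(list(e, filled)))
  expect_equal(dt$intensity_term[dt$id == "e"], 1)
  expect_equal(dt$area_term[dt$id == "e"], 1)
})

test_that("contrast tiers sort into the expected difficulty order", {
  hits <- 0L
  trials <- 20L
  for (t in seq_len(trials)) {
    smp <- list(make_lesion_sample("lo", 100, 0.08, noise = 0.03, seed = t),
                make_lesion_sample("mid", 100, 0.25, noise = 0.03,
                                   seed = t + 100),
                make_lesion_sample("hi", 100, 0.50, noise = 0.03,
                                   seed = t + 200))
    dt <- difficulty_table(smp)
    o <- dt$id[order(dt$total)]
    if (identical(o, c("hi", "mid", "lo"))) hits <- hits + 1L
  }
  expect_gte(hits / trials, 0.95)
})

test_that("tertile stages are sized, nested and deterministic", {
  sc <- data.frame(id = sprintf("s%02d", 1:9),
                   total = seq(0.1, 0.9, length.out = 9),
                   level = factor(rep(c("easy", "medium", "hard"), each = 3),
                                  levels = c("easy", "medium", "hard")))
  st <- build_stages(sc)
  expect_equal(vapply(st, function(s) length(s$ids), 1L), c(3L, 6L, 9L))
  # all-equal scores: deterministic tie-break by id keeps the same sizes
  smp <- lapply(1:9, function(i)
    make_lesion_sample(sprintf("t%02d", i), 100, 0.4, seed = 99))
  dt <- difficulty_table(smp)
  expect_equal(as.integer(table(dt$level)), c(3L, 3L, 3L))
  dt2 <- difficulty_table(smp)
  expect_identical(dt, dt2)
  expect_error(build_stages(dt[1:2, ]), "at least 3")
})

test_that("stage sets are nested and cover the cohort (property fuzz)", {
  withr::with_seed(41, {
    for (rep in 1:5) {
      n <- sample(10:100, 1)
      smp <- lapply(seq_len(n), function(i)
        make_lesion_sample(sprintf("r%03d", i), sample(9:400, 1),
                           runif(1, 0.1, 0.5), seed = rep * 1000 + i))
      dt <- suppressMessages(difficulty_table(smp))
      st <- build_stages(dt)
      expect_true(all(st[[1]]$ids %in% st[[2]]$ids))
      expect_true(all(st[[2]]$ids %in% st[[3]]$ids))
      expect_setequal(st[[3]]$ids, dt$id)
    }
  })
})

test_that("single-stage curriculum reduces to plain training", {
  smp <- suppressMessages(make_dataset(n_eyes = 8, input_size = 64, seed = 5))
  mc <- model_config(widths = c(8, 12, 16, 20), input_size = 64,
                     n_samples = 1, head_hidden = 8)
  tc <- trainer_config(epochs = 1, batch_size = 4, lr = 1e-3, n_samples = 1,
                       seed = 3)
  all_ids <- names(smp)
  one_stage <- list(list(stage = "I", levels = "easy", ids = all_ids,
                         epochs = 1L))
  f1 <- staged_fit(model_init(mc, 2), smp, one_stage, tc)
  f2 <- train_model(model_init(mc, 2), smp, tc)
  expect_equal(f1$loss_trace[["I"]], f2$trace, tolerance = 1e-12)
  expect_equal(f1$model$params, f2$model$params, tolerance = 1e-12)
})

test_that("three-stage trace reports per-stage metrics in table layout", {
  smp <- suppressMessages(make_dataset(n_eyes = 12, input_size = 64, seed = 6))
  val <- suppressMessages(make_dataset(n_eyes = 6, input_size = 64, seed = 7))
  mc <- model_config(widths = c(8, 12, 16, 20), input_size = 64,
                     n_samples = 1, head_hidden = 8)
  tc <- trainer_config(epochs = 3, batch_size = 4, lr = 1e-3, n_samples = 1,
                       seed = 3)
  tc$val <- val
  dt <- suppressMessages(difficulty_table(smp))
  st <- build_stages(dt, epochs = 1L)
  fit <- suppressMessages(staged_fit(model_init(mc, 2), smp, st, tc))
  expect_equal(nrow(fit$stage_trace), 3L)
  expect_equal(fit$stage_trace$stage, c("I", "II", "III"))
  expect_true(all(c("dice", "iou", "auc", "acc", "sen", "spe") %in%
                    names(fit$stage_trace)))
  expect_true(all(is.finite(fit$stage_trace$dice)))
})
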