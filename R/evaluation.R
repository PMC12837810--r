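# Evaluation suite: segmentation overlap and surface-distance metrics,
# AUC with DeLong variance and the paired DeLong test, patient-grouped 4:1
# split and k-fold assignment, classification metrics with bootstrap CIs, and
# cohort summary statistics.

#' Responder label from the CMT rule
#'
#' An eye responds when central macular thickness decreased by at least 10\%
#' at 3 months: `(baseline - followup) / baseline >= 0.10` (boundary
#' inclusive).
#'
#' @param cmt_baseline,cmt_3month Positive CMT values (micrometers).
#' @return Logical vector.
#' @export
responder_label <- function(cmt_baseline, cmt_3month) {
  if (any(cmt_baseline <= 0) || any(cmt_3month <= 0))
    stopf("responder_label: CMT values must be positive")
  (cmt_baseline - cmt_3month) / cmt_baseline >= 0.10
}

boundary_pixels <- function(M) {
  # 4-neighbourhood inner boundary of a binary mask
  H <- nrow(M); W <- ncol(M)
  pad <- matrix(0L, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- M
  core <- pad[2:(H + 1L), 2:(W + 1L)] &
    pad[1:H, 2:(W + 1L)] & pad[3:(H + 2L), 2:(W + 1L)] &
    pad[2:(H + 1L), 1:W] & pad[2:(H + 1L), 3:(W + 2L)]
  which(M == 1L & !core, arr.ind = TRUE)
}

#' Segmentation metrics: Dice, IOU, 95\% Hausdorff distance
#'
#' Dice = 2|P&G| / (|P|+|G|); IOU = |P&G| / |P|G|; hd95 is the 95th percentile
#' (linear interpolation) of the symmetric set of directed surface distances
#' between the 4-neighbourhood boundaries, scaled by `spacing`. Both masks
#' empty gives (1, 1, 0); exactly one empty gives Dice = IOU = 0 and hd95 =
#' image diagonal, with attribute `degenerate = TRUE`.
#'
#' @param P,G Binary masks of equal shape.
#' @param spacing Physical units per pixel (default 1).
#' @return Named vector `dice`, `iou`, `hd95`.
#' @export
seg_metrics <- function(P, G, spacing = 1) {
  if (!all(dim(P) == dim(G))) stopf("seg_metrics: shape mismatch")
  P <- (P != 0) * 1L; G <- (G != 0) * 1L
  np <- sum(P); ng <- sum(G)
  if (np == 0 && ng == 0)
    return(c(dice = 1, iou = 1, hd95 = 0))
  if (np == 0 || ng == 0) {
    out <- c(dice = 0, iou = 0,
             hd95 = spacing * sqrt(nrow(P)^2 + ncol(P)^2))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  inter <- sum(P & G)
  dice <- 2 * inter / (np + ng)
  iou <- inter / (np + ng - inter)
  bp <- boundary_pixels(P); bg <- boundary_pixels(G)
  # distance of every pixel to the nearest boundary pixel of the other mask
  dist_to <- function(bset) {
    m <- matrix(1L, nrow(P), ncol(P))
    m[bset] <- 0L
    EBImage::distmap(m, metric = "euclidean")
  }
  dPG <- dist_to(bg)[bp]
  dGP <- dist_to(bp)[bg]
  hd95 <- spacing * stats::quantile(c(dPG, dGP), 0.95, names = FALSE)
  c(dice = dice, iou = iou, hd95 = hd95)
}

#' AUC with DeLong variance and logit-scale CI
#'
#' AUC through the Mann-Whitney statistic, variance by DeLong's structural
#' components, and a 95\% CI by the normal approximation on the logit scale.
#'
#' @param scores Numeric prediction scores (higher = positive).
#' @param labels Logical or 0/1 labels; both classes must be present.
#' @return List `auc`, `var`, `ci` (length 2).
#' @export
auc_delong <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2L)
    stopf("auc_delong: both classes must be present")
  r <- pROC::roc(labels, scores, levels = c(0, 1), direction = "<",
                 quiet = TRUE)
  a <- as.numeric(pROC::auc(r))
  v <- suppressWarnings(as.numeric(pROC::var(r, method = "delong")))
  if (a <= 0 || a >= 1 || v <= 0) {
    ci <- c(max(0, a - 1.96 * sqrt(max(v, 0))),
            min(1, a + 1.96 * sqrt(max(v, 0))))
  } else {
    lg <- stats::qlogis(a)
    se <- sqrt(v) / (a * (1 - a))
    ci <- stats::plogis(lg + c(-1.96, 1.96) * se)
  }
  list(auc = a, var = v, ci = ci)
}

#' Paired DeLong test for two correlated AUCs
#'
#' @param scoresA,scoresB Paired score vectors over the same subjects.
#' @param labels Common labels.
#' @return List `p` (two-sided), `z`, `aucA`, `aucB`.
#' @export
delong_test <- function(scoresA, scoresB, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2L)
    stopf("delong_test: both classes must be present")
  rA <- pROC::roc(labels, scoresA, levels = c(0, 1), direction = "<",
                  quiet = TRUE)
  rB <- pROC::roc(labels, scoresB, levels = c(0, 1), direction = "<",
                  quiet = TRUE)
  tt <- pROC::roc.test(rA, rB, method = "delong", paired = TRUE)
  z <- if (!is.null(tt$statistic)) as.numeric(tt$statistic) else NA_real_
  p <- as.numeric(tt$p.value)
  if (is.nan(p)) {                    # degenerate covariance (equal scores)
    notice("delong_test: degenerate covariance; returning p = 1")
    p <- 1; z <- 0
  }
  list(p = p, z = z, aucA = as.numeric(pROC::auc(rA)),
       aucB = as.numeric(pROC::auc(rB)))
}

#' Classification metrics with bootstrap CIs
#'
#' Accuracy, sensitivity, specificity, F1 and precision at a score threshold,
#' with 95\% CIs from a stratified bootstrap, plus AUC (DeLong CI) and the
#' confusion matrix.
#'
#' @param scores Prediction scores.
#' @param labels True labels (logical).
#' @param threshold Decision threshold on the score (default 0.5).
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Bootstrap seed.
#' @return List with per-metric estimates and CIs, `auc`, and `confusion`
#'   (TN, FP, FN, TP).
#' @export
classification_metrics <- function(scores, labels, threshold = 0.5,
                                   n_boot = 2000L, seed = 1L) {
  labels <- as.logical(labels)
  point <- function(sc, lb) {
    pred <- sc >= threshold
    tp <- sum(pred & lb); tn <- sum(!pred & !lb)
    fp <- sum(pred & !lb); fn <- sum(!pred & lb)
    pre <- if (tp + fp > 0) tp / (tp + fp) else 0
    sen <- if (tp + fn > 0) tp / (tp + fn) else 0
    c(acc = (tp + tn) / length(lb), sen = sen,
      spe = if (tn + fp > 0) tn / (tn + fp) else 0,
      f1 = if (pre + sen > 0) 2 * pre * sen / (pre + sen) else 0,
      pre = pre)
  }
  est <- point(scores, labels)
  ip <- which(labels); ineg <- which(!labels)
  cis <- NULL
  if (n_boot > 0L) {
    boot <- with_seed(seed, {
      t(vapply(seq_len(n_boot), function(b) {
        i <- c(sample(ip, length(ip), replace = TRUE),
               sample(ineg, length(ineg), replace = TRUE))
        point(scores[i], labels[i])
      }, est))
    })
    cis <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975))
  }
  pred <- scores >= threshold
  conf <- c(TN = sum(!pred & !labels), FP = sum(pred & !labels),
            FN = sum(!pred & labels), TP = sum(pred & labels))
  list(estimates = est, ci = cis, auc = auc_delong(scores, labels),
       confusion = conf)
}

# ---- splits -----------------------------------------------------------------

#' Patient-grouped 4:1 train/test split
#'
#' Randomly assigns whole patients so that the training side holds exactly
#' `floor(0.8 * N)` eyes (402 eyes give 321 train / 81 test), never splitting
#' a patient's two eyes, stratified over the responder label when feasible. If
#' the grouping makes the exact count unattainable, the nearest attainable
#' split is returned with a warning.
#'
#' @param records Cohort data.frame (needs `patient_id`, `eye_id`,
#'   `responder`).
#' @param seed Integer seed.
#' @param ratio Training fraction (default 0.8).
#' @return List `train`, `test` (eye-id vectors) and `target_train`.
#' @export
split_grouped <- function(records, seed = 1L, ratio = 0.8) {
  N <- nrow(records)
  target_train <- floor(ratio * N)
  target_test <- N - target_train
  pats <- split(records, records$patient_id)
  p_ids <- names(pats)
  eyes_of <- vapply(pats, nrow, 1L)
  resp_of <- vapply(pats, function(d) mean(d$responder) >= 0.5, TRUE)
  with_seed(seed, {
    # stratified order: shuffle within responder strata, then interleave
    # proportionally by within-stratum rank
    key <- numeric(length(p_ids)); names(key) <- p_ids
    for (r in c(TRUE, FALSE)) {
      ids <- p_ids[resp_of == r]
      if (length(ids) == 0) next
      key[ids[sample.int(length(ids))]] <- seq_along(ids) / length(ids)
    }
    ord <- p_ids[order(key)]
    test_ids <- character(0); cnt <- 0L
    for (pid in ord) {
      if (cnt + eyes_of[pid] <= target_test) {
        test_ids <- c(test_ids, pid); cnt <- cnt + eyes_of[pid]
        if (cnt == target_test) break
      }
    }
    if (cnt < target_test) {
      # swap in a patient with the exact remaining eye count if one exists
      need <- target_test - cnt
      cand <- setdiff(p_ids, test_ids)
      hit <- cand[eyes_of[cand] == need]
      if (length(hit) > 0) {
        test_ids <- c(test_ids, hit[1]); cnt <- cnt + need
      } else {
        warning("grouped split: exact eye count unattainable; off by ",
                target_test - cnt)
      }
    }
    train_ids <- setdiff(p_ids, test_ids)
    list(train = records$eye_id[records$patient_id %in% train_ids],
         test = records$eye_id[records$patient_id %in% test_ids],
         target_train = target_train)
  })
}

#' Patient-grouped k-fold assignment
#'
#' Whole patients are dealt to the currently smallest fold in shuffled order,
#' so fold eye-counts differ by at most one patient's eyes (<= 2).
#'
#' @param records Training-part cohort data.frame.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer fold id (1..k) per row of `records`.
#' @export
kfold_grouped <- function(records, k = 5L, seed = 1L) {
  p_ids <- unique(records$patient_id)
  if (length(p_ids) < k) stopf("kfold: fewer patients (%d) than folds (%d)",
                               length(p_ids), k)
  eyes_of <- table(records$patient_id)
  with_seed(seed, {
    ord <- p_ids[sample.int(length(p_ids))]
    sizes <- integer(k)
    fold_of <- setNames(integer(length(ord)), ord)
    for (pid in ord) {
      f <- which.min(sizes)
      fold_of[pid] <- f
      sizes[f] <- sizes[f] + eyes_of[[pid]]
    }
    as.integer(fold_of[records$patient_id])
  })
}

# ---- cohort statistics ------------------------------------------------------

#' Cohort summary statistics by response group
#'
#' Mann-Whitney U (normal approximation, tie-corrected) for numeric
#' covariates; chi-square with Yates continuity correction for 2x2 categorical
#' tables. Emits per-group mean +/- SD (or counts and percentages) alongside
#' the p-value, in the layout of a baseline-characteristics table. Covariates
#' constant across both groups are skipped with a notice.
#'
#' @param records Cohort data.frame.
#' @param numeric_vars,categorical_vars Covariate column names.
#' @return data.frame with one row per covariate.
#' @export
cohort_stats <- function(records,
                         numeric_vars = c("age", "cmt_baseline", "iop",
                                          "bcva"),
                         categorical_vars = c("gender", "erm_present")) {
  g1 <- records[records$responder, , drop = FALSE]
  g0 <- records[!records$responder, , drop = FALSE]
  if (nrow(g1) == 0 || nrow(g0) == 0)
    stopf("cohort_stats: both groups must be nonempty")
  rows <- list()
  fmt_ms <- function(x) sprintf("%.2f ± %.2f", mean(x), stats::sd(x))
  for (v in numeric_vars) {
    if (stats::sd(records[[v]]) < 1e-12) {
      notice("cohort_stats: '%s' constant; test skipped", v)
      next
    }
    p <- stats::wilcox.test(g1[[v]], g0[[v]], exact = FALSE,
                            correct = TRUE)$p.value
    rows[[v]] <- data.frame(covariate = v, responsive = fmt_ms(g1[[v]]),
                            nonresponsive = fmt_ms(g0[[v]]),
                            p_value = p, test = "mann-whitney",
                            stringsAsFactors = FALSE)
  }
  for (v in categorical_vars) {
    tab <- table(factor(records[[v]]), records$responder)
    if (nrow(tab) < 2L) {
      notice("cohort_stats: '%s' constant; test skipped", v)
      next
    }
    p <- stats::chisq.test(tab, correct = TRUE)$p.value
    fmt_ct <- function(d) {
      t1 <- table(factor(d[[v]]))
      paste(sprintf("%s %d (%.2f%%)", names(t1), as.integer(t1),
                    100 * as.integer(t1) / nrow(d)), collapse = "; ")
    }
    rows[[v]] <- data.frame(covariate = v, responsive = fmt_ct(g1),
                            nonresponsive = fmt_ct(g0),
                            p_value = p, test = "chi-square",
                            stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(covariate = character(0), responsive = character(0),
                      nonresponsive = character(0), p_value = numeric(0),
                      test = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
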