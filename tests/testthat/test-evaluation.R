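# Metrics, DeLong, grouped splits, cohort statistics.

test_that("responder rule has an inclusive 10% boundary", {
  expect_true(responder_label(500, 450))      # exactly 10%
  expect_false(responder_label(500, 451))
  expect_false(responder_label(400, 500))     # thickening
  expect_error(responder_label(0, 450), "positive")
  expect_error(responder_label(500, -1), "positive")
})

test_that("segmentation metrics match closed-form toy cases", {
  P <- matrix(0L, 12, 12); G <- matrix(0L, 12, 12)
  P[3:4, 3:4] <- 1L; G[3:4, 3:6] <- 1L       # 2x2 inside a 2x4, 4 px shared
  m <- seg_metrics(P, G)
  expect_equal(unname(m["dice"]), 8 / 12)
  expect_equal(unname(m["iou"]), 4 / 8)
  # identical masks; disjoint masks
  expect_equal(unname(seg_metrics(G, G)), c(1, 1, 0))
  D <- matrix(0L, 12, 12); D[9:10, 9:10] <- 1L
  md <- seg_metrics(P, D)
  expect_equal(unname(md["dice"]), 0)
  expect_equal(unname(md["iou"]), 0)
  # empty-empty and one-empty conventions
  E <- matrix(0L, 12, 12)
  expect_equal(unname(seg_metrics(E, E)), c(1, 1, 0))
  me <- seg_metrics(P, E)
  expect_equal(unname(me["dice"]), 0)
  expect_equal(unname(me["hd95"]), sqrt(2 * 144))
  expect_true(attr(me, "degenerate"))
  expect_error(seg_metrics(P, matrix(0L, 5, 5)), "mismatch")
})

test_that("hd95 agrees with all-pairs distances and is symmetric", {
  set.seed(3)
  for (i in 1:10) {
    P <- matrix(0L, 24, 24); G <- matrix(0L, 24, 24)
    P[sample(24, 6), sample(24, 6)] <- 1L
    G[sample(24, 6), sample(24, 6)] <- 1L
    h1 <- seg_metrics(P, G)["hd95"]
    h2 <- seg_metrics(G, P)["hd95"]
    expect_equal(unname(h1), unname(h2))
    expect_equal(unname(h1), oracle_hd95(P, G), tolerance = 1e-9)
    m <- seg_metrics(P, G)
    expect_gte(m["dice"], m["iou"])
  }
})

test_that("AUC equals the exhaustive pair count and is rank-invariant", {
  set.seed(6)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    sc <- rnorm(n); lb <- runif(n) < 0.5
    if (length(unique(lb)) < 2) next
    a <- auc_delong(sc, lb)
    expect_equal(a$auc, oracle_auc(sc, lb), tolerance = 1e-12)
    # strictly monotone transform leaves the AUC unchanged
    a2 <- auc_delong(exp(3 * sc) + 2, lb)
    expect_equal(a2$auc, a$auc, tolerance = 1e-12)
    expect_true(a$ci[1] <= a$auc && a$auc <= a$ci[2])
  }
  # perfect separation
  expect_equal(auc_delong(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auc, 1)
  expect_error(auc_delong(rnorm(5), rep(TRUE, 5)), "both classes")
})

test_that("label-independent scores give chance-level AUC", {
  set.seed(14)
  aucs <- vapply(1:30, function(i) {
    sc <- rnorm(200); lb <- rep(c(TRUE, FALSE), 100)
    auc_delong(sc, lb)$auc
  }, 1)
  se <- sqrt(1 / 12) / sqrt(100)   # conservative order for n1 = n0 = 100
  expect_lt(abs(mean(aucs) - 0.5), 3 * se)
})

test_that("DeLong test matches a permutation oracle and its degeneracies", {
  set.seed(20)
  n <- 60
  lb <- rep(c(TRUE, FALSE), n / 2)
  x <- rnorm(n) + lb * 1.2
  sA <- x + rnorm(n, 0, 0.6)
  sB <- rnorm(n)
  eq <- suppressMessages(delong_test(sA, sA, lb))
  expect_equal(eq$p, 1)
  # informative vs uninformative scores separate decisively
  p_inf <- delong_test(x + rnorm(n, 0, 0.1), rnorm(n), lb)$p
  expect_lt(p_inf, 0.01)
  # permutation oracle: swap the two scores per subject at random
  dt <- delong_test(sA, sB, lb)
  obs <- abs(auc_delong(sA, lb)$auc - auc_delong(sB, lb)$auc)
  perm <- vapply(1:2000, function(b) {
    sw <- runif(n) < 0.5
    a1 <- ifelse(sw, sB, sA); b1 <- ifelse(sw, sA, sB)
    abs(auc_delong(a1, lb)$auc - auc_delong(b1, lb)$auc)
  }, 1)
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(dt$p - p_perm), 0.02)
})

test_that("grouped split hits exact counts and never splits a patient", {
  rec <- toy_records(200, seed = 2, two_eye = 30L)   # 230 eyes
  sp <- split_grouped(rec, seed = 1)
  expect_equal(length(sp$train), floor(0.8 * 230))
  expect_length(intersect(sp$train, sp$test), 0)
  # 5 single-eye patients -> 4 / 1
  r5 <- toy_records(5, seed = 3)
  sp5 <- split_grouped(r5, seed = 2)
  expect_equal(length(sp5$train), 4L)
  expect_equal(length(sp5$test), 1L)
  # fuzz: patients never straddle; assignment deterministic under seed
  for (s in 1:30) {
    spx <- split_grouped(rec, seed = s)
    pt <- unique(rec$patient_id[rec$eye_id %in% spx$train])
    pe <- unique(rec$patient_id[rec$eye_id %in% spx$test])
    expect_length(intersect(pt, pe), 0)
  }
  expect_identical(split_grouped(rec, seed = 9), split_grouped(rec, seed = 9))
})

test_that("grouped k-fold balances, covers, and validates", {
  rec <- toy_records(321, seed = 4)
  f <- kfold_grouped(rec, k = 5, seed = 1)
  expect_equal(sort(as.integer(table(f))), c(64L, 64L, 64L, 64L, 65L))
  expect_setequal(unique(f), 1:5)
  expect_identical(f, kfold_grouped(rec, k = 5, seed = 1))
  # two-eye patients stay within one fold; sizes differ by <= 2
  rec2 <- toy_records(40, seed = 5, two_eye = 12L)
  f2 <- kfold_grouped(rec2, k = 5, seed = 2)
  per_pat <- tapply(f2, rec2$patient_id, function(x) length(unique(x)))
  expect_true(all(per_pat == 1))
  expect_lte(diff(range(table(f2))), 2L)
  expect_error(kfold_grouped(toy_records(3, seed = 1), k = 5), "fewer")
})

test_that("cohort statistics use the configured tests and layouts", {
  co <- generate_cohort(120, 130, seed = 31)
  st <- cohort_stats(co)
  expect_true(all(c("covariate", "responsive", "nonresponsive", "p_value",
                    "test") %in% names(st)))
  expect_equal(st$test[st$covariate == "age"], "mann-whitney")
  expect_equal(st$test[st$covariate == "gender"], "chi-square")
  # CMT separates the groups by construction
  expect_lt(st$p_value[st$covariate == "cmt_baseline"], 0.01)
  # identical group distributions: Mann-Whitney cannot reject
  ident <- data.frame(responder = rep(c(TRUE, FALSE), each = 20),
                      age = rep(seq(40, 78, 2), 2))
  sti <- cohort_stats(ident, numeric_vars = "age",
                      categorical_vars = character(0))
  expect_gte(sti$p_value, 0.99)
  # covariate constant in both groups is skipped with a notice
  co2 <- co
  co2$age <- 50
  expect_message(
    cohort_stats(co2, numeric_vars = "age",
                 categorical_vars = character(0)),
    "constant")
})

test_that("tiny-sample Mann-Whitney agrees with exhaustive enumeration", {
  x <- c(1.0, 1.7, 2.3, 0.8)
  y <- c(2.2, 2.0, 2.1, 3.1)
  p_approx <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  # enumerate all assignments of the 8 ranks to group 1
  vals <- c(x, y)
  combos <- utils::combn(8, 4)
  U_obs <- sum(rank(vals)[1:4]) - 4 * 5 / 2
  U_all <- apply(combos, 2, function(ix) sum(rank(vals)[ix]) - 10)
  p_exact <- mean(abs(U_all - 8) >= abs(U_obs - 8))
  expect_lt(abs(p_approx - p_exact), 0.02)
})

test_that("classification metrics satisfy their identities", {
  set.seed(42)
  sc <- runif(80); lb <- sc + rnorm(80, 0, 0.3) > 0.5
  cm <- classification_metrics(sc, lb, n_boot = 200, seed = 2)
  conf <- cm$confusion
  expect_equal(sum(conf), 80)
  expect_equal(unname(cm$estimates["sen"]),
               unname(conf["TP"] / (conf["TP"] + conf["FN"])))
  expect_equal(unname(cm$estimates["spe"]),
               unname(conf["TN"] / (conf["TN"] + conf["FP"])))
  expect_true(all(cm$estimates >= 0 & cm$estimates <= 1))
  expect_true(all(cm$ci[1, ] <= cm$ci[2, ]))
})
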