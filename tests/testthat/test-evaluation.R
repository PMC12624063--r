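test_that("boundary splits group grades as below-vs-above the cut", {
  fz <- grade_scale("fazekas")
  expect_identical(boundary_split(c(0, 1, 2, 3), 2, fz),
                   c(FALSE, FALSE, FALSE, TRUE))
  bd <- grade_scale("braindock")
  expect_identical(boundary_split(c(3, 4), 3, bd), c(FALSE, TRUE))
  expect_identical(boundary_split(rep(0, 5), 1, fz), rep(FALSE, 5))
  expect_error(boundary_split(c(0, 1), 3, fz), "boundary")
  expect_error(boundary_split(4, 0, fz), "scale")
})

test_that("binary metrics follow the confusion-table hand counts", {
  m <- binary_metrics(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(m$accuracy, 1); expect_equal(m$f1, 1)
  # TP 1, FP 1, FN 1, TN 1
  m2 <- binary_metrics(c(TRUE, TRUE, FALSE, FALSE),
                       c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(m2$accuracy, 0.5); expect_equal(m2$f1, 0.5)
  # no positives anywhere: F1 defined as 0
  m3 <- binary_metrics(rep(FALSE, 4), rep(FALSE, 4))
  expect_equal(m3$accuracy, 1); expect_equal(m3$f1, 0)
  expect_error(binary_metrics(c(TRUE, FALSE), TRUE), "length")
})

test_that("multi-class metrics match forced arithmetic", {
  fz <- grade_scale("fazekas")
  m <- multiclass_metrics(c(0, 1, 2, 3), c(0, 1, 2, 3), fz)
  expect_equal(m$accuracy, 1); expect_equal(m$macro_f1, 1)
  expect_equal(m$mae, 0)
  m2 <- multiclass_metrics(c(0, 1, 2, 3), c(1, 1, 2, 2), fz)
  expect_equal(m2$accuracy, 0.5)
  expect_equal(m2$mae, 0.5)
})

test_that("metrics and kappas match naive oracles on random tables", {
  set.seed(123)
  fz <- grade_scale("fazekas")
  for (rep in 1:60) {
    n <- sample(5:30, 1)
    gt <- sample(0:3, n, replace = TRUE)
    pred <- sample(0:3, n, replace = TRUE)
    m <- multiclass_metrics(gt, pred, fz)
    expect_equal(m$accuracy, naive_accuracy(gt, pred), tolerance = 1e-12)
    expect_equal(m$macro_f1, naive_macro_f1(gt, pred), tolerance = 1e-12)
    expect_equal(m$mae, naive_mae(gt, pred), tolerance = 1e-12)
    expect_equal(cohen_kappa(gt, pred), naive_cohen_kappa(gt, pred),
                 tolerance = 1e-12)
    mat <- matrix(sample(0:3, n * 3, replace = TRUE), ncol = 3)
    expect_equal(fleiss_kappa(mat), naive_fleiss_kappa(mat),
                 tolerance = 1e-12)
    for (g in 0:2) {
      b <- binary_metrics(boundary_split(gt, g, fz),
                          boundary_split(pred, g, fz))
      expect_equal(b$f1, naive_binary_f1(gt >= g + 1, pred >= g + 1),
                   tolerance = 1e-12)
    }
  }
})

test_that("Cohen's kappa has its closed-form landmarks", {
  expect_equal(cohen_kappa(c(0, 1, 2, 0), c(0, 1, 2, 0)), 1)
  expect_equal(cohen_kappa(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  expect_equal(cohen_kappa(c(0, 0, 1, 1), c(1, 1, 0, 0)), -1)
  expect_equal(cohen_kappa(rep(2, 5), rep(2, 5)), 1)  # degenerate agreement
  expect_error(cohen_kappa(0:1, 0:2), "length")
  # symmetry and invariance under category relabeling
  set.seed(2)
  a <- sample(0:3, 40, replace = TRUE)
  b <- sample(0:3, 40, replace = TRUE)
  expect_equal(cohen_kappa(a, b), cohen_kappa(b, a))
  relabel <- c(7, 5, 9, 3)  # bijection 0..3 -> arbitrary codes
  expect_equal(cohen_kappa(relabel[a + 1], relabel[b + 1]),
               cohen_kappa(a, b), tolerance = 1e-12)
})

test_that("Fleiss' kappa handles panels, degeneracy and the 2-rater case", {
  mat <- cbind(c(0, 1, 2, 0), c(0, 1, 2, 0), c(0, 1, 2, 0))
  expect_equal(fleiss_kappa(mat), 1)
  expect_warning(k <- fleiss_kappa(matrix(1, 4, 3)), "undefined")
  expect_true(is.nan(k))
  expect_error(fleiss_kappa(matrix(c(0, NA, 1, 1), 2, 2)), "complete")
  # 2 raters: equals the pooled-marginal kappa on a 4-subject toy
  a <- c(0, 0, 1, 1); b <- c(0, 1, 1, 1)
  # hand computation: P_bar = mean(per-subject agreement) over pairs,
  # pooled p = (freq over all 8 ratings)
  po <- mean(a == b)
  p0 <- sum(c(a, b) == 0) / 8; p1 <- sum(c(a, b) == 1) / 8
  pe <- p0^2 + p1^2
  expect_equal(fleiss_kappa(cbind(a, b)), (po - pe) / (1 - pe))
})

test_that("reports recompute to the standalone metrics and scale layout", {
  set.seed(55)
  fz <- grade_scale("fazekas")
  bd <- grade_scale("braindock")
  gt <- sample(0:3, 50, replace = TRUE)
  ai <- pmax(0, pmin(3, gt + sample(-1:1, 50, TRUE, prob = c(.2, .6, .2))))
  human <- pmax(0, pmin(3, gt + sample(-1:1, 50, TRUE)))
  rep_fz <- grading_report(gt, list(ai = ai, human = human), fz)
  expect_equal(nrow(rep_fz), 2)
  expect_equal(sum(grepl("^acc_", names(rep_fz))), 3)  # 3 Fazekas boundaries
  gt_bd <- sample(0:4, 50, replace = TRUE)
  rep_bd <- grading_report(gt_bd, list(ai = gt_bd), bd)
  expect_equal(sum(grepl("^acc_", names(rep_bd))), 4)  # 4 Brain Dock boundaries
  expect_true(all(rep_bd$mae == 0))
  # internal consistency with the standalone operations
  expect_equal(rep_fz$acc_1v2[1],
               binary_metrics(boundary_split(gt, 1, fz),
                              boundary_split(ai, 1, fz))$accuracy)
  expect_equal(rep_fz$multiclass_f1[2],
               multiclass_metrics(gt, human, fz)$macro_f1)
  # identical vectors: everything perfect
  perfect <- grading_report(gt, list(ai = gt), fz)
  expect_true(all(perfect[, grepl("acc|f1", names(perfect))] == 1))
  expect_equal(perfect$mae, 0)
})

test_that("metrics are invariant under subject permutation", {
  set.seed(66)
  gt <- sample(0:3, 30, replace = TRUE)
  pred <- sample(0:3, 30, replace = TRUE)
  perm <- sample(30)
  fz <- grade_scale("fazekas")
  expect_equal(multiclass_metrics(gt, pred, fz),
               multiclass_metrics(gt[perm], pred[perm], fz))
  expect_equal(cohen_kappa(gt, pred), cohen_kappa(gt[perm], pred[perm]))
  mat <- cbind(gt, pred, sample(0:3, 30, replace = TRUE))
  expect_equal(fleiss_kappa(mat), fleiss_kappa(mat[perm, ]))
})

test_that("boundary accuracy equals multi-class accuracy on two grades", {
  set.seed(44)
  fz <- grade_scale("fazekas")
  gt <- sample(1:2, 40, replace = TRUE)
  pred <- sample(1:2, 40, replace = TRUE)
  b <- binary_metrics(boundary_split(gt, 1, fz), boundary_split(pred, 1, fz))
  expect_equal(b$accuracy, multiclass_metrics(gt, pred, fz)$accuracy)
})

test_that("Cohen's kappa agrees with e1071's independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(17)
  for (rep in 1:10) {
    a <- sample(0:3, 25, replace = TRUE)
    b <- sample(0:3, 25, replace = TRUE)
    tab <- table(factor(a, 0:3), factor(b, 0:3))
    expect_equal(cohen_kappa(a, b), e1071::classAgreement(tab)$kappa,
                 tolerance = 1e-12)
  }
})

test_that("agreement report combines Fleiss and pairwise Cohen kappas", {
  set.seed(10)
  ratings <- cbind(r1 = sample(0:3, 20, TRUE), r2 = sample(0:3, 20, TRUE),
                   r3 = sample(0:3, 20, TRUE))
  ai <- sample(0:3, 20, TRUE)
  rep <- agreement_report(ratings, ai)
  expect_equal(rep$fleiss_kappa, fleiss_kappa(ratings))
  expect_equal(rep$cohen_kappa[["r2"]], cohen_kappa(ai, ratings[, "r2"]))
  expect_equal(rep$mean_cohen_kappa, mean(rep$cohen_kappa))
})
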