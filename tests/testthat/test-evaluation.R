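# Five-metric evaluation against brute-force oracles.

test_that("confusion counts match exhaustive enumeration", {
  a <- binary_label_volume(array(c(1, 0, 1, 0), c(2, 2, 1)))
  b <- binary_label_volume(array(c(1, 1, 0, 0), c(2, 2, 1)))
  cc <- confusion_counts(a, b)
  expect_equal(cc$TP, 1); expect_equal(cc$FP, 1)
  expect_equal(cc$FN, 1); expect_equal(cc$TN, 1)
  expect_equal(cc$TP + cc$FP + cc$FN + cc$TN, 4)
  same <- confusion_counts(a, a)
  expect_equal(same$FP + same$FN, 0)
  compl <- binary_label_volume(1 - a$data)
  opp <- confusion_counts(a, compl)
  expect_equal(opp$TP + opp$TN, 0)
  expect_error(confusion_counts(a, binary_label_volume(array(0, c(2, 1, 2)))),
               "shape")
})

test_that("overlap metrics follow the counting formulas and conventions", {
  cc <- structure(list(TP = 3, FP = 1, FN = 1, TN = 10),
                  class = "confusion_counts")
  m <- overlap_metrics(cc)
  expect_equal(m$dsc, 0.75)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  # both empty -> all 1 by convention
  empty <- structure(list(TP = 0, FP = 0, FN = 0, TN = 8),
                     class = "confusion_counts")
  expect_equal(overlap_metrics(empty), list(dsc = 1, precision = 1,
                                            recall = 1))
  # prediction-only foreground: precision 0, recall 1 (gt empty)
  fp <- structure(list(TP = 0, FP = 5, FN = 0, TN = 3),
                  class = "confusion_counts")
  m2 <- overlap_metrics(fp)
  expect_equal(m2$precision, 0)
  expect_equal(m2$recall, 1)
  expect_equal(m2$dsc, 0)
})

test_that("directed average distance equals the double-loop oracle", {
  expect_equal(directed_avg_distance(matrix(c(0, 0, 0), 1),
                                     matrix(c(3, 0, 0), 1)), 3)
  A0 <- matrix(c(1, 1, 1), 1)
  expect_equal(directed_avg_distance(A0, A0), 0)
  set.seed(51)
  for (i in 1:5) {
    A <- matrix(sample(1:12, 90, replace = TRUE), 30, 3)
    B <- matrix(sample(1:12, 90, replace = TRUE), 30, 3)
    expect_equal(directed_avg_distance(A, B),
                 mean(oracle_nn_dists(A, B)), tolerance = 1e-12)
    sp <- c(0.5, 0.5, 2)
    expect_equal(directed_avg_distance(A, B, sp),
                 mean(oracle_nn_dists(A, B, sp)), tolerance = 1e-12)
  }
  expect_equal(directed_avg_distance(A0, A0[0, , drop = FALSE]), Inf)
})

test_that("AVD and 95HD match brute-force oracles on random volumes", {
  p1 <- random_label_volume(c(10, 10, 6), 1, seed = 1)
  expect_equal(avd(p1, p1), 0)
  expect_equal(hd95(p1, p1), 0)
  # single displaced pair
  a <- array(0, c(8, 4, 4)); a[1, 1, 1] <- 1
  b <- array(0, c(8, 4, 4)); b[4, 1, 1] <- 1
  av <- binary_label_volume(a); bv <- binary_label_volume(b)
  expect_equal(avd(av, bv), 3)
  expect_equal(hd95(av, bv), 3)
  set.seed(52)
  for (i in 1:5) {
    P <- random_label_volume(c(12, 12, 8), 50, seed = 100 + i)
    G <- random_label_volume(c(12, 12, 8), 50, seed = 200 + i)
    cp <- which(P$data == 1, arr.ind = TRUE)
    cg <- which(G$data == 1, arr.ind = TRUE)
    expect_equal(avd(P, G), oracle_avd(cp, cg), tolerance = 1e-12)
    expect_equal(hd95(P, G), oracle_hd95(cp, cg), tolerance = 1e-12)
    # symmetry and ordering against the exact Hausdorff distance
    expect_equal(avd(P, G), avd(G, P))
    expect_equal(hd95(P, G), hd95(G, P))
    expect_lte(hd95(P, G), oracle_hd(cp, cg))
    expect_lte(avd(P, G), oracle_hd(cp, cg))
  }
})

test_that("degenerate foregrounds follow the stated conventions", {
  e <- binary_label_volume(array(0, c(4, 4, 2)))
  f <- random_label_volume(c(4, 4, 2), 3, seed = 3)
  expect_warning(z <- avd(e, e), "empty")
  expect_equal(z, 0)
  expect_warning(i1 <- avd(e, f), "Inf")
  expect_equal(i1, Inf)
  expect_warning(i2 <- hd95(f, e), "Inf")
  expect_equal(i2, Inf)
})

test_that("all five metrics are translation invariant", {
  set.seed(53)
  base_p <- array(0, c(16, 16, 8)); base_g <- array(0, c(16, 16, 8))
  base_p[3:6, 3:6, 2:4] <- rbinom(48, 1, 0.5)
  base_g[3:6, 3:6, 2:4] <- rbinom(48, 1, 0.5)
  shift <- function(arr, d) {
    out <- array(0, dim(arr))
    out[(1 + d[1]):16, (1 + d[2]):16, (1 + d[3]):8] <-
      arr[1:(16 - d[1]), 1:(16 - d[2]), 1:(8 - d[3])]
    out
  }
  r0 <- evaluate_segmentation(binary_label_volume(base_p),
                              binary_label_volume(base_g))
  r1 <- evaluate_segmentation(binary_label_volume(shift(base_p, c(5, 2, 3))),
                              binary_label_volume(shift(base_g, c(5, 2, 3))))
  for (m in c("dsc", "precision", "recall", "avd", "hd95"))
    expect_equal(r1[[m]], r0[[m]], tolerance = 1e-12)
})

test_that("the full report agrees with its component metrics", {
  P <- random_label_volume(c(10, 8, 6), 30, seed = 4)
  G <- random_label_volume(c(10, 8, 6), 25, seed = 5)
  rep <- evaluate_segmentation(P, G)
  cc <- confusion_counts(P, G)
  om <- overlap_metrics(cc)
  expect_equal(rep$dsc, om$dsc)
  expect_equal(rep$precision, om$precision)
  expect_equal(rep$recall, om$recall)
  expect_equal(rep$avd, avd(P, G))
  expect_equal(rep$hd95, hd95(P, G))
  expect_equal(rep$counts$TP + rep$counts$FP + rep$counts$FN +
                 rep$counts$TN, 480)
  df <- as.data.frame(rep)
  expect_named(df, c("dsc", "precision", "recall", "avd", "hd95",
                     "TP", "FP", "FN", "TN"))
})
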