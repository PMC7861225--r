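# Heuristic mask, patch-centre sampling, patch extraction, CV splits.

test_that("heuristic mask matches trivial constant cases", {
  v0 <- volume(array(0, c(20, 20, 20)))
  expect_true(all(compute_heuristic_mask(v0)$data == 0))
  v100 <- volume(array(100, c(20, 20, 20)))
  expect_true(all(compute_heuristic_mask(v100)$data == 1))
})

test_that("heuristic mask equals the brute-force box-mean oracle", {
  set.seed(3)
  for (w in c(4, 5)) {                    # even and odd windows
    arr <- array(0, c(12, 10, 8))
    arr[4:9, 3:7, 2:5] <- 160
    arr <- arr + array(runif(length(arr), 0, 5), dim(arr))
    v <- volume(arr)
    got <- compute_heuristic_mask(v, window = w, threshold = 10)
    want <- (oracle_boxmean(arr, w) > 10) * 1
    expect_identical(got$data, array(as.numeric(want), dim(arr)))
  }
})

test_that("raising the threshold never adds mask voxels", {
  set.seed(4)
  v <- volume(array(runif(16 * 16 * 16, 0, 40), c(16, 16, 16)))
  m5 <- compute_heuristic_mask(v, 4, 5)$data
  m10 <- compute_heuristic_mask(v, 4, 10)$data
  m20 <- compute_heuristic_mask(v, 4, 20)$data
  expect_true(all(m10 <= m5))
  expect_true(all(m20 <= m10))
})

test_that("mask parameter errors are raised", {
  v <- volume(array(0, c(8, 8, 8)))
  expect_error(compute_heuristic_mask(v, window = 16), "larger")
  expect_error(compute_heuristic_mask(v, window = 0), ">= 1")
})

test_that("patch centres respect mask membership and the vessel quota", {
  set.seed(5)
  lab <- array(0, c(16, 16, 8)); lab[8:9, 8, 4] <- 1
  mask <- array(0, c(16, 16, 8)); mask[4:13, 4:13, 2:7] <- 1
  labv <- binary_label_volume(lab); maskv <- binary_label_volume(mask)

  c0 <- sample_patch_centers(labv, maskv, n = 10, vessel_fraction = 0,
                             seed = 1)
  expect_equal(nrow(c0), 10)
  expect_true(all(mask[as.matrix(c0[, 1:3])] == 1))

  # only 2 vessel voxels: quota of 4 forces sampling with replacement
  c1 <- sample_patch_centers(labv, maskv, n = 4, vessel_fraction = 1,
                             seed = 2)
  expect_equal(nrow(c1), 4)
  expect_true(all(lab[as.matrix(c1[, 1:3])] == 1))

  c2 <- sample_patch_centers(labv, maskv, n = 50, vessel_fraction = 0.5,
                             seed = 3)
  expect_equal(sum(c2$is_vessel_centric), 25)

  expect_identical(sample_patch_centers(labv, maskv, 20, 0.5, seed = 9),
                   sample_patch_centers(labv, maskv, 20, 0.5, seed = 9))
})

test_that("degenerate sampling inputs raise data errors", {
  lab0 <- binary_label_volume(array(0, c(8, 8, 4)))
  mask <- binary_label_volume(array(1, c(8, 8, 4)))
  expect_error(sample_patch_centers(lab0, mask, 10, 0.5, 1), "no vessel")
  mask0 <- binary_label_volume(array(0, c(8, 8, 4)))
  expect_error(sample_patch_centers(lab0, mask0, 10, 0, 1), "empty mask")
  lab_s <- binary_label_volume(array(0, c(4, 4, 4)))
  expect_error(sample_patch_centers(lab_s, mask, 10, 0, 1), "shape")
})

test_that("extract_patch crops, pads and nests consistently", {
  set.seed(6)
  v <- volume(array(rnorm(32 * 32 * 16), c(32, 32, 16)))
  # pure crop at the exact middle: centre occupies index size/2 (0-based)
  p <- extract_patch(v, c(16, 16, 8), c(8, 8, 4))
  expect_identical(p, v$data[12:19, 12:19, 6:9])
  # corner: leading halves are padding
  q <- extract_patch(v, c(1, 1, 1), c(8, 8, 4), pad_value = -1)
  expect_true(all(q[1:4, , ] == -1))
  expect_true(all(q[, 1:4, ] == -1))
  expect_true(all(q[, , 1:2] == -1))
  expect_identical(q[5:8, 5:8, 3:4], v$data[1:4, 1:4, 1:2])
  # nesting: central crop of the context equals the primary patch
  for (ctr in list(c(16, 16, 8), c(2, 30, 3), c(31, 1, 16))) {
    big <- extract_patch(v, ctr, c(16, 16, 8))
    small <- extract_patch(v, ctr, c(8, 8, 4))
    expect_identical(big[5:12, 5:12, 3:6], small)
  }
  expect_error(extract_patch(v, c(0, 1, 1), c(4, 4, 4)), "outside")
  expect_error(extract_patch(v, c(33, 1, 1), c(4, 4, 4)), "outside")
})

test_that("stratified 4-fold splits reproduce the 170/29/65 arithmetic", {
  sp <- make_cv_splits(c(A = 74, B = 9, C = 181), folds = 4,
                       val_fraction = 0.15, seed = 1)
  expect_length(sp, 4)
  for (f in sp) {
    expect_length(f$test, 65)
    expect_length(f$val, 29)
    expect_length(f$train, 170)
    expect_length(intersect(f$train, f$val), 0)
    expect_length(intersect(f$train, f$test), 0)
    expect_length(intersect(f$val, f$test), 0)
    src <- table(f$source_of[f$test])
    expect_equal(unname(src[c("A", "B", "C")]), c(18, 2, 45),
                 ignore_attr = TRUE)
  }
  # each id appears in at most one test set; floor remainders never tested
  all_test <- unlist(lapply(sp, `[[`, "test"))
  expect_false(any(duplicated(all_test)))
  expect_length(all_test, 4 * (18 + 2 + 45))
})

test_that("small-cohort splits follow the stated floor rules", {
  sp <- make_cv_splits(c(A = 4), folds = 4, val_fraction = 0, seed = 2)
  for (f in sp) {
    expect_length(f$test, 1)
    expect_length(f$train, 3)
    expect_length(f$val, 0)
  }
  sp2 <- make_cv_splits(c(A = 8, B = 8), folds = 4, val_fraction = 0.25,
                        seed = 3)
  for (f in sp2) {
    expect_length(f$test, 4)
    expect_length(f$val, 3)
    expect_length(f$train, 9)
  }
  expect_identical(make_cv_splits(c(A = 8, B = 8), seed = 7),
                   make_cv_splits(c(A = 8, B = 8), seed = 7))
  expect_error(make_cv_splits(c(A = 8), val_fraction = 1), "val_fraction")
  expect_error(make_cv_splits(c(A = 8), folds = 1), "folds")
})
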