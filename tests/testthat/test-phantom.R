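# Synthetic vascular phantom generator.

test_that("vessel trees are deterministic, rooted and tapering", {
  spec <- tiny_phantom_spec()
  t1 <- generate_vessel_tree(spec, seed = 1)
  t2 <- generate_vessel_tree(spec, seed = 1)
  expect_identical(t1, t2)
  spec0 <- tiny_phantom_spec(branch_prob = 0)
  tr <- generate_vessel_tree(spec0, seed = 2)
  expect_length(tr$polylines, 1)          # no branching: one polyline
  # radius tapers monotonically from root to leaves, across many trees
  for (s in 1:20) {
    tr <- generate_vessel_tree(spec, seed = s)
    root_r <- tr$polylines[[1]][1, 4]
    for (pl in tr$polylines) {
      expect_true(all(diff(pl[, 4]) <= 1e-12))
      expect_lte(pl[1, 4], root_r)
      expect_gte(min(pl[, 4]), spec$radius_range[1] * 0.97)
    }
  }
})

test_that("rasterisation matches a point-in-cylinder test for a tube", {
  shape <- c(24L, 12L, 12L)
  tube <- structure(list(polylines = list(cbind(
    x = c(4, 20), y = c(6.5, 6.5), z = c(6.5, 6.5), r = c(2, 2))),
    shape = shape), class = "vessel_tree")
  lab <- rasterize_tree(tube, shape)
  want <- array(0, shape)
  for (x in 1:24) for (y in 1:12) for (z in 1:12) {
    t <- min(max((x - 4) / 16, 0), 1)
    px <- 4 + 16 * t
    d <- sqrt((x - px)^2 + (y - 6.5)^2 + (z - 6.5)^2)
    if (d <= 2) want[x, y, z] <- 1
  }
  expect_identical(lab$data, want)
  # a minimum-radius tube yields a thin connected chain
  thin <- structure(list(polylines = list(cbind(
    x = c(4, 20), y = c(6, 6), z = c(6, 6), r = c(0.5, 0.5))),
    shape = shape), class = "vessel_tree")
  thin_lab <- rasterize_tree(thin, shape)
  per_slice <- apply(thin_lab$data[5:19, , ], 1, sum)
  expect_true(all(per_slice >= 1 & per_slice <= 4))
  # empty tree
  empty <- structure(list(polylines = list(), shape = shape),
                     class = "vessel_tree")
  expect_true(all(rasterize_tree(empty, shape)$data == 0))
})

test_that("synthesised volumes support heuristic mask separation", {
  # full-size phantoms: the 16-voxel mask window needs air margins around
  # the head that the miniature test spec does not provide
  spec <- phantom_spec()
  dat <- generate_dataset(2, spec, seed = 3)
  rho <- angioseg:::phantom_rho(spec$shape)
  # pure-air voxels: those whose whole 16-window contains no head/shell
  # voxel (the mask is designed to keep a thick border band around the
  # skull, so only windows of pure air must be excluded)
  head_ind <- array(as.numeric(rho <= 1.12), spec$shape)
  pure_air <- angioseg:::cpp_boxmean(head_ind, spec$shape, 16) == 0
  expect_gt(mean(pure_air), 0.05)   # the check must have material support
  for (e in dat) {
    mask <- compute_heuristic_mask(e$volume)
    # the mask keeps essentially the whole head region...
    expect_gt(mean(mask$data[rho <= 1]), 0.99)
    # ...and excludes at least 95% of pure-air windows
    expect_lt(mean(mask$data[pure_air]), 0.05)
    # vessel fraction within the head stays in a plausible bracket
    expect_gte(e$vessel_fraction, 0.003)
    expect_lte(e$vessel_fraction, 0.05)
    # intensity ordering: vessels > tissue > air
    tissue <- rho <= 1 & e$labels$data == 0
    air <- rho > 1.3
    expect_gt(mean(e$volume$data[e$labels$data == 1]),
              mean(e$volume$data[tissue]))
    expect_gt(mean(e$volume$data[tissue]), mean(e$volume$data[air]))
  }
})

test_that("distractors are never labelled as vessel", {
  spec <- tiny_phantom_spec()
  for (s in 4:6) {
    lab <- angioseg:::phantom_labels(spec, seed = s)
    vol <- synthesize_volume(lab, spec, seed = s + 100)
    # voxels at distractor-like intensity that are labelled must all be
    # vessels; distractor blobs themselves carry label 0 by construction,
    # so the bright unlabelled voxel count must be substantial
    bright_unlabelled <- vol$data > 200 & lab$data == 0
    expect_gt(sum(bright_unlabelled), 50)
    # vessel voxels sit near the vessel mean, not the distractor mean
    expect_gt(mean(vol$data[lab$data == 1]), 250)
  }
})

test_that("dataset generation tags sources round-robin and varies seeds", {
  spec <- tiny_phantom_spec()
  dat <- generate_dataset(4, spec, seed = 9, sources = c("A", "B"))
  expect_equal(vapply(dat, `[[`, "", "source"), c("A", "B", "A", "B"))
  # distinct items are genuinely distinct volumes
  hashes <- vapply(dat, function(e) paste(sum(e$volume$data),
                                          sum(e$labels$data)), "")
  expect_false(any(duplicated(hashes)))
  # same master seed reproduces the dataset
  dat2 <- generate_dataset(4, spec, seed = 9, sources = c("A", "B"))
  expect_identical(dat[[2]]$volume$data, dat2[[2]]$volume$data)
  # invariants of every generated pair
  for (e in dat) {
    expect_s3_class(e$volume, "volume")
    expect_s3_class(e$labels, "binary_label_volume")
    expect_identical(dim(e$volume$data), dim(e$labels$data))
  }
})

test_that("phantom specification guards its physical brackets", {
  expect_error(tiny_phantom_spec(target_vessel_fraction = 0.2),
               "physiological")
  expect_error(phantom_spec(radius_range = c(0.2, 2)), "0.5")
  expect_error(phantom_spec(intensities = list(air = 50, tissue = 80,
                                               vessel = 300, skull = 120,
                                               distractor = 250)),
               "air")
})
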