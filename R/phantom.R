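# Synthetic TOF-like vascular phantoms: branching tubular trees inside an
# ellipsoidal head with a bright skull shell, bright non-vessel
# distractors, and Gaussian noise. Every stage of the framework is
# testable on these volumes with no external data.

#' Phantom specification
#'
#' Geometry and intensity constants of the synthetic volumes. The
#' defaults emulate the salient properties of head angiography: sparse
#' tubular foreground (vessel fraction within the head in the
#' physiological bracket 0.3-1.5%), near-zero air around a bright head
#' region (so an intensity-10 threshold separates them), a bright border
#' shell as skull analogue, and bright non-vessel distractor structures
#' (sinus/extracranial analogues) that are deliberately NOT labelled.
#'
#' @param shape volume shape (default `c(128, 128, 32)`).
#' @param voxel_size voxel spacing in mm (default `c(0.5, 0.5, 0.65)`).
#' @param n_trees vessel trees grown initially; more are added until the
#'   target vessel fraction is reached.
#' @param radius_range root/minimum tube radius in voxels (min >= 0.5).
#' @param branch_prob per-step probability of spawning a side branch.
#' @param target_vessel_fraction target vessel fraction of head voxels,
#'   within `[0.003, 0.015]`.
#' @param intensities named list of mean intensities: `air`, `tissue`,
#'   `vessel`, `skull`, `distractor`.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param n_distractors number of bright unlabelled blobs.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128, 128, 32),
                         voxel_size = c(0.5, 0.5, 0.65),
                         n_trees = 3, radius_range = c(0.8, 3),
                         branch_prob = 0.08,
                         target_vessel_fraction = 0.008,
                         intensities = list(air = 2, tissue = 80,
                                            vessel = 300, skull = 120,
                                            distractor = 250),
                         noise_sd = 5, n_distractors = 4) {
  shape <- as.integer(unlist(shape))
  voxel_size <- as.numeric(unlist(voxel_size))
  radius_range <- as.numeric(unlist(radius_range))
  if (radius_range[1] < 0.5)
    stop("minimum radius must be >= 0.5 voxel", call. = FALSE)
  if (target_vessel_fraction < 0.003 || target_vessel_fraction > 0.015)
    stop("target_vessel_fraction outside the physiological bracket ",
         "[0.003, 0.015]", call. = FALSE)
  with(intensities, {
    if (!(vessel > tissue && tissue > 10 && 10 > air))
      stop("need vessel mean > tissue mean > threshold 10 > air mean",
           call. = FALSE)
  })
  structure(list(shape = shape, voxel_size = voxel_size,
                 n_trees = n_trees, radius_range = radius_range,
                 branch_prob = branch_prob,
                 target_vessel_fraction = target_vessel_fraction,
                 intensities = intensities, noise_sd = noise_sd,
                 n_distractors = n_distractors),
            class = "phantom_spec")
}

# Normalised ellipsoid radius of every voxel: rho <= 1 is head tissue,
# 1 < rho <= 1.12 the skull shell, rho > 1.12 air. Semi-axes are 0.44 of
# the shape so the shell still fits inside the field of view (an inscribed
# ellipsoid can occupy at most ~52% of the volume).
phantom_rho <- function(shape) {
  ctr <- (shape + 1) / 2
  semi <- 0.44 * shape
  x2 <- ((seq_len(shape[1]) - ctr[1]) / semi[1])^2
  y2 <- ((seq_len(shape[2]) - ctr[2]) / semi[2])^2
  z2 <- ((seq_len(shape[3]) - ctr[3]) / semi[3])^2
  sqrt(outer(outer(x2, y2, `+`), z2, `+`))
}

rho_at <- function(pos, shape) {
  ctr <- (shape + 1) / 2
  semi <- 0.44 * shape
  sqrt(sum(((pos - ctr) / semi)^2))
}

rand_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v * v))
}

#' Grow a stochastic vessel tree
#'
#' A rooted branching tree grown by a direction-persistent random walk
#' inside the head ellipsoid. The tube radius tapers monotonically from
#' root to leaves (per-step taper 0.97, branch factor 0.7); branches stop
#' at the minimum radius or near the head boundary.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed; the tree is deterministic under it.
#' @return An object of class `vessel_tree`: a list with `polylines`, each
#'   an `n x 4` matrix of centreline nodes `(x, y, z, r)` (the first node
#'   of a child polyline is its fork point on the parent).
#' @export
generate_vessel_tree <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  r_min <- spec$radius_range[1]; r_max <- spec$radius_range[2]
  with_seed(seed, {
    polylines <- list()
    # each queue item: start position, direction, start radius
    root <- (shape + 1) / 2 + 0.5 * 0.44 * shape * rand_unit() *
      runif(1, 0, 0.9)
    queue <- list(list(pos = root, dir = rand_unit(), r = r_max))
    n_nodes <- 0L
    while (length(queue) > 0L && n_nodes < 4000L) {
      it <- queue[[1L]]; queue <- queue[-1L]
      pos <- it$pos; dir <- it$dir; r <- it$r
      nodes <- matrix(c(pos, r), 1L, 4L)
      for (step in seq_len(300L)) {
        dir <- 0.75 * dir + 0.25 * rand_unit()
        dir <- dir / sqrt(sum(dir * dir))
        pos <- pos + 2 * dir
        r <- r * 0.97
        if (r < r_min || rho_at(pos, shape) > 0.92) break
        nodes <- rbind(nodes, c(pos, r))
        if (runif(1) < spec$branch_prob && r * 0.7 >= r_min)
          queue <- c(queue, list(list(pos = pos, dir = rand_unit(),
                                      r = r * 0.7)))
      }
      n_nodes <- n_nodes + nrow(nodes)
      if (nrow(nodes) >= 2L)
        polylines[[length(polylines) + 1L]] <- nodes
    }
    structure(list(polylines = polylines, shape = shape),
              class = "vessel_tree")
  })
}

#' Rasterise a vessel tree into a binary label volume
#'
#' A voxel is labelled 1 iff its centre lies within the local
#' (linearly interpolated) tube radius of any centreline segment.
#'
#' @param tree a `vessel_tree` (or a list of them).
#' @param shape volume shape.
#' @param voxel_size spacing recorded on the output volume.
#' @return A [binary_label_volume()].
#' @export
rasterize_tree <- function(tree, shape, voxel_size = c(1, 1, 1)) {
  shape <- as.integer(shape)
  lab <- array(0, shape)
  trees <- if (inherits(tree, "vessel_tree")) list(tree) else tree
  for (tr in trees) for (pl in tr$polylines) {
    if (nrow(pl) < 2L) next
    for (s in seq_len(nrow(pl) - 1L)) {
      p0 <- pl[s, 1:3]; p1 <- pl[s + 1L, 1:3]
      r0 <- pl[s, 4]; r1 <- pl[s + 1L, 4]
      rmax <- max(r0, r1)
      lo <- pmax(floor(pmin(p0, p1) - rmax), 1)
      hi <- pmin(ceiling(pmax(p0, p1) + rmax), shape)
      if (any(lo > hi)) next
      gx <- lo[1]:hi[1]; gy <- lo[2]:hi[2]; gz <- lo[3]:hi[3]
      g <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
      d <- p1 - p0; dd <- sum(d * d)
      rel <- sweep(g, 2, p0)
      t <- if (dd == 0) rep(0, nrow(g)) else
        pmin(pmax(as.numeric(rel %*% d) / dd, 0), 1)
      dist <- sqrt(rowSums((rel - outer(t, d))^2))
      rad <- r0 + t * (r1 - r0)
      inside <- dist <= rad
      if (any(inside))
        lab[g[inside, , drop = FALSE]] <- 1
    }
  }
  binary_label_volume(lab, voxel_size)
}

# Vessel labels at the target foreground fraction: grow trees until the
# vessel fraction within the head reaches the specified target.
phantom_labels <- function(spec, seed = 1L) {
  shape <- spec$shape
  head_n <- sum(phantom_rho(shape) <= 1)
  lab <- array(0, shape)
  k <- 0L
  repeat {
    k <- k + 1L
    tr <- generate_vessel_tree(spec, seed = seed * 131L + k)
    lab <- pmax(lab, rasterize_tree(tr, shape, spec$voxel_size)$data)
    frac <- sum(lab) / head_n
    if ((k >= spec$n_trees && frac >= spec$target_vessel_fraction) ||
        k >= 60L)
      break
  }
  binary_label_volume(lab, spec$voxel_size)
}

#' Synthesise an intensity volume around vessel labels
#'
#' Paints the air background, the ellipsoidal tissue head, the skull
#' shell, bright unlabelled distractor blobs and the vessels themselves,
#' then adds Gaussian noise and clips at zero.
#'
#' @param labels a [binary_label_volume()] of vessel ground truth.
#' @param spec a [phantom_spec()] whose shape matches `labels`.
#' @param seed integer seed.
#' @return A [volume()].
#' @export
synthesize_volume <- function(labels, spec, seed = 1L) {
  stopifnot(inherits(labels, "binary_label_volume"),
            inherits(spec, "phantom_spec"))
  shape <- spec$shape
  if (!identical(dim(labels$data), shape))
    stop("labels shape does not match spec shape", call. = FALSE)
  ints <- spec$intensities
  rho <- phantom_rho(shape)
  with_seed(seed, {
    img <- array(ints$air, shape)
    img[rho <= 1.12] <- ints$skull
    img[rho <= 1] <- ints$tissue
    # bright blobs inside the head, never labelled as vessel
    for (i in seq_len(spec$n_distractors)) {
      ctr <- (shape + 1) / 2 + 0.44 * shape * rand_unit() * runif(1, 0, 0.75)
      semi <- runif(3, 2, 5)
      lo <- pmax(floor(ctr - semi), 1); hi <- pmin(ceiling(ctr + semi), shape)
      g <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2],
                                 z = lo[3]:hi[3]))
      rel2 <- sweep(g, 2, ctr)^2
      inside <- as.numeric(rel2 %*% (1 / semi^2)) <= 1
      sel <- g[inside & labels$data[g] == 0, , drop = FALSE]
      if (nrow(sel) > 0) img[sel] <- ints$distractor
    }
    img[labels$data == 1] <- ints$vessel
    img <- img + array(rnorm(length(img), 0, spec$noise_sd), shape)
    img[img < 0] <- 0
    volume(img, spec$voxel_size)
  })
}

#' Generate a phantom dataset
#'
#' `n` independent phantom pairs, round-robin-tagged across synthetic
#' source cohorts (emulating multi-cohort stratification). Optionally
#' written to disk as NIfTI pairs plus a manifest CSV.
#'
#' @param n number of volumes.
#' @param spec a [phantom_spec()].
#' @param seed integer seed; item `i` derives its own seed from it.
#' @param sources character vector of synthetic source tags.
#' @param dir optional output directory for `<id>_tof.nii.gz`,
#'   `<id>_label.nii.gz` and `manifest.csv`.
#' @return A list of entries with `id`, `source`, `volume`, `labels` and
#'   `vessel_fraction` (of head voxels).
#' @export
generate_dataset <- function(n, spec = phantom_spec(), seed = 1L,
                             sources = c("A", "B"), dir = NULL) {
  stopifnot(n >= 1)
  head_n <- sum(phantom_rho(spec$shape) <= 1)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    item_seed <- seed * 1009L + i
    labels <- phantom_labels(spec, seed = item_seed)
    vol <- synthesize_volume(labels, spec, seed = item_seed + 500000L)
    id <- sprintf("phantom%03d", i)
    out[[i]] <- list(id = id,
                     source = sources[(i - 1L) %% length(sources) + 1L],
                     volume = vol, labels = labels,
                     vessel_fraction = sum(labels$data) / head_n)
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (e in out) {
      write_volume(e$volume, file.path(dir, paste0(e$id, "_tof.nii.gz")))
      write_volume(e$labels, file.path(dir, paste0(e$id, "_label.nii.gz")))
    }
    manifest <- do.call(rbind, lapply(out, function(e)
      data.frame(id = e$id, source = e$source, seed = seed,
                 vessel_fraction = e$vessel_fraction)))
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  out
}
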