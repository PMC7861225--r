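# Independent brute-force oracles used across the suite. These are
# deliberately naive (triple loops, full distance matrices) and never share
# code with the implementation they check.

# Sliding box-mean with replicate padding; window w covers offsets
# -floor(w/2) .. w-1-floor(w/2) per axis.
oracle_boxmean <- function(arr, w) {
  d <- dim(arr)
  lo <- w %/% 2; hi <- w - 1 - w %/% 2
  out <- array(0, d)
  cl <- function(i, n) pmin(pmax(i, 1), n)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    s <- 0
    for (dx in -lo:hi) for (dy in -lo:hi) for (dz in -lo:hi)
      s <- s + arr[cl(x + dx, d[1]), cl(y + dy, d[2]), cl(z + dz, d[3])]
    out[x, y, z] <- s / w^3
  }
  out
}

# Zero-padded stride-1 3x3x3 convolution; W indexed [offset, cin, cout]
# with offset o = (dx+1) + 3*(dy+1) + 9*(dz+1) + 1.
oracle_conv3 <- function(arr4, W, b) {
  d <- dim(arr4)[1:3]; cin <- dim(arr4)[4]; cout <- length(b)
  out <- array(0, c(d, cout))
  for (co in 1:cout) for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    s <- b[co]
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      xx <- x + dx; yy <- y + dy; zz <- z + dz
      if (xx >= 1 && xx <= d[1] && yy >= 1 && yy <= d[2] &&
          zz >= 1 && zz <= d[3]) {
        o <- (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1) + 1
        for (ci in 1:cin)
          s <- s + arr4[xx, yy, zz, ci] * W[o, ci, co]
      }
    }
    out[x, y, z, co] <- s
  }
  out
}

# Directed mean / percentile nearest-neighbour distances by full double loop.
oracle_nn_dists <- function(A, B, spacing = c(1, 1, 1)) {
  vapply(seq_len(nrow(A)), function(i) {
    min(sqrt(colSums((t(B) * spacing - A[i, ] * spacing)^2)))
  }, 0)
}

oracle_avd <- function(P, G, spacing = c(1, 1, 1)) {
  max(mean(oracle_nn_dists(P, G, spacing)),
      mean(oracle_nn_dists(G, P, spacing)))
}

oracle_hd95 <- function(P, G, spacing = c(1, 1, 1)) {
  max(quantile(oracle_nn_dists(P, G, spacing), 0.95, names = FALSE),
      quantile(oracle_nn_dists(G, P, spacing), 0.95, names = FALSE))
}

oracle_hd <- function(P, G, spacing = c(1, 1, 1)) {
  max(oracle_nn_dists(P, G, spacing), oracle_nn_dists(G, P, spacing))
}

# Closed-form trainable-parameter count from the layer recipe:
# 27*cin*cout + cout per 3x3x3 convolution, cin*cout + cout per 1x1x1
# convolution, 2*c per batch-norm layer.
oracle_param_count <- function(variant, base_width = 32, levels = 4,
                               fc_width = 8 * base_width) {
  w <- base_width * 2^(0:(levels - 1))
  paths <- if (variant %in% c("context", "bravenet")) 2 else 1
  enc <- 0
  for (l in 1:levels) {
    cin <- if (l == 1) 1 else w[l - 1]
    enc <- enc + (27 * cin * w[l] + w[l]) + 2 * w[l] +
      (27 * w[l] * w[l] + w[l]) + 2 * w[l]
  }
  total <- paths * (2 + enc)                      # input BN per path
  cb <- w[levels] * paths
  total <- total + (cb * fc_width + fc_width) +
    (fc_width * fc_width + fc_width)
  for (l in (levels - 1):1) {
    up <- if (l == levels - 1) fc_width else w[l + 1]
    cin <- up + w[l] * paths
    total <- total + (27 * cin * w[l] + w[l]) + 2 * w[l] +
      (27 * w[l] * w[l] + w[l]) + 2 * w[l]
  }
  if (variant %in% c("ds", "bravenet"))
    for (l in (levels - 1):2) total <- total + w[l] + 1
  total + w[1] + 1
}

# Small binary volumes with a given number of foreground voxels.
random_label_volume <- function(shape, n_fg, seed) {
  set.seed(seed)
  arr <- array(0, shape)
  arr[sample(prod(shape), n_fg)] <- 1
  binary_label_volume(arr)
}

# Tiny architecture used throughout the unit tests.
tiny_arch <- function(variant, base_width = 2, dropout_rate = 0.1) {
  architecture_config(variant, base_width = base_width,
                      dropout_rate = dropout_rate,
                      primary_patch = c(16, 16, 8),
                      context_patch = c(32, 32, 16))
}

# Small phantom specification for fast tests.
tiny_phantom_spec <- function(...) {
  phantom_spec(shape = c(48, 48, 16), n_trees = 2,
               radius_range = c(0.6, 2), n_distractors = 2, ...)
}
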