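# Numerical kernels of the network engine: convolution against a
# brute-force oracle, pooling/upsampling adjoints, and end-to-end
# backpropagation against finite differences.

conv_fw <- angioseg:::cpp_conv3_fw
conv_bw <- angioseg:::cpp_conv3_bw

test_that("3-D convolution matches the brute-force oracle", {
  set.seed(11)
  d <- c(5L, 4L, 3L); cin <- 2L; cout <- 3L; B <- 2L
  arrs <- lapply(1:B, function(i) array(rnorm(prod(d) * cin), c(d, cin)))
  X <- do.call(rbind, lapply(arrs, function(a) matrix(a, ncol = cin)))
  W <- matrix(rnorm(27 * cin * cout), 27 * cin, cout)
  b <- rnorm(cout)
  got <- conv_fw(X, d, B, W, b)
  # W rows are offset-major: row (o-1)*cin + ci  <->  oracle W[o, ci, co]
  Wo <- array(0, c(27, cin, cout))
  for (o in 1:27) for (ci in 1:cin)
    Wo[o, ci, ] <- W[(o - 1) * cin + ci, ]
  for (i in 1:B) {
    want <- oracle_conv3(arrs[[i]], Wo, b)
    rows <- ((i - 1) * prod(d) + 1):(i * prod(d))
    expect_equal(got[rows, ], matrix(want, ncol = cout), tolerance = 1e-5)
  }
})

test_that("convolution backward is the adjoint of forward", {
  set.seed(12)
  d <- c(4L, 4L, 2L); cin <- 3L; cout <- 2L; B <- 2L
  n <- prod(d) * B
  X <- matrix(rnorm(n * cin), n, cin)
  W <- matrix(rnorm(27 * cin * cout), 27 * cin, cout)
  dY <- matrix(rnorm(n * cout), n, cout)
  fw <- conv_fw(X, d, B, W, rep(0, cout))
  bw <- conv_bw(X, d, B, W, dY)
  # <conv(X), dY> == <X, dX> for the linear (bias-free) map
  expect_equal(sum(fw * dY), sum(X * bw$dX), tolerance = 1e-4)
  # dW check: <conv(X; W), dY> == <W, dW>
  expect_equal(sum(fw * dY), sum(W * bw$dW), tolerance = 1e-4)
})

test_that("pooling and upsampling behave as exact local operators", {
  set.seed(13)
  d <- c(4L, 4L, 2L); B <- 2L
  X <- matrix(rnorm(prod(d) * B * 3), prod(d) * B, 3)
  mp <- angioseg:::cpp_maxpool_fw(X, d, B)
  # every output is the max over its 2x2x2 block
  a1 <- array(X[1:prod(d), 1], d)
  expect_equal(mp$out[1, 1], max(a1[1:2, 1:2, 1:2]))
  expect_equal(mp$out[2, 1], max(a1[3:4, 1:2, 1:2]))
  # backward routes gradient to the argmax only
  dY <- matrix(0, nrow(mp$out), 3); dY[1, 1] <- 5
  dX <- angioseg:::cpp_maxpool_bw(dY, mp$idx, nrow(X))
  expect_equal(sum(dX != 0), 1)
  expect_equal(sum(dX), 5)

  ap <- angioseg:::cpp_avgpool_fw(X, d, B)
  expect_equal(ap[1, 2], mean(array(X[1:prod(d), 2], d)[1:2, 1:2, 1:2]))

  up <- angioseg:::cpp_upsample_fw(X, d, B)
  expect_equal(nrow(up), 8 * nrow(X))
  a2 <- array(up[1:(8 * prod(d)), 1], 2L * d)
  expect_equal(a2[1:2, 1:2, 1:2], array(a1[1, 1, 1], c(2, 2, 2)))
  # adjoint identity for upsampling
  dY2 <- matrix(rnorm(8 * prod(d) * B * 3), 8 * prod(d) * B, 3)
  dX2 <- angioseg:::cpp_upsample_bw(dY2, d, B)
  expect_equal(sum(up * dY2), sum(X * dX2), tolerance = 1e-10)
})

test_that("backpropagation matches finite differences through every layer", {
  set.seed(21)
  cfg <- architecture_config("bravenet", base_width = 2,
                             primary_patch = c(8, 8, 8),
                             context_patch = c(16, 16, 16),
                             dropout_rate = 0)
  net <- build_network(cfg, seed = 3)
  B <- 2L; dims_p <- c(8L, 8L, 8L); dims_c <- c(16L, 16L, 16L)
  nvox <- prod(dims_p)
  Xp <- matrix(rnorm(B * nvox, 100, 50), ncol = 1)
  Xc <- matrix(rnorm(B * prod(dims_c), 100, 50), ncol = 1)
  G <- matrix(rbinom(B * nvox, 1, 0.1), ncol = 1)
  w <- ds_weights(3)
  loss_of <- function(net) {
    fw <- angioseg:::net_forward(net, Xp, dims_p, B, Xc, dims_c,
                                 train = TRUE)
    tot <- 0
    for (b in 1:B) {
      rows <- ((b - 1) * nvox + 1):(b * nvox)
      for (i in seq_along(w))
        tot <- tot + w[i] *
          (1 - soft_dsc(fw$heads[[i]][rows, 1], G[rows, 1])) / B
    }
    tot
  }
  fw <- angioseg:::net_forward(net, Xp, dims_p, B, Xc, dims_c,
                               train = TRUE, keep_cache = TRUE)
  lg <- angioseg:::batch_loss_and_grads(fw$heads, G, nvox, B, w, 1)
  grads <- angioseg:::net_backward(net, fw, lg$dheads, dims_p, B)
  check <- c("enc.p.1.conv1.W", "enc.c.2.conv2.W", "in_bn.p.gamma",
             "in_bn.c.beta", "fc1.W", "dec.3.conv1.W", "dec.1.conv2.W",
             "head.2.W", "head.3.W", "final.W", "enc.p.3.bn1.gamma",
             "dec.2.bn2.beta", "enc.c.1.conv1.b")
  # step and floor sized for the single-precision forward accumulation
  h <- 1e-3
  for (nm in check) {
    ks <- sample(length(net$params[[nm]]), min(2, length(net$params[[nm]])))
    for (k in ks) {
      n2 <- net; n2$params[[nm]][k] <- n2$params[[nm]][k] + h
      n3 <- net; n3$params[[nm]][k] <- n3$params[[nm]][k] - h
      fd <- (loss_of(n2) - loss_of(n3)) / (2 * h)
      an <- grads[[nm]][k]
      expect_lt(abs(fd - an), 0.08 * max(abs(fd), abs(an)) + 3e-3,
                label = sprintf("gradient of %s[%d] (fd %.3g, bp %.3g)",
                                nm, k, fd, an))
    }
  }
})

test_that("dropout masks are applied only in training mode", {
  cfg <- tiny_arch("unet", base_width = 2, dropout_rate = 0.5)
  net <- build_network(cfg, seed = 4)
  x <- array(rnorm(16 * 16 * 8, 100, 30), c(16, 16, 8))
  # inference is deterministic
  p1 <- predict_patch(net, x)[[1]]
  p2 <- predict_patch(net, x)[[1]]
  expect_identical(p1, p2)
  # training forwards differ across RNG draws through dropout
  X <- matrix(as.numeric(x), ncol = 1)
  set.seed(1)
  f1 <- angioseg:::net_forward(net, X, c(16L, 16L, 8L), 1L, train = TRUE)
  f2 <- angioseg:::net_forward(net, X, c(16L, 16L, 8L), 1L, train = TRUE)
  expect_false(identical(f1$heads[[1]], f2$heads[[1]]))
})
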