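# The four network variants: baseline U-Net, context (dual-encoder
# multiscale) variant, deeply supervised variant, and their combination.
#
# The engine is a hand-written static computation graph over the C++
# kernels in src/ops.cpp: stride-1 zero-padded 3x3x3 convolutions (im2col +
# GEMM), 2x2x2 max/average pooling, parameter-free nearest-neighbour
# upsampling, batch normalisation, ReLU and sigmoid. Tensors are
# (batch * nvox) x channels matrices, voxel index x-fastest.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

#' Architecture configuration
#'
#' Declarative description of one of the four network variants. All
#' variants share a 4-level encoder-decoder backbone: two (conv 3x3x3 ->
#' ReLU -> batch-norm) sequences per level (dropout after the first
#' batch-norm of each encoder level), 2x2x2 max-pooling between encoder
#' levels, channel width doubling per level, a bottom level followed by two
#' fully connected layers realised as 1x1x1 convolutions, a decoder
#' mirroring the encoder with parameter-free nearest-neighbour upsampling
#' and skip concatenation, and a final 1x1x1 convolution with sigmoid. An
#' initial batch-normalisation layer is applied to the raw input of every
#' encoder path, so the networks consume raw unnormalised intensities.
#'
#' Variants: `"context"` and `"bravenet"` add a second, parameter-disjoint
#' encoder fed with the 2x2x2 average-pooled context patch (twice the
#' primary edge length, brought to primary dimensions at half resolution);
#' its per-level feature maps join the skip concatenations and its bottom
#' output is concatenated with the primary bottom before the 1x1x1 layers.
#' `"ds"` and `"bravenet"` add deep supervision: each intermediate decoder
#' level is upsampled to output resolution and passed through its own
#' 1x1x1 convolution + sigmoid head.
#'
#' @param variant one of `"unet"`, `"context"`, `"ds"`, `"bravenet"`.
#' @param levels number of resolution levels (default 4).
#' @param base_width channels of the first level (default 32); widths
#'   double per level.
#' @param dropout_rate encoder dropout rate (default 0.1).
#' @param primary_patch primary/label patch shape, each axis divisible by
#'   `2^(levels - 1)`.
#' @param context_patch context patch shape, exactly `2 * primary_patch`.
#' @param fc_width channels of the two bottom 1x1x1 layers (default
#'   `8 * base_width`, i.e. 256 at base width 32).
#' @return An object of class `architecture_config`.
#' @export
architecture_config <- function(variant = c("unet", "context", "ds",
                                            "bravenet"),
                                levels = 4, base_width = 32,
                                dropout_rate = 0.1,
                                primary_patch = c(64, 64, 8),
                                context_patch = 2 * primary_patch,
                                fc_width = 8 * base_width) {
  variant <- match.arg(variant)
  levels <- as.integer(levels); base_width <- as.integer(base_width)
  primary_patch <- as.integer(unlist(primary_patch))
  context_patch <- as.integer(unlist(context_patch))
  if (levels < 2) stop("levels must be >= 2", call. = FALSE)
  if (base_width < 1) stop("base_width must be >= 1", call. = FALSE)
  if (!identical(context_patch, 2L * primary_patch))
    stop("context_patch must be 2 x primary_patch per axis", call. = FALSE)
  if (any(primary_patch %% 2L^(levels - 1L) != 0L))
    stop("primary_patch must be divisible by 2^(levels-1) per axis; got (",
         paste(primary_patch, collapse = ", "), ") with ", levels,
         " levels", call. = FALSE)
  structure(list(variant = variant, levels = levels,
                 base_width = base_width, dropout_rate = dropout_rate,
                 primary_patch = primary_patch,
                 context_patch = context_patch,
                 fc_width = as.integer(fc_width),
                 kernel = c(3L, 3L, 3L), pool = c(2L, 2L, 2L)),
            class = "architecture_config")
}

has_context <- function(cfg) cfg$variant %in% c("context", "bravenet")
has_ds <- function(cfg) cfg$variant %in% c("ds", "bravenet")
level_width <- function(cfg, l) cfg$base_width * 2L^(l - 1L)

glorot <- function(fan_in, fan_out, nr, nc) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Build a network from a configuration
#'
#' Instantiates all trainable parameters (convolution kernels via Glorot
#' uniform initialisation, zero biases, batch-norm scale 1 / shift 0) and
#' the batch-norm running statistics. Two builds with the same seed are
#' parameter-identical.
#'
#' @param cfg an [architecture_config()].
#' @param seed integer seed for weight initialisation.
#' @return An object of class `angioseg_network` with elements `config`,
#'   `params` (named list of trainable arrays) and `state` (batch-norm
#'   running statistics).
#' @export
build_network <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "architecture_config"))
  L <- cfg$levels
  params <- list(); state <- list()
  add_bn <- function(name, ch) {
    params[[paste0(name, ".gamma")]] <<- rep(1, ch)
    params[[paste0(name, ".beta")]] <<- rep(0, ch)
    state[[paste0(name, ".mean")]] <<- rep(0, ch)
    state[[paste0(name, ".var")]] <<- rep(1, ch)
  }
  add_conv3 <- function(name, cin, cout) {
    params[[paste0(name, ".W")]] <<- glorot(27 * cin, 27 * cout,
                                            27 * cin, cout)
    params[[paste0(name, ".b")]] <<- rep(0, cout)
  }
  add_conv1 <- function(name, cin, cout) {
    params[[paste0(name, ".W")]] <<- glorot(cin, cout, cin, cout)
    params[[paste0(name, ".b")]] <<- rep(0, cout)
  }
  with_seed(seed, {
    paths <- if (has_context(cfg)) c("p", "c") else "p"
    for (P in paths) {
      add_bn(paste0("in_bn.", P), 1L)
      for (l in seq_len(L)) {
        w <- level_width(cfg, l)
        cin <- if (l == 1L) 1L else level_width(cfg, l - 1L)
        pre <- sprintf("enc.%s.%d", P, l)
        add_conv3(paste0(pre, ".conv1"), cin, w)
        add_bn(paste0(pre, ".bn1"), w)
        add_conv3(paste0(pre, ".conv2"), w, w)
        add_bn(paste0(pre, ".bn2"), w)
      }
    }
    cb <- level_width(cfg, L) * length(paths)
    add_conv1("fc1", cb, cfg$fc_width)
    add_conv1("fc2", cfg$fc_width, cfg$fc_width)
    for (l in (L - 1L):1L) {
      w <- level_width(cfg, l)
      up_ch <- if (l == L - 1L) cfg$fc_width else level_width(cfg, l + 1L)
      cin <- up_ch + w * length(paths)
      pre <- sprintf("dec.%d", l)
      add_conv3(paste0(pre, ".conv1"), cin, w)
      add_bn(paste0(pre, ".bn1"), w)
      add_conv3(paste0(pre, ".conv2"), w, w)
      add_bn(paste0(pre, ".bn2"), w)
    }
    if (has_ds(cfg) && L >= 3L)
      for (l in (L - 1L):2L)
        add_conv1(sprintf("head.%d", l), level_width(cfg, l), 1L)
    add_conv1("final", level_width(cfg, 1L), 1L)
  })
  structure(list(config = cfg, params = params, state = state),
            class = "angioseg_network")
}

#' Count trainable parameters
#'
#' The exact number of independently optimised scalars: convolution
#' kernels and biases plus batch-norm scale and shift vectors. Running
#' statistics are not trainable and are excluded.
#'
#' @param net an `angioseg_network`.
#' @return Integer count.
#' @export
count_trainable_parameters <- function(net) {
  stopifnot(inherits(net, "angioseg_network"))
  sum(vapply(net$params, length, 0L))
}

#' @export
print.angioseg_network <- function(x, ...) {
  cat("<angioseg_network> variant=", x$config$variant,
      ", base_width=", x$config$base_width,
      ", levels=", x$config$levels,
      ", parameters=", format(count_trainable_parameters(x), big.mark = ","),
      "\n", sep = "")
  invisible(x)
}

#' Downsample a context patch by 2x2x2 average pooling
#'
#' Each output voxel is the arithmetic mean of its 2x2x2 input block,
#' bringing the context patch to primary-patch dimensions at half
#' resolution. All input dimensions must be even.
#'
#' @param patch 3-D numeric array with even dimensions.
#' @return A 3-D array of half the edge length per axis.
#' @export
downsample_context <- function(patch) {
  d <- dim(patch)
  if (length(d) != 3L || any(d %% 2L != 0L))
    stop("all patch dimensions must be even", call. = FALSE)
  out <- cpp_avgpool_fw(matrix(as.numeric(patch), ncol = 1L), d, 1L)
  array(out, dim = d %/% 2L)
}

# ---- forward / backward -------------------------------------------------

# Stack a list of equally shaped 3-D arrays into a (B*nvox) x 1 matrix.
patches_to_batch <- function(patches) {
  dims <- dim(patches[[1]])
  X <- matrix(unlist(patches, use.names = FALSE), ncol = 1L)
  list(X = X, dims = as.integer(dims), B = length(patches))
}

# Forward pass. `Xp` / `Xc`: (B*nvox) x 1 input matrices (context may be
# NULL for single-scale variants). Returns list(heads, cache, state);
# heads are (B*nvox_out) x 1 probability matrices, final head last.
net_forward <- function(net, Xp, dims_p, B, Xc = NULL, dims_c = NULL,
                        train = FALSE, keep_cache = FALSE,
                        final_only = FALSE) {
  cfg <- net$config
  params <- net$params; state <- net$state
  L <- cfg$levels
  cache <- if (keep_cache) new.env(parent = emptyenv()) else NULL
  put <- function(name, val) if (!is.null(cache)) assign(name, val, cache)

  bn <- function(name, X) {
    g <- params[[paste0(name, ".gamma")]]
    be <- params[[paste0(name, ".beta")]]
    if (train) {
      s <- cpp_colstats(X)
      mean <- s$mean; var <- s$var
      state[[paste0(name, ".mean")]] <<-
        BN_MOMENTUM * state[[paste0(name, ".mean")]] + (1 - BN_MOMENTUM) * mean
      state[[paste0(name, ".var")]] <<-
        BN_MOMENTUM * state[[paste0(name, ".var")]] + (1 - BN_MOMENTUM) * var
    } else {
      mean <- state[[paste0(name, ".mean")]]
      var <- state[[paste0(name, ".var")]]
    }
    invstd <- 1 / sqrt(var + BN_EPS)
    put(name, list(X = X, mean = mean, invstd = invstd))
    cpp_bn_fw(X, mean, invstd, g, be)
  }
  conv3 <- function(name, X, dims, B) {
    put(name, list(X = X, dims = dims, B = B))
    cpp_conv3_fw(X, dims, B, params[[paste0(name, ".W")]],
                 params[[paste0(name, ".b")]])
  }
  conv1 <- function(name, X) {
    put(name, X)
    sweep(X %*% params[[paste0(name, ".W")]], 2,
          params[[paste0(name, ".b")]], "+")
  }
  relu <- function(name, X) {
    Y <- cpp_relu_fw(X); put(name, Y); Y
  }
  dropout <- function(name, X) {
    rate <- cfg$dropout_rate
    if (!train || rate <= 0) return(X)
    mask <- matrix((runif(length(X)) >= rate) / (1 - rate),
                   nrow(X), ncol(X))
    put(name, mask)
    X * mask
  }

  encode <- function(P, X0, dims0) {
    X <- bn(paste0("in_bn.", P), X0)
    dims <- dims0
    skips <- vector("list", L)
    for (l in seq_len(L)) {
      pre <- sprintf("enc.%s.%d", P, l)
      X <- conv3(paste0(pre, ".conv1"), X, dims, B)
      X <- relu(paste0(pre, ".relu1"), X)
      X <- bn(paste0(pre, ".bn1"), X)
      X <- dropout(paste0(pre, ".drop"), X)
      X <- conv3(paste0(pre, ".conv2"), X, dims, B)
      X <- relu(paste0(pre, ".relu2"), X)
      X <- bn(paste0(pre, ".bn2"), X)
      skips[[l]] <- list(X = X, dims = dims)
      if (l < L) {
        mp <- cpp_maxpool_fw(X, dims, B)
        put(sprintf("enc.%s.%d.pool", P, l),
            list(idx = mp$idx, nrowX = nrow(X)))
        X <- mp$out
        dims <- dims %/% 2L
      }
    }
    skips
  }

  skips_p <- encode("p", Xp, dims_p)
  skips_c <- NULL
  if (has_context(cfg)) {
    if (is.null(Xc)) stop("variant '", cfg$variant,
                          "' requires a context patch", call. = FALSE)
    Xc_half <- cpp_avgpool_fw(Xc, dims_c, B)   # to primary dims, half res
    skips_c <- encode("c", Xc_half, dims_p)
  }

  bottom <- if (has_context(cfg))
    cbind(skips_p[[L]]$X, skips_c[[L]]$X) else skips_p[[L]]$X
  put("bottom.split", ncol(skips_p[[L]]$X))
  X <- conv1("fc1", bottom)
  X <- relu("fc1.relu", X)
  X <- conv1("fc2", X)
  X <- relu("fc2.relu", X)

  dims <- skips_p[[L]]$dims
  heads <- list()
  for (l in (L - 1L):1L) {
    pre <- sprintf("dec.%d", l)
    up <- cpp_upsample_fw(X, dims, B)
    put(paste0(pre, ".up"), list(dims_in = dims, ch = ncol(X)))
    dims <- dims * 2L
    parts <- list(up, skips_p[[l]]$X)
    if (has_context(cfg)) parts <- c(parts, list(skips_c[[l]]$X))
    X <- do.call(cbind, parts)
    put(paste0(pre, ".cat"), vapply(parts, ncol, 0L))
    X <- conv3(paste0(pre, ".conv1"), X, dims, B)
    X <- relu(paste0(pre, ".relu1"), X)
    X <- bn(paste0(pre, ".bn1"), X)
    X <- conv3(paste0(pre, ".conv2"), X, dims, B)
    X <- relu(paste0(pre, ".relu2"), X)
    X <- bn(paste0(pre, ".bn2"), X)
    if (has_ds(cfg) && l >= 2L && !final_only) {
      H <- X; hd <- dims
      nup <- 0L
      while (!identical(hd, dims_p)) { H <- cpp_upsample_fw(H, hd, B)
                                       hd <- hd * 2L; nup <- nup + 1L }
      put(sprintf("head.%d.meta", l), list(dims_dec = dims, nup = nup))
      Hl <- conv1(sprintf("head.%d", l), H)
      Hp <- cpp_sigmoid(Hl)
      put(sprintf("head.%d.p", l), Hp)
      heads[[length(heads) + 1L]] <- Hp
    }
  }
  Fl <- conv1("final", X)
  Fp <- cpp_sigmoid(Fl)
  put("final.p", Fp)
  heads[[length(heads) + 1L]] <- Fp
  list(heads = heads, cache = cache, state = state)
}

# Backward pass. `dheads`: gradients of the loss w.r.t. each head's
# probability output (same order as forward heads, final last). Returns a
# named list of gradients matching net$params.
net_backward <- function(net, fw, dheads, dims_p, B) {
  cfg <- net$config
  params <- net$params
  cache <- fw$cache
  L <- cfg$levels
  grads <- list()
  gadd <- function(name, val)
    grads[[name]] <<- if (is.null(grads[[name]])) val else grads[[name]] + val
  get_c <- function(name) get(name, cache)

  bn_bw <- function(name, dY) {
    cc <- get_c(name)
    r <- cpp_bn_bw(cc$X, dY, cc$mean, cc$invstd,
                   params[[paste0(name, ".gamma")]])
    gadd(paste0(name, ".gamma"), as.numeric(r$dgamma))
    gadd(paste0(name, ".beta"), as.numeric(r$dbeta))
    r$dX
  }
  conv3_bw <- function(name, dY) {
    cc <- get_c(name)
    r <- cpp_conv3_bw(cc$X, cc$dims, cc$B, params[[paste0(name, ".W")]], dY)
    gadd(paste0(name, ".W"), r$dW)
    gadd(paste0(name, ".b"), as.numeric(r$db))
    r$dX
  }
  conv1_bw <- function(name, dY) {
    X <- get_c(name)
    gadd(paste0(name, ".W"), crossprod(X, dY))
    gadd(paste0(name, ".b"), colSums(dY))
    dY %*% t(params[[paste0(name, ".W")]])
  }
  relu_bw <- function(name, dY) cpp_relu_bw(get_c(name), dY)
  drop_bw <- function(name, dY) {
    if (exists(name, cache)) dY * get_c(name) else dY
  }

  # final head through sigmoid
  Fp <- get_c("final.p")
  dX <- conv1_bw("final", dheads[[length(dheads)]] * Fp * (1 - Fp))

  dskip_p <- vector("list", L); dskip_c <- vector("list", L)
  hidx <- length(dheads) - 1L   # intermediate heads, shallowest last
  for (l in 1L:(L - 1L)) {
    pre <- sprintf("dec.%d", l)
    if (has_ds(cfg) && l >= 2L) {
      Hp <- get_c(sprintf("head.%d.p", l))
      dH <- conv1_bw(sprintf("head.%d", l), dheads[[hidx]] * Hp * (1 - Hp))
      hidx <- hidx - 1L
      meta <- get_c(sprintf("head.%d.meta", l))
      hd <- dims_p
      for (i in seq_len(meta$nup)) { hd <- hd %/% 2L
                                     dH <- cpp_upsample_bw(dH, hd, B) }
      dX <- dX + dH
    }
    dX <- bn_bw(paste0(pre, ".bn2"), dX)
    dX <- relu_bw(paste0(pre, ".relu2"), dX)
    dX <- conv3_bw(paste0(pre, ".conv2"), dX)
    dX <- bn_bw(paste0(pre, ".bn1"), dX)
    dX <- relu_bw(paste0(pre, ".relu1"), dX)
    dX <- conv3_bw(paste0(pre, ".conv1"), dX)
    splits <- get_c(paste0(pre, ".cat"))
    iu <- seq_len(splits[1])
    dup <- dX[, iu, drop = FALSE]
    dskip_p[[l]] <- dX[, splits[1] + seq_len(splits[2]), drop = FALSE]
    if (has_context(cfg))
      dskip_c[[l]] <- dX[, splits[1] + splits[2] + seq_len(splits[3]),
                         drop = FALSE]
    upm <- get_c(paste0(pre, ".up"))
    dX <- cpp_upsample_bw(dup, upm$dims_in, B)
  }

  dX <- relu_bw("fc2.relu", dX)
  dX <- conv1_bw("fc2", dX)
  dX <- relu_bw("fc1.relu", dX)
  dX <- conv1_bw("fc1", dX)
  sp <- get_c("bottom.split")
  dbot_p <- dX[, seq_len(sp), drop = FALSE]
  dbot_c <- if (has_context(cfg))
    dX[, sp + seq_len(ncol(dX) - sp), drop = FALSE]

  decode_path <- function(P, dskips, dbot) {
    dX <- dbot + dskips[[L]]
    for (l in L:1L) {
      pre <- sprintf("enc.%s.%d", P, l)
      if (l < L) {
        pm <- get_c(paste0(pre, ".pool"))
        dX <- cpp_maxpool_bw(dX, pm$idx, pm$nrowX) + dskips[[l]]
      }
      dX <- bn_bw(paste0(pre, ".bn2"), dX)
      dX <- relu_bw(paste0(pre, ".relu2"), dX)
      dX <- conv3_bw(paste0(pre, ".conv2"), dX)
      dX <- drop_bw(paste0(pre, ".drop"), dX)
      dX <- bn_bw(paste0(pre, ".bn1"), dX)
      dX <- relu_bw(paste0(pre, ".relu1"), dX)
      dX <- conv3_bw(paste0(pre, ".conv1"), dX)
    }
    bn_bw(paste0("in_bn.", P), dX)
  }
  # encoder skip gradients: deepest level receives only the bottom path,
  # shallower levels were filled during the decoder loop above
  dskip_p[[L]] <- matrix(0, nrow(dbot_p), ncol(dbot_p))
  decode_path("p", dskip_p, dbot_p)
  if (has_context(cfg)) {
    dskip_c[[L]] <- matrix(0, nrow(dbot_c), ncol(dbot_c))
    decode_path("c", dskip_c, dbot_c)
  }
  grads
}

#' Run a network on a single patch pair
#'
#' Convenience inference wrapper: forward pass in evaluation mode on one
#' primary (and, for context variants, context) patch.
#'
#' @param net an `angioseg_network`.
#' @param primary 3-D array of the primary patch shape.
#' @param context 3-D array of the context patch shape, or `NULL`.
#' @return A list of 3-D probability arrays, one per output head, each of
#'   the primary patch shape; the final head is last.
#' @export
predict_patch <- function(net, primary, context = NULL) {
  cfg <- net$config
  dims_p <- as.integer(dim(primary))
  Xp <- matrix(as.numeric(primary), ncol = 1L)
  Xc <- NULL; dims_c <- NULL
  if (has_context(cfg)) {
    if (is.null(context)) stop("variant '", cfg$variant,
                               "' requires a context patch", call. = FALSE)
    dims_c <- as.integer(dim(context))
    Xc <- matrix(as.numeric(context), ncol = 1L)
  }
  fw <- net_forward(net, Xp, dims_p, 1L, Xc, dims_c, train = FALSE)
  lapply(fw$heads, function(h) array(h, dim = dims_p))
}

#' Save / load a network checkpoint
#'
#' The checkpoint embeds the architecture configuration, all trainable
#' parameters and the batch-norm running statistics.
#'
#' @param net an `angioseg_network`.
#' @param path checkpoint file path.
#' @return `save_network` returns `path` invisibly; `load_network` returns
#'   the restored `angioseg_network`.
#' @export
save_network <- function(net, path) {
  stopifnot(inherits(net, "angioseg_network"))
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "angioseg_network"))
  net
}
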