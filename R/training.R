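# Optimisation protocol: Adam on the weighted soft-Dice loss with
# patch-level validation monitoring and early stopping, plus the
# cross-validation experiment driver.

#' Training configuration
#'
#' @param learning_rate Adam step size (default 1e-3; see
#'   [select_learning_rate()] for the candidate-selection procedure).
#' @param lr_candidates learning rates considered during model selection.
#' @param batch_size patches per optimisation step (default 16).
#' @param max_epochs upper bound on epochs; early stopping is expected to
#'   fire first.
#' @param patience epochs without validation-loss improvement before
#'   stopping (default 3).
#' @param eps stabiliser of the soft-Dice loss.
#' @param seed integer seed controlling shuffling, dropout and weight
#'   initialisation downstream.
#' @return An object of class `training_config`.
#' @export
training_config <- function(learning_rate = 1e-3,
                            lr_candidates = c(1e-2, 1e-3, 1e-4),
                            batch_size = 16, max_epochs = 100,
                            patience = 3, eps = 1, seed = 1L) {
  if (patience < 1) stop("patience must be >= 1", call. = FALSE)
  if (batch_size < 1) stop("batch_size must be >= 1", call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  structure(list(learning_rate = learning_rate,
                 lr_candidates = lr_candidates,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 eps = eps, seed = as.integer(seed)),
            class = "training_config")
}

# Early-stopping bookkeeping on a sequence of validation losses.
# Improvement means strictly smaller than the best so far; training stops
# after `patience` consecutive epochs without improvement.
early_stop_trace <- function(val_losses, patience) {
  best <- Inf; best_epoch <- 0L; stop_epoch <- length(val_losses)
  stopped <- FALSE
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) { best <- val_losses[e]; best_epoch <- e }
    if (e - best_epoch >= patience) { stop_epoch <- e; stopped <- TRUE; break }
  }
  list(best_epoch = best_epoch, stop_epoch = stop_epoch,
       stopped_early = stopped)
}

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t; c2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + eps)
  }
  list(params = params, state = st)
}

# Assemble a batch of patch samples into forward-pass inputs.
batch_inputs <- function(samples, use_context) {
  Xp <- patches_to_batch(lapply(samples, `[[`, "primary"))
  G <- matrix(unlist(lapply(samples, `[[`, "label"), use.names = FALSE),
              ncol = 1L)
  Xc <- NULL; dims_c <- NULL
  if (use_context) {
    ctx <- patches_to_batch(lapply(samples, `[[`, "context"))
    Xc <- ctx$X; dims_c <- ctx$dims
  }
  list(Xp = Xp$X, dims_p = Xp$dims, B = Xp$B, Xc = Xc, dims_c = dims_c,
       G = G)
}

# Mean per-patch composite loss and per-head probability gradients.
batch_loss_and_grads <- function(heads, G, nvox, B, w, eps) {
  loss <- 0
  dheads <- lapply(heads, function(h) h * 0)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * nvox + 1L):(b * nvox)
    g <- G[rows, 1L]
    for (i in seq_along(heads)) {
      p <- heads[[i]][rows, 1L]
      loss <- loss + w[i] * (1 - soft_dsc(p, g, eps = eps)) / B
      dheads[[i]][rows, 1L] <-
        -(w[i] / B) * soft_dsc_gradient(p, g, eps = eps)
    }
  }
  list(loss = loss, dheads = dheads)
}

# Mean composite validation loss in inference mode.
patch_validation_loss <- function(net, samples, w, batch_size, eps) {
  use_ctx <- has_context(net$config)
  total <- 0
  for (chunk in split(samples, ceiling(seq_along(samples) / batch_size))) {
    bi <- batch_inputs(chunk, use_ctx)
    fw <- net_forward(net, bi$Xp, bi$dims_p, bi$B, bi$Xc, bi$dims_c,
                      train = FALSE)
    nvox <- prod(bi$dims_p)
    for (b in seq_len(bi$B)) {
      rows <- ((b - 1L) * nvox + 1L):(b * nvox)
      g <- bi$G[rows, 1L]
      total <- total + sum(vapply(seq_along(w), function(i)
        w[i] * (1 - soft_dsc(fw$heads[[i]][rows, 1L], g, eps = eps)), 0))
    }
  }
  total / length(samples)
}

#' Train a network on patch samples
#'
#' Adam optimisation of the deep-supervision-weighted soft-Dice loss.
#' Patch-level validation loss is monitored after every epoch (in
#' inference mode, using batch-norm running statistics); training stops
#' when it has not improved for `patience` consecutive epochs or at
#' `max_epochs`, and the returned network carries the weights of the best
#' validation epoch. Fully reproducible under `cfg$seed`.
#'
#' @param net a freshly built `angioseg_network` (Glorot-initialised).
#' @param train_samples,val_samples lists of patch samples from
#'   [sample_patches()]; both non-empty.
#' @param cfg a [training_config()].
#' @return A list with `net` (best-epoch weights) and `history` (a list
#'   with per-epoch `train_loss` and `val_loss`, `best_epoch` and
#'   `stopped_early`).
#' @export
train_model <- function(net, train_samples, val_samples, cfg) {
  stopifnot(inherits(net, "angioseg_network"),
            inherits(cfg, "training_config"))
  if (length(train_samples) == 0L)
    stop("empty training stream", call. = FALSE)
  if (length(val_samples) == 0L)
    stop("empty validation stream with early stopping enabled",
         call. = FALSE)
  use_ctx <- has_context(net$config)
  n_heads <- if (has_ds(net$config)) net$config$levels - 1L else 1L
  w <- ds_weights(n_heads)
  nvox <- prod(net$config$primary_patch)
  adam <- adam_init(net$params)
  train_loss <- numeric(0); val_loss <- numeric(0)
  best <- Inf; best_epoch <- 0L; best_net <- net; stopped <- FALSE

  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(length(train_samples))
      ep_loss <- 0; n_batches <- 0L
      for (chunk in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
        bi <- batch_inputs(train_samples[chunk], use_ctx)
        fw <- net_forward(net, bi$Xp, bi$dims_p, bi$B, bi$Xc, bi$dims_c,
                          train = TRUE, keep_cache = TRUE)
        net$state <- fw$state
        lg <- batch_loss_and_grads(fw$heads, bi$G, nvox, bi$B, w, cfg$eps)
        grads <- net_backward(net, fw, lg$dheads, bi$dims_p, bi$B)
        upd <- adam_step(net$params, grads, adam, cfg$learning_rate)
        net$params <- upd$params; adam <- upd$state
        ep_loss <- ep_loss + lg$loss; n_batches <- n_batches + 1L
      }
      train_loss[epoch] <- ep_loss / n_batches
      val_loss[epoch] <- patch_validation_loss(net, val_samples, w,
                                               cfg$batch_size, cfg$eps)
      if (val_loss[epoch] < best) {
        best <- val_loss[epoch]; best_epoch <- epoch; best_net <- net
      }
      if (epoch - best_epoch >= cfg$patience) { stopped <- TRUE; break }
    }
  })
  list(net = best_net,
       history = list(train_loss = train_loss, val_loss = val_loss,
                      best_epoch = best_epoch, stopped_early = stopped))
}

#' Select the learning rate by mean validation performance
#'
#' Returns the candidate with the highest mean whole-volume validation
#' Dice across folds; exact ties break toward the smaller rate.
#'
#' @param candidates numeric vector of learning rates.
#' @param fold_dsc matrix of validation Dice values, folds in rows, one
#'   column per candidate (in the order of `candidates`).
#' @return The selected learning rate.
#' @export
select_learning_rate <- function(candidates, fold_dsc) {
  if (length(candidates) == 0L) stop("empty candidates", call. = FALSE)
  fold_dsc <- as.matrix(fold_dsc)
  if (ncol(fold_dsc) != length(candidates))
    stop("fold_dsc must have one column per candidate", call. = FALSE)
  means <- colMeans(fold_dsc)
  best <- which(means == max(means))
  candidates[best[which.min(candidates[best])]]
}

#' Run the cross-validation experiment
#'
#' Splits the dataset with [make_cv_splits()] (stratified by source tag),
#' then per fold: computes heuristic masks, samples vessel-centric patch
#' centres on training and validation volumes, trains a network, predicts
#' every test volume whole, and evaluates the five metrics. The summary is
#' a mean (SD) per metric across folds.
#'
#' @param dataset list of entries, each a list with `volume`
#'   ([volume()]), `labels` ([binary_label_volume()]) and `source` (cohort
#'   tag).
#' @param arch an [architecture_config()].
#' @param cfg a [training_config()].
#' @param n_centers patch centres sampled per training volume (the
#'   reference protocol uses 2000).
#' @param vessel_fraction vessel-centric fraction of the centres.
#' @param folds,val_fraction passed to [make_cv_splits()].
#' @param keep_networks keep the fold networks in the result (needed for
#'   ensembling).
#' @return A list with `splits`, `per_volume` (metrics per test volume),
#'   `per_fold` (fold means), `summary` (mean and SD rows across folds),
#'   `histories`, and optionally `networks`.
#' @export
run_cross_validation <- function(dataset, arch, cfg, n_centers = 2000,
                                 vessel_fraction = 0.5, folds = 4,
                                 val_fraction = 0.15,
                                 keep_networks = TRUE) {
  sources <- vapply(dataset, `[[`, "", "source")
  cohort_sizes <- table(sources)
  ids <- character(length(dataset))
  for (s in names(cohort_sizes)) {
    k <- which(sources == s)
    ids[k] <- sprintf("%s-%03d", s, seq_along(k))
  }
  by_id <- stats::setNames(seq_along(dataset), ids)
  splits <- make_cv_splits(as.list(cohort_sizes), folds = folds,
                           val_fraction = val_fraction, seed = cfg$seed)
  use_ctx <- has_context(arch)
  ctx_patch <- if (use_ctx) arch$context_patch
  gather <- function(id_vec, seed0) {
    out <- list()
    for (i in seq_along(id_vec)) {
      e <- dataset[[by_id[[id_vec[i]]]]]
      mask <- compute_heuristic_mask(e$volume)
      ctr <- sample_patch_centers(e$labels, mask, n = n_centers,
                                  vessel_fraction = vessel_fraction,
                                  seed = seed0 + i)
      out <- c(out, sample_patches(e$volume, e$labels, ctr,
                                   primary = arch$primary_patch,
                                   context = ctx_patch))
    }
    out
  }
  per_volume <- list(); per_fold <- list(); histories <- list()
  networks <- list()
  for (f in seq_len(folds)) {
    sp <- splits[[f]]
    train_s <- gather(sp$train, cfg$seed + 1000L * f)
    val_s <- gather(sp$val, cfg$seed + 1000L * f + 500L)
    net <- build_network(arch, seed = cfg$seed + f)
    fit <- train_model(net, train_s, val_s, cfg)
    histories[[f]] <- fit$history
    if (keep_networks) networks[[f]] <- fit$net
    rows <- lapply(sp$test, function(id) {
      e <- dataset[[by_id[[id]]]]
      pred <- binarize(predict_volume(fit$net, e$volume))
      rep <- evaluate_segmentation(pred, e$labels)
      data.frame(fold = f, id = id, source = e$source,
                 dsc = rep$dsc, precision = rep$precision,
                 recall = rep$recall, avd = rep$avd, hd95 = rep$hd95)
    })
    fold_df <- do.call(rbind, rows)
    per_volume[[f]] <- fold_df
    per_fold[[f]] <- data.frame(
      fold = f, t(colMeans(fold_df[, c("dsc", "precision", "recall",
                                       "avd", "hd95")])))
  }
  per_volume <- do.call(rbind, per_volume)
  per_fold <- do.call(rbind, per_fold)
  met <- c("dsc", "precision", "recall", "avd", "hd95")
  summary <- rbind(mean = colMeans(per_fold[, met]),
                   sd = apply(per_fold[, met], 2, sd))
  out <- list(splits = splits, per_volume = per_volume,
              per_fold = per_fold, summary = as.data.frame(summary),
              histories = histories)
  if (keep_networks) out$networks <- networks
  out
}
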