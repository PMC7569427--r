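#' Training configuration
#'
#' Adam hyperparameters and training-loop settings. Defaults follow common
#' practice for patch-based vessel segmentation: learning rate 0.001,
#' beta1 0.9, beta2 0.999, epsilon 1e-8, batch size 32, 100 epochs, a 90/10
#' train/validation split, and He-normal kernel initialisation.
#'
#' @param lr Adam learning rate.
#' @param beta1,beta2,epsilon Adam moment decays and stabiliser.
#' @param batch_size patches per gradient step.
#' @param epochs passes over the training patches.
#' @param val_fraction fraction of patches held out for validation.
#' @param init weight initialisation scheme (\code{"he_normal"}).
#' @param seed RNG seed governing the split, shuffling and initialisation.
#' @param n_train_patches patch budget used by \code{\link{run_experiment}}.
#' @param loss a \code{\link{loss_config}}; the training loop uses
#'   mean-reduced cross-entropy plus the Dice term over each mini-batch.
#' @export
train_config <- function(lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-8, batch_size = 32L, epochs = 100L,
                         val_fraction = 0.1, init = "he_normal", seed = 1L,
                         n_train_patches = 2000L,
                         loss = loss_config(reduction = "mean")) {
  if (val_fraction <= 0 || val_fraction >= 1)
    stop("train_config: val_fraction must be in (0, 1)")
  if (batch_size < 1) stop("train_config: batch_size must be >= 1")
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), val_fraction = val_fraction,
                 init = init, seed = as.integer(seed),
                 n_train_patches = as.integer(n_train_patches), loss = loss),
            class = "train_config")
}

#' (Re)initialise model weights
#'
#' He-normal initialisation: every convolution kernel entry is drawn from a
#' zero-mean normal with variance 2/fan_in (fan_in = kernel area times
#' input channels); biases and BN shifts start at zero, BN scales at one,
#' and weight-normalisation scales at the initial column norms so the
#' effective weights equal the drawn directions.
#'
#' @param model a \code{wanet_model}.
#' @param scheme only \code{"he_normal"} is available.
#' @param seed RNG seed.
#' @return The model with fresh parameters and reset BN statistics.
#' @export
init_weights <- function(model, scheme = "he_normal", seed = 1L) {
  stopifnot(inherits(model, "wanet_model"))
  if (!identical(scheme, "he_normal"))
    stop(sprintf("init_weights: unknown scheme '%s'", scheme))
  set.seed(seed)
  model$params <- .init_registry(model$shapes)
  model$state <- .fresh_state(model$params, model$shapes)
  model
}

# Per-batch loss and logit gradient: mean binary cross-entropy on the
# vessel class plus the smoothed Dice loss over the flattened batch. The
# cross-entropy is evaluated and differentiated in logit space (log-softmax),
# so its gradient (p - y)/n stays bounded even when the softmax saturates.
.loss_and_grad <- function(fw, y, lcfg) {
  z1 <- fw$logits[, 1L]; z2 <- fw$logits[, 2L]
  m <- pmax(z1, z2)
  lse <- m + log(exp(z1 - m) + exp(z2 - m))
  ce <- -mean(y * (z2 - lse) + (1 - y) * (z1 - lse))
  pv <- fw$prob[, 2L]
  dc <- dice_loss(pv, y, lcfg$smooth)
  dz2 <- (pv - y) / length(pv) + pv * (1 - pv) * dice_loss_grad(pv, y, lcfg$smooth)
  list(loss = ce + dc, ce = ce, dice = dc,
       dlogits = cbind(-dz2, dz2, deparse.level = 0))
}

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adam_step <- function(params, grads, st, cfg) {
  st$t <- st$t + 1L
  c1 <- 1 - cfg$beta1^st$t
  c2 <- 1 - cfg$beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    st$m[[nm]] <- cfg$beta1 * st$m[[nm]] + (1 - cfg$beta1) * g
    st$v[[nm]] <- cfg$beta2 * st$v[[nm]] + (1 - cfg$beta2) * g * g
    params[[nm]] <- params[[nm]] -
      cfg$lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + cfg$epsilon)
  }
  list(params = params, st = st)
}

# Stack of (S, S, P) patches -> (P*S*S, 1) matrix for the selected indices.
.patch_matrix <- function(patches, idx) {
  sub <- patches[, , idx, drop = FALSE]
  d <- dim(sub)
  dim(sub) <- c(d[1], d[2], 1L, d[3])
  nhwc_from_array(sub)
}

#' Train a segmentation model
#'
#' Mini-batch Adam on the combined cross-entropy + Dice objective. The
#' patches are split into training and validation sets by a seeded shuffle;
#' each epoch is one pass over the training patches. Per-epoch training
#' loss, validation loss and validation pixel accuracy are recorded, and
#' the parameters with the best validation loss are retained alongside the
#' final ones.
#'
#' @param model a \code{wanet_model} (freshly built models are already
#'   He-normal initialised).
#' @param patches S x S x P array of preprocessed image patches.
#' @param labels S x S x P binary array of matching mask patches.
#' @param cfg a \code{\link{train_config}}.
#' @param verbose print one line per epoch.
#' @return A \code{wanet_fit}: \code{model} (final parameters),
#'   \code{best_params}, \code{best_epoch} and \code{history} (data.frame
#'   epoch, train_loss, val_loss, val_acc, seconds).
#' @export
train_model <- function(model, patches, labels, cfg = train_config(),
                        verbose = FALSE) {
  stopifnot(inherits(model, "wanet_model"))
  P <- dim(patches)[3]
  if (!all(dim(labels) == dim(patches)))
    stop("train_model: labels shape differs from patches")
  if (P < 2) stop("train_model: need at least 2 patches")
  set.seed(cfg$seed)
  perm <- sample.int(P)
  n_val <- max(1L, round(cfg$val_fraction * P))
  val_idx <- perm[seq_len(n_val)]
  train_idx <- perm[-seq_len(n_val)]
  if (length(train_idx) < cfg$batch_size && length(train_idx) < 1)
    stop("train_model: no training patches left after the split")
  lcfg <- cfg$loss
  adam <- .adam_init(model$params)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), val_acc = numeric(),
                     seconds = numeric())
  best <- list(loss = Inf, params = model$params, epoch = 0L)

  eval_set <- function(idx) {
    tot_loss <- 0; tot_correct <- 0; tot_px <- 0
    for (s in seq(1L, length(idx), by = cfg$batch_size)) {
      sel <- idx[s:min(s + cfg$batch_size - 1L, length(idx))]
      X <- .patch_matrix(patches, sel)
      y <- as.vector(.patch_matrix(labels, sel))
      fw <- wa_forward(model, X, length(sel))
      lg <- .loss_and_grad(fw, y, lcfg)
      tot_loss <- tot_loss + lg$loss * length(y)
      tot_correct <- tot_correct + sum((fw$prob[, 2L] >= 0.5) == (y > 0))
      tot_px <- tot_px + length(y)
    }
    c(loss = tot_loss / tot_px, acc = tot_correct / tot_px)
  }

  for (epoch in seq_len(cfg$epochs)) {
    t0 <- Sys.time()
    set.seed(cfg$seed + epoch)
    order_ep <- sample(train_idx)
    ep_loss <- 0; n_batches <- 0L
    for (s in seq(1L, length(order_ep), by = cfg$batch_size)) {
      sel <- order_ep[s:min(s + cfg$batch_size - 1L, length(order_ep))]
      X <- .patch_matrix(patches, sel)
      y <- as.vector(.patch_matrix(labels, sel))
      fw <- wa_forward(model, X, length(sel), training = TRUE,
                       keep_cache = TRUE)
      lg <- .loss_and_grad(fw, y, lcfg)
      if (!is.finite(lg$loss))
        stop(sprintf("train_model: non-finite loss at epoch %d", epoch))
      G <- wa_backward(model, fw, lg$dlogits)
      upd <- .adam_step(model$params, G, adam, cfg)
      model$params <- upd$params
      adam <- upd$st
      ep_loss <- ep_loss + lg$loss
      n_batches <- n_batches + 1L
    }
    vl <- eval_set(val_idx)
    secs <- as.numeric(Sys.time() - t0, units = "secs")
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = ep_loss / n_batches,
                                   val_loss = vl["loss"],
                                   val_acc = vl["acc"], seconds = secs))
    if (vl["loss"] < best$loss)
      best <- list(loss = vl["loss"], params = model$params, epoch = epoch)
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  acc %.4f  (%.1fs)",
                      epoch, ep_loss / n_batches, vl["loss"], vl["acc"], secs))
  }
  rownames(hist) <- NULL
  structure(list(model = model, history = hist,
                 best_params = best$params, best_epoch = best$epoch),
            class = "wanet_fit")
}

#' @export
print.wanet_fit <- function(x, ...) {
  n <- nrow(x$history)
  cat(sprintf("wanet_fit: %d epochs; train loss %.4f -> %.4f; best val %.4f (epoch %d)\n",
              n, x$history$train_loss[1], x$history$train_loss[n],
              min(x$history$val_loss), x$best_epoch))
  invisible(x)
}

#' Predict a full-image vessel probability map
#'
#' Extracts overlapping patches on a grid, runs the network on each, and
#' averages the per-pixel vessel probabilities of all patches covering a
#' pixel.
#'
#' @param model a \code{wanet_model}.
#' @param image preprocessed H x W matrix in [0, 1].
#' @param stride grid stride in pixels (default 5; larger is faster,
#'   slightly less smooth).
#' @param fov optional field-of-view mask; probabilities outside are set to
#'   zero in the returned map.
#' @param batch_size forward mini-batch size.
#' @return H x W matrix of vessel probabilities.
#' @export
predict_image <- function(model, image, stride = 5L, fov = NULL,
                          batch_size = 128L) {
  stopifnot(inherits(model, "wanet_model"))
  S <- model$config$patch_size
  pg <- extract_patches(image, size = S, stride = stride, mode = "grid")
  probs <- predict_patches(model, pg$patches, batch_size = batch_size)
  vessel <- probs[, , 2L, , drop = FALSE]
  dim(vessel) <- c(S, S, dim(probs)[4])
  map <- reconstruct_map(pg, vessel)
  if (!is.null(fov)) map[fov == 0] <- 0
  map
}

#' Save / load a model checkpoint
#'
#' The checkpoint archives the parameter registry (name to array), the
#' batch-norm running statistics, and the network configuration serialised
#' as JSON.
#'
#' @param model a \code{wanet_model}.
#' @param path file path (conventionally \code{.rds}).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "wanet_model"))
  st <- as.list(model$state)
  cfg_json <- jsonlite::toJSON(unclass(model$config), auto_unbox = TRUE,
                               digits = NA)
  saveRDS(list(config_json = as.character(cfg_json), params = model$params,
               state = st), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  cl <- jsonlite::fromJSON(obj$config_json)
  cfg <- network_config(variant = cl$variant,
                        slim_widths = as.integer(cl$slim_widths),
                        laspp_channels = as.integer(cl$laspp_channels),
                        laspp_dilations = as.integer(cl$laspp_dilations),
                        r = cl$r, leaky_slope = cl$leaky_slope,
                        patch_size = as.integer(cl$patch_size),
                        in_channels = as.integer(cl$in_channels),
                        classes = as.integer(cl$classes),
                        wn_all = isTRUE(cl$wn_all))
  model <- build_wa_net(cfg, seed = 0L)
  if (!identical(sort(names(model$params)), sort(names(obj$params))))
    stop("load_checkpoint: parameter registry does not match the config")
  model$params <- obj$params
  st <- .fresh_state(model$params, model$shapes)
  for (nm in names(obj$state)) st[[nm]] <- obj$state[[nm]]
  model$state <- st
  model
}

#' Run a full synthetic experiment
#'
#' Orchestrates the pipeline end to end: generate synthetic training and
#' test retinas, preprocess them, sample training patches, train the
#' network, predict probability maps for the held-out test images, and
#' evaluate. Training and test images may come from different generator
#' configurations (a synthetic analogue of training on one cohort and
#' testing on another).
#'
#' @param config a list (or path to a YAML/JSON file) with any of:
#'   \code{seed}; \code{outdir} (optional output directory);
#'   \code{n_train_images}, \code{n_test_images}; \code{synth_train},
#'   \code{synth_test} (\code{\link{synth_config}} lists); \code{model}
#'   (\code{\link{network_config}} arguments); \code{train}
#'   (\code{\link{train_config}} arguments); \code{n_patches};
#'   \code{stride}; \code{threshold}; \code{verbose}.
#' @return A report list: pooled \code{metrics}, per-image AUCs,
#'   \code{history}, and file paths when \code{outdir} was given.
#' @export
run_experiment <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  seed <- config$seed %||% 1L
  n_tr <- config$n_train_images %||% 12L
  n_te <- config$n_test_images %||% 4L
  n_patches <- config$n_patches %||% 2000L
  stride <- config$stride %||% 5L
  threshold <- config$threshold %||% 0.5
  verbose <- isTRUE(config$verbose)
  sy_tr <- do.call(synth_config, config$synth_train %||% list())
  sy_te <- if (is.null(config$synth_test)) sy_tr
           else do.call(synth_config, config$synth_test)
  mcfg <- do.call(network_config, config$model %||% list())
  tcfg <- do.call(train_config,
                  utils::modifyList(list(seed = seed,
                                         n_train_patches = n_patches),
                                    config$train %||% list()))
  pcfg <- do.call(preprocess_config, config$preprocess %||% list())

  train_set <- generate_fundus_dataset(n_tr, sy_tr, seed = seed)
  test_set <- generate_fundus_dataset(n_te, sy_te, seed = seed + 500L)

  per_img <- ceiling(n_patches / n_tr)
  pat <- list(); lab <- list()
  for (i in seq_along(train_set)) {
    im <- preprocess_pipeline(train_set[[i]]$image, pcfg)
    pg <- extract_patches(im, mask = train_set[[i]]$mask,
                          size = mcfg$patch_size, mode = "random",
                          n = per_img, seed = seed * 131L + i,
                          fov = train_set[[i]]$fov)
    pat[[i]] <- pg$patches
    lab[[i]] <- pg$mask_patches
  }
  S <- mcfg$patch_size
  patches <- array(unlist(pat), c(S, S, per_img * n_tr))[, , seq_len(n_patches), drop = FALSE]
  labels <- array(unlist(lab), c(S, S, per_img * n_tr))[, , seq_len(n_patches), drop = FALSE]

  model <- build_wa_net(mcfg, seed = seed)
  fit <- train_model(model, patches, labels, tcfg, verbose = verbose)

  maps <- list(); auc_img <- numeric(n_te)
  pool_p <- list(); pool_y <- list(); pool_f <- list()
  for (i in seq_along(test_set)) {
    im <- preprocess_pipeline(test_set[[i]]$image, pcfg)
    mp <- predict_image(fit$model, im, stride = stride)
    maps[[i]] <- mp
    auc_img[i] <- roc_auc(mp, test_set[[i]]$mask, fov = test_set[[i]]$fov)$auc
    keep <- test_set[[i]]$fov > 0
    pool_p[[i]] <- mp[keep]
    pool_y[[i]] <- test_set[[i]]$mask[keep]
  }
  pp <- unlist(pool_p); yy <- unlist(pool_y)
  pooled <- summarize_metrics(confusion_counts(matrix(pp), matrix(yy),
                                               threshold))
  pooled$auc <- roc_auc(pp, yy)$auc
  report <- list(metrics = pooled, per_image_auc = auc_img,
                 history = fit$history, best_epoch = fit$best_epoch,
                 config = list(seed = seed, n_train_images = n_tr,
                               n_test_images = n_te, n_patches = n_patches,
                               stride = stride, threshold = threshold))

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(config$outdir, "maps"), showWarnings = FALSE)
    save_checkpoint(fit$model, file.path(config$outdir, "checkpoint.rds"))
    utils::write.csv(fit$history, file.path(config$outdir, "history.csv"),
                     row.names = FALSE)
    for (i in seq_along(maps))
      write_probability_map(maps[[i]],
                            file.path(config$outdir, "maps",
                                      sprintf("test_%02d.png", i)))
    mj <- list(acc = pooled$acc, sens = pooled$sens, spec = pooled$spec,
               prec = pooled$prec, f1 = pooled$f1, auc = pooled$auc,
               per_image_auc = auc_img, best_epoch = fit$best_epoch)
    jsonlite::write_json(mj, file.path(config$outdir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    ra <- roc_auc(pp, yy)
    utils::write.csv(ra$roc, file.path(config$outdir, "roc.csv"),
                     row.names = FALSE)
    report$outdir <- config$outdir
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
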