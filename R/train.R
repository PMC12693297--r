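# Triplet training loop with validation split, early stopping, and
# best-checkpoint restore.
#
# Siamese weight sharing makes the full-batch gradient cheap: each unique
# compound is embedded once per epoch, triplet-loss gradients are
# accumulated at the embedding level, and a single backward pass per
# compound yields the exact parameter gradient.

#' Split triplets into training and validation sets
#'
#' Disjoint, exhaustive partition of the triplet rows, deterministic under a
#' fixed seed. The validation set holds `round(val_fraction * n)` triplets
#' (at least 1).
#'
#' @param triplets Data frame from [mine_triplets()].
#' @param val_fraction Fraction held out for validation, in (0, 1).
#' @param seed Integer seed.
#' @return List with data frames `train` and `val`.
#' @export
split_triplets <- function(triplets, val_fraction = 0.2, seed = 1L) {
  n <- nrow(triplets)
  if (n < 2L) stop("need at least 2 triplets to split")
  if (!(val_fraction > 0 && val_fraction < 1)) {
    stop("'val_fraction' must be in (0, 1)")
  }
  n_val <- max(1L, min(n - 1L, round(val_fraction * n)))
  idx <- .with_seed(seed, sample.int(n, n_val))
  list(train = triplets[-idx, , drop = FALSE],
       val = triplets[idx, , drop = FALSE])
}

#' Early-stopping rule
#'
#' Stop when no new best (lower by at least `min_delta`) validation loss has
#' been recorded in the last `patience` epochs.
#'
#' @param val_losses Numeric vector of per-epoch validation losses.
#' @param patience Number of epochs without improvement tolerated.
#' @param min_delta Minimum decrease counting as an improvement.
#' @return `TRUE` if training should stop.
#' @export
early_stop <- function(val_losses, patience, min_delta = 1e-4) {
  if (length(val_losses) < 1L) stop("need at least one validation loss")
  best <- Inf
  best_at <- 0L
  for (i in seq_along(val_losses)) {
    if (val_losses[[i]] < best - min_delta) {
      best <- val_losses[[i]]
      best_at <- i
    }
  }
  (length(val_losses) - best_at) >= patience
}

# Mean triplet loss and per-compound embedding gradients for a triplet set.
.triplet_pass <- function(E, triplets, margin, with_grad = FALSE) {
  n <- nrow(triplets)
  dE <- if (with_grad) matrix(0, nrow(E), ncol(E),
                              dimnames = dimnames(E)) else NULL
  total <- 0
  for (t in seq_len(n)) {
    a <- triplets$anchor[[t]]; p <- triplets$positive[[t]]
    ng <- triplets$negative[[t]]
    va <- E[a, ]; vp <- E[p, ]; vn <- E[ng, ]
    dap <- sqrt(sum((va - vp)^2))
    dan <- sqrt(sum((va - vn)^2))
    loss <- dap - dan + margin
    if (loss > 0) {
      total <- total + loss
      if (with_grad) {
        up <- if (dap > 0) (va - vp) / dap else 0 * va
        un <- if (dan > 0) (va - vn) / dan else 0 * va
        dE[a, ] <- dE[a, ] + (up - un) / n
        dE[p, ] <- dE[p, ] - up / n
        dE[ng, ] <- dE[ng, ] + un / n
      }
    }
  }
  list(loss = total / n, dE = dE)
}

#' Train the Siamese model with triplet loss
#'
#' Full-batch training with Adam, a held-out validation triplet set, early
#' stopping on the validation loss, and restoration of the best-validation
#' checkpoint at the end. Fully reproducible under a fixed seed.
#'
#' @param model A [siamese_model()].
#' @param samples Named list of multimodal samples (see [load_samples()])
#'   covering every id referenced by `triplets`.
#' @param triplets Data frame from [mine_triplets()].
#' @param max_epochs Epoch cap (default 20, the optimal duration for
#'   datasets of this scale).
#' @param patience Early-stopping patience in epochs (default 5); must not
#'   exceed `max_epochs`.
#' @param val_fraction Fraction of triplets held out (default 0.2).
#' @param lr Adam learning rate (default 1e-3).
#' @param seed Seed for the split and any subsampling.
#' @param triplet_cap Optional per-epoch cap on training triplets
#'   (deterministic subsample); default `NULL` = use all.
#' @param min_delta Minimum validation-loss improvement (default 1e-4).
#' @param verbose Print per-epoch losses?
#' @return An object of class `"siamese_fit"`: list with `model` (best
#'   checkpoint), `history` (data frame epoch/train_loss/val_loss),
#'   `best_epoch`, `stopped_epoch`, `split`.
#' @export
fit_siamese <- function(model, samples, triplets, max_epochs = 20L,
                        patience = 5L, val_fraction = 0.2, lr = 1e-3,
                        seed = 1L, triplet_cap = NULL, min_delta = 1e-4,
                        verbose = FALSE) {
  stopifnot(inherits(model, "siamese_model"))
  if (patience > max_epochs) stop("'patience' must be <= 'max_epochs'")
  ids <- unique(c(triplets$anchor, triplets$positive, triplets$negative))
  missing_ids <- setdiff(ids, names(samples))
  if (length(missing_ids)) {
    bad <- triplets[triplets$anchor %in% missing_ids |
                      triplets$positive %in% missing_ids |
                      triplets$negative %in% missing_ids, ][1, ]
    stop("no sample for id(s) ", paste(missing_ids, collapse = ", "),
         " (first affected triplet: ", bad$anchor, "/", bad$positive, "/",
         bad$negative, ")")
  }
  sp <- split_triplets(triplets, val_fraction, seed)
  if (!nrow(sp$train) || !nrow(sp$val)) stop("empty train or validation set")
  cfg <- model$config
  params <- model$params
  state <- .adam_init(params)
  hist_train <- numeric(0)
  hist_val <- numeric(0)
  best_val <- Inf
  best_params <- params
  best_epoch <- 0L
  epoch <- 0L
  glcms <- lapply(samples, function(s) as.numeric(s$glcm))
  embed_all <- function(prm, use, cache = FALSE) {
    E <- matrix(0, length(use), cfg$embedding_dim, dimnames = list(use, NULL))
    caches <- if (cache) vector("list", length(use)) else NULL
    for (i in seq_along(use)) {
      f <- .embed_fwd(prm, cfg, samples[[use[[i]]]]$mep, glcms[[use[[i]]]])
      E[i, ] <- f$e
      if (cache) caches[[i]] <- f$cache
    }
    if (cache) names(caches) <- use
    list(E = E, caches = caches)
  }
  val_ids <- unique(c(sp$val$anchor, sp$val$positive, sp$val$negative))
  while (epoch < max_epochs) {
    epoch <- epoch + 1L
    tr <- sp$train
    if (!is.null(triplet_cap) && nrow(tr) > triplet_cap) {
      keep <- .with_seed(seed + epoch, sample.int(nrow(tr), triplet_cap))
      tr <- tr[sort(keep), , drop = FALSE]
    }
    tr_ids <- unique(c(tr$anchor, tr$positive, tr$negative))
    fw <- embed_all(params, tr_ids, cache = TRUE)
    pass <- .triplet_pass(fw$E, tr, cfg$margin, with_grad = TRUE)
    grads <- NULL
    for (id in tr_ids) {
      de <- pass$dE[id, ]
      if (all(de == 0)) next
      bw <- .embed_bwd(params, cfg, fw$caches[[id]], de)
      grads <- if (is.null(grads)) bw$grads else {
        Map(`+`, grads, bw$grads)
      }
    }
    if (!is.null(grads)) {
      st <- .adam_step(params, grads, state, lr = lr)
      params <- st$params
      state <- st$state
    }
    vE <- embed_all(params, val_ids)$E
    vloss <- .triplet_pass(vE, sp$val, cfg$margin)$loss
    hist_train <- c(hist_train, pass$loss)
    hist_val <- c(hist_val, vloss)
    if (vloss < best_val - min_delta) {
      best_val <- vloss
      best_params <- params
      best_epoch <- epoch
    }
    if (verbose) {
      message(sprintf("epoch %2d  train %.4f  val %.4f", epoch,
                      pass$loss, vloss))
    }
    if (early_stop(hist_val, patience, min_delta)) break
  }
  if (best_epoch == 0L) {          # validation never improved over Inf-delta
    best_epoch <- which.min(hist_val)
    best_params <- params
  }
  out_model <- model
  out_model$params <- best_params
  structure(list(
    model = out_model,
    history = data.frame(epoch = seq_along(hist_train),
                         train_loss = hist_train, val_loss = hist_val),
    best_epoch = best_epoch,
    stopped_epoch = epoch,
    split = sp
  ), class = "siamese_fit")
}

#' @export
print.siamese_fit <- function(x, ...) {
  h <- x$history
  cat("Fitted Siamese multimodal similarity model\n")
  cat("  epochs run : ", x$stopped_epoch, " (best epoch ", x$best_epoch,
      ")\n", sep = "")
  cat(sprintf("  final loss : train %.4f, val %.4f\n",
              h$train_loss[nrow(h)], h$val_loss[nrow(h)]))
  cat(sprintf("  best val   : %.4f\n", min(h$val_loss)))
  invisible(x)
}

#' @export
summary.siamese_fit <- function(object, ...) {
  print(object)
  print(object$model)
  invisible(object)
}

#' @export
coef.siamese_fit <- function(object, ...) object$model$params

#' Plot training and validation loss curves
#'
#' @param x A `"siamese_fit"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.siamese_fit <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "triplet loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Predict embeddings or pairwise similarity for new samples
#'
#' @param object A `"siamese_fit"`.
#' @param samples Named list of multimodal samples.
#' @param type `"embeddings"` (matrix, one row per sample) or
#'   `"similarity"` (inverse-distance matrix).
#' @param ... Unused.
#' @export
predict.siamese_fit <- function(object, samples,
                                type = c("embeddings", "similarity"), ...) {
  type <- match.arg(type)
  E <- embed_samples(object$model, samples)
  if (type == "embeddings") E else inverse_distance_matrix(E)
}

#' Save / load a fitted model checkpoint
#'
#' The checkpoint is a single RDS archive containing config, weights and
#' training history.
#'
#' @param fit A `"siamese_fit"` (or `"siamese_model"`).
#' @param path Checkpoint file path.
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  readRDS(path)
}

#' Export a training history as CSV
#'
#' @param fit A `"siamese_fit"`.
#' @param path Output CSV path.
#' @export
write_history_csv <- function(fit, path) {
  utils::write.csv(fit$history, path, row.names = FALSE)
  invisible(path)
}
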