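# Training loop: Adam, cosine learning-rate decay over the planned steps,
# MSE loss, early stopping on validation loss, best-epoch checkpointing.

adam_init <- function(p) {
  list(m = lapply(p, function(x) array(0, dim(x) %||% length(x))),
       v = lapply(p, function(x) array(0, dim(x) %||% length(x))),
       t = 0L)
}

adam_step <- function(p, g, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(g)) {
    gi <- g[[nm]]
    if (is.null(gi)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * as.vector(gi)
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * as.vector(gi)^2
    upd <- lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
    p[[nm]] <- if (is.null(dim(p[[nm]]))) {
      p[[nm]] - as.vector(upd)
    } else {
      p[[nm]] - array(upd, dim(p[[nm]]))
    }
  }
  list(p = p, st = st)
}

predict_batched <- function(p, bn, cfg, seq_mat, ref_mat, mask_ref,
                            batch_size = 1024L) {
  n <- nrow(seq_mat)
  out <- numeric(n)
  for (s in seq.int(1L, n, batch_size)) {
    e <- min(s + batch_size - 1L, n)
    out[s:e] <- forward_pass(p, bn, cfg, seq_mat[s:e, , drop = FALSE],
                             ref_mat[s:e, , drop = FALSE],
                             train = FALSE, mask_ref = mask_ref)$pred
  }
  out
}

#' Train the two-branch density model
#'
#' Minimizes mean squared error with Adam under a cosine learning-rate decay
#' normalized over the planned steps (`max_epochs x batches/epoch`).
#' Training stops early when the validation loss has not decreased for
#' `patience` epochs, and the returned model carries the parameters of the
#' best validation epoch. Fully reproducible given `train_cfg$seed`.
#'
#' @param ds a `WindowDataset` from [build_windows()].
#' @param split a `DatasetSplit` in `"fraction"` mode providing `train` and
#'   `validation` partitions (the `test` partition is left untouched).
#' @param model_cfg a [model_config()]; its `W` must match `ds$W`.
#' @param train_cfg a [train_config()].
#' @param mask_ref train as a pure sequence model (reference branch replaced
#'   by a learned constant vector).
#' @param verbose print per-epoch losses.
#' @return a `ribocast_model`: configs, learned parameters, batch-norm
#'   statistics, data-transform metadata, and a training `log` data frame
#'   (epoch, train_mse, val_mse) with `best_epoch` and `stop_epoch`.
#' @export
train_model <- function(ds, split, model_cfg = model_config(W = ds$W),
                        train_cfg = train_config(), mask_ref = FALSE,
                        verbose = FALSE) {
  abort_if(model_cfg$W != ds$W, "model W (", model_cfg$W,
           ") does not match dataset W (", ds$W, ")")
  abort_if(split$mode != "fraction",
           "train_model needs a fraction-mode split (train/validation)")
  idx_tr <- which(split$assignment == "train")
  idx_va <- which(split$assignment == "validation")
  abort_if(!length(idx_tr), "empty training set")
  abort_if(!length(idx_va), "empty validation set")

  seq_tr <- ds$seq[idx_tr, , drop = FALSE]
  ref_tr <- ds$ref[idx_tr, , drop = FALSE]
  y_tr <- ds$target[idx_tr]
  seq_va <- ds$seq[idx_va, , drop = FALSE]
  ref_va <- ds$ref[idx_va, , drop = FALSE]
  y_va <- ds$target[idx_va]

  n_tr <- length(y_tr)
  bsz <- min(train_cfg$batch_size, n_tr)
  steps_per_epoch <- ceiling(n_tr / bsz)
  total_steps <- train_cfg$max_epochs * steps_per_epoch

  res <- with_seed(train_cfg$seed, {
    p <- init_params(model_cfg)
    bn <- init_bn_state(model_cfg)
    opt <- adam_init(p)
    best <- list(p = p, bn = bn, val = Inf, epoch = 0L)
    log <- data.frame(epoch = integer(), train_mse = double(),
                      val_mse = double())
    stale <- 0L
    step <- 0L
    epoch <- 0L
    while (epoch < train_cfg$max_epochs) {
      epoch <- epoch + 1L
      perm <- sample.int(n_tr)
      tr_loss <- 0
      for (s in seq.int(1L, n_tr, bsz)) {
        e <- min(s + bsz - 1L, n_tr)
        b <- perm[s:e]
        fw <- forward_pass(p, bn, model_cfg, seq_tr[b, , drop = FALSE],
                           ref_tr[b, , drop = FALSE], train = TRUE,
                           mask_ref = mask_ref, keep_cache = TRUE)
        bn <- fw$bn
        resid <- fw$pred - y_tr[b]
        tr_loss <- tr_loss + sum(resid^2)
        g <- backward_pass(2 * resid / length(b), fw$cache, p, model_cfg)
        lr <- cosine_lr(step / total_steps, train_cfg$start_lr)
        upd <- adam_step(p, g, opt, lr)
        p <- upd$p
        opt <- upd$st
        step <- step + 1L
      }
      val_pred <- predict_batched(p, bn, model_cfg, seq_va, ref_va, mask_ref)
      val_mse <- mean((val_pred - y_va)^2)
      log <- rbind(log, data.frame(epoch = epoch, train_mse = tr_loss / n_tr,
                                   val_mse = val_mse))
      if (verbose) {
        message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                        tr_loss / n_tr, val_mse))
      }
      if (val_mse < best$val - 1e-12) {
        best <- list(p = p, bn = bn, val = val_mse, epoch = epoch)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= train_cfg$patience) break
      }
    }
    list(best = best, log = log, stop_epoch = epoch)
  })

  structure(list(config = model_cfg, train_config = train_cfg,
                 params = res$best$p, bn = res$best$bn,
                 mask_ref = mask_ref,
                 meta = list(W = ds$W,
                             ref_transform = ds$ref_transform,
                             target_transform = ds$target_transform,
                             pseudocount = ds$pseudocount),
                 log = res$log, best_epoch = res$best$epoch,
                 stop_epoch = res$stop_epoch),
            class = "ribocast_model")
}

#' @export
print.ribocast_model <- function(x, ...) {
  cat(sprintf(paste0("<ribocast_model> W=%d, %d conv blocks, %d filters, ",
                     "%d heads%s; best epoch %d/%d (val MSE %.5f)\n"),
              x$config$W, x$config$conv_blocks, x$config$filters,
              x$config$attention_heads,
              if (x$mask_ref) ", reference masked" else "",
              x$best_epoch, x$stop_epoch,
              x$log$val_mse[match(x$best_epoch, x$log$epoch)]))
  invisible(x)
}

#' Predict densities for a window dataset
#'
#' Deterministic evaluation-mode forward pass. The dataset must have been
#' built with the model's window size and data transforms; mismatching
#' transform metadata is an error (silent mis-scaling is refused).
#'
#' @param object a `ribocast_model`.
#' @param ds a `WindowDataset`.
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return numeric vector of predictions, aligned with the instances of `ds`
#'   (attributes `gene` and `center_index` carry provenance).
#' @export
predict.ribocast_model <- function(object, ds, batch_size = 1024L, ...) {
  abort_if(ds$W != object$meta$W, "dataset W (", ds$W,
           ") does not match model W (", object$meta$W, ")")
  abort_if(!identical(ds$ref_transform, object$meta$ref_transform),
           "reference transform mismatch: dataset '", ds$ref_transform,
           "' vs model '", object$meta$ref_transform, "'")
  abort_if(!identical(ds$target_transform, object$meta$target_transform),
           "target transform mismatch: dataset '", ds$target_transform,
           "' vs model '", object$meta$target_transform, "'")
  pred <- predict_batched(object$params, object$bn, object$config,
                          ds$seq, ds$ref, object$mask_ref, batch_size)
  attr(pred, "gene") <- ds$gene
  attr(pred, "center_index") <- ds$center_index
  pred
}

#' Correlation and error metrics between predictions and truth
#'
#' @param pred,truth numeric vectors of equal length (>= 3).
#' @return list with `pearson`, `spearman` (average ranks for ties) and
#'   `mse`; correlations are `NA` with a warning when either vector has zero
#'   variance.
#' @export
evaluate_predictions <- function(pred, truth) {
  abort_if(length(pred) != length(truth), "length mismatch")
  abort_if(length(pred) < 3L, "need at least 3 paired values")
  if (stats::sd(pred) == 0 || stats::sd(truth) == 0) {
    warning("zero variance; correlations undefined", call. = FALSE)
    return(list(pearson = NA_real_, spearman = NA_real_,
                mse = mean((pred - truth)^2)))
  }
  list(pearson = stats::cor(pred, truth),
       spearman = stats::cor(pred, truth, method = "spearman"),
       mse = mean((pred - truth)^2))
}
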