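# Weakly supervised treatment classification: the pretext task that
# induces the morphology representation.  Single cells are classified
# into their treatment label (a weak label: it has no single-cell
# resolution and no guarantee of a phenotype), with balanced epochs,
# augmentation, optional online label smoothing, and per-epoch
# precision/recall/F1 reporting on both split schemes.

#' Training configuration
#'
#' @param backbone `"toy_cnn"` (desk-scale trainable CNN) or
#'   `"efficientnet_b0"` (feature-extraction backbone; see
#'   [efficientnet_b0()] — not trainable at desk scale).
#' @param epochs training epochs (30 by default).
#' @param batch_size minibatch size (32).
#' @param learning_rate plain SGD learning rate (0.005, momentum 0).
#' @param ols_enabled enable online label smoothing.
#' @param ols_alpha weight of the previous label in the online update
#'   (0.03): `L = alpha * L_prev + (1 - alpha) * L_pred`.
#' @param label_smoothing static label smoothing mixed into every target
#'   (0.1).
#' @param augment apply [augment_crop()] to every training crop.
#' @param n_filters,dense_dim toy backbone widths.
#' @param eval_subsample cap on cells used for per-epoch F1 curves.
#' @param seed master seed; epoch resampling derives from it.
#' @return `training_config` object.
#' @export
training_config <- function(backbone = c("toy_cnn", "efficientnet_b0"),
                            epochs = 30, batch_size = 32,
                            learning_rate = 0.005,
                            ols_enabled = FALSE, ols_alpha = 0.03,
                            label_smoothing = 0.1, augment = TRUE,
                            n_filters = c(16, 32), dense_dim = 64,
                            eval_subsample = 2000, seed = 1) {
  backbone <- match.arg(backbone)
  if (ols_alpha < 0 || ols_alpha > 1) stopf("ols_alpha must be in [0, 1]")
  if (label_smoothing < 0 || label_smoothing >= 1)
    stopf("label_smoothing must be in [0, 1)")
  structure(list(backbone = backbone, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 ols_enabled = isTRUE(ols_enabled), ols_alpha = ols_alpha,
                 label_smoothing = label_smoothing,
                 augment = isTRUE(augment), n_filters = n_filters,
                 dense_dim = dense_dim,
                 eval_subsample = as.integer(eval_subsample),
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Online label smoothing update
#'
#' `L = alpha * L_hard + (1 - alpha) * L_soft`: at the start of training
#' `L_hard` is the one-hot ground truth; in later epochs it is the label
#' produced by the previous epoch, and `L_soft` is the distribution
#' predicted at the end of the current epoch.
#'
#' @param L_hard,L_soft probability vectors (or matrices with matching
#'   shape/classes).
#' @param alpha mixing weight on `L_hard` (default 0.03).
#' @return The updated label distribution.
#' @export
ols_update <- function(L_hard, L_soft, alpha = 0.03) {
  if (!identical(dim(L_hard) %||% length(L_hard),
                 dim(L_soft) %||% length(L_soft)))
    stopf("L_hard and L_soft must cover the same classes")
  nh <- colnames(L_hard) %||% names(L_hard)
  ns <- colnames(L_soft) %||% names(L_soft)
  if (!is.null(nh) && !is.null(ns) && !identical(nh, ns))
    stopf("L_hard and L_soft must cover the same classes")
  if (alpha < 0 || alpha > 1) stopf("alpha must be in [0, 1]")
  alpha * L_hard + (1 - alpha) * L_soft
}

# Macro-averaged F1 plus per-class precision/recall from label vectors.
# Classes absent from `truth` get NA precision/recall (reported missing,
# not zero); macro-F1 averages over classes present in the truth.
classification_report <- function(truth, pred, classes) {
  per <- data.frame(class = classes, precision = NA_real_,
                    recall = NA_real_, f1 = NA_real_, support = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(classes)) {
    k <- classes[i]
    tp <- sum(truth == k & pred == k)
    fp <- sum(truth != k & pred == k)
    fn <- sum(truth == k & pred != k)
    per$support[i] <- sum(truth == k)
    if (per$support[i] > 0) {
      per$precision[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
      per$recall[i] <- tp / (tp + fn)
      per$f1[i] <- if (per$precision[i] + per$recall[i] > 0)
        2 * per$precision[i] * per$recall[i] /
          (per$precision[i] + per$recall[i]) else 0
    }
  }
  list(per_class = per,
       macro_f1 = mean(per$f1[per$support > 0]),
       accuracy = mean(truth == pred))
}

#' Train the weakly supervised treatment classifier
#'
#' Categorical cross-entropy over treatment classes with static label
#' smoothing, balanced epochs via [balanced_epoch_sample()],
#' augmentation of every training crop, plain SGD, and optional online
#' label smoothing ([ols_update()]) applied to per-example labels at the
#' end of each epoch.  Per-epoch train/validation macro-F1 learning
#' curves are recorded.
#'
#' @param cell_index cell index (after filters).
#' @param split a split data.frame from [split_leave_cells_out()] or
#'   [split_leave_plates_out()].
#' @param cfg a [training_config()].
#' @param crops `n x s x s x C` array aligned with `cell_index` rows,
#'   values in `[0, 1]` (see [load_crops()]).
#' @return `trained_model`: backbone parameters, class list, declared
#'   feature layer, training log (epoch, loss, train/val macro-F1).
#' @export
train_classifier <- function(cell_index, split, cfg, crops) {
  stopifnot(inherits(cfg, "training_config"))
  if (cfg$backbone != "toy_cnn")
    stopf("only the toy_cnn backbone is trainable at desk scale")
  classes <- sort(unique(cell_index$Treatment))
  K <- length(classes)
  if (K < 2) stopf("training needs >= 2 classes")
  side <- dim(crops)[2]; C <- dim(crops)[4]

  tag <- split$split[match(cell_index$cell_id, split$cell_id)]
  train_rows <- which(tag == "train")
  val_rows <- which(tag == "val")
  if (length(val_rows) == 0)
    warning("empty validation split; learning curves are train-only")
  if (length(train_rows) == 0) stopf("empty training split")

  params <- toy_cnn_init(side, C, K, cfg$n_filters, cfg$dense_dim,
                         seed = cfg$seed)
  crops <- normalize_crops(crops)   # backbone input contract
  y <- match(cell_index$Treatment, classes)
  labels <- matrix(0, nrow(cell_index), K)   # evolving per-example labels
  labels[cbind(seq_len(nrow(cell_index)), y)] <- 1
  ls <- cfg$label_smoothing

  log_rows <- list()
  eval_f1 <- function(rows) {
    if (length(rows) == 0) return(NA_real_)
    if (length(rows) > cfg$eval_subsample)
      rows <- with_seed(cfg$seed,
                        rows[sample.int(length(rows), cfg$eval_subsample)])
    fw <- toy_cnn_forward(params, crops[rows, , , , drop = FALSE])
    pred <- classes[max.col(fw$probs)]
    classification_report(cell_index$Treatment[rows], pred, classes)$macro_f1
  }

  for (e in seq_len(cfg$epochs)) {
    ids <- balanced_epoch_sample(cell_index[train_rows, , drop = FALSE],
                                 seed = derive_seed(cfg$seed, "epoch", e))
    rows <- match(ids, cell_index$cell_id)
    epoch_loss <- 0; n_batches <- 0
    last_pred <- matrix(NA_real_, nrow(cell_index), K)
    with_seed(derive_seed(cfg$seed, "sgd", e), {
      for (b0 in seq(1, length(rows), by = cfg$batch_size)) {
        bi <- rows[b0:min(b0 + cfg$batch_size - 1, length(rows))]
        xb <- crops[bi, , , , drop = FALSE]
        if (cfg$augment) {
          for (j in seq_along(bi))
            xb[j, , , ] <- augment_crop(array(xb[j, , , ],
                                              dim = dim(xb)[-1]))
        }
        tgt <- labels[bi, , drop = FALSE] * (1 - ls) + ls / K
        fw <- toy_cnn_forward(params, xb, keep_cache = TRUE)
        epoch_loss <- epoch_loss -
          mean(rowSums(tgt * log(fw$probs + 1e-12)))
        n_batches <- n_batches + 1
        dlogits <- (fw$probs - tgt) / length(bi)
        g <- toy_cnn_backward(params, fw, dlogits)
        params <- toy_cnn_sgd_step(params, g, cfg$learning_rate)
        last_pred[bi, ] <- fw$probs
      }
    })
    if (cfg$ols_enabled) {
      seen <- which(!is.na(last_pred[, 1]))
      labels[seen, ] <- ols_update(labels[seen, , drop = FALSE],
                                   last_pred[seen, , drop = FALSE],
                                   cfg$ols_alpha)
    }
    log_rows[[e]] <- data.frame(
      epoch = e, loss = epoch_loss / max(n_batches, 1),
      train_macro_f1 = eval_f1(train_rows),
      val_macro_f1 = eval_f1(val_rows))
  }

  structure(list(backbone = "toy_cnn", params = params, classes = classes,
                 feature_layer = "dense1",
                 log = if (length(log_rows)) do.call(rbind, log_rows) else
                   data.frame(epoch = integer(0), loss = numeric(0),
                              train_macro_f1 = numeric(0),
                              val_macro_f1 = numeric(0)),
                 cfg = cfg, input_side = side, n_channels = C),
            class = "trained_model")
}

#' Predict treatment class probabilities for crops
#'
#' @param model a `trained_model`.
#' @param crops `n x s x s x C` array in `[0, 1]`.
#' @return n x K probability matrix with class columns.
#' @export
predict_cells <- function(model, crops) {
  fw <- toy_cnn_forward(model$params, normalize_crops(crops))
  colnames(fw$probs) <- model$classes
  fw$probs
}

#' Pretext-task report: per-class precision/recall and macro F1
#'
#' Computed from the single-cell confusion matrix on one partition of a
#' split.  Classes absent from the partition are reported with missing
#' (NA) precision/recall rather than zero.
#'
#' @param model a `trained_model`.
#' @param crops crop array aligned with `cell_index`.
#' @param cell_index cell index data.frame.
#' @param split split assignment data.frame.
#' @param partition `"train"` or `"val"`.
#' @return list with `per_class` (class, precision, recall, f1, support),
#'   `macro_f1`, `accuracy`.
#' @export
pretext_report <- function(model, crops, cell_index, split,
                           partition = "val") {
  tag <- split$split[match(cell_index$cell_id, split$cell_id)]
  rows <- which(tag == partition)
  if (length(rows) == 0) stopf("partition '%s' is empty", partition)
  probs <- predict_cells(model, crops[rows, , , , drop = FALSE])
  pred <- model$classes[max.col(probs)]
  classification_report(cell_index$Treatment[rows], pred, model$classes)
}
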