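# EfficientNet-B0 feature-extraction backbone.
#
# The architecture (stem + seven MBConv stages with squeeze-and-
# excitation, swish activations, compound-scaling filter rounding) is
# implemented from its published specification so that layer shapes are
# exact: the expansion activation of the first block of stage 6
# ("block6a") has 672 channels in B0, which is the feature layer used
# for profiling.  Weights are randomly initialized (seeded); pretrained
# ImageNet weights are an external binary artifact and may be supplied
# by the caller as a compatible parameter list.  The backbone is
# forward-only: it extracts features, it is not trainable here.

# B0 stage table: expansion factor, output channels, repeats, stride,
# kernel size (stage i = blocks "block<i>a", "block<i>b", ...).
.b0_stages <- data.frame(
  expand = c(1, 6, 6, 6, 6, 6, 6),
  channels = c(16, 24, 40, 80, 112, 192, 320),
  repeats = c(1, 2, 2, 3, 3, 4, 1),
  stride = c(1, 2, 2, 2, 1, 2, 1),
  kernel = c(3, 3, 5, 5, 3, 5, 3))

# Width rounding used by compound scaling (divisor 8).
round_filters <- function(filters, width = 1, divisor = 8) {
  f <- filters * width
  new_f <- max(divisor, floor((f + divisor / 2) / divisor) * divisor)
  if (new_f < 0.9 * f) new_f <- new_f + divisor
  as.integer(new_f)
}

round_repeats <- function(repeats, depth = 1) as.integer(ceiling(depth * repeats))

# Walk the architecture and produce the per-block layer plan.
.b0_plan <- function(width = 1, depth = 1) {
  stem <- round_filters(32, width)
  blocks <- list()
  cin <- stem
  for (s in seq_len(nrow(.b0_stages))) {
    st <- .b0_stages[s, ]
    cout <- round_filters(st$channels, width)
    reps <- round_repeats(st$repeats, depth)
    for (r in seq_len(reps)) {
      blocks[[length(blocks) + 1]] <- list(
        id = sprintf("block%d%s", s, letters[r]),
        cin = cin, cout = cout,
        cexp = as.integer(cin * st$expand),
        expand = st$expand, kernel = st$kernel,
        stride = if (r == 1) st$stride else 1L,
        se_reduce = max(1L, as.integer(cin * 0.25)))
      cin <- cout
    }
  }
  list(stem = stem, blocks = blocks)
}

#' Instantiate an EfficientNet-B0 feature extractor
#'
#' Builds the B0 layer graph (stem convolution and 16 MBConv blocks with
#' squeeze-and-excitation) with seeded random weights, up to and
#' including the block6a expansion activation whose global average pool
#' is the 672-dimensional feature vector.
#'
#' @param input_channels input channels (3 for the pseudo-RGB path, 5
#'   for native Cell Painting crops).
#' @param feature_layer currently only `"block6a_expand_activation"`.
#' @param seed weight-initialization seed.
#' @return `efficientnet_b0` object with the layer plan and weights.
#' @export
efficientnet_b0 <- function(input_channels = 3,
                            feature_layer = "block6a_expand_activation",
                            seed = 1) {
  plan <- .b0_plan()
  feat_block <- sub("_expand_activation$", "", feature_layer)
  ids <- vapply(plan$blocks, `[[`, character(1), "id")
  fi <- match(feat_block, ids)
  if (is.na(fi))
    stopf("feature layer '%s' not found; available: %s", feature_layer,
          paste(paste0(ids, "_expand_activation"), collapse = ", "))
  he <- function(fan_in, n) stats::rnorm(n, 0, sqrt(2 / fan_in))
  weights <- with_seed(seed, {
    w <- list(stem = array(he(9 * input_channels,
                              9 * input_channels * plan$stem),
                           dim = c(3, 3, input_channels, plan$stem)))
    for (b in plan$blocks[seq_len(fi)]) {
      bw <- list()
      if (b$expand != 1)
        bw$expand <- array(he(b$cin, b$cin * b$cexp),
                           dim = c(1, 1, b$cin, b$cexp))
      if (b$id != feat_block) {
        bw$dw <- array(he(b$kernel^2, b$kernel^2 * b$cexp),
                       dim = c(b$kernel, b$kernel, b$cexp))
        bw$se_red <- matrix(he(b$cexp, b$cexp * b$se_reduce),
                            b$cexp, b$se_reduce)
        bw$se_red_b <- rep(0, b$se_reduce)
        bw$se_exp <- matrix(he(b$se_reduce, b$se_reduce * b$cexp),
                            b$se_reduce, b$cexp)
        bw$se_exp_b <- rep(0, b$cexp)
        bw$project <- array(he(b$cexp, b$cexp * b$cout),
                            dim = c(1, 1, b$cexp, b$cout))
      }
      w[[b$id]] <- bw
    }
    w
  })
  structure(list(plan = plan, weights = weights,
                 input_channels = as.integer(input_channels),
                 feature_layer = feature_layer, feature_block = fi,
                 feature_dim = plan$blocks[[fi]]$cexp, seed = seed),
            class = "efficientnet_b0")
}

#' Feature dimensionality of a backbone
#'
#' For EfficientNet-B0 this is the channel count of the declared feature
#' layer, derived from the architecture (672 for block6a's expansion in
#' B0) and independent of input spatial size; for a trained toy CNN it
#' is the dense feature-layer width.
#'
#' @param model an `efficientnet_b0` or `trained_model`.
#' @return integer feature dimension.
#' @export
feature_dim <- function(model) {
  if (inherits(model, "efficientnet_b0")) return(model$feature_dim)
  if (inherits(model, "trained_model")) return(length(model$params$bd))
  stopf("unknown model type")
}

# Forward one H x W x C image ([-1, 1] floats) to the feature layer.
.b0_forward_one <- function(model, x) {
  w <- model$weights
  plan <- model$plan
  h <- swish(conv2d(x, w$stem, stride = 2, pad = "same"))
  for (bi in seq_len(model$feature_block)) {
    b <- plan$blocks[[bi]]
    bw <- w[[b$id]]
    inp <- h
    h <- if (b$expand != 1)
      swish(conv2d(h, bw$expand, stride = 1, pad = "same")) else h
    if (bi == model$feature_block) return(global_avg_pool(h))
    h <- swish(depthwise_conv2d(h, bw$dw, stride = b$stride, pad = "same"))
    # squeeze and excitation
    se <- global_avg_pool(h)
    se <- swish(drop(se %*% bw$se_red) + bw$se_red_b)
    se <- sigmoid(drop(se %*% bw$se_exp) + bw$se_exp_b)
    h <- sweep(h, 3, se, `*`)
    h <- conv2d(h, bw$project, stride = 1, pad = "same")
    if (b$stride == 1 && b$cin == b$cout) h <- h + inp
  }
  stop("unreachable")
}

#' Extract single-cell features with a backbone
#'
#' One inference pass per cell; the feature vector is the global average
#' pool of the declared feature layer.  A 5-channel trained model
#' consumes all channels simultaneously; with the `efficientnet_b0`
#' backbone the result has length 672.
#'
#' @param model a `trained_model` (toy CNN) or [efficientnet_b0()] whose
#'   `input_channels` matches the crops.
#' @param crops `n x s x s x C` array.  Toy-CNN crops are `[0, 1]`;
#'   B0 inputs are expected in `[-1, 1]`.
#' @return `n x d` feature matrix.
#' @export
extract_features <- function(model, crops) {
  n <- dim(crops)[1]
  if (inherits(model, "trained_model")) {
    fw <- toy_cnn_forward(model$params, normalize_crops(crops))
    return(fw$features)
  }
  if (inherits(model, "efficientnet_b0")) {
    if (dim(crops)[4] != model$input_channels)
      stopf("crops have %d channels, model expects %d", dim(crops)[4],
            model$input_channels)
    out <- matrix(0, n, model$feature_dim)
    for (i in seq_len(n))
      out[i, ] <- .b0_forward_one(model,
                                  array(crops[i, , , ],
                                        dim = dim(crops)[-1]))
    return(out)
  }
  stopf("unknown model type")
}

#' Pseudo-RGB encoding of one fluorescence channel
#'
#' Resizes a single-channel crop to `size x size` (bilinear), min-max
#' rescales and maps it affinely to `[-1, 1]`, and replicates it to
#' three identical channels, the format ImageNet-pretrained models
#' expect.  A constant channel maps to all `-1` (degenerate min-max).
#'
#' @param channel_image numeric matrix (one channel of a crop).
#' @param size output side (default 224).
#' @return `size x size x 3` array in `[-1, 1]`.
#' @export
pseudo_rgb <- function(channel_image, size = 224) {
  x <- as.matrix(EBImage::resize(channel_image, w = size, h = size))
  rng <- range(x)
  x <- if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) * 2 - 1
       else matrix(-1, size, size)
  array(rep(x, 3), dim = c(size, size, 3))
}

#' Pretrained-style features via the pseudo-RGB protocol
#'
#' Each of the five channels is encoded with [pseudo_rgb()] and passed
#' through a 3-channel EfficientNet-B0 (five inference passes per cell);
#' the per-channel 672-vectors are concatenated in channel order into a
#' 3,360-dimensional feature vector.
#'
#' @param model a 3-channel [efficientnet_b0()].
#' @param crops `n x s x s x 5` array.
#' @param size pseudo-RGB input side (default 224).
#' @return `n x (5 * 672)` feature matrix.
#' @export
extract_pretrained_rgb_features <- function(model, crops, size = 224) {
  stopifnot(inherits(model, "efficientnet_b0"))
  if (model$input_channels != 3)
    stopf("pseudo-RGB extraction needs a 3-channel backbone")
  C <- dim(crops)[4]
  if (C != 5) stopf("pseudo-RGB concatenation is defined for 5-channel crops, got %d", C)
  n <- dim(crops)[1]
  d <- model$feature_dim
  out <- matrix(0, n, C * d)
  for (i in seq_len(n)) {
    for (cc in seq_len(C)) {
      rgb <- pseudo_rgb(crops[i, , , cc], size = size)
      out[i, (cc - 1) * d + seq_len(d)] <- .b0_forward_one(model, rgb)
    }
  }
  out
}

#' Write per-site feature archives
#'
#' One plain-text CSV per field of view (`<plate>/<well>_<site>.csv`,
#' rows in locations order) plus an `index.csv` sidecar, mirroring
#' per-field-of-view array storage.
#'
#' @param features `n x d` matrix aligned with `cell_index` rows.
#' @param cell_index cell index data.frame.
#' @param dir output directory.
#' @return invisible sidecar data.frame.
#' @export
write_feature_archive <- function(features, cell_index, dir) {
  skey <- paste(cell_index$Metadata_Plate, cell_index$Metadata_Well,
                cell_index$Metadata_Site, sep = "|")
  rows <- list()
  for (s in unique(skey)) {
    sel <- which(skey == s)
    plate <- cell_index$Metadata_Plate[sel[1]]
    f <- sprintf("%s/%s_%s.csv", plate, cell_index$Metadata_Well[sel[1]],
                 cell_index$Metadata_Site[sel[1]])
    dir.create(file.path(dir, plate), recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(features[sel, , drop = FALSE]),
                     file.path(dir, f), row.names = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      Metadata_Plate = plate,
      Metadata_Well = cell_index$Metadata_Well[sel[1]],
      Metadata_Site = cell_index$Metadata_Site[sel[1]],
      path = f, n_cells = length(sel), stringsAsFactors = FALSE)
  }
  sidecar <- do.call(rbind, rows)
  utils::write.csv(sidecar, file.path(dir, "index.csv"), row.names = FALSE)
  invisible(sidecar)
}

#' Read a per-site feature archive written by [write_feature_archive()]
#'
#' @param dir archive directory.
#' @return list with `features` (matrix) and `index` (sidecar rows,
#'   one per site, in archive order).
#' @export
read_feature_archive <- function(dir) {
  sidecar <- utils::read.csv(file.path(dir, "index.csv"),
                             stringsAsFactors = FALSE)
  mats <- lapply(sidecar$path, function(p)
    as.matrix(utils::read.csv(file.path(dir, p))))
  list(features = do.call(rbind, mats), index = sidecar)
}

#' Simple per-channel intensity features
#'
#' A fast, deterministic baseline featurizer for desk-scale pipeline
#' runs: per channel the mean, standard deviation and the 25th, 75th and
#' 90th intensity percentiles of the crop (5 features per channel).
#'
#' @param crops `n x s x s x C` array.
#' @return `n x (5 * C)` matrix with named columns.
#' @export
extract_baseline_features <- function(crops) {
  n <- dim(crops)[1]; C <- dim(crops)[4]
  out <- matrix(0, n, 5 * C)
  cn <- character(5 * C)
  for (cc in seq_len(C)) {
    m <- matrix(crops[, , , cc], n, prod(dim(crops)[2:3]))
    qs <- t(apply(m, 1, stats::quantile, probs = c(0.25, 0.75, 0.9),
                  names = FALSE))
    blk <- (cc - 1) * 5
    out[, blk + 1] <- rowMeans(m)
    out[, blk + 2] <- apply(m, 1, stats::sd)
    out[, blk + 3:5] <- qs
    cn[blk + 1:5] <- sprintf("Ch%d_%s", cc,
                             c("mean", "sd", "q25", "q75", "q90"))
  }
  colnames(out) <- cn
  out
}
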