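# Single-cell training corpus: cell index construction with the
# max-concentration and minimum-cell-count filters, nucleus-centered
# cropping, the two train/validation split schemes, balanced epoch
# sampling, augmentation, and multiple-instance-learning bags.

#' Build the single-cell index of an experiment
#'
#' Joins nucleus locations with image metadata into one row per cell and
#' applies the corpus filters: when a treatment was screened at several
#' concentrations only the maximum concentration is kept, and treatment
#' classes with fewer than `min_cells` cells are dropped (negative
#' controls are never dropped).
#'
#' @param bundle an `experiment_bundle`.
#' @param min_cells minimum cells per treatment class (default 100).
#' @param max_concentration_only apply the concentration filter.
#' @return data.frame with columns `cell_id`, `Metadata_Plate`,
#'   `Metadata_Well`, `Metadata_Site`, `X`, `Y`, `Treatment`, `Control`,
#'   `Concentration`.
#' @export
build_cell_index <- function(bundle, min_cells = 100,
                             max_concentration_only = TRUE) {
  loc <- bundle$locations
  idx <- bundle$image_index
  key <- function(d) paste(d$Metadata_Plate, d$Metadata_Well,
                           d$Metadata_Site, sep = "|")
  m <- match(key(loc), key(idx))
  if (anyNA(m)) stopf("locations reference sites absent from the index")
  cells <- data.frame(
    Metadata_Plate = loc$Metadata_Plate,
    Metadata_Well = loc$Metadata_Well,
    Metadata_Site = loc$Metadata_Site,
    X = loc$Nuclei_Location_Center_X,
    Y = loc$Nuclei_Location_Center_Y,
    Treatment = idx$Treatment[m],
    Control = idx$Control[m],
    Concentration = idx$Concentration[m],
    stringsAsFactors = FALSE)
  if (max_concentration_only && nrow(cells) > 0) {
    cmax <- tapply(cells$Concentration, cells$Treatment, max)
    keep <- cells$Concentration == cmax[cells$Treatment]
    cells <- cells[keep, , drop = FALSE]
  }
  if (min_cells > 0 && nrow(cells) > 0) {
    sizes <- table(cells$Treatment[!cells$Control])
    small <- names(sizes)[sizes < min_cells]
    cells <- cells[cells$Control | !(cells$Treatment %in% small), ,
                   drop = FALSE]
  }
  rownames(cells) <- NULL
  cells$cell_id <- sprintf("%s|%s|%s|%d", cells$Metadata_Plate,
                           cells$Metadata_Well, cells$Metadata_Site,
                           stats::ave(seq_len(nrow(cells)),
                                      key(cells), FUN = seq_along))
  cells[, c("cell_id", "Metadata_Plate", "Metadata_Well", "Metadata_Site",
            "X", "Y", "Treatment", "Control", "Concentration")]
}

#' Crop fixed-size patches centered on nuclei
#'
#' Each crop is `crop_size x crop_size x C`, centered on the nucleus with
#' the half-open window `[c - crop_size/2, c + crop_size/2)` in 0-based
#' pixel coordinates (`X` = column).  No resizing and no masking: cell
#' context is preserved, and regions outside the image support are
#' zero-filled.
#'
#' @param field H x W x C image array.
#' @param centers data.frame with 0-based `X`, `Y` columns.
#' @param crop_size crop side in pixels.
#' @return list of crop arrays, in `centers` order.
#' @export
crop_cells <- function(field, centers, crop_size = 128) {
  d <- dim(field)
  H <- d[1]; W <- d[2]; C <- if (length(d) == 3) d[3] else 1L
  if (length(d) == 2) dim(field) <- c(H, W, 1L)
  half <- crop_size %/% 2
  out <- vector("list", nrow(centers))
  for (i in seq_len(nrow(centers))) {
    cx <- round(centers$X[i]); cy <- round(centers$Y[i])
    if (cx < 0 || cx > W - 1 || cy < 0 || cy > H - 1)
      stopf("center %d at (%s, %s) lies outside the %d x %d image",
            i, format(centers$X[i]), format(centers$Y[i]), H, W)
    crop <- array(0, dim = c(crop_size, crop_size, C))
    # half-open source window in 0-based coordinates
    r0 <- cy - half; c0 <- cx - half
    rs <- max(r0, 0):min(r0 + crop_size - 1, H - 1)
    cs <- max(c0, 0):min(c0 + crop_size - 1, W - 1)
    crop[rs - r0 + 1, cs - c0 + 1, ] <- field[rs + 1, cs + 1, , drop = FALSE]
    out[[i]] <- crop
  }
  out
}

#' Materialize all crops of a cell index as one array
#'
#' Loads each site image once and extracts nucleus-centered crops,
#' rescaled from integer counts to `[0, 1]`.
#'
#' @param bundle an `experiment_bundle`.
#' @param cell_index output of [build_cell_index()].
#' @param crop_size crop side in pixels.
#' @param scale divisor turning counts into `[0, 1]` (default `2^16 - 1`).
#' @return numeric array `n_cells x crop_size x crop_size x C`, rows
#'   aligned with `cell_index`.
#' @export
load_crops <- function(bundle, cell_index, crop_size = 128, scale = 65535) {
  C <- bundle$config$n_channels %||%
    length(grep("^Channel_\\d+_Path$", names(bundle$image_index)))
  n <- nrow(cell_index)
  out <- array(0, dim = c(n, crop_size, crop_size, C))
  skey <- paste(cell_index$Metadata_Plate, cell_index$Metadata_Well,
                cell_index$Metadata_Site, sep = "|")
  for (s in unique(skey)) {
    rows <- which(skey == s)
    r1 <- rows[1]
    field <- load_site_image(bundle, cell_index$Metadata_Plate[r1],
                             cell_index$Metadata_Well[r1],
                             cell_index$Metadata_Site[r1])
    crops <- crop_cells(field, cell_index[rows, c("X", "Y")], crop_size)
    for (j in seq_along(rows)) out[rows[j], , , ] <- crops[[j]] / scale
  }
  out
}

#' Per-channel contrast normalization of crops
#'
#' Rescales every channel of every crop to `[0, 1]` by its own min-max
#' range (constant channels map to zero).  This is the input contract of
#' the trainable backbone: pixel brightness is treated as meaningful
#' relative to structure within the same channel, not absolutely, which
#' also makes training and inference see identically scaled inputs (the
#' augmentation pipeline renormalizes the same way).
#'
#' @param crops `n x s x s x C` array.
#' @return normalized array, same shape.
#' @export
normalize_crops <- function(crops) {
  n <- dim(crops)[1]; C <- dim(crops)[4]
  for (i in seq_len(n)) {
    for (cc in seq_len(C)) {
      x <- crops[i, , , cc]
      r <- range(x)
      crops[i, , , cc] <- if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1])
                          else x * 0
    }
  }
  crops
}

#' Leave-cells-out train/validation split
#'
#' Random cells of every well go to training, the rest to validation,
#' stratified so that each well contributes `round(train_frac * n)`
#' training cells (approximately 60% by default).
#'
#' @param cell_index cell index data.frame.
#' @param train_frac training fraction within each well.
#' @param seed RNG seed.
#' @return data.frame `cell_id`, `split` (`"train"`/`"val"`) with
#'   attributes `scheme = "leave_cells_out"` and `seed`.
#' @export
split_leave_cells_out <- function(cell_index, train_frac = 0.6, seed = 1) {
  if (nrow(cell_index) == 0) stopf("empty cell index")
  if (train_frac < 0 || train_frac > 1) stopf("train_frac must be in [0, 1]")
  wkey <- paste(cell_index$Metadata_Plate, cell_index$Metadata_Well,
                sep = "|")
  split <- rep("val", nrow(cell_index))
  with_seed(seed, {
    for (w in unique(wkey)) {
      rows <- which(wkey == w)
      n_train <- round(train_frac * length(rows))
      if (n_train > 0)
        split[rows[sample.int(length(rows), n_train)]] <- "train"
    }
  })
  out <- data.frame(cell_id = cell_index$cell_id, split = split,
                    stringsAsFactors = FALSE)
  attr(out, "scheme") <- "leave_cells_out"
  attr(out, "seed") <- seed
  out
}

#' Leave-plates-out train/validation split
#'
#' Searches plate subsets (smallest first, deterministic order) for one
#' whose held-out plates give every treatment at least
#' `n_replicate_wells_out` validation wells while keeping at least one
#' training well per treatment.  Plates are atomic: all cells of a plate
#' share one tag.
#'
#' @param cell_index cell index data.frame.
#' @param n_replicate_wells_out required held-out replicate wells per
#'   treatment.
#' @return split data.frame as in [split_leave_cells_out()], with
#'   attributes `scheme`, `plates_out` and `heldout_wells` (per-treatment
#'   held-out well counts).
#' @export
split_leave_plates_out <- function(cell_index, n_replicate_wells_out = 2) {
  if (nrow(cell_index) == 0) stopf("empty cell index")
  wells <- unique(cell_index[, c("Metadata_Plate", "Metadata_Well",
                                 "Treatment", "Control")])
  trts <- sort(unique(wells$Treatment[!wells$Control]))
  plates <- sort(unique(wells$Metadata_Plate))
  count_wells <- function(tr, pl)
    sum(wells$Treatment == tr & wells$Metadata_Plate %in% pl)
  total <- vapply(trts, count_wells, numeric(1), pl = plates)
  short <- trts[total < n_replicate_wells_out + 1]
  if (length(short) > 0)
    stopf("leave-plates-out infeasible: treatment(s) %s have too few wells",
          paste(short, collapse = ", "))
  for (k in seq_len(length(plates) - 1)) {
    combos <- utils::combn(plates, k, simplify = FALSE)
    for (out_pl in combos) {
      held <- vapply(trts, count_wells, numeric(1), pl = out_pl)
      kept <- vapply(trts, count_wells, numeric(1),
                     pl = setdiff(plates, out_pl))
      if (all(held >= n_replicate_wells_out) && all(kept >= 1)) {
        split <- ifelse(cell_index$Metadata_Plate %in% out_pl,
                        "val", "train")
        res <- data.frame(cell_id = cell_index$cell_id, split = split,
                          stringsAsFactors = FALSE)
        attr(res, "scheme") <- "leave_plates_out"
        attr(res, "plates_out") <- out_pl
        attr(res, "heldout_wells") <- held
        return(res)
      }
    }
  }
  stopf("leave-plates-out infeasible: no plate subset gives every treatment %d held-out wells and 1 training well",
        n_replicate_wells_out)
}

#' Balanced epoch sample of cell ids
#'
#' Every class (each treatment and the control class) contributes exactly
#' the median class size m: classes above the median are subsampled
#' without replacement, classes below it are oversampled with
#' replacement.  Call once per epoch to resample.
#'
#' @param cell_index cell index (typically the training partition).
#' @param seed RNG seed for this epoch.
#' @return character vector of cell ids, shuffled, of length
#'   `m * n_classes`.
#' @export
balanced_epoch_sample <- function(cell_index, seed = 1) {
  if (nrow(cell_index) == 0) stopf("empty cell index")
  cls <- split(cell_index$cell_id, cell_index$Treatment)
  m <- round(stats::median(lengths(cls)))
  with_seed(seed, {
    ids <- unlist(lapply(cls, function(x) {
      if (length(x) >= m) sample(x, m)
      else sample(x, m, replace = TRUE)
    }), use.names = FALSE)
    sample(ids)
  })
}

#' Augment one single-cell crop
#'
#' Three steps, matching common practice for fluorescence crops:
#' (1) with probability 0.5, a random sub-square of side 80-100% of the
#' crop is taken and resized back (bilinear); (2) an independent
#' horizontal flip (p = 0.5) and a rotation by a random multiple of 90
#' degrees; (3) per-channel brightness/contrast jitter in which all
#' pixels of a channel change by the same amounts, followed by
#' re-clipping to `[0, 1]` and per-channel min-max renormalization
#' (pixel brightness is meaningful relative to structure within the same
#' channel, not absolutely).
#'
#' @param crop `s x s x C` array with values in `[0, 1]`.
#' @param crop_prob probability of the crop-and-resize branch.
#' @param scale_range sub-square side range as a fraction of the crop.
#' @param brightness_delta brightness shift is drawn uniformly from
#'   `[-brightness_delta, brightness_delta]` (fraction of dynamic range).
#' @param contrast_range contrast factor range.
#' @param draws optional list of pre-drawn decisions for testing:
#'   `do_crop`, `scale`, `ox`, `oy` (offsets in `[0,1]`), `flip`,
#'   `rot` (0-3), `contrast`, `brightness` (per channel).
#' @return augmented crop, same shape.
#' @export
augment_crop <- function(crop, crop_prob = 0.5, scale_range = c(0.8, 1.0),
                         brightness_delta = 0.15,
                         contrast_range = c(0.8, 1.2), draws = NULL) {
  d <- dim(crop); s <- d[1]; C <- d[3]
  dr <- draws %||% list(
    do_crop = stats::runif(1) < crop_prob,
    scale = stats::runif(1, scale_range[1], scale_range[2]),
    ox = stats::runif(1), oy = stats::runif(1),
    flip = stats::runif(1) < 0.5,
    rot = sample(0:3, 1),
    contrast = stats::runif(C, contrast_range[1], contrast_range[2]),
    brightness = stats::runif(C, -brightness_delta, brightness_delta))

  if (isTRUE(dr$do_crop)) {
    side <- max(2L, round(dr$scale * s))
    r0 <- 1L + floor(dr$oy * (s - side + 0.999))
    c0 <- 1L + floor(dr$ox * (s - side + 0.999))
    sub <- crop[r0:(r0 + side - 1), c0:(c0 + side - 1), , drop = FALSE]
    res <- array(0, dim = d)
    for (cc in seq_len(C))
      res[, , cc] <- as.matrix(EBImage::resize(sub[, , cc], w = s, h = s))
    crop <- res
  }
  if (isTRUE(dr$flip)) crop <- crop[, d[2]:1, , drop = FALSE]
  r <- (dr$rot %||% 0) %% 4
  if (r > 0) {
    for (i in seq_len(r)) {
      # 90 degree counter-clockwise rotation of each channel
      crop <- aperm(crop, c(2, 1, 3))[d[1]:1, , , drop = FALSE]
    }
  }
  for (cc in seq_len(C)) {
    x <- crop[, , cc] * dr$contrast[cc] + dr$brightness[cc]
    x <- pmin(pmax(x, 0), 1)
    rng <- range(x)
    crop[, , cc] <- if (rng[2] > rng[1])
      (x - rng[1]) / (rng[2] - rng[1]) else x * 0
  }
  crop
}

#' Build multiple-instance-learning bags
#'
#' Bags of `bag_size` cells with weak labels: a bag labeled with the
#' negative-control class contains only control cells; a bag labeled
#' with a treatment contains between `treated_range[1]` and
#' `treated_range[2]` cells of that treatment (25-75% of the bag) with
#' the remainder drawn from negative controls.  Every class gets the
#' same number of bags; call once per epoch to resample.
#'
#' @param cell_index cell index data.frame.
#' @param bag_size cells per bag.
#' @param n_bags_per_class bags per class; default
#'   `max(1, round(m / bag_size))` with m the median class size.
#' @param treated_range inclusive range of treated members per treated bag.
#' @param seed RNG seed.
#' @return list of bags: `list(label=, cell_ids=, n_treated=)`.
#' @export
build_mil_bags <- function(cell_index, bag_size = 16,
                           n_bags_per_class = NULL,
                           treated_range = c(4, 12), seed = 1) {
  ctrl_ids <- cell_index$cell_id[cell_index$Control]
  if (length(ctrl_ids) == 0) stopf("no negative-control cells available")
  cls <- split(cell_index$cell_id[!cell_index$Control],
               cell_index$Treatment[!cell_index$Control])
  ctrl_label <- unique(cell_index$Treatment[cell_index$Control])[1]
  sizes <- c(lengths(cls), length(ctrl_ids))
  n_bags <- n_bags_per_class %||%
    max(1L, round(round(stats::median(sizes)) / bag_size))
  samp <- function(x, k) x[sample.int(length(x), k, replace = k > length(x))]
  with_seed(seed, {
    bags <- list()
    for (b in seq_len(n_bags)) {
      bags[[length(bags) + 1]] <- list(
        label = ctrl_label, cell_ids = samp(ctrl_ids, bag_size),
        n_treated = 0L)
    }
    for (tr in names(cls)) {
      for (b in seq_len(n_bags)) {
        k <- sample(seq(treated_range[1], treated_range[2]), 1)
        bags[[length(bags) + 1]] <- list(
          label = tr,
          cell_ids = c(samp(cls[[tr]], k), samp(ctrl_ids, bag_size - k)),
          n_treated = as.integer(k))
      }
    }
    bags
  })
}
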