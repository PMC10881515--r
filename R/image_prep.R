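# Preprocessing and compression of 16-bit microscopy images:
# retrospective per-plate-channel illumination correction, percentile
# histogram stretch, 16 -> 8 bit quantization and lossless PNG export.

#' Fit a retrospective illumination correction function
#'
#' The correction surface is the pixelwise mean across all images of one
#' plate-channel, downscaled to 25% of the image height/width, smoothed
#' (median filter with window = 1/4 of the downscaled dimension followed
#' by a Gaussian blur with sigma = window/4; robust to the cells
#' themselves), and rescaled so that its robust minimum (1st percentile)
#' equals 1.0 — correction therefore only dims relatively bright regions.
#'
#' @param images list of numeric matrices (one channel of every field of
#'   view of one plate), all the same shape.
#' @param plate,channel identity recorded in the result.
#' @param smooth_window median-filter window in pixels of the downscaled
#'   surface; default `max(3, round(min(dim)/4))`.
#' @return An object of class `illumination_function` with elements
#'   `surface` (the downscaled positive correction field), `full_shape`,
#'   `plate`, `channel`.
#' @export
fit_illumination <- function(images, plate = NA, channel = NA,
                             smooth_window = NULL) {
  if (length(images) == 0) stopf("fit_illumination needs >= 1 image")
  shp <- dim(images[[1]])
  for (im in images) {
    if (!identical(dim(im), shp)) stopf("all images must share one shape")
  }
  m <- Reduce(`+`, images) / length(images)
  ds_shape <- pmax(round(0.25 * shp), 1)
  surf <- EBImage::resize(m, w = ds_shape[1], h = ds_shape[2])
  w <- smooth_window %||% max(3L, round(min(ds_shape) / 4))
  # medianFilter operates on [0,1] data
  hi <- max(surf)
  if (hi > 0) {
    radius <- max(1L, as.integer(w %/% 2))
    surf <- EBImage::medianFilter(surf / hi, radius) * hi
    surf <- as.matrix(EBImage::gblur(surf, sigma = max(w / 4, 0.5)))
  }
  robust_min <- stats::quantile(surf, 0.01, names = FALSE, type = 7)
  if (robust_min <= 0) robust_min <- max(min(surf[surf > 0]), 1e-6)
  surf <- pmax(surf / robust_min, 1e-6)
  structure(list(surface = surf, full_shape = shp,
                 plate = plate, channel = channel),
            class = "illumination_function")
}

#' Upsample an illumination surface to a target shape
#'
#' @param fn an `illumination_function`.
#' @param shape target `c(height, width)`; default the fitted full shape.
#' @return numeric matrix of the requested shape, strictly positive.
#' @export
illumination_surface <- function(fn, shape = fn$full_shape) {
  up <- as.matrix(EBImage::resize(fn$surface, w = shape[1], h = shape[2]))
  pmax(up, 1e-6)
}

#' Persist an illumination function as plain text
#'
#' One file per plate-channel: the surface as a headerless CSV matrix
#' plus a JSON sidecar (`<path>.json`) with plate, channel and the full
#' image shape.
#'
#' @param fn an `illumination_function`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_illumination <- function(fn, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(fn$surface, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(plate = fn$plate, channel = fn$channel,
                            full_shape = fn$full_shape),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load an illumination function written by [write_illumination()]
#'
#' @param path CSV path.
#' @return an `illumination_function`.
#' @export
read_illumination <- function(path) {
  surf <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(surf) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(surface = surf, full_shape = as.integer(meta$full_shape),
                 plate = meta$plate, channel = meta$channel),
            class = "illumination_function")
}

#' Apply an illumination correction function to one image
#'
#' Divides the image pixelwise by the upsampled correction surface.
#'
#' @param image numeric matrix.
#' @param fn an `illumination_function` fitted on images of this shape.
#' @return corrected image, numeric (double), non-negative.
#' @export
apply_illumination <- function(image, fn) {
  if (!identical(dim(image), fn$full_shape))
    stopf("image shape (%s) does not match illumination function (%s)",
          paste(dim(image), collapse = "x"),
          paste(fn$full_shape, collapse = "x"))
  image / illumination_surface(fn, dim(image))
}

#' Percentile histogram stretch and 16-to-8 bit quantization
#'
#' Pixels below the `p_low` and above the `p_high` percentile of this
#' image (linear-interpolation empirical percentiles) are clipped, the
#' clipped range is mapped affinely to `[0, 255]` and rounded
#' half-to-even.  Constant (zero-range) images map to all zeros.
#'
#' @param image numeric matrix.
#' @param p_low,p_high clipping percentiles, in percent.
#' @return integer matrix with values in `[0, 255]` and attribute
#'   `bits = 8`.
#' @export
stretch_and_quantize <- function(image, p_low = 0.05, p_high = 99.95) {
  if (length(image) == 0) stopf("empty image")
  if (p_low >= p_high) stopf("p_low must be < p_high")
  q <- stats::quantile(image, c(p_low, p_high) / 100, names = FALSE,
                       type = 7)
  out <- if (q[2] <= q[1]) {
    matrix(0L, nrow(image), ncol(image))
  } else {
    x <- pmin(pmax(image, q[1]), q[2])
    matrix(as.integer(round((x - q[1]) / (q[2] - q[1]) * 255)),
           nrow(image), ncol(image))
  }
  attr(out, "bits") <- 8L
  out
}

#' Raw buffer size of an image at a given bit depth
#'
#' Encodes the pixel buffer with `writeBin` at the integer width implied
#' by the bit depth and returns its length in bytes (8-bit pixels take
#' one byte, 16-bit pixels two).
#'
#' @param image numeric/integer matrix.
#' @param bits bit depth (8 or 16); default taken from the image's
#'   `bits` attribute, else 16.
#' @return number of bytes.
#' @export
image_buffer_bytes <- function(image, bits = attr(image, "bits") %||% 16L) {
  if (!bits %in% c(8L, 16L)) stopf("bits must be 8 or 16")
  length(writeBin(as.integer(image), raw(), size = bits / 8))
}

#' Compress every image of an experiment bundle to 8-bit PNG
#'
#' Per plate and channel: fit the illumination correction function on all
#' sites, then correct, stretch, quantize and save each image as a
#' lossless 8-bit grayscale PNG mirroring the original layout.
#'
#' @param bundle an `experiment_bundle` with images on disk.
#' @param out_dir output directory.
#' @param use_illum disable illumination correction with `FALSE`.
#' @param overwrite refuse to clobber an existing manifest unless TRUE.
#' @return A manifest data.frame (original, compressed, plate, channel,
#'   bytes_in, bytes_out, status) with a `summary` attribute counting
#'   failures; `n_failed > 0` marks a degraded run.
#' @export
compress_dataset <- function(bundle, out_dir, use_illum = TRUE,
                             overwrite = FALSE) {
  idx <- bundle$image_index
  chan_cols <- grep("^Channel_\\d+_Path$", names(idx), value = TRUE)
  manifest_path <- file.path(out_dir, "compression_manifest.csv")
  if (file.exists(manifest_path) && !overwrite)
    stopf("manifest already exists in %s (use overwrite = TRUE)", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (plate in unique(idx$Metadata_Plate)) {
    prows <- which(idx$Metadata_Plate == plate)
    for (ci in seq_along(chan_cols)) {
      paths <- idx[[chan_cols[ci]]][prows]
      imgs <- list(); ok <- logical(length(paths))
      for (i in seq_along(paths)) {
        im <- tryCatch(
          round(tiff::readTIFF(file.path(bundle$root, paths[i])) * 65535),
          error = function(e) NULL)
        ok[i] <- !is.null(im)
        imgs[[i]] <- im
      }
      fn <- if (use_illum && any(ok))
        fit_illumination(imgs[ok], plate = plate, channel = ci) else NULL
      for (i in seq_along(paths)) {
        rel_out <- sub("\\.tiff?$", ".png", paths[i])
        status <- "ok"
        if (!ok[i]) {
          status <- "read_error"
          warning(sprintf("skipping unreadable image %s", paths[i]))
        } else {
          im <- imgs[[i]]
          if (!is.null(fn)) im <- apply_illumination(im, fn)
          q8 <- stretch_and_quantize(im)
          dir.create(dirname(file.path(out_dir, rel_out)),
                     recursive = TRUE, showWarnings = FALSE)
          png::writePNG(q8 / 255, file.path(out_dir, rel_out))
        }
        rows[[length(rows) + 1]] <- data.frame(
          original = paths[i], compressed = rel_out, plate = plate,
          channel = ci,
          bytes_in = if (ok[i])
            file.size(file.path(bundle$root, paths[i])) else NA_real_,
          bytes_out = if (ok[i])
            file.size(file.path(out_dir, rel_out)) else NA_real_,
          status = status, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  attr(manifest, "summary") <- list(
    n_images = nrow(manifest),
    n_failed = sum(manifest$status != "ok"),
    compression_ratio = sum(manifest$bytes_in, na.rm = TRUE) /
      max(sum(manifest$bytes_out, na.rm = TRUE), 1))
  manifest
}
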