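# Synthetic Cell Painting experiment generator.
#
# The generator emulates the structure of a high-throughput perturbation
# screen: plates hold wells, wells hold fields of view (sites), each site
# is a 5-channel 16-bit image of blob-like cells.  Two latent variables
# drive pixel content, mirroring the causal structure of real screens:
#   * the treatment applied to the well shifts per-channel blob intensity
#     and size along a mechanism-of-action (MoA) direction, scaled by a
#     per-treatment effect size;
#   * technical confounders add plate-level multiplicative gains and
#     illumination gradients plus well-position-level additive background
#     shifts, independent of any phenotype.
# Treatments recur at the same well positions across plates by default,
# mimicking plate-map designs that are not fully randomized.

#' Configuration of a synthetic perturbation experiment
#'
#' @param n_plates number of plates.
#' @param wells_per_plate wells per plate; `NULL` derives the smallest
#'   layout holding all treatment positions plus control wells.
#' @param sites_per_well fields of view imaged per well.
#' @param n_treatments number of non-control treatments.
#' @param n_moa_classes number of mechanism-of-action classes; treatments
#'   are assigned round-robin so every class keeps at least two members
#'   (the evaluation needs every class to be queryable).
#' @param replicates_per_treatment minimum number of replicate wells per
#'   treatment across the experiment.
#' @param control_label label of the negative-control "treatment".
#' @param effect_sizes numeric vector (length `n_treatments`) of
#'   non-negative phenotype shift magnitudes, in log-intensity units.
#'   The default grades effects from weak (0.1) to strong (1.2).
#' @param confounder_sizes named numeric `c(plate=, well=)` scaling the
#'   two levels of the technical-variation hierarchy.  The plate level
#'   drives per-plate-channel log-gains, the within-image illumination
#'   gradient amplitude, and the plate's base defocus blur and seeding
#'   density drift; the well level drives the per-well additive
#'   background shift (fraction of the background level) plus well-
#'   position jitter of blur and density nested within the plate.
#' @param cells_per_site_mean Poisson mean of the cell count per site.
#' @param image_shape `c(height, width)` in pixels.
#' @param n_channels number of fluorescence channels (channel 1 = nuclei).
#' @param bit_depth pixel depth of the written TIFFs (16).
#' @param crop_size single-cell crop size the experiment is designed for;
#'   `image_shape` must be at least twice this in both dimensions.
#' @param randomize_layout if `TRUE`, the well-position assignment of
#'   treatments is re-randomized per plate instead of the default fixed
#'   plate map.
#' @param seed master seed; every field of view derives its own stream
#'   from it via [derive_seed()].
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_plates = 3,
                              wells_per_plate = NULL,
                              sites_per_well = 3,
                              n_treatments = 20,
                              n_moa_classes = NULL,
                              replicates_per_treatment = NULL,
                              control_label = "DMSO",
                              effect_sizes = NULL,
                              confounder_sizes = c(plate = 0.3, well = 0.15),
                              cells_per_site_mean = 12,
                              image_shape = c(160, 160),
                              n_channels = 5,
                              bit_depth = 16,
                              crop_size = 64,
                              randomize_layout = FALSE,
                              seed = 1) {
  n_moa_classes <- n_moa_classes %||% min(5L, n_treatments %/% 2L)
  replicates_per_treatment <- replicates_per_treatment %||% n_plates
  if (is.null(effect_sizes)) {
    effect_sizes <- if (n_treatments > 0)
      round(seq(0.2, 2.0, length.out = n_treatments), 3) else numeric(0)
  }
  if (length(effect_sizes) != n_treatments)
    stopf("effect_sizes must have length n_treatments (%d), got %d",
          n_treatments, length(effect_sizes))
  if (any(effect_sizes < 0)) stopf("effect_sizes must be non-negative")
  if (n_treatments > 0 && n_moa_classes > n_treatments)
    stopf("n_moa_classes (%d) exceeds n_treatments (%d)",
          n_moa_classes, n_treatments)
  if (n_treatments > 0 && n_moa_classes > 0 &&
      n_treatments < 2 * n_moa_classes)
    stopf(paste("every MoA class needs >= 2 treatments:",
                "n_treatments must be >= 2 * n_moa_classes"))
  if (any(image_shape < 2 * crop_size))
    stopf("image_shape (%d x %d) is smaller than 2 x crop_size (%d)",
          image_shape[1], image_shape[2], crop_size)
  if (length(confounder_sizes) != 2)
    stopf("confounder_sizes must be c(plate=, well=)")
  names(confounder_sizes) <- c("plate", "well")

  ppt <- if (n_treatments > 0)
    as.integer(ceiling(replicates_per_treatment / n_plates)) else 0L
  min_wells <- n_treatments * ppt + 2L
  wells_per_plate <- wells_per_plate %||%
    (n_treatments * ppt + max(4L, ceiling(0.5 * max(n_treatments, 1L))))
  if (wells_per_plate < min_wells)
    stopf("wells_per_plate = %d cannot hold %d treatment positions plus controls",
          wells_per_plate, n_treatments * ppt)

  structure(list(
    n_plates = as.integer(n_plates),
    wells_per_plate = as.integer(wells_per_plate),
    sites_per_well = as.integer(sites_per_well),
    n_treatments = as.integer(n_treatments),
    n_moa_classes = as.integer(n_moa_classes),
    replicates_per_treatment = as.integer(replicates_per_treatment),
    positions_per_treatment = ppt,
    control_label = control_label,
    effect_sizes = effect_sizes,
    confounder_sizes = confounder_sizes,
    cells_per_site_mean = cells_per_site_mean,
    image_shape = as.integer(image_shape),
    n_channels = as.integer(n_channels),
    bit_depth = as.integer(bit_depth),
    crop_size = as.integer(crop_size),
    randomize_layout = isTRUE(randomize_layout),
    seed = as.integer(seed)
  ), class = "experiment_config")
}

# Rendering constants: photon-count scale of a 16-bit sCMOS-like sensor.
.render_const <- list(
  background = 300,        # background level, counts
  amp_nucleus = 4000,      # peak nucleus blob amplitude (channel 1)
  amp_cyto = 2500,         # peak cytoplasm ring amplitude (other channels)
  r_nucleus = 5,           # nucleus Gaussian sigma, px
  r_cyto = 9,              # cytoplasm ring radius, px
  noise_sd = 30,           # additive read-noise sd, counts
  shot = 0.02,             # multiplicative (shot-like) noise coefficient
  cell_jitter = 0.15,      # per-cell lognormal intensity jitter sd
  margin = 12              # minimum distance of nucleus centers to borders
)

#' Render one synthetic field of view
#'
#' Cells are drawn as a Gaussian nucleus blob in channel 1 and Gaussian
#' annular cytoplasm rings in the remaining channels.  The treatment
#' effect moves per-channel blob intensity and radius monotonically:
#' channel c is scaled by `exp(effect * dir[c])` in intensity and by
#' `exp(0.4 * effect * dir[n_channels + c])` in radius, where `dir` is a
#' unit phenotype direction.  Confounders enter as a per-channel
#' multiplicative gain, a linear illumination gradient across the field,
#' and an additive well-position background offset.
#'
#' @param n_cells number of cells to render (0 gives background only).
#' @param shape `c(height, width)` pixels.
#' @param n_channels number of channels.
#' @param treatment_effect non-negative effect magnitude.
#' @param effect_direction unit vector of length `2 * n_channels`
#'   (intensity components then radius components); `NULL` means no
#'   phenotype direction (effect ignored).
#' @param plate_gain per-channel multiplicative gain (scalar recycled).
#' @param illum_gradient `list(angle=, amplitude=)`: a multiplicative
#'   linear gradient `1 + amplitude * (proj - 0.5)` along `angle`.
#' @param well_offset per-channel additive background offset, counts.
#' @param blur defocus blur of this field in pixels (standard deviation
#'   added in quadrature to the blob widths, amplitude renormalized to
#'   conserve integrated intensity) — a structural well-level confounder
#'   that survives per-channel contrast normalization.
#' @param seed RNG seed for this field (see [derive_seed()]).
#' @return `list(image = H x W x C array of integer counts in
#'   [0, 2^16 - 1], centers = data.frame(X, Y))` with 0-based pixel
#'   coordinates, `X` = column.
#' @export
render_field <- function(n_cells, shape = c(160, 160), n_channels = 5,
                         treatment_effect = 0, effect_direction = NULL,
                         plate_gain = 1,
                         illum_gradient = list(angle = 0, amplitude = 0),
                         well_offset = 0, blur = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  H <- shape[1]; W <- shape[2]; C <- n_channels
  k <- .render_const
  plate_gain <- rep_len(plate_gain, C)
  well_offset <- rep_len(well_offset, C)
  if (is.null(effect_direction)) effect_direction <- rep(0, 2 * C)

  int_fac <- exp(treatment_effect * effect_direction[seq_len(C)])
  rad_fac <- exp(0.4 * treatment_effect * effect_direction[C + seq_len(C)])

  img <- array(0, dim = c(H, W, C))
  centers <- data.frame(X = numeric(0), Y = numeric(0))
  if (n_cells > 0) {
    m <- k$margin
    cx <- runif(n_cells, m, W - 1 - m)   # 0-based column
    cy <- runif(n_cells, m, H - 1 - m)   # 0-based row
    jit <- matrix(exp(rnorm(n_cells * C, 0, k$cell_jitter)), n_cells, C)
    for (i in seq_len(n_cells)) {
      for (cc in seq_len(C)) {
        if (cc == 1) {
          amp <- k$amp_nucleus * int_fac[cc] * jit[i, cc]
          sig <- k$r_nucleus * rad_fac[cc]
          rad <- 0
        } else {
          amp <- k$amp_cyto * int_fac[cc] * jit[i, cc]
          rad <- k$r_cyto * rad_fac[cc]
          sig <- 0.35 * rad
        }
        if (blur > 0) {
          sig_eff <- sqrt(sig^2 + blur^2)
          amp <- amp * (sig / sig_eff)^(if (cc == 1) 2 else 1)
          sig <- sig_eff
        }
        ext <- ceiling(rad + 3.5 * sig)
        rows <- max(1, floor(cy[i] + 1 - ext)):min(H, ceiling(cy[i] + 1 + ext))
        cols <- max(1, floor(cx[i] + 1 - ext)):min(W, ceiling(cx[i] + 1 + ext))
        dy <- (rows - 1) - cy[i]
        dx <- (cols - 1) - cx[i]
        d <- sqrt(outer(dy^2, dx^2, `+`))
        blob <- amp * exp(-((d - rad)^2) / (2 * sig^2))
        img[rows, cols, cc] <- img[rows, cols, cc] + blob
      }
    }
    centers <- data.frame(X = cx, Y = cy)
  }

  # illumination gradient field (shared across channels within the site)
  a <- illum_gradient$angle %||% 0
  amp <- illum_gradient$amplitude %||% 0
  if (amp != 0) {
    gx <- matrix((seq_len(W) - 1) / max(W - 1, 1), H, W, byrow = TRUE)
    gy <- matrix((seq_len(H) - 1) / max(H - 1, 1), H, W)
    proj <- cos(a) * gx + sin(a) * gy
    proj <- (proj - min(proj)) / max(max(proj) - min(proj), 1e-12)
    grad <- 1 + amp * (proj - 0.5)
  } else {
    grad <- 1
  }

  for (cc in seq_len(C)) {
    x <- (img[, , cc] + k$background + well_offset[cc]) * plate_gain[cc]
    x <- x * grad
    noise <- rnorm(H * W, 0, k$noise_sd) + x * rnorm(H * W, 0, k$shot)
    x <- x + noise
    img[, , cc] <- pmin(pmax(round(x), 0), 65535)
  }
  list(image = img, centers = centers)
}

# Build the plate layout: a wells-per-plate long assignment of treatments
# and controls to named well positions.  Returns a data.frame with one
# row per (plate, well).
.plate_layout <- function(cfg) {
  npos <- cfg$wells_per_plate
  ncols <- ceiling(sqrt(npos))
  nrows <- ceiling(npos / ncols)
  pos_names <- sprintf("%s%02d",
                       rep(LETTERS[seq_len(nrows)], each = ncols),
                       rep(seq_len(ncols), nrows))[seq_len(npos)]
  n_tr_pos <- cfg$n_treatments * cfg$positions_per_treatment
  # controls spread evenly over the plate
  ctrl_idx <- unique(round(seq(1, npos, length.out = npos - n_tr_pos)))
  while (length(ctrl_idx) < npos - n_tr_pos)
    ctrl_idx <- sort(union(ctrl_idx, setdiff(seq_len(npos), ctrl_idx)[1]))
  base_assign <- rep(NA_character_, npos)
  base_assign[ctrl_idx] <- cfg$control_label
  if (cfg$n_treatments > 0) {
    tr_names <- sprintf("TRT%03d", seq_len(cfg$n_treatments))
    base_assign[setdiff(seq_len(npos), ctrl_idx)] <-
      rep(tr_names, each = cfg$positions_per_treatment)
  }
  rows <- lapply(seq_len(cfg$n_plates), function(p) {
    assign <- base_assign
    if (cfg$randomize_layout) {
      # keep controls somewhere on the plate, shuffle everything
      assign <- sample(assign)
    }
    data.frame(Metadata_Plate = sprintf("Plate%d", p),
               Metadata_Well = pos_names,
               Position = seq_len(npos),
               Treatment = assign,
               Control = assign == cfg$control_label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate a complete synthetic Cell Painting experiment
#'
#' Renders every field of view to per-channel 16-bit TIFF files under
#' `out_dir/images/` and assembles the metadata index, per-site nucleus
#' locations, MoA annotations and the ground-truth record of every
#' parameter used for rendering.  Deterministic given `cfg$seed`.
#'
#' @param cfg an [experiment_config()].
#' @param out_dir output directory (created if missing).
#' @param write_images if `FALSE`, images are kept in memory only
#'   (returned in the `images` element) and no TIFFs are written.
#' @return An object of class `experiment_bundle`: list with `root`,
#'   `image_index`, `locations`, `annotations`, `truth`, `config` (and
#'   `images` when `write_images = FALSE`).
#' @export
generate_experiment <- function(cfg, out_dir = tempfile("synthexp"),
                                write_images = TRUE) {
  stopifnot(inherits(cfg, "experiment_config"))
  C <- cfg$n_channels
  layout <- NULL
  truth <- NULL

  with_seed(cfg$seed, {
    layout <- .plate_layout(cfg)

    # MoA classes and phenotype directions
    if (cfg$n_treatments > 0) {
      tr_names <- sprintf("TRT%03d", seq_len(cfg$n_treatments))
      moa <- if (cfg$n_moa_classes > 0)
        sprintf("MoA%02d", ((seq_len(cfg$n_treatments) - 1) %%
                              cfg$n_moa_classes) + 1)
      else rep("MoA01", cfg$n_treatments)
      moa_dirs <- matrix(rnorm(max(cfg$n_moa_classes, 1) * 2 * C),
                         ncol = 2 * C)
      moa_dirs <- moa_dirs / sqrt(rowSums(moa_dirs^2))
      tr_dirs <- t(vapply(seq_len(cfg$n_treatments), function(i) {
        d <- moa_dirs[((i - 1) %% max(cfg$n_moa_classes, 1)) + 1, ] +
          0.25 * rnorm(2 * C)
        d / sqrt(sum(d^2))
      }, numeric(2 * C)))
      rownames(tr_dirs) <- tr_names
    } else {
      tr_names <- character(0); moa <- character(0)
      tr_dirs <- matrix(numeric(0), nrow = 0, ncol = 2 * C)
    }

    # confounders
    cs <- cfg$confounder_sizes
    plate_names <- sprintf("Plate%d", seq_len(cfg$n_plates))
    plate_gains <- matrix(exp(rnorm(cfg$n_plates * C, 0, cs["plate"])),
                          cfg$n_plates, C,
                          dimnames = list(plate_names, NULL))
    gradients <- data.frame(
      Metadata_Plate = plate_names,
      angle = runif(cfg$n_plates, 0, 2 * pi),
      amplitude = pmin(cs[["plate"]] * runif(cfg$n_plates, 0.5, 1.5), 0.8))
    # Structural confounders are hierarchical: a plate-level base
    # (acquisition-day defocus and seeding-density drift) plus
    # well-position jitter nested within the plate.  Together with the
    # per-channel gains and illumination gradients they confound
    # treatment within a plate and do not transfer across plates.
    plate_blur <- abs(rnorm(cfg$n_plates, 0, 1)) * 4 * cs["plate"]
    well_blur <- pmax(
      matrix(plate_blur, cfg$n_plates, cfg$wells_per_plate) +
        matrix(rnorm(cfg$n_plates * cfg$wells_per_plate, 0, 1) *
                 2 * cs["well"],
               cfg$n_plates, cfg$wells_per_plate), 0)
    well_density <- exp(
      matrix(rnorm(cfg$n_plates, 0, 0.6 * cs["plate"]),
             cfg$n_plates, cfg$wells_per_plate) +
        matrix(rnorm(cfg$n_plates * cfg$wells_per_plate, 0,
                     0.6 * cs["well"]),
               cfg$n_plates, cfg$wells_per_plate))
    well_offsets <- array(
      rnorm(cfg$n_plates * cfg$wells_per_plate * C, 0, cs["well"]) *
        .render_const$background,
      dim = c(cfg$n_plates, cfg$wells_per_plate, C))

    truth <- list(
      treatments = data.frame(Treatment = tr_names, MoA = moa,
                              effect_size = cfg$effect_sizes,
                              stringsAsFactors = FALSE),
      directions = tr_dirs,
      plate_gains = plate_gains,
      gradients = gradients,
      well_offsets = well_offsets,
      plate_blur = plate_blur,
      well_blur = well_blur,
      well_density = well_density,
      config = unclass(cfg))
  })

  if (write_images) dir.create(file.path(out_dir, "images"),
                               recursive = TRUE, showWarnings = FALSE)

  eff <- stats::setNames(cfg$effect_sizes, truth$treatments$Treatment)
  idx_rows <- list(); loc_rows <- list(); mem_images <- list()
  for (r in seq_len(nrow(layout))) {
    plate <- layout$Metadata_Plate[r]
    well <- layout$Metadata_Well[r]
    pidx <- match(plate, rownames(truth$plate_gains))
    tr <- layout$Treatment[r]
    is_ctrl <- layout$Control[r]
    for (s in seq_len(cfg$sites_per_well)) {
      sseed <- derive_seed(cfg$seed, plate, well, s)
      res <- with_seed(sseed, {
        n_cells <- stats::rpois(
          1, cfg$cells_per_site_mean *
            truth$well_density[pidx, layout$Position[r]])
        render_field(
          n_cells, shape = cfg$image_shape, n_channels = C,
          treatment_effect = if (is_ctrl) 0 else eff[[tr]],
          effect_direction = if (is_ctrl) NULL else truth$directions[tr, ],
          plate_gain = truth$plate_gains[pidx, ],
          illum_gradient = list(angle = truth$gradients$angle[pidx],
                                amplitude = truth$gradients$amplitude[pidx]),
          well_offset = truth$well_offsets[pidx, layout$Position[r], ],
          blur = truth$well_blur[pidx, layout$Position[r]])
      })
      paths <- sprintf("images/%s/%s_s%d_ch%d.tiff", plate, well, s,
                       seq_len(C))
      if (write_images) {
        dir.create(file.path(out_dir, "images", plate),
                   recursive = TRUE, showWarnings = FALSE)
        for (cc in seq_len(C)) {
          tiff::writeTIFF(res$image[, , cc] / 65535,
                          file.path(out_dir, paths[cc]),
                          bits.per.sample = 16, compression = "none")
        }
      } else {
        mem_images[[sprintf("%s/%s/%d", plate, well, s)]] <- res$image
      }
      row <- data.frame(Metadata_Plate = plate, Metadata_Well = well,
                        Metadata_Site = s, stringsAsFactors = FALSE)
      for (cc in seq_len(C)) row[[sprintf("Channel_%d_Path", cc)]] <- paths[cc]
      row$Treatment <- tr
      row$Control <- is_ctrl
      row$Concentration <- 1.0
      idx_rows[[length(idx_rows) + 1]] <- row
      if (nrow(res$centers) > 0) {
        loc_rows[[length(loc_rows) + 1]] <- data.frame(
          Metadata_Plate = plate, Metadata_Well = well, Metadata_Site = s,
          Nuclei_Location_Center_X = res$centers$X,
          Nuclei_Location_Center_Y = res$centers$Y,
          stringsAsFactors = FALSE)
      }
    }
  }

  image_index <- do.call(rbind, idx_rows)
  rownames(image_index) <- NULL
  locations <- if (length(loc_rows) > 0) do.call(rbind, loc_rows) else
    data.frame(Metadata_Plate = character(0), Metadata_Well = character(0),
               Metadata_Site = integer(0),
               Nuclei_Location_Center_X = numeric(0),
               Nuclei_Location_Center_Y = numeric(0))
  rownames(locations) <- NULL
  annotations <- truth$treatments[, c("Treatment", "MoA")]

  bundle <- structure(list(root = if (write_images) out_dir else NA_character_,
                           image_index = image_index,
                           locations = locations,
                           annotations = annotations,
                           truth = truth,
                           config = cfg),
                      class = "experiment_bundle")
  if (!write_images) bundle$images <- mem_images
  bundle
}

#' Load the 5-channel image of one site of a bundle
#'
#' @param bundle an `experiment_bundle`.
#' @param plate,well,site site identity.
#' @return H x W x C array of counts in `[0, 65535]`.
#' @export
load_site_image <- function(bundle, plate, well, site) {
  key <- sprintf("%s/%s/%s", plate, well, site)
  if (!is.null(bundle$images) && !is.null(bundle$images[[key]]))
    return(bundle$images[[key]])
  idx <- bundle$image_index
  r <- which(idx$Metadata_Plate == plate & idx$Metadata_Well == well &
               idx$Metadata_Site == site)
  if (length(r) != 1) stopf("site %s not found in image index", key)
  paths <- unlist(idx[r, grep("^Channel_\\d+_Path$", names(idx))])
  chans <- lapply(paths, function(p)
    round(tiff::readTIFF(file.path(bundle$root, p)) * 65535))
  array(unlist(chans), dim = c(dim(chans[[1]]), length(chans)))
}

#' Write the tables of an experiment bundle to disk
#'
#' Emits `index.csv`, `locations/<plate>/<well>_<site>.csv`,
#' `annotations.csv` and `truth.json` under `out_dir`.  Paths inside the
#' index are relative to `out_dir`.
#'
#' @param bundle an `experiment_bundle`.
#' @param out_dir target directory (created if missing).
#' @param overwrite refuse to clobber an existing `index.csv` unless TRUE.
#' @return Invisibly, a manifest data.frame (one row per written or
#'   referenced file, with a `type` column: `"table"` or `"image"`).
#' @export
write_bundle <- function(bundle, out_dir = bundle$root, overwrite = FALSE) {
  stopifnot(inherits(bundle, "experiment_bundle"))
  if (file.exists(file.path(out_dir, "index.csv")) && !overwrite)
    stopf("index.csv already exists in %s (use overwrite = TRUE)", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$image_index, file.path(out_dir, "index.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$annotations, file.path(out_dir, "annotations.csv"),
                   row.names = FALSE)
  files <- c("index.csv", "annotations.csv")
  idx <- bundle$image_index
  for (r in seq_len(nrow(idx))) {
    plate <- idx$Metadata_Plate[r]; well <- idx$Metadata_Well[r]
    site <- idx$Metadata_Site[r]
    d <- file.path(out_dir, "locations", plate)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    loc <- bundle$locations[
      bundle$locations$Metadata_Plate == plate &
        bundle$locations$Metadata_Well == well &
        bundle$locations$Metadata_Site == site,
      c("Nuclei_Location_Center_X", "Nuclei_Location_Center_Y"),
      drop = FALSE]
    f <- sprintf("locations/%s/%s_%s.csv", plate, well, site)
    utils::write.csv(loc, file.path(out_dir, f), row.names = FALSE)
    files <- c(files, f)
  }
  truth_json <- bundle$truth
  truth_json$directions <- as.data.frame(truth_json$directions)
  truth_json$plate_gains <- as.data.frame(truth_json$plate_gains)
  truth_json$well_offsets <- lapply(
    seq_len(dim(truth_json$well_offsets)[1]),
    function(p) as.data.frame(truth_json$well_offsets[p, , , drop = TRUE]))
  truth_json$well_blur <- as.data.frame(truth_json$well_blur)
  truth_json$well_density <- as.data.frame(truth_json$well_density)
  jsonlite::write_json(truth_json, file.path(out_dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE, dataframe = "columns")
  files <- c(files, "truth.json")
  manifest <- rbind(
    data.frame(path = files, type = "table", stringsAsFactors = FALSE),
    data.frame(path = unlist(idx[, grep("^Channel_\\d+_Path$", names(idx))],
                             use.names = FALSE),
               type = "image", stringsAsFactors = FALSE))
  invisible(manifest)
}

#' Read an experiment bundle written by [write_bundle()]
#'
#' @param dir directory holding `index.csv` and friends.
#' @return An `experiment_bundle` (without in-memory images; sites are
#'   loaded on demand from the TIFFs by [load_site_image()]).
#' @export
read_bundle <- function(dir) {
  idx <- utils::read.csv(file.path(dir, "index.csv"),
                         stringsAsFactors = FALSE)
  ann <- utils::read.csv(file.path(dir, "annotations.csv"),
                         stringsAsFactors = FALSE)
  loc_rows <- list()
  for (r in seq_len(nrow(idx))) {
    f <- file.path(dir, sprintf("locations/%s/%s_%s.csv",
                                idx$Metadata_Plate[r], idx$Metadata_Well[r],
                                idx$Metadata_Site[r]))
    loc <- utils::read.csv(f, stringsAsFactors = FALSE)
    if (nrow(loc) > 0) {
      loc_rows[[length(loc_rows) + 1]] <- data.frame(
        Metadata_Plate = idx$Metadata_Plate[r],
        Metadata_Well = idx$Metadata_Well[r],
        Metadata_Site = idx$Metadata_Site[r],
        loc, stringsAsFactors = FALSE)
    }
  }
  locations <- if (length(loc_rows) > 0) do.call(rbind, loc_rows) else
    data.frame(Metadata_Plate = character(0), Metadata_Well = character(0),
               Metadata_Site = integer(0),
               Nuclei_Location_Center_X = numeric(0),
               Nuclei_Location_Center_Y = numeric(0))
  rownames(locations) <- NULL
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  structure(list(root = dir, image_index = idx, locations = locations,
                 annotations = ann, truth = truth, config = truth$config),
            class = "experiment_bundle")
}
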