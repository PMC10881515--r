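test_that("image index enumerates plates x wells x sites with one file per channel", {
  cfg <- experiment_config(n_plates = 2, wells_per_plate = 4,
                           sites_per_well = 2, n_treatments = 2,
                           n_moa_classes = 1, image_shape = c(64, 64),
                           crop_size = 32, cells_per_site_mean = 3,
                           seed = 1)
  b <- generate_experiment(cfg, write_images = FALSE)
  expect_equal(nrow(b$image_index), 2 * 4 * 2)
  expect_length(grep("^Channel_\\d+_Path$", names(b$image_index)), 5)
  # all referenced channel paths are distinct
  paths <- unlist(b$image_index[grep("^Channel", names(b$image_index))])
  expect_equal(length(unique(paths)), 16 * 5)
})

test_that("a treatment-free experiment has only control wells and no annotations", {
  cfg <- experiment_config(n_plates = 1, wells_per_plate = 4,
                           sites_per_well = 1, n_treatments = 0,
                           image_shape = c(64, 64), crop_size = 32,
                           cells_per_site_mean = 3, seed = 2)
  b <- generate_experiment(cfg, write_images = FALSE)
  expect_true(all(b$image_index$Control))
  expect_equal(nrow(b$annotations), 0)
})

test_that("generation is deterministic given the config seed", {
  cfg <- experiment_config(n_plates = 1, wells_per_plate = 4,
                           sites_per_well = 1, n_treatments = 2,
                           n_moa_classes = 1, image_shape = c(64, 64),
                           crop_size = 32, cells_per_site_mean = 4,
                           seed = 7)
  b1 <- generate_experiment(cfg, write_images = FALSE)
  b2 <- generate_experiment(cfg, write_images = FALSE)
  expect_identical(b1$image_index, b2$image_index)
  expect_identical(b1$locations, b2$locations)
  expect_identical(b1$images, b2$images)
})

test_that("design invariants hold: controls everywhere, replicates across plates, queryable MoAs", {
  b <- fixture_bundle
  idx <- b$image_index
  for (p in unique(idx$Metadata_Plate))
    expect_true(any(idx$Control[idx$Metadata_Plate == p]))
  wells <- unique(idx[!idx$Control,
                      c("Metadata_Plate", "Metadata_Well", "Treatment")])
  tab <- table(wells$Treatment)
  expect_true(all(tab >= fixture_cfg$replicates_per_treatment))
  plates_per_trt <- tapply(wells$Metadata_Plate, wells$Treatment,
                           function(x) length(unique(x)))
  expect_true(all(plates_per_trt >= 2))
  expect_true(all(table(b$annotations$MoA) >= 2))
  # every site with locations exists in the index
  k1 <- paste(b$locations$Metadata_Plate, b$locations$Metadata_Well,
              b$locations$Metadata_Site)
  k2 <- paste(idx$Metadata_Plate, idx$Metadata_Well, idx$Metadata_Site)
  expect_true(all(k1 %in% k2))
  # truth records exactly the parameters used
  expect_equal(b$truth$treatments$effect_size, fixture_cfg$effect_sizes)
})

test_that("invalid designs are rejected", {
  expect_error(experiment_config(n_treatments = 2, n_moa_classes = 3),
               "exceeds|>= 2")
  expect_error(experiment_config(image_shape = c(100, 100),
                                 crop_size = 64),
               "smaller than 2 x crop_size")
  expect_error(experiment_config(n_treatments = 4, effect_sizes = c(1, 2)),
               "length")
})

test_that("with zero effects and zero confounders treated and control pixels are indistinguishable", {
  # render level: with zero effect the treated rendering process is the
  # control process, so fields with equal cell counts are exchangeable
  dirn <- rep(1 / sqrt(10), 10)
  f_t <- render_field(8, shape = c(96, 96), n_channels = 5,
                      treatment_effect = 0, effect_direction = dirn,
                      seed = 101)
  f_c <- render_field(8, shape = c(96, 96), n_channels = 5,
                      treatment_effect = 0, seed = 202)
  set.seed(1)
  expect_gt(suppressWarnings(stats::ks.test(
    sample(f_t$image, 1000), sample(f_c$image, 1000))$p.value), 0.01)

  # experiment level: enough sites that the latent per-site cell count
  # averages out of the pooled pixel marginal
  cfg <- experiment_config(n_plates = 1, wells_per_plate = 10,
                           sites_per_well = 10, n_treatments = 5,
                           n_moa_classes = 2,
                           effect_sizes = rep(0, 5),
                           confounder_sizes = c(plate = 0, well = 0),
                           image_shape = c(96, 96), crop_size = 32,
                           cells_per_site_mean = 8, seed = 5)
  b <- generate_experiment(cfg, write_images = FALSE)
  idx <- b$image_index
  key <- function(r) sprintf("%s/%s/%d", idx$Metadata_Plate[r],
                             idx$Metadata_Well[r], idx$Metadata_Site[r])
  pool <- function(rows)
    unlist(lapply(rows, function(r) as.vector(b$images[[key(r)]])))
  # pool pixels across wells so the per-site latent cell count averages
  # out and draws approximate the marginal pixel distribution
  set.seed(1)
  px_t <- sample(pool(which(!idx$Control)), 1000)
  px_c <- sample(pool(which(idx$Control)), 1000)
  expect_gt(suppressWarnings(stats::ks.test(px_t, px_c)$p.value), 0.01)
})

test_that("render_field handles empty fields and is seed-deterministic", {
  r0 <- render_field(0, shape = c(64, 64), n_channels = 3, seed = 9)
  expect_equal(nrow(r0$centers), 0)
  expect_true(all(r0$image >= 0))
  r1 <- render_field(5, shape = c(64, 64), n_channels = 3,
                     treatment_effect = 0, seed = 11)
  r2 <- render_field(5, shape = c(64, 64), n_channels = 3,
                     treatment_effect = 0, seed = 11)
  expect_identical(r1$image, r2$image)
  expect_equal(nrow(r1$centers), 5)
})

test_that("stronger injected effects move well profiles monotonically away from controls", {
  dirn <- rep(1 / sqrt(10), 10)  # brighten + enlarge all channels
  ctrl <- render_field(10, shape = c(96, 96), n_channels = 5,
                       treatment_effect = 0, seed = 21)
  ctrl_crops <- crop_cells(ctrl$image / 65535, ctrl$centers, 32)
  arr <- function(crops) {
    a <- array(0, dim = c(length(crops), 32, 32, 5))
    for (i in seq_along(crops)) a[i, , , ] <- crops[[i]]
    a
  }
  ctrl_prof <- colMeans(extract_baseline_features(arr(ctrl_crops)))
  d <- vapply(c(0.2, 1.0, 2.0), function(eff) {
    f <- render_field(10, shape = c(96, 96), n_channels = 5,
                      treatment_effect = eff, effect_direction = dirn,
                      seed = 22)
    prof <- colMeans(extract_baseline_features(
      arr(crop_cells(f$image / 65535, f$centers, 32))))
    sqrt(sum((prof - ctrl_prof)^2))
  }, numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("bundles round-trip through disk and the manifest enumerates every image", {
  man <- write_bundle(fixture_bundle, file.path(tempdir(), "rt"),
                      overwrite = TRUE)
  b2 <- read_bundle(file.path(tempdir(), "rt"))
  expect_equal(b2$image_index, fixture_bundle$image_index)
  expect_equal(b2$annotations, fixture_bundle$annotations)
  expect_equal(b2$locations, fixture_bundle$locations, tolerance = 1e-12)
  expect_equal(sum(man$type == "image"),
               nrow(fixture_bundle$image_index) * 5)
  # refuses to clobber without the flag
  expect_error(write_bundle(fixture_bundle, file.path(tempdir(), "rt")),
               "overwrite")
})

test_that("site images load back from TIFF exactly", {
  idx <- fixture_bundle$image_index[1, ]
  img <- load_site_image(fixture_bundle, idx$Metadata_Plate,
                         idx$Metadata_Well, idx$Metadata_Site)
  expect_equal(dim(img), c(96, 96, 5))
  expect_true(all(img == round(img)))
  expect_true(max(img) <= 65535 && min(img) >= 0)
})

test_that("randomized layouts still place controls on every plate", {
  cfg <- experiment_config(n_plates = 2, wells_per_plate = 6,
                           sites_per_well = 1, n_treatments = 2,
                           n_moa_classes = 1, image_shape = c(64, 64),
                           crop_size = 32, cells_per_site_mean = 2,
                           randomize_layout = TRUE, seed = 3)
  b <- generate_experiment(cfg, write_images = FALSE)
  for (p in unique(b$image_index$Metadata_Plate))
    expect_true(any(b$image_index$Control[b$image_index$Metadata_Plate == p]))
})
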