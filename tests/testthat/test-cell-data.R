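test_that("crops are centered, ordered and zero-padded with exact index arithmetic", {
  field <- array(1, dim = c(64, 64, 2))
  cr <- crop_cells(field, data.frame(X = 31, Y = 31), crop_size = 16)
  expect_length(cr, 1)
  expect_true(all(cr[[1]] == 1))

  # corner crop: window [-8, 8) x [-8, 8) keeps only the in-support
  # quadrant, in the bottom-right of the crop
  vals <- array(seq_len(8 * 8 * 1), dim = c(8, 8, 1))
  cc <- crop_cells(vals, data.frame(X = 0, Y = 0), crop_size = 8)[[1]]
  expected <- array(0, dim = c(8, 8, 1))
  expected[5:8, 5:8, 1] <- vals[1:4, 1:4, 1]
  expect_equal(cc, expected)
  expect_equal(sum(cc != 0), 4 * 4)

  cr3 <- crop_cells(field, data.frame(X = c(10, 20, 30), Y = c(10, 20, 30)),
                    crop_size = 8)
  expect_length(cr3, 3)
  expect_error(crop_cells(field, data.frame(X = 99, Y = 1), 8), "outside")
})

test_that("cropping is translation-consistent away from borders", {
  set.seed(1)
  base <- array(runif(64 * 64 * 2), dim = c(64, 64, 2))
  shifted <- array(0, dim = c(64, 64, 2))
  shifted[6:64, 6:64, ] <- base[1:59, 1:59, ]
  a <- crop_cells(base, data.frame(X = 30, Y = 30), 16)[[1]]
  b <- crop_cells(shifted, data.frame(X = 35, Y = 35), 16)[[1]]
  expect_equal(a, b)
})

test_that("leave-cells-out splits ~60% of each well and is seed-deterministic", {
  ci <- make_cell_index(n_plates = 1, wells_per_plate = 3,
                        cells_per_well = 10)
  sp <- split_leave_cells_out(ci, train_frac = 0.6, seed = 4)
  expect_setequal(sp$split, c("train", "val"))
  per_well <- tapply(sp$split == "train",
                     paste(ci$Metadata_Plate, ci$Metadata_Well), sum)
  expect_true(all(per_well == 6))
  sp2 <- split_leave_cells_out(ci, train_frac = 0.6, seed = 4)
  expect_identical(sp, sp2)
  all_train <- split_leave_cells_out(ci, train_frac = 1, seed = 1)
  expect_true(all(all_train$split == "train"))
  expect_error(split_leave_cells_out(ci[0, ], seed = 1), "empty")
})

test_that("leave-plates-out holds out whole plates with the required replicate wells", {
  ci <- make_cell_index(n_plates = 5, wells_per_plate = 4,
                        cells_per_well = 4, n_treatments = 3)
  sp <- split_leave_plates_out(ci, n_replicate_wells_out = 2)
  tag <- sp$split[match(ci$cell_id, sp$cell_id)]
  # plate atomicity
  per_plate <- tapply(tag, ci$Metadata_Plate,
                      function(x) length(unique(x)))
  expect_true(all(per_plate == 1))
  expect_true(all(attr(sp, "heldout_wells") == 2))
  expect_length(attr(sp, "plates_out"), 2)

  # a treatment confined to one plate makes the design infeasible
  ci2 <- ci
  ci2$Treatment[ci2$Treatment == "TRT001" &
                  ci2$Metadata_Plate != "Plate1"] <- "TRT002"
  expect_error(split_leave_plates_out(ci2, 2), "infeasible")
})

test_that("balanced epochs draw the median class size from every class", {
  ci <- make_cell_index(n_plates = 1, wells_per_plate = 3,
                        cells_per_well = 10, n_treatments = 2)
  # class sizes {10, 20, 60}
  ci <- ci[c(1:10, rep(11:20, 2), rep(21:30, 6)), ]
  ci$cell_id <- sprintf("c%05d", seq_len(nrow(ci)))
  sizes <- table(ci$Treatment)
  expect_setequal(as.integer(sizes), c(10, 20, 60))
  ids <- balanced_epoch_sample(ci, seed = 1)
  expect_length(ids, 60)
  drawn <- table(ci$Treatment[match(ids, ci$cell_id)])
  expect_true(all(drawn == 20))
  # oversampled class repeats cells; larger class subsamples without
  # replacement
  small_ids <- ids[ci$Treatment[match(ids, ci$cell_id)] ==
                     names(sizes)[sizes == 10]]
  expect_true(any(duplicated(small_ids)))
  big_ids <- ids[ci$Treatment[match(ids, ci$cell_id)] ==
                   names(sizes)[sizes == 60]]
  expect_false(any(duplicated(big_ids)))

  # equal class sizes give a permutation of all cells
  ci_eq <- make_cell_index(n_plates = 1, wells_per_plate = 3,
                           cells_per_well = 8, n_treatments = 2)
  ids_eq <- sort(balanced_epoch_sample(ci_eq, seed = 2))
  expect_identical(ids_eq, sort(ci_eq$cell_id))

  # a singleton class is oversampled to the median
  ci_one <- rbind(ci_eq, transform(ci_eq[1, ], Treatment = "TRT999",
                                   cell_id = "c99999"))
  ids_one <- balanced_epoch_sample(ci_one, seed = 3)
  expect_equal(sum(ids_one == "c99999"), 8)
})

test_that("augmentation branches behave as documented", {
  set.seed(5)
  crop <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  crop[1, 1, ] <- 0; crop[2, 2, ] <- 1   # span [0, 1] per channel
  idl <- list(do_crop = FALSE, flip = FALSE, rot = 0,
              contrast = rep(1, 3), brightness = rep(0, 3))
  expect_equal(augment_crop(crop, draws = idl), crop)

  # brightness/contrast jitter preserves within-channel pixel ranks
  # (amplitudes chosen inside [0,1] so clipping introduces no ties)
  jit <- modifyList(idl, list(contrast = c(0.9, 0.85, 0.95),
                              brightness = c(0.05, 0.02, 0.01)))
  out <- augment_crop(crop, draws = jit)
  for (cc in 1:3) {
    expect_equal(stats::cor(rank(crop[, , cc]), rank(out[, , cc])), 1)
  }
  # with clipping the map is still monotone non-decreasing
  big <- modifyList(idl, list(contrast = c(1.3, 1.3, 1.3),
                              brightness = c(0.2, 0.2, 0.2)))
  outb <- augment_crop(crop, draws = big)
  for (cc in 1:3) {
    o <- order(crop[, , cc])
    expect_true(all(diff(outb[, , cc][o]) >= -1e-12))
  }

  # crop-and-resize at scale 0.8 magnifies a centered disc by 1/0.8
  disc <- array(0, dim = c(64, 64, 1))
  d <- sqrt(outer((1:64 - 32.5)^2, (1:64 - 32.5)^2, `+`))
  disc[, , 1][d <= 10] <- 1
  zoom <- modifyList(idl, list(do_crop = TRUE, scale = 0.8,
                               ox = 0.5, oy = 0.5,
                               contrast = 1, brightness = 0))
  zoomed <- augment_crop(disc, draws = zoom)
  radius <- function(x) sqrt(sum(x > 0.5) / pi)
  expect_equal(radius(zoomed[, , 1]), radius(disc[, , 1]) / 0.8,
               tolerance = 0.1)
  expect_equal(dim(zoomed), dim(disc))

  # flips and rotations permute pixels only
  geo <- modifyList(idl, list(flip = TRUE, rot = 3))
  expect_setequal(as.vector(augment_crop(crop, draws = geo)),
                  as.vector(crop))
})

test_that("normalize_crops maps every channel to [0,1] and zeros constants", {
  crops <- array(runif(2 * 8 * 8 * 2, 5, 9), dim = c(2, 8, 8, 2))
  crops[2, , , 2] <- 3.3
  nc <- normalize_crops(crops)
  expect_equal(min(nc[1, , , 1]), 0)
  expect_equal(max(nc[1, , , 1]), 1)
  expect_true(all(nc[2, , , 2] == 0))
})

test_that("MIL bags follow the weak-label composition rules", {
  ci <- make_cell_index(n_plates = 1, wells_per_plate = 4,
                        cells_per_well = 20, n_treatments = 3)
  bags <- build_mil_bags(ci, bag_size = 16, n_bags_per_class = 5, seed = 2)
  labs <- vapply(bags, `[[`, character(1), "label")
  expect_true(all(table(labs) == 5))
  is_ctrl <- ci$Control[match(unlist(lapply(bags, `[[`, "cell_ids")),
                              ci$cell_id)]
  for (bg in bags) {
    members_ctrl <- ci$Control[match(bg$cell_ids, ci$cell_id)]
    expect_length(bg$cell_ids, 16)
    if (bg$label == "DMSO") {
      expect_true(all(members_ctrl))
      expect_equal(bg$n_treated, 0L)
    } else {
      expect_true(bg$n_treated >= 4 && bg$n_treated <= 12)
      expect_equal(sum(!members_ctrl), bg$n_treated)
      trt <- ci$Treatment[match(bg$cell_ids, ci$cell_id)]
      expect_true(all(trt[!members_ctrl] == bg$label))
    }
  }
  expect_error(build_mil_bags(ci[!ci$Control, ], seed = 1), "control")
})

test_that("the cell index applies the concentration and minimum-count filters", {
  ci <- build_cell_index(fixture_bundle, min_cells = 0)
  expect_equal(nrow(ci), nrow(fixture_bundle$locations))
  expect_true(all(c("cell_id", "Treatment", "Control") %in% names(ci)))

  # min_cells drops small treatment classes but never controls
  sizes <- table(ci$Treatment[!ci$Control])
  thr <- max(sizes)  # strictly keeps only the largest class(es)
  ci2 <- build_cell_index(fixture_bundle, min_cells = thr)
  expect_true(all(table(ci2$Treatment[!ci2$Control]) >= thr))
  expect_equal(sum(ci2$Control), sum(ci$Control))

  # concentration filter: duplicate one treatment's rows at a lower dose
  b <- fixture_bundle
  lowc <- b$image_index[!b$image_index$Control, ][1, ]
  trt <- lowc$Treatment
  b$image_index$Concentration[b$image_index$Treatment == trt &
    b$image_index$Metadata_Plate == lowc$Metadata_Plate] <- 0.1
  ci3 <- build_cell_index(b, min_cells = 0)
  kept <- unique(ci3$Concentration[ci3$Treatment == trt])
  expect_equal(kept, 1)
})
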