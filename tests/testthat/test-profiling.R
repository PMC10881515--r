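meta_row <- function(plate, well, site, trt, ctrl, n) {
  data.frame(Metadata_Plate = plate, Metadata_Well = well,
             Metadata_Site = site, Treatment = trt, Control = ctrl,
             stringsAsFactors = FALSE)[rep(1, n), ]
}

test_that("aggregation follows the median -> mean -> mean hierarchy", {
  feats <- rbind(c(0, 0), c(2, 2), c(10, 10))
  meta <- meta_row("P1", "W1", 1, "T1", FALSE, 3)
  site <- aggregate_profiles(feats, meta, level = "site")
  expect_equal(unname(profile_matrix(site)[1, ]), c(2, 2))

  feats2 <- rbind(c(0, 0), c(2, 2), c(10, 10),   # site 1 -> (2,2)
                  c(4, 4), c(4, 4))              # site 2 -> (4,4)
  meta2 <- rbind(meta, meta_row("P1", "W1", 2, "T1", FALSE, 2))
  well <- aggregate_profiles(feats2, meta2, level = "well")
  expect_equal(unname(profile_matrix(well)[1, ]), c(3, 3))

  # wells (3,3) and (5,5) of the same treatment -> treatment (4,4)
  feats3 <- rbind(feats2, c(5, 5), c(5, 5))
  meta3 <- rbind(meta2, meta_row("P2", "W1", 1, "T1", FALSE, 2))
  trt <- aggregate_profiles(feats3, meta3, level = "treatment")
  expect_equal(unname(profile_matrix(trt)[1, ]), c(4, 4))
})

test_that("aggregation is permutation-invariant and matches a brute-force oracle", {
  set.seed(10)
  n <- 60
  meta <- do.call(rbind, lapply(1:2, function(p)
    do.call(rbind, lapply(1:3, function(w)
      meta_row(sprintf("P%d", p), sprintf("W%d", w),
               sample(1:2, 1), sprintf("T%d", w %% 2 + 1), w == 3, 10)))))
  feats <- matrix(rnorm(nrow(meta) * 4), ncol = 4)
  well <- aggregate_profiles(feats, meta, level = "well")

  perm <- sample(nrow(meta))
  well_p <- aggregate_profiles(feats[perm, ], meta[perm, ], level = "well")
  ord <- order(well$Metadata_Plate, well$Metadata_Well)
  ord_p <- order(well_p$Metadata_Plate, well_p$Metadata_Well)
  expect_equal(well[ord, ], well_p[ord_p, ], ignore_attr = TRUE)

  # independent brute force: per well, mean over per-site medians
  for (r in sample(nrow(well), 3)) {
    rows <- meta$Metadata_Plate == well$Metadata_Plate[r] &
      meta$Metadata_Well == well$Metadata_Well[r]
    sites <- unique(meta$Metadata_Site[rows])
    site_meds <- sapply(sites, function(s) {
      sel <- rows & meta$Metadata_Site == s
      apply(feats[sel, , drop = FALSE], 2, stats::median)
    })
    expect_equal(unname(profile_matrix(well)[r, ]),
                 unname(rowMeans(site_meds)))
  }
})

test_that("well profiles containing NA features are removed before use", {
  feats <- rbind(c(1, 1), c(NA, 2), c(3, 3))
  meta <- rbind(meta_row("P1", "W1", 1, "T1", FALSE, 1),
                meta_row("P1", "W2", 1, "T2", FALSE, 1),
                meta_row("P1", "W3", 1, "T1", FALSE, 1))
  expect_message(well <- aggregate_profiles(feats, meta, level = "well"),
                 "NA")
  expect_equal(nrow(well), 2)
  expect_false(any(is.na(profile_matrix(well))))
})

test_that("sphering matches hand computations in one dimension", {
  ctrl <- matrix(c(-1, 1), ncol = 1)   # mu = 0, Sigma = 1
  expect_equal(fit_sphering(ctrl, lambda = 0)$Q[1, 1], 1)
  expect_equal(fit_sphering(ctrl, lambda = 3)$Q[1, 1], 0.5)
  expect_error(fit_sphering(matrix(1, 1, 1)), ">= 2")
})

test_that("an identity covariance gives an identity transform at lambda 0", {
  set.seed(11)
  Z <- matrix(rnorm(4000 * 4), ncol = 4)
  Z <- sweep(Z, 2, colMeans(Z))
  # exact whitening of the sample so Sigma is the identity by construction
  S <- crossprod(Z) / nrow(Z)
  e <- eigen(S, symmetric = TRUE)
  X <- Z %*% e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
  tr <- fit_sphering(X, lambda = 0)
  expect_equal(tr$Q, diag(4), tolerance = 1e-6)
})

test_that("whitening and regularization have the stated spectra", {
  set.seed(12)
  X <- matrix(rnorm(200 * 6), ncol = 6) %*% diag(c(5, 4, 3, 2, 1, 0.5))
  tr0 <- fit_sphering(X, lambda = 0)
  Xc <- apply_sphering(tr0, X)
  expect_equal(crossprod(sweep(Xc, 2, colMeans(Xc))) / nrow(Xc), diag(6),
               tolerance = 1e-8, ignore_attr = TRUE)

  lam <- 0.7
  trl <- fit_sphering(X, lambda = lam)
  Xl <- apply_sphering(trl, X)
  covl <- crossprod(Xl) / nrow(Xl)
  expect_equal(sort(eigen(covl, symmetric = TRUE)$values, decreasing = TRUE),
               sort(tr0$eigenvalues / (tr0$eigenvalues + lam),
                    decreasing = TRUE),
               tolerance = 1e-8)
  expect_true(all(eigen(covl)$values > 0 & eigen(covl)$values < 1))

  # lambda -> infinity collapses Q to uniform shrinkage lambda^(-1/2) I
  big <- 1e6 * max(tr0$eigenvalues)
  trb <- fit_sphering(X, lambda = big)
  expect_lt(max(abs(trb$Q - diag(6) / sqrt(big))) * sqrt(big), 1e-5)

  # Q is symmetric
  expect_lt(max(abs(trl$Q - t(trl$Q))), 1e-8)
})

test_that("singular control covariance demands regularization", {
  X <- matrix(rnorm(3 * 10), 3, 10)  # n < d
  expect_error(fit_sphering(X, lambda = 0), "lambda")
  expect_s3_class(fit_sphering(X, lambda = 1e-3), "sphering_transform")
})

test_that("applying sphering preserves metadata and checks dimensions", {
  wp <- data.frame(Metadata_Plate = "P1", Metadata_Well = c("W1", "W2"),
                   Metadata_Treatment = c("T1", "DMSO"),
                   Metadata_Control = c(FALSE, TRUE),
                   A = c(1, 2), B = c(3, 4))
  tr <- structure(list(Q = diag(2), lambda = 0, mu = c(0, 0),
                       eigenvalues = c(1, 1), n = 2, d = 2,
                       centered = TRUE), class = "sphering_transform")
  out <- apply_sphering(tr, wp)
  expect_equal(out, wp, ignore_attr = TRUE)
  expect_error(apply_sphering(tr, wp[, c(1:4, 5)]), "dims")
})

test_that("cosine similarity satisfies its contract", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1), c(2, 2)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(-1, 0)), -1)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero-norm")
})

test_that("effect scores match the five-step hand computation", {
  # 1-D well profiles on one plate: controls {-3,-1,1,3} have median 0,
  # distances {3,1,1,3} (mean 2, sd 1); a treated well at 5 has Z = 3
  wp <- data.frame(
    Metadata_Plate = "P1",
    Metadata_Well = sprintf("W%d", 1:5),
    Metadata_Treatment = c(rep("DMSO", 4), "T1"),
    Metadata_Control = c(rep(TRUE, 4), FALSE),
    F1 = c(-3, -1, 1, 3, 5))
  es <- effect_scores(wp)
  expect_equal(es$treatments$score[es$treatments$Treatment == "T1"], 3)
  expect_equal(sort(es$wells$distance[es$wells$Metadata_Control]),
               c(1, 1, 3, 3))

  # degenerate controls: all wells identical
  wp0 <- wp; wp0$F1 <- 1
  expect_error(effect_scores(wp0), "degenerate")

  # plates without enough controls are skipped with a warning
  wp2 <- rbind(wp, data.frame(Metadata_Plate = "P2", Metadata_Well = "W1",
                              Metadata_Treatment = "DMSO",
                              Metadata_Control = TRUE, F1 = 0))
  expect_warning(es2 <- effect_scores(wp2), "skipped")
  expect_equal(es2$treatments$score, es$treatments$score)
})

test_that("control Z-scores are calibrated and null treatments score near zero", {
  set.seed(13)
  n_wells <- 60
  wp <- data.frame(
    Metadata_Plate = rep(c("P1", "P2", "P3"), each = n_wells),
    Metadata_Well = rep(sprintf("W%02d", seq_len(n_wells)), 3),
    Metadata_Treatment = rep(c(rep("DMSO", 20),
                               sprintf("T%02d", 1:40)), 3),
    Metadata_Control = rep(c(rep(TRUE, 20), rep(FALSE, 40)), 3))
  X <- matrix(rnorm(nrow(wp) * 8), ncol = 8)
  colnames(X) <- sprintf("F%d", 1:8)
  wp <- cbind(wp, X)
  es <- effect_scores(wp)
  # with no injected effect, treated wells look like controls
  expect_lt(abs(mean(es$wells$z[!es$wells$Metadata_Control])), 0.3)
  # control Z-scores have mean 0 and unit spread per plate by construction
  for (p in unique(wp$Metadata_Plate)) {
    zc <- es$wells$z[es$wells$Metadata_Control &
                       es$wells$Metadata_Plate == p]
    expect_equal(mean(zc), 0, tolerance = 1e-9)
    expect_equal(sqrt(mean(zc^2)), 1, tolerance = 1e-9)
  }
})

test_that("effect bands have the published sizes and are disjoint", {
  mk <- function(N) data.frame(Treatment = sprintf("T%04d", seq_len(N)),
                               score = stats::runif(N))
  set.seed(14)
  expect_length(select_effect_band(mk(205), "weak"), 41)
  expect_length(select_effect_band(mk(995), "median"), 199)
  expect_length(select_effect_band(mk(1550), "strong"), 310)

  df <- mk(50)
  bands <- lapply(c("weak", "median", "strong"), select_effect_band,
                  scores = df)
  expect_equal(length(unique(unlist(bands))), 30)  # 3 x 10, no overlap

  # the strong band of five treatments is the single top-ranked one
  df5 <- mk(5)
  top <- df5$Treatment[which.max(df5$score)]
  expect_equal(select_effect_band(df5, "strong"), top)

  # ties are broken by treatment id for reproducibility
  dft <- data.frame(Treatment = c("B", "A", "C", "D", "E"),
                    score = c(1, 1, 2, 3, 4))
  expect_equal(select_effect_band(dft, "weak"), "A")
  expect_error(select_effect_band(df, "weak", frac = 0), "frac")
})
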