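# Profile aggregation, sphering batch correction, similarity and
# treatment-effect scoring.
#
# Profiles are plain data frames: `Metadata_*` columns carry identity,
# all remaining columns are numeric features.  Aggregation follows the
# median -> mean -> mean hierarchy: single cells are aggregated with the
# coordinatewise median per field of view (robust to segmentation and
# featurization noise among hundreds of cells), sites with the mean per
# well, and replicate wells with the mean per treatment.

.agg_by <- function(mat, keys, fun) {
  groups <- split(seq_len(nrow(mat)), keys)
  out <- t(vapply(groups, function(rows)
    apply(mat[rows, , drop = FALSE], 2, fun), numeric(ncol(mat))))
  out
}

#' Aggregate single-cell features into site/well/treatment profiles
#'
#' @param features `n x d` numeric matrix of single-cell features.
#' @param cell_meta data.frame aligned with `features` rows, with
#'   columns `Metadata_Plate`, `Metadata_Well`, `Metadata_Site`,
#'   `Treatment`, `Control`.
#' @param level `"site"`, `"well"` or `"treatment"`.
#' @param na_action well rows containing any NA feature are dropped
#'   (with a message) before well-level aggregation.
#' @return profile table data.frame at the requested level.
#' @export
aggregate_profiles <- function(features, cell_meta,
                               level = c("well", "site", "treatment"),
                               na_action = c("drop_wells", "keep")) {
  level <- match.arg(level)
  na_action <- match.arg(na_action)
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    colnames(features) <- sprintf("F%03d", seq_len(ncol(features)))
  stopifnot(nrow(features) == nrow(cell_meta))

  skey <- paste(cell_meta$Metadata_Plate, cell_meta$Metadata_Well,
                cell_meta$Metadata_Site, sep = "|")
  site_mat <- .agg_by(features, skey, stats::median)
  first <- function(keys, col) {
    i <- match(rownames(site_mat), keys); cell_meta[[col]][i]
  }
  site_meta <- data.frame(
    Metadata_Plate = first(skey, "Metadata_Plate"),
    Metadata_Well = first(skey, "Metadata_Well"),
    Metadata_Site = first(skey, "Metadata_Site"),
    Metadata_Treatment = first(skey, "Treatment"),
    Metadata_Control = first(skey, "Control"),
    stringsAsFactors = FALSE)
  if (level == "site")
    return(cbind(site_meta, as.data.frame(site_mat, row.names = FALSE)))

  wkey <- paste(site_meta$Metadata_Plate, site_meta$Metadata_Well,
                sep = "|")
  well_mat <- .agg_by(site_mat, wkey, mean)
  wi <- match(rownames(well_mat), wkey)
  well_meta <- site_meta[wi, c("Metadata_Plate", "Metadata_Well",
                               "Metadata_Treatment", "Metadata_Control")]
  rownames(well_meta) <- NULL
  if (na_action == "drop_wells") {
    bad <- rowSums(is.na(well_mat)) > 0
    if (any(bad)) {
      message(sprintf("dropping %d well profile(s) containing NA features",
                      sum(bad)))
      well_mat <- well_mat[!bad, , drop = FALSE]
      well_meta <- well_meta[!bad, , drop = FALSE]
    }
  }
  well <- cbind(well_meta, as.data.frame(well_mat, row.names = FALSE))
  if (level == "well") return(well)

  aggregate_treatments(well)
}

#' Aggregate well profiles to treatment profiles
#'
#' Mean across replicate wells of each treatment.
#'
#' @param well_profiles well-level profile table.
#' @return treatment-level profile table (one row per treatment).
#' @export
aggregate_treatments <- function(well_profiles) {
  mat <- profile_matrix(well_profiles)
  tkey <- well_profiles$Metadata_Treatment
  tr_mat <- .agg_by(mat, tkey, mean)
  ti <- match(rownames(tr_mat), tkey)
  out <- data.frame(Metadata_Treatment = rownames(tr_mat),
                    Metadata_Control = well_profiles$Metadata_Control[ti],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  cbind(out, as.data.frame(tr_mat, row.names = FALSE))
}

#' Fit the sphering (ZCA whitening) batch-correction transform
#'
#' Computed from negative-control well profiles only: controls model the
#' unwanted technical variation under the assumption that their
#' phenotype is neutral.  With the centered control matrix X (n x d),
#' the covariance is `Sigma = X'X / n`, its eigendecomposition
#' `Sigma = U D U'`, and the correction matrix
#' `Q = U (D + lambda)^(-1/2) U'`: directions of large control variance
#' are shrunk, directions of small variance amplified, with `lambda`
#' bounding the amplification.
#'
#' @param control_profiles well-level profile table (or plain matrix) of
#'   negative controls only.
#' @param lambda regularization added to every eigenvalue before the
#'   inverse square root (default `1e-3`); `lambda = 0` requires more
#'   controls than dimensions.
#' @param center subtract the control mean (default TRUE; `FALSE`
#'   reproduces the uncentered second-moment formula literally).
#' @return `sphering_transform`: list with symmetric `Q` (d x d),
#'   `lambda`, `mu`, `eigenvalues`, `n`, `d`.
#' @export
fit_sphering <- function(control_profiles, lambda = 1e-3, center = TRUE) {
  X <- if (is.data.frame(control_profiles))
    profile_matrix(control_profiles) else as.matrix(control_profiles)
  n <- nrow(X); d <- ncol(X)
  if (n < 2) stopf("sphering needs >= 2 control profiles, got %d", n)
  if (lambda < 0) stopf("lambda must be >= 0")
  mu <- if (center) colMeans(X) else rep(0, d)
  Xc <- sweep(X, 2, mu)
  Sigma <- crossprod(Xc) / n
  eig <- eigen(Sigma, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  if (lambda == 0 && min(ev) < max(ev) * 1e-10)
    stopf("control covariance is singular; use lambda > 0")
  Q <- eig$vectors %*% diag(1 / sqrt(ev + lambda), d) %*% t(eig$vectors)
  Q <- (Q + t(Q)) / 2
  structure(list(Q = Q, lambda = lambda, mu = mu, eigenvalues = ev,
                 n = n, d = d, centered = center),
            class = "sphering_transform")
}

#' Apply a sphering transform to well profiles
#'
#' Corrected profile `t' = Q (t - mu)`, applied to every well (controls
#' and treatments alike); metadata columns pass through.
#'
#' @param transform a [fit_sphering()] result.
#' @param profiles well-level profile table or matrix.
#' @return corrected profiles, same type and shape.
#' @export
apply_sphering <- function(transform, profiles) {
  is_df <- is.data.frame(profiles)
  X <- if (is_df) profile_matrix(profiles) else as.matrix(profiles)
  if (ncol(X) != transform$d)
    stopf("profiles have %d feature dims, transform expects %d",
          ncol(X), transform$d)
  Xc <- sweep(X, 2, transform$mu) %*% transform$Q
  colnames(Xc) <- colnames(X)
  if (!is_df) return(Xc)
  cbind(profiles[, meta_cols(profiles), drop = FALSE],
        as.data.frame(Xc, row.names = FALSE))
}

#' Cosine similarity of two profiles
#'
#' `A . B / (||A|| ||B||)`: symmetric, scale-invariant, in `[-1, 1]`.
#'
#' @param a,b numeric vectors.
#' @return scalar similarity.
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stopf("cosine similarity is undefined for zero-norm profiles")
  sum(a * b) / (na * nb)
}

#' Z-scored treatment-effect estimates
#'
#' Five steps per plate: (1) the median profile of the plate's control
#' wells; (2) the Euclidean distance of every well profile to it;
#' (3) mean and standard deviation of the control-well distances;
#' (4) Z-scores of the treated-well distances against those statistics;
#' (5) a treatment's effect score is the mean Z across its replicate
#' wells over all plates.  Profiles should be batch-corrected first
#' (sphering with `lambda = 1e-2` in the reference workflow).
#'
#' @param well_profiles corrected well-level profile table with
#'   `Metadata_Plate`, `Metadata_Treatment`, `Metadata_Control`.
#' @return `effect_score_table`: list with `treatments` (Treatment,
#'   score, n_wells) and the per-well audit table `wells` (plate, well,
#'   treatment, distance, z).
#' @export
effect_scores <- function(well_profiles) {
  mat <- profile_matrix(well_profiles)
  well_rows <- list()
  for (plate in unique(well_profiles$Metadata_Plate)) {
    pr <- which(well_profiles$Metadata_Plate == plate)
    ctrl <- pr[well_profiles$Metadata_Control[pr]]
    if (length(ctrl) < 2) {
      warning(sprintf("plate %s has < 2 control wells; skipped", plate))
      next
    }
    m_p <- apply(mat[ctrl, , drop = FALSE], 2, stats::median)
    dist <- sqrt(rowSums(sweep(mat[pr, , drop = FALSE], 2, m_p)^2))
    cd <- dist[match(ctrl, pr)]
    # population (n-denominator) standard deviation: the controls ARE the
    # reference distribution, not a sample from a larger one
    mu <- mean(cd); sdev <- sqrt(mean((cd - mu)^2))
    if (sdev == 0) stopf("degenerate controls on plate %s (zero distance spread)", plate)
    well_rows[[length(well_rows) + 1]] <- data.frame(
      Metadata_Plate = plate,
      Metadata_Well = well_profiles$Metadata_Well[pr],
      Metadata_Treatment = well_profiles$Metadata_Treatment[pr],
      Metadata_Control = well_profiles$Metadata_Control[pr],
      distance = dist, z = (dist - mu) / sdev,
      stringsAsFactors = FALSE)
  }
  if (length(well_rows) == 0) stopf("no plate had >= 2 control wells")
  wells <- do.call(rbind, well_rows)
  tw <- wells[!wells$Metadata_Control, , drop = FALSE]
  sc <- tapply(tw$z, tw$Metadata_Treatment, mean)
  treatments <- data.frame(Treatment = names(sc), score = as.numeric(sc),
                           n_wells = as.integer(table(tw$Metadata_Treatment)[names(sc)]),
                           stringsAsFactors = FALSE)
  rownames(treatments) <- NULL
  structure(list(treatments = treatments, wells = wells),
            class = "effect_score_table")
}

#' Select an effect-strength band of treatments
#'
#' Treatments are ranked in ascending order of effect score (ties broken
#' by treatment id) and a fraction `frac` is taken from the bottom
#' (weak), the middle (median) or the top (strong) of the distribution.
#'
#' @param scores an `effect_score_table`, or a data.frame with
#'   `Treatment` and `score` columns.
#' @param band `"weak"`, `"median"` or `"strong"`.
#' @param frac band width as a fraction of all treatments (default 0.2;
#'   `k = round(frac * N)` treatments are selected).
#' @return character vector of treatment ids, in rank order.
#' @export
select_effect_band <- function(scores, band = c("weak", "median", "strong"),
                               frac = 0.2) {
  band <- match.arg(band)
  if (frac <= 0 || frac > 1) stopf("frac must be in (0, 1]")
  df <- if (inherits(scores, "effect_score_table")) scores$treatments
        else scores
  N <- nrow(df)
  if (N < ceiling(1 / frac)) stopf("need >= %d treatments for frac = %g",
                                   ceiling(1 / frac), frac)
  ord <- order(df$score, df$Treatment)
  k <- round(frac * N)
  idx <- switch(band,
    weak = seq_len(k),
    strong = seq(N - k + 1, N),
    median = {
      start <- floor((N - k) / 2) + 1
      seq(start, start + k - 1)
    })
  df$Treatment[ord[idx]]
}
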