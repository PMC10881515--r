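# Retrieval-based biological evaluation: leave-one-treatment-out queries
# against an annotated library, scored with interpolated mean average
# precision and Fisher folds of enrichment, plus the sphering
# regularization scan and a plate-silhouette diagnostic.

#' Build ranked leave-one-treatment-out queries
#'
#' A treatment is an eligible query when it shares an annotation class
#' (MoA / pathway) with at least one other annotated treatment in the
#' profile table, so that a match is possible.  Its library is every
#' other annotated treatment, ranked by cosine similarity (descending,
#' ties broken by treatment id); a library entry is a positive hit when
#' it shares at least one annotation with the query.
#'
#' @param treatment_profiles treatment-level profile table.
#' @param annotations data.frame `Treatment`, `MoA` (several rows allowed
#'   per treatment for multi-annotation).
#' @return list of `ranked_query` objects: `list(query=, library=)`
#'   where `library` is a data.frame (Treatment, similarity, positive)
#'   in rank order, plus `n_positives`.
#' @export
build_queries <- function(treatment_profiles, annotations) {
  ann <- annotations[annotations$Treatment %in%
                       treatment_profiles$Metadata_Treatment, , drop = FALSE]
  if (nrow(ann) == 0) stopf("no annotated treatments present in profiles")
  moas <- split(as.character(ann$MoA), ann$Treatment)
  trts <- names(moas)
  mat <- profile_matrix(treatment_profiles)
  rownames(mat) <- treatment_profiles$Metadata_Treatment
  share <- function(a, b) length(intersect(moas[[a]], moas[[b]])) > 0
  queries <- list()
  for (q in trts) {
    lib <- setdiff(trts, q)
    pos <- vapply(lib, share, logical(1), a = q)
    if (!any(pos)) next   # no class-mate in the library: ineligible
    sims <- vapply(lib, function(t)
      cosine_similarity(mat[q, ], mat[t, ]), numeric(1))
    ord <- order(-sims, lib)
    res <- structure(list(query = q,
                          library = data.frame(Treatment = lib[ord],
                                               similarity = sims[ord],
                                               positive = pos[ord],
                                               stringsAsFactors = FALSE),
                          n_positives = sum(pos)),
                     class = "ranked_query")
    queries[[length(queries) + 1]] <- res
  }
  if (length(queries) == 0)
    stopf("no eligible queries: no annotation class has >= 2 treatments")
  queries
}

#' Interpolated average precision of one ranked query
#'
#' Walking the ranked list, precision `TP/(TP+FP)` and recall
#' `TP/(TP+FN)` are computed at every item; the interpolated precision
#' at recall r is `p_inter(r) = max_{r' >= r} p(r')`, and the average
#' precision is the mean of `p_inter` over the recall grid
#' `{j/K : j = 1..K}`.  By default K is the query's own number of
#' positives; [mean_average_precision()] passes the shared dataset-wide
#' grid.
#'
#' @param result a `ranked_query`.
#' @param grid_k number of recall points (default `n_positives`).
#' @return scalar average precision in `[0, 1]`.
#' @export
average_precision <- function(result, grid_k = NULL) {
  pos <- result$library$positive
  P <- sum(pos)
  if (P == 0) stopf("query '%s' has no positives (ineligible)", result$query)
  tp <- cumsum(pos)
  prec <- tp / seq_along(pos)
  rec <- tp / P
  K <- grid_k %||% P
  grid <- seq_len(K) / K
  p_inter <- vapply(grid, function(r) {
    ok <- rec >= r - 1e-12
    if (any(ok)) max(prec[ok]) else 0
  }, numeric(1))
  mean(p_inter)
}

#' Mean average precision over all queries
#'
#' Every query's precision-recall curve is interpolated onto the shared
#' recall grid with `K = max` number of positives over queries (the
#' maximum number of recall points possible in the dataset), then
#' averaged per query and across queries.
#'
#' @param results list of `ranked_query` objects.
#' @return scalar mAP.
#' @export
mean_average_precision <- function(results) {
  if (length(results) == 0) stopf("no queries")
  K <- max(vapply(results, `[[`, numeric(1), "n_positives"))
  mean(vapply(results, average_precision, numeric(1), grid_k = K))
}

#' Folds of enrichment of positive hits in the top of the ranked lists
#'
#' Per query the ranked list is cut at the top `top_frac` fraction
#' (`k = max(1, ceiling(top_frac * L))`) and a 2 x 2 contingency table is
#' formed: positives/negatives above the cut (a, b) and below it (c, d).
#' The cross-product odds ratio `(a d) / (b c)` is computed with the
#' Haldane correction (+0.5 to every cell when any cell is zero) and
#' averaged over queries; one-sided Fisher's exact test p-values are
#' recorded alongside for audit.  `literal = TRUE` reports the
#' row-sum-ratio reading `(a + b) / (c + d)` instead (ranking-
#' independent; retained for reference only).
#'
#' @param results list of `ranked_query` objects.
#' @param top_frac top fraction of connections (default 0.01).
#' @param literal use the row-sum-ratio variant.
#' @return list with `mean_odds_ratio`, `per_query` data.frame (query,
#'   odds_ratio, p_value, a, b, c, d, k) and `top_frac`.
#' @export
folds_of_enrichment <- function(results, top_frac = 0.01, literal = FALSE) {
  if (length(results) == 0) stopf("no queries")
  rows <- lapply(results, function(res) {
    pos <- res$library$positive
    L <- length(pos)
    if (L < 2) stopf("library of query '%s' has < 2 items", res$query)
    k <- max(1L, ceiling(top_frac * L))
    a <- sum(pos[seq_len(k)]); b <- k - a
    c_ <- sum(pos) - a; d <- L - k - c_
    or <- if (literal) {
      (a + b) / max(c_ + d, 1)
    } else if (min(a, b, c_, d) == 0) {
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
    } else {
      (a * d) / (b * c_)
    }
    p <- stats::fisher.test(matrix(c(a, c_, b, d), 2, 2),
                            alternative = "greater")$p.value
    data.frame(query = res$query, odds_ratio = or, p_value = p,
               a = a, b = b, c = c_, d = d, k = k,
               stringsAsFactors = FALSE)
  })
  per_query <- do.call(rbind, rows)
  list(mean_odds_ratio = mean(per_query$odds_ratio),
       per_query = per_query, top_frac = top_frac)
}

#' Run the full matching evaluation on treatment profiles
#'
#' @param treatment_profiles treatment-level profile table.
#' @param annotations annotation table.
#' @param top_frac folds-of-enrichment threshold.
#' @return `metrics_report`: list with `map`, `folds_of_enrichment`,
#'   `n_queries`, `per_query` (AP and odds ratio per query).
#' @export
evaluate_matching <- function(treatment_profiles, annotations,
                              top_frac = 0.01) {
  queries <- build_queries(treatment_profiles, annotations)
  K <- max(vapply(queries, `[[`, numeric(1), "n_positives"))
  ap <- vapply(queries, average_precision, numeric(1), grid_k = K)
  foe <- folds_of_enrichment(queries, top_frac = top_frac)
  per_query <- data.frame(query = vapply(queries, `[[`, character(1),
                                         "query"),
                          average_precision = ap,
                          odds_ratio = foe$per_query$odds_ratio,
                          stringsAsFactors = FALSE)
  structure(list(map = mean(ap),
                 folds_of_enrichment = foe$mean_odds_ratio,
                 n_queries = length(queries), top_frac = top_frac,
                 per_query = per_query),
            class = "metrics_report")
}

#' Sphering regularization scan
#'
#' Recomputes the matching metrics for a list of regularization values,
#' with an uncorrected baseline as the leftmost point: for each lambda
#' the transform is fitted on control wells, applied to all wells,
#' aggregated to treatment level and evaluated.
#'
#' @param well_profiles well-level profile table (with controls).
#' @param annotations annotation table.
#' @param lambdas numeric vector of regularization values.
#' @param top_frac folds-of-enrichment threshold.
#' @return data.frame with one row per point (`lambda = NA` for the
#'   uncorrected baseline): lambda, map, folds_of_enrichment, n_queries.
#' @export
regularization_scan <- function(well_profiles, annotations, lambdas,
                                top_frac = 0.01) {
  if (length(lambdas) < 1) stopf("need >= 1 lambda value")
  eval_one <- function(wp, lam) {
    rep <- evaluate_matching(
      aggregate_treatments(wp[!wp$Metadata_Control, , drop = FALSE]),
      annotations, top_frac)
    data.frame(lambda = lam, map = rep$map,
               folds_of_enrichment = rep$folds_of_enrichment,
               n_queries = rep$n_queries)
  }
  rows <- list(eval_one(well_profiles, NA_real_))
  ctrl <- well_profiles[well_profiles$Metadata_Control, , drop = FALSE]
  for (lam in lambdas) {
    tr <- tryCatch(fit_sphering(ctrl, lambda = lam),
                   error = function(e)
                     stopf("lambda = %g: %s", lam, conditionMessage(e)))
    rows[[length(rows) + 1]] <-
      eval_one(apply_sphering(tr, well_profiles), lam)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean silhouette width of well profiles grouped by plate
#'
#' A diagnostic for plate-level batch effects: high values mean wells
#' cluster by plate in feature space; effective batch correction lowers
#' it.
#'
#' @param well_profiles well-level profile table.
#' @return mean silhouette width (requires >= 2 plates).
#' @export
plate_silhouette <- function(well_profiles) {
  plates <- factor(well_profiles$Metadata_Plate)
  if (nlevels(plates) < 2) stopf("plate silhouette needs >= 2 plates")
  sil <- cluster::silhouette(as.integer(plates),
                             stats::dist(profile_matrix(well_profiles)))
  mean(sil[, "sil_width"])
}
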