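# Independent brute-force oracles used to cross-check the retrieval
# metrics and the aggregation pipeline.  These are written directly from
# the definitions and share no code with the implementation.

# Average precision from a logical positives-in-rank-order vector:
# precision/recall at every rank, interpolated precision
# p_inter(r) = max over ranks with recall >= r of precision, averaged
# over the recall grid {j/K}.
oracle_ap <- function(pos, K = sum(pos)) {
  stopifnot(sum(pos) > 0)
  P <- sum(pos)
  prec <- numeric(length(pos)); rec <- numeric(length(pos))
  tp <- 0
  for (i in seq_along(pos)) {
    if (pos[i]) tp <- tp + 1
    prec[i] <- tp / i
    rec[i] <- tp / P
  }
  vals <- numeric(K)
  for (j in seq_len(K)) {
    r <- j / K
    best <- 0
    for (i in seq_along(pos)) {
      if (rec[i] >= r - 1e-12 && prec[i] > best) best <- prec[i]
    }
    vals[j] <- best
  }
  mean(vals)
}

# Wrap a positives vector as a ranked_query (similarities descending).
make_query <- function(pos, id = "Q") {
  L <- length(pos)
  structure(list(query = id,
                 library = data.frame(
                   Treatment = sprintf("T%03d", seq_len(L)),
                   similarity = seq(1, 0, length.out = L),
                   positive = as.logical(pos),
                   stringsAsFactors = FALSE),
                 n_positives = sum(pos)),
            class = "ranked_query")
}

# Minimal in-memory cell index for split/sampling tests.
make_cell_index <- function(n_plates = 2, wells_per_plate = 4,
                            cells_per_well = 10, n_treatments = 2,
                            control_label = "DMSO") {
  rows <- list()
  trts <- c(rep(sprintf("TRT%03d", seq_len(n_treatments)),
                length.out = max(wells_per_plate - 1, n_treatments)),
            control_label)[seq_len(wells_per_plate)]
  for (p in seq_len(n_plates)) {
    for (w in seq_len(wells_per_plate)) {
      rows[[length(rows) + 1]] <- data.frame(
        Metadata_Plate = sprintf("Plate%d", p),
        Metadata_Well = sprintf("W%02d", w),
        Metadata_Site = 1L,
        X = 0, Y = 0,
        Treatment = trts[w],
        Control = trts[w] == control_label,
        Concentration = 1,
        stringsAsFactors = FALSE)[rep(1, cells_per_well), ]
    }
  }
  ci <- do.call(rbind, rows)
  rownames(ci) <- NULL
  ci$cell_id <- sprintf("c%05d", seq_len(nrow(ci)))
  ci
}
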