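#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed and string labels
#'
#' Used to give every rendered field of view its own RNG stream so that
#' rendering is order-independent: the stream depends only on the master
#' seed and the (plate, well, site) identity, never on how many images
#' were rendered before.
#'
#' @param seed master integer seed.
#' @param ... character labels hashed into the stream (e.g. plate, well, site).
#' @return An integer seed in [0, 2^31 - 2].
#' @export
derive_seed <- function(seed, ...) {
  labels <- paste(c(...), collapse = "/")
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(labels)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# metadata / feature column helpers for profile tables
meta_cols <- function(df) grep("^Metadata_", names(df), value = TRUE)

feature_cols <- function(df) setdiff(names(df), meta_cols(df))

#' Extract the numeric feature matrix of a profile table
#'
#' Profile tables are data frames whose `Metadata_*` columns carry
#' identity (plate, well, treatment, control status) and whose remaining
#' columns are numeric features.
#'
#' @param profiles a profile table.
#' @return numeric matrix (rows = profiles).
#' @export
profile_matrix <- function(profiles) {
  as.matrix(profiles[, feature_cols(profiles), drop = FALSE])
}
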