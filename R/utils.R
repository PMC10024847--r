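#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers do not disturb the
#' caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a master seed
#'
#' Counter scheme: child = (master * 48271 + index * 1000003 + stream * 7919)
#' mod (2^31 - 1), so cohorts are extensible (adding patients never reshuffles
#' earlier ones) and independent stages draw from distinct streams.
#'
#' @param master Master integer seed.
#' @param index Case / iteration counter (0-based or 1-based, caller's choice).
#' @param stream Stage discriminator (0 = volumes, 1 = labels, 2 = splits, ...).
#' @return An integer in [1, 2^31 - 2].
#' @export
derive_seed <- function(master, index, stream = 0L) {
  m <- 2147483647
  x <- (as.numeric(master) %% m) * 48271 + as.numeric(index) * 1000003 +
    as.numeric(stream) * 7919
  as.integer(x %% m) + 1L
}

# stratified index sample: draws round(frac * n_g) per label group (at least 1
# per group present) without replacement; returns sorted indices
stratified_sample <- function(labels, frac) {
  idx <- integer(0)
  for (g in unique(labels)) {
    pool <- which(labels == g)
    k <- max(1L, round(frac * length(pool)))
    idx <- c(idx, if (length(pool) == 1L) pool else sample(pool, k))
  }
  sort(idx)
}

# stratified k-fold assignment: returns integer fold id per observation,
# each class spread as evenly as possible across folds
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (g in unique(labels)) {
    pool <- which(labels == g)
    pool <- if (length(pool) > 1L) sample(pool) else pool
    fold[pool] <- rep_len(seq_len(k), length(pool))
  }
  fold
}

`%||%` <- function(a, b) if (is.null(a)) b else a
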