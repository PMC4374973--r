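# Internal helpers.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation (kept below 2^31).
derive_seed <- function(seed, salt) {
  (as.double(seed) * 48271 + salt * 9973) %% 2147483587 + 1
}

onehot <- function(i, n) {
  v <- numeric(n)
  if (length(i) && !is.na(i) && i >= 1) v[i] <- 1
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map between flat response-unit ids and (dimension, feature) pairs
#'
#' Stimulus input and Response layers share a dimensions-by-features layout;
#' unit `id` codes dimension `d` and feature level `f` as
#' `id = (d - 1) * n_features + f`.
#'
#' @param dimension,feature 1-based dimension and feature-level indices.
#' @param id flat 1-based unit id.
#' @param n_features feature levels per dimension (default 4).
#' @return `feature_id()` returns the flat id; `feature_dim()` and
#'   `feature_level()` recover the dimension and feature level.
#' @examples
#' feature_id(2, 3)      # 7
#' feature_dim(7)        # 2
#' feature_level(7)      # 3
#' @export
feature_id <- function(dimension, feature, n_features = 4) {
  (dimension - 1L) * n_features + feature
}

#' @rdname feature_id
#' @export
feature_dim <- function(id, n_features = 4) {
  ((id - 1L) %/% n_features) + 1L
}

#' @rdname feature_id
#' @export
feature_level <- function(id, n_features = 4) {
  ((id - 1L) %% n_features) + 1L
}
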